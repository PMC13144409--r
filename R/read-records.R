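#' Aligned read record
#'
#' Container for one aligned read with base-level reference comparison:
#' the genomic coordinate, reference base, read base and Phred quality of
#' every aligned (match or mismatch) position. Insertions consume no
#' reference coordinate and deleted reference bases are not represented, so
#' only substitutions can ever yield conversion events.
#'
#' @param read_id read name (scalar character).
#' @param chrom reference sequence name.
#' @param ref_pos integer vector of 0-based genomic coordinates covered by
#'   aligned bases, strictly increasing.
#' @param ref character vector of reference bases (`A/C/G/T/N`), one per
#'   coordinate.
#' @param alt character vector of read bases, one per coordinate.
#' @param qual integer vector of Phred qualities, one per coordinate.
#' @param gene_id gene the read is assigned to, or `NA`.
#' @param strand genome strand of that gene (`"+"` or `"-"`), or `NA`.
#' @param cell_barcode,umi single-cell tags, or `NA` for bulk data.
#'
#' @return An object of class `slam_read`.
#' @examples
#' r <- slam_read("r1", "chr1", 0:3, c("T","T","G","A"), c("T","C","G","G"),
#'                rep(30L, 4), gene_id = "g1", strand = "+")
#' extract_mismatches(r)
#' @export
slam_read <- function(read_id, chrom, ref_pos, ref, alt, qual,
                      gene_id = NA_character_, strand = NA_character_,
                      cell_barcode = NA_character_, umi = NA_character_) {
  n <- length(ref_pos)
  if (length(ref) != n || length(alt) != n || length(qual) != n) {
    stopf("malformed read '%s': ref_pos/ref/alt/qual lengths differ (%d/%d/%d/%d)",
          read_id, n, length(ref), length(alt), length(qual))
  }
  if (n > 1L && any(diff(ref_pos) <= 0L)) {
    stopf("malformed read '%s': coordinates not strictly increasing", read_id)
  }
  bad <- !(ref %in% c(DNA_BASES, "N")) | !(alt %in% c(DNA_BASES, "N"))
  if (any(bad)) {
    stopf("malformed read '%s': non-ACGTN base at offset %d", read_id,
          which(bad)[1L])
  }
  if (!is.na(strand) && !strand %in% c("+", "-")) {
    stopf("read '%s': strand must be '+', '-' or NA", read_id)
  }
  structure(
    list(read_id = as.character(read_id), chrom = as.character(chrom),
         ref_pos = as.integer(ref_pos), ref = ref, alt = alt,
         qual = as.integer(qual), gene_id = as.character(gene_id),
         strand = as.character(strand),
         cell_barcode = as.character(cell_barcode), umi = as.character(umi)),
    class = "slam_read")
}

#' @export
print.slam_read <- function(x, ...) {
  mm <- sum(x$ref != x$alt & x$ref %in% DNA_BASES & x$alt %in% DNA_BASES)
  cat(sprintf("<slam_read %s> %s:%d-%d gene=%s strand=%s  %d bases, %d mismatches\n",
              x$read_id, x$chrom, min(x$ref_pos), max(x$ref_pos) + 1L,
              x$gene_id, x$strand, length(x$ref_pos), mm))
  invisible(x)
}

#' Extract substitution events from an aligned read
#'
#' Returns every aligned position where the read base differs from the
#' reference base and both are unambiguous (`A/C/G/T`). Positions where
#' either base is `N` never yield an event.
#'
#' @param read a [slam_read()].
#' @return A data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `qual`; zero rows when the read matches the reference.
#' @export
extract_mismatches <- function(read) {
  if (!inherits(read, "slam_read")) stopf("expected a slam_read")
  keep <- read$ref != read$alt & read$ref %in% DNA_BASES & read$alt %in% DNA_BASES
  data.frame(chrom = rep(read$chrom, sum(keep)),
             pos = read$ref_pos[keep],
             ref = read$ref[keep],
             alt = read$alt[keep],
             qual = read$qual[keep],
             stringsAsFactors = FALSE)
}
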
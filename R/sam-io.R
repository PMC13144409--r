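# --- MD tag construction and parsing -----------------------------------

# MD string for a gapless alignment: run-lengths of matches interleaved
# with the reference base at each mismatch
md_string <- function(ref, alt) {
  mm <- which(ref != alt)
  if (length(mm) == 0L) return(as.character(length(ref)))
  parts <- character(0)
  prev <- 0L
  for (i in mm) {
    parts <- c(parts, as.character(i - prev - 1L), ref[i])
    prev <- i
  }
  paste0(paste(parts, collapse = ""), length(ref) - prev)
}

# tokenize a CIGAR string into (len, op) pairs
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) stopf("unparsable CIGAR '%s'", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

# aligned (query offset, 0-based ref position) pairs for one record
cigar_aligned_pairs <- function(cigar, pos0) {
  ops <- parse_cigar(cigar)
  qoff <- integer(0); rpos <- integer(0)
  q <- 0L; r <- pos0
  for (i in seq_along(ops$op)) {
    len <- ops$len[i]
    switch(ops$op[i],
      "M" = , "=" = , "X" = {
        qoff <- c(qoff, q + seq_len(len))
        rpos <- c(rpos, r + seq_len(len) - 1L)
        q <- q + len; r <- r + len
      },
      "I" = , "S" = { q <- q + len },
      "D" = , "N" = { r <- r + len },
      "H" = , "P" = NULL)
  }
  list(qoff = qoff, rpos = rpos)
}

# reconstruct reference bases over the aligned positions from the MD tag.
# read_bases: read base per aligned position (deletions not represented).
md_ref_bases <- function(md, read_bases, read_id = "?") {
  ref <- read_bases
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
  i <- 0L
  for (tok in toks) {
    if (grepl("^\\d+$", tok)) {
      i <- i + as.integer(tok)
    } else if (startsWith(tok, "^")) {
      # deleted reference bases: consume nothing in the aligned arrays
    } else {
      i <- i + 1L
      if (i > length(ref)) {
        stopf("read '%s': MD tag '%s' overruns the alignment", read_id, md)
      }
      ref[i] <- toupper(tok)
    }
  }
  if (i != length(ref)) {
    stopf("read '%s': MD tag '%s' does not span the alignment (%d of %d)",
          read_id, md, i, length(ref))
  }
  ref
}

# --- SAM writing (synthetic reads) --------------------------------------

#' Write aligned reads as a SAM file
#'
#' Plain-text SAM writer for synthetic read sets: gapless alignments with
#' an MD tag encoding the reference mismatches, plus `GX` (gene), `CB`
#' (cell barcode / sample) and `UB` (UMI) tags where present.
#'
#' @param reads list of [slam_read()] with contiguous coordinates.
#' @param path output file (`.sam`).
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_lengths) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  recs <- vapply(reads, function(r) {
    n <- length(r$ref_pos)
    if (n > 1L && any(diff(r$ref_pos) != 1L)) {
      stopf("read '%s': write_sam requires contiguous alignments", r$read_id)
    }
    nm <- sum(r$ref != r$alt)
    tags <- c(sprintf("NM:i:%d", nm), sprintf("MD:Z:%s", md_string(r$ref, r$alt)))
    if (!is.na(r$gene_id)) tags <- c(tags, sprintf("GX:Z:%s", r$gene_id))
    if (!is.na(r$cell_barcode)) tags <- c(tags, sprintf("CB:Z:%s", r$cell_barcode))
    if (!is.na(r$umi)) tags <- c(tags, sprintf("UB:Z:%s", r$umi))
    paste(c(r$read_id, "0", r$chrom, as.character(r$ref_pos[1L] + 1L), "255",
            sprintf("%dM", n), "*", "0", "0",
            paste(r$alt, collapse = ""),
            intToUtf8(r$qual + 33L),
            tags), collapse = "\t")
  }, "")
  writeLines(c(header, recs), path)
  invisible(path)
}

# --- SAM/BAM ingest -----------------------------------------------------

#' Read aligned reads into read records
#'
#' Ingests a SAM or BAM file through Rsamtools and reconstructs, for every
#' mapped record, the per-base reference comparison from the CIGAR and MD
#' tag (or from a supplied reference FASTA when MD tags are absent).
#' Coordinates are converted from SAM's 1-based convention to the 0-based
#' half-open convention used throughout.
#'
#' @param path SAM or BAM file.
#' @param gene_annot optional data.frame with `gene_id` and `strand` used
#'   to attach the gene strand to each read.
#' @param tags names of the cell barcode / UMI / gene tags (defaults
#'   CB/UB/GX).
#' @param reference optional FASTA path used when records carry no MD tag
#'   (requires the Biostrings package).
#' @return list of [slam_read()]. Skipped records (unmapped, or
#'   irrecoverable mismatch information) are reported via `message()`.
#' @export
read_alignments <- function(path, gene_annot = NULL,
                            tags = c(cb = "CB", umi = "UB", gene = "GX"),
                            reference = NULL) {
  if (!file.exists(path)) stopf("alignment file '%s' not found", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq", "qual"),
    tag = unique(c("MD", unname(tags))))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  ref_seqs <- NULL
  if (!is.null(reference)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stopf("reading a reference FASTA requires the Biostrings package")
    }
    ref_seqs <- Biostrings::readDNAStringSet(reference)
    names(ref_seqs) <- sub("\\s.*$", "", names(ref_seqs))
  }
  strand_of <- if (!is.null(gene_annot)) {
    setNames(gene_annot$strand, gene_annot$gene_id)
  } else character()

  get_tag <- function(name) {
    v <- x$tag[[name]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  md <- get_tag("MD")
  cb <- get_tag(tags[["cb"]]); ub <- get_tag(tags[["umi"]])
  gx <- get_tag(tags[["gene"]])

  out <- vector("list", n)
  n_skipped <- 0L; n_nogene <- 0L
  for (i in seq_len(n)) {
    if (is.na(x$pos[i]) || is.na(x$cigar[i])) { n_skipped <- n_skipped + 1L; next }
    pairs <- cigar_aligned_pairs(x$cigar[i], x$pos[i] - 1L)
    if (length(pairs$qoff) == 0L) { n_skipped <- n_skipped + 1L; next }
    seq_chars <- strsplit(as.character(x$seq[i]), "")[[1L]]
    qual_int <- as.integer(charToRaw(as.character(x$qual[i]))) - 33L
    alt <- seq_chars[pairs$qoff]
    qual <- qual_int[pairs$qoff]
    chrom <- as.character(x$rname[i])
    ref <- if (!is.na(md[i])) {
      md_ref_bases(md[i], alt, x$qname[i])
    } else if (!is.null(ref_seqs)) {
      strsplit(as.character(ref_seqs[[chrom]][pairs$rpos + 1L]), "")[[1L]]
    } else {
      stopf(paste("record '%s' has no MD tag and no reference FASTA was",
                  "given; re-run alignment with MD tags (samtools calmd)",
                  "or pass `reference=`"), x$qname[i])
    }
    gene <- gx[i]
    if (is.na(gene)) n_nogene <- n_nogene + 1L
    strand <- if (!is.na(gene) && gene %in% names(strand_of)) {
      strand_of[[gene]]
    } else NA_character_
    out[[i]] <- slam_read(x$qname[i], chrom, pairs$rpos, ref, alt, qual,
                          gene_id = gene, strand = strand,
                          cell_barcode = cb[i], umi = ub[i])
  }
  out <- out[!vapply(out, is.null, NA)]
  if (n_skipped > 0L) message(n_skipped, " unmapped/unparsable records skipped")
  if (n_nogene > 0L) message(n_nogene, " records without a gene tag")
  out
}

# --- tabular / matrix / BED writers -------------------------------------

version_comment <- function(config = NULL) {
  h <- if (is.null(config)) "none" else config_hash(config)
  sprintf("# slamclock %s config=%s",
          as.character(utils::packageVersion("slamclock")), h)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row and a leading comment line carrying the
#' tool version and configuration hash.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config optional [pipeline_config()] echoed as a hash.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(version_comment(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path file path.
#' @return data.frame (comment lines ignored).
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write an SNV blacklist as BED
#'
#' 0-based half-open intervals of width one; low-coverage positions are
#' written with the name `low_coverage`, masked SNVs with `snv`.
#'
#' @param blacklist an [snv_blacklist()].
#' @param path output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_blacklist_bed <- function(blacklist, path) {
  split_keys <- function(keys, label) {
    if (length(keys) == 0L) return(NULL)
    sp <- strsplit(keys, ":", fixed = TRUE)
    data.frame(chrom = vapply(sp, `[`, "", 1L),
               start = as.integer(vapply(sp, `[`, "", 2L)),
               name = label, stringsAsFactors = FALSE)
  }
  df <- rbind(split_keys(blacklist$positions, "snv"),
              split_keys(blacklist$low_coverage_positions, "low_coverage"))
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    name = character())
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$start + 1L, df$name)
  writeLines(lines, path)
  invisible(path)
}

#' Read an SNV blacklist from BED
#' @param path `.bed` path written by [write_blacklist_bed()].
#' @return an [snv_blacklist()].
#' @export
read_blacklist_bed <- function(path) {
  if (file.size(path) == 0L) return(snv_blacklist())
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name"))
  keys <- pos_key(df$chrom, df$start)
  snv_blacklist(positions = keys[df$name == "snv"],
                low_coverage_positions = keys[df$name == "low_coverage"])
}

#' Write labeled/unlabeled matrices as a Matrix Market pair
#'
#' Emits `labeled.mtx` and `unlabeled.mtx` with shared `features.tsv` and
#' `barcodes.tsv`, the conventional sparse single-cell exchange layout.
#'
#' @param m a [labeled_matrices()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_labeled_matrices <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$labeled, file.path(dir, "labeled.mtx"))
  Matrix::writeMM(m$unlabeled, file.path(dir, "unlabeled.mtx"))
  writeLines(rownames(m$labeled), file.path(dir, "features.tsv"))
  writeLines(colnames(m$labeled), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a labeled/unlabeled Matrix Market pair
#' @param dir directory written by [write_labeled_matrices()].
#' @return a [labeled_matrices()].
#' @export
read_labeled_matrices <- function(dir) {
  rd <- function(name) {
    m <- as(Matrix::readMM(file.path(dir, name)), "CsparseMatrix")
    dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                        readLines(file.path(dir, "barcodes.tsv")))
    m
  }
  labeled_matrices(rd("labeled.mtx"), rd("unlabeled.mtx"))
}

#' Read gene sets (GMT or two-column TSV)
#'
#' @param path `.gmt` file (set name, description, genes...) or a TSV with
#'   columns set name and gene.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, "", 1L)
    return(sets)
  }
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("set", "gene"))
  lapply(split(df$gene, df$set), unique)
}

# write the full bulk simulation bundle to a directory
write_bulk_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- setNames(sim$genome$chrom_len, sim$genome$chrom)
  for (s in sim$samples) {
    write_sam(s$reads, file.path(dir, paste0(s$sample_id, ".sam")), lens)
  }
  write_tsv_table(sim$genes, file.path(dir, "genes.tsv"))
  write_tsv_table(sim$truth_counts, file.path(dir, "truth_counts.tsv"))
  cfg <- sim$config
  cfg$fourSU_halflife <- cfg$fourSU_halflife %||% "off"
  yaml::write_yaml(c(unclass(cfg), list(seed = sim$seed)),
                   file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
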
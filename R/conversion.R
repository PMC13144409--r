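#' SNV blacklist
#'
#' Set of genomic positions whose apparent conversion fraction indicates a
#' genetic variant rather than metabolic labeling, plus the set of positions
#' with too little coverage to classify.
#'
#' @param positions character vector of `"chrom:pos"` keys (0-based) to mask.
#' @param low_coverage_positions keys with coverage below the calling
#'   threshold; disjoint from `positions`.
#' @return An object of class `snv_blacklist`.
#' @export
snv_blacklist <- function(positions = character(),
                          low_coverage_positions = character()) {
  positions <- unique(as.character(positions))
  low_coverage_positions <- unique(as.character(low_coverage_positions))
  if (length(intersect(positions, low_coverage_positions)) > 0L) {
    stopf("blacklist and low-coverage sets must be disjoint")
  }
  structure(list(positions = positions,
                 low_coverage_positions = low_coverage_positions),
            class = "snv_blacklist")
}

#' @export
print.snv_blacklist <- function(x, ...) {
  cat(sprintf("<snv_blacklist> %d masked, %d low-coverage positions\n",
              length(x$positions), length(x$low_coverage_positions)))
  invisible(x)
}

# transcript-sense T positions of a read in genomic coordinates:
# reference T for plus-strand genes, reference A for minus-strand genes
t_sense_bases <- function(strand) {
  if (strand == "+") c(ref = "T", conv = "C") else c(ref = "A", conv = "G")
}

#' Count transcript-sense T-to-C conversions in one read
#'
#' For a plus-strand gene, counts genomic T positions and T-to-C
#' substitutions; for a minus-strand gene, genomic A positions and A-to-G
#' substitutions (T-to-C in transcript sense). Positions failing the
#' quality filter, carrying an `N` read base, or present in the SNV
#' blacklist are removed from both the numerator and the denominator.
#'
#' @param read a [slam_read()] with known gene strand (or `strand` given).
#' @param blacklist an [snv_blacklist()] or `NULL`.
#' @param min_qual minimum Phred quality for a position to be counted
#'   (default 20).
#' @param strand override for the read's gene strand.
#' @param strict_low_coverage if `TRUE`, low-coverage positions recorded in
#'   the blacklist are masked as well (the conservative reading of
#'   discarding sites with under 10 reads); default `FALSE` keeps them.
#' @return An object of class `conversion_call`: list with `n_t_covered`,
#'   `n_tc`, `converted_positions` (`"chrom:pos"` keys), and the read's
#'   `gene_id`, `cell_barcode`, `umi`.
#' @export
count_tc <- function(read, blacklist = NULL, min_qual = 20,
                     strand = read$strand, strict_low_coverage = FALSE) {
  if (!inherits(read, "slam_read")) stopf("expected a slam_read")
  if (is.na(strand)) {
    stopf("read '%s': gene strand unknown; strand-aware conversion counting needs it",
          read$read_id)
  }
  bases <- t_sense_bases(strand)
  keys <- pos_key(read$chrom, read$ref_pos)
  eligible <- read$ref == bases[["ref"]] &
    read$qual >= min_qual &
    read$alt %in% DNA_BASES
  if (!is.null(blacklist)) {
    masked <- keys %in% blacklist$positions
    if (strict_low_coverage) {
      masked <- masked | keys %in% blacklist$low_coverage_positions
    }
    eligible <- eligible & !masked
  }
  conv <- eligible & read$alt == bases[["conv"]]
  structure(list(n_t_covered = sum(eligible),
                 n_tc = sum(conv),
                 converted_positions = keys[conv],
                 gene_id = read$gene_id,
                 cell_barcode = read$cell_barcode,
                 umi = read$umi),
            class = "conversion_call")
}

#' Tally coverage and conversions per transcript-sense T position
#'
#' Aggregates, over a stream of reads from one library, how many
#' quality-passing reads cover each transcript-sense T position and how many
#' of those show a T-to-C conversion. The tally is the input to SNV
#' blacklist calling and is deterministic with respect to read order.
#'
#' @param reads list of [slam_read()]; reads with unknown strand are skipped
#'   with a warning.
#' @param min_qual minimum Phred quality per position (default 20).
#' @return data.frame with columns `chrom`, `pos` (0-based), `coverage`,
#'   `conversions`, sorted by `chrom` then `pos`.
#' @export
build_position_tally <- function(reads, min_qual = 20) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      coverage = integer(), conversions = integer(),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  n_skipped <- 0L
  chroms <- character(); poss <- integer(); convs <- logical()
  for (read in reads) {
    if (is.na(read$strand)) { n_skipped <- n_skipped + 1L; next }
    bases <- t_sense_bases(read$strand)
    eligible <- read$ref == bases[["ref"]] &
      read$qual >= min_qual &
      read$alt %in% DNA_BASES
    if (!any(eligible)) next
    chroms <- c(chroms, rep(read$chrom, sum(eligible)))
    poss <- c(poss, read$ref_pos[eligible])
    convs <- c(convs, read$alt[eligible] == bases[["conv"]])
  }
  if (n_skipped > 0L) {
    warnf("%d reads without gene strand skipped in position tally", n_skipped)
  }
  if (length(poss) == 0L) return(empty)
  key <- paste0(chroms, ":", poss)
  cov <- tapply(rep(1L, length(key)), key, sum)
  cnv <- tapply(as.integer(convs), key, sum)
  keys <- names(cov)
  sp <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(sp, `[`, "", 1L),
                    pos = as.integer(vapply(sp, `[`, "", 2L)),
                    coverage = as.integer(cov),
                    conversions = as.integer(cnv[keys]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call an SNV blacklist from a position tally
#'
#' A position is blacklisted as a probable single-nucleotide variant when it
#' has at least `min_cov` reads of coverage and at least a fraction
#' `min_frac` of them carry the T-to-C conversion. Positions with coverage
#' below `min_cov` cannot be classified and are recorded separately.
#'
#' @param tally data.frame from [build_position_tally()].
#' @param min_frac minimum conversion fraction to call an SNV (default 0.25).
#' @param min_cov minimum coverage to classify a position (default 10).
#' @return An [snv_blacklist()].
#' @export
call_snv_blacklist <- function(tally, min_frac = 0.25, min_cov = 10) {
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      is.na(min_frac) || min_frac <= 0 || min_frac > 1) {
    stopf("min_frac must be in (0, 1]")
  }
  if (!is_count(min_cov) || min_cov < 1) stopf("min_cov must be a count >= 1")
  if (nrow(tally) == 0L) return(snv_blacklist())
  keys <- pos_key(tally$chrom, tally$pos)
  classified <- tally$coverage >= min_cov
  snv <- classified & (tally$conversions / tally$coverage) >= min_frac
  snv_blacklist(positions = keys[snv],
                low_coverage_positions = keys[!classified])
}

#' Conversion rate per group
#'
#' The conversion rate is the number of transcript-sense T-to-C
#' substitutions per covered T position, pooled within each group:
#' `rate = sum(n_tc) / sum(n_t_covered)`. Quality-masked and blacklisted
#' positions are excluded from numerator and denominator alike, so the rate
#' is a per-eligible-site estimate.
#'
#' @param reads list of [slam_read()].
#' @param scope `"global"`, `"per_gene"` or `"per_cell"`.
#' @param blacklist,min_qual,strict_low_coverage passed to [count_tc()].
#' @return data.frame with columns `group`, `n_tc`, `n_t_covered`, `rate`;
#'   groups whose denominator is zero get `rate = NA` (missing, not 0).
#' @export
conversion_rate <- function(reads, scope = c("global", "per_gene", "per_cell"),
                            blacklist = NULL, min_qual = 20,
                            strict_low_coverage = FALSE) {
  scope <- match.arg(scope)
  calls <- lapply(reads, count_tc, blacklist = blacklist, min_qual = min_qual,
                  strict_low_coverage = strict_low_coverage)
  group <- switch(scope,
    global = rep("global", length(calls)),
    per_gene = vapply(calls, function(x) x$gene_id, ""),
    per_cell = vapply(calls, function(x) x$cell_barcode, ""))
  # reads without a gene (or barcode) contribute to global but not per-group rates
  keep <- !is.na(group)
  n_tc <- vapply(calls, function(x) x$n_tc, 0L)[keep]
  n_t <- vapply(calls, function(x) x$n_t_covered, 0L)[keep]
  group <- group[keep]
  if (length(group) == 0L) {
    return(data.frame(group = character(), n_tc = integer(),
                      n_t_covered = integer(), rate = numeric(),
                      stringsAsFactors = FALSE))
  }
  num <- tapply(n_tc, group, sum)
  den <- tapply(n_t, group, sum)
  out <- data.frame(group = names(num),
                    n_tc = as.integer(num),
                    n_t_covered = as.integer(den[names(num)]),
                    stringsAsFactors = FALSE)
  out$rate <- ifelse(out$n_t_covered > 0, out$n_tc / out$n_t_covered, NA_real_)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Substitution spectrum of a read set
#'
#' Counts, in transcript sense, each of the 12 substitution types and the
#' number of eligible covered sites per reference base. For minus-strand
#' genes both reference and read base are complemented, so a genomic A-to-G
#' appears as T-to-C. Used to estimate the sequencing/chemistry error
#' background from the 11 non-(T-to-C) rates.
#'
#' @param reads list of [slam_read()] with known strands.
#' @param min_qual minimum Phred quality per position.
#' @return data.frame with one row per (ref, alt) pair, `ref != alt`,
#'   columns `ref`, `alt`, `n_sub`, `n_sites` (covered sites with that
#'   reference base) and `rate`.
#' @export
substitution_spectrum <- function(reads, min_qual = 20) {
  sub_counts <- matrix(0L, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  site_counts <- setNames(rep(0L, 4L), DNA_BASES)
  for (read in reads) {
    if (is.na(read$strand)) next
    ok <- read$qual >= min_qual & read$ref %in% DNA_BASES & read$alt %in% DNA_BASES
    if (!any(ok)) next
    ref <- read$ref[ok]; alt <- read$alt[ok]
    if (read$strand == "-") {
      ref <- COMPLEMENT[ref]; alt <- COMPLEMENT[alt]
    }
    tt <- table(factor(ref, DNA_BASES))
    site_counts <- site_counts + as.integer(tt)
    mm <- ref != alt
    if (any(mm)) {
      tab <- table(factor(ref[mm], DNA_BASES), factor(alt[mm], DNA_BASES))
      sub_counts <- sub_counts + as.integer(tab)
    }
  }
  grid <- expand.grid(ref = DNA_BASES, alt = DNA_BASES,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, , drop = FALSE]
  grid$n_sub <- sub_counts[cbind(grid$ref, grid$alt)]
  grid$n_sites <- as.integer(site_counts[grid$ref])
  grid$rate <- ifelse(grid$n_sites > 0, grid$n_sub / grid$n_sites, NA_real_)
  rownames(grid) <- NULL
  grid[order(grid$ref, grid$alt), , drop = FALSE]
}
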
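# fixture builders shared across test files

# a read over positions start..start+len-1 with given ref/alt strings
mk_read <- function(ref, alt, qual = 30L, start = 0L, strand = "+",
                    gene = "g1", id = "r1", chrom = "chr1", cb = NA, umi = NA) {
  ref <- strsplit(ref, "")[[1L]]
  alt <- strsplit(alt, "")[[1L]]
  n <- length(ref)
  slam_read(id, chrom, start + seq_len(n) - 1L, ref, alt,
            rep_len(as.integer(qual), n), gene_id = gene, strand = strand,
            cell_barcode = cb, umi = umi)
}

# random read of length n over a random reference, with mismatches planted
# at rate p_mm; returns the slam_read
random_read <- function(n, strand = "+", p_mm = 0.05, id = "r",
                        qual_range = c(10L, 40L), start = NULL) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- ref
  mm <- runif(n) < p_mm
  alt[mm] <- vapply(ref[mm], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, "")
  start <- if (is.null(start)) sample.int(1000L, 1L) else start
  slam_read(id, "chr1", start + seq_len(n) - 1L, ref, alt,
            sample(qual_range[1L]:qual_range[2L], n, replace = TRUE),
            gene_id = "g1", strand = strand)
}

# brute-force oracle for count_tc: plain per-position string comparison
oracle_count_tc <- function(read, blacklist_keys = character(),
                            min_qual = 20, strand = read$strand) {
  ref_b <- if (strand == "+") "T" else "A"
  conv_b <- if (strand == "+") "C" else "G"
  n_t <- 0L; n_tc <- 0L
  for (i in seq_along(read$ref_pos)) {
    key <- paste0(read$chrom, ":", read$ref_pos[i])
    if (read$ref[i] != ref_b) next
    if (read$qual[i] < min_qual) next
    if (!read$alt[i] %in% c("A", "C", "G", "T")) next
    if (key %in% blacklist_keys) next
    n_t <- n_t + 1L
    if (read$alt[i] == conv_b) n_tc <- n_tc + 1L
  }
  list(n_t_covered = n_t, n_tc = n_tc)
}

# tiny paired single-cell fixture with explicit counts
mk_pair <- function(sham_lab, sham_unl, inj_lab, inj_unl,
                    cell_type = "mac") {
  gn <- rownames(sham_lab)
  mk <- function(lab, unl) labeled_matrices(lab, unl)
  ct <- function(m) setNames(rep(cell_type, ncol(m)), colnames(m))
  condition_pair(mk(sham_lab, sham_unl), mk(inj_lab, inj_unl),
                 ct(sham_lab), ct(inj_lab))
}

# dense count matrix with dimnames
cmat <- function(x, genes, cells) {
  matrix(x, length(genes), length(cells), dimnames = list(genes, cells))
}
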
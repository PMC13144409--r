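#' Pipeline configuration
#'
#' All tunable thresholds of the analysis in one validated object:
#' the Phred quality cutoff (Q20), the labeled-call conversion threshold
#' (`k_min`, default 1), the SNV blacklist rule (fraction 0.25 at coverage
#' 10), the half-life fit window and acceptance (`tau` in 0.5-48 h,
#' `r2_min` 0.7), and the injury-response settings (pseudocount,
#' permutations, seed).
#'
#' @param min_qual Phred quality cutoff per base (default 20).
#' @param k_min distinct conversions to call a molecule labeled (default 1).
#' @param snv_min_frac,snv_min_cov SNV blacklist thresholds (0.25, 10).
#' @param strict_low_coverage also mask positions with sub-threshold
#'   coverage (default FALSE).
#' @param tau_bounds half-life bounds in hours (0.5, 48).
#' @param r2_min minimum fit R^2 for the half-life summary (0.7).
#' @param max_time latest labeling timepoint used in fits (12 h).
#' @param alpha_mode plateau handling in the decay fit (`"free"`).
#' @param pseudocount injury-response pseudocount (1).
#' @param min_count minimum corrected labeled counts for a tested gene (5).
#' @param n_perm permutations for the response significance (1000).
#' @param seed RNG seed for stochastic stages.
#' @param tags SAM tag names for cell barcode / UMI / gene.
#' @param paths named list of input/output paths for [run_pipeline()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_qual = 20, k_min = 1, snv_min_frac = 0.25,
                            snv_min_cov = 10, strict_low_coverage = FALSE,
                            tau_bounds = c(0.5, 48), r2_min = 0.7,
                            max_time = 12, alpha_mode = "free",
                            pseudocount = 1, min_count = 5, n_perm = 1000,
                            seed = 1L,
                            tags = c(cb = "CB", umi = "UB", gene = "GX"),
                            paths = list()) {
  stopifnot(min_qual >= 0, is_count(k_min), k_min >= 1,
            snv_min_frac > 0, snv_min_frac <= 1,
            is_count(snv_min_cov), snv_min_cov >= 1,
            is.logical(strict_low_coverage),
            length(tau_bounds) == 2L, tau_bounds[1L] > 0,
            tau_bounds[2L] > tau_bounds[1L],
            r2_min >= 0, r2_min <= 1, max_time > 0,
            alpha_mode %in% c("free", "fixed_1"),
            pseudocount >= 0, min_count >= 0,
            is_count(n_perm), n_perm >= 10, is_count(seed),
            all(c("cb", "umi", "gene") %in% names(tags)))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(x))`
#' reproduces `x`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$tags <- as.list(x$tags)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$tags <- unlist(x$tags)
  x$tau_bounds <- as.numeric(x$tau_bounds)
  do.call(pipeline_config, x)
}

#' Hash of a configuration
#'
#' Stable fingerprint written into output file comments so that every
#' artifact records the exact settings that produced it.
#'
#' @param config a [pipeline_config()] (or any serializable object).
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the stages the configured inputs allow and writes versioned
#' artifacts plus a machine-readable JSON manifest into `out_dir`:
#'
#' * `paths$sam` (character vector of SAM/BAM files) and `paths$genes`
#'   (gene annotation TSV with `gene_id`, `strand`): conversion calling,
#'   per-gene/global conversion-rate tables, SNV blacklist (BED), and
#'   labeled/unlabeled quantification (MTX pair) over all samples.
#' * `paths$timecourse` (TSV with gene_id, time_h, replicate, labeled,
#'   unlabeled): half-life fitting and summary.
#' * `paths$sc_sham` / `paths$sc_injured` (MTX directories) plus
#'   `paths$annotations` (barcode, cell_type, condition TSV) and
#'   `paths$cell_type`: injury-response table with permutation
#'   significance.
#'
#' A failing stage writes a `FAILED` marker file (preserving partial
#' outputs) and raises the error.
#'
#' @param config a [pipeline_config()] with `paths` set.
#' @param out_dir output directory.
#' @return named list of written artifact paths (also in
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  p <- config$paths
  run <- function() {
    if (!is.null(p$sam)) {
      gene_annot <- if (!is.null(p$genes)) read_tsv_table(p$genes) else NULL
      all_reads <- list()
      for (f in p$sam) {
        all_reads[[f]] <- read_alignments(f, gene_annot = gene_annot,
                                          tags = config$tags)
      }
      reads <- unlist(all_reads, recursive = FALSE, use.names = FALSE)
      tally <- build_position_tally(reads, min_qual = config$min_qual)
      blacklist <- call_snv_blacklist(tally, min_frac = config$snv_min_frac,
                                      min_cov = config$snv_min_cov)
      artifacts$blacklist <<- write_blacklist_bed(
        blacklist, file.path(out_dir, "snv_blacklist.bed"))
      for (scope in c("global", "per_gene", "per_cell")) {
        tab <- conversion_rate(reads, scope = scope, blacklist = blacklist,
                               min_qual = config$min_qual,
                               strict_low_coverage = config$strict_low_coverage)
        artifacts[[paste0("rates_", scope)]] <<- write_tsv_table(
          tab, file.path(out_dir, sprintf("conversion_rates_%s.tsv", scope)),
          config)
      }
      calls <- classify_molecules(reads, blacklist = blacklist,
                                  min_qual = config$min_qual,
                                  k_min = config$k_min,
                                  strict_low_coverage = config$strict_low_coverage)
      m <- build_matrices(calls)
      artifacts$matrices <<- write_labeled_matrices(
        m, file.path(out_dir, "matrices"))
    }
    if (!is.null(p$timecourse)) {
      tc <- timecourse_ratios(read_tsv_table(p$timecourse))
      fits <- fit_decay_all(tc, tau_bounds = config$tau_bounds,
                            alpha_mode = config$alpha_mode,
                            max_time = config$max_time)
      artifacts$decay_fits <<- write_tsv_table(
        fits, file.path(out_dir, "decay_fits.tsv"), config)
      sm <- summarize_halflives(fits, r2_min = config$r2_min,
                                tau_bounds = config$tau_bounds)
      artifacts$halflife_summary <<- write_tsv_table(
        data.frame(n_genes = sm$n_genes, mean_tau = sm$mean_tau,
                   median_tau = sm$median_tau),
        file.path(out_dir, "halflife_summary.tsv"), config)
    }
    if (!is.null(p$sc_sham) && !is.null(p$sc_injured)) {
      ann <- read_tsv_table(p$annotations)
      sham <- read_labeled_matrices(p$sc_sham)
      injured <- read_labeled_matrices(p$sc_injured)
      ct_map <- function(cond) {
        a <- ann[ann$condition == cond, , drop = FALSE]
        setNames(a$cell_type, a$barcode)
      }
      pair <- condition_pair(sham, injured, ct_map("sham"), ct_map("injured"))
      res <- permutation_test(pair, p$cell_type, n_perm = config$n_perm,
                              seed = config$seed,
                              pseudocount = config$pseudocount,
                              min_count = config$min_count)
      artifacts$injury_response <<- write_tsv_table(
        res, file.path(out_dir, sprintf("injury_response_%s.tsv",
                                        p$cell_type)), config)
    }
    if (length(artifacts) == 0L) {
      stopf("no runnable stage: config$paths selects no inputs")
    }
  }
  tryCatch(run(), error = function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    stop(e)
  })
  manifest <- list(tool = "slamclock",
                   version = as.character(utils::packageVersion("slamclock")),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  config_echo <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, config_echo)
  c(artifacts, list(manifest = file.path(out_dir, "manifest.json"),
                    config = config_echo))
}
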
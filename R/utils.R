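#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats median optimize p.adjust rbinom rlnorm rnorm rpois runif
#'   setNames weighted.mean qnorm quantile sd
#' @importFrom utils head read.table write.table combn packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# position keys are "chrom:pos" with pos 0-based
pos_key <- function(chrom, pos) paste0(chrom, ":", pos)

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Standard error of the mean
#' @param x numeric vector
#' @return SEM, or NA for fewer than two values
#' @keywords internal
sem <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
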
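#' Rarefy an ASV count table to a fixed depth
#'
#' Samples with fewer than `depth` reads are dropped (with a message);
#' the remaining samples are subsampled without replacement to exactly
#' `depth` reads, addressing unequal sequencing depths.
#'
#' @param counts matrix of nonnegative integer counts, animals in rows.
#' @param depth target number of sequences per sample.
#' @param seed integer seed for the subsampling.
#' @export
rarefy <- function(counts, depth, seed = 1) {
  stopifnot(is.matrix(counts), depth > 0, all(counts >= 0))
  tot <- rowSums(counts)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " sequences")
  if (any(!keep))
    message("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(utils::head(rownames(counts)[!keep], 5L), collapse = ", "))
  counts <- counts[keep, , drop = FALSE]
  set.seed(seed)
  exact <- rowSums(counts) == depth
  if (any(!exact)) {
    # depth adequacy was checked above; vegan's advisory warnings about
    # count magnitudes are not informative here
    sub <- suppressWarnings(
      vegan::rrarefy(counts[!exact, , drop = FALSE], depth))
    counts[!exact, ] <- sub
  }
  counts
}

#' Discard low-prevalence ASVs
#'
#' Keeps ASVs with nonzero counts in at least `min_prevalence` of the
#' samples (an ASV present in exactly 20% of samples is retained under the
#' default).
#'
#' @param counts count matrix, animals in rows.
#' @param min_prevalence minimum fraction of samples with a nonzero count.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.20) {
  stopifnot(min_prevalence > 0, min_prevalence <= 1)
  prev <- colMeans(counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("no ASV reaches prevalence ", min_prevalence)
  counts[, keep, drop = FALSE]
}

#' Standardized log relative-abundance matrix M
#'
#' Adds a pseudocount, converts each sample to relative abundances
#' \eqn{P_{jk}}, takes natural logs, and standardizes each ASV column:
#' \eqn{m_{jk} = (\log P_{jk} - \mathrm{mean}(\log P_{.k})) /
#' \mathrm{sd}(\log P_{.k})}.  The population standard deviation
#' (denominator n) is the default, which makes `trace(O)/n = 1` exact;
#' zero-variance columns are dropped with a warning.
#'
#' @param counts rarefied, prevalence-filtered count matrix.
#' @param pseudocount constant added to every element before the
#'   relative-abundance conversion (default 1).
#' @param sd_denominator `"n"` (population, default) or `"n-1"` (sample).
#' @export
standardize_abundance <- function(counts, pseudocount = 1,
                                  sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  n <- nrow(counts)
  if (n < 2) stop("at least two samples are required to standardize")
  x <- counts + pseudocount
  P <- x / rowSums(x)
  L <- log(P)
  mu <- colMeans(L)
  cent <- sweep(L, 2L, mu)
  ss <- colMeans(cent^2)
  if (sd_denominator == "n-1") ss <- ss * n / (n - 1)
  s <- sqrt(ss)
  zero <- s < 1e-12
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance ASV column(s)")
    cent <- cent[, !zero, drop = FALSE]
    s <- s[!zero]
  }
  M <- sweep(cent, 2L, s, "/")
  structure(M, kind = "M")
}

#' Microbial relationship matrix O = MM'/m
#'
#' @param M standardized log relative-abundance matrix from
#'   [standardize_abundance()] (animals x ASVs).
#' @return symmetric PSD matrix (animals x animals) with
#'   `attr(, "kind") == "O"`.
#' @export
build_O <- function(M) {
  stopifnot(is.matrix(M), ncol(M) >= 1)
  structure(tcrossprod(M) / ncol(M), kind = "O")
}

#' Full microbiome preprocessing pipeline
#'
#' Enforces the order rarefy -> prevalence filter -> pseudocount +
#' standardize -> O.
#'
#' @inheritParams rarefy
#' @inheritParams prevalence_filter
#' @inheritParams standardize_abundance
#' @return list with `counts` (rarefied + filtered), `M`, `O`.
#' @export
microbiome_pipeline <- function(counts, depth, min_prevalence = 0.20,
                                pseudocount = 1, sd_denominator = "n",
                                seed = 1) {
  counts <- rarefy(counts, depth, seed = seed)
  counts <- prevalence_filter(counts, min_prevalence)
  M <- standardize_abundance(counts, pseudocount, sd_denominator)
  list(counts = counts, M = M, O = build_O(M))
}
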
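#' Estimate per-sample size factors
#'
#' Size factors scale raw read counts so that samples sequenced to different
#' depths are comparable: the model mean for gene g in sample i is
#' `s_i * lambda_g`. Three estimators are provided; all normalize by the sum
#' over training samples, so the returned factors are positive and sum to 1.
#'
#' * `"total"` — sample i's total read count divided by the grand total over
#'   all samples.
#' * `"median-ratio"` — the median-of-ratios estimator: per sample, the
#'   median over genes of the ratio of the count to the gene's geometric mean
#'   across samples, then normalized to sum to 1. Genes with a zero count in
#'   any sample have geometric mean zero and are excluded from the median.
#' * `"upper-quartile"` — per sample, the 75th percentile of its gene counts
#'   (linear-interpolation quantile), normalized to sum to 1.
#'
#' @param counts A count matrix (genes x samples), see [as_count_matrix()].
#' @param method One of `"total"`, `"median-ratio"`, `"upper-quartile"`.
#' @return A named numeric vector of size factors (one per sample, summing
#'   to 1) with attribute `method`.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m, "total")          # (1/3, 2/3)
#' size_factors(m, "median-ratio")   # (1/3, 2/3)
#' @export
size_factors <- function(counts,
                         method = c("total", "median-ratio", "upper-quartile")) {
  counts <- as_count_matrix(counts)
  method <- match.arg(method)
  raw <- switch(method,
    "total" = {
      tot <- colSums(counts)
      if (any(tot == 0)) {
        stop(sprintf("sample '%s' has zero total count; its size factor is undefined",
                     colnames(counts)[which(tot == 0)[1L]]), call. = FALSE)
      }
      tot
    },
    "median-ratio" = {
      gm <- geometric_means(counts)
      usable <- gm > 0
      if (!any(usable)) {
        stop(paste("median-of-ratios size factors need at least one gene with",
                   "strictly positive counts in every sample; filter low-count",
                   "genes or use method = 'total'"), call. = FALSE)
      }
      apply(counts[usable, , drop = FALSE] / gm[usable], 2L, stats::median)
    },
    "upper-quartile" = {
      q <- apply(counts, 2L, stats::quantile, probs = 0.75, names = FALSE)
      if (any(q == 0)) {
        stop(sprintf(paste("sample '%s' has upper quartile 0; filter",
                           "genes with predominantly zero counts first"),
                     colnames(counts)[which(q == 0)[1L]]), call. = FALSE)
      }
      q
    })
  s <- raw / sum(raw)
  names(s) <- colnames(counts)
  attr(s, "method") <- method
  s
}

#' Size factor for a test sample
#'
#' Estimates the size factor of a single test sample on the scale of the
#' training size factors, using only training-data totals in the
#' denominator: a test sample that is an exact copy of a training sample
#' gets that sample's size factor.
#'
#' @param x_star Integer count vector for the test sample (length G, same
#'   gene order as the training matrix).
#' @param counts The training count matrix.
#' @param method Size-factor estimator, as in [size_factors()].
#' @return A positive scalar.
#' @export
size_factor_test <- function(x_star, counts,
                             method = c("total", "median-ratio", "upper-quartile")) {
  counts <- as_count_matrix(counts)
  method <- match.arg(method)
  x_star <- validate_test_counts(x_star, rownames(counts))
  stats <- test_sf_stats(counts, method)
  size_factor_test_from_stats(x_star, stats)
}

# Per-gene geometric mean across samples; exactly 0 when any count is 0.
geometric_means <- function(counts) {
  gm <- exp(rowMeans(log(counts)))
  gm[apply(counts == 0, 1L, any)] <- 0
  gm
}

validate_test_counts <- function(x_star, gene_ids) {
  if (!is.numeric(x_star)) stop("test counts must be numeric", call. = FALSE)
  if (length(x_star) != length(gene_ids)) {
    stop(sprintf("test sample has %d genes but the model/training data has %d",
                 length(x_star), length(gene_ids)), call. = FALSE)
  }
  if (any(!is.finite(x_star) | x_star < 0 | x_star != round(x_star))) {
    stop("test counts must be non-negative integers", call. = FALSE)
  }
  if (!is.null(names(x_star)) && !identical(names(x_star), gene_ids)) {
    stop("test sample gene identifiers do not match the training genes (order matters)",
         call. = FALSE)
  }
  as.numeric(x_star)
}

# The training-side summaries needed to place a test sample on the training
# size-factor scale; stored inside fitted models so prediction does not need
# the training counts.
test_sf_stats <- function(counts, method) {
  switch(method,
    "total" = list(method = method, grand_total = sum(counts)),
    "median-ratio" = {
      gm <- geometric_means(counts)
      usable <- gm > 0
      if (!any(usable)) {
        stop("median-of-ratios needs a gene with strictly positive counts in every sample",
             call. = FALSE)
      }
      m_i <- apply(counts[usable, , drop = FALSE] / gm[usable], 2L, stats::median)
      list(method = method, geo_means = gm, m_sum = sum(m_i))
    },
    "upper-quartile" = {
      q_i <- apply(counts, 2L, stats::quantile, probs = 0.75, names = FALSE)
      list(method = method, q_sum = sum(q_i))
    })
}

size_factor_test_from_stats <- function(x_star, stats) {
  s_star <- switch(stats$method,
    "total" = {
      if (sum(x_star) == 0) {
        stop("test sample has zero total count; its size factor is undefined",
             call. = FALSE)
      }
      sum(x_star) / stats$grand_total
    },
    "median-ratio" = {
      usable <- stats$geo_means > 0
      stats::median(x_star[usable] / stats$geo_means[usable]) / stats$m_sum
    },
    "upper-quartile" = {
      q_star <- stats::quantile(x_star, probs = 0.75, names = FALSE)
      if (q_star == 0) {
        stop("test sample has upper quartile 0; filter low-count genes first",
             call. = FALSE)
      }
      q_star / stats$q_sum
    })
  if (!is.finite(s_star) || s_star <= 0) {
    stop("estimated test size factor is not a positive number; check the test counts",
         call. = FALSE)
  }
  s_star
}
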
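#' Method-of-moments dispersion estimates
#'
#' Initial per-gene dispersion estimates from the negative binomial
#' mean-variance relation `Var = mu + mu^2 * phi`: with `m_g` and `v_g` the
#' sample mean and unbiased sample variance of the size-factor-normalized
#' counts `X_ig / s_i`, the estimate is `(v_g - m_g) / m_g^2`. Raw moment
#' estimates can be negative (underdispersion in the sample); since the
#' negative binomial dispersion is non-negative they are clamped at 0.
#' Genes with zero mean get dispersion 0.
#'
#' By default moments are pooled across all samples, consistent with the
#' dispersion entering the discriminant score as a class-independent
#' parameter. With `labels` given, moments are instead taken within each
#' class and the per-class estimates averaged (every class then needs at
#' least two samples); this is intended for sensitivity analysis.
#'
#' @param counts Training count matrix (genes x samples), n >= 2.
#' @param sf Size factors from [size_factors()] (any positive per-sample
#'   scale works; only ratios matter up to the overall mean level).
#' @param labels Optional factor of class labels enabling within-class
#'   moments.
#' @return Numeric vector of per-gene initial dispersion estimates (>= 0).
#' @export
mom_dispersion <- function(counts, sf, labels = NULL) {
  counts <- as_count_matrix(counts)
  if (length(sf) != ncol(counts) || any(!is.finite(sf) | sf <= 0)) {
    stop("sf must be one positive size factor per sample", call. = FALSE)
  }
  if (is.null(labels)) {
    if (ncol(counts) < 2L) {
      stop("at least two samples are needed to estimate dispersion", call. = FALSE)
    }
    return(mom_dispersion_one(counts, sf))
  }
  labels <- validate_labels(labels, counts)
  if (any(table(labels) < 2L)) {
    stop("within-class moment estimation needs at least two samples per class",
         call. = FALSE)
  }
  per_class <- vapply(levels(labels), function(k) {
    idx <- which(labels == k)
    mom_dispersion_one(counts[, idx, drop = FALSE], sf[idx])
  }, numeric(nrow(counts)))
  rowMeans(per_class)
}

mom_dispersion_one <- function(counts, sf) {
  norm <- sweep(counts, 2L, sf, "/")
  m <- rowMeans(norm)
  v <- rowSums((norm - m)^2) / (ncol(norm) - 1L)
  phi <- numeric(length(m))
  pos <- m > 0
  phi[pos] <- pmax(0, (v[pos] - m[pos]) / m[pos]^2)
  names(phi) <- rownames(counts)
  phi
}

#' Shrinkage target for the dispersion estimator
#'
#' The shrunk dispersions are a convex combination of the gene-wise moment
#' estimates and a common target `xi`. Two strategies are offered:
#'
#' * `"mean"` (default) — `xi` is the arithmetic mean of the initial
#'   estimates, the natural center of the cross-gene distribution.
#' * `"grid"` — `xi` minimizes the average squared difference between the
#'   shrunk and the initial estimates over a 100-point evenly spaced grid
#'   spanning the range of the initial estimates, ties broken toward the
#'   smaller value. Taken literally over an unbounded range this objective
#'   is degenerate (it keeps decreasing as the target moves away from the
#'   data, because the weight collapses faster than the squared distance
#'   grows), which is why the search is restricted to the observed range.
#'
#' @param phi_tilde Initial per-gene dispersion estimates (finite, length
#'   >= 3).
#' @param strategy `"mean"` or `"grid"`.
#' @return The scalar target value.
#' @export
select_xi <- function(phi_tilde, strategy = c("mean", "grid")) {
  strategy <- match.arg(strategy)
  if (length(phi_tilde) < 3L) {
    stop("at least 3 genes are needed to estimate a shrinkage target", call. = FALSE)
  }
  if (any(!is.finite(phi_tilde))) {
    stop("initial dispersion estimates must all be finite", call. = FALSE)
  }
  if (strategy == "mean") return(mean(phi_tilde))
  grid <- seq(min(phi_tilde), max(phi_tilde), length.out = 100L)
  obj <- vapply(grid, function(xi) {
    delta <- shrinkage_weight(phi_tilde, xi)
    mean((delta * (xi - phi_tilde))^2)
  }, numeric(1L))
  grid[which.min(obj)]  # which.min takes the first minimum: the smaller xi
}

#' Shrinkage weight for the dispersion estimator
#'
#' The weight placed on the common target: the ratio of the cross-gene
#' variance of the initial estimates (divisor G - 1) to their mean squared
#' distance from the target (divisor G - 2), clamped to `[0, 1]` so the
#' shrunk estimate is always a convex combination. When every initial
#' estimate equals the target the ratio is 0/0; full shrinkage (weight 1)
#' is returned, which leaves the estimates unchanged.
#'
#' @param phi_tilde Initial per-gene dispersion estimates (length >= 3).
#' @param xi Scalar target value.
#' @return The weight, a scalar in `[0, 1]`.
#' @examples
#' shrinkage_weight(c(1, 2, 3), 2)  # 0.5
#' @export
shrinkage_weight <- function(phi_tilde, xi) {
  G <- length(phi_tilde)
  if (G < 3L) stop("at least 3 genes are needed to compute the shrinkage weight",
                   call. = FALSE)
  num <- sum((phi_tilde - mean(phi_tilde))^2) / (G - 1L)
  den <- sum((phi_tilde - xi)^2) / (G - 2L)
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

#' Shrinkage estimation of gene-wise dispersions
#'
#' Complete dispersion fit: method-of-moments initial estimates on
#' size-factor-normalized counts, a shrinkage target, the shrinkage weight,
#' and the shrunk estimates
#' `phi_hat_g = delta * xi + (1 - delta) * phi_tilde_g`. Shrinking the noisy
#' gene-wise estimates toward a common target stabilizes them when the
#' sample size is small.
#'
#' @inheritParams mom_dispersion
#' @param xi_strategy Target selection strategy, see [select_xi()].
#' @return An object of class `"dispersion_fit"`: a list with elements
#'   `phi_initial`, `xi`, `delta`, `phi_hat`, `xi_strategy`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnbinom(400, size = 2, mu = 20), 100, 4,
#'             dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
#' fit <- shrink_dispersion(m, size_factors(m))
#' fit$delta
#' @export
shrink_dispersion <- function(counts, sf, xi_strategy = c("mean", "grid"),
                              labels = NULL) {
  xi_strategy <- match.arg(xi_strategy)
  phi_tilde <- mom_dispersion(counts, sf, labels = labels)
  xi <- select_xi(phi_tilde, xi_strategy)
  delta <- shrinkage_weight(phi_tilde, xi)
  phi_hat <- delta * xi + (1 - delta) * phi_tilde
  structure(list(phi_initial = phi_tilde, xi = xi, delta = delta,
                 phi_hat = phi_hat, xi_strategy = xi_strategy),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("Dispersion fit: %d genes\n", length(x$phi_hat)))
  cat(sprintf("  target xi       : %.4g (strategy '%s')\n", x$xi, x$xi_strategy))
  cat(sprintf("  shrinkage weight: %.4g\n", x$delta))
  cat(sprintf("  median phi_hat  : %.4g\n", stats::median(x$phi_hat)))
  invisible(x)
}
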
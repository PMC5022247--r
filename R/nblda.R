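#' Fit a negative binomial linear discriminant model
#'
#' Fits the gene-wise negative binomial model
#' `X_ig | y_i = k ~ NB(mean = s_i * lambda_g * d_kg, dispersion = phi_g)`
#' on labeled training counts, with genes assumed independent. The plug-in
#' estimates are:
#'
#' * `lambda_g` — the total read count of gene g over all training samples
#'   (consistent with training size factors summing to 1, so that
#'   `sum_i s_i * lambda_g` matches the gene's expected total);
#' * `d_kg` — the class effect
#'   `(sum of class-k counts + 1) / (sum of class-k size factors * lambda_g + 1)`,
#'   a posterior-mean estimate under a gamma prior whose `+1` smoothing keeps
#'   every effect strictly positive (an all-zero gene gets `d_kg = 1`);
#' * `pi_k` — the empirical class frequency `n_k / n`;
#' * `phi_g` — the shrinkage dispersion estimate from [shrink_dispersion()];
#' * `s_i` — size factors from [size_factors()].
#'
#' @param counts Training count matrix (genes x samples), see
#'   [as_count_matrix()].
#' @param labels Class labels: a factor (or vector coercible to one) of
#'   length `ncol(counts)`. Class indices follow the lexicographic order of
#'   the class names.
#' @param size_factor Size-factor estimator (see [size_factors()]); also
#'   used for test samples at prediction time.
#' @param xi_strategy Dispersion shrinkage-target strategy (see
#'   [select_xi()]).
#' @param mom_within_class If `TRUE`, dispersion moments are computed within
#'   class and averaged (sensitivity analysis; needs >= 2 samples per class).
#' @return An object of class `"nblda"`: a list with elements `lambda`
#'   (per-gene totals), `d` (K x G matrix of class effects), `pi` (class
#'   priors), `phi` (per-gene dispersions), `sf` (training size factors),
#'   `sf_method`, `sf_stats` (training summaries used to scale test
#'   samples), `dispersion` (the full [shrink_dispersion()] fit),
#'   `class_names`, and `gene_ids`.
#' @examples
#' sim <- simulate_counts(sim_config(G = 50, n = 12, de_prop = 0.4,
#'                                   sigma = 2, phi = 1, seed = 7))
#' fit <- nblda_fit(sim$train$counts, sim$train$y)
#' fit
#' @export
nblda_fit <- function(counts, labels,
                      size_factor = c("total", "median-ratio", "upper-quartile"),
                      xi_strategy = c("mean", "grid"),
                      mom_within_class = FALSE) {
  counts <- as_count_matrix(counts)
  labels <- validate_labels(labels, counts)
  size_factor <- match.arg(size_factor)
  xi_strategy <- match.arg(xi_strategy)
  if (nlevels(labels) == 1L) {
    warning("training data has a single class; the model will always predict it",
            call. = FALSE)
  }

  s <- size_factors(counts, size_factor)
  lambda <- rowSums(counts)
  n_k <- table(labels)
  d <- t(vapply(levels(labels), function(k) {
    idx <- which(labels == k)
    (rowSums(counts[, idx, drop = FALSE]) + 1) / (sum(s[idx]) * lambda + 1)
  }, numeric(nrow(counts))))
  dimnames(d) <- list(levels(labels), rownames(counts))

  disp <- shrink_dispersion(counts, s, xi_strategy = xi_strategy,
                            labels = if (mom_within_class) labels else NULL)

  structure(list(
    lambda = stats::setNames(lambda, rownames(counts)),
    d = d,
    pi = as.numeric(n_k) / length(labels),
    phi = stats::setNames(disp$phi_hat, rownames(counts)),
    sf = as.numeric(s),
    sf_method = size_factor,
    sf_stats = test_sf_stats(counts, size_factor),
    dispersion = disp,
    class_names = levels(labels),
    gene_ids = rownames(counts)
  ), class = "nblda")
}

#' @export
print.nblda <- function(x, ...) {
  cat(sprintf("Negative binomial LDA model: %d genes, %d classes (%s)\n",
              length(x$gene_ids), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  cat(sprintf("  size factors    : %s\n", x$sf_method))
  cat(sprintf("  median dispersion: %.4g (shrinkage weight %.3g)\n",
              stats::median(x$phi), x$dispersion$delta))
  invisible(x)
}

# Validate externally supplied / deserialized parameters before scoring.
check_model_params <- function(model) {
  if (any(!is.finite(model$d) | model$d <= 0)) {
    stop("class effects d_kg must all be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(model$phi) | model$phi < 0)) {
    stop("dispersions must be finite and non-negative", call. = FALSE)
  }
  if (any(model$lambda < 0)) stop("per-gene totals must be non-negative", call. = FALSE)
  if (any(model$pi <= 0) || abs(sum(model$pi) - 1) > 1e-8) {
    stop("class priors must be positive and sum to 1", call. = FALSE)
  }
  invisible(model)
}

#' Negative binomial discriminant score
#'
#' Per-class log-posterior, up to an additive constant shared by all
#' classes, of a test count vector under the fitted negative binomial
#' model:
#' \deqn{score_k = \sum_g X^*_g [\log d_{kg} - \log(1 + s^* \lambda_g d_{kg}
#' \phi_g)] - \sum_g \phi_g^{-1} \log(1 + s^* \lambda_g d_{kg} \phi_g) +
#' \log \pi_k.}
#' Genes with dispersion exactly 0 contribute their analytic Poisson limit,
#' `X*_g log d_kg - s* lambda_g d_kg`, rather than an epsilon-perturbed
#' value.
#'
#' @param model A fitted `"nblda"` model.
#' @param x_star Integer count vector for one test sample (training gene
#'   order).
#' @param s_star Positive size factor of the test sample, typically from
#'   [size_factor_test()] with the model's method.
#' @return Named numeric vector of per-class scores.
#' @seealso [plda_score()] for the zero-dispersion baseline,
#'   [predict.nblda()] for classification of many samples.
#' @export
nblda_score <- function(model, x_star, s_star) {
  check_model_params(model)
  x_star <- validate_test_counts(x_star, model$gene_ids)
  if (!is.finite(s_star) || s_star <= 0) {
    stop("s_star must be a positive number", call. = FALSE)
  }
  a <- sweep(model$d, 2L, s_star * model$lambda, "*")  # K x G: s* lambda_g d_kg
  pois <- model$phi == 0
  L <- sweep(a, 2L, model$phi, "*")
  L <- log1p(L)
  term1 <- log(model$d) - L
  term2 <- sweep(L, 2L, ifelse(pois, 1, model$phi), "/")
  if (any(pois)) {
    term1[, pois] <- log(model$d[, pois, drop = FALSE])
    term2[, pois] <- a[, pois, drop = FALSE]
  }
  scores <- as.numeric(term1 %*% x_star) - rowSums(term2) + log(model$pi)
  stats::setNames(scores, model$class_names)
}

#' Poisson-limit discriminant score
#'
#' The discriminant score of the Poisson model, which is the zero-dispersion
#' limit of [nblda_score()]:
#' \deqn{score_k = \sum_g X^*_g \log d_{kg} - \sum_g s^* \lambda_g d_{kg} +
#' \log \pi_k.}
#' This is the plain Poisson linear discriminant baseline (no shrinkage of
#' the class effects and no power transformation).
#'
#' @inheritParams nblda_score
#' @return Named numeric vector of per-class scores.
#' @export
plda_score <- function(model, x_star, s_star) {
  check_model_params(model)
  x_star <- validate_test_counts(x_star, model$gene_ids)
  if (!is.finite(s_star) || s_star <= 0) {
    stop("s_star must be a positive number", call. = FALSE)
  }
  a <- sweep(model$d, 2L, s_star * model$lambda, "*")
  scores <- as.numeric(log(model$d) %*% x_star) - rowSums(a) + log(model$pi)
  stats::setNames(scores, model$class_names)
}

#' Classify test samples with a fitted model
#'
#' Estimates each test sample's size factor with the model's size-factor
#' method, computes per-class discriminant scores, and assigns each sample
#' to the class with the maximal score (exact ties broken toward the
#' first class in lexicographic order). Posterior class probabilities are
#' the softmax of the score vector — valid because the dropped constant in
#' the score is identical across classes — computed with max subtraction
#' for numerical stability.
#'
#' @param object A fitted `"nblda"` model.
#' @param newdata Count matrix of test samples (genes x samples, training
#'   gene order) or a single count vector.
#' @param type `"class"` for predicted labels (default), `"posterior"` for
#'   the samples x classes probability matrix, `"score"` for the raw
#'   discriminant scores, or `"all"` for a list with all three plus the
#'   estimated test size factors.
#' @param method `"nblda"` (default) or `"plda"` to score with the
#'   Poisson-limit baseline.
#' @param ... Unused.
#' @return See `type`. Predicted labels are a factor with the model's class
#'   levels.
#' @examples
#' sim <- simulate_counts(sim_config(G = 50, n = 12, de_prop = 0.4,
#'                                   sigma = 2, phi = 1, seed = 7))
#' fit <- nblda_fit(sim$train$counts, sim$train$y)
#' pred <- predict(fit, sim$test$counts)
#' table(pred, sim$test$y)
#' @export
predict.nblda <- function(object, newdata, type = c("class", "posterior", "score", "all"),
                          method = c("nblda", "plda"), ...) {
  type <- match.arg(type)
  method <- match.arg(method)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "test1"))
  }
  if (nrow(newdata) != length(object$gene_ids)) {
    stop(sprintf("test data has %d genes but the model has %d",
                 nrow(newdata), length(object$gene_ids)), call. = FALSE)
  }
  if (!is.null(rownames(newdata)) &&
      !identical(rownames(newdata), object$gene_ids)) {
    stop("test gene identifiers do not match the model's genes (order matters)",
         call. = FALSE)
  }
  score_fun <- if (method == "nblda") nblda_score else plda_score
  m <- ncol(newdata)
  K <- length(object$class_names)
  scores <- matrix(NA_real_, m, K,
                   dimnames = list(colnames(newdata), object$class_names))
  s_star <- numeric(m)
  for (j in seq_len(m)) {
    s_star[j] <- size_factor_test_from_stats(
      validate_test_counts(newdata[, j], object$gene_ids), object$sf_stats)
    scores[j, ] <- score_fun(object, newdata[, j], s_star[j])
  }
  posterior <- t(apply(scores, 1L, function(v) {
    w <- exp(v - max(v))
    w / sum(w)
  }))
  if (K == 1L) posterior <- matrix(1, m, 1L, dimnames = dimnames(scores))
  cls <- factor(object$class_names[apply(scores, 1L, which.max)],
                levels = object$class_names)
  switch(type,
         class = cls,
         posterior = posterior,
         score = scores,
         all = list(class = cls, posterior = posterior, score = scores,
                    s_star = s_star))
}
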
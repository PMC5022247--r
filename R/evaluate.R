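#' Misclassification rate
#'
#' Fraction of samples whose predicted class differs from the true class.
#'
#' @param predicted Predicted labels (factor or vector).
#' @param truth True labels, same length.
#' @return A number in `[0, 1]`.
#' @export
misclassification_rate <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1L) {
    stop("predicted and truth must have equal length >= 1", call. = FALSE)
  }
  mean(as.character(predicted) != as.character(truth))
}

#' Repeated-simulation classifier comparison
#'
#' Monte-Carlo evaluation of the negative binomial discriminant and/or its
#' Poisson-limit baseline under one simulation design: per replicate, a
#' fresh dataset is simulated, the model is fitted on the training half,
#' the test half is classified, and the misclassification rate recorded.
#' Replicate seeds are derived deterministically from the configuration's
#' seed, so results are reproducible bitwise.
#'
#' @param config A [sim_config()]; its `seed` is the master seed of the
#'   experiment.
#' @param methods Character subset of `c("nblda", "plda")`.
#' @param reps Number of simulation replicates (>= 1).
#' @param size_factor,xi_strategy Passed to [nblda_fit()].
#' @return An object of class `"nblda_experiment"`: a data frame with one
#'   row per method (`method`, `mean_rate`, `se`, `reps`) and the
#'   configuration in attribute `config`. `se` is the Monte-Carlo standard
#'   error of the mean rate. The per-replicate rates are kept in attribute
#'   `rates` (a reps x methods matrix).
#' @examples
#' cfg <- sim_config(G = 50, n = 8, de_prop = 0.4, sigma = 5, phi = 20, seed = 1)
#' run_experiment(cfg, reps = 5)
#' @export
run_experiment <- function(config, methods = c("nblda", "plda"), reps = 100L,
                           size_factor = "total", xi_strategy = "mean") {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config", call. = FALSE)
  methods <- match.arg(methods, c("nblda", "plda"), several.ok = TRUE)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)

  rep_seeds <- component_seeds(config$seed, reps)
  rates <- matrix(NA_real_, reps, length(methods),
                  dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    cfg_r <- config
    cfg_r$seed <- rep_seeds[r]
    sim <- simulate_counts(cfg_r)
    fit <- nblda_fit(sim$train$counts, sim$train$y,
                     size_factor = size_factor, xi_strategy = xi_strategy)
    for (m in methods) {
      pred <- predict(fit, sim$test$counts, type = "class", method = m)
      rates[r, m] <- misclassification_rate(pred, sim$test$y)
    }
  }
  out <- data.frame(method = methods,
                    mean_rate = colMeans(rates),
                    se = apply(rates, 2L, stats::sd) / sqrt(reps),
                    reps = reps,
                    row.names = NULL)
  attr(out, "config") <- config
  attr(out, "rates") <- rates
  class(out) <- c("nblda_experiment", "data.frame")
  out
}

#' Discriminant score as a function of dispersion
#'
#' Numerical comparison of the data-dependent part of the negative binomial
#' and Poisson discriminant scores (the two terms that differ between them;
#' the prior term and the shared constant are dropped) for a stylized test
#' sample in which every gene has the same count, class effect, rate and
#' size factor. The Poisson score does not involve the dispersion and is a
#' constant; the negative binomial score is traced either over a grid of
#' common dispersions (`phi_grid`) or, per grid point, with gene-specific
#' dispersions drawn i.i.d. from a chi-squared distribution
#' (`chisq_df_grid`), each draw taken from a seeded stream so the jagged
#' curve is reproducible.
#'
#' @param phi_grid Numeric grid of common dispersion values (mutually
#'   exclusive with `chisq_df_grid`).
#' @param chisq_df_grid Numeric grid of chi-squared degrees of freedom for
#'   the heterogeneous-dispersion mode.
#' @param x_star Per-gene test count (default 10).
#' @param d Common class effect (default 1.5).
#' @param s_star Test size factor (default 1).
#' @param lambda Common per-gene rate (default 10).
#' @param G Number of genes (default 500).
#' @param seed Seed for the chi-squared draws (required in that mode).
#' @return A data frame with the grid column (`phi` or `chisq_df`), the
#'   negative binomial score `nblda`, and the constant Poisson score
#'   `plda`.
#' @examples
#' curve <- score_vs_dispersion(phi_grid = seq(0, 20, by = 0.5))
#' head(curve)
#' @export
score_vs_dispersion <- function(phi_grid = NULL, chisq_df_grid = NULL,
                                x_star = 10, d = 1.5, s_star = 1, lambda = 10,
                                G = 500, seed = 1L) {
  if (is.null(phi_grid) == is.null(chisq_df_grid)) {
    stop("supply exactly one of phi_grid or chisq_df_grid", call. = FALSE)
  }
  a <- s_star * lambda * d
  plda_val <- G * (x_star * log(d) - a)
  gene_term <- function(phi) {
    # per-gene score contribution; analytic Poisson limit at phi = 0
    out <- ifelse(phi == 0,
                  x_star * log(d) - a,
                  x_star * (log(d) - log1p(a * phi)) - log1p(a * phi) / phi)
    sum(out)
  }
  if (!is.null(phi_grid)) {
    if (length(phi_grid) < 1L) stop("phi_grid is empty", call. = FALSE)
    if (any(phi_grid < 0)) stop("dispersions must be >= 0", call. = FALSE)
    nb <- vapply(phi_grid, function(phi) gene_term(rep(phi, G)), numeric(1L))
    return(data.frame(phi = phi_grid, nblda = nb, plda = plda_val))
  }
  if (length(chisq_df_grid) < 1L) stop("chisq_df_grid is empty", call. = FALSE)
  if (any(chisq_df_grid <= 0)) stop("degrees of freedom must be > 0", call. = FALSE)
  seeds <- component_seeds(seed, length(chisq_df_grid))
  nb <- vapply(seq_along(chisq_df_grid), function(j) {
    set.seed(seeds[j])
    gene_term(stats::rchisq(G, df = chisq_df_grid[j]))
  }, numeric(1L))
  data.frame(chisq_df = chisq_df_grid, nblda = nb, plda = plda_val)
}
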
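#' Simulation configuration
#'
#' Describes one synthetic two-group (or K-group) RNA-Seq experiment drawn
#' from the gene-wise negative binomial model. Per dataset: size factors
#' `s_i` are i.i.d. uniform on `sf_range`; per-gene rates `lambda_g` are
#' i.i.d. exponential with rate `lambda_rate` (default 0.04, mean 25 reads);
#' a fixed fraction `de_prop` of genes is differentially expressed, with
#' log class effects `log d_kg` i.i.d. normal with standard deviation
#' `sigma` (constant genes have `d_kg = 1` exactly); and counts are drawn as
#' `X_ig | y_i = k ~ NB(mean = s_i * lambda_g * d_kg, dispersion = phi)`
#' with a common dispersion `phi` (`phi = 0` gives Poisson counts). The
#' training and test sets each contain `n` samples with balanced class
#' labels (any remainder goes to the earliest classes); test-set size
#' factors are drawn afresh.
#'
#' @param G Number of genes (>= 1).
#' @param n Samples per dataset (train and test each get `n`; `n >= K`).
#' @param de_prop Fraction of differentially expressed genes in `[0, 1]`;
#'   exactly `round(de_prop * G)` genes (the first ones) are flagged.
#' @param sigma Standard deviation of the log class effects (>= 0).
#' @param phi Common negative binomial dispersion (>= 0; 0 is Poisson).
#' @param K Number of classes (default 2).
#' @param sf_range Support of the uniform size-factor distribution
#'   (default `c(0.2, 2.2)`).
#' @param lambda_rate Rate of the exponential distribution of `lambda_g`
#'   (default 0.04).
#' @param seed Integer seed; the same configuration always yields the same
#'   dataset.
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_counts()]
#' @export
sim_config <- function(G, n, de_prop, sigma, phi, K = 2L,
                       sf_range = c(0.2, 2.2), lambda_rate = 0.04, seed = 1L) {
  cfg <- list(G = as.integer(G), n = as.integer(n), K = as.integer(K),
              de_prop = de_prop, sigma = sigma, phi = phi,
              sf_range = as.numeric(sf_range), lambda_rate = lambda_rate,
              seed = as.integer(seed))
  with(cfg, {
    if (G < 1L) stop("G must be >= 1", call. = FALSE)
    if (K < 1L) stop("K must be >= 1", call. = FALSE)
    if (n < K) stop("n must be >= K so every class is represented", call. = FALSE)
    if (de_prop < 0 || de_prop > 1) stop("de_prop must lie in [0, 1]", call. = FALSE)
    if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
    if (phi < 0) stop("phi must be >= 0", call. = FALSE)
    if (length(sf_range) != 2L || any(sf_range <= 0) || diff(sf_range) < 0) {
      stop("sf_range must be a positive interval", call. = FALSE)
    }
    if (lambda_rate <= 0) stop("lambda_rate must be > 0", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Draw negative binomial counts with a mean/dispersion parameterization
#'
#' Draws from `NB(mean = mu, dispersion = phi)`, i.e. with variance
#' `mu + mu^2 * phi`. Internally this is `rnbinom` with size `r = 1 / phi`
#' and probability `r / (r + mu)`; `phi = 0` draws from `Poisson(mu)`.
#'
#' @param n Number of draws.
#' @param mu Mean(s), strictly positive (recycled).
#' @param phi Common dispersion, `>= 0`.
#' @return Integer vector of counts.
#' @export
nb_draw <- function(n, mu, phi) {
  if (any(!is.finite(mu) | mu <= 0)) stop("mu must be strictly positive", call. = FALSE)
  if (length(phi) != 1L || !is.finite(phi) || phi < 0) {
    stop("phi must be a single non-negative number", call. = FALSE)
  }
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

# Independent sub-seeds per dataset component, so e.g. enlarging G does not
# perturb the size-factor draws.
component_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

balanced_labels <- function(n, K) {
  n_k <- rep(n %/% K, K) + (seq_len(K) <= n %% K)
  factor(rep(sprintf("class%d", seq_len(K)), times = n_k),
         levels = sprintf("class%d", seq_len(K)))
}

#' Simulate a labeled RNA-Seq count dataset
#'
#' Generates matched training and test count matrices with class labels
#' from the negative binomial design described in [sim_config()], plus the
#' ground-truth parameters used to generate them.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"nblda_sim"`: a list with components
#'   `train` and `test` (each a list with `counts`, a genes x samples
#'   matrix, and `y`, a factor of labels), `truth` (list with `s_train`,
#'   `s_test`, `lambda`, `d` (K x G), `phi`, and the logical DE mask
#'   `de_genes`), and `config`.
#' @examples
#' sim <- simulate_counts(sim_config(G = 20, n = 8, de_prop = 0.4,
#'                                   sigma = 2, phi = 1, seed = 1))
#' dim(sim$train$counts)
#' table(sim$train$y)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  seeds <- component_seeds(config$seed, 6L)
  G <- config$G; n <- config$n; K <- config$K

  set.seed(seeds[1L])
  s_train <- stats::runif(n, config$sf_range[1L], config$sf_range[2L])
  set.seed(seeds[2L])
  s_test <- stats::runif(n, config$sf_range[1L], config$sf_range[2L])
  set.seed(seeds[3L])
  lambda <- stats::rexp(G, rate = config$lambda_rate)

  n_de <- round(config$de_prop * G)
  de_genes <- seq_len(G) <= n_de
  set.seed(seeds[4L])
  d <- matrix(1, K, G)
  if (n_de > 0L) {
    d[, de_genes] <- exp(matrix(stats::rnorm(K * n_de, 0, config$sigma), K, n_de))
  }

  gene_ids <- sprintf("gene%d", seq_len(G))
  y <- balanced_labels(n, K)
  dimnames(d) <- list(levels(y), gene_ids)

  draw_set <- function(s, y, seed, prefix) {
    set.seed(seed)
    mu <- (lambda %o% s) * t(d[as.integer(y), , drop = FALSE])  # G x n
    counts <- matrix(nb_draw(G * n, as.vector(mu), config$phi), G, n,
                     dimnames = list(gene_ids, sprintf("%s%d", prefix, seq_len(n))))
    list(counts = as_count_matrix(counts), y = y)
  }

  structure(list(
    train = draw_set(s_train, y, seeds[5L], "train"),
    test = draw_set(s_test, y, seeds[6L], "test"),
    truth = list(s_train = s_train, s_test = s_test, lambda = lambda,
                 d = d, phi = config$phi, de_genes = de_genes),
    config = config
  ), class = "nblda_sim")
}

#' @export
print.nblda_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated dataset: G = %d genes, n = %d + %d samples, K = %d classes\n",
    cfg$G, cfg$n, cfg$n, cfg$K))
  cat(sprintf("  DE genes %.0f%%, sigma = %g, dispersion phi = %g, seed = %d\n",
              100 * cfg$de_prop, cfg$sigma, cfg$phi, cfg$seed))
  invisible(x)
}
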
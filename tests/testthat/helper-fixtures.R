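# Small in-code fixtures shared across test files.

toy_counts <- function(values, G, n) {
  matrix(values, G, n,
         dimnames = list(sprintf("g%d", seq_len(G)), sprintf("s%d", seq_len(n))))
}

# Hand-built model object, bypassing nblda_fit, for direct score checks.
manual_model <- function(lambda, d, pi, phi, class_names = rownames(d),
                         gene_ids = colnames(d)) {
  structure(list(
    lambda = stats::setNames(lambda, gene_ids),
    d = d, pi = pi,
    phi = stats::setNames(phi, gene_ids),
    sf = rep(1 / 2, 2), sf_method = "total",
    sf_stats = list(method = "total", grand_total = sum(lambda)),
    dispersion = NULL, class_names = class_names, gene_ids = gene_ids
  ), class = "nblda")
}

# Random model with positive effects and non-negative dispersions.
# scale = "unit" keeps s*.lambda.d of order 1 (used for Poisson-limit checks,
# where the limit error is first order in phi with coefficient
# sum_g X*_g a_g + a_g^2 / 2).
random_model <- function(seed, G = 10, K = 2, scale = c("counts", "unit")) {
  scale <- match.arg(scale)
  set.seed(seed)
  gene_ids <- sprintf("g%d", seq_len(G))
  class_names <- sprintf("c%d", seq_len(K))
  lambda <- switch(scale,
                   counts = rexp(G, 0.04),
                   unit = runif(G, 0.2, 1.5))
  d <- matrix(exp(rnorm(K * G, 0, if (scale == "unit") 0.3 else 1)),
              K, G, dimnames = list(class_names, gene_ids))
  w <- rgamma(K, 1)
  phi <- rexp(G, 2)
  manual_model(lambda, d, w / sum(w), phi, class_names, gene_ids)
}

# Brute-force Bayes posteriors from the full NB pmf (all constant terms
# included), the independent oracle for the discriminant score.
brute_force_posterior <- function(model, x_star, s_star) {
  K <- length(model$class_names)
  loglik <- vapply(seq_len(K), function(k) {
    mu <- s_star * model$lambda * model$d[k, ]
    ll <- ifelse(model$phi == 0,
                 stats::dpois(x_star, lambda = mu, log = TRUE),
                 stats::dnbinom(x_star, size = 1 / model$phi, mu = mu, log = TRUE))
    # a gene with mu = 0 can only emit a zero count (log-prob 0)
    zero <- mu == 0
    ll[zero] <- ifelse(x_star[zero] == 0, 0, -Inf)
    sum(ll) + log(model$pi[k])
  }, numeric(1L))
  w <- exp(loglik - max(loglik))
  w / sum(w)
}
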
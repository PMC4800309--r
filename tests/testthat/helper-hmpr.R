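# shared fixture builders (all programmatic; no data files)

demo_scr <- function() scr_params(g = 0.8, T_os = 1.2, t_r = 0.7, t_d = 3.5)

demo_sc <- function() sc_params(demo_scr(), a0 = 0.3, c = 2)

# uniformly sampled segment from known truth (+ optional Gaussian noise)
make_trace <- function(truth = demo_sc(), rate = 32, len = 10, noise = 0) {
  tt <- seq(0, by = 1 / rate, length.out = round(rate * len))
  v <- sc_waveform(truth, tt)
  if (noise > 0) v <- v + rnorm(length(v), 0, noise)
  sc_trace(tt, v)
}

# random valid SCR parameter draw (for property-style loops)
random_scr <- function() {
  scr_params(g = runif(1, 0.05, 2), T_os = runif(1, 0, 3),
             t_r = runif(1, 0.2, 2), t_d = runif(1, 0.5, 10))
}

random_sc <- function() {
  sc_params(random_scr(), a0 = runif(1, 0, 1), c = runif(1, 0, 5))
}

# order-3 bivariate polynomial recovery problem (shared by module and
# acceptance tests): truth drawn once from `seed`, n training rows with
# N(0, sigma) noise, plus a noiseless evaluation grid
make_poly3_problem <- function(seed, n = 84, sigma = 0.05) {
  set.seed(seed)
  E <- monomial_exponents(2, 3)
  beta <- runif(nrow(E), 0.5, 2) * sample(c(-1, 1), nrow(E), replace = TRUE)
  X <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  y <- drop(build_design(X, E) %*% beta) + rnorm(n, 0, sigma)
  gx <- seq(-2, 2, length.out = 12)
  Xg <- as.matrix(expand.grid(x1 = gx, x2 = gx))
  yg <- drop(build_design(Xg, E) %*% beta)
  list(exponents = E, beta = beta, X = X, y = y,
       eval_X = Xg, eval_y = yg)
}

# full relative coefficient error of a fitted model against a known truth
# on the full order-p basis (missing/pruned terms count as zero)
coef_rel_errors <- function(fit, exponents, beta, var_names = c("x1", "x2")) {
  labels <- hmpr:::monomial_labels(exponents, var_names)
  full <- stats::setNames(rep(0, nrow(exponents)), labels)
  full[names(coef(fit))] <- coef(fit)
  abs(full - beta) / abs(beta)
}
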
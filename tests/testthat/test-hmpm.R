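test_that("monomial_exponents enumerates the graded basis", {
  expect_identical(monomial_exponents(2, 1),
                   matrix(c(0L, 1L, 0L, 0L, 0L, 1L), ncol = 2))
  expect_identical(monomial_exponents(3, 0), matrix(c(0L, 0L, 0L), 1))
  expect_equal(nrow(monomial_exponents(2, 8)), choose(10, 2))
  # brute-force oracle: filter a full grid of exponent tuples
  for (m in 1:3) for (p in c(0, 2, 5)) {
    grid <- as.matrix(expand.grid(rep(list(0:p), m)))
    expect_equal(nrow(monomial_exponents(m, p)), sum(rowSums(grid) <= p))
    E <- monomial_exponents(m, p)
    expect_false(anyDuplicated(as.data.frame(E)) > 0)
    expect_true(all(diff(rowSums(E)) >= 0))  # graded order
  }
})

test_that("build_design matches the elementwise power-product oracle", {
  expect_equal(build_design(matrix(c(2, 3), 1), matrix(c(1L, 1L), 1)),
               matrix(6, 1))
  E <- monomial_exponents(2, 3)
  expect_equal(build_design(matrix(c(1, 1), 1), E),
               matrix(1, 1, nrow(E)))
  set.seed(9)
  X <- matrix(runif(10, -2, 2), 5, 2)
  D <- build_design(X, E)
  for (i in 1:5) for (k in seq_len(nrow(E)))
    expect_equal(D[i, k], X[i, 1]^E[k, 1] * X[i, 2]^E[k, 2],
                 tolerance = 1e-12)
  expect_error(build_design(matrix(NA_real_, 1, 2), E), "invalid-data")
})

test_that("truncated_ls reproduces pseudoinverse and normal-equation oracles", {
  y <- c(3, -1, 2)
  expect_equal(truncated_ls(diag(3), y)$coefficients, y)
  # rank-deficient: duplicated column; oracle = full-SVD pseudoinverse
  set.seed(13)
  A <- cbind(1, runif(20), runif(20))
  A <- cbind(A, A[, 2])  # duplicate
  yy <- rnorm(20)
  sv <- svd(A)
  dinv <- ifelse(sv$d > 1e-8 * sv$d[1], 1 / sv$d, 0)
  oracle <- drop(sv$v %*% (dinv * drop(crossprod(sv$u, yy))))
  expect_equal(truncated_ls(A, yy)$coefficients, oracle, tolerance = 1e-8)
  # well-conditioned 50 x 6: oracle = normal equations
  A2 <- cbind(1, matrix(rnorm(250), 50, 5))
  y2 <- rnorm(50)
  expect_equal(truncated_ls(A2, y2)$coefficients,
               drop(solve(crossprod(A2), crossprod(A2, y2))),
               tolerance = 1e-8)
  expect_error(truncated_ls(matrix(numeric(0), 0, 2), numeric(0)),
               "empty-data")
  # saturated fit: df = 0 flags p-values undefined
  sat <- truncated_ls(matrix(rnorm(9), 3, 3), rnorm(3))
  expect_true(all(is.na(sat$p_values)))
})

test_that("pruning removes exactly the insignificant terms", {
  set.seed(7)
  X <- cbind(x1 = runif(200, -1, 1), x2 = runif(200, -1, 1))
  y <- 3 + 2 * X[, 1] + rnorm(200, 0, 0.01)
  fit <- fit_hmpm(X, y, 2)
  expect_setequal(names(coef(fit)), c("1", "x1"))
  expect_equal(unname(coef(fit)["1"]), 3, tolerance = 0.01)
  expect_equal(unname(coef(fit)["x1"]), 2, tolerance = 0.01)
  # fully significant model is a fixed point of pruning
  pruned_again <- prune_insignificant(fit)
  expect_identical(names(coef(pruned_again)), names(coef(fit)))
})

test_that("fit_hmpm interpolates exact polynomials and matches MLR at order 1", {
  set.seed(3)
  x <- runif(30, -2, 2)
  y <- 1 - 2 * x + 0.5 * x^2
  fit <- fit_hmpm(matrix(x, ncol = 1), y, 2, prune = FALSE)
  expect_equal(unname(coef(fit)), c(1, -2, 0.5), tolerance = 1e-8)
  # a first-order polynomial model is ordinary multivariate linear regression
  X2 <- cbind(a = rnorm(40), b = rnorm(40))
  y2 <- 1 + 0.5 * X2[, 1] - 2 * X2[, 2] + rnorm(40, 0, 0.2)
  f1 <- fit_hmpm(X2, y2, 1, prune = FALSE)
  lmf <- lm(y2 ~ a + b, data = as.data.frame(X2))
  expect_equal(unname(coef(f1)), unname(coef(lmf)), tolerance = 1e-10)
})

test_that("a seeded noisy cubic in two variables is recovered", {
  prob <- make_poly3_problem(seed = 1)
  fit <- fit_hmpm(prob$X, prob$y, 3)
  expect_lt(max(coef_rel_errors(fit, prob$exponents, prob$beta)), 0.05)
})

test_that("predict evaluates hand-checkable models and round-trips serialization", {
  prob <- make_poly3_problem(seed = 2)
  fit <- fit_hmpm(prob$X, prob$y, 3, target_label = "resp")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hmpm(fit, path)
  back <- read_hmpm(path)
  expect_identical(predict(back, prob$eval_X), predict(fit, prob$eval_X))
  # hand evaluation: intercept 1, slope 2 in x1 -> 1 + 2*3 = 7 at (3, 7)
  hand <- paste(c("# hmpm model serialization v1", "# variables: x1,x2",
                  "# order: 1", "# target: resp",
                  "e_x1\te_x2\tcoefficient\tse\tp_value",
                  "0\t0\t1\tNA\tNA", "1\t0\t2\tNA\tNA"), collapse = "\n")
  path2 <- withr::local_tempfile(lines = hand)
  m <- read_hmpm(path2)
  expect_equal(predict(m, matrix(c(3, 7), 1)), 7)
  expect_error(predict(m, matrix(1, 2, 3)), "schema")
})

test_that("model files with inconsistent content are rejected", {
  bad <- paste(c("# hmpm model serialization v1", "# variables: x1,x2",
                 "# order: 2", "# target: valence",
                 "e_x1\te_x2\tcoefficient\tse\tp_value",
                 "1\t0\t2\tNA\tNA", "1\t0\t3\tNA\tNA"), collapse = "\n")
  path <- withr::local_tempfile(lines = bad)
  expect_error(read_hmpm(path), "duplicate exponent")
  over <- sub("1\t0\t3", "2\t1\t3", bad)
  path2 <- withr::local_tempfile(lines = over)
  expect_error(read_hmpm(path2), "exceeds declared order")
  ok <- sub("1\t0\t3", "0\t1\t3", bad)
  path3 <- withr::local_tempfile(lines = ok)
  expect_error(load_published_model(path3, "arousal"), "targets 'valence'")
  expect_s3_class(load_published_model(path3, "valence"), "hmpm")
})

test_that("select_order picks the generating order of a noisy cubic", {
  prob <- make_poly3_problem(seed = 1)
  single <- select_order(prob$X, prob$y, orders = 4)
  expect_equal(single$best_order, 4)
  sel <- select_order(prob$X, prob$y, 1:6, fit_config(),
                      prob$eval_X, prob$eval_y)
  expect_equal(sel$best_order, 3)
  expect_equal(nrow(sel$reports), 6)
  expect_true(all(diff(sel$reports$order) == 1))
})

test_that("gradient matches hand cases and central finite differences", {
  hand <- paste(c("# hmpm model serialization v1", "# variables: g,t_d",
                  "# order: 1", "# target: valence",
                  "e_g\te_t_d\tcoefficient\tse\tp_value",
                  "0\t0\t4\tNA\tNA", "1\t0\t1\tNA\tNA", "0\t1\t2\tNA\tNA"),
                collapse = "\n")
  lin <- read_hmpm(withr::local_tempfile(lines = hand))
  expect_equal(gradient(lin, c(0.3, 2.5)), c(g = 1, t_d = 2))
  const <- read_hmpm(withr::local_tempfile(lines = paste(
    c("# hmpm model serialization v1", "# variables: g,t_d", "# order: 0",
      "# target: valence", "e_g\te_t_d\tcoefficient\tse\tp_value",
      "0\t0\t5\tNA\tNA"), collapse = "\n")))
  expect_equal(gradient(const, c(1, 1)), c(g = 0, t_d = 0))
  # order-5 seeded model vs central differences
  set.seed(31)
  X <- cbind(x1 = runif(60, -1.5, 1.5), x2 = runif(60, -1.5, 1.5))
  E <- monomial_exponents(2, 5)
  y <- drop(build_design(X, E) %*% rnorm(nrow(E))) + rnorm(60, 0, 0.01)
  fit <- fit_hmpm(X, y, 5, fit_config(significance_level = 0.5))
  pts <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  G <- gradient(fit, pts)
  h <- 1e-6
  for (v in 1:2) {
    Pp <- pts; Pm <- pts
    Pp[, v] <- Pp[, v] + h; Pm[, v] <- Pm[, v] - h
    fd <- (predict(fit, Pp) - predict(fit, Pm)) / (2 * h)
    expect_equal(G[, v], fd, tolerance = 1e-4)
  }
})

test_that("gradient_field evaluates the grid and rejects empty grids", {
  hand <- paste(c("# hmpm model serialization v1", "# variables: g,t_d",
                  "# order: 1", "# target: valence",
                  "e_g\te_t_d\tcoefficient\tse\tp_value",
                  "0\t0\t4\tNA\tNA", "1\t0\t1\tNA\tNA", "0\t1\t2\tNA\tNA"),
                collapse = "\n")
  lin <- read_hmpm(withr::local_tempfile(lines = hand))
  gf <- gradient_field(lin, c(0, 0), c(1, 1), n = 3)
  expect_equal(nrow(gf), 9)
  expect_true(all(gf$d_g == 1) && all(gf$d_t_d == 2))
  expect_equal(gf$value, 4 + gf$g + 2 * gf$t_d)
  expect_error(gradient_field(lin, c(0, 0), c(1, 1), n = 0), "empty grid")
  expect_error(gradient_field(lin, 0, c(1, 1)), "schema")
})

test_that("polynomial fits satisfy their least-squares invariants", {
  prob <- make_poly3_problem(seed = 4)
  # residual orthogonality to retained design columns
  fit <- fit_hmpm(prob$X, prob$y, 3)
  D <- build_design(prob$X, fit$exponents)
  expect_lt(max(abs(crossprod(D, residuals(fit)))), 1e-6)
  # nesting: unpruned training MSE never grows with the order
  msep <- vapply(1:5, function(p) {
    f <- fit_hmpm(prob$X, prob$y, p, prune = FALSE)
    mean(residuals(f)^2)
  }, numeric(1))
  expect_true(all(diff(msep) <= 1e-10))
  # truncated LS equals plain LS on well-conditioned problems
  A <- cbind(1, matrix(rnorm(120), 40, 3))
  yy <- rnorm(40)
  expect_equal(truncated_ls(A, yy, 1e-8)$coefficients,
               drop(solve(crossprod(A), crossprod(A, yy))),
               tolerance = 1e-10)
})

test_that("coefficient RMSE shrinks as the training size grows", {
  rmse_at <- function(n) {
    set.seed(77)
    E <- monomial_exponents(2, 2)
    beta <- c(1, 0.8, -0.6, 0.4, 0.5, -0.3)
    X <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
    y <- drop(build_design(X, E) %*% beta) + rnorm(n, 0, 0.3)
    fit <- fit_hmpm(X, y, 2, prune = FALSE)
    sqrt(mean((coef(fit) - beta)^2))
  }
  errs <- vapply(c(50, 200, 1000), rmse_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("hmpm formula interface, summary and simulate behave", {
  tab <- generate_feature_table(default_affective_config(seed = 3))
  fit <- hmpm(valence ~ gain + decay_time_constant, tab, order = 2)
  expect_s3_class(fit, "hmpm")
  expect_identical(fit$target_label, "valence")
  expect_equal(predict(fit, tab), fitted(fit))
  s <- summary(fit)
  expect_true(all(c("Estimate", "Pr(>|t|)") %in% colnames(s$coefficients)))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(tab), 3L))
})
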
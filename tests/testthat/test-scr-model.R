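test_that("scr_waveform scales with gain and decays to zero", {
  tt <- seq(0, 10, by = 0.1)
  expect_equal(scr_waveform(scr_params(0, 1, 0.5, 4), tt), rep(0, length(tt)))
  # exponential decay limit far past onset
  expect_lt(scr_waveform(scr_params(1, 1, 0.5, 4), 1e3), 1e-3)
  expect_error(scr_waveform(scr_params(1, 1, 0.5, 4) * NA, tt),
               "invalid-parameter")
  expect_error(scr_params(-1, 1, 0.5, 4), "invalid-parameter")
  expect_error(scr_params(1, 1, 0, 4), "invalid-parameter")
})

test_that("scr_waveform is non-negative and vanishing at infinity for random draws", {
  set.seed(101)
  for (k in 1:25) {
    p <- random_scr()
    f <- scr_waveform(p, seq(0, 12, by = 0.05))
    expect_true(all(f >= 0))
    expect_lt(scr_waveform(p, 500), 1e-6)
  }
})

test_that("scr_waveform peak matches the dense-grid oracle fixture", {
  # frozen from numerical maximization of the implemented form on a
  # 1e-4 s grid over [0, 10] for g=0.8, T_os=1.2, t_r=0.7, t_d=3.5
  p <- demo_scr()
  tt <- seq(0, 10, by = 1e-3)
  f <- scr_waveform(p, tt)
  expect_equal(tt[which.max(f)], 2.1704, tolerance = 1e-3)
  expect_equal(max(f), 0.485029301280, tolerance = 1e-6)
})

test_that("sc_waveform adds tail and tonic terms to the pure SCR", {
  tt <- seq(0, 10, by = 0.05)
  scr <- demo_scr()
  expect_identical(sc_waveform(sc_params(scr, 0, 0), tt),
                   scr_waveform(scr, tt))
  expect_equal(sc_waveform(sc_params(scr_params(0, 1, 0.5, 3), 0, 2.5), tt),
               rep(2.5, length(tt)))
  # both phasic terms decay: limit is the tonic level
  full <- sc_params(scr, a0 = 0.4, c = 1.7)
  expect_equal(sc_waveform(full, 1e3), 1.7, tolerance = 1e-3)
})

test_that("sc_waveform decomposes additively for random parameter draws", {
  set.seed(202)
  tt <- seq(0, 10, by = 0.1)
  for (k in 1:20) {
    p <- random_sc()
    tail_term <- p[["a0"]] * exp(-tt / p[["t_d"]])
    expect_equal(sc_waveform(p, tt) - p[["c"]] - tail_term,
                 scr_waveform(p[c("g", "T_os", "t_r", "t_d")], tt),
                 tolerance = 1e-12)
  }
})

test_that("average_segments is the pointwise mean across subjects", {
  tr <- make_trace()
  expect_equal(average_segments(list(tr))$values, tr$values)
  neg <- sc_trace(tr$times, -tr$values)
  expect_equal(average_segments(list(tr, neg))$values,
               rep(0, length(tr$times)))
  # 27 synthetic subject traces against an explicit summation oracle
  set.seed(303)
  subj <- lapply(1:27, function(i) make_trace(random_sc(), noise = 0.02))
  oracle <- Reduce(`+`, lapply(subj, `[[`, "values")) / 27
  expect_equal(average_segments(subj)$values, oracle, tolerance = 1e-12)
})

test_that("average_segments rejects incompatible or empty input", {
  tr <- make_trace()
  short <- sc_trace(tr$times[1:50], tr$values[1:50])
  expect_error(average_segments(list(tr, short)), "incompatible-traces")
  expect_error(average_segments(list()), "empty-input")
  other_rate <- make_trace(rate = 16)
  expect_error(average_segments(list(tr, other_rate)), "incompatible")
})

test_that("initial_guess handles degenerate traces and stays feasible", {
  flat <- sc_trace(seq(0, 5, by = 0.1), rep(4, 51))
  g0 <- initial_guess(flat)
  expect_equal(g0[["c"]], 4)
  expect_equal(g0[["a0"]], 0)
  expect_equal(g0[["g"]], 0)
  expect_gt(g0[["t_r"]], 0)
  expect_gt(g0[["t_d"]], 0)
  single <- sc_trace(0, 2.2)
  expect_equal(initial_guess(single)[["c"]], 2.2)
})

test_that("fit_sc_segment keeps the truth as a fixed point", {
  truth <- demo_sc()
  tr <- make_trace(truth)
  fit <- fit_sc_segment(tr, init = truth)
  expect_lt(fit$sse, 1e-10)
  expect_equal(unclass(fit$params), unclass(truth), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 20)
})

test_that("fit_sc_segment recovers noiseless truth from the heuristic start", {
  # 20 seeded parameter sets, init = initial_guess(trace)
  cfg <- default_affective_config(seed = 17, trace_noise_sd = 0)
  for (x in generate_sc_traces(cfg, n = 20)) {
    fit <- fit_sc_segment(x$trace, max_iterations = 100)
    rel <- abs((coef(fit) - unclass(x$truth)) / unclass(x$truth))
    expect_lt(max(rel), 0.01)
  }
})

test_that("noisy Monte-Carlo recovery keeps gain and decay within 10%", {
  # sigma = 0.01 uS, 100 samples at 10 Hz, 20 replicates
  set.seed(42)
  truth <- demo_sc()
  tt <- seq(0, by = 0.1, length.out = 100)
  errs <- t(replicate(20, {
    tr <- sc_trace(tt, sc_waveform(truth, tt) + rnorm(100, 0, 0.01))
    est <- coef(fit_sc_segment(tr, max_iterations = 100))
    c(abs(est[["g"]] - truth[["g"]]) / truth[["g"]],
      abs(est[["t_d"]] - truth[["t_d"]]) / truth[["t_d"]])
  }))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("fit_sc_segment never increases the SSE relative to its start", {
  set.seed(404)
  tr <- make_trace(demo_sc(), noise = 0.02)
  for (k in 1:10) {
    init <- random_sc()
    sse_init <- sum((tr$values - sc_waveform(init, tr$times))^2)
    fit <- fit_sc_segment(tr, init = init, max_iterations = 15)
    expect_lte(fit$sse, sse_init + 1e-12)
    expect_lte(fit$iterations, 15)
  }
})

test_that("median noiseless recovery error over 50 seeded traces is tiny", {
  cfg <- default_affective_config(seed = 23, trace_noise_sd = 0)
  errs <- vapply(generate_sc_traces(cfg, n = 50), function(x) {
    fit <- fit_sc_segment(x$trace, max_iterations = 100)
    max(abs((coef(fit) - unclass(x$truth)) / unclass(x$truth)))
  }, numeric(1))
  expect_lt(median(errs), 1e-3)
})

test_that("fit_sc_segment rejects underdetermined segments", {
  tiny <- sc_trace(seq(0, 0.5, by = 0.1), rep(1, 6))
  expect_error(fit_sc_segment(tiny), "underdetermined-fit")
  flat <- sc_trace(seq(0, 2, by = 0.1), rep(3, 21))
  expect_no_error(fit_sc_segment(flat, max_iterations = 5))
})
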
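test_that("extend_column enumerates all unordered pairs deterministically", {
  ext <- extend_column(rnorm(8))
  expect_length(ext$values, 28)
  expect_equal(nrow(ext$pair_index), 28)
  expect_false(anyDuplicated(ext$pair_index) > 0)
  expect_true(all(ext$pair_index[, 1] < ext$pair_index[, 2]))
  # lexicographic: first pairs share the smallest first index
  expect_equal(ext$pair_index[1:7, 1], rep(1L, 7))
  expect_equal(ext$pair_index[1:7, 2], 2:8)
})

test_that("extend_column fixed points and hand-evaluated fixture", {
  expect_equal(extend_column(c(1, 1, 1))$values, rep(1, 3))
  # hand evaluation for {1,2,3}: xbar = 2, eta = 2 + (xi_i+xi_j-4)/sqrt(2)
  expect_equal(extend_column(c(1, 2, 3))$values,
               c(2 - 1 / sqrt(2), 2, 2 + 1 / sqrt(2)), tolerance = 1e-12)
  expect_error(extend_column(1), "too-few-values")
  expect_error(extend_column(c(1, NA, 3)), "finite")
})

test_that("extended values keep the theorem's moments and correlations under known mu", {
  set.seed(11)
  R <- 10000; n <- 8
  S <- matrix(rnorm(R * n, 5, 2), R, n)
  # per-replicate extension with the known population mean
  eta <- t(apply(S, 1, function(x) extend_column(x, mu = 5)$values))
  idx <- t(combn(n, 2))
  k12 <- which(idx[, 1] == 1 & idx[, 2] == 2)
  k13 <- which(idx[, 1] == 1 & idx[, 2] == 3)
  k34 <- which(idx[, 1] == 3 & idx[, 2] == 4)
  # claim 1: mean mu and variance sigma^2 (3 SE bands)
  se_mean <- sd(eta[, k12]) / sqrt(R)
  expect_lt(abs(mean(eta[, k12]) - 5), 3 * se_mean)
  se_var <- sqrt(2 * 16 / R)
  expect_lt(abs(var(eta[, k12]) - 4), 3 * se_var)
  # claim 2: overlapping pairs correlate at 0.5, disjoint at 0
  expect_lt(abs(cor(eta[, k12], eta[, k13]) - 0.5), 0.02)
  expect_lt(abs(cor(eta[, k12], eta[, k34])), 0.02)
  # claim 3: source correlation 1/sqrt(2), non-source 0
  expect_lt(abs(cor(eta[, k12], S[, 1]) - 1 / sqrt(2)), 0.02)
  expect_lt(abs(cor(eta[, k12], S[, 5])), 0.02)
})

test_that("extend_table produces per-class all-pairs rows with shared pairing", {
  tab <- generate_feature_table(default_affective_config(seed = 2))
  sim <- extend_table(tab)
  expect_equal(nrow(sim), 3 * choose(8, 2))
  expect_true(all(sim$provenance == "simulated"))
  expect_true(all(table(sim$affect_class) == 28))
  # the SAME source pair feeds every column of a simulated row
  cls <- "pleasant"
  src <- tab[tab$affect_class == cls, ]
  row1 <- sim[sim$affect_class == cls & sim$source_pair == "1-2", ]
  for (col in c("gain", "decay_time_constant", "valence", "arousal")) {
    v <- src[[col]]
    expect_equal(row1[[col]],
                 mean(v) + (v[1] + v[2] - 2 * mean(v)) / sqrt(2),
                 tolerance = 1e-12)
  }
  # per-class per-column mean of the simulated rows equals the source mean
  for (cls in unique(tab$affect_class)) {
    expect_equal(mean(sim$gain[sim$affect_class == cls]),
                 mean(tab$gain[tab$affect_class == cls]), tolerance = 1e-10)
  }
})

test_that("extend_table keeps zero-variance classes fixed and checks schema", {
  tab <- data.frame(stimulus_id = paste0("s", 1:4),
                    affect_class = "neutral",
                    onset_time = 1.5, gain = 0.4, rise_time = 0.8,
                    decay_time_constant = 3, valence = 5, arousal = 4,
                    provenance = "experimental")
  sim <- extend_table(tab)
  expect_equal(nrow(sim), choose(4, 2))
  expect_true(all(sim$gain == 0.4) && all(sim$valence == 5))
  expect_error(extend_table(tab, group_column = "nope"), "schema")
})

test_that("a noiseless linear relation between columns survives extension exactly", {
  set.seed(5)
  g <- runif(8, 0.2, 1)
  tab <- data.frame(stimulus_id = paste0("s", 1:8), affect_class = "a",
                    gain = g, valence = pmin(pmax(2 * g + 3, 1), 9),
                    provenance = "experimental")
  sim <- extend_table(tab, columns = c("gain", "valence"))
  expect_equal(sim$valence, 2 * sim$gain + 3, tolerance = 1e-12)
  expect_equal(cor(sim$gain, sim$valence, method = "spearman"), 1)
})
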
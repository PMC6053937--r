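test_that("Jacobs transform maps [-1,1] onto [0,1] linearly and validates input", {
  expect_equal(jacobs_transform(c(-1, 0, 1)), c(0, 0.5, 1))
  m <- matrix(c(-0.5, 0.5), 1, 2)
  expect_equal(jacobs_transform(m), (m + 1) / 2)
  expect_error(jacobs_transform(1.2), "\\[-1, 1\\]")
  expect_error(jacobs_transform(NA_real_), "missing")
})

test_that("alarm propensity is the per-cell alarm proportion; empty cells stay NA", {
  tr <- make_trials(c("a", "a", "b"), c("p1", "p2", "p1"),
                    n = c(9, 10, 4), alarms = c(9, 3, 2))
  est <- estimate_alarm_propensity(tr)
  expect_equal(est$I["p1", "a"], 1.0)
  expect_equal(est$I["p2", "a"], 0.3)
  expect_equal(est$I["p1", "b"], 0.5)
  expect_true(is.na(est$I["p2", "b"]))   # no trials: flagged, not imputed
  expect_equal(est$n_trials["p2", "b"], 0L)
  expect_error(estimate_alarm_propensity(tr[0, ]), "empty")
})

test_that("call profile normalises per-predator alarm rates, not raw counts", {
  # one-hot: alarms only to one predator
  tr <- make_trials(c("a", "a"), c("p1", "p2"), n = c(8, 8), alarms = c(6, 0))
  C <- estimate_call_profile(tr)
  expect_equal(unname(C[, "a"]), c(1, 0))
  # equal rates with unequal trial counts still give a uniform profile
  tr2 <- make_trials(c("a", "a"), c("p1", "p2"), n = c(10, 20),
                     alarms = c(5, 10))
  C2 <- estimate_call_profile(tr2)
  expect_equal(unname(C2[, "a"]), c(0.5, 0.5))
  # caller with zero alarms anywhere: column undefined, flagged
  tr3 <- rbind(tr2, make_trials(c("b", "b"), c("p1", "p2"),
                                n = c(5, 5), alarms = c(0, 0)))
  C3 <- estimate_call_profile(tr3)
  expect_true(all(is.na(C3[, "b"])))
  expect_identical(attr(C3, "undefined_callers"), "b")
  expect_equal(colSums(C3[, "a", drop = FALSE]), c(a = 1))
})

test_that("consistency and reliability match explicit loop summation", {
  for (s in 1:5) {
    cfg <- random_index_config(s, n_receivers = 4, n_predators = 5,
                               n_callers = 3)
    L <- caller_consistency(cfg$I, cfg$eps, cfg$A)
    expect_equal(unname(unclass(L)), oracle_consistency(cfg$I, cfg$eps, cfg$A),
                 tolerance = 1e-12, ignore_attr = TRUE)
    Lu <- caller_consistency(cfg$I, cfg$eps, cfg$A, normalize = FALSE)
    expect_equal(unname(unclass(Lu)),
                 oracle_consistency(cfg$I, cfg$eps, cfg$A, normalize = FALSE),
                 tolerance = 1e-12, ignore_attr = TRUE)
    C <- sweep(cfg$I, 2, colSums(cfg$I), "/")
    V <- call_reliability(C, cfg$eps)
    expect_equal(unname(unclass(V)), oracle_reliability(C, cfg$eps),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("index limits: perfect informant, silent species, degenerate profiles", {
  cfg <- random_index_config(7, 4, 5, 3)
  ones <- cfg$I; ones[] <- 1
  expect_equal(unname(unclass(caller_consistency(ones, cfg$eps, cfg$A))),
               matrix(1, 4, 3), ignore_attr = TRUE)
  zeros <- cfg$I; zeros[] <- 0
  expect_equal(unname(unclass(caller_consistency(zeros, cfg$eps, cfg$A))),
               matrix(0, 4, 3), ignore_attr = TRUE)
  # one-hot call profile: V equals the vulnerability to that predator
  C <- matrix(0, 5, 3); C[2, ] <- 1
  V <- call_reliability(C, cfg$eps)
  for (j in 1:3) expect_equal(unname(V[, j]), unname(cfg$eps[, 2]))
  # constant vulnerability: V constant whatever the profile
  epsc <- cfg$eps; epsc[] <- 0.37
  Cr <- sweep(cfg$I, 2, colSums(cfg$I), "/")
  expect_equal(unname(unclass(call_reliability(Cr, epsc))),
               matrix(0.37, 4, 3), ignore_attr = TRUE)
})

test_that("index properties: bounds, monotonicity, predator-label permutation", {
  set.seed(11)
  for (s in 1:40) {
    cfg <- random_index_config(100 + s)
    L <- caller_consistency(cfg$I, cfg$eps, cfg$A)
    C <- sweep(cfg$I, 2, colSums(cfg$I), "/")
    V <- call_reliability(C, cfg$eps)
    expect_true(all(L >= 0 & L <= 1))
    expect_true(all(V >= 0 & V <= 1))
    # raising one propensity entry never lowers any consistency
    I2 <- cfg$I
    x <- sample(nrow(I2), 1); j <- sample(ncol(I2), 1)
    I2[x, j] <- min(1, I2[x, j] + 0.3)
    expect_true(all(caller_consistency(I2, cfg$eps, cfg$A) >= L - 1e-12))
    # raising a vulnerability entry never lowers reliability (C fixed)
    e2 <- cfg$eps
    i <- sample(nrow(e2), 1); x2 <- sample(ncol(e2), 1)
    e2[i, x2] <- min(1, e2[i, x2] + 0.3)
    expect_true(all(call_reliability(C, e2) >= V - 1e-12))
    # permuting predator labels consistently leaves L and V unchanged
    p <- sample(nrow(cfg$I))
    Lp <- caller_consistency(cfg$I[p, ], cfg$eps[, p], cfg$A[p])
    Vp <- call_reliability(C[p, ], cfg$eps[, p])
    expect_equal(unclass(Lp), unclass(L), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unclass(Vp), unclass(V), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("normalized and raw consistency rank callers identically per receiver", {
  for (s in 1:20) {
    cfg <- random_index_config(300 + s)
    Ln <- caller_consistency(cfg$I, cfg$eps, cfg$A)
    Lu <- caller_consistency(cfg$I, cfg$eps, cfg$A, normalize = FALSE)
    for (i in seq_len(nrow(Ln)))
      expect_equal(order(Ln[i, ]), order(Lu[i, ]))
  }
})

test_that("consistency flags receivers with zero encounter-weighted vulnerability", {
  cfg <- random_index_config(9, 3, 4, 2)
  cfg$eps[2, ] <- 0
  L <- caller_consistency(cfg$I, cfg$eps, cfg$A)
  expect_true(all(is.na(L[2, ])))
  expect_identical(attr(L, "undefined_receivers"), rownames(cfg$eps)[2])
})

test_that("body-size ratio follows the asymmetric two-branch form", {
  expect_equal(body_size_ratio(100, 100), 1)
  expect_equal(body_size_ratio(100, 50), 2)
  expect_equal(body_size_ratio(50, 100), 0)
  # continuity at equality and correct sides
  expect_true(body_size_ratio(100.01, 100) > 1)
  expect_true(body_size_ratio(99.99, 100) < 1)
  expect_true(body_size_ratio(10, 500) < 0)
  expect_error(body_size_ratio(-1, 5), "positive")
})

test_that("unit-interval scaling is affine, order-preserving, and rejects constants", {
  expect_equal(scale_unit_interval(c(1, 2, 3)), c(0, 0.5, 1))
  v <- c(-38, -10, 0, 1.5, 2)
  s <- scale_unit_interval(v)
  expect_equal(range(s), c(0, 1))
  set.seed(4)
  x <- rnorm(50)
  expect_equal(rank(scale_unit_interval(x)), rank(x))
  expect_error(scale_unit_interval(rep(2, 5)), "constant|degenerate")
})

test_that("derive_indices ties the pieces together consistently", {
  cm <- generate_community(5)
  tr <- simulate_predator_trials(cm, 30, seed = 6)
  ix <- derive_indices(cm, tr)
  expect_equal(dim(ix$L), c(12, 12))
  nonvocal <- names(cm$vocal)[!cm$vocal]
  expect_true(all(ix$L[, nonvocal] == 0))         # silent species informs never
  expect_true(all(is.na(ix$V[, nonvocal])))       # no calls, no reliability
  expect_equal(diag(ix$size_ratio), rep(1, 12), ignore_attr = TRUE)
  # true-propensity route agrees with estimates as trial counts grow
  ix0 <- derive_indices(cm)
  expect_lt(max(abs(ix0$L[, cm$vocal] - ix$L[, cm$vocal])), 0.2)
})
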
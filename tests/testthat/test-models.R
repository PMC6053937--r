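test_that("covariate standardization centres, scales, records, and validates", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 10, 40))
  s <- standardize_covariates(d, c("a", "b"))
  expect_equal(s$a, c(-1, 0, 1))
  expect_equal(mean(s$b), 0)
  expect_equal(sd(s$b), 1)
  expect_equal(attr(s, "standardization")$a, c(center = 2, scale = 1))
  s2 <- standardize_covariates(s, "a")
  expect_equal(s2$a, s$a, tolerance = 1e-12)
  expect_error(standardize_covariates(d, "zzz"), "zzz")
  expect_error(standardize_covariates(data.frame(a = rep(1, 4)), "a"),
               "zero SD")
})

test_that("AICc matches its closed form, limits to AIC, and guards n <= k+1", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  expect_equal(aicc(-50, 4, 1e9), -2 * -50 + 8, tolerance = 1e-6)
  set.seed(31)
  for (r in 1:20) {
    ll <- rnorm(1, -100, 20); k <- sample(1:6, 1); n <- k + 1 + sample(5:50, 1)
    expect_equal(aicc(ll, k, n), -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
  expect_error(aicc(-10, 5, 6), "n > k \\+ 1")
})

test_that("model specs enforce marginality and build the right formulas", {
  expect_error(model_spec("y", "binomial", c("a:b", "a")), "marginality")
  expect_error(model_spec("y", "binomial", "I(x^2)"), "marginality")
  sp <- model_spec("y", "lognormal", c("a", "b", "a:b"), "g")
  expect_equal(deparse(alarmnet:::spec_formula(sp)),
               "log(y) ~ a + b + a:b + (1 | g)")
})

test_that("candidate enumeration respects marginality and matches a counting oracle", {
  base <- model_spec("y", "binomial", c("a", "b"))
  expect_length(build_candidate_set(base), 4)
  withint <- model_spec("y", "binomial", c("a", "b", "a:b"))
  cands <- build_candidate_set(withint)
  expect_length(cands, 5)   # {}, {a}, {b}, {a,b}, {a,b,ab}
  for (cd in cands)
    if ("a:b" %in% cd$fixed_terms)
      expect_true(all(c("a", "b") %in% cd$fixed_terms))
  # independent oracle: filter the full power set with a different mechanism
  full <- model_spec("response", "binomial", alarmnet:::response_model_terms(),
                     "receiver")
  terms <- full$fixed_terms
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(terms)))
  names(combos) <- terms
  legal <- apply(combos, 1, function(row) {
    inset <- terms[as.logical(row)]
    all(vapply(inset, function(t_)
      all(alarmnet:::closure_requires(t_) %in% inset), logical(1)))
  })
  expect_length(build_candidate_set(full), sum(legal))
  # complexity cap
  expect_true(all(lengths(lapply(build_candidate_set(withint, max_terms = 1),
                                 `[[`, "fixed_terms")) <= 1))
})

test_that("AICc selection finds a strong predictor and reports a sorted table", {
  set.seed(41)
  n <- 2000
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(2 * d$x1))
  full <- model_spec("y", "binomial", c("x1", "x2"))
  sel <- select_model(build_candidate_set(full), d)
  expect_true("x1" %in% sel$best$spec$fixed_terms)
  expect_true(!is.unsorted(sel$table$aicc))
  expect_equal(sel$table$delta_aicc[1], 0)
  # single candidate returns trivially
  one <- select_model(model_spec("y", "binomial", "x1"), d)
  expect_equal(one$best$spec$fixed_terms, "x1")
  # AICc ranking invariant to covariate relabeling
  d2 <- d; names(d2) <- c("p", "q", "y")
  full2 <- model_spec("y", "binomial", c("p", "q"))
  sel2 <- select_model(build_candidate_set(full2), d2)
  expect_equal(sel2$table$aicc, sel$table$aicc, tolerance = 1e-8)
})

test_that("standardizing covariates rescales coefficients without changing fit", {
  set.seed(43)
  n <- 500
  d <- data.frame(x = runif(n, 0, 40), z = rnorm(n, 10, 3))
  d$y <- rbinom(n, 1, plogis(0.05 * d$x - 0.1 * d$z))
  raw <- fit_model(model_spec("y", "binomial", c("x", "z")), d)
  ds <- standardize_covariates(d, c("x", "z"))
  std <- fit_model(model_spec("y", "binomial", c("x", "z")), ds)
  expect_equal(raw$loglik, std$loglik, tolerance = 1e-8)
  sx <- attr(ds, "standardization")$x["scale"]
  expect_equal(unname(std$coefficients$estimate[std$coefficients$term == "x"]),
               unname(raw$coefficients$estimate[raw$coefficients$term == "x"] * sx),
               tolerance = 1e-6)
})

test_that("with zero random-intercept SD, mixed and fixed fits agree", {
  cm <- generate_community(51, overrides = list(ranef_sd = 0))
  ix <- derive_indices(cm)
  S <- alarmnet:::community_similarity(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 60, seed = 52)
  d <- prepare_playback_covariates(
    pb[pb$call_kind == "heterospecific", ], ix, S)
  d <- d[!is.na(d$similarity), ]
  d$response <- as.numeric(d$responded)
  terms <- alarmnet:::response_model_terms()
  mixed <- fit_model(model_spec("response", "binomial", terms, "receiver"), d)
  fixed <- fit_model(model_spec("response", "binomial", terms), d)
  m <- mixed$coefficients$estimate[match(fixed$coefficients$term,
                                         mixed$coefficients$term)]
  expect_lt(max(abs(m - fixed$coefficients$estimate)), 1e-3)
})

test_that("the alarm-production model recovers a coupled vulnerability slope", {
  cm <- generate_community(53, propensity_coupling = list(slope = 1.76))
  tr <- simulate_predator_trials(cm, 9, seed = 54)
  f <- fit_alarm_model(tr, cm$vulnerability)
  expect_s3_class(f, "alarm_fit")
  expect_equal(nrow(f$vulnerability_coef), 1)
  # determinism: identical data give identical fits
  f2 <- fit_alarm_model(tr, cm$vulnerability)
  expect_equal(f$coefficients, f2$coefficients)
  # null case: propensity unrelated to vulnerability (species-level baseline
  # only) gives |z| < 1.96 in >= 90% of replicates
  hits <- 0
  for (r in 1:50) {
    cmr <- generate_community(600 + r,
                              propensity_coupling = list(slope = 0,
                                                         cell_sd = 0))
    trr <- simulate_predator_trials(cmr, 9, seed = 700 + r)
    fr <- fit_alarm_model(trr, cmr$vulnerability)
    if (abs(fr$vulnerability_coef$statistic) < 1.96) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("the preliminary call-type model contrasts alarms against control", {
  b <- null_betas(); b["intercept"] <- 0.85; b["control"] <- -3
  cm <- generate_community(55, overrides = list(true_betas = b))
  ix <- derive_indices(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 14, seed = 56)
  pre <- preliminary_calltype_model(pb)
  expect_equal(nrow(pre$contrasts), 2)
  expect_true(all(pre$contrasts$estimate > 0))
  expect_true(all(pre$contrasts$p_value < 0.05))
  expect_equal(sum(pre$data$call_kind == "control"), 0)
  expect_error(preliminary_calltype_model(
    pb[pb$call_kind != "control", ]), "absent")
})

test_that("the response-model suite fits all six responses with shared terms", {
  cm <- generate_community(57)
  ix <- derive_indices(cm)
  S <- alarmnet:::community_similarity(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 12, seed = 58)
  pb <- pb[pb$call_kind != "control", ]
  suite <- fit_response_models(pb, ix, S, nagq = 0)
  expect_named(suite, c("probability", "latency", "duration", "headlift",
                        "head_ups", "scratches"))
  expect_true(all(vapply(suite, function(f) f$converged, logical(1))))
  # duration model excludes censored trials
  expect_lt(suite$duration$n, suite$latency$n + 1)
  # conspecific trials excluded by default
  expect_lt(suite$probability$n, sum(pb$call_kind == "heterospecific") + 1)
  # lognormal models carry LRT p-values for droppable terms
  lat <- suite$latency$coefficients
  expect_true(any(!is.na(lat$p_value[lat$term == "consistency"])))
  expect_true(is.na(lat$p_value[lat$term == "size_ratio"]))  # locked by marginality
  expect_error(fit_response_models(
    simulate_playbacks(cm, ix, n_per_pair = 2, seed = 2), ix, S),
    "control trials")
})

test_that("Wilcoxon control check matches the exact signed-rank distribution", {
  # identical pairs: degenerate, no signal
  res <- wilcoxon_control_check(rep(1, 8), rep(1, 8))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  # all positive differences, n = 10: V is the maximum n(n+1)/2 = 55
  set.seed(61)
  base <- runif(10)
  res2 <- wilcoxon_control_check(base + runif(10, 0.1, 1), base)
  expect_equal(res2$V, 55)
  # exact enumeration oracle over all 2^n sign assignments (n = 8)
  ctrl <- c(0.9, 0.3, 1.8, 0.05, 1.1, 0.6, 0.45, 1.4)
  basl <- c(0.2, 0.7, 0.9, 0.5, 0.35, 0.55, 1.0, 0.8)
  d <- ctrl - basl
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  Vs <- as.matrix(signs) %*% rk
  p_oracle <- mean(Vs >= max(V, sum(rk) - V) | Vs <= min(V, sum(rk) - V))
  res3 <- wilcoxon_control_check(ctrl, basl)
  expect_equal(res3$V, V)
  expect_equal(res3$p, p_oracle)
  expect_error(wilcoxon_control_check(1:3, c(-1, 2, 3)), "nonnegative")
  expect_error(wilcoxon_control_check(1:3, 1:4), "paired")
})
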
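test_that("community generation has the right shapes and is seed-deterministic", {
  cm <- generate_community(1, 12, 5)
  expect_length(cm$body_mass_kg, 12)
  expect_length(cm$predator_abundance, 5)
  expect_equal(dim(cm$jacobs_matrix), c(12, 5))
  expect_equal(dim(cm$alarm_propensity), c(5, 12))
  expect_identical(generate_community(1, 12, 5), cm)
  expect_false(identical(generate_community(2, 12, 5), cm))
  expect_silent(validate_community(cm))
  expect_error(generate_community(1, 1, 5), ">= 2")
})

test_that("overrides are applied and validated with the offending field named", {
  cm <- generate_community(3, overrides = list(control_rate = 0.1))
  expect_equal(cm$control_rate, 0.1)
  bad <- generate_community(3)
  bad_masses <- bad$body_mass_kg; bad_masses[1] <- -5
  expect_error(
    validate_community(generate_community(3,
      overrides = list(body_mass_kg = bad_masses))), "body_mass")
  expect_error(generate_community(3, overrides = list(nonsense = 1)),
               "nonsense")
})

test_that("non-vocal species never call and never appear as playback callers", {
  vocal <- setNames(rep(TRUE, 12), sprintf("herb%02d", 1:12))
  vocal["herb05"] <- FALSE; vocal["herb12"] <- TRUE
  cm <- generate_community(2, overrides = list(vocal = vocal))
  expect_true(all(cm$alarm_propensity[, "herb05"] == 0))
  ix <- derive_indices(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 2, seed = 9)
  callers <- unique(pb$caller[!is.na(pb$caller)])
  expect_length(callers, 11)
  expect_false("herb05" %in% callers)
})

test_that("predator-simulation design arithmetic and Bernoulli structure hold", {
  cm <- generate_community(4)
  tr <- simulate_predator_trials(cm, 9, seed = 5)
  expect_equal(nrow(tr), 12 * 6 * 9)   # species x (predators + control) x reps
  counts <- table(tr$focal_species, ifelse(is.na(tr$predator_id), "control",
                                           tr$predator_id))
  expect_true(all(counts == 9))        # exactly balanced
  expect_identical(simulate_predator_trials(cm, 9, seed = 5), tr)

  ones <- cm$alarm_propensity; ones[] <- 1; ones[, !cm$vocal] <- 0
  cm1 <- generate_community(4, overrides = list(alarm_propensity = ones))
  tr1 <- simulate_predator_trials(cm1, 4, seed = 6)
  pred_vocal <- tr1$model_kind == "predator" & cm1$vocal[tr1$focal_species]
  expect_true(all(tr1$alarm_given[pred_vocal]))

  half <- cm$alarm_propensity; half[] <- 0.5; half[, !cm$vocal] <- 0
  cmh <- generate_community(4, overrides = list(alarm_propensity = half))
  trh <- simulate_predator_trials(cmh, 200, seed = 7)
  ph <- trh[trh$model_kind == "predator" & cmh$vocal[trh$focal_species], ]
  rates <- tapply(ph$alarm_given, paste(ph$focal_species, ph$predator_id),
                  mean)
  sd3 <- 3 * sqrt(0.25 / 200)
  expect_true(all(abs(rates - 0.5) <= sd3))
})

test_that("playback design is balanced: receivers x (vocal callers + control)", {
  cm <- generate_community(6)
  ix <- derive_indices(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 18, seed = 8)
  expect_equal(nrow(pb), 12 * 12 * 18)       # 11 vocal callers + control
  expect_equal(sum(pb$call_kind == "control"), 12 * 18)
  cell <- table(pb$receiver, ifelse(is.na(pb$caller), "control", pb$caller))
  expect_equal(unname(diff(range(cell[cell > 0]))), 0)  # balanced design
  expect_identical(simulate_playbacks(cm, ix, n_per_pair = 18, seed = 8), pb)
  # caller present iff not control; conspecific iff caller == receiver
  expect_true(all(is.na(pb$caller) == (pb$call_kind == "control")))
  consp <- pb$call_kind == "conspecific"
  expect_true(all(pb$caller[consp] == pb$receiver[consp]))
})

test_that("null generator produces ~50% pooled response when all betas are zero", {
  cm <- generate_community(10, overrides = list(true_betas = null_betas(),
                                                ranef_sd = 0))
  ix <- derive_indices(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 35, seed = 11)  # 5040 trials
  p <- mean(pb$responded)
  se <- sqrt(0.25 / nrow(pb))
  expect_lt(abs(p - 0.5), 3 * se)
})

test_that("a strong consistency effect shows up monotonically across quartiles", {
  b <- null_betas(); b["consistency"] <- 3
  cm <- generate_community(12, overrides = list(true_betas = b, ranef_sd = 0))
  ix <- derive_indices(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 35, seed = 13)
  het <- prepare_playback_covariates(pb[pb$call_kind == "heterospecific", ],
                                     ix, alarmnet:::community_similarity(cm))
  q <- cut(het$consistency, breaks = quantile(het$consistency, 0:4 / 4),
           include.lowest = TRUE)
  rates <- tapply(het$responded, q, mean)
  expect_true(all(diff(rates) >= 0))
})

test_that("latent strength variables respect their conditional definitions", {
  cm <- generate_community(14)
  ix <- derive_indices(cm)
  pb <- simulate_playbacks(cm, ix, n_per_pair = 6, seed = 15)
  off <- !pb$responded
  expect_true(all(is.na(pb$latency_s[off])))
  expect_true(all(is.na(pb$duration_s[off])))
  expect_true(all(pb$n_head_ups[off] == 0))
  on <- pb$responded
  expect_true(all(pb$latency_s[on] > 0 & pb$latency_s[on] <= 10))
  ok <- on & !pb$duration_censored
  expect_true(all(pb$duration_s[ok] > pb$latency_s[ok]))
  expect_true(all(is.na(pb$duration_s[pb$duration_censored])))
})
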
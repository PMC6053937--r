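# Synthetic multi-species communities and trial simulators. The generator
# reproduces the statistical structure of the two field experiments the
# analysis consumes: Bernoulli alarm trials per species x predator model
# combination, and a balanced playback design whose binary response follows a
# logistic model with a per-receiver random intercept, with lognormal
# response-strength variables and negative-binomial counts generated
# conditional on a response occurring.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Covariate vocabulary for the playback response models
#'
#' Canonical names of the fixed-effect terms in the response model suite:
#' receiver body size, linear and quadratic size ratio and their interactions
#' with receiver size, the four caller information/familiarity covariates,
#' and the five environmental covariates. `true_betas` maps in a community
#' configuration use these names plus `intercept`, `conspecific` and
#' `control` offsets.
#'
#' @return character vector of coefficient names.
#' @export
playback_beta_names <- function() {
  c("intercept", "conspecific", "control",
    "receiver_size", "size_ratio", "size_ratio2",
    "receiver_size_x_size_ratio", "receiver_size_x_size_ratio2",
    "consistency", "reliability", "similarity", "abundance",
    "grass_height", "cover_proximity", "speaker_distance",
    "wind_speed", "group_size")
}

default_true_betas <- function() {
  b <- stats::setNames(numeric(length(playback_beta_names())),
                       playback_beta_names())
  # call-type offsets sized like typical field playback contrasts; all
  # hypothesis-effect coefficients default to zero so that effects are
  # injected explicitly per analysis
  b["intercept"] <- 0.4
  b["conspecific"] <- 0.96
  b["control"] <- -2.4
  b
}

default_strength_betas <- function() {
  list(latency   = c(intercept = log(2)),
       duration  = c(intercept = log(20)),
       headlift  = c(intercept = log(20)),
       head_ups  = c(intercept = log(2)),
       scratches = c(intercept = log(0.8)))
}

default_covariate_ranges <- function() {
  list(distance_m = c(20, 100),        # predator model distance
       grass_height_cm = c(5, 60),
       cover_proximity_m = c(5, 200),
       speaker_distance_mean = 35,     # playback volume calibrated at 35 m
       speaker_distance_sd = 5,
       wind_speed_max = 6,
       group_size_lambda = 8,
       young_prob = 0.3)
}

#' Generate a synthetic herbivore-predator community configuration
#'
#' Draws a complete ground-truth community: body masses (log-uniform),
#' relative abundances of herbivores and predators (lognormal), a Jacobs
#' predator-preference matrix (uniform on \[-1, 1\]), per-predator alarm
#' propensities, acoustic feature centroids for vocal species, and the true
#' response-model coefficients used by the playback simulator. One species is
#' non-vocal by default (it has no alarm call, no acoustic features, and
#' never appears as a playback caller). The `propensity_coupling` knob makes
#' a species' alarm propensity to a predator increase with its own
#' vulnerability to that predator on the logit scale, emulating
#' information-bearing alarm systems.
#'
#' @param seed integer RNG seed; the configuration is deterministic given
#'   the seed and arguments.
#' @param n_herbivores,n_predators community sizes (defaults 12 and 5).
#' @param overrides named list of fields to replace after generation
#'   (validated against the configuration invariants).
#' @param propensity_coupling list with `slope` (logit-scale coupling of
#'   alarm propensity to own vulnerability; 0 disables), `intercept`,
#'   `species_sd` (spread of per-species baseline propensities) and
#'   `cell_sd` (species x predator cell-level noise; set 0 for propensities
#'   exactly determined by the species baseline and the coupling).
#' @return object of class `alarm_community`.
#' @export
generate_community <- function(seed, n_herbivores = 12, n_predators = 5,
                               overrides = NULL,
                               propensity_coupling = list(slope = 0,
                                                          intercept = -0.8,
                                                          species_sd = 0.5)) {
  if (n_herbivores < 2 || n_predators < 2)
    stop("n_herbivores and n_predators must both be >= 2")
  pc <- utils::modifyList(list(slope = 0, intercept = -0.8, species_sd = 0.5, cell_sd = 1),
                          as.list(propensity_coupling))
  cfg <- with_seed(seed, {
    species <- sprintf("herb%02d", seq_len(n_herbivores))
    predators <- sprintf("pred%d", seq_len(n_predators))
    mass <- stats::setNames(exp(stats::runif(n_herbivores, log(15), log(900))),
                            species)
    h_ab <- stats::setNames(stats::rlnorm(n_herbivores, 3, 1), species)
    p_ab <- stats::setNames(stats::rlnorm(n_predators, 0, 1), predators)
    jac <- matrix(stats::runif(n_herbivores * n_predators, -1, 1),
                  n_herbivores, n_predators,
                  dimnames = list(species = species, predator = predators))
    vocal <- stats::setNames(rep(TRUE, n_herbivores), species)
    vocal[n_herbivores] <- FALSE
    eps <- jacobs_transform(jac)
    # logit-scale propensity: species baseline + optional coupling to own
    # vulnerability + cell-level noise (cell_sd = 0 gives a propensity that
    # is exactly constant within species when the coupling slope is 0)
    a0 <- pc$intercept + stats::rnorm(n_herbivores, 0, pc$species_sd)
    cell <- matrix(stats::rnorm(n_herbivores * n_predators, 0, pc$cell_sd),
                   n_herbivores, n_predators)
    I <- t(stats::plogis(a0 + pc$slope * eps + cell))  # predator x species
    dimnames(I) <- list(predator = predators, species = species)
    feat_lo <- c(0.1, 0, 1, 0, 200, 100, 500)
    feat_hi <- c(2, 5, 5, 1, 3000, 2000, 8000)
    feats <- sapply(seq_len(7), function(k)
      stats::runif(n_herbivores, feat_lo[k], feat_hi[k]))
    dimnames(feats) <- list(species = species, feature = acoustic_feature_names())
    list(seed = as.integer(seed),
         species = species, predators = predators,
         body_mass_kg = mass,
         herbivore_abundance = h_ab,
         predator_abundance = p_ab,
         jacobs_matrix = jac,
         vulnerability = eps,
         vocal = vocal,
         alarm_propensity = I,
         acoustic_features = feats,
         true_betas = default_true_betas(),
         strength_betas = default_strength_betas(),
         dispersion = list(latency_sdlog = 0.45, duration_sdlog = 0.5,
                           headlift_sdlog = 0.4, head_ups_theta = 2,
                           scratches_theta = 2),
         control_rate = 0.05,
         ranef_sd = 0.5,
         duration_censor_rate = 0.05,
         covariate_ranges = default_covariate_ranges(),
         trial_counts = list(predator_sim = 9, playback = 17),
         propensity_coupling = pc)
  })
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown override field(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
    if ("jacobs_matrix" %in% names(overrides) &&
        !("vulnerability" %in% names(overrides)))
      cfg$vulnerability <- jacobs_transform(cfg$jacobs_matrix)
  }
  # non-vocal species never alarm and have no acoustic signature
  cfg$alarm_propensity[, !cfg$vocal] <- 0
  cfg$acoustic_features <- cfg$acoustic_features[cfg$vocal, , drop = FALSE]
  structure(cfg, class = "alarm_community")
}

#' Validate a community configuration
#'
#' Checks every configuration invariant (probability ranges, Jacobs range,
#' mass positivity, vocal-flag consistency, dimension agreement) and fails
#' with the name of the offending field.
#'
#' @param community an `alarm_community`.
#' @return the community, invisibly, if valid.
#' @export
validate_community <- function(community) {
  c_ <- community
  fail <- function(field, why) stop("invalid community field `", field, "`: ",
                                    why, call. = FALSE)
  if (any(c_$body_mass_kg <= 0)) fail("body_masses", "masses must be > 0")
  if (any(c_$herbivore_abundance < 0))
    fail("herbivore_abundances", "must be nonnegative")
  if (any(c_$predator_abundance < 0) || sum(c_$predator_abundance) <= 0)
    fail("predator_abundances", "must be nonnegative with positive sum")
  if (any(c_$jacobs_matrix < -1 | c_$jacobs_matrix > 1))
    fail("jacobs_matrix", "values must lie in [-1, 1]")
  if (any(c_$alarm_propensity < 0 | c_$alarm_propensity > 1))
    fail("alarm_propensity", "probabilities must lie in [0, 1]")
  if (!any(c_$vocal)) fail("vocal_flags", "at least one species must be vocal")
  if (any(c_$alarm_propensity[, !c_$vocal] != 0))
    fail("alarm_propensity", "non-vocal species must have zero propensity")
  if (any(c_$acoustic_features < 0))
    fail("acoustic_features", "features must be nonnegative")
  if (!setequal(rownames(c_$acoustic_features),
                c_$species[c_$vocal]))
    fail("acoustic_features", "exactly the vocal species must have features")
  if (c_$control_rate < 0 || c_$control_rate > 1)
    fail("control_rate", "must be a probability")
  if (c_$ranef_sd < 0) fail("ranef_sd", "must be nonnegative")
  invisible(community)
}

#' @export
print.alarm_community <- function(x, ...) {
  cat("Synthetic alarm-call community (seed ", x$seed, ")\n", sep = "")
  cat("  ", length(x$species), " herbivores (", sum(x$vocal), " vocal), ",
      length(x$predators), " predators\n", sep = "")
  cat("  body mass ", format(min(x$body_mass_kg), digits = 3), "-",
      format(max(x$body_mass_kg), digits = 3), " kg\n", sep = "")
  cat("  propensity-vulnerability coupling slope: ",
      x$propensity_coupling$slope, "\n", sep = "")
  invisible(x)
}

#' Simulate predator-simulation (model presentation) trials
#'
#' For every herbivore x (predator model + control) combination,
#' `n_per_combination` independent trials are drawn. Alarm occurrence is
#' Bernoulli with the community's alarm propensity I(x, j) for predator
#' models and with `control_rate` for the control model (non-vocal species
#' never alarm). Trial covariates (distance to model, group size, presence
#' of young) are drawn from the configured ranges.
#'
#' @param community an `alarm_community`.
#' @param n_per_combination trials per species x model combination (>= 1).
#' @param seed integer RNG seed.
#' @return data frame of trials, one row per presentation.
#' @export
simulate_predator_trials <- function(community,
                                     n_per_combination =
                                       community$trial_counts$predator_sim,
                                     seed = community$seed) {
  validate_community(community)
  if (n_per_combination < 1) stop("n_per_combination must be >= 1")
  models <- c(community$predators, "control")
  grid <- expand.grid(focal_species = community$species, model = models,
                      rep = seq_len(n_per_combination),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- community$covariate_ranges
  with_seed(seed, {
    n <- nrow(grid)
    is_ctrl <- grid$model == "control"
    p <- ifelse(is_ctrl,
                community$control_rate * community$vocal[grid$focal_species],
                NA_real_)
    idx <- cbind(match(grid$model, community$predators),
                 match(grid$focal_species, community$species))
    p[!is_ctrl] <- community$alarm_propensity[idx[!is_ctrl, , drop = FALSE]]
    data.frame(
      trial_id = seq_len(n),
      focal_species = grid$focal_species,
      model_kind = ifelse(is_ctrl, "control", "predator"),
      predator_id = ifelse(is_ctrl, NA_character_, grid$model),
      distance_m = stats::runif(n, r$distance_m[1], r$distance_m[2]),
      group_size = 1L + stats::rpois(n, r$group_size_lambda),
      young_present = stats::runif(n) < r$young_prob,
      alarm_given = stats::runif(n) < p,
      stringsAsFactors = FALSE)
  })
}

#' Simulate per-call acoustic feature tables
#'
#' Draws `n_calls` analysed calls per vocal species around the community's
#' species-level feature centroids, with multiplicative lognormal measurement
#' noise. Non-vocal species contribute no calls.
#'
#' @param community an `alarm_community`.
#' @param n_calls calls per vocal species (default 10).
#' @param noise_sdlog lognormal sdlog of per-call noise.
#' @param seed integer RNG seed.
#' @return per-call feature data frame (see [acoustic_feature_names()]).
#' @export
simulate_call_features <- function(community, n_calls = 10,
                                   noise_sdlog = 0.15,
                                   seed = community$seed) {
  validate_community(community)
  cent <- community$acoustic_features
  with_seed(seed, {
    rows <- do.call(rbind, lapply(rownames(cent), function(s) {
      noise <- matrix(stats::rlnorm(n_calls * ncol(cent), 0, noise_sdlog),
                      n_calls, ncol(cent))
      X <- sweep(noise, 2, cent[s, ], "*")
      data.frame(species = s, call = seq_len(n_calls), X,
                 stringsAsFactors = FALSE)
    }))
    names(rows)[-(1:2)] <- acoustic_feature_names()
    rownames(rows) <- NULL
    rows
  })
}

community_similarity <- function(community) {
  tab <- data.frame(species = rownames(community$acoustic_features),
                    community$acoustic_features,
                    stringsAsFactors = FALSE)
  names(tab)[-1] <- acoustic_feature_names()
  acoustic_similarity(tab)
}

#' Prepare the model covariates for a playback trial table
#'
#' Attaches the fixed-effect covariates of the response models to a playback
#' trial table, on the scales the models use: caller consistency, call
#' reliability, acoustic similarity, caller abundance, body-size ratio and
#' receiver body size are affinely rescaled to \[0, 1\] over the
#' heterospecific caller-receiver pair grid (so the scaling is a property of
#' the community, not of the particular trial sample), while the continuous
#' environmental covariates and integer group size are standardized to mean
#' 0, SD 1 over the supplied trials. Control trials carry zeros for the
#' caller-specific covariates (no caller is defined); receivers without a
#' conspecific alarm call get `NA` acoustic similarity, which excludes those
#' trials from models that use the covariate.
#'
#' @param trials playback trial data frame (`receiver`, `caller`,
#'   `call_kind`, raw environmental columns).
#' @param indices an `alarm_indices` object for the same community.
#' @param similarity acoustic similarity matrix over vocal species
#'   (receiver x caller orientation; symmetric).
#' @return `trials` with covariate columns appended.
#' @export
prepare_playback_covariates <- function(trials, indices, similarity) {
  stopifnot(inherits(indices, "alarm_indices"))
  vocal <- names(indices$vocal)[indices$vocal]
  all_sp <- names(indices$vocal)
  het <- expand.grid(receiver = all_sp, caller = vocal,
                     stringsAsFactors = FALSE)
  het <- het[het$receiver != het$caller, ]
  pair_scale <- function(M) {
    vals <- M[cbind(het$receiver, het$caller)]
    rng <- range(vals, na.rm = TRUE)
    if (diff(rng) == 0) stop("degenerate index range; cannot scale")
    function(i, j) (M[cbind(i, j)] - rng[1]) / (rng[2] - rng[1])
  }
  sc_L <- pair_scale(indices$L)
  sc_V <- pair_scale(indices$V)
  sc_R <- pair_scale(indices$size_ratio)
  S <- matrix(NA_real_, length(all_sp), length(all_sp),
              dimnames = list(all_sp, all_sp))
  S[rownames(similarity), colnames(similarity)] <- similarity
  sc_S <- pair_scale(S)
  ab <- scale_unit_interval(indices$abundance[vocal])
  rs <- scale_unit_interval(indices$mass_kg)

  ctrl <- trials$call_kind == "control"
  i <- trials$receiver
  j <- ifelse(ctrl, NA_character_, trials$caller)
  z <- function(x) as.numeric(scale(x))
  out <- trials
  out$receiver_size <- rs[i]
  out$size_ratio  <- ifelse(ctrl, 0, sc_R(i, j))
  out$consistency <- ifelse(ctrl, 0, sc_L(i, j))
  out$reliability <- ifelse(ctrl, 0, sc_V(i, j))
  out$similarity  <- ifelse(ctrl, 0, sc_S(i, j))
  out$abundance   <- ifelse(ctrl, 0, ab[j])
  out$grass_height   <- z(trials$grass_height_cm)
  out$cover_proximity <- z(trials$cover_proximity_m)
  out$speaker_distance <- z(trials$speaker_distance_m)
  out$wind_speed <- z(trials$wind_speed_ms)
  out$group_size_raw <- trials$group_size
  out$group_size <- z(trials$group_size)
  out
}

linpred <- function(betas, X) {
  b <- stats::setNames(numeric(length(playback_beta_names())),
                       playback_beta_names())
  unknown <- setdiff(names(betas), names(b))
  if (length(unknown))
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
  b[names(betas)] <- betas
  ctrl <- as.numeric(X$call_kind == "control")
  consp <- as.numeric(X$call_kind == "conspecific")
  sim <- ifelse(is.na(X$similarity), 0, X$similarity)
  noncall <- 1 - ctrl  # caller-specific terms only where a caller exists
  b["intercept"] + b["control"] * ctrl + b["conspecific"] * consp +
    noncall * (b["receiver_size"] * X$receiver_size +
               b["size_ratio"] * X$size_ratio +
               b["size_ratio2"] * X$size_ratio^2 +
               b["receiver_size_x_size_ratio"] * X$receiver_size * X$size_ratio +
               b["receiver_size_x_size_ratio2"] * X$receiver_size * X$size_ratio^2 +
               b["consistency"] * X$consistency +
               b["reliability"] * X$reliability +
               b["similarity"] * sim +
               b["abundance"] * X$abundance) +
    b["grass_height"] * X$grass_height +
    b["cover_proximity"] * X$cover_proximity +
    b["speaker_distance"] * X$speaker_distance +
    b["wind_speed"] * X$wind_speed +
    b["group_size"] * X$group_size
}

#' Simulate a balanced playback experiment
#'
#' Generates a balanced receiver x (vocal caller + control) playback design
#' with `n_per_pair` trials per combination. The binary response is drawn
#' from a logistic model whose linear predictor combines the community's
#' `true_betas` with the prepared covariates (see
#' [prepare_playback_covariates()]) and a per-receiver normal random
#' intercept of SD `ranef_sd`. Conditional on a response, latency, time to
#' resumed foraging and head-lift speed are lognormal and the head-up and
#' scratch counts negative-binomial, each with its own (by default
#' intercept-only) linear predictor; a small fraction of durations is
#' censored (foraging never resumes within the observation).
#'
#' @param community an `alarm_community`.
#' @param indices an `alarm_indices` computed for the same community.
#' @param n_per_pair trials per receiver-caller combination (>= 1).
#' @param seed integer RNG seed.
#' @param similarity optional acoustic similarity matrix; defaults to the
#'   similarity of the community's feature centroids.
#' @return data frame of playback trials with latent response variables.
#' @export
simulate_playbacks <- function(community, indices,
                               n_per_pair = community$trial_counts$playback,
                               seed = community$seed,
                               similarity = NULL) {
  validate_community(community)
  if (!inherits(indices, "alarm_indices"))
    stop("`indices` must be an alarm_indices object (see derive_indices())")
  if (n_per_pair < 1) stop("n_per_pair must be >= 1")
  if (is.null(similarity)) similarity <- community_similarity(community)
  vocal <- community$species[community$vocal]
  callers <- c(vocal, "control")
  grid <- expand.grid(receiver = community$species, caller = callers,
                      rep = seq_len(n_per_pair),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- community$covariate_ranges
  with_seed(seed, {
    n <- nrow(grid)
    ctrl <- grid$caller == "control"
    trials <- data.frame(
      trial_id = seq_len(n),
      receiver = grid$receiver,
      caller = ifelse(ctrl, NA_character_, grid$caller),
      call_kind = ifelse(ctrl, "control",
                         ifelse(grid$caller == grid$receiver,
                                "conspecific", "heterospecific")),
      grass_height_cm = stats::runif(n, r$grass_height_cm[1],
                                     r$grass_height_cm[2]),
      cover_proximity_m = stats::runif(n, r$cover_proximity_m[1],
                                       r$cover_proximity_m[2]),
      speaker_distance_m = pmax(10, stats::rnorm(n, r$speaker_distance_mean,
                                                 r$speaker_distance_sd)),
      wind_speed_ms = stats::runif(n, 0, r$wind_speed_max),
      group_size = 1L + stats::rpois(n, r$group_size_lambda),
      stringsAsFactors = FALSE)
    X <- prepare_playback_covariates(trials, indices, similarity)
    ranef <- stats::setNames(stats::rnorm(length(community$species), 0,
                                          community$ranef_sd),
                             community$species)
    eta <- linpred(community$true_betas, X) + ranef[trials$receiver]
    responded <- stats::runif(n) < stats::plogis(eta)

    sb <- community$strength_betas
    dsp <- community$dispersion
    strength_eta <- function(b) linpred(b, X)
    lat <- stats::rlnorm(n, strength_eta(sb$latency), dsp$latency_sdlog)
    for (k in seq_len(20)) {  # latency is defined within the 10-s window
      over <- lat > 10
      if (!any(over)) break
      lat[over] <- stats::rlnorm(sum(over), strength_eta(sb$latency)[over],
                                dsp$latency_sdlog)
    }
    lat <- pmin(lat, 10)
    dur <- lat + stats::rlnorm(n, strength_eta(sb$duration),
                               dsp$duration_sdlog)
    hls <- stats::rlnorm(n, strength_eta(sb$headlift), dsp$headlift_sdlog)
    nhu <- stats::rnbinom(n, mu = exp(strength_eta(sb$head_ups)),
                          size = dsp$head_ups_theta)
    nsc <- stats::rnbinom(n, mu = exp(strength_eta(sb$scratches)),
                          size = dsp$scratches_theta)
    cens <- stats::runif(n) < community$duration_censor_rate

    trials$responded <- responded
    trials$latency_s <- ifelse(responded, lat, NA_real_)
    trials$duration_censored <- responded & cens
    trials$duration_s <- ifelse(responded & !cens, dur, NA_real_)
    trials$headlift_speed <- ifelse(responded, hls, NA_real_)
    trials$n_head_ups <- ifelse(responded, nhu, 0L)
    trials$n_scratches <- ifelse(responded, nsc, 0L)
    trials
  })
}
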
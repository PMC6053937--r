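# End-to-end pipeline plumbing: a validated configuration object, input
# validation for externally supplied tables, and a staged runner that
# executes generate/load -> indices -> acoustics -> responses -> models ->
# network, writing CSV/YAML/GraphML artefacts and a run manifest.

#' Build a pipeline configuration
#'
#' Exactly one of `synthetic` (a seeded synthetic-community block) or
#' `paths` (named paths to real input tables) must be supplied.
#'
#' @param output_dir directory for all stage artefacts.
#' @param synthetic list with `seed`, optional `n_herbivores`,
#'   `n_predators`, `overrides`, `propensity_coupling`, `n_predator_trials`,
#'   `n_per_pair`.
#' @param paths named list of input CSV paths (`predator_trials`,
#'   `playbacks`, `species`, `jacobs`, `predator_abundance`,
#'   `acoustic_features`).
#' @param normalize_consistency,similarity_scale,network_threshold,
#'   include_conspecific analysis options (see the respective functions).
#' @return object of class `alarm_pipeline_config`.
#' @export
pipeline_config <- function(output_dir, synthetic = NULL, paths = NULL,
                            normalize_consistency = TRUE,
                            similarity_scale = TRUE,
                            network_threshold = 0.72,
                            include_conspecific = FALSE) {
  if (is.null(synthetic) == is.null(paths))
    stop("exactly one of `synthetic` or `paths` must be given")
  if (!is.null(synthetic) && is.null(synthetic$seed))
    stop("synthetic block requires a `seed`")
  if (network_threshold < 0 || network_threshold > 1)
    stop("network_threshold must lie in [0, 1]")
  structure(list(output_dir = output_dir, synthetic = synthetic,
                 paths = paths,
                 normalize_consistency = normalize_consistency,
                 similarity_scale = similarity_scale,
                 network_threshold = network_threshold,
                 include_conspecific = include_conspecific),
            class = "alarm_pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "output_dir")], f)
  unname(tools::md5sum(f))
}

#' Validate input tables against the pipeline's invariants
#'
#' Schema and range checks for every table the analysis consumes:
#' probability and index ranges, call-profile column sums, mass positivity,
#' Jacobs range, feature nonnegativity. The data are never mutated; the
#' report carries one row per violation with the table, the check and a
#' row/column diagnostic.
#'
#' @param tables named list of data frames / matrices; recognised names are
#'   `species` (columns `species`, `body_mass_kg`, `abundance`, `vocal`),
#'   `jacobs`, `vulnerability`, `call_profile`, `alarm_propensity`,
#'   `predator_abundance`, `acoustic_features`, `predator_trials`,
#'   `playbacks`.
#' @return data frame report (zero rows when everything passes).
#' @export
validate_inputs <- function(tables) {
  report <- list()
  note <- function(table, check, where, detail)
    report[[length(report) + 1L]] <<-
      data.frame(table = table, check = check, where = where,
                 detail = detail, stringsAsFactors = FALSE)
  tb <- tables
  if (!is.null(tb$species)) {
    s <- tb$species
    bad <- which(s$body_mass_kg <= 0)
    for (i in bad) note("species", "mass_positive", s$species[i],
                        paste("mass", s$body_mass_kg[i]))
    bad <- which(s$abundance < 0)
    for (i in bad) note("species", "abundance_nonnegative", s$species[i],
                        paste("abundance", s$abundance[i]))
  }
  if (!is.null(tb$jacobs)) {
    J <- as.matrix(tb$jacobs)
    idx <- which(J < -1 | J > 1, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      note("jacobs", "range_pm1",
           paste(rownames(J)[idx[r, 1]], colnames(J)[idx[r, 2]], sep = ":"),
           paste("value", J[idx[r, , drop = FALSE]]))
  }
  for (nm in c("vulnerability", "alarm_propensity")) {
    if (is.null(tb[[nm]])) next
    M <- as.matrix(tb[[nm]])
    idx <- which(M < 0 | M > 1, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      note(nm, "range_unit",
           paste(rownames(M)[idx[r, 1]], colnames(M)[idx[r, 2]], sep = ":"),
           paste("value", M[idx[r, , drop = FALSE]]))
  }
  if (!is.null(tb$call_profile)) {
    C <- as.matrix(tb$call_profile)
    cs <- colSums(C)
    bad <- which(!is.na(cs) & abs(cs - 1) > 1e-8)
    for (j in bad) note("call_profile", "column_sums_to_one",
                        colnames(C)[j], paste("sum", format(cs[j])))
  }
  if (!is.null(tb$predator_abundance)) {
    A <- tb$predator_abundance
    if (any(A < 0) || sum(A) <= 0)
      note("predator_abundance", "nonnegative_positive_sum", "all",
           paste("sum", sum(A)))
  }
  if (!is.null(tb$acoustic_features)) {
    X <- tb$acoustic_features
    feats <- intersect(acoustic_feature_names(), names(X))
    for (f in feats) {
      bad <- which(X[[f]] < 0)
      for (i in bad) note("acoustic_features", "nonnegative",
                          paste0(f, "[", i, "]"), paste("value", X[[f]][i]))
    }
  }
  if (!is.null(tb$playbacks)) {
    p <- tb$playbacks
    bad <- which(p$call_kind == "control" & !is.na(p$caller))
    for (i in bad) note("playbacks", "control_has_no_caller",
                        paste0("row ", i), p$caller[i])
    bad <- which(p$call_kind != "control" & is.na(p$caller))
    for (i in bad) note("playbacks", "caller_required",
                        paste0("row ", i), p$call_kind[i])
    bad <- which(p$call_kind == "conspecific" & p$caller != p$receiver)
    for (i in bad) note("playbacks", "conspecific_caller_is_receiver",
                        paste0("row ", i),
                        paste(p$caller[i], "vs", p$receiver[i]))
  }
  if (!is.null(tb$predator_trials)) {
    p <- tb$predator_trials
    bad <- which((p$model_kind == "predator") != !is.na(p$predator_id))
    for (i in bad) note("predator_trials", "predator_id_iff_predator_kind",
                        paste0("row ", i), p$model_kind[i])
  }
  if (!length(report))
    return(data.frame(table = character(0), check = character(0),
                      where = character(0), detail = character(0)))
  do.call(rbind, report)
}

read_required <- function(paths, name) {
  p <- paths[[name]]
  if (is.null(p) || !file.exists(p %||% ""))
    stop("required input table `", name, "` missing",
         if (!is.null(p)) paste0(" (file not found: ", p, ")"))
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes six stages in order — generate/load (community plus
#' predator-simulation trials), indices, acoustics, responses (playback
#' trials, event logs and coding), models (preliminary call-type model,
#' alarm-production model, six response models) and network — writing each
#' stage's artefacts under `output_dir` and returning a manifest (seed,
#' configuration hash, per-stage row counts). A stage failure halts the run
#' with the stage name and cause. Deterministic for a fixed configuration:
#' two runs produce identical CSV artefacts.
#'
#' @param config an `alarm_pipeline_config`.
#' @return manifest list, invisibly written as `manifest.yaml`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "alarm_pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  syn <- config$synthetic
  synth_mode <- !is.null(syn)

  gen <- stage("generate", {
    if (synth_mode) {
      cm <- generate_community(
        syn$seed,
        n_herbivores = syn$n_herbivores %||% 12,
        n_predators = syn$n_predators %||% 5,
        overrides = syn$overrides,
        propensity_coupling = syn$propensity_coupling %||% list(slope = 0))
      validate_community(cm)
      tr <- simulate_predator_trials(
        cm, syn$n_predator_trials %||% cm$trial_counts$predator_sim,
        seed = syn$seed * 11L)
      yaml::write_yaml(list(seed = cm$seed,
                            n_herbivores = length(cm$species),
                            n_predators = length(cm$predators),
                            control_rate = cm$control_rate,
                            ranef_sd = cm$ranef_sd,
                            true_betas = as.list(cm$true_betas)),
                       out("community.yaml"))
      utils::write.csv(data.frame(species = cm$species,
                                  body_mass_kg = cm$body_mass_kg,
                                  abundance = cm$herbivore_abundance,
                                  vocal = cm$vocal),
                       out("species.csv"), row.names = FALSE)
    } else {
      sp <- read_required(config$paths, "species")
      jac <- read_required(config$paths, "jacobs")
      pab <- read_required(config$paths, "predator_abundance")
      tr <- read_required(config$paths, "predator_trials")
      J <- as.matrix(jac[-1]); rownames(J) <- jac[[1]]
      cm <- structure(list(
        seed = NA_integer_,
        species = sp$species, predators = colnames(J),
        body_mass_kg = stats::setNames(sp$body_mass_kg, sp$species),
        herbivore_abundance = stats::setNames(sp$abundance, sp$species),
        predator_abundance = stats::setNames(pab$abundance, pab$predator),
        jacobs_matrix = J,
        vulnerability = jacobs_transform(J),
        vocal = stats::setNames(as.logical(sp$vocal), sp$species)),
        class = "alarm_community")
    }
    utils::write.csv(tr, out("predator_trials.csv"), row.names = FALSE)
    list(community = cm, ptrials = tr)
  })
  community <- gen$community
  ptrials <- gen$ptrials

  indices <- stage("indices", {
    ix <- derive_indices(community, ptrials,
                         normalize_consistency = config$normalize_consistency)
    write_index_long(ix$L, out("consistency.csv"), "consistency")
    write_index_long(ix$V, out("reliability.csv"), "reliability")
    write_index_long(ix$size_ratio, out("size_ratio.csv"), "size_ratio")
    ix
  })
  similarity <- stage("acoustics", {
    calls <- if (synth_mode)
      simulate_call_features(community, seed = syn$seed * 13L)
    else read_required(config$paths, "acoustic_features")
    S <- acoustic_similarity(calls, scale = config$similarity_scale)
    utils::write.csv(as.data.frame(S), out("acoustic_similarity.csv"))
    S
  })
  resp <- stage("responses", {
    if (synth_mode) {
      pb <- simulate_playbacks(community, indices,
                               n_per_pair = syn$n_per_pair %||%
                                 community$trial_counts$playback,
                               seed = syn$seed * 17L, similarity = similarity)
      logs <- playback_event_logs(pb)
      coded <- code_responses(logs)
    } else {
      pb <- read_required(config$paths, "playbacks")
      coded <- pb[intersect(names(pb),
                            c("trial_id", "responded", "latency_s",
                              "duration_s", "duration_censored",
                              "headlift_speed", "n_head_ups",
                              "n_scratches"))]
    }
    utils::write.csv(pb, out("playbacks.csv"), row.names = FALSE)
    utils::write.csv(coded, out("responses.csv"), row.names = FALSE)
    list(playbacks = pb, coded = coded)
  })
  playbacks <- resp$playbacks

  fits <- stage("models", {
    pre <- preliminary_calltype_model(playbacks)
    m1 <- fit_alarm_model(ptrials, indices$epsilon)
    suite <- fit_response_models(pre$data, indices, similarity,
                                 include_conspecific =
                                   config$include_conspecific)
    tab <- do.call(rbind, lapply(names(suite), function(nm)
      cbind(model = nm, response = suite[[nm]]$spec$response,
            suite[[nm]]$coefficients)))
    utils::write.csv(tab, out("model_coefficients.csv"), row.names = FALSE)
    list(preliminary = pre, alarm = m1, responses = suite)
  })
  network <- stage("network", {
    P <- response_probability_matrix(playbacks)
    g <- build_network(P, config$network_threshold)
    write_network(g, out("network.graphml"), out("network_edges.csv"))
    g
  })
  manifest <- list(
    package = "alarmnet",
    package_version = as.character(utils::packageVersion("alarmnet")),
    seed = if (synth_mode) syn$seed else NA,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list(
      generate = list(n_species = length(community$species),
                      predator_trials = nrow(ptrials)),
      indices = list(pairs = length(indices$L)),
      acoustics = list(species = nrow(similarity)),
      responses = list(playbacks = nrow(playbacks),
                       coded = nrow(resp$coded)),
      models = list(fitted = 2 + length(fits$responses)),
      network = list(nodes = igraph::vcount(network),
                     edges = igraph::ecount(network))))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
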
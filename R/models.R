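# Model suite for alarm production and playback responses: binomial GLM(M)s,
# log-linear mixed models and negative-binomial mixed models, with
# AICc-based all-subsets selection under marginality constraints. Fitting is
# delegated to stats::glm, lme4 and glmmTMB; model construction, covariate
# preparation, candidate enumeration and selection logic live here.

#' Standardize covariate columns to mean 0, SD 1
#'
#' Mean-centres and scales the named columns (typically integer covariates
#' such as group size) and records the transformation parameters in the
#' `"standardization"` attribute so coefficients can be back-transformed.
#'
#' @param table data frame.
#' @param vars names of numeric columns to standardize.
#' @return the table with standardized columns.
#' @export
standardize_covariates <- function(table, vars) {
  miss <- setdiff(vars, names(table))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
  params <- list()
  for (v in vars) {
    x <- table[[v]]
    if (!is.numeric(x)) stop("column `", v, "` is not numeric")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("column `", v, "` has zero SD")
    m <- mean(x)
    table[[v]] <- (x - m) / s
    params[[v]] <- c(center = m, scale = s)
  }
  attr(table, "standardization") <- params
  table
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1). The correction requires
#' n > k + 1 and vanishes as n grows, recovering the ordinary AIC.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc value.
#' @examples
#' aicc(-10, 2, 10)  # 24 + 12/7
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: need n > k + 1 (got n = ", n, ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

term_components <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# direct marginality requirements of a term: an interaction requires each of
# its components, and a quadratic I(x^2) (alone or inside an interaction)
# requires its linear term
term_requires <- function(term) {
  comp <- term_components(term)
  req <- character(0)
  if (length(comp) > 1) req <- comp
  for (c_ in comp) {
    m <- regmatches(c_, regexec("^I\\((.+)\\^2\\)$", c_))[[1]]
    if (length(m) == 2) req <- c(req, m[2])
  }
  setdiff(unique(req), term)
}

closure_requires <- function(term) {
  req <- term_requires(term)
  repeat {
    more <- unique(unlist(lapply(req, term_requires)))
    new <- setdiff(more, req)
    if (!length(new)) return(req)
    req <- c(req, new)
  }
}

#' Construct a model specification
#'
#' A declarative description of one candidate model: response variable,
#' family, fixed-effect terms (interactions as `"a:b"`, quadratics as
#' `"I(a^2)"`), an optional random-intercept grouping factor, and an
#' optional data-filter expression recorded for provenance. Marginality is
#' enforced at construction: every interaction requires its main effects and
#' every quadratic its linear term.
#'
#' @param response response variable name.
#' @param family one of `"binomial"` (logit link), `"lognormal"`
#'   (linear model on the log response) or `"negbin"` (negative binomial
#'   with log link).
#' @param fixed_terms character vector of fixed-effect terms.
#' @param random_intercept grouping factor name, or `NULL` for none.
#' @param data_filter optional string describing the subset the model is
#'   fitted on (provenance only).
#' @return object of class `alarm_model_spec`.
#' @export
model_spec <- function(response, family = c("binomial", "lognormal", "negbin"),
                       fixed_terms, random_intercept = NULL,
                       data_filter = NULL) {
  family <- match.arg(family)
  fixed_terms <- unique(fixed_terms)
  for (t_ in fixed_terms) {
    need <- closure_requires(t_)
    miss <- setdiff(need, fixed_terms)
    if (length(miss))
      stop("term `", t_, "` requires `", paste(miss, collapse = "`, `"),
           "` (marginality)")
  }
  structure(list(response = response, family = family,
                 fixed_terms = fixed_terms,
                 random_intercept = random_intercept,
                 data_filter = data_filter),
            class = "alarm_model_spec")
}

spec_formula <- function(spec) {
  lhs <- if (spec$family == "lognormal") paste0("log(", spec$response, ")")
         else spec$response
  rhs <- if (length(spec$fixed_terms)) paste(spec$fixed_terms, collapse = " + ")
         else "1"
  if (!is.null(spec$random_intercept))
    rhs <- paste0(rhs, " + (1 | ", spec$random_intercept, ")")
  stats::as.formula(paste(lhs, "~", rhs))
}

#' Enumerate the AICc candidate set for a full model
#'
#' All subsets of the full model's fixed terms that respect marginality
#' (interactions only with their main effects, quadratics only with their
#' linear terms); the random intercept, when present, is retained in every
#' candidate. Candidates are ordered deterministically by number of terms,
#' then by term order in the full model.
#'
#' @param full_spec an `alarm_model_spec` describing the full model.
#' @param max_terms optional upper bound on the number of fixed terms per
#'   candidate (a dredge-style complexity cap).
#' @param max_candidates abort if the candidate set would exceed this size.
#' @return list of `alarm_model_spec` objects (the null model included).
#' @export
build_candidate_set <- function(full_spec, max_terms = Inf,
                                max_candidates = Inf) {
  stopifnot(inherits(full_spec, "alarm_model_spec"))
  terms <- full_spec$fixed_terms
  p <- length(terms)
  if (p > 20) stop("candidate enumeration over ", p,
                   " terms is intractable; reduce the term set")
  req <- lapply(terms, function(t_) match(closure_requires(t_), terms))
  keep <- list()
  for (mask in 0:(2^p - 1)) {
    inset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    if (length(inset) > max_terms) next
    ok <- all(vapply(inset, function(k) all(req[[k]] %in% inset), logical(1)))
    if (ok) keep[[length(keep) + 1L]] <- inset
  }
  ord <- order(lengths(keep),
               vapply(keep, function(s) paste(sprintf("%02d", s),
                                              collapse = ""), ""))
  keep <- keep[ord]
  if (length(keep) > max_candidates)
    stop("candidate set has ", length(keep), " models, exceeding max_candidates")
  lapply(keep, function(s)
    model_spec(full_spec$response, full_spec$family, terms[s],
               full_spec$random_intercept, full_spec$data_filter))
}

coef_table <- function(cm) {
  data.frame(term = rownames(cm),
             estimate = cm[, 1], se = cm[, 2], statistic = cm[, 3],
             p_value = if (ncol(cm) >= 4) cm[, 4]
                       else 2 * stats::pnorm(-abs(cm[, 3])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit one model specification
#'
#' Dispatches on family and presence of a random intercept:
#' binomial models go to [stats::glm()] or [lme4::glmer()], lognormal models
#' are linear (mixed) models on the log response via [stats::lm()] or
#' [lme4::lmer()] (maximum likelihood, so that AICc comparisons are valid),
#' and negative-binomial models go to [glmmTMB::glmmTMB()]. Rows with
#' missing values in any model variable are dropped. P-values are Wald by
#' default; `pvalues = "lrt"` replaces them with single-term
#' likelihood-ratio tests for every droppable term (terms locked in by
#' marginality get `NA`).
#'
#' @param spec an `alarm_model_spec`.
#' @param data data frame containing all model variables.
#' @param pvalues `"wald"` or `"lrt"`.
#' @param nagq integration points for binomial mixed fits (passed to
#'   `glmer` as `nAGQ`); `0` is faster and adequate for large balanced
#'   simulations, `1` (adaptive Laplace) is the default.
#' @return object of class `alarm_fit`: the fitted model plus a coefficient
#'   table, log-likelihood, parameter count, n, AICc and convergence flag.
#' @export
fit_model <- function(spec, data, pvalues = c("wald", "lrt"), nagq = 1) {
  stopifnot(inherits(spec, "alarm_model_spec"))
  pvalues <- match.arg(pvalues)
  f <- spec_formula(spec)
  mixed <- !is.null(spec$random_intercept)
  fit <- if (spec$family == "binomial") {
    if (mixed)
      lme4::glmer(f, data = data, family = stats::binomial(), nAGQ = nagq,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    else stats::glm(f, data = data, family = stats::binomial())
  } else if (spec$family == "lognormal") {
    if (mixed) lme4::lmer(f, data = data, REML = FALSE)
    else stats::lm(f, data = data)
  } else {
    glmmTMB::glmmTMB(f, data = data, family = glmmTMB::nbinom2())
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  cm <- if (inherits(fit, "glmmTMB")) summary(fit)$coefficients$cond
        else summary(fit)$coefficients
  tab <- coef_table(cm)
  converged <- model_converged(fit)
  if (spec$family == "binomial" && any(abs(tab$estimate) > 10)) {
    converged <- FALSE
    attr(tab, "separation") <- TRUE
  }
  out <- structure(list(spec = spec, model = fit, coefficients = tab,
                        loglik = as.numeric(ll), k = k, n = n,
                        aicc = aicc(as.numeric(ll), k, n),
                        converged = converged),
                   class = "alarm_fit")
  if (pvalues == "lrt") out <- add_lrt_pvalues(out, data, nagq)
  out
}

model_converged <- function(fit) {
  if (inherits(fit, "merMod")) {
    msgs <- fit@optinfo$conv$lme4$messages
    # a boundary (singular) fit is a valid ML estimate, not a failure
    length(setdiff(msgs, grep("singular", msgs, value = TRUE))) == 0
  }
  else if (inherits(fit, "glmmTMB"))
    isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  else if (inherits(fit, "glm")) isTRUE(fit$converged)
  else TRUE
}

add_lrt_pvalues <- function(fit, data, nagq = 1) {
  spec <- fit$spec
  droppable <- spec$fixed_terms[
    vapply(spec$fixed_terms, function(t_)
      !t_ %in% unlist(lapply(setdiff(spec$fixed_terms, t_), closure_requires)),
      logical(1))]
  fit$coefficients$p_value <- NA_real_
  for (t_ in droppable) {
    red <- model_spec(spec$response, spec$family,
                      setdiff(spec$fixed_terms, t_),
                      spec$random_intercept, spec$data_filter)
    rfit <- fit_model(red, data, pvalues = "wald", nagq = nagq)
    stat <- 2 * (fit$loglik - rfit$loglik)
    df <- fit$k - rfit$k
    p <- stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
    row <- match(term_to_coef(t_, fit$coefficients$term), fit$coefficients$term)
    if (!is.na(row)) fit$coefficients$p_value[row] <- p
  }
  fit$pvalue_method <- "lrt"
  fit
}

# map a spec term to its coefficient-table row label (single-df terms only)
term_to_coef <- function(term, labels) {
  if (term %in% labels) return(term)
  comp <- term_components(term)
  hit <- labels[vapply(labels, function(l)
    setequal(term_components(l), comp), logical(1))]
  if (length(hit) == 1) hit else NA_character_
}

#' @export
print.alarm_fit <- function(x, ...) {
  cat("Model fit:", x$spec$family, "  response:", x$spec$response, "\n")
  cat("  n =", x$n, " k =", x$k, " logLik =", format(x$loglik, digits = 5),
      " AICc =", format(x$aicc, digits = 6),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Fit all candidates and select by AICc
#'
#' Fits every candidate specification, ranks the fits by AICc (ties broken
#' by fewer parameters, then by deterministic term order) and returns the
#' best converged fit together with the full selection table. Candidates
#' that fail to fit are kept in the table as non-converged with infinite
#' AICc.
#'
#' @param candidates list of `alarm_model_spec` (see
#'   [build_candidate_set()]), or a single spec.
#' @param data model data frame.
#' @param ... passed to [fit_model()].
#' @return list with `best` (an `alarm_fit`) and `table` (ranked selection
#'   data frame with terms, k, logLik, AICc and delta-AICc).
#' @export
select_model <- function(candidates, data, ...) {
  if (inherits(candidates, "alarm_model_spec")) candidates <- list(candidates)
  stopifnot(length(candidates) >= 1)
  fits <- lapply(candidates, function(sp)
    tryCatch(fit_model(sp, data, ...), error = function(e) e))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "alarm_fit"))
      data.frame(model = i,
                 terms = paste(f$spec$fixed_terms, collapse = " + "),
                 n_terms = length(f$spec$fixed_terms),
                 k = f$k, loglik = f$loglik, aicc = f$aicc,
                 converged = f$converged, stringsAsFactors = FALSE)
    else
      data.frame(model = i,
                 terms = paste(candidates[[i]]$fixed_terms, collapse = " + "),
                 n_terms = length(candidates[[i]]$fixed_terms),
                 k = NA_integer_, loglik = NA_real_, aicc = Inf,
                 converged = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$aicc[!tab$converged] <- Inf
  ord <- order(tab$aicc, tab$k, tab$terms)
  tab <- tab[ord, ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  best_id <- tab$model[tab$converged][1]
  if (is.na(best_id)) stop("no candidate model converged")
  list(best = fits[[best_id]], table = tab)
}

#' Alarm-production model for predator-simulation trials
#'
#' Logistic regression of alarm occurrence on predator-model trials, with
#' focal species identity, the focal species' own vulnerability to the
#' presented predator, optionally their interaction, distance to the model,
#' (standardized) group size and the presence of young as explanatory
#' variables. The vulnerability coefficient tests whether species alarm-call
#' preferentially to the predators they are most vulnerable to.
#'
#' @param trials predator-simulation trial data frame; control presentations
#'   are dropped (they are handled by the preliminary call-type model).
#' @param epsilon vulnerability matrix (species x predator).
#' @param include_interaction include the species x vulnerability
#'   interaction (default `TRUE`).
#' @return `alarm_fit` with an extra `vulnerability_coef` element (the row
#'   of the coefficient table testing the vulnerability effect).
#' @export
fit_alarm_model <- function(trials, epsilon, include_interaction = TRUE) {
  d <- trials[trials$model_kind == "predator", , drop = FALSE]
  if (nrow(d) == 0) stop("no predator trials")
  d$vulnerability <- epsilon[cbind(d$focal_species, d$predator_id)]
  d$alarm <- as.numeric(d$alarm_given)
  d$focal_species <- factor(d$focal_species)
  d <- standardize_covariates(d, "group_size")
  terms <- c("focal_species", "vulnerability",
             if (include_interaction) "focal_species:vulnerability",
             "distance_m", "group_size", "young_present")
  spec <- model_spec("alarm", "binomial", terms,
                     data_filter = "model_kind == 'predator'")
  fit <- fit_model(spec, d)
  fit$vulnerability_coef <-
    fit$coefficients[fit$coefficients$term == "vulnerability", ]
  fit
}

#' Preliminary call-type model and control-trial exclusion
#'
#' Models the binary playback response on the full trial set with receiver
#' species, call type (control / conspecific / heterospecific; control is
#' the reference level), optionally their interaction, and the environmental
#' covariates. Returns the contrasts of both alarm-call types against the
#' control sound and the control-free dataset used by all downstream
#' response models.
#'
#' @param playbacks playback trial table including control trials.
#' @param include_interaction include receiver x call-type interaction.
#' @return list of class `alarm_calltype`: `fit`, `contrasts` (conspecific
#'   and heterospecific vs control) and `data` (trials without controls).
#' @export
preliminary_calltype_model <- function(playbacks, include_interaction = TRUE) {
  lev <- c("control", "conspecific", "heterospecific")
  found <- intersect(lev, unique(playbacks$call_kind))
  if (length(found) < 3)
    stop("call type level(s) absent: ",
         paste(setdiff(lev, found), collapse = ", "))
  d <- playbacks
  d$call_kind <- factor(d$call_kind, levels = lev)
  d$receiver <- factor(d$receiver)
  d$response <- as.numeric(d$responded)
  d <- standardize_covariates(d, "group_size")
  terms <- c("receiver", "call_kind",
             if (include_interaction) "receiver:call_kind",
             "grass_height_cm", "cover_proximity_m", "speaker_distance_m",
             "wind_speed_ms", "group_size")
  spec <- model_spec("response", "binomial", terms)
  fit <- fit_model(spec, d)
  ct <- fit$coefficients[fit$coefficients$term %in%
                           c("call_kindconspecific",
                             "call_kindheterospecific"), ]
  structure(list(fit = fit, contrasts = ct,
                 data = playbacks[playbacks$call_kind != "control", ,
                                  drop = FALSE]),
            class = "alarm_calltype")
}

response_model_terms <- function() {
  c("receiver_size", "size_ratio", "I(size_ratio^2)",
    "receiver_size:size_ratio", "receiver_size:I(size_ratio^2)",
    "consistency", "reliability", "similarity", "abundance",
    "grass_height", "cover_proximity", "speaker_distance",
    "wind_speed", "group_size")
}

#' Fit the playback response-model suite
#'
#' Fits the six response models on heterospecific playback trials (control
#' trials must already be excluded; conspecific trials are excluded by
#' default): a binomial mixed model for response probability; log-linear
#' mixed models for latency, time to resumed foraging and head-lift speed
#' (fitted on responded trials, duration additionally excluding censored
#' trials); and negative-binomial mixed models for head-up and scratch
#' counts. All models share the same fixed-effect terms — receiver body
#' size, linear and quadratic size ratio and their interactions with
#' receiver size, caller consistency, call reliability, acoustic similarity,
#' caller abundance and the five environmental covariates — and a
#' per-receiver random intercept. Covariates are prepared with
#' [prepare_playback_covariates()]. P-values are Wald for the binomial and
#' negative-binomial mixed models and likelihood-ratio tests for the
#' log-linear mixed models.
#'
#' @param playbacks playback trials without control rows (see
#'   [preliminary_calltype_model()]).
#' @param indices an `alarm_indices` object.
#' @param similarity acoustic similarity matrix.
#' @param include_conspecific keep conspecific trials (default `FALSE`).
#' @param models subset of model names to fit.
#' @param nagq integration setting for the binomial mixed fit.
#' @return named list of `alarm_fit` objects, class `alarm_fit_suite`.
#' @export
fit_response_models <- function(playbacks, indices, similarity,
                                include_conspecific = FALSE,
                                models = c("probability", "latency",
                                           "duration", "headlift",
                                           "head_ups", "scratches"),
                                nagq = 1) {
  models <- match.arg(models, several.ok = TRUE)
  if (any(playbacks$call_kind == "control"))
    stop("control trials must be excluded first (preliminary_calltype_model)")
  d <- playbacks
  if (!include_conspecific)
    d <- d[d$call_kind == "heterospecific", , drop = FALSE]
  d <- prepare_playback_covariates(d, indices, similarity)
  d <- d[!is.na(d$similarity), , drop = FALSE]  # receivers with no own alarm
  d$response <- as.numeric(d$responded)
  terms <- response_model_terms()
  resp <- d[d$responded, , drop = FALSE]
  dur <- resp[!resp$duration_censored & !is.na(resp$duration_s), , drop = FALSE]
  defs <- list(
    probability = list(spec = model_spec("response", "binomial", terms,
                                         "receiver"), data = d,
                       pv = "wald"),
    latency = list(spec = model_spec("latency_s", "lognormal", terms,
                                     "receiver"), data = resp, pv = "lrt"),
    duration = list(spec = model_spec("duration_s", "lognormal", terms,
                                      "receiver",
                                      data_filter = "!duration_censored"),
                    data = dur, pv = "lrt"),
    headlift = list(spec = model_spec("headlift_speed", "lognormal", terms,
                                      "receiver"), data = resp, pv = "lrt"),
    head_ups = list(spec = model_spec("n_head_ups", "negbin", terms,
                                      "receiver"), data = resp, pv = "wald"),
    scratches = list(spec = model_spec("n_scratches", "negbin", terms,
                                       "receiver"), data = resp, pv = "wald"))
  fits <- lapply(defs[models], function(def)
    fit_model(def$spec, def$data, pvalues = def$pv, nagq = nagq))
  structure(fits, class = "alarm_fit_suite")
}

#' @export
print.alarm_fit_suite <- function(x, ...) {
  cat("Playback response model suite (", length(x), " models)\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-12s n = %5d  AICc = %10.2f%s\n", nm, x[[nm]]$n,
                x[[nm]]$aicc, if (!x[[nm]]$converged) "  [not converged]" else ""))
  invisible(x)
}

#' Wilcoxon signed-rank check of control playbacks against baseline
#'
#' Tests whether per-subject head-up rates during control playbacks differ
#' from undisturbed baseline observation, using the exact signed-rank
#' statistic V (the sum of ranks of positive differences; V = n(n+1)/2 when
#' every control rate exceeds its baseline).
#'
#' @param control,baseline paired nonnegative per-subject rates.
#' @return list with `V`, `p`, `n` (pairs with nonzero difference) and a
#'   `degenerate` flag (all differences zero).
#' @export
wilcoxon_control_check <- function(control, baseline) {
  if (length(control) != length(baseline))
    stop("control and baseline must be paired (equal length)")
  if (any(control < 0 | baseline < 0)) stop("rates must be nonnegative")
  d <- control - baseline
  if (all(d == 0))  # no signal at all: flagged, p = 1 by convention
    return(list(V = 0, p = 1, n = 0L, degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(control, baseline,
                                            paired = TRUE, exact = TRUE))
  list(V = unname(wt$statistic), p = wt$p.value, n = sum(d != 0),
       degenerate = FALSE)
}
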
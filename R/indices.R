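#' Transform a Jacobs selectivity index to a vulnerability weight
#'
#' Predator preference for a prey species is commonly reported as the Jacobs
#' index, a selectivity measure in \[-1, 1\] where -1 means complete avoidance
#' and +1 complete preference. Downstream indices need a weight in \[0, 1\]
#' where values close to 1 indicate high vulnerability; the default transform
#' is the affine map (D + 1) / 2, the unique affine bijection between the two
#' ranges.
#'
#' @param D numeric vector or matrix of Jacobs index values in \[-1, 1\].
#' @param transform monotone function mapping \[-1, 1\] onto \[0, 1\];
#'   defaults to the affine map.
#' @return object of the same shape as `D` with values in \[0, 1\].
#' @examples
#' jacobs_transform(c(-1, 0, 1))
#' @export
jacobs_transform <- function(D, transform = function(d) (d + 1) / 2) {
  if (!is.numeric(D)) stop("`D` must be numeric")
  if (any(is.na(D))) stop("`D` contains missing values")
  if (any(D < -1 | D > 1)) {
    stop("Jacobs index values must lie in [-1, 1]; offending value(s): ",
         paste(utils::head(D[D < -1 | D > 1], 3), collapse = ", "))
  }
  eps <- transform(D)
  if (any(eps < 0 | eps > 1)) stop("`transform` produced values outside [0, 1]")
  eps
}

#' Estimate per-predator alarm propensities from predator-simulation trials
#'
#' For each (predator, focal species) cell, the alarm propensity I(x, j) is
#' the proportion of simulation trials in which species j alarm-called when
#' presented with a model of predator x. Cells with no trials are left `NA`
#' and flagged; they are never imputed, because an observed zero (a species
#' that never alarms) is informative while an unobserved cell is not.
#'
#' @param trials data frame of predator-simulation trials with columns
#'   `focal_species`, `model_kind` ("predator" or "control"), `predator_id`
#'   and logical `alarm_given`.
#' @return list with matrices `I` (predator x species alarm proportions) and
#'   `n_trials` (cell counts); `NA` entries in `I` mark empty cells.
#' @export
estimate_alarm_propensity <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) stop("empty trial list")
  need <- c("focal_species", "model_kind", "predator_id", "alarm_given")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack column(s): ", paste(miss, collapse = ", "))
  pred <- trials[trials$model_kind == "predator", , drop = FALSE]
  if (nrow(pred) == 0L) stop("no predator trials present")
  predators <- sort(unique(pred$predator_id))
  species   <- sort(unique(trials$focal_species))
  n <- table(factor(pred$predator_id, predators),
             factor(pred$focal_species, species))
  a <- stats::xtabs(alarm_given ~ factor(predator_id, predators) +
                      factor(focal_species, species), data = pred)
  n_mat <- matrix(as.integer(n), nrow(n), ncol(n),
                  dimnames = list(predator = predators, species = species))
  I <- matrix(as.numeric(a) / ifelse(n_mat > 0, n_mat, NA_real_),
              nrow(n_mat), ncol(n_mat), dimnames = dimnames(n_mat))
  list(I = I, n_trials = n_mat)
}

#' Estimate call-profile matrix from predator-simulation trials
#'
#' C(x, j) is the proportion of species j's alarm calls elicited by predator
#' x when all predator models are presented with equal frequency. Because
#' realised trial counts need not be exactly equal, the estimate normalises
#' per-predator alarm *rates* rather than raw call counts: with exactly
#' balanced trials the two coincide, with unbalanced trials the rate form
#' removes the sampling-frequency bias. Callers with no alarms at all get an
#' all-`NA` column, flagged in the `"undefined_callers"` attribute — a caller
#' that never calls has no call profile.
#'
#' @inheritParams estimate_alarm_propensity
#' @return matrix C (predator x caller), each defined column summing to 1;
#'   attribute `"undefined_callers"` lists callers with no alarms.
#' @export
estimate_call_profile <- function(trials) {
  est <- estimate_alarm_propensity(trials)
  I <- est$I
  tot <- colSums(I, na.rm = TRUE)
  any_obs <- colSums(!is.na(I)) > 0
  C <- sweep(I, 2, ifelse(tot > 0, tot, NA_real_), "/")
  undefined <- colnames(I)[!(any_obs & tot > 0)]
  C[, colnames(I) %in% undefined] <- NA_real_
  attr(C, "undefined_callers") <- undefined
  C
}

#' Caller consistency index
#'
#' The consistency L(i, j) of caller species j from the viewpoint of receiver
#' species i is the probability that j alarm-calls when presented with a
#' predator, weighted by the relative encounter probability of that predator
#' and by the receiver's vulnerability to it, summed over all predators. The
#' default normalised form divides by the total encounter-weighted
#' vulnerability so that a perfect informant (one that always calls to every
#' predator) scores exactly 1; the raw weighted sum is available with
#' `normalize = FALSE` for sensitivity analysis. Low L(i, j) means j often
#' stays silent when i's predators are present (false negatives).
#'
#' @param I alarm-propensity matrix, predator x caller, entries in \[0, 1\].
#' @param epsilon vulnerability matrix, receiver x predator, entries in
#'   \[0, 1\].
#' @param A nonnegative predator abundance weights (length = n predators);
#'   normalised internally to sum to 1.
#' @param normalize divide by the receiver's total encounter-weighted
#'   vulnerability (default `TRUE`).
#' @return matrix L, receiver x caller; rows with zero total weight are `NA`
#'   and flagged in attribute `"undefined_receivers"`.
#' @export
caller_consistency <- function(I, epsilon, A, normalize = TRUE) {
  I <- as.matrix(I); epsilon <- as.matrix(epsilon)
  if (ncol(epsilon) != nrow(I))
    stop("nonconformable: epsilon has ", ncol(epsilon),
         " predators but I has ", nrow(I))
  if (length(A) != nrow(I)) stop("`A` must have one weight per predator")
  if (any(A < 0) || all(A == 0)) stop("`A` must be nonnegative, not all zero")
  if (any(I < 0 | I > 1, na.rm = TRUE)) stop("`I` entries must lie in [0, 1]")
  if (any(epsilon < 0 | epsilon > 1, na.rm = TRUE))
    stop("`epsilon` entries must lie in [0, 1]")
  a <- A / sum(A)
  W <- sweep(epsilon, 2, a, "*")              # receiver x predator weights
  L <- W %*% I
  denom <- rowSums(W)
  if (normalize) {
    L <- sweep(L, 1, ifelse(denom > 0, denom, NA_real_), "/")
  }
  undef <- rownames(epsilon)[denom == 0]
  if (length(undef)) L[denom == 0, ] <- NA_real_
  dimnames(L) <- list(receiver = rownames(epsilon), caller = colnames(I))
  attr(L, "undefined_receivers") <- undef
  L
}

#' Call reliability index
#'
#' The reliability V(i, j) of a single alarm call of species j for receiver i
#' is the vulnerability-weighted composition of j's calls: the sum over
#' predators of the proportion of j's calls elicited by each predator times
#' the receiver's vulnerability to that predator. Since the call profile is a
#' probability distribution over predators, V is a convex combination of
#' vulnerabilities and lies in \[0, 1\]. Low V(i, j) means most of j's calls
#' denote carnivores that do not threaten i (false positives).
#'
#' @param C call-profile matrix, predator x caller; each defined column sums
#'   to 1 (undefined callers all-`NA`).
#' @param epsilon vulnerability matrix, receiver x predator.
#' @return matrix V, receiver x caller; columns for undefined callers `NA`.
#' @export
call_reliability <- function(C, epsilon) {
  C <- as.matrix(C); epsilon <- as.matrix(epsilon)
  if (ncol(epsilon) != nrow(C))
    stop("nonconformable: epsilon has ", ncol(epsilon),
         " predators but C has ", nrow(C))
  defined <- colSums(!is.na(C)) == nrow(C)
  cs <- colSums(C[, defined, drop = FALSE])
  if (any(abs(cs - 1) > 1e-8))
    stop("call-profile columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  V <- matrix(NA_real_, nrow(epsilon), ncol(C),
              dimnames = list(receiver = rownames(epsilon),
                              caller = colnames(C)))
  V[, defined] <- epsilon %*% C[, defined, drop = FALSE]
  attr(V, "undefined_callers") <- colnames(C)[!defined]
  V
}

#' Asymmetric body-size ratio between receiver and caller
#'
#' Lovich-Gibbons style ratio: receiver:caller mass when the receiver is the
#' larger species, and 2 - (caller:receiver) when the receiver is smaller.
#' The two branches agree (value 1) at equal masses, so the measure is
#' continuous; values above 1 mean a larger receiver, values below 1 (possibly
#' negative for extreme mismatches) a smaller one.
#'
#' @param receiver_mass,caller_mass positive adult body masses (kg);
#'   recycled to a common length.
#' @return numeric vector of size ratios.
#' @examples
#' body_size_ratio(100, 50)  # receiver twice as large -> 2
#' body_size_ratio(50, 100)  # receiver half as large  -> 0
#' @export
body_size_ratio <- function(receiver_mass, caller_mass) {
  if (any(receiver_mass <= 0, na.rm = TRUE) ||
      any(caller_mass <= 0, na.rm = TRUE))
    stop("body masses must be positive")
  ifelse(receiver_mass >= caller_mass,
         receiver_mass / caller_mass,
         2 - caller_mass / receiver_mass)
}

#' Affinely rescale a vector onto the unit interval
#'
#' Maps the minimum to 0 and the maximum to 1, preserving order and relative
#' spacing. Used to place covariates measured on arbitrary scales (size
#' ratio, acoustic similarity, abundance, consistency) on a common \[0, 1\]
#' scale before modelling.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return rescaled vector in \[0, 1\].
#' @export
scale_unit_interval <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    stop("unit-interval scaling undefined for constant or degenerate input")
  (values - min(v)) / (max(v) - min(v))
}

#' Derive the per-pair information-content indices for a community
#'
#' Bundles everything the response models need about each (receiver, caller)
#' pair: caller consistency L, call reliability V, the asymmetric body-size
#' ratio, caller relative abundance, body masses and vocal flags. Alarm
#' propensities and call profiles are estimated from predator-simulation
#' trials when supplied; otherwise the community's generating (true) alarm
#' propensities are used directly, with the call profile derived from them
#' under equal predator presentation frequency.
#'
#' @param community an `alarm_community` (see [generate_community()]).
#' @param predator_trials optional data frame of predator-simulation trials
#'   from which to estimate propensities; `NULL` uses the community's true
#'   values.
#' @param normalize_consistency passed to [caller_consistency()].
#' @return object of class `alarm_indices`: list with matrices `L`, `V`
#'   (receiver x caller), `size_ratio` (receiver x caller), vectors
#'   `abundance`, `mass_kg`, `vocal`, and the `epsilon` matrix used.
#' @export
derive_indices <- function(community, predator_trials = NULL,
                           normalize_consistency = TRUE) {
  stopifnot(inherits(community, "alarm_community"))
  eps <- community$vulnerability
  if (is.null(predator_trials)) {
    I <- community$alarm_propensity
    tot <- colSums(I)
    C <- sweep(I, 2, ifelse(tot > 0, tot, NA_real_), "/")
    attr(C, "undefined_callers") <- colnames(I)[tot == 0]
  } else {
    I <- estimate_alarm_propensity(predator_trials)$I
    I <- I[community$predators, community$species, drop = FALSE]
    C <- estimate_call_profile(predator_trials)
    C <- C[community$predators, community$species, drop = FALSE]
  }
  L <- caller_consistency(I, eps, community$predator_abundance,
                          normalize = normalize_consistency)
  V <- call_reliability(C, eps)
  m <- community$body_mass_kg
  sr <- outer(m, m, body_size_ratio)
  dimnames(sr) <- list(receiver = names(m), caller = names(m))
  structure(
    list(L = L, V = V, size_ratio = sr,
         abundance = community$herbivore_abundance,
         mass_kg = m, vocal = community$vocal,
         epsilon = eps, I = I, C = C),
    class = "alarm_indices")
}

#' @export
print.alarm_indices <- function(x, ...) {
  cat("Alarm information-content indices\n")
  cat("  receivers:", nrow(x$L), " callers:", ncol(x$L),
      " (", sum(x$vocal), "vocal )\n")
  cat("  mean consistency L:",
      format(mean(x$L[, x$vocal], na.rm = TRUE), digits = 3),
      "  mean reliability V:",
      format(mean(x$V[, x$vocal], na.rm = TRUE), digits = 3), "\n")
  invisible(x)
}

#' Write a receiver x caller index matrix in long format
#'
#' @param mat matrix with receiver rows and caller columns.
#' @param path output CSV path.
#' @param value_name name for the value column.
#' @return the long data frame, invisibly.
#' @export
write_index_long <- function(mat, path, value_name = "value") {
  long <- data.frame(
    receiver = rep(rownames(mat), times = ncol(mat)),
    caller = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat))
  names(long)[3] <- value_name
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}
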
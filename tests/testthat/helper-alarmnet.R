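# Shared fixtures, all built in code.

null_betas <- function() {
  stats::setNames(numeric(length(playback_beta_names())),
                  playback_beta_names())
}

# random index inputs on the scale the community uses
random_index_config <- function(seed, n_receivers = 12, n_predators = 5,
                                n_callers = n_receivers) {
  set.seed(seed)
  list(I = matrix(runif(n_predators * n_callers), n_predators, n_callers,
                  dimnames = list(paste0("p", 1:n_predators),
                                  paste0("c", 1:n_callers))),
       eps = matrix(runif(n_receivers * n_predators), n_receivers, n_predators,
                    dimnames = list(paste0("r", 1:n_receivers),
                                    paste0("p", 1:n_predators))),
       A = runif(n_predators, 0.1, 2))
}

# independent brute-force oracles (explicit scalar loops)
oracle_consistency <- function(I, eps, A, normalize = TRUE) {
  a <- A / sum(A)
  L <- matrix(NA_real_, nrow(eps), ncol(I))
  for (i in seq_len(nrow(eps))) for (j in seq_len(ncol(I))) {
    num <- 0; den <- 0
    for (x in seq_len(nrow(I))) {
      num <- num + I[x, j] * eps[i, x] * a[x]
      den <- den + eps[i, x] * a[x]
    }
    L[i, j] <- if (normalize) num / den else num
  }
  L
}

oracle_reliability <- function(C, eps) {
  V <- matrix(NA_real_, nrow(eps), ncol(C))
  for (i in seq_len(nrow(eps))) for (j in seq_len(ncol(C))) {
    s <- 0
    for (x in seq_len(nrow(C))) s <- s + C[x, j] * eps[i, x]
    V[i, j] <- s
  }
  V
}

# tiny predator-trial table with given per-cell counts/alarms
make_trials <- function(species, predator, n, alarms) {
  do.call(rbind, lapply(seq_along(species), function(k)
    data.frame(focal_species = species[k],
               model_kind = "predator",
               predator_id = predator[k],
               alarm_given = rep(c(TRUE, FALSE),
                                 c(alarms[k], n[k] - alarms[k])),
               stringsAsFactors = FALSE)))
}

random_feature_table <- function(seed, n_species = 5, n_calls = 4) {
  set.seed(seed)
  tab <- data.frame(species = rep(paste0("sp", 1:n_species), each = n_calls))
  for (f in acoustic_feature_names())
    tab[[f]] <- runif(nrow(tab), 0.1, 10)
  tab
}

# event log rows
ev <- function(time_s, event) data.frame(time_s = time_s, event = event)
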
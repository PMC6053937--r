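# Behavioural response coding. Playback videos are assumed to have been
# transcribed into tidy event logs (one row per behavioural event with a
# timestamp); this module converts those logs into the binary and continuous
# response variables used by the model suite, and can render the latent
# responses of simulated trials into event logs so that coding can be
# validated end-to-end.

#' Event kinds recognised in behavioural logs
#' @return character vector of valid `event` values.
#' @export
event_kinds <- function() {
  c("head_up_start", "head_up_end", "forage_start", "forage_end",
    "scratch", "other_behaviour_change")
}

#' Default set of events that count as a behavioural response
#'
#' A response is any behavioural change after the playback other than
#' continued foraging; by default head-lifts, scratches and other coded
#' behaviour changes qualify, while foraging-state transitions do not. The
#' vocabulary is configurable because the full behavioural ethogram differs
#' between studies.
#'
#' @return character vector of qualifying event kinds.
#' @export
response_event_kinds <- function() {
  c("head_up_start", "scratch", "other_behaviour_change")
}

check_event_log <- function(events, trial = NULL) {
  need <- c("time_s", "event")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("malformed event log", if (!is.null(trial)) paste0(" (trial ", trial, ")"),
         ": missing column(s) ", paste(miss, collapse = ", "))
  if (is.unsorted(events$time_s))
    stop("malformed event log", if (!is.null(trial)) paste0(" (trial ", trial, ")"),
         ": timestamps must be non-decreasing")
  bad <- setdiff(unique(events$event), event_kinds())
  if (length(bad))
    stop("malformed event log", if (!is.null(trial)) paste0(" (trial ", trial, ")"),
         ": unknown event kind(s) ", paste(bad, collapse = ", "))
  invisible(events)
}

# forage intervals as (start, end) pairs; an interval open at the log end is
# closed at max(log time, floor_end)
forage_intervals <- function(events, floor_end = -Inf) {
  st <- events$time_s[events$event == "forage_start"]
  en <- events$time_s[events$event == "forage_end"]
  log_end <- max(c(events$time_s, floor_end))
  if (length(en) < length(st)) en <- c(en, log_end)
  if (length(st) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = st, end = en[seq_along(st)])
}

#' Code the binary playback response from an event log
#'
#' `TRUE` iff any qualifying behavioural event (see
#' [response_event_kinds()]) occurs within `window_s` seconds after playback
#' onset. The window is closed on the right: an event at exactly
#' `onset + window_s` counts as a response.
#'
#' @param events event log for one trial (`time_s`, `event`).
#' @param onset_s playback onset time (s) on the log's clock.
#' @param window_s response window length (default 10 s).
#' @param response_events event kinds that qualify as a response.
#' @param trial optional trial id used in error messages.
#' @return logical scalar.
#' @export
code_binary_response <- function(events, onset_s, window_s = 10,
                                 response_events = response_event_kinds(),
                                 trial = NULL) {
  check_event_log(events, trial)
  if (onset_s < 0) stop("onset must be nonnegative")
  any(events$event %in% response_events &
        events$time_s > onset_s &
        events$time_s <= onset_s + window_s)
}

#' Code latency, duration and counts from an event log
#'
#' Produces the full response record for one trial: the binary response;
#' latency to the first qualifying event; time until foraging was resumed
#' for at least `min_forage_s` seconds (anchored to the start of the first
#' post-onset foraging interval of at least that length); counts of head-ups
#' and scratches after onset; and the supplied head-lift speed. All
#' continuous variables are undefined (`NA`) when no response occurred.
#' Trials where the animal responded but never resumed foraging within the
#' log are flagged `duration_censored` with `NA` duration.
#'
#' @inheritParams code_binary_response
#' @param min_forage_s minimum resumed-foraging bout length (default 10 s).
#' @param headlift_speed optional externally measured head-lift angular
#'   speed for this trial (carried through when a response occurred).
#' @return one-row data frame: `responded`, `latency_s`, `duration_s`,
#'   `duration_censored`, `headlift_speed`, `n_head_ups`, `n_scratches`.
#' @export
code_continuous_response <- function(events, onset_s, window_s = 10,
                                     min_forage_s = 10,
                                     response_events = response_event_kinds(),
                                     headlift_speed = NA_real_,
                                     trial = NULL) {
  check_event_log(events, trial)
  responded <- code_binary_response(events, onset_s, window_s,
                                    response_events, trial)
  post <- events[events$time_s > onset_s, , drop = FALSE]
  n_head_ups <- sum(post$event == "head_up_start")
  n_scratches <- sum(post$event == "scratch")
  latency <- duration <- NA_real_
  censored <- FALSE
  if (responded) {
    qual <- post$time_s[post$event %in% response_events]
    latency <- min(qual) - onset_s
    iv <- forage_intervals(events)
    iv <- iv[iv$start > onset_s & (iv$end - iv$start) >= min_forage_s, ,
             drop = FALSE]
    if (nrow(iv)) duration <- iv$start[1] - onset_s else censored <- TRUE
  }
  data.frame(responded = responded,
             latency_s = latency,
             duration_s = duration,
             duration_censored = censored,
             headlift_speed = if (responded) headlift_speed else NA_real_,
             n_head_ups = n_head_ups,
             n_scratches = n_scratches)
}

#' Pre-trial relaxation filter
#'
#' Playback trials target animals that were relaxed and foraging
#' continuously for at least `min_forage_s` seconds immediately before the
#' playback. `TRUE` iff a single foraging interval covers
#' \[onset - min_forage_s, onset\].
#'
#' @inheritParams code_binary_response
#' @param min_forage_s required pre-onset foraging bout (default 20 s).
#' @return logical scalar.
#' @export
pretrial_relaxation_filter <- function(events, onset_s, min_forage_s = 20,
                                       trial = NULL) {
  check_event_log(events, trial)
  iv <- forage_intervals(events, floor_end = onset_s)
  any(iv$start <= onset_s - min_forage_s & iv$end >= onset_s)
}

#' Render simulated playback trials as behavioural event logs
#'
#' Produces, for each simulated trial, an event log whose coding (see
#' [code_responses()]) recovers the trial's latent response variables
#' exactly: a pre-onset foraging bout, the first qualifying event at
#' onset + latency, head-up and scratch events spread over the response
#' bout, and (unless the duration was censored) foraging resuming at
#' onset + duration for longer than the minimum bout length.
#'
#' @param trials playback trial table from [simulate_playbacks()].
#' @param onset_s playback onset time on each log's clock (default 30 s).
#' @return object of class `alarm_event_logs`: list with `events` (long data
#'   frame `trial_id`, `time_s`, `event`) and `meta` (`trial_id`, `onset_s`,
#'   `headlift_speed`).
#' @export
playback_event_logs <- function(trials, onset_s = 30) {
  stopifnot(is.data.frame(trials), "responded" %in% names(trials))
  one <- function(k) {
    t_on <- onset_s
    ev <- data.frame(time_s = t_on - 25, event = "forage_start")
    if (trials$responded[k]) {
      lat <- trials$latency_s[k]
      cens <- isTRUE(trials$duration_censored[k])
      dur <- if (cens) NA_real_ else trials$duration_s[k]
      nh <- trials$n_head_ups[k]; ns <- trials$n_scratches[k]
      span_end <- t_on + if (cens) lat + 30 else dur
      slots <- max(nh + ns, 1L)
      step <- 0.9 * (span_end - (t_on + lat)) / slots
      at <- t_on + lat + (seq_len(slots) - 1) * step
      ev <- rbind(ev, data.frame(time_s = t_on + lat, event = "forage_end"))
      if (nh + ns == 0L) {
        ev <- rbind(ev, data.frame(time_s = at[1],
                                   event = "other_behaviour_change"))
      } else {
        kinds <- c(rep("head_up_start", nh), rep("scratch", ns))
        ev <- rbind(ev, data.frame(time_s = at, event = kinds))
        if (nh > 0)
          ev <- rbind(ev, data.frame(time_s = at[seq_len(nh)] + 0.4 * step,
                                     event = "head_up_end"))
      }
      if (!cens)
        ev <- rbind(ev,
                    data.frame(time_s = c(t_on + dur, t_on + dur + 15),
                               event = c("forage_start", "forage_end")))
    }
    ev <- ev[order(ev$time_s), , drop = FALSE]
    ev$trial_id <- trials$trial_id[k]
    ev[c("trial_id", "time_s", "event")]
  }
  events <- do.call(rbind, lapply(seq_len(nrow(trials)), one))
  rownames(events) <- NULL
  structure(list(
    events = events,
    meta = data.frame(trial_id = trials$trial_id, onset_s = onset_s,
                      headlift_speed = trials$headlift_speed)),
    class = "alarm_event_logs")
}

#' Code all trials of an event-log set
#'
#' Applies [code_continuous_response()] to every trial in an
#' `alarm_event_logs` object (or to a long event data frame plus metadata)
#' and returns one response record per trial.
#'
#' @param logs an `alarm_event_logs` object.
#' @param ... passed to [code_continuous_response()].
#' @return data frame with one coded response row per trial.
#' @export
code_responses <- function(logs, ...) {
  stopifnot(inherits(logs, "alarm_event_logs"))
  split_ev <- split(logs$events[c("time_s", "event")], logs$events$trial_id)
  out <- lapply(seq_len(nrow(logs$meta)), function(k) {
    id <- logs$meta$trial_id[k]
    ev <- split_ev[[as.character(id)]]
    rec <- code_continuous_response(ev, logs$meta$onset_s[k],
                                    headlift_speed = logs$meta$headlift_speed[k],
                                    trial = id, ...)
    cbind(trial_id = id, rec)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
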
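# Joining trial events with the respiratory phase: exclusion rules,
# epoching around stimulus onsets, per-trial cycle durations.

#' Apply trial exclusion rules
#'
#' A trial is included when (i) its onset falls inside a segmented,
#' typical respiratory cycle, (ii) a response was given (only where a
#' response deadline applies), and (iii) its reaction time lies within
#' `[rt_min_s, rt_max_s]`. Each excluded trial carries exactly one primary
#' reason, assessed in the order no-coverage, atypical-cycle, no-response,
#' rt-too-short / rt-too-long.
#'
#' @param table trial table with `onset_s`, `rt_s`, `responded`.
#' @param cycles a `cycle_set` (after [flag_atypical()]).
#' @param rt_min_s,rt_max_s reaction-time bounds, seconds.
#' @param deadline_required if `TRUE`, trials without a response are
#'   excluded (blocked-deadline paradigm); if `FALSE` they are retained.
#' @return the table with logical `included`, character `reason` (NA for
#'   included trials) and `cycle_duration_s` columns.
#' @export
filter_trials <- function(table, cycles, rt_min_s = 0.2, rt_max_s = 3.0,
                          deadline_required = TRUE) {
  stopifnot(inherits(cycles, "cycle_set"))
  ph <- phase_at(cycles, table$onset_s)
  reason <- rep(NA_character_, nrow(table))
  covered <- !is.na(ph$cycle)
  reason[!covered] <- "no-coverage"
  atyp <- covered & !ph$valid
  reason[is.na(reason) & atyp] <- "atypical-cycle"
  if (deadline_required) {
    noresp <- !is.na(table$responded) & !table$responded
    reason[is.na(reason) & noresp] <- "no-response"
  }
  has_rt <- !is.na(table$rt_s)
  reason[is.na(reason) & has_rt & table$rt_s < rt_min_s] <- "rt-too-short"
  reason[is.na(reason) & has_rt & table$rt_s > rt_max_s] <- "rt-too-long"
  table$included <- is.na(reason)
  table$reason <- reason
  table$cycle_duration_s <- ifelse(covered,
                                   cycles$end_s[ph$cycle] - cycles$onset_s[ph$cycle],
                                   NA_real_)
  table
}

#' Epoch the respiratory phase around stimulus onsets
#'
#' Slices the continuous 20 Hz phase series into trial epochs on a time
#' axis relative to stimulus onset; each trial's onset is mapped to the
#' nearest phase-series sample. Cells outside the recording span or inside
#' atypical cycles are masked invalid. The default window spans -8 to +4 s
#' (241 samples at 20 Hz).
#'
#' @param phase a `phase_series` from [compute_phase()].
#' @param table trial table; only rows with `included == TRUE` are epoched
#'   (all rows if there is no `included` column).
#' @param window_s length-2 numeric, epoch window relative to onset.
#' @return an `epoched_phase`: list with `phase` (trials x time matrix),
#'   `valid` (logical mask), `time_s` (relative axis), `onset_s`,
#'   `condition`, `fs_out`.
#' @export
epoch_phase <- function(phase, table, window_s = c(-8, 4)) {
  stopifnot(inherits(phase, "phase_series"))
  if (!is.null(table$included)) table <- table[table$included, , drop = FALSE]
  if (nrow(table) == 0) stop("no included trials to epoch")
  fs <- phase$fs_out
  rel_k <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  rel_t <- rel_k / fs
  k_start <- round(phase$time_s[1] * fs)
  n_grid <- length(phase$time_s)
  k0 <- round(table$onset_s * fs)
  col_idx <- outer(k0 - k_start, rel_k, "+") + 1L
  inrange <- col_idx >= 1L & col_idx <= n_grid
  ph <- matrix(NA_real_, nrow(table), length(rel_k))
  vv <- matrix(FALSE, nrow(table), length(rel_k))
  ph[inrange] <- phase$phase_rad[col_idx[inrange]]
  vv[inrange] <- phase$valid[col_idx[inrange]]
  vv[is.na(ph)] <- FALSE
  if (all(!vv)) warning("epoch window has no valid samples for any trial")
  structure(list(phase = ph, valid = vv, time_s = rel_t,
                 onset_s = table$onset_s, condition = table$condition,
                 fs_out = fs),
            class = "epoched_phase")
}

#' Duration of the respiratory cycle containing each stimulus onset
#'
#' Cycle membership is half-open (`[onset, end)`), so an onset exactly at
#' a shared boundary trough belongs to the cycle starting there.
#'
#' @param table trial table with `onset_s`.
#' @param cycles a `cycle_set`.
#' @return the table with `cycle_duration_s` (NA where the onset is not
#'   covered by a complete cycle).
#' @export
cycle_duration_at_onset <- function(table, cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  ph <- phase_at(cycles, table$onset_s)
  table$cycle_duration_s <- ifelse(!is.na(ph$cycle),
                                   cycles$end_s[ph$cycle] - cycles$onset_s[ph$cycle],
                                   NA_real_)
  table
}

#' Subset an epoched phase by condition
#'
#' @param epochs an `epoched_phase`.
#' @param condition condition label to keep.
#' @return an `epoched_phase` with only that condition's trials.
#' @export
epochs_by_condition <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epoched_phase"))
  sel <- epochs$condition == condition
  structure(list(phase = epochs$phase[sel, , drop = FALSE],
                 valid = epochs$valid[sel, , drop = FALSE],
                 time_s = epochs$time_s, onset_s = epochs$onset_s[sel],
                 condition = epochs$condition[sel], fs_out = epochs$fs_out),
            class = "epoched_phase")
}
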
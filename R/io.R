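# Plain-text readers/writers for traces, cycles, phase series and trial
# tables.

#' Read a respiration trace from CSV
#'
#' Accepts either a two-column file (`time_s`, `amplitude`) — the sampling
#' rate is inferred from the time column, which must be uniform — or a
#' single-column amplitude file with `fs` supplied.
#'
#' @param path file path.
#' @param fs sampling rate, Hz; required for single-column files.
#' @return a [respiration_trace()].
#' @export
read_respiration_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (ncol(d) >= 2) {
    dt <- diff(d[[1]])
    if (any(abs(dt - dt[1]) > 1e-6))
      stop("non-uniform time column: trace has gaps")
    respiration_trace(d[[2]], fs = 1 / dt[1], t0 = d[[1]][1])
  } else {
    if (is.null(fs)) stop("single-column trace needs an explicit fs")
    respiration_trace(d[[1]], fs = fs)
  }
}

#' Write a respiration trace as two-column CSV
#'
#' @param trace a [respiration_trace()].
#' @param path output path.
#' @export
write_respiration_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              amplitude = trace$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a cycle set as TSV
#' @param cycles a `cycle_set`.
#' @param path output path.
#' @export
write_cycles_tsv <- function(cycles, path) {
  utils::write.table(as.data.frame(cycles), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phase series as CSV
#' @param phase a `phase_series`.
#' @param path output path.
#' @export
write_phase_csv <- function(phase, path) {
  utils::write.csv(data.frame(time_s = phase$time_s,
                              phase_rad = phase$phase_rad,
                              valid = phase$valid),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a trial table as TSV
#' @param table trial table.
#' @param path output path.
#' @export
write_trial_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#' @param path file path.
#' @return data frame.
#' @export
read_trial_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
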
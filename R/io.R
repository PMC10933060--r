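#' Trace, spike-train, raster and report writers
#'
#' Plain-text output formats: traces as CSV with header
#' `time_ms,v_mV,u,qs_flag`; spike trains as one time (ms) per line; rasters
#' as CSV `time_ms,neuron_id`; sweep reports as CSV matching the comparison
#' columns `delta_mv,te_pct,nrmsd_pct,csp_pct,speedup_pct`.
#'
#' @param trace an `izh_trace`.
#' @param path output file path.
#' @return The path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_ms = trace$times, v_mV = trace$v, u = trace$u,
                   qs_flag = as.integer(trace$qs_mask))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @param spikes a `spike_train`.
#' @export
write_spike_train <- function(spikes, path) {
  writeLines(format(as.numeric(spikes), trim = TRUE), path)
  invisible(path)
}

#' @rdname writers
#' @param sim a `network_sim` or raster data frame.
#' @export
write_raster_csv <- function(sim, path) {
  raster <- if (inherits(sim, "network_sim")) sim$raster else sim
  names(raster) <- c("time_ms", "neuron_id")
  write.csv(raster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @param report a data frame as returned by [duplex_sweep()].
#' @export
write_comparison_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write pattern bitmaps
#'
#' Pattern fixtures are 7 lines of 6 characters, `#` for an active pixel,
#' `.` for inactive.
#'
#' @param path file path.
#' @param label label to attach to the read stimulus.
#' @param ... passed to [pattern_stimulus()].
#' @return [read_pattern()] returns a `pattern_stimulus`.
#' @export
read_pattern <- function(path, label = NULL, ...) {
  rows <- readLines(path)
  rows <- rows[nzchar(rows)]
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  pattern_stimulus(label, grid = parse_glyph(rows), ...)
}

#' @rdname read_pattern
#' @param p a `pattern_stimulus`.
#' @export
write_pattern <- function(p, path) {
  m <- matrix(c(".", "#")[p$grid + 1L], 7, 6, byrow = TRUE)
  writeLines(apply(m, 1, paste, collapse = ""), path)
  invisible(path)
}
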
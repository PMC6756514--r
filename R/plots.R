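#' QC plot: lag map slices
#'
#' @param ls a [track_lags()] result.
#' @param slices z indices to display (defaults to three evenly spaced).
#' @export
plot_lag_map <- function(ls, slices = NULL) {
  stopifnot(inherits(ls, "lag_structure"))
  d <- dim(ls$lag_map)
  if (is.null(slices)) slices <- unique(round(seq(1, d[3], length.out = 3)))
  op <- graphics::par(mfrow = c(1, length(slices)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  zlim <- c(-1, 1) * max(abs(ls$lag_map), na.rm = TRUE)
  for (z in slices) {
    graphics::image(ls$lag_map[, , z], col = pal, zlim = zlim, axes = FALSE,
                    main = sprintf("lag (s), z = %d", z))
  }
  invisible(ls)
}

#' QC plot: lag-bin seed time courses
#'
#' Seed series stacked from upstream (warm) to downstream (cool).
#'
#' @param ls a [track_lags()] result.
#' @param t_range optional time window (s) to display.
#' @export
plot_seed_series <- function(ls, t_range = NULL) {
  stopifnot(inherits(ls, "lag_structure"))
  S <- ls$seed_series
  tt <- (seq_len(nrow(S)) - 1) * ls$frame_interval_s
  keep <- if (is.null(t_range)) rep(TRUE, length(tt)) else
    tt >= t_range[1] & tt <= t_range[2]
  pal <- grDevices::hcl.colors(ncol(S), "Blue-Red 2", rev = TRUE)
  off <- 2 * stats::sd(S) * seq_len(ncol(S))
  graphics::matplot(tt[keep], sweep(S[keep, , drop = FALSE], 2, off),
                    type = "l", lty = 1, col = pal,
                    xlab = "time (s)", ylab = "seed series (offset)",
                    main = "lag-bin seed time courses")
  invisible(ls)
}

#' QC plot: rBTT / relative velocity trace
#'
#' @param trace an [rbtt_trace()] result.
#' @param what `"velocity"`, `"rbtt"`, or `"phase_diff"`.
#' @export
plot_rbtt <- function(trace, what = c("velocity", "rbtt", "phase_diff")) {
  what <- match.arg(what)
  graphics::plot(trace$time, trace[[what]], type = "l",
                 xlab = "time (s)", ylab = what,
                 main = paste(unique(trace$label), what))
  graphics::abline(h = switch(what, velocity = 1, rbtt = 1, phase_diff = 0.5),
                   lty = 2, col = "grey")
  invisible(trace)
}
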
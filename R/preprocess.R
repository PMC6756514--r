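#' Detect motion/intensity spike frames
#'
#' Flags frames violating either of two stringent data-repair criteria:
#' a global-mean intensity change exceeding `global_thresh_pct` percent of
#' the session mean, or a head displacement exceeding `trans_thresh_mm`
#' (Euclidean norm of the three translation steps) or `rot_thresh_deg` (any
#' rotation step). Either criterion suffices (OR); the per-criterion hits are
#' both reported so an AND rule is recoverable.
#'
#' Changes are measured against a short running-median reference (window of
#' 5 frames), so a transient deflection of one or two frames flags exactly
#' those frames — not the recovery step, and without mistaking slow in-band
#' drift of the global signal for dropout. Sustained level shifts are left
#' to the motion regressors.
#'
#' @param vol a [ts_volume()].
#' @param motion optional motion table (6 columns, one row per frame).
#' @param global_thresh_pct global-change threshold, percent of session mean.
#' @param trans_thresh_mm translation step threshold (mm, Euclidean norm).
#' @param rot_thresh_deg rotation step threshold (degrees, per axis).
#' @return A `repair_report`: data frame with columns `frame`,
#'   `global_change`, `displacement` (logical criterion hits), with the
#'   interpolation method recorded in `attr(, "interpolation")`.
#' @export
detect_spikes <- function(vol, motion = NULL, global_thresh_pct = 1,
                          trans_thresh_mm = 1, rot_thresh_deg = 1) {
  nt <- n_frames(vol)
  g <- global_signal(vol)
  gm <- mean(g)
  ref <- stats::runmed(g, 5, endrule = "median")
  hit_g <- abs(g - ref) / gm * 100 > global_thresh_pct
  hit_m <- logical(nt)
  if (!is.null(motion)) {
    m <- as.matrix(motion)
    if (nrow(m) != nt)
      stop("motion table rows (", nrow(m), ") must match frame count (", nt, ")")
    dev <- m - apply(m, 2, stats::runmed, k = 5, endrule = "median")
    hit_m <- sqrt(rowSums(dev[, 1:3, drop = FALSE]^2)) > trans_thresh_mm |
      apply(abs(dev[, 4:6, drop = FALSE]) > rot_thresh_deg, 1, any)
  }
  flagged <- which(hit_g | hit_m)
  rep <- data.frame(frame = flagged, global_change = hit_g[flagged],
                    displacement = hit_m[flagged])
  attr(rep, "interpolation") <- "linear"
  class(rep) <- c("repair_report", "data.frame")
  rep
}

#' Repair flagged frames by linear interpolation
#'
#' Flagged frames are replaced by linear interpolation between the nearest
#' unflagged neighbours; flagged frames at the edges take the nearest
#' unflagged value.
#'
#' @param vol a [ts_volume()].
#' @param report a `repair_report` from [detect_spikes()] (or any data frame
#'   with a `frame` column).
#' @return The repaired `ts_volume`.
#' @export
repair_frames <- function(vol, report) {
  bad <- report$frame
  if (length(bad) == 0) return(vol)
  nt <- n_frames(vol)
  stopifnot(all(bad >= 1 & bad <= nt))
  good <- setdiff(seq_len(nt), bad)
  if (length(good) == 0) stop("all frames flagged; nothing to interpolate from")
  M <- vox_matrix(vol)
  for (t in bad) {
    lo <- good[good < t]
    hi <- good[good > t]
    if (length(lo) == 0) M[t, ] <- M[min(hi), ]
    else if (length(hi) == 0) M[t, ] <- M[max(lo), ]
    else {
      l <- max(lo); h <- min(hi)
      w <- (h - t) / (h - l)
      M[t, ] <- w * M[l, ] + (1 - w) * M[h, ]
    }
  }
  set_vox_matrix(vol, M)
}

#' 24-parameter motion nuisance design
#'
#' Expands the 6 rigid-body parameter series into 24 nuisance regressors:
#' their first temporal differences, the same differences delayed by one
#' frame, and the squares of those 12 series. The raw parameters themselves
#' are excluded to avoid carrying global-signal content when the head is
#' still. Leading frames of the difference/delay columns are zero-padded.
#'
#' @param motion motion table (6 columns, >= 3 rows).
#' @return Numeric matrix with 24 columns.
#' @export
motion_design <- function(motion) {
  m <- as.matrix(motion)
  if (nrow(m) < 3) stop("need at least 3 frames")
  if (ncol(m) != 6) stop("motion table must have 6 columns")
  d <- rbind(0, diff(m))
  dl <- rbind(0, d[-nrow(d), , drop = FALSE])
  X <- cbind(d, dl, d^2, dl^2)
  colnames(X) <- c(paste0("d_", colnames(m)), paste0("dlag_", colnames(m)),
                   paste0("d2_", colnames(m)), paste0("dlag2_", colnames(m)))
  X
}

#' Regress a nuisance design out of every voxel
#'
#' Per-voxel ordinary least squares on the design plus an intercept; the
#' fitted nuisance component is removed and the original voxel mean
#' restored. Collinear columns are dropped (with a message).
#'
#' @param vol a [ts_volume()].
#' @param design numeric matrix, one row per frame.
#' @return The cleaned `ts_volume`.
#' @export
regress_out <- function(vol, design) {
  design <- as.matrix(design)
  nt <- n_frames(vol)
  if (nrow(design) != nt) stop("design rows must match frame count")
  X <- cbind(intercept = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    message("regress_out: dropping ", ncol(X) - qx$rank,
            " collinear design column(s)")
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
  }
  M <- vox_matrix(vol)
  mu <- colMeans(M)
  res <- qr.resid(qx, M)
  set_vox_matrix(vol, sweep(res, 2, mu, "+"))
}

#' Convert to percent signal change
#'
#' `y(t) <- 100 * (y(t) - mean) / mean` per voxel; the sample SD of the
#' result is the sLFO magnitude measure used in the regional analysis.
#' Out-of-mask voxels are zeroed.
#'
#' @param vol a [ts_volume()]; in-mask voxel means must be positive.
#' @return The converted `ts_volume`.
#' @export
percent_change <- function(vol) {
  M <- vox_matrix(vol)
  mu <- colMeans(M)
  if (any(mu <= 0))
    stop("percent_change: non-positive voxel mean inside mask")
  d <- dim(vol$data)
  vol$data <- array(0, d)
  set_vox_matrix(vol, 100 * sweep(sweep(M, 2, mu, "-"), 2, mu, "/"))
}
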
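#' Dual-echo acquisition pair
#'
#' Simultaneous signals at two echo times with identical geometry and frame
#' count; the basis of the monoexponential S0/T2* decomposition.
#'
#' @param S1,S2 [ts_volume()]s acquired at `te1_ms` and `te2_ms`.
#' @param te1_ms,te2_ms echo times in milliseconds, `0 < te1 < te2`.
#' @return An `me_pair`.
#' @export
me_pair <- function(S1, S2, te1_ms, te2_ms) {
  stopifnot(inherits(S1, "ts_volume"), inherits(S2, "ts_volume"))
  if (!identical(dim(S1$data), dim(S2$data)))
    stop("echo geometries/frame counts differ")
  if (!(te1_ms > 0 && te1_ms < te2_ms)) stop("need 0 < te1 < te2")
  structure(list(S1 = S1, S2 = S2, te1_ms = te1_ms, te2_ms = te2_ms),
            class = "me_pair")
}

#' Decompose a dual-echo pair into S0 and T2* fields
#'
#' Per frame and voxel, under single-compartment monoexponential decay
#' `S(TE) = S0 * exp(-TE / T2*)`:
#' `T2* = (TE2 - TE1) / ln(S1/S2)` and
#' `S0 = S1^(TE2/(TE2-TE1)) / S2^(TE1/(TE2-TE1))`.
#' Samples with non-positive signal, `S1 = S2`, negative T2*, or T2*
#' exceeding `t2s_max_ms` are treated as noise: marked invalid and carried
#' as missing (never interpolated here). Exactly `t2s_max_ms` is valid
#' (the rule rejects values *exceeding* the bound).
#'
#' @param me an [me_pair()].
#' @param t2s_max_ms upper validity bound for T2* (ms).
#' @return A `decay_fields` list: `t2s` and `s0` 4D arrays (invalid = NA),
#'   `valid` 4D logical, `frame_interval_s`, `mask`, echo times.
#' @export
me_decompose <- function(me, t2s_max_ms = 100) {
  stopifnot(inherits(me, "me_pair"))
  s1 <- me$S1$data
  s2 <- me$S2$data
  dte <- me$te2_ms - me$te1_ms
  pos <- s1 > 0 & s2 > 0
  lr <- ifelse(pos, log(s1 / s2), NA_real_)
  t2s <- ifelse(pos & lr > 0, dte / lr, NA_real_)
  valid <- !is.na(t2s) & t2s <= t2s_max_ms * (1 + 1e-12)  # closed boundary
  t2s[!valid] <- NA_real_
  s0 <- ifelse(valid, s1^(me$te2_ms / dte) / s2^(me$te1_ms / dte), NA_real_)
  structure(list(t2s = t2s, s0 = s0, valid = valid,
                 te1_ms = me$te1_ms, te2_ms = me$te2_ms,
                 frame_interval_s = me$S1$frame_interval_s,
                 mask = me$S1$mask, space_meta = me$S1$space_meta),
            class = "decay_fields")
}

#' @export
print.decay_fields <- function(x, ...) {
  cat(sprintf("<decay_fields> TE %.4g/%.4g ms; %.1f%% samples valid\n",
              x$te1_ms, x$te2_ms, 100 * mean(x$valid)))
  invisible(x)
}

#' Synthesize a signal at an arbitrary echo time
#'
#' `S(TE) = S0 * exp(-TE / T2*)` from decomposed fields; `TE = 0` returns S0
#' itself. Invalid samples stay NA.
#'
#' @param df a [me_decompose()] result.
#' @param te_ms echo time in milliseconds, `>= 0`.
#' @return A [ts_volume()] (mask inherited from the pair).
#' @export
me_synthesize <- function(df, te_ms) {
  stopifnot(inherits(df, "decay_fields"), te_ms >= 0)
  y <- if (te_ms == 0) df$s0 else df$s0 * exp(-te_ms / df$t2s)
  ts_volume(y, df$frame_interval_s, mask = df$mask,
            space_meta = df$space_meta)
}

#' Interpolate invalid samples before temporal analysis
#'
#' Invalid (noise-rule) samples are replaced per voxel by linear
#' interpolation over time, for use by band-pass/lag analyses only; the
#' number of interpolated samples is reported.
#'
#' @param vol a [ts_volume()] possibly containing NA samples.
#' @return The interpolated `ts_volume` (voxels that are entirely NA are
#'   dropped from the mask).
#' @export
interpolate_invalid <- function(vol) {
  M <- vox_matrix(vol)
  nbad <- sum(is.na(M))
  if (nbad > 0) {
    nt <- nrow(M)
    allna <- colSums(is.na(M)) == nt
    for (v in which(!allna & colSums(is.na(M)) > 0)) {
      ok <- !is.na(M[, v])
      M[!ok, v] <- stats::approx(which(ok), M[ok, v], xout = which(!ok),
                                 rule = 2)$y
    }
    message("interpolate_invalid: ", nbad, " sample(s) interpolated, ",
            sum(allna), " all-NA voxel(s) removed from mask")
    if (any(allna)) {
      mask_idx <- which(vol$mask)
      vol$mask[mask_idx[allna]] <- FALSE
      M <- M[, !allna, drop = FALSE]
    }
  }
  set_vox_matrix(vol, M)
}
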
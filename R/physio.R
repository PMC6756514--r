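#' Baseline BOLD physiology parameters
#'
#' Parameter set for the static BOLD signal model used by the synthetic-data
#' generator: the power-law BOLD fraction and the off-resonance frequency
#' shift of partially deoxygenated blood.
#'
#' @param OEF oxygen extraction fraction (fraction of delivered O2 extracted).
#' @param Hct hematocrit (erythrocyte volume fraction of blood).
#' @param CBV0 baseline tissue blood volume fraction.
#' @param TE echo time in seconds.
#' @param B0 main field strength in tesla.
#' @param gamma gyromagnetic ratio in MHz/T.
#' @param delta_chi0 susceptibility difference between fully oxygenated and
#'   fully deoxygenated blood (SI, dimensionless).
#' @param beta_exp power-law exponent linking T2* to deoxy-Hb content.
#' @param SaO2 arterial (inflow) oxygen saturation.
#' @return A `physio_params` list.
#' @export
physio_params <- function(OEF = 0.45, Hct = 0.40, CBV0 = 0.03,
                          TE = 0.030, B0 = 3, gamma = 42.58,
                          delta_chi0 = 2.64e-7, beta_exp = 1.5,
                          SaO2 = 1.0) {
  p <- list(OEF = OEF, Hct = Hct, CBV0 = CBV0, TE = TE, B0 = B0,
            gamma = gamma, delta_chi0 = delta_chi0, beta_exp = beta_exp,
            SaO2 = SaO2)
  for (nm in c("OEF", "Hct", "CBV0", "SaO2"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  for (nm in c("TE", "B0", "gamma", "delta_chi0"))
    if (p[[nm]] <= 0) stop(nm, " must be positive")
  structure(p, class = "physio_params")
}

# Baseline deoxy-Hb density (arbitrary units proportional to concentration):
# the extracted fraction of the saturated inflow plus the deoxygenated
# fraction already present in the inflow when SaO2 < 1.
.deoxy_hb0 <- function(p, SaO2 = p$SaO2) {
  p$Hct * (SaO2 * p$OEF + (1 - SaO2))
}

# Susceptibility scale factor M = TE * B0 * CBV0 * [deoxy-Hb]^beta.
.bold_M <- function(p, SaO2 = p$SaO2) {
  p$TE * p$B0 * p$CBV0 * .deoxy_hb0(p, SaO2)^p$beta_exp
}

#' Fractional BOLD signal change under the power-law model
#'
#' Computes `M * (1 - cmro2_ratio^beta * cbv_ratio * cbf_ratio^(-beta))`,
#' where `M = TE * B0 * CBV0 * [deoxy-Hb]^beta` and the baseline deoxy-Hb
#' density includes the `(1 - SaO2)` inflow contribution, so the dependence
#' of baseline BOLD on inflow saturation is reproduced (see
#' [bold_vs_sao2()]).
#'
#' @param p a [physio_params()] object.
#' @param cmro2_ratio,cbf_ratio,cbv_ratio activation-to-baseline ratios of
#'   oxygen metabolism, blood flow, and blood volume; all positive.
#' @return Fractional BOLD change (dimensionless).
#' @export
bold_fraction <- function(p, cmro2_ratio = 1, cbf_ratio = 1, cbv_ratio = 1) {
  stopifnot(inherits(p, "physio_params"))
  if (any(c(cmro2_ratio, cbf_ratio, cbv_ratio) <= 0))
    stop("all ratios must be positive")
  .bold_M(p) * (1 - cmro2_ratio^p$beta_exp * cbv_ratio * cbf_ratio^(-p$beta_exp))
}

#' Baseline BOLD offset versus inflow oxygen saturation
#'
#' Relative baseline BOLD signal at inflow saturation `sao2` versus the fully
#' saturated condition, computed by letting the deoxy-Hb density ratio play
#' the power-law role: `M(SaO2=1) * (1 - (dHb(sao2)/dHb(1))^beta)`. Decreasing
#' saturation raises baseline deoxy-Hb and lowers the BOLD signal, so the
#' curve is monotone decreasing in falling `sao2`.
#'
#' @param p a [physio_params()] object.
#' @param sao2 vector of inflow saturations in `[0, 1]`.
#' @return Fractional BOLD offset (0 at `sao2 = 1`, negative below).
#' @export
bold_vs_sao2 <- function(p, sao2) {
  stopifnot(inherits(p, "physio_params"), all(sao2 >= 0 & sao2 <= 1))
  ratio <- .deoxy_hb0(p, sao2) / .deoxy_hb0(p, 1)
  .bold_M(p, 1) * (1 - ratio^p$beta_exp)
}

#' Off-resonance frequency shift of blood
#'
#' `delta_omega = gamma * (4/3) * pi * delta_chi0 * Hct * OEF * B0`, in the
#' units of `gamma * B0` (MHz for the default MHz/T).
#'
#' @param p a [physio_params()] object.
#' @return The frequency shift.
#' @export
off_resonance_shift <- function(p) {
  stopifnot(inherits(p, "physio_params"))
  p$gamma * (4 / 3) * pi * p$delta_chi0 * p$Hct * p$OEF * p$B0
}
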
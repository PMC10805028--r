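# Porewater geochemistry: dissolved CH4 from headspace equilibration.

#' Dissolved porewater CH4 concentration
#'
#' Standard headspace mass balance: porewater is equilibrated against a
#' helium headspace at atmospheric pressure and the equilibrated headspace
#' CH4 is measured by gas chromatography. The moles recovered in the
#' headspace are \code{conc * V_headspace}; dividing by the water volume
#' and the extraction efficiency gives the original dissolved
#' concentration:
#' \deqn{[CH4]_{aq} = c_{head} \cdot V_{head} / (V_{water} \cdot e)}
#' Henry's-law partitioning of the residual dissolved fraction is folded
#' into the single extraction-efficiency constant (default 0.95).
#'
#' When the headspace measurement is a mol fraction (ppmv), it is first
#' converted to a gas-phase molar concentration with the ideal gas law at
#' the given temperature and pressure.
#'
#' @param headspace_conc measured equilibrated-headspace CH4 concentration.
#' @param headspace_volume_ml,water_volume_ml volumes in mL (> 0).
#' @param extraction_efficiency fraction of dissolved CH4 recovered into
#'   the headspace, in (0, 1]; default 0.95.
#' @param conc_unit "uM" (micromolar in the headspace gas) or "ppmv".
#' @param temperature_K,pressure_atm gas conditions for the ppmv
#'   conversion (defaults 298.15 K, 1 atm).
#' @return Dissolved CH4 in uM.
#' @export
dissolved_ch4 <- function(headspace_conc, headspace_volume_ml,
                          water_volume_ml, extraction_efficiency = 0.95,
                          conc_unit = c("uM", "ppmv"),
                          temperature_K = 298.15, pressure_atm = 1) {
  conc_unit <- match.arg(conc_unit)
  if (any(extraction_efficiency <= 0 | extraction_efficiency > 1))
    stop("extraction efficiency must lie in (0, 1]", call. = FALSE)
  if (any(headspace_volume_ml <= 0) || any(water_volume_ml <= 0))
    stop("volumes must be positive", call. = FALSE)
  if (any(headspace_conc < 0))
    stop("headspace concentration must be non-negative", call. = FALSE)
  conc_uM <- if (conc_unit == "ppmv") {
    # x ppmv -> partial pressure x*1e-6*P; n/V = p/(RT) mol/L -> uM
    headspace_conc * pressure_atm / (0.0820574 * temperature_K)
  } else headspace_conc
  conc_uM * (headspace_volume_ml / water_volume_ml) / extraction_efficiency
}

#' Dissolved CH4 for a table of porewater samples
#'
#' @param samples data.frame with columns \code{headspace_conc},
#'   \code{headspace_volume_ml}, \code{water_volume_ml} and optionally
#'   \code{extraction_efficiency} (default 0.95).
#' @param ... passed to [dissolved_ch4()].
#' @return The input with a \code{dissolved_ch4_uM} column appended.
#' @export
dissolved_ch4_table <- function(samples, ...) {
  eff <- if ("extraction_efficiency" %in% names(samples))
    samples$extraction_efficiency else 0.95
  samples$dissolved_ch4_uM <- dissolved_ch4(
    samples$headspace_conc, samples$headspace_volume_ml,
    samples$water_volume_ml, eff, ...)
  samples
}
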
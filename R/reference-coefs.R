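#' Packaged reference regression coefficients
#'
#' Reference coefficient vectors for the two multilinear
#' morphology-to-metabolism regressions distributed with the package: net
#' hovering oxygen consumption (\code{mo2net}, mg O2 kg^-1 h^-1) and the
#' hovering-to-resting ratio (\code{ratio}, dimensionless), each as a
#' function of seven morphological predictors measured on 13 species of
#' near-neutrally buoyant fishes. They serve as the generative ground truth
#' of \code{\link{gen_species_table}} and as the recovery target for the
#' regression stage.
#'
#' The predictors, in order: body mass (kg), fineness ratio TL/MBD
#' (total length over maximum body depth), signed COM–COB offset along the
#' anterior–posterior axis (proportion of body length), signed COM–COB
#' offset along the dorsal–ventral axis (proportion of body depth, dorsal
#' origin, so negative means COB ventral of COM), fineness ratio TL/MBW,
#' pectoral fin position and caudal fin position (anterior–posterior
#' proportions of body length).
#'
#' @param response \code{"mo2net"} or \code{"ratio"}.
#' @return Named numeric vector of length 8 (intercept first).
#' @examples
#' hover_reference_coefs("mo2net")[["fineness_depth"]]  # 201.28
#' @export
hover_reference_coefs <- function(response = c("mo2net", "ratio")) {
  response <- match.arg(response)
  tab <- cbind(
    mo2net = c(1501.05, -440.24, 201.28, -114.18, -116.80,
               194.16, -1297.36, -1297.60),
    ratio  = c(9.35, -2.91, 0.63, -0.34, -0.80, 0.21, -3.94, -6.97)
  )
  rownames(tab) <- c("(Intercept)", hover_predictors())
  tab[, response]
}

#' Names of the morphological predictors
#'
#' The canonical predictor order used by the generator, the design matrices
#' and the reference coefficient vectors.
#'
#' @return Character vector of length 7.
#' @export
hover_predictors <- function() {
  c("mass", "fineness_depth", "comcob_ap", "comcob_dv",
    "fineness_width", "pect_fin_ap", "caud_fin_ap")
}

#' Default full-model regression formula
#'
#' @param response \code{"mo2net"} or \code{"ratio"}.
#' @return A formula regressing the response on all seven predictors.
#' @export
mo2_formula <- function(response = c("mo2net", "ratio")) {
  response <- match.arg(response)
  stats::as.formula(
    paste(response, "~", paste(hover_predictors(), collapse = " + ")),
    env = globalenv())
}
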
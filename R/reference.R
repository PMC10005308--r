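# Published best-fit hindered-rotation ACF parameters for the parinaric acid
# probes, used as desk-scale inputs (limiting anisotropy, mean correlation
# times, round-trip fitting benchmarks).

#' Published ACF fit parameters for parinaric acid probes
#'
#' Best-fit parameters of the triexponential-plus-residual ACF model for
#' cis- and trans-parinaric acid in fluid (POPC) and gel (DPPC)
#' phosphatidylcholine bilayers at 298 K, as reported in the MD literature.
#' Absent exponential terms carry amplitude 0. These serve as inputs for
#' limiting-anisotropy estimates, mean-correlation-time calculations and
#' fitting round-trip benchmarks.
#'
#' @return A named list of [acf_fit_params()] objects with elements
#'   `"cPnA_POPC"`, `"tPnA_POPC"`, `"cPnA_DPPC"`, `"tPnA_DPPC"`.
#' @export
pna_acf_reference <- function() {
  list(
    cPnA_POPC = acf_fit_params(a = c(0.42, 0.58),
                               phi = c(0.10, 1.8), a_inf = 0.032),
    tPnA_POPC = acf_fit_params(a = c(0.27, 0.33, 0.047),
                               phi = c(0.46, 2.6, 15), a_inf = 0.26),
    cPnA_DPPC = acf_fit_params(a = c(0.11, 0.050),
                               phi = c(2.9, 120), a_inf = 0.71),
    tPnA_DPPC = acf_fit_params(a = c(0.02, 0.01, 0.01),
                               phi = c(0.16, 22, 850), a_inf = 0.92)
  )
}

#' Published proximity-conditioned tilt variances in the gel phase
#'
#' Variances (deg^2) of the gel-phase (DPPC) sn-1 chain tilt distribution
#' conditioned on the distance R between lipid and nearest-probe centres of
#' mass: far (R > 1.2 nm), mid (0.7-1.2 nm) and near (R < 0.7 nm), for each
#' probe. Inputs for the SD-increase statistic.
#'
#' @return A data.frame with columns `probe`, `far`, `mid`, `near`.
#' @export
pna_tilt_variance_reference <- function() {
  data.frame(probe = c("cPnA", "tPnA"),
             far = c(33.5, 37.3),
             mid = c(64.4, 49.6),
             near = c(85.1, 51.4))
}
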
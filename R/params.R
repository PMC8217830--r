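#' Physical parameters of the tissue region
#'
#' Bundles the physical constants of the tissue oxygen-transport equation:
#' oxygen diffuses with diffusivity `D`, is supplied volumetrically from the
#' capillary bed at rate `K * (1 - P / P0)` (a homogeneous source pulling the
#' tissue towards the average capillary PO2 `P0`), and is consumed by
#' Michaelis-Menten kinetics `M0 * P / (P + P50)`.
#'
#' All internal computation uses micrometres, seconds and mmHg. Literature
#' diffusivities quoted in cm^2/s convert as 1 cm^2/s = 1e8 um^2/s, so the
#' default `D = 2410` um^2/s corresponds to 2.41e-5 cm^2/s.
#'
#' @param D Oxygen diffusivity in tissue (um^2/s). Default 2410 (2.41e-5 cm^2/s).
#' @param k Oxygen solubility in tissue (mL O2/mL/mmHg). Default 3.89e-5.
#' @param M0 Maximal volumetric oxygen consumption (mL O2/mL/s). Default 1.57e-4.
#' @param P50 PO2 at which consumption is half-maximal (mmHg). Default 0.5.
#' @param P0 Average capillary PO2 (mmHg). Default 48.
#' @param K Capillary-to-tissue oxygen transport rate (mmHg/s). Default 30.
#' @return An object of class `tissue_params`.
#' @examples
#' tp <- tissue_params()
#' tp$M0 / tp$k  # consumption prefactor in PO2 units, ~4.04 mmHg/s
#' @export
tissue_params <- function(D = 2410, k = 3.89e-5, M0 = 1.57e-4,
                          P50 = 0.5, P0 = 48, K = 30) {
  p <- list(D = D, k = k, M0 = M0, P50 = P50, P0 = P0, K = K)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tissue_params: '", nm, "' must be a single strictly positive number")
  }
  structure(p, class = "tissue_params")
}

#' Physical parameters of the PDMS membrane
#'
#' The gas-permeable polydimethylsiloxane (PDMS) layer between the glass slide
#' and the tissue. Oxygen is neither produced nor consumed there; it only
#' diffuses, with a diffusivity comparable to tissue but a much lower
#' solubility, which is what lets the membrane spread a gas challenge
#' laterally beyond the window footprint.
#'
#' @param D Oxygen diffusivity in PDMS (um^2/s). Default 3400 (3.40e-5 cm^2/s).
#' @param k Oxygen solubility in PDMS (mL O2/mL/mmHg). Default 1.32e-5.
#' @param thickness Membrane thickness (um). Default 25.
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(D = 3400, k = 1.32e-5, thickness = 25) {
  p <- list(D = D, k = k, thickness = thickness)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("membrane_params: '", nm, "' must be a single strictly positive number")
  }
  structure(p, class = "membrane_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters (um/s/mmHg):\n")
  cat(sprintf("  D   = %g um^2/s\n  k   = %g mL O2/mL/mmHg\n", x$D, x$k))
  cat(sprintf("  M0  = %g mL O2/mL/s  (M0/k = %.4g mmHg/s)\n", x$M0, x$M0 / x$k))
  cat(sprintf("  P50 = %g mmHg\n  P0  = %g mmHg\n  K   = %g mmHg/s\n",
              x$P50, x$P0, x$K))
  invisible(x)
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("PDMS membrane parameters (um/s/mmHg):\n")
  cat(sprintf("  D' = %g um^2/s\n  k' = %g mL O2/mL/mmHg\n  thickness = %g um\n",
              x$D, x$k, x$thickness))
  invisible(x)
}

#' Net local reaction rate of tissue PO2
#'
#' Evaluates the pointwise source/sink balance of the tissue equation in PO2
#' units: the tissue equation divided through by the solubility `k` gives
#' `dP/dt = D lap(P) + K (1 - P/P0) - (M0/k) P / (P + P50)`; this function
#' returns the non-diffusive part. It is strictly decreasing in `P`, so it
#' has a unique non-negative root (see [equilibrium_po2()]).
#'
#' @param P PO2 (mmHg), vectorised. Must be non-negative; a negative value is
#'   treated as an error because it signals solver instability upstream.
#' @param params A [tissue_params()] object.
#' @return Net rate of PO2 change (mmHg/s), same length as `P`.
#' @examples
#' reaction_rate(0, tissue_params())    # source only: K = 30 mmHg/s
#' reaction_rate(48, tissue_params())   # source vanishes at P = P0
#' @export
reaction_rate <- function(P, params = tissue_params()) {
  stopifnot(inherits(params, "tissue_params"))
  if (any(!is.finite(P)) || any(P < 0))
    stop("reaction_rate: P must be finite and non-negative ",
         "(negative PO2 indicates an unstable solve)")
  params$K * (1 - P / params$P0) -
    (params$M0 / params$k) * P / (P + params$P50)
}

#' Equilibrium tissue PO2 of the reaction term
#'
#' The PO2 at which capillary supply exactly balances Michaelis-Menten
#' consumption, i.e. the unique positive root of [reaction_rate()]. A uniform
#' field at this value is a fixed point of the solver in the absence of any
#' window boundary condition, and it is the far-field plateau a localised
#' challenge decays towards.
#'
#' @param params A [tissue_params()] object.
#' @param tol Root tolerance in mmHg (default 1e-12).
#' @return Equilibrium PO2 (mmHg). About 41.6 mmHg at the default parameters.
#' @export
equilibrium_po2 <- function(params = tissue_params(), tol = 1e-12) {
  stopifnot(inherits(params, "tissue_params"))
  # rate(0) = K > 0 and rate(P0) < 0, so the root is bracketed by [0, P0]
  stats::uniroot(function(P) reaction_rate(P, params),
                 lower = 0, upper = params$P0, tol = tol)$root
}
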
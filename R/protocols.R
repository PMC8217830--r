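#' Convert an O2 gas fraction to a partial pressure
#'
#' The chamber gas composition is prescribed as a dry O2 fraction; the model
#' boundary condition needs mmHg. By default the conversion assumes dry gas at
#' the given total pressure; with `humidified = TRUE` the fraction is applied
#' to `pressure - 47` mmHg, subtracting water-vapour pressure at 37 C.
#'
#' @param fraction O2 fraction in `[0, 1]`, vectorised.
#' @param pressure Total pressure (mmHg), default 760.
#' @param humidified Subtract 47 mmHg water vapour before converting.
#' @return PO2 (mmHg).
#' @examples
#' percent_to_po2(0.05)  # 38 mmHg
#' percent_to_po2(0.02)  # 15.2 mmHg
#' @export
percent_to_po2 <- function(fraction, pressure = 760, humidified = FALSE) {
  if (any(fraction < 0 | fraction > 1))
    stop("percent_to_po2: fraction must lie in [0, 1]")
  if (pressure <= 0) stop("percent_to_po2: pressure must be positive")
  fraction * (pressure - if (humidified) 47 else 0)
}

#' Time-varying gas composition at the exchange window
#'
#' A piecewise-constant, right-continuous schedule of chamber O2 fractions.
#' The window boundary PO2 switches instantaneously at segment edges,
#' matching the modelling assumption that gas exchange in the chamber is much
#' faster than diffusion into the tissue.
#'
#' @param durations Segment durations (s), all positive.
#' @param fractions O2 fraction per segment, each in `[0, 1]`.
#' @param pressure Total pressure (mmHg).
#' @param humidified Passed to [percent_to_po2()].
#' @return An object of class `gas_protocol`.
#' @export
gas_protocol <- function(durations, fractions, pressure = 760,
                         humidified = FALSE) {
  if (length(durations) != length(fractions) || length(durations) == 0)
    stop("gas_protocol: durations and fractions must be equal-length, non-empty")
  if (any(durations <= 0)) stop("gas_protocol: durations must be positive")
  if (any(fractions < 0 | fractions > 1))
    stop("gas_protocol: fractions must lie in [0, 1]")
  structure(list(durations = as.numeric(durations),
                 fractions = as.numeric(fractions),
                 pressure = pressure, humidified = humidified,
                 t_end = cumsum(as.numeric(durations))),
            class = "gas_protocol")
}

#' The standard square-wave oxygen challenge
#'
#' The 6-minute chamber protocol used throughout this package's worked
#' examples: 1 min of 5% O2, 2 min of 12%, 2 min of 2%, and 1 min of 5%
#' (CO2 and balance N2 are carrier-gas bookkeeping and never enter the
#' model).
#'
#' @inheritParams gas_protocol
#' @return A [gas_protocol()] totalling 360 s.
#' @export
square_wave_protocol <- function(pressure = 760, humidified = FALSE) {
  gas_protocol(durations = c(60, 120, 120, 60),
               fractions = c(0.05, 0.12, 0.02, 0.05),
               pressure = pressure, humidified = humidified)
}

#' Window boundary PO2 at a given time
#'
#' Looks up the segment containing `t` and converts its O2 fraction to mmHg.
#' At a segment edge the later segment's value applies (right-continuity), so
#' the switch is instantaneous.
#'
#' @param protocol A [gas_protocol()].
#' @param t Time (s), `0 <= t <= ` total duration, vectorised.
#' @return PO2 (mmHg).
#' @export
window_po2_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "gas_protocol"))
  total <- sum(protocol$durations)
  if (any(t < 0 | t > total))
    stop("window_po2_at: t must lie within [0, ", total, "] s")
  # right-continuous: t on an edge belongs to the later segment
  idx <- findInterval(t, c(0, protocol$t_end), rightmost.closed = TRUE,
                      left.open = FALSE)
  idx <- pmin(idx, length(protocol$fractions))
  percent_to_po2(protocol$fractions[idx], protocol$pressure,
                 protocol$humidified)
}

#' @export
print.gas_protocol <- function(x, ...) {
  cat("Gas protocol (", sum(x$durations), " s total, ",
      x$pressure, " mmHg", if (x$humidified) ", humidified", "):\n", sep = "")
  po2 <- percent_to_po2(x$fractions, x$pressure, x$humidified)
  for (i in seq_along(x$durations))
    cat(sprintf("  %5g s at %4.1f%% O2 (%.1f mmHg)\n",
                x$durations[i], 100 * x$fractions[i], po2[i]))
  invisible(x)
}
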
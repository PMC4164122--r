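# Gravity-dependent ventilation and perfusion distribution.
#
# Regional ventilation and perfusion per unit lung volume decline linearly
# with height above the lung base (upright posture); each segment's share of
# total alveolar flow or cardiac output is its height weight times its volume
# fraction, renormalized over the lung.

#' Ventilation weight per percent lung volume at a given height
#'
#' Linear regression of normalized regional ventilation rate against height in
#' the lung, `-0.00031*h + 0.064`, with `h` in percent from the lung base.
#' Strictly positive over the physical range 0-100.
#'
#' @param h Height, % from lung base, in \[0, 100\]. Vectorized.
#' @return Ventilation rate per percent lung volume (dimensionless weight).
#' @export
ventilation_weight <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0 | h > 100))
    stop_invalid("height must lie in [0, 100] % from lung base")
  -0.00031 * h + 0.064
}

#' Perfusion weight per percent lung volume at a given height
#'
#' Linear regression of normalized regional perfusion against height,
#' `-0.0009*h + 0.1`. The steeper slope than the ventilation relation makes
#' perfusion the more heterogeneous of the two distributions.
#'
#' @inheritParams ventilation_weight
#' @return Perfusion rate per percent lung volume (dimensionless weight).
#' @export
perfusion_weight <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0 | h > 100))
    stop_invalid("height must lie in [0, 100] % from lung base")
  -0.0009 * h + 0.1
}

#' Fractional ventilation and perfusion flows per segment
#'
#' For each lung segment the raw weight is `weight(height) * volume`; the raw
#' weights are renormalized to a partition of unity so that segmental flows
#' conserve total ventilation and cardiac output.
#'
#' @param segments Either a `lung_model` or its `$segments` data frame (needs
#'   columns `f` or `volume_pct`, and `height_pct`).
#' @param kind `"ventilation"` or `"perfusion"`.
#' @return A named numeric vector of fractions (names = segment ids), summing
#'   to 1.
#' @export
segment_flow_fractions <- function(segments, kind = c("ventilation", "perfusion")) {
  kind <- match.arg(kind)
  if (inherits(segments, "lung_model")) segments <- segments$segments
  if (is.null(segments) || nrow(segments) == 0L)
    stop_invalid("segment table is empty")
  vol <- if (!is.null(segments$f)) segments$f else
    segments$volume_pct / sum(segments$volume_pct)
  w <- switch(kind,
              ventilation = ventilation_weight(segments$height_pct),
              perfusion   = perfusion_weight(segments$height_pct))
  raw <- w * vol
  out <- raw / sum(raw)
  names(out) <- segments$id
  out
}

#' Both flow-fraction vectors for a lung model
#'
#' @param model A `lung_model`.
#' @return A list with components `ventilation` and `perfusion`, each a
#'   normalized fraction vector over segments.
#' @export
flow_fractions <- function(model) {
  list(ventilation = segment_flow_fractions(model, "ventilation"),
       perfusion   = segment_flow_fractions(model, "perfusion"))
}
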
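#' Blade-element mechanical-sensitivity profile of a flapping wing
#'
#' Under the strip (blade-element) model of flapping flight, a wing section
#' at spanwise position r experiences aerodynamic force
#' `dF ~ c(r) r^2 dr` (local chord times the square of the distance from the
#' wing base, from the section's flapping velocity), and an inertial moment
#' with the same `r^2` dependence. The force *per unit area* is
#' `dF / (c(r) dr) ~ r^2`: chord taper cancels, so the per-area sensitivity
#' follows the square law regardless of planform. The profile is normalized
#' to 1 at the wingtip.
#'
#' @param positions Spanwise positions `r/R` in `[0, 1]`.
#' @param chord_profile Optional chord values at `positions` (> 0); affects
#'   only the reported per-section total force, never the per-area law.
#' @param exponent Power of the distance law (default 2, the uniform-chord
#'   blade-element result; exposed for sensitivity analysis).
#' @return A data.frame of class `"sensitivity_profile"`: `position`,
#'   `force_per_area`, `moment_per_area`, and `section_force` (chord-weighted,
#'   normalized to its maximum) when a chord profile is given.
#' @export
sensitivity_profile <- function(positions, chord_profile = NULL, exponent = 2) {
  if (exponent < 0) stop("exponent must be >= 0")
  if (any(positions < 0 | positions > 1)) stop("positions must lie in [0, 1]")
  s <- positions^exponent
  out <- data.frame(position = positions, force_per_area = s,
                    moment_per_area = s)
  if (!is.null(chord_profile)) {
    if (length(chord_profile) != length(positions) || any(chord_profile <= 0))
      stop("chord_profile must be positive, one value per position")
    sf <- chord_profile * s
    out$section_force <- sf / max(sf)
  }
  class(out) <- c("sensitivity_profile", "data.frame")
  attr(out, "exponent") <- exponent
  out
}

#' Hypothesis templates for the spanwise evolutionary-rate pattern
#'
#' Converts a mechanical-sensitivity profile into the two idealized
#' expectations for how evolutionary tempo could respond to it:
#' * `"gradient"`: tempo tracks the sensitivity profile smoothly (monotone in
#'   the per-area force), crossing the wrist without a break;
#' * `"modular"`: tempo is discretized by the armwing/handwing modules into
#'   two levels (the mean sensitivity within each region), with a step at the
#'   wrist and the higher level distal.
#'
#' These are qualitative shape templates for comparison and plotting against
#' fitted sigma^2 or disparity profiles; no fitted link between sensitivity
#' and rate magnitude is claimed.
#'
#' @param sens A `"sensitivity_profile"` from [sensitivity_profile()].
#' @param hypothesis `"gradient"` or `"modular"`.
#' @param wrist_position Spanwise position of the wrist as a fraction of the
#'   wing length (used by the modular template; default 0.4).
#' @return A data.frame of class `"span_profile"`: `position`, `value`
#'   (template, normalized to max 1).
#' @export
predicted_rate_shape <- function(sens, hypothesis = c("gradient", "modular"),
                                 wrist_position = 0.4) {
  hypothesis <- match.arg(hypothesis)
  s <- sens$force_per_area
  pos <- sens$position
  v <- if (hypothesis == "gradient") {
    s
  } else {
    distal <- pos >= wrist_position
    lev <- c(mean(s[!distal]), mean(s[distal]))
    ifelse(distal, lev[2], lev[1])
  }
  if (max(v) > 0) v <- v / max(v)
  out <- data.frame(position = pos, value = v)
  class(out) <- c("span_profile", "data.frame")
  attr(out, "statistic") <- paste0("template_", hypothesis)
  out
}
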
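#' Vascular compartment for IVIM attenuation modelling
#'
#' Describes one vascular pool (capillaries, penetrating veins, arteries, ...)
#' by its mean vessel segment length and mean blood velocity. Blood flowing
#' through a randomly oriented vessel network behaves, over a diffusion
#' gradient, like a pseudo-diffusion process (the intravoxel incoherent
#' motion, IVIM, picture): the mean displacement equals the segment length
#' and the speed equals that of the blood, giving a pseudo-diffusion
#' coefficient D* proportional to `L * v`.
#'
#' @param name Text label, e.g. `"capillary"`.
#' @param segment_length Mean vessel segment length L in meters; must be > 0.
#' @param mean_velocity Mean blood velocity v in m/s; must be >= 0.
#' @param pseudo_diffusion Optional explicit D* in m^2/s. Defaults to
#'   [pseudo_diffusion_coefficient()] of `segment_length` and `mean_velocity`.
#' @param blood_diffusion Water self-diffusion coefficient in blood, m^2/s.
#'   Default `1.5e-9` (blood water at body temperature); D* of any flowing
#'   pool is orders of magnitude larger.
#' @param dstar_scale Proportionality constant for the D* = scale * L * v
#'   rule when `pseudo_diffusion` is not given. See
#'   [pseudo_diffusion_coefficient()].
#' @return An object of class `vessel_compartment`.
#' @seealso [preset_compartments()] for the canonical capillary / vein /
#'   artery trio.
#' @examples
#' vessel_compartment("capillary", segment_length = 100e-6, mean_velocity = 1e-3)
#' @export
vessel_compartment <- function(name, segment_length, mean_velocity,
                               pseudo_diffusion = NULL,
                               blood_diffusion = 1.5e-9,
                               dstar_scale = 1 / 10) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive(segment_length, "segment_length")
  if (!is.numeric(mean_velocity) || length(mean_velocity) != 1L ||
      !is.finite(mean_velocity) || mean_velocity < 0) {
    abort_field("`mean_velocity` must be a single non-negative number")
  }
  check_nonneg(blood_diffusion, "blood_diffusion")
  if (is.null(pseudo_diffusion)) {
    pseudo_diffusion <- pseudo_diffusion_coefficient(
      segment_length, mean_velocity, scale = dstar_scale
    )
  }
  check_nonneg(pseudo_diffusion, "pseudo_diffusion")
  structure(
    list(
      name = name,
      segment_length = segment_length,
      mean_velocity = mean_velocity,
      pseudo_diffusion = pseudo_diffusion,
      blood_diffusion = blood_diffusion
    ),
    class = "vessel_compartment"
  )
}

#' @export
print.vessel_compartment <- function(x, ...) {
  cat(sprintf(
    "<vessel_compartment> %s: L = %.3g m, v = %.3g m/s, D* = %.3g m^2/s, D_blood = %.3g m^2/s\n",
    x$name, x$segment_length, x$mean_velocity, x$pseudo_diffusion, x$blood_diffusion
  ))
  invisible(x)
}

#' Canonical capillary / penetrating-vein / artery compartments
#'
#' The three cortical vascular pools with the literature displacement and
#' velocity values: capillaries (L = 100 um, v = 1 mm/s, D* = 1e-8 m^2/s),
#' penetrating veins (L = 1 mm, v = 2.5 mm/s, D* = 2.5e-7 m^2/s), and
#' arteries (L = 1 mm, v = 12 mm/s, D* = 1.2e-6 m^2/s).
#'
#' @param dstar_scale Proportionality constant passed to
#'   [vessel_compartment()]; default 1/10.
#' @return A named list of three `vessel_compartment` objects:
#'   `capillary`, `vein`, `artery`.
#' @export
preset_compartments <- function(dstar_scale = 1 / 10) {
  list(
    capillary = vessel_compartment("capillary", 100e-6, 1e-3, dstar_scale = dstar_scale),
    vein      = vessel_compartment("vein",      1e-3,   2.5e-3, dstar_scale = dstar_scale),
    artery    = vessel_compartment("artery",    1e-3,   12e-3,  dstar_scale = dstar_scale)
  )
}

#' IVIM pseudo-diffusion coefficient from segment length and velocity
#'
#' D* = scale * L * v. The default `scale = 1/10` reproduces the standard
#' printed values for all three cortical compartments (capillary 1e-8,
#' penetrating vein 2.5e-7, artery 1.2e-6 m^2/s); the conventional IVIM
#' factor 1/6 (from the isotropic random-walk derivation) is selectable.
#'
#' @param segment_length Mean vessel segment length in meters (> 0).
#' @param mean_velocity Mean blood velocity in m/s (>= 0).
#' @param scale Dimensionless proportionality constant (> 0); `1/10` by
#'   default, `1/6` for the random-walk convention.
#' @return D* in m^2/s.
#' @examples
#' pseudo_diffusion_coefficient(100e-6, 1e-3)  # capillary: 1e-8
#' pseudo_diffusion_coefficient(1e-3, 2.5e-3)  # penetrating vein: 2.5e-7
#' @export
pseudo_diffusion_coefficient <- function(segment_length, mean_velocity,
                                         scale = 1 / 10) {
  check_positive(segment_length, "segment_length")
  if (!is.numeric(mean_velocity) || any(!is.finite(mean_velocity)) ||
      any(mean_velocity < 0)) {
    abort_field("`mean_velocity` must be non-negative and finite")
  }
  check_positive(scale, "scale")
  scale * segment_length * mean_velocity
}

#' Bipolar velocity-nulling gradient specification
#'
#' Amplitude and timing of a bipolar (two opposite-lobe) gradient pair:
#' gyromagnetic ratio gamma (Hz/T), gradient amplitude G (T/m), lobe
#' duration delta (s) and lobe separation Delta (s). Yields the diffusion
#' b-value via [bipolar_b_value()] and the flow critical velocity via
#' [critical_velocity()].
#'
#' @param G Gradient amplitude in T/m.
#' @param delta Lobe duration in seconds.
#' @param Delta Lobe separation (leading edge to leading edge) in seconds;
#'   must satisfy `Delta >= delta` so the lobes do not overlap.
#' @param gamma Gyromagnetic ratio in Hz/T; proton default `42.577e6`.
#' @return An object of class `vn_gradient_spec`.
#' @examples
#' vn_gradient_spec(G = 40e-3, delta = 2e-3, Delta = 3e-3)
#' @export
vn_gradient_spec <- function(G, delta, Delta, gamma = 42.577e6) {
  check_positive(G, "G")
  check_positive(delta, "delta")
  check_positive(Delta, "Delta")
  check_positive(gamma, "gamma")
  if (Delta < delta) {
    abort_field("`Delta` must be >= `delta`: bipolar lobes must not overlap")
  }
  structure(list(gamma = gamma, G = G, delta = delta, Delta = Delta),
            class = "vn_gradient_spec")
}

#' @export
print.vn_gradient_spec <- function(x, ...) {
  cat(sprintf(
    "<vn_gradient_spec> G = %.3g mT/m, delta = %.3g ms, Delta = %.3g ms, gamma = %.4g MHz/T\n",
    x$G * 1e3, x$delta * 1e3, x$Delta * 1e3, x$gamma / 1e6
  ))
  cat(sprintf("  b = %.4g s/mm^2, critical velocity = %.3g mm/s\n",
              bipolar_b_value(x), critical_velocity(x) * 1e3))
  invisible(x)
}

#' b-value of a rectangular bipolar gradient pair
#'
#' Stejskal-Tanner expression for rectangular lobes,
#' `b = (2 pi gamma)^2 G^2 delta^2 (Delta - delta/3)`, converted to the
#' conventional s/mm^2. Ramp times are ignored (rectangular-lobe
#' approximation).
#'
#' @param spec A [vn_gradient_spec()].
#' @return b-value in s/mm^2.
#' @examples
#' bipolar_b_value(vn_gradient_spec(G = 40e-3, delta = 2e-3, Delta = 3e-3))
#' @export
bipolar_b_value <- function(spec) {
  stopifnot(inherits(spec, "vn_gradient_spec"))
  b_si <- (2 * pi * spec$gamma)^2 * spec$G^2 * spec$delta^2 *
    (spec$Delta - spec$delta / 3)
  b_si / B_PER_MM2_TO_SI
}

#' Critical velocity of a bipolar gradient pair
#'
#' The blood velocity at which the bipolar pair accrues pi radians of phase,
#' beyond which flowing spins are strongly attenuated:
#' `v_c = 1 / (2 gamma G Delta delta)`.
#'
#' @param spec A [vn_gradient_spec()].
#' @return Critical velocity in m/s.
#' @examples
#' critical_velocity(vn_gradient_spec(G = 40e-3, delta = 2e-3, Delta = 3e-3))
#' @export
critical_velocity <- function(spec) {
  stopifnot(inherits(spec, "vn_gradient_spec"))
  1 / (2 * spec$gamma * spec$G * spec$Delta * spec$delta)
}

#' Phase accrued by spins moving at constant velocity under a bipolar pair
#'
#' First-moment phase `phi = 2 pi gamma G delta Delta v` (radians). At
#' `v = critical_velocity(spec)` this equals pi by construction; exposed for
#' cross-checking the two formulas.
#'
#' @param spec A [vn_gradient_spec()].
#' @param v Velocity in m/s.
#' @return Phase in radians.
#' @export
bipolar_flow_phase <- function(spec, v) {
  stopifnot(inherits(spec, "vn_gradient_spec"))
  2 * pi * spec$gamma * spec$G * spec$delta * spec$Delta * v
}

#' IVIM signal retention under a velocity-nulling gradient
#'
#' Fraction of the compartment's signal surviving a diffusion weighting b:
#' `S/S0 = exp(-b (D* + D_blood))`, or the simplified `exp(-b D*)` when the
#' small blood-water diffusion term is neglected (valid because
#' D* >> D_blood for all flowing pools).
#'
#' @param b Diffusion weighting in s/mm^2 (vectorised, >= 0).
#' @param compartment A [vessel_compartment()].
#' @param include_blood_diffusion If `TRUE`, use `D* + D_blood`; default
#'   `FALSE` uses the simplified form.
#' @return Retention fraction(s) in (0, 1].
#' @examples
#' comps <- preset_compartments()
#' vn_attenuation(7, comps$vein)       # ~0.174
#' vn_attenuation(7, comps$capillary)  # ~0.932
#' @export
vn_attenuation <- function(b, compartment, include_blood_diffusion = FALSE) {
  stopifnot(inherits(compartment, "vessel_compartment"))
  if (!is.numeric(b) || any(!is.finite(b)) || any(b < 0)) {
    abort_field("`b` must be non-negative and finite (s/mm^2)")
  }
  D <- compartment$pseudo_diffusion +
    if (include_blood_diffusion) compartment$blood_diffusion else 0
  exp(-b * B_PER_MM2_TO_SI * D)
}

#' Per-compartment attenuation curves over a b-value grid
#'
#' Evaluates [vn_attenuation()] for each compartment over an ascending
#' b-grid, producing the design curves from which a velocity-nulling
#' b-value is chosen: small b should suppress vein signal while barely
#' touching capillaries.
#'
#' @param compartments A non-empty list of [vessel_compartment()] objects
#'   (e.g. [preset_compartments()]).
#' @param b_grid Ascending non-negative b values in s/mm^2.
#' @param include_blood_diffusion Passed to [vn_attenuation()].
#' @return A tibble of class `vn_attenuation_curve` with columns `b`,
#'   `compartment`, `retention`.
#' @examples
#' curve <- attenuation_curves(preset_compartments(), seq(0, 10, by = 0.5))
#' @export
attenuation_curves <- function(compartments, b_grid,
                               include_blood_diffusion = FALSE) {
  if (!is.list(compartments) || length(compartments) == 0L) {
    abort_field("`compartments` must be a non-empty list of vessel_compartment objects")
  }
  if (!is.numeric(b_grid) || any(!is.finite(b_grid)) || any(b_grid < 0)) {
    abort_field("`b_grid` must be non-negative and finite")
  }
  if (is.unsorted(b_grid, strictly = FALSE)) {
    abort_field("`b_grid` must be ascending")
  }
  out <- purrr::map_dfr(compartments, function(comp) {
    tibble::tibble(
      b = b_grid,
      compartment = comp$name,
      retention = vn_attenuation(b_grid, comp, include_blood_diffusion)
    )
  })
  class(out) <- c("vn_attenuation_curve", class(out))
  out
}

#' Recommend a b-value interval from attenuation curves
#'
#' Returns the part of the b-grid where the suppressed compartment (veins)
#' retains at most `vein_max_retention` of its signal while the preserved
#' compartment (capillaries) retains at least `capillary_min_retention`.
#' An empty result is a valid, reported outcome: the thresholds are then
#' incompatible on this grid.
#'
#' @param curve A `vn_attenuation_curve` from [attenuation_curves()].
#' @param vein_max_retention Maximum tolerated vein retention, in (0, 1).
#' @param capillary_min_retention Minimum required capillary retention, in (0, 1).
#' @param vein,capillary Compartment names to read from the curve.
#' @return A tibble with columns `b`, `vein_retention`,
#'   `capillary_retention`, containing the admissible sub-grid (possibly
#'   zero rows).
#' @examples
#' curve <- attenuation_curves(preset_compartments(), seq(0, 10, by = 1))
#' recommend_b(curve, 0.2, 0.9)
#' @export
recommend_b <- function(curve, vein_max_retention, capillary_min_retention,
                        vein = "vein", capillary = "capillary") {
  stopifnot(inherits(curve, "vn_attenuation_curve"))
  for (thr in c(vein_max_retention, capillary_min_retention)) {
    if (!is.numeric(thr) || length(thr) != 1L || thr <= 0 || thr > 1) {
      abort_field("retention thresholds must lie inside (0, 1]")
    }
  }
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(curve),
    names_from = "compartment", values_from = "retention"
  )
  if (!all(c(vein, capillary) %in% names(wide))) {
    abort_field(sprintf("curve lacks compartment '%s' or '%s'", vein, capillary))
  }
  ok <- wide[[vein]] <= vein_max_retention &
    wide[[capillary]] >= capillary_min_retention
  tibble::tibble(
    b = wide$b[ok],
    vein_retention = wide[[vein]][ok],
    capillary_retention = wide[[capillary]][ok]
  )
}

#' @importFrom ggplot2 autoplot
#' @method autoplot vn_attenuation_curve
#' @export
autoplot.vn_attenuation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$b, y = .data$retention, colour = .data$compartment
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = expression(b ~ "(s/mm"^2 * ")"),
      y = expression(S / S[0]),
      colour = NULL,
      title = "IVIM signal retention under velocity-nulling gradients"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Design table for choosing a velocity-nulling b-value
#'
#' Convenience wrapper combining per-compartment retention at each b with
#' the critical velocity of a matching gradient spec (when supplied).
#'
#' @param b_grid Ascending b values in s/mm^2.
#' @param compartments List of compartments; default [preset_compartments()].
#' @param spec Optional [vn_gradient_spec()]; when given, each b is realised
#'   by scaling the spec's amplitude `G` at fixed timing and the implied
#'   critical velocity is reported.
#' @return A tibble with one row per b: retention per compartment (wide) and
#'   optionally `critical_velocity_mm_s`.
#' @export
design_b_table <- function(b_grid, compartments = preset_compartments(),
                           spec = NULL) {
  curve <- attenuation_curves(compartments, b_grid)
  wide <- tidyr::pivot_wider(tibble::as_tibble(curve),
                             names_from = "compartment",
                             values_from = "retention")
  if (!is.null(spec)) {
    b0 <- bipolar_b_value(spec)
    # b scales with G^2 at fixed timing, v_c with 1/G
    g_scale <- sqrt(wide$b / b0)
    vc <- ifelse(g_scale > 0, critical_velocity(spec) / g_scale, Inf)
    wide$critical_velocity_mm_s <- vc * 1e3
  }
  wide
}
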
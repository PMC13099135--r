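#' Temporal phase unwrapping
#'
#' Removes 2-pi jumps from a wrapped phase time series: successive
#' differences are mapped into `(-pi, pi]` and re-accumulated, so the output
#' is congruent to the input modulo 2 pi and has no step larger than pi.
#' Temporal-only: each voxel's series is unwrapped independently.
#'
#' @param phase Numeric vector of wrapped phase values in radians.
#' @return Unwrapped phase vector of the same length.
#' @examples
#' ramp <- 0.4 * (0:50)
#' wrapped <- atan2(sin(ramp), cos(ramp))
#' all.equal(temporal_unwrap(wrapped), ramp)
#' @export
temporal_unwrap <- function(phase) {
  if (!is.numeric(phase) || any(!is.finite(phase))) {
    abort_field("`phase` must be a finite numeric vector")
  }
  if (length(phase) <= 1L) return(phase)
  d <- diff(phase)
  # map steps into (-pi, pi]
  d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))
  phase[1] + cumsum(c(0, d))
}

#' Phase regression of macrovascular signal from a magnitude series
#'
#' Large vessels modulate both the magnitude and the phase of the complex
#' fMRI signal, while the microvascular (capillary-level) BOLD response is
#' essentially magnitude-only. Regressing the magnitude time series on the
#' (unwrapped) phase time series and removing the fitted phase-coupled
#' component therefore suppresses the macrovascular contribution:
#' `cleaned = magnitude - beta1 * (phase - mean(phase))`. The raw mean is
#' preserved so percent-signal-change computations downstream are
#' unaffected, and the cleaned series is orthogonal to the centred phase
#' regressor.
#'
#' @param magnitude Numeric magnitude series (>= 3 time points).
#' @param phase Unwrapped phase series of the same length, radians.
#' @param sign Slope constraint: `"unrestricted"` (default, plain OLS) or
#'   `"positive"`/`"negative"` to zero the slope when it has the
#'   physiologically inconsistent sign.
#' @return A list of class `phase_regress_fit` with elements `cleaned`
#'   (numeric series), `beta0`, `beta1`, `constant_phase` (logical: input
#'   returned untouched because the phase carried no variance).
#' @seealso [phase_regress_dataset()] to apply per unit/layer across a
#'   [laminar_dataset()]; [temporal_unwrap()].
#' @examples
#' ph <- sin(seq(0, 6 * pi, length.out = 100))
#' mag <- 100 + 2 * ph + rnorm(100, sd = 0.1)
#' fit <- phase_regress(mag, ph)
#' fit$beta1 # ~2
#' @export
phase_regress <- function(magnitude, phase,
                          sign = c("unrestricted", "positive", "negative")) {
  sign <- match.arg(sign)
  if (length(magnitude) != length(phase)) {
    abort_field(sprintf("magnitude (%d) and phase (%d) lengths differ",
                        length(magnitude), length(phase)))
  }
  if (length(magnitude) < 3L) abort_field("need at least 3 time points")
  ph_c <- phase - mean(phase)
  if (stats::sd(phase) < .Machine$double.eps^0.5) {
    message("phase_regress: constant phase, magnitude returned unchanged")
    out <- list(cleaned = magnitude, beta0 = mean(magnitude), beta1 = 0,
                constant_phase = TRUE)
    class(out) <- "phase_regress_fit"
    return(out)
  }
  beta1 <- sum(ph_c * (magnitude - mean(magnitude))) / sum(ph_c^2)
  if (sign == "positive" && beta1 < 0) beta1 <- 0
  if (sign == "negative" && beta1 > 0) beta1 <- 0
  cleaned <- magnitude - beta1 * ph_c
  out <- list(cleaned = cleaned, beta0 = mean(magnitude), beta1 = beta1,
              constant_phase = FALSE)
  class(out) <- "phase_regress_fit"
  out
}

#' @export
print.phase_regress_fit <- function(x, ...) {
  cat(sprintf("<phase_regress_fit> beta1 = %.4g%s\n", x$beta1,
              if (x$constant_phase) " (constant phase: pass-through)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy phase_regress_fit
#' @export
tidy.phase_regress_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "phase"),
    estimate = c(x$beta0, x$beta1)
  )
}

#' Apply phase regression across a laminar dataset
#'
#' Unwraps the phase and runs [phase_regress()] independently for every
#' unit-by-layer series. Applied early, before temporal filtering, to keep
#' magnitude and phase processing aligned.
#'
#' @param dataset A [laminar_dataset()] with a phase channel.
#' @param unwrap Unwrap phase temporally first (default `TRUE`).
#' @param sign Passed to [phase_regress()].
#' @return A list with `dataset` (cleaned [laminar_dataset()], phase
#'   retained) and `beta_map` (tibble `unit`, `layer`, `beta1`).
#' @export
phase_regress_dataset <- function(dataset, unwrap = TRUE,
                                  sign = "unrestricted") {
  stopifnot(inherits(dataset, "laminar_dataset"))
  if (is.null(dataset$phase)) {
    abort_field("dataset has no phase channel; phase regression refused")
  }
  d <- dim(dataset$magnitude)
  cleaned <- dataset$magnitude
  beta <- matrix(NA_real_, d[1], d[2])
  for (u in seq_len(d[1])) {
    for (l in seq_len(d[2])) {
      ph <- dataset$phase[u, l, ]
      if (unwrap) ph <- temporal_unwrap(ph)
      fit <- suppressMessages(phase_regress(dataset$magnitude[u, l, ], ph,
                                            sign = sign))
      cleaned[u, l, ] <- fit$cleaned
      beta[u, l] <- fit$beta1
    }
  }
  out <- dataset
  out$magnitude <- cleaned
  list(
    dataset = out,
    beta_map = tibble::tibble(
      unit = rep(seq_len(d[1]), times = d[2]),
      layer = rep(seq_len(d[2]), each = d[1]),
      beta1 = as.vector(beta)
    )
  )
}
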
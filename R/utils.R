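# b-values are entered and reported in s/mm^2; diffusion coefficients in
# m^2/s. The single conversion constant lives here.
B_PER_MM2_TO_SI <- 1e6

# Pearson r magnitudes are clipped to this before atanh so that perfectly
# correlated series map to a finite Fisher-z ceiling.
R_CLIP <- 1 - 1e-7

abort_field <- function(msg) stop(msg, call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_field(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort_field(sprintf("`%s` must be non-negative and finite", name))
  }
  invisible(x)
}

#' Fisher z-transform of a correlation coefficient
#'
#' Variance-stabilising `atanh` transform used throughout the connectivity
#' analyses. Magnitudes are clipped to `1 - 1e-7` so that `r = 1` (a series
#' correlated with itself) maps to a finite ceiling rather than `Inf`.
#'
#' @param r Numeric vector of Pearson correlations in `[-1, 1]`.
#' @return Numeric vector of Fisher z values.
#' @examples
#' fisher_z(0.5) # 0.5493
#' fisher_z(c(-0.3, 0, 0.3))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) abort_field("`r` must be numeric")
  bad <- is.finite(r) & abs(r) > 1 + 1e-12
  if (any(bad)) {
    abort_field(sprintf("correlations must lie in [-1, 1]; got %g", r[which(bad)[1]]))
  }
  r <- pmin(pmax(r, -R_CLIP), R_CLIP)
  atanh(r)
}

#' Ceiling value of the clipped Fisher z-transform
#'
#' The z value assigned to a perfect correlation after clipping; useful for
#' recognising self-correlation entries in depth-by-depth matrices.
#'
#' @return A single number, `atanh(1 - 1e-7)`.
#' @export
fisher_z_ceiling <- function() atanh(R_CLIP)
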
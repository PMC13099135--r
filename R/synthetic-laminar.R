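#' Equidistant cortical depth grid
#'
#' Normalised cortical depth with 0 at the grey-matter/white-matter boundary
#' and 1 at the CSF/grey-matter boundary. The default 20 bins span
#' `[-0.125, 1.0625]`, slightly overshooting both boundaries so the most
#' superficial and deepest bins capture partial-volume vertices.
#'
#' @param n_layers Number of equidistant bins (>= 2); default 20.
#' @param depth_min,depth_max Normalised depth range; defaults `-0.125` and
#'   `1.0625`.
#' @return An object of class `depth_grid` with elements `n_layers`,
#'   `depth_min`, `depth_max`, `edges` (length `n_layers + 1`), `mid`
#'   (bin midpoints, ordered deep to superficial: layer 1 is deepest).
#' @examples
#' depth_grid()
#' depth_grid(n_layers = 10, depth_min = 0, depth_max = 1)
#' @export
depth_grid <- function(n_layers = 20, depth_min = -0.125, depth_max = 1.0625) {
  if (!is.numeric(n_layers) || length(n_layers) != 1L || n_layers < 2 ||
      n_layers != round(n_layers)) {
    abort_field("`n_layers` must be an integer >= 2")
  }
  if (!is.finite(depth_min) || !is.finite(depth_max) || depth_min >= depth_max) {
    abort_field("`depth_min` must be strictly less than `depth_max`")
  }
  edges <- seq(depth_min, depth_max, length.out = n_layers + 1)
  structure(
    list(
      n_layers = as.integer(n_layers),
      depth_min = depth_min,
      depth_max = depth_max,
      edges = edges,
      mid = (edges[-1] + edges[-length(edges)]) / 2
    ),
    class = "depth_grid"
  )
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> %d equidistant layers over [%g, %g] (0 = GM/WM, 1 = CSF/GM)\n",
              x$n_layers, x$depth_min, x$depth_max))
  invisible(x)
}

#' Double-gamma hemodynamic response function
#'
#' Canonical HRF: a gamma-density peak minus a scaled gamma-density
#' undershoot, normalised so the peak amplitude is 1. Defaults are the
#' common convention: peak delay 6 s, undershoot delay 16 s, unit
#' dispersions, undershoot ratio 1/6.
#'
#' @param t Time in seconds (vectorised, >= 0).
#' @param peak_delay,peak_disp Shape of the positive lobe: the gamma density
#'   has shape `peak_delay / peak_disp` and scale `peak_disp` (seconds).
#' @param undershoot_delay,undershoot_disp Same for the undershoot lobe.
#' @param undershoot_ratio Amplitude of the undershoot relative to the peak
#'   lobe before normalisation; default 1/6.
#' @return HRF amplitude at `t`, unit peak.
#' @examples
#' tt <- seq(0, 30, by = 0.1)
#' h <- double_gamma_hrf(tt)
#' tt[which.max(h)] # peak near 5 s
#' @export
double_gamma_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 1 / 6) {
  for (nm in c("peak_delay", "undershoot_delay", "peak_disp", "undershoot_disp")) {
    check_positive(get(nm), nm)
  }
  check_nonneg(undershoot_ratio, "undershoot_ratio")
  if (any(!is.finite(t)) || any(t < 0)) abort_field("`t` must be >= 0 and finite")
  raw <- function(tt) {
    stats::dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
      undershoot_ratio *
        stats::dgamma(tt, shape = undershoot_delay / undershoot_disp,
                      scale = undershoot_disp)
  }
  # unit-peak normalisation on a dense internal grid
  peak <- max(raw(seq(0, peak_delay + 10 * peak_disp, by = 0.01)))
  raw(t) / peak
}

#' Block task design
#'
#' On/off block paradigm: each ON block of `block_on` seconds is immediately
#' followed by `block_off` seconds of rest, sampled every TR. Defaults
#' match a 30 s on / 30 s off button-pressing paradigm at TR = 4 s.
#'
#' @param n_blocks Number of ON blocks.
#' @param block_on,block_off Durations in seconds; defaults 30/30.
#' @param TR Repetition time in seconds; default 4.
#' @param n_volumes Number of volumes; default exactly covers the blocks.
#' @return An object of class `task_design`.
#' @examples
#' task_design(n_blocks = 18) # 270 volumes at TR = 4 s
#' @export
task_design <- function(n_blocks, block_on = 30, block_off = 30, TR = 4,
                        n_volumes = NULL) {
  check_positive(block_on, "block_on")
  check_positive(block_off, "block_off")
  check_positive(TR, "TR")
  check_positive(n_blocks, "n_blocks")
  if (is.null(n_volumes)) {
    n_volumes <- ceiling(n_blocks * (block_on + block_off) / TR)
  }
  if (n_volumes * TR < n_blocks * (block_on + block_off)) {
    abort_field("`n_volumes` * TR must cover all blocks")
  }
  structure(
    list(n_blocks = as.integer(n_blocks), block_on = block_on,
         block_off = block_off, TR = TR, n_volumes = as.integer(n_volumes)),
    class = "task_design"
  )
}

#' Boxcar stimulus vector of a task design
#'
#' @param design A [task_design()].
#' @return 0/1 vector of length `n_volumes` (1 during ON blocks), sampled at
#'   volume acquisition times `(0, TR, 2 TR, ...)`.
#' @export
design_boxcar <- function(design) {
  stopifnot(inherits(design, "task_design"))
  t_vol <- (seq_len(design$n_volumes) - 1) * design$TR
  cycle <- design$block_on + design$block_off
  within <- t_vol %% cycle
  as.numeric(t_vol < design$n_blocks * cycle & within < design$block_on)
}

#' HRF-convolved task regressor
#'
#' Boxcar convolved with the double-gamma HRF at the design's TR; this is
#' the regressor used both by the simulator and by the depth-profile GLM,
#' scaled to unit peak so simulated percent-signal-change amplitudes read
#' directly as plateau response size.
#'
#' @param design A [task_design()].
#' @param ... HRF parameters passed to [double_gamma_hrf()].
#' @return Numeric vector of length `n_volumes`.
#' @export
task_regressor <- function(design, ...) {
  box <- design_boxcar(design)
  h <- double_gamma_hrf(seq(0, 32, by = design$TR), ...)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(box)]
  conv / max(conv)
}

#' Layer-specific neural activation profile
#'
#' Ground-truth depth profile of neural (capillary-level) percent signal
#' change. `double_peak` emulates the primary-motor-cortex hallmark — a
#' superficial peak (sensory/associative input) and a deep peak
#' (corticospinal output) with a quiet middle; `superficial_only` and
#' `flat` are controls.
#'
#' @param kind `"double_peak"`, `"superficial_only"` or `"flat"`.
#' @param grid A [depth_grid()].
#' @param peak_depths Normalised depths of the Gaussian bumps; defaults
#'   `c(0.25, 0.8)` for `double_peak`, `0.9` for `superficial_only`.
#' @param peak_widths Gaussian SDs in depth units (recycled).
#' @param amplitudes Peak amplitudes in percent signal change (recycled
#'   against `peak_depths`).
#' @return A tibble of class `neural_profile` with columns `layer`, `depth`
#'   (bin midpoint; layer 1 deepest), `amplitude`.
#' @examples
#' make_neural_profile("double_peak", depth_grid())
#' @export
make_neural_profile <- function(kind = c("double_peak", "superficial_only", "flat"),
                                grid = depth_grid(),
                                peak_depths = NULL, peak_widths = 0.08,
                                amplitudes = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "depth_grid"))
  if (kind == "flat") {
    amp <- if (is.null(amplitudes)) 1 else amplitudes[1]
    out <- tibble::tibble(layer = seq_len(grid$n_layers), depth = grid$mid,
                          amplitude = rep(amp, grid$n_layers))
    class(out) <- c("neural_profile", class(out))
    return(out)
  }
  if (is.null(peak_depths)) {
    peak_depths <- if (kind == "double_peak") c(0.25, 0.8) else 0.9
  }
  if (is.null(amplitudes)) amplitudes <- rep(1, length(peak_depths))
  peak_widths <- rep_len(peak_widths, length(peak_depths))
  if (length(amplitudes) != length(peak_depths)) {
    abort_field("`amplitudes` must match `peak_depths` in length")
  }
  if (any(peak_depths < grid$depth_min | peak_depths > grid$depth_max)) {
    abort_field("`peak_depths` must lie inside the depth range")
  }
  amp <- rowSums(vapply(seq_along(peak_depths), function(k) {
    amplitudes[k] * exp(-(grid$mid - peak_depths[k])^2 / (2 * peak_widths[k]^2))
  }, numeric(grid$n_layers)))
  out <- tibble::tibble(layer = seq_len(grid$n_layers), depth = grid$mid,
                        amplitude = amp)
  class(out) <- c("neural_profile", class(out))
  out
}

profile_vector <- function(profile) {
  if (inherits(profile, "neural_profile") || is.data.frame(profile)) {
    profile$amplitude
  } else if (is.numeric(profile)) {
    profile
  } else {
    abort_field("`profile` must be a neural_profile tibble or numeric vector")
  }
}

#' Draining-vein leakage operator
#'
#' Linear layers-by-layers operator carrying capillary-level BOLD upward
#' through ascending (penetrating) veins: the measured signal at layer l is
#' the local signal plus `alpha * w_l` times the signal of every deeper
#' layer, where `w_l` is the vein density at layer l, increasing linearly
#' from deep to superficial and normalised to mean 1. With layer 1 deepest,
#' the matrix `K = I + alpha * W` is lower triangular — signal flows only
#' toward the surface — and reduces to the identity at `alpha = 0`.
#'
#' @param grid A [depth_grid()].
#' @param alpha Drainage strength, >= 0 (0 = no leakage).
#' @param vein_density_slope Relative increase of vein density from the
#'   deepest to the most superficial layer (default 1, i.e. the superficial
#'   density is twice the deep density before normalisation).
#' @return An object of class `leakage_operator` with elements `K`
#'   (n_layers x n_layers), `alpha`, `vein_density`, `grid`.
#' @examples
#' op <- build_leakage_operator(depth_grid(), alpha = 0.3)
#' @export
build_leakage_operator <- function(grid, alpha, vein_density_slope = 1) {
  stopifnot(inherits(grid, "depth_grid"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    abort_field("`alpha` must be a single non-negative number")
  }
  n <- grid$n_layers
  frac <- (grid$mid - min(grid$mid)) / (max(grid$mid) - min(grid$mid))
  w <- 1 + vein_density_slope * frac
  if (any(w < 0)) abort_field("vein density must be non-negative; reduce `vein_density_slope`")
  w <- w / mean(w)
  K <- diag(n)
  for (l in seq_len(n)) {
    deeper <- seq_len(l - 1L) # layer 1 deepest: m < l are deeper than l
    K[l, deeper] <- alpha * w[l]
  }
  structure(list(K = K, alpha = alpha, vein_density = w, grid = grid),
            class = "leakage_operator")
}

#' @export
print.leakage_operator <- function(x, ...) {
  cat(sprintf("<leakage_operator> %d layers, alpha = %g (K = I at alpha = 0)\n",
              x$grid$n_layers, x$alpha))
  invisible(x)
}

#' Measured depth profile after drainage and velocity-nulling
#'
#' Composes the leakage operator with compartment-specific VN retention:
#' the capillary (local) part of the signal survives with fraction
#' `vn_retention_cap`, the venous (drained) part with `vn_retention_vein`:
#' `measured = cap * p + vein * (K - I) p`. Retentions (1, 1) give the
#' plain drained profile `K p`; vein retention 0 recovers the capillary
#' profile shape exactly.
#'
#' @param profile A [make_neural_profile()] tibble or numeric vector.
#' @param op A [build_leakage_operator()].
#' @param vn_retention_vein,vn_retention_cap Retention fractions in (0, 1];
#'   typically [vn_attenuation()] of the vein and capillary compartments at
#'   the chosen b.
#' @return A tibble of class `neural_profile` with columns `layer`, `depth`,
#'   `amplitude` (the measured profile).
#' @examples
#' grid <- depth_grid()
#' p <- make_neural_profile("double_peak", grid)
#' op <- build_leakage_operator(grid, alpha = 0.3)
#' apply_drainage(p, op)                                   # no VN (b = 0)
#' comps <- preset_compartments()
#' apply_drainage(p, op,
#'   vn_retention_vein = vn_attenuation(7, comps$vein),
#'   vn_retention_cap = vn_attenuation(7, comps$capillary))
#' @export
apply_drainage <- function(profile, op, vn_retention_vein = 1,
                           vn_retention_cap = 1) {
  stopifnot(inherits(op, "leakage_operator"))
  for (r in c(vn_retention_vein, vn_retention_cap)) {
    if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1) {
      abort_field("VN retentions must lie in (0, 1]")
    }
  }
  p <- profile_vector(profile)
  n <- op$grid$n_layers
  if (length(p) != n) {
    abort_field(sprintf("profile has %d layers but operator expects %d",
                        length(p), n))
  }
  measured <- vn_retention_cap * p +
    vn_retention_vein * ((op$K - diag(n)) %*% p)[, 1]
  out <- tibble::tibble(layer = seq_len(n), depth = op$grid$mid,
                        amplitude = measured)
  class(out) <- c("neural_profile", class(out))
  out
}

#' Laminar fMRI dataset container
#'
#' Magnitude (and optionally phase) time series indexed by spatial unit
#' (voxel, vertex or ROI), cortical layer, and time.
#'
#' @param magnitude 3-d array `unit x layer x time`, positive where tissue.
#' @param phase Optional array of the same shape, radians.
#' @param TR Repetition time in seconds.
#' @param grid A [depth_grid()] matching the layer dimension.
#' @param ground_truth Optional list of simulation truth (profile,
#'   covariance, parameters) retained for testing.
#' @param roi Optional integer/character vector of length `n_units`
#'   labelling each unit's ROI.
#' @return An object of class `laminar_dataset`.
#' @export
laminar_dataset <- function(magnitude, phase = NULL, TR, grid,
                            ground_truth = NULL, roi = NULL) {
  stopifnot(is.array(magnitude), length(dim(magnitude)) == 3L,
            inherits(grid, "depth_grid"))
  check_positive(TR, "TR")
  if (dim(magnitude)[2] != grid$n_layers) {
    abort_field(sprintf("magnitude has %d layers but grid has %d",
                        dim(magnitude)[2], grid$n_layers))
  }
  if (!is.null(phase) && !identical(dim(phase), dim(magnitude))) {
    abort_field(sprintf(
      "phase shape (%s) must match magnitude shape (%s)",
      paste(dim(phase), collapse = "x"), paste(dim(magnitude), collapse = "x")
    ))
  }
  if (!is.null(roi) && length(roi) != dim(magnitude)[1]) {
    abort_field("`roi` must label every unit")
  }
  structure(
    list(magnitude = magnitude, phase = phase, TR = TR, grid = grid,
         ground_truth = ground_truth, roi = roi),
    class = "laminar_dataset"
  )
}

#' @export
print.laminar_dataset <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "<laminar_dataset> %d units x %d layers x %d volumes, TR = %g s, phase: %s\n",
    d[1], d[2], d[3], x$TR, if (is.null(x$phase)) "absent" else "present"
  ))
  invisible(x)
}

#' @method as_tibble laminar_dataset
#' @export
#' @importFrom tibble as_tibble
as_tibble.laminar_dataset <- function(x, ...) {
  d <- dim(x$magnitude)
  out <- tidyr::expand_grid(
    unit = seq_len(d[1]), layer = seq_len(d[2]), volume = seq_len(d[3])
  )
  # expand_grid varies the last column fastest; array index varies the first
  out$magnitude <- as.vector(aperm(x$magnitude, c(3, 2, 1)))
  if (!is.null(x$phase)) out$phase <- as.vector(aperm(x$phase, c(3, 2, 1)))
  out$depth <- x$grid$mid[out$layer]
  out$time <- (out$volume - 1) * x$TR
  out
}

#' Simulate a block-task laminar BOLD run
#'
#' Forward model: a layer-specific neural profile is pushed through the
#' draining-vein leakage operator under compartment-specific VN retention,
#' modulated by the HRF-convolved block regressor, and embedded in a
#' baseline of 100 (so amplitudes are percent signal change) with additive
#' Gaussian noise. The phase channel carries the macrovascular (venous,
#' drained) component only, scaled by `phase_gain`, plus phase noise —
#' emulating the magnitude-correlated phase of large vessels that phase
#' regression exploits.
#'
#' @param design A [task_design()].
#' @param profile Ground-truth neural profile ([make_neural_profile()]).
#' @param op A [build_leakage_operator()]; `NULL` means no leakage.
#' @param vn_retention_vein,vn_retention_cap VN retentions in (0, 1].
#' @param n_units Number of spatial units (voxels) per layer column.
#' @param noise_sd Magnitude noise SD in baseline units (>= 0).
#' @param phase_gain Radians of phase per baseline-unit of macrovascular
#'   signal; 0 disables the phase channel's vascular content.
#' @param phase_noise_sd Phase noise SD in radians.
#' @param seed Mandatory integer seed; identical seeds give bit-identical
#'   datasets.
#' @return A [laminar_dataset()] with ground truth attached.
#' @export
simulate_task_run <- function(design, profile, op = NULL,
                              vn_retention_vein = 1, vn_retention_cap = 1,
                              n_units = 1, noise_sd = 0,
                              phase_gain = 0, phase_noise_sd = 0,
                              seed) {
  stopifnot(inherits(design, "task_design"))
  if (missing(seed)) abort_field("`seed` is mandatory")
  if (noise_sd < 0) abort_field("`noise_sd` must be >= 0")
  if (phase_noise_sd < 0) abort_field("`phase_noise_sd` must be >= 0")
  p <- profile_vector(profile)
  n_layers <- length(p)
  if (is.null(op)) {
    g <- if (is.data.frame(profile) && !is.null(attr(profile, "grid"))) {
      attr(profile, "grid")
    } else {
      depth_grid(n_layers = n_layers)
    }
    op <- build_leakage_operator(g, alpha = 0)
  }
  grid <- op$grid
  measured <- apply_drainage(p, op, vn_retention_vein, vn_retention_cap)$amplitude
  venous <- vn_retention_vein * ((op$K - diag(n_layers)) %*% p)[, 1]
  x <- task_regressor(design)
  nt <- design$n_volumes
  baseline <- 100
  clean <- baseline * (1 + outer(measured, x) / 100)      # layer x time
  macro <- baseline * outer(venous, x) / 100              # layer x time

  withr_seed <- function(expr) { # local RNG, no global-state leakage
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  res <- withr_seed({
    mag <- array(rep(clean, each = n_units), dim = c(n_units, n_layers, nt)) +
      array(stats::rnorm(n_units * n_layers * nt, sd = noise_sd),
            dim = c(n_units, n_layers, nt))
    ph <- phase_gain * array(rep(macro, each = n_units),
                             dim = c(n_units, n_layers, nt)) +
      array(stats::rnorm(n_units * n_layers * nt, sd = phase_noise_sd),
            dim = c(n_units, n_layers, nt))
    list(mag = mag, ph = ph)
  })
  laminar_dataset(
    res$mag, phase = res$ph, TR = design$TR, grid = grid,
    ground_truth = list(
      kind = "task", profile = p, measured_profile = measured,
      venous_profile = venous, design = design, regressor = x,
      vn_retention_vein = vn_retention_vein,
      vn_retention_cap = vn_retention_cap,
      alpha = op$alpha, noise_sd = noise_sd, phase_gain = phase_gain,
      phase_noise_sd = phase_noise_sd, seed = seed
    )
  )
}

fft_bandlimit <- function(x, band, TR) {
  # brick-wall band restriction of the columns of x (time in rows)
  nt <- nrow(x)
  freqs <- (seq_len(nt) - 1) / (nt * TR)
  freqs <- pmin(freqs, 1 / TR - freqs) # two-sided
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) abort_field("band keeps no Fourier component at this length/TR")
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / nt
}

#' Simulate a resting-state laminar run with known depth-by-ROI covariance
#'
#' Generates band-limited Gaussian time series over `roi_count * n_layers`
#' channels whose population correlation matrix equals `target_covariance`:
#' white noise is brick-wall restricted to the band, each channel is
#' standardised, and the channels are mixed with the symmetric square root
#' of the target. Empirical Fisher-z estimates converge to the target as
#' `n_volumes` grows.
#'
#' @param grid A [depth_grid()].
#' @param roi_count Number of ROIs (columns); channels are ordered layer
#'   fastest within ROI.
#' @param target_covariance Symmetric positive semi-definite correlation
#'   matrix of size `(roi_count * n_layers)`; default identity.
#' @param band Passband in Hz, inside `(0, 1/(2 TR))`; default 0.01-0.1.
#' @param TR Repetition time in seconds; default 4.
#' @param n_volumes Number of volumes; default 300.
#' @param noise_sd SD of additive broadband sensor noise on top of the
#'   band-limited signal (default 0 = noise-free in-band structure).
#' @param seed Mandatory integer seed.
#' @return A [laminar_dataset()] with `roi` labels and ground truth
#'   (`target_covariance`, band, seed). Magnitude is `100 + signal`.
#' @export
simulate_rest_run <- function(grid = depth_grid(), roi_count = 1,
                              target_covariance = NULL,
                              band = c(0.01, 0.1), TR = 4, n_volumes = 300,
                              noise_sd = 0, seed) {
  stopifnot(inherits(grid, "depth_grid"))
  if (missing(seed)) abort_field("`seed` is mandatory")
  check_positive(TR, "TR")
  nyq <- 1 / (2 * TR)
  if (length(band) != 2L || band[1] <= 0 || band[2] > nyq || band[1] >= band[2]) {
    abort_field(sprintf("`band` must lie inside (0, %g Hz) (Nyquist at TR = %g s)",
                        nyq, TR))
  }
  n_ch <- roi_count * grid$n_layers
  if (is.null(target_covariance)) target_covariance <- diag(n_ch)
  if (!isTRUE(all.equal(target_covariance, t(target_covariance), tolerance = 1e-8))) {
    abort_field("`target_covariance` must be symmetric")
  }
  if (nrow(target_covariance) != n_ch) {
    abort_field(sprintf("`target_covariance` must be %d x %d", n_ch, n_ch))
  }
  ev <- eigen(target_covariance, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    abort_field(sprintf(
      "`target_covariance` is not positive semi-definite: smallest eigenvalue %g",
      min(ev$values)
    ))
  }
  sqrt_cov <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_ch) %*% t(ev$vectors)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  white <- matrix(stats::rnorm(n_volumes * n_ch), nrow = n_volumes)
  bl <- fft_bandlimit(white, band, TR)
  bl <- scale(bl) # unit variance per channel, zero mean
  mixed <- bl %*% sqrt_cov # time x channel, population correlation = target
  if (noise_sd > 0) {
    mixed <- mixed + matrix(stats::rnorm(n_volumes * n_ch, sd = noise_sd),
                            nrow = n_volumes)
  }
  # channels ordered layer-fastest within ROI -> array roi x layer x time
  mag <- array(100 + t(mixed), dim = c(grid$n_layers, roi_count, n_volumes))
  mag <- aperm(mag, c(2, 1, 3))
  laminar_dataset(
    mag, TR = TR, grid = grid, roi = seq_len(roi_count),
    ground_truth = list(
      kind = "rest", target_covariance = target_covariance, band = band,
      noise_sd = noise_sd, seed = seed
    )
  )
}
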
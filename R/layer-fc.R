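#' Zero-phase temporal filtering of fMRI time series
#'
#' Order-4 Butterworth filter applied forward and backward
#' (zero phase shift): band-pass for resting-state series (default
#' 0.01-0.1 Hz) or high-pass only for task series (pass `band = c(f, NA)`
#' or a single cutoff). Passband sinusoids survive within a few percent;
#' components at twice the cutoff are attenuated by more than 90%.
#'
#' @param x Numeric series, or a matrix with time in rows (filtered
#'   column-wise).
#' @param band Two-sided passband in Hz, or `c(f, NA)` / single value for
#'   high-pass at f. Must lie inside `(0, 1/(2 TR))`.
#' @param TR Sampling interval in seconds.
#' @param order Butterworth order per pass; default 4.
#' @return Filtered series/matrix of the same shape (mean removed by the
#'   high-pass edge).
#' @examples
#' t <- seq(0, 400, by = 4)
#' bandpass_filter(sin(2 * pi * 0.05 * t), c(0.01, 0.1), TR = 4)
#' @export
bandpass_filter <- function(x, band = c(0.01, 0.1), TR, order = 4) {
  check_positive(TR, "TR")
  nyq <- 1 / (2 * TR)
  if (length(band) == 1L) band <- c(band, NA_real_)
  if (!is.finite(band[1]) || band[1] <= 0 || band[1] >= nyq) {
    abort_field(sprintf("lower cutoff %g Hz outside (0, Nyquist = %g Hz)",
                        band[1], nyq))
  }
  highpass_only <- !is.finite(band[2])
  if (!highpass_only && (band[2] <= band[1] || band[2] > nyq)) {
    abort_field(sprintf("upper cutoff %g Hz outside (%g, Nyquist = %g Hz)",
                        band[2], band[1], nyq))
  }
  filt <- if (highpass_only) {
    signal::butter(order, band[1] / nyq, type = "high")
  } else {
    signal::butter(order, band / nyq, type = "pass")
  }
  apply_one <- function(v) {
    n <- length(v)
    v <- v - mean(v) # the passband excludes DC in either mode
    # odd-reflection padding confines the filter's edge transients to the
    # discarded pads
    L <- min(n - 1L, 200L)
    pre <- 2 * v[1] - v[seq(L + 1L, 2L)]
    post <- 2 * v[n] - v[seq(n - 1L, n - L)]
    out <- as.numeric(signal::filtfilt(filt, c(pre, v, post)))
    out[seq(L + 1L, L + n)]
  }
  if (is.matrix(x)) apply(x, 2, apply_one) else apply_one(x)
}

#' Band-pass filter every series of a laminar dataset
#'
#' @param dataset A [laminar_dataset()].
#' @inheritParams bandpass_filter
#' @return The dataset with filtered magnitude (phase untouched).
#' @export
bandpass_dataset <- function(dataset, band = c(0.01, 0.1), order = 4) {
  stopifnot(inherits(dataset, "laminar_dataset"))
  d <- dim(dataset$magnitude)
  out <- dataset
  for (u in seq_len(d[1])) {
    out$magnitude[u, , ] <- t(bandpass_filter(
      t(dataset$magnitude[u, , , drop = TRUE]),
      band = band, TR = dataset$TR, order = order
    ))
  }
  out
}

layers_in_range <- function(grid, projection) {
  if (length(projection) != 2L || projection[1] > projection[2]) {
    abort_field("`projection` must be c(lo, hi) with lo <= hi")
  }
  which(grid$mid >= projection[1] & grid$mid <= projection[2])
}

#' Layer-specific seed time course
#'
#' Mean time series over all units of an ROI restricted to the layers whose
#' depth midpoint lies inside the projection range — e.g. `c(0.1, 0.15)`
#' for a deep-layer seed, `c(0.85, 0.9)` superficial, `c(0.1, 0.9)` for the
#' overall cortical-depth seed.
#'
#' @param dataset A [laminar_dataset()].
#' @param roi Units forming the ROI: integer unit indices, or values matched
#'   against `dataset$roi` labels. `NULL` means all units.
#' @param projection Depth range `c(lo, hi)` in normalised depth.
#' @return Numeric time series of length `n_volumes`.
#' @export
layer_seed_timecourse <- function(dataset, roi = NULL,
                                  projection = c(0, 1)) {
  stopifnot(inherits(dataset, "laminar_dataset"))
  units <- resolve_units(dataset, roi)
  lay <- layers_in_range(dataset$grid, projection)
  if (length(lay) == 0L) {
    abort_field(sprintf("no layers with depth midpoint in [%g, %g]",
                        projection[1], projection[2]))
  }
  sub <- dataset$magnitude[units, lay, , drop = FALSE]
  apply(sub, 3, mean)
}

resolve_units <- function(dataset, roi) {
  if (is.null(roi)) return(seq_len(dim(dataset$magnitude)[1]))
  if (!is.null(dataset$roi) && !is.numeric(roi)) {
    units <- which(dataset$roi %in% roi)
  } else if (!is.null(dataset$roi) && any(roi %in% dataset$roi)) {
    units <- which(dataset$roi %in% roi)
  } else {
    units <- as.integer(roi)
  }
  if (length(units) == 0L || any(units > dim(dataset$magnitude)[1])) {
    abort_field(sprintf("ROI '%s' selects no units in the dataset",
                        paste(roi, collapse = ",")))
  }
  units
}

#' Seed-based functional connectivity map across units and depths
#'
#' Pearson correlation of every unit's depth-resolved series with a seed
#' time course, Fisher-z transformed. With a single regressor this equals
#' the standardised GLM slope up to the monotone r-to-t map, so the GLM and
#' correlation formulations of seed FC coincide. When `depth_ranges` is
#' given, series are averaged within each range before correlating.
#'
#' @param seed Seed time series (e.g. [layer_seed_timecourse()]).
#' @param dataset A [laminar_dataset()].
#' @param depth_ranges Optional named list of `c(lo, hi)` projection ranges;
#'   default one value per layer.
#' @return A tibble with columns `unit`, `layer` (or `range`), `r`, `z`.
#'   Zero-variance series give `NA` with a warning.
#' @export
seed_fc_map <- function(seed, dataset, depth_ranges = NULL) {
  stopifnot(inherits(dataset, "laminar_dataset"))
  d <- dim(dataset$magnitude)
  if (length(seed) != d[3]) abort_field("seed length must equal n_volumes")
  corr_or_na <- function(v) {
    if (stats::sd(v) < .Machine$double.eps^0.5) NA_real_ else stats::cor(seed, v)
  }
  if (is.null(depth_ranges)) {
    grid_tbl <- tidyr::expand_grid(unit = seq_len(d[1]), layer = seq_len(d[2]))
    r <- purrr::map2_dbl(grid_tbl$unit, grid_tbl$layer,
                         ~ corr_or_na(dataset$magnitude[.x, .y, ]))
    out <- dplyr::mutate(grid_tbl, r = r, z = fisher_z_na(r))
  } else {
    if (is.null(names(depth_ranges))) {
      names(depth_ranges) <- vapply(depth_ranges,
                                    function(p) sprintf("%g-%g", p[1], p[2]), "")
    }
    grid_tbl <- tidyr::expand_grid(unit = seq_len(d[1]),
                                   range = names(depth_ranges))
    r <- purrr::map2_dbl(grid_tbl$unit, grid_tbl$range, function(u, rg) {
      lay <- layers_in_range(dataset$grid, depth_ranges[[rg]])
      corr_or_na(apply(dataset$magnitude[u, lay, , drop = FALSE], 3, mean))
    })
    out <- dplyr::mutate(grid_tbl, r = r, z = fisher_z_na(r))
  }
  if (anyNA(out$r)) {
    warning(sprintf("%d zero-variance series set to NA", sum(is.na(out$r))),
            call. = FALSE)
  }
  out
}

fisher_z_na <- function(r) {
  out <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  out[ok] <- fisher_z(r[ok])
  out
}

#' Intracortical depth-by-depth connectivity matrix
#'
#' For each unit (vertex/column), the Pearson correlation matrix across its
#' depth-resolved time series is Fisher-z transformed; matrices are then
#' averaged unweighted across units. Draining veins inflate the
#' superficial-layer block of this matrix; velocity-nulling reduces that
#' inflation. Units containing a constant depth series are skipped and
#' counted.
#'
#' @param dataset A [laminar_dataset()] (filtered resting-state data).
#' @param units Optional subset of unit indices.
#' @return A symmetric `n_layers x n_layers` matrix of class
#'   `depth_fc_matrix`; diagonal at the Fisher-z clip ceiling. Attribute
#'   `n_units_used` records how many units entered the average.
#' @export
intracortical_depth_matrix <- function(dataset, units = NULL) {
  stopifnot(inherits(dataset, "laminar_dataset"))
  d <- dim(dataset$magnitude)
  if (d[2] < 2L) abort_field("need at least 2 depth bins")
  if (d[3] < 2L) abort_field("need at least 2 time points")
  units <- if (is.null(units)) seq_len(d[1]) else units
  acc <- matrix(0, d[2], d[2])
  used <- 0L
  skipped <- 0L
  for (u in units) {
    m <- t(dataset$magnitude[u, , , drop = TRUE]) # time x layer
    if (any(apply(m, 2, stats::sd) < .Machine$double.eps^0.5)) {
      skipped <- skipped + 1L
      next
    }
    acc <- acc + fisher_z(stats::cor(m))
    used <- used + 1L
  }
  if (used == 0L) abort_field("every unit had a constant depth series")
  if (skipped > 0L) {
    message(sprintf("intracortical_depth_matrix: skipped %d unit(s) with constant series",
                    skipped))
  }
  out <- acc / used
  out <- (out + t(out)) / 2
  structure(out, class = c("depth_fc_matrix", "matrix"),
            grid = dataset$grid, n_units_used = used)
}

#' @method autoplot depth_fc_matrix
#' @export
autoplot.depth_fc_matrix <- function(object, ...) {
  tbl <- depth_fc_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$depth_a, y = .data$depth_b,
                                    fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "depth bin", y = "depth bin", fill = "Fisher z",
                  title = "Intracortical depth-by-depth connectivity") +
    ggplot2::theme_minimal()
}

#' Long-format view of a depth FC matrix
#'
#' @param m A `depth_fc_matrix` (or any numeric matrix).
#' @return Tibble with columns `depth_a`, `depth_b`, `z`.
#' @export
depth_fc_tibble <- function(m) {
  tibble::tibble(
    depth_a = rep(seq_len(nrow(m)), times = ncol(m)),
    depth_b = rep(seq_len(ncol(m)), each = nrow(m)),
    z = as.vector(unclass(m))
  )
}

#' Depth-dependent connectivity between ROI pairs
#'
#' For each pair of ROIs A and B: the layer-averaged time series of A at
#' depth i is correlated with that of B at depth j, giving a
#' depths-of-A by depths-of-B Fisher-z matrix — the depth-resolved
#' connectome cell from which feedforward/feedback asymmetries are read.
#'
#' @param dataset A [laminar_dataset()] whose units carry ROI labels
#'   (`dataset$roi`), or supply `labels`.
#' @param labels Optional per-unit ROI labels overriding `dataset$roi`.
#' @param rois Optional subset of ROI labels (default: all, in label
#'   order). Each requested ROI must be present in the data.
#' @return A tibble with columns `roi_a`, `roi_b`, `depth_a`, `depth_b`,
#'   `r`, `z`, covering unordered pairs including A = B.
#' @seealso [pair_matrix()] to extract one pair as a matrix.
#' @export
roi_pair_depth_fc <- function(dataset, labels = NULL, rois = NULL) {
  stopifnot(inherits(dataset, "laminar_dataset"))
  labels <- if (is.null(labels)) dataset$roi else labels
  if (is.null(labels)) abort_field("dataset has no ROI labels; supply `labels`")
  d <- dim(dataset$magnitude)
  if (length(labels) != d[1]) abort_field("`labels` must label every unit")
  all_rois <- unique(labels)
  if (is.null(rois)) rois <- all_rois
  missing_rois <- setdiff(rois, all_rois)
  if (length(missing_rois) > 0L) {
    abort_field(sprintf("ROI label(s) absent from data: %s",
                        paste(missing_rois, collapse = ", ")))
  }
  if (length(rois) < 2L && length(all_rois) < 2L) {
    abort_field("need at least 2 ROIs for pairwise depth FC")
  }
  # layer-mean series per ROI: list of time x layer matrices
  series <- lapply(rois, function(rr) {
    units <- which(labels == rr)
    t(apply(dataset$magnitude[units, , , drop = FALSE], c(2, 3), mean))
  })
  names(series) <- as.character(rois)
  pairs <- tidyr::expand_grid(a = seq_along(rois), b = seq_along(rois)) |>
    dplyr::filter(.data$a <= .data$b)
  purrr::pmap_dfr(pairs, function(a, b) {
    r <- stats::cor(series[[a]], series[[b]])
    tibble::tibble(
      roi_a = rois[a], roi_b = rois[b],
      depth_a = rep(seq_len(d[2]), times = d[2]),
      depth_b = rep(seq_len(d[2]), each = d[2]),
      r = as.vector(r),
      z = fisher_z(as.vector(r))
    )
  })
}

#' Extract one ROI pair's depth FC matrix
#'
#' @param fc_tbl Output of [roi_pair_depth_fc()].
#' @param roi_a,roi_b ROI labels.
#' @param value Column to spread; default `"z"`.
#' @return A depths-of-A x depths-of-B matrix of class `depth_fc_matrix`.
#' @export
pair_matrix <- function(fc_tbl, roi_a, roi_b, value = "z") {
  sub <- dplyr::filter(fc_tbl, .data$roi_a == !!roi_a, .data$roi_b == !!roi_b)
  if (nrow(sub) == 0L) { # pair may be stored in the other order, transposed
    sub <- dplyr::filter(fc_tbl, .data$roi_a == !!roi_b, .data$roi_b == !!roi_a)
    if (nrow(sub) == 0L) abort_field("ROI pair not found in `fc_tbl`")
    n <- max(sub$depth_a)
    m <- matrix(NA_real_, n, n)
    m[cbind(sub$depth_b, sub$depth_a)] <- sub[[value]]
    return(structure(m, class = c("depth_fc_matrix", "matrix")))
  }
  n <- max(sub$depth_a)
  m <- matrix(NA_real_, n, n)
  m[cbind(sub$depth_a, sub$depth_b)] <- sub[[value]]
  structure(m, class = c("depth_fc_matrix", "matrix"))
}

#' Element-wise group statistics on connectivity matrices
#'
#' One-sample (z against zero) or paired (condition A minus condition B)
#' t-tests on each matrix element across subjects, with Benjamini-Hochberg
#' FDR correction over the tested element set. For symmetric matrices only
#' the upper triangle is tested; intracortical diagonals (self-correlation
#' ceilings) are excluded.
#'
#' @param matrices List of per-subject matrices (all the same shape), or a
#'   3-d array with subjects along the third dimension.
#' @param matrices2 For `mode = "paired"`, the matched second-condition
#'   list; the test is on element-wise differences `matrices - matrices2`.
#' @param mode `"one_sample"` or `"paired"`.
#' @param q_threshold FDR threshold for the significance mask; default 0.05.
#' @param exclude_diag Drop diagonal elements (default `TRUE` for square
#'   matrices).
#' @return A tibble of class `group_fc_test` with columns `row`, `col`,
#'   `estimate` (mean z or mean difference), `t`, `p`, `q`, `significant`.
#'   Attribute `n_subjects` records the group size.
#' @export
group_matrix_test <- function(matrices, matrices2 = NULL,
                              mode = c("one_sample", "paired"),
                              q_threshold = 0.05, exclude_diag = TRUE) {
  mode <- match.arg(mode)
  strip <- function(x) matrix(as.numeric(x), nrow = nrow(x))
  as_list <- function(m) {
    if (is.list(m)) lapply(m, strip)
    else if (is.array(m) && length(dim(m)) == 3L) {
      lapply(seq_len(dim(m)[3]), function(k) m[, , k])
    } else abort_field("`matrices` must be a list of matrices or a 3-d array")
  }
  ms <- as_list(matrices)
  n <- length(ms)
  if (n < 3L) abort_field("need at least 3 subjects for a group test")
  if (mode == "paired") {
    if (is.null(matrices2)) abort_field("paired mode requires `matrices2`")
    ms2 <- as_list(matrices2)
    if (length(ms2) != n) abort_field("paired mode requires matched pairs")
    ms <- purrr::map2(ms, ms2, `-`)
  }
  dims <- dim(ms[[1]])
  symmetric <- dims[1] == dims[2] &&
    all(vapply(ms, function(m) isTRUE(all.equal(m, t(m), tolerance = 1e-8)),
               logical(1)))
  idx <- tidyr::expand_grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
  if (symmetric) idx <- dplyr::filter(idx, .data$row <= .data$col)
  if (exclude_diag && dims[1] == dims[2]) {
    idx <- dplyr::filter(idx, .data$row != .data$col)
  }
  stack <- vapply(ms, function(m) m[cbind(idx$row, idx$col)],
                  numeric(nrow(idx)))
  if (is.null(dim(stack))) stack <- matrix(stack, nrow = 1L)
  mu <- rowMeans(stack)
  sdv <- apply(stack, 1, stats::sd)
  # degenerate elements (zero spread): t = 0 when the mean is 0 too
  tstat <- ifelse(sdv == 0, ifelse(mu == 0, 0, sign(mu) * Inf),
                  mu / (sdv / sqrt(n)))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- dplyr::mutate(idx, estimate = mu, t = tstat, p = p, q = q,
                       significant = q < q_threshold)
  structure(out, class = c("group_fc_test", class(out)),
            n_subjects = n, mode = mode, symmetric = symmetric)
}

#' @method glance group_fc_test
#' @export
glance.group_fc_test <- function(x, ...) {
  tibble::tibble(
    n_subjects = attr(x, "n_subjects"),
    mode = attr(x, "mode"),
    n_elements = nrow(x),
    n_significant = sum(x$significant),
    min_q = min(x$q)
  )
}

#' @method autoplot group_fc_test
#' @export
autoplot.group_fc_test <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$row, y = .data$col,
                                       fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(object, .data$significant),
                        shape = 4, size = 1) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "depth bin", y = "depth bin", fill = "t",
                  title = "Group test on depth FC elements (x = FDR-significant)") +
    ggplot2::theme_minimal()
}
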
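#' Predict Debye-Scherrer ring positions from a unit cell
#'
#' Enumerates all reflections with d >= `d_min` that survive the lattice
#' centering extinction rule, groups them by equal d-spacing and reports
#' one ring per group with its multiplicity. Ring positions are given both
#' as d (Angstrom) and as the scattering vector s = 4 pi sin(theta)/lambda
#' = 2 pi / d, in inverse nanometres (s = 20 pi / d for d in Angstrom) —
#' the axis convention of SAXS powder fingerprints.
#'
#' @param cell A [unit_cell()].
#' @param centering Centering extinction rule; defaults to the cell's own
#'   centering. `P` passes all; `I` requires h+k+l even; `F` requires
#'   h, k, l all of the same parity; `A`/`B`/`C` require k+l / h+l / h+k
#'   even; `H` requires -h+k+l divisible by 3.
#' @param d_min Smallest d enumerated, Angstrom (> 0).
#' @return Object of class `powder_fingerprint`: a tibble of peaks sorted
#'   ascending in s with columns `d_A`, `s_nm_inv`, `h`, `k`, `l`
#'   (representative), `multiplicity`.
#' @examples
#' fp <- enumerate_rings(unit_cell(10, 10, 10, lattice_type = "cubic"), d_min = 4)
#' @export
enumerate_rings <- function(cell, centering = NULL, d_min) {
  stopifnot(d_min > 0)
  if (is.null(centering)) centering <- cell$centering
  hmax <- floor(cell$a / d_min + 1e-9)
  kmax <- floor(cell$b / d_min + 1e-9)
  lmax <- floor(cell$c / d_min + 1e-9)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  keep <- switch(centering,
    P = rep(TRUE, nrow(g)),
    I = (g$h + g$k + g$l) %% 2 == 0,
    F = (g$h %% 2 == g$k %% 2) & (g$k %% 2 == g$l %% 2),
    A = (g$k + g$l) %% 2 == 0,
    B = (g$h + g$l) %% 2 == 0,
    C = (g$h + g$k) %% 2 == 0,
    H = (-g$h + g$k + g$l) %% 3 == 0,
    stop(sprintf("unknown centering rule '%s'", centering), call. = FALSE))
  g <- g[keep, ]
  g$d <- d_spacing(g$h, g$k, g$l, cell)
  g <- g[g$d >= d_min, ]
  g <- g[order(-g$d, g$h, g$k, g$l), ]
  # group reflections whose d agree within 1e-6 relative
  ring_id <- cumsum(c(TRUE, abs(diff(g$d)) / g$d[-nrow(g)] > 1e-6))
  peaks <- tibble(d = g$d, h = g$h, k = g$k, l = g$l, ring = ring_id) |>
    dplyr::arrange(.data$ring, dplyr::desc(.data$h), dplyr::desc(.data$k),
                   dplyr::desc(.data$l)) |>
    dplyr::group_by(.data$ring) |>
    dplyr::summarise(d_A = mean(.data$d),
                     h = dplyr::first(.data$h),
                     k = dplyr::first(.data$k),
                     l = dplyr::first(.data$l),
                     multiplicity = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(s_nm_inv = 20 * pi / .data$d_A) |>
    dplyr::arrange(.data$s_nm_inv) |>
    dplyr::select(dplyr::all_of(c("d_A", "s_nm_inv", "h", "k", "l",
                                  "multiplicity")))
  class(peaks) <- c("powder_fingerprint", class(peaks))
  peaks
}

#' Render a fingerprint as a continuous powder curve
#'
#' Sums one Gaussian per ring on a regular s grid; each peak's area is
#' proportional to multiplicity times the supplied weight (ring positions,
#' not structure-factor intensities, carry the fingerprint information).
#'
#' @param fingerprint A [enumerate_rings()] fingerprint.
#' @param peak_width Gaussian sigma in s units, nm^-1 (> 0).
#' @param weights Relative per-ring weights (default all 1).
#' @param s_grid Optional s grid; default spans the rings with margin.
#' @return Tibble: `s_nm_inv`, `intensity`.
#' @export
simulate_curve <- function(fingerprint, peak_width = 0.05, weights = NULL,
                           s_grid = NULL) {
  stopifnot(peak_width > 0)
  np <- nrow(fingerprint)
  if (is.null(weights)) weights <- rep(1, np)
  stopifnot(length(weights) == np)
  if (is.null(s_grid)) {
    lo <- max(0, min(fingerprint$s_nm_inv) - 6 * peak_width)
    hi <- max(fingerprint$s_nm_inv) + 6 * peak_width
    s_grid <- seq(lo, hi, length.out = 2000)
  }
  intensity <- rep(0, length(s_grid))
  for (i in seq_len(np)) {
    area <- fingerprint$multiplicity[i] * weights[i]
    intensity <- intensity + area *
      stats::dnorm(s_grid, fingerprint$s_nm_inv[i], peak_width)
  }
  tibble(s_nm_inv = s_grid, intensity = intensity)
}

#' Describe a 2D detector image for radial averaging
#'
#' @param data Numeric matrix of pixel intensities (rows = slow axis).
#' @param pixel_mm Pixel size in mm.
#' @param center_px Length-2 beam center (fast, slow), pixels.
#' @param distance_mm Sample-detector distance, mm.
#' @param wavelength_A X-ray wavelength, Angstrom.
#' @param mask Logical matrix, TRUE = masked (excluded); default none.
#' @return Object of class `detector_image`.
#' @export
detector_image <- function(data, pixel_mm, center_px, distance_mm,
                           wavelength_A, mask = NULL) {
  stopifnot(is.matrix(data), pixel_mm > 0, distance_mm > 0,
            wavelength_A > 0, length(center_px) == 2)
  if (center_px[1] < 1 || center_px[1] > ncol(data) ||
      center_px[2] < 1 || center_px[2] > nrow(data)) {
    stop("beam center lies outside the image", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(FALSE, nrow(data), ncol(data))
  stopifnot(identical(dim(mask), dim(data)))
  structure(list(data = data, pixel_mm = pixel_mm, center_px = center_px,
                 distance_mm = distance_mm, wavelength_A = wavelength_A,
                 mask = mask),
            class = "detector_image")
}

# scattering vector s (nm^-1) for a radius in pixels
s_of_radius <- function(r_px, image) {
  two_theta <- atan(r_px * image$pixel_mm / image$distance_mm)
  # s = 4 pi sin(theta) / lambda, lambda in nm
  4 * pi * sin(two_theta / 2) / (image$wavelength_A / 10)
}

# inverse: radius in pixels at which scattering vector s falls
radius_of_s <- function(s_nm_inv, image) {
  theta <- asin(s_nm_inv * (image$wavelength_A / 10) / (4 * pi))
  image$distance_mm * tan(2 * theta) / image$pixel_mm
}

#' Radially average a detector image to I(s)
#'
#' Computes each unmasked pixel's scattering vector s = 4 pi sin(theta)/
#' lambda from its radius, the detector distance and the wavelength, and
#' averages intensities in `n_bins` equal-width s bins.
#'
#' @param image A [detector_image()].
#' @param n_bins Number of s bins (default 200).
#' @return Tibble: `s_nm_inv` (bin centers), `intensity` (mean), `n_pixels`.
#' @export
radial_average <- function(image, n_bins = 200) {
  if (all(image$mask)) stop("all pixels are masked", call. = FALSE)
  nr <- nrow(image$data); nc <- ncol(image$data)
  fs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ss <- matrix(rep(seq_len(nr), nc), nr, nc)
  r <- sqrt((fs - image$center_px[1])^2 + (ss - image$center_px[2])^2)
  s <- s_of_radius(r, image)
  ok <- !image$mask
  s <- s[ok]; v <- image$data[ok]
  edges <- seq(0, max(s) + 1e-12, length.out = n_bins + 1)
  bin <- findInterval(s, edges, rightmost.closed = TRUE)
  bin <- pmin(bin, n_bins)
  sums <- tapply(v, bin, sum)
  ns <- tapply(v, bin, length)
  idx <- as.integer(names(sums))
  tibble(s_nm_inv = (edges[idx] + edges[idx + 1]) / 2,
         intensity = as.numeric(sums / ns),
         n_pixels = as.integer(ns))
}

# 2D moving-average with edge-aware normalisation (mean over pixels of the
# window that fall inside the image)
box_mean_2d <- function(m, window) {
  half <- (window - 1L) %/% 2L
  pad_sum <- function(x) {
    # running sum over rows then columns via cumsum on padded matrices
    cs <- function(v) {
      n <- length(v)
      c0 <- cumsum(v)
      hi <- pmin(seq_len(n) + half, n)
      lo <- pmax(seq_len(n) - half, 1L)
      c0[hi] - c(0, c0)[lo]
    }
    y <- t(apply(x, 1, cs))   # smooth along rows (horizontal)
    apply(y, 2, cs)           # then along columns (vertical)
  }
  pad_sum(m) / pad_sum(matrix(1, nrow(m), ncol(m)))
}

#' Subtract a fraction of the moving-average background
#'
#' Estimates the background as the 2D moving average of the image over a
#' square window and subtracts `fraction` of it from each pixel, clipping
#' at zero — the standard treatment for making weak Debye-Scherrer rings
#' visible on powder images (90% subtraction by default). Masked pixels
#' are untouched.
#'
#' @param image A [detector_image()].
#' @param window_px Odd window size >= 3.
#' @param fraction Fraction of background to subtract, in [0, 1]
#'   (default 0.90).
#' @return A [detector_image()] with the corrected data.
#' @export
subtract_background_moving_average <- function(image, window_px = 21,
                                               fraction = 0.90) {
  stopifnot(window_px >= 3, window_px %% 2 == 1,
            fraction >= 0, fraction <= 1)
  bg <- box_mean_2d(image$data, as.integer(window_px))
  out <- pmax(image$data - fraction * bg, 0)
  out[image$mask] <- image$data[image$mask]
  image$data <- out
  image
}

#' Compare two powder fingerprints by peak positions
#'
#' Greedy nearest-neighbour matching of ring s positions within a
#' tolerance, each ring used at most once; the match fraction is
#' matched / max(n1, n2). This operationalises whether two crystal forms
#' give "the same" powder fingerprint.
#'
#' @param f1,f2 Fingerprints from [enumerate_rings()] (or any tibble with
#'   `s_nm_inv`).
#' @param s_tolerance Maximum |s1 - s2| for a match, nm^-1 (> 0).
#' @return List: `match_fraction`, `matched` (tibble `s1`, `s2`, `ds`),
#'   `unmatched1`, `unmatched2` (numeric vectors of s).
#' @export
compare_fingerprints <- function(f1, f2, s_tolerance = 0.05) {
  stopifnot(s_tolerance > 0)
  s1 <- f1$s_nm_inv; s2 <- f2$s_nm_inv
  if (!length(s1) || !length(s2)) {
    warning("empty fingerprint; match fraction 0", call. = FALSE)
    return(list(match_fraction = 0,
                matched = tibble(s1 = double(), s2 = double(),
                                 ds = double()),
                unmatched1 = s1, unmatched2 = s2))
  }
  pairs <- expand.grid(i = seq_along(s1), j = seq_along(s2))
  pairs$ds <- abs(s1[pairs$i] - s2[pairs$j])
  pairs <- pairs[pairs$ds <= s_tolerance, ]
  pairs <- pairs[order(pairs$ds), ]
  used1 <- logical(length(s1)); used2 <- logical(length(s2))
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE; keep[r] <- TRUE
    }
  }
  m <- pairs[keep, ]
  list(match_fraction = nrow(m) / max(length(s1), length(s2)),
       matched = tibble(s1 = s1[m$i], s2 = s2[m$j], ds = m$ds),
       unmatched1 = s1[!used1], unmatched2 = s2[!used2])
}

#' Pick curve maxima (peak positions) from a powder curve
#'
#' @param curve Tibble `s_nm_inv`, `intensity` (e.g. from
#'   [radial_average()]).
#' @param min_prominence Minimum height above the local baseline, as a
#'   fraction of the curve maximum (default 0.05).
#' @return Numeric vector of peak s positions.
#' @export
find_curve_peaks <- function(curve, min_prominence = 0.05) {
  v <- curve$intensity
  n <- length(v)
  if (n < 3) return(numeric())
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
              FALSE)
  thr <- min(v) + min_prominence * (max(v) - min(v))
  curve$s_nm_inv[is_max & v > thr]
}
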
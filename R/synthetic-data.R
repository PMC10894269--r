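#' Simulate a helical line-scan serial dataset with known ground truth
#'
#' Generates a stream dataset emulating fixed-target serial collection:
#' crystals are placed at random, non-overlapping footprints of 3-15
#' frames within single scan lines; per-frame spot counts are a Gaussian
#' bump per crystal (peak height 30-200) on a Poisson background (mean 2);
#' frames under a footprint carry an indexed crystal with a random (fixed
#' per crystal, optionally frame-perturbed) orientation and reflections
#' drawn from a log-normal true intensity table (sdlog 1) with
#' multiplicative Gaussian noise and a per-crystal scale log-uniform in
#' [0.5, 2]. Every random element is a pure function of `seed`.
#'
#' @param geometry A [scan_geometry()].
#' @param n_crystals Number of crystals to place (>= 0).
#' @param cell A [unit_cell()] shared by all crystals.
#' @param pg A [point_group()] used to build the true intensity table and
#'   to emit symmetry-equivalent observation indices.
#' @param noise_fraction Multiplicative Gaussian noise sigma as a fraction
#'   of the true intensity (0 = noise-free).
#' @param seed Integer seed.
#' @param d_min Resolution cutoff of the true intensity table, Angstrom.
#' @param obs_fraction Fraction of the truth table observed per frame.
#' @param perturb_orientation If TRUE, each frame's orientation is rotated
#'   by < 1 degree about a random axis relative to the crystal's.
#' @return List: `dataset` (a [stream_dataset()]) and `truth` (list with
#'   `seed`, `crystals` tibble, `orientations`, `intensities` tibble,
#'   `scales`).
#' @export
simulate_scan <- function(geometry, n_crystals, cell, pg,
                          noise_fraction = 0.01, seed = 1, d_min = 3,
                          obs_fraction = 0.3,
                          perturb_orientation = FALSE) {
  stopifnot(n_crystals >= 0, noise_fraction >= 0)
  set.seed(seed)
  fpl <- geometry$frames_per_line
  n_frames <- fpl * geometry$n_lines
  truth_int <- enumerate_asu(pg, cell, d_min)
  truth_int$intensity_true <- stats::rlnorm(nrow(truth_int),
                                            meanlog = log(1000), sdlog = 1)
  counts <- stats::rpois(n_frames, 2)
  occupied <- rep(FALSE, n_frames)
  crystals <- list()
  for (ci in seq_len(n_crystals)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      len <- sample(3:15, 1)
      if (len > fpl) next
      line <- sample(seq_len(geometry$n_lines), 1) - 1L
      start_in_line <- sample(seq_len(fpl - len + 1), 1) - 1L
      s <- line * fpl + start_in_line
      e <- s + len - 1L
      # reserve a 2-frame background margin around each footprint so
      # neighbouring crystals stay resolvable as separate bumps
      ms <- max(line * fpl, s - 2L); me <- min((line + 1L) * fpl - 1L, e + 2L)
      if (any(occupied[(ms + 1L):(me + 1L)])) next
      occupied[(ms + 1L):(me + 1L)] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place a crystal footprint after 1000 attempts",
           call. = FALSE)
    }
    ctr <- s + (len - 1L) %/% 2L
    peak <- stats::runif(1, 30, 200)
    scale <- exp(stats::runif(1, log(0.5), log(2)))
    crystals[[ci]] <- list(
      id = ci, line = line, start_frame = s, end_frame = e,
      center_frame = ctr, n_frames = len, peak_count = peak,
      scale = scale, orientation = orientation_matrix(cell,
                                                      random_rotation()),
      resolution_limit = stats::runif(1, d_min * 0.7, d_min * 1.6))
  }
  # spot-count bumps
  for (cr in crystals) {
    frames <- cr$start_frame:cr$end_frame
    sigma_b <- cr$n_frames / 4
    bump <- cr$peak_count * exp(-(frames - cr$center_frame)^2 /
                                  (2 * sigma_b^2))
    counts[frames + 1L] <- counts[frames + 1L] + round(bump)
  }
  frame_owner <- rep(NA_integer_, n_frames)
  for (cr in crystals) {
    frame_owner[(cr$start_frame + 1L):(cr$end_frame + 1L)] <- cr$id
  }
  n_ops <- length(pg$ops)
  chunks <- lapply(seq_len(n_frames) - 1L, function(f) {
    owner <- frame_owner[f + 1L]
    crys <- list()
    if (!is.na(owner)) {
      cr <- crystals[[owner]]
      n_obs <- max(3L, round(obs_fraction * nrow(truth_int)))
      pick <- sample.int(nrow(truth_int), n_obs)
      ops <- pg$ops[sample.int(n_ops, n_obs, replace = TRUE)]
      hkl <- t(vapply(seq_len(n_obs), function(i) {
        as.integer(ops[[i]] %*% c(truth_int$h[pick[i]],
                                  truth_int$k[pick[i]],
                                  truth_int$l[pick[i]]))
      }, integer(3)))
      itrue <- truth_int$intensity_true[pick]
      iobs <- itrue * cr$scale *
        (1 + noise_fraction * stats::rnorm(n_obs))
      sig <- pmax(noise_fraction, 0.01) * itrue * cr$scale
      orient <- cr$orientation
      if (perturb_orientation) {
        orient <- orient %*%
          t(rotation_about(stats::rnorm(3), stats::runif(1, 0, 1)))
      }
      refl <- tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                     intensity = iobs, sigma = sig, peak = iobs,
                     background = round(stats::runif(n_obs, 5, 15), 2),
                     fs = round(stats::runif(n_obs, 0, 4000), 1),
                     ss = round(stats::runif(n_obs, 0, 4000), 1),
                     panel = "p0")
      crys <- list(crystal_record(cell, orientation = orient,
                                  resolution_limit =
                                    round(cr$resolution_limit, 4),
                                  reflections = refl))
    }
    stream_chunk(frame_index = f,
                 image_id = sprintf("scan_%05d.h5", f),
                 event_id = sprintf("//%d", f),
                 n_peaks = counts[f + 1L], crystals = crys)
  })
  truth_crystals <- dplyr::bind_rows(lapply(crystals, function(cr) {
    tibble(id = cr$id, line = cr$line, start_frame = cr$start_frame,
           center_frame = cr$center_frame, end_frame = cr$end_frame,
           n_frames = cr$n_frames, peak_count = cr$peak_count,
           scale = cr$scale, resolution_limit = cr$resolution_limit)
  }))
  list(dataset = stream_dataset(chunks = chunks),
       truth = list(seed = seed, crystals = truth_crystals,
                    orientations = lapply(crystals, `[[`, "orientation"),
                    intensities = truth_int,
                    scales = vapply(crystals, `[[`, numeric(1), "scale")))
}

#' Inject salt powder-ring outliers into a dataset
#'
#' Adds `n_per_band` artificially bright reflections per resolution band to
#' randomly chosen crystals, with peak value `intensity_multiplier` times
#' the dataset's 99th peak-intensity percentile, and records the injected
#' outliers exactly (the ground truth for [filter_salt()] validation).
#'
#' @param dataset A [stream_dataset()] with indexed crystals.
#' @param bands A [resolution_bands()] tibble (the `max_intensity` column
#'   is ignored here).
#' @param intensity_multiplier Outlier brightness relative to the 99th
#'   percentile (default 20).
#' @param n_per_band Outliers per band (default 3).
#' @param seed Integer seed.
#' @return List: `dataset` (with outliers added) and `outliers` (tibble
#'   `frame_index`, `crystal`, `h`, `k`, `l`, `d`, `peak`).
#' @export
inject_salt_rings <- function(dataset, bands, intensity_multiplier = 20,
                              n_per_band = 3, seed = 1) {
  set.seed(seed)
  if (n_per_band == 0) {
    return(list(dataset = dataset,
                outliers = tibble(frame_index = integer(),
                                  crystal = integer(), h = integer(),
                                  k = integer(), l = integer(),
                                  d = double(), peak = double())))
  }
  refl <- reflections_table(dataset)
  if (!nrow(refl)) stop("dataset has no reflections", call. = FALSE)
  q99 <- stats::quantile(refl$peak, 0.99, names = FALSE)
  target <- intensity_multiplier * q99
  indexed <- which(vapply(dataset$chunks,
                          function(ch) length(ch$crystals) > 0, logical(1)))
  outliers <- list()
  chunks <- dataset$chunks
  for (b in seq_len(nrow(bands))) {
    for (r in seq_len(n_per_band)) {
      ci <- sample(indexed, 1)
      cr <- chunks[[ci]]$crystals[[1]]
      cand <- hkl_in_band(cr$cell, bands$d_min[b], bands$d_max[b])
      if (!nrow(cand)) {
        stop(sprintf("no lattice points in band %.2f-%.2f A for this cell",
                     bands$d_min[b], bands$d_max[b]), call. = FALSE)
      }
      pick <- cand[sample.int(nrow(cand), 1), ]
      newr <- tibble(h = pick$h, k = pick$k, l = pick$l,
                     intensity = round(target, 2),
                     sigma = round(0.05 * target, 2),
                     peak = round(target, 2), background = 10,
                     fs = round(stats::runif(1, 0, 4000), 1),
                     ss = round(stats::runif(1, 0, 4000), 1), panel = "p0")
      cr$reflections <- dplyr::bind_rows(cr$reflections, newr)
      chunks[[ci]]$crystals[[1]] <- cr
      outliers[[length(outliers) + 1L]] <-
        tibble(frame_index = chunks[[ci]]$frame_index, crystal = 1L,
               h = pick$h, k = pick$k, l = pick$l, d = pick$d,
               peak = round(target, 2))
    }
  }
  list(dataset = stream_dataset(chunks = chunks, header = dataset$header),
       outliers = dplyr::bind_rows(outliers))
}

# lattice points of a cell with d in [d_min, d_max)
hkl_in_band <- function(cell, d_min, d_max) {
  hmax <- floor(cell$a / d_min + 1e-9)
  kmax <- floor(cell$b / d_min + 1e-9)
  lmax <- floor(cell$c / d_min + 1e-9)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  g$d <- d_spacing(g$h, g$k, g$l, cell)
  as_tibble(g[g$d >= d_min & g$d < d_max, ])
}

#' Simulate a powder-diffraction detector image
#'
#' Renders radially symmetric Gaussian annuli at the detector radii of a
#' fingerprint's rings, over a flat background, with Poisson noise. Rings
#' falling outside the detector are skipped with a warning.
#'
#' @param fingerprint A [enumerate_rings()] fingerprint (may be empty).
#' @param n_px Image size (square), pixels.
#' @param pixel_mm,distance_mm,wavelength_A Detector geometry, see
#'   [detector_image()].
#' @param ring_width_px Gaussian sigma of each annulus, pixels.
#' @param ring_amplitude Peak height of each annulus above background.
#' @param background Flat background level (default 10).
#' @param seed Integer seed.
#' @return A [detector_image()].
#' @export
simulate_powder_image <- function(fingerprint, n_px = 256, pixel_mm = 0.5,
                                  distance_mm = 300, wavelength_A = 1.0,
                                  ring_width_px = 2, ring_amplitude = 200,
                                  background = 10, seed = 1) {
  set.seed(seed)
  center <- c((n_px + 1) / 2, (n_px + 1) / 2)
  img <- detector_image(matrix(background, n_px, n_px), pixel_mm, center,
                        distance_mm, wavelength_A)
  fs <- matrix(rep(seq_len(n_px), each = n_px), n_px, n_px)
  ss <- matrix(rep(seq_len(n_px), n_px), n_px, n_px)
  r <- sqrt((fs - center[1])^2 + (ss - center[2])^2)
  m <- img$data
  max_r <- min(center[1] - 1, n_px - center[1])
  for (i in seq_len(nrow(fingerprint))) {
    r0 <- radius_of_s(fingerprint$s_nm_inv[i], img)
    if (!is.finite(r0) || r0 > max_r) {
      warning(sprintf("ring at s = %.3f nm^-1 falls outside the detector; skipped",
                      fingerprint$s_nm_inv[i]), call. = FALSE)
      next
    }
    m <- m + ring_amplitude * exp(-(r - r0)^2 / (2 * ring_width_px^2))
  }
  img$data <- matrix(stats::rpois(length(m), as.vector(m)), n_px, n_px)
  img
}

#' Simulate an endpoint-dilution titer plate from a known titer
#'
#' Infection events per well are Poisson with mean
#' `0.69 * titer * inoculum_ml * 10^dilution` (0.69 = ln 2 converting a
#' TCID50 titer to infectious units); each event grows into a cluster of
#' at least two fluorescent cells, so the ">= 2 fluorescent cells" scoring
#' rule marks exactly the wells with at least one infection event.
#'
#' @param true_titer_per_ml Ground-truth titer, TCID50 per mL (> 0).
#' @param dilution_log10 Row dilutions (default -2 .. -9).
#' @param wells Wells per dilution (default 6).
#' @param inoculum_ml Inoculum per well, mL (default 0.02).
#' @param seed Integer seed.
#' @return A [titer_plate()]; the truth is attached as attribute
#'   `true_titer_per_ml`, the raw per-well fluorescent counts as
#'   attribute `well_counts`.
#' @export
simulate_plate <- function(true_titer_per_ml, dilution_log10 = -(2:9),
                           wells = 6, inoculum_ml = 0.02, seed = 1) {
  stopifnot(true_titer_per_ml > 0)
  set.seed(seed)
  counts <- lapply(dilution_log10, function(x) {
    lambda <- 0.69 * true_titer_per_ml * inoculum_ml * 10^x
    events <- stats::rpois(wells, lambda)
    vapply(events, function(ev) {
      # each infection event renders as a cluster of >= 2 fluorescent
      # cells; saturated wells are capped (the score only needs >= 2)
      ev <- min(ev, 1e4)
      if (ev == 0) 0L else sum(2L + stats::rpois(ev, 8))
    }, integer(1))
  })
  positives <- score_wells(counts, threshold = 2)
  plate <- titer_plate(dilution_log10, positives, wells = wells,
                       inoculum_ml = inoculum_ml)
  attr(plate, "true_titer_per_ml") <- true_titer_per_ml
  attr(plate, "well_counts") <- counts
  plate
}
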
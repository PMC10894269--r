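#' Define resolution bands for salt-ring filtering
#'
#' Each band is a half-open d interval `[d_min, d_max)` with a maximum
#' allowed reflection intensity; reflections inside the band above the
#' threshold are treated as salt powder-ring contamination. Half-open
#' intervals let adjacent bands partition cleanly.
#'
#' @param d_min,d_max Band limits in Angstrom, `0 < d_min < d_max`
#'   (vectorised: one band per element).
#' @param max_intensity Intensity ceiling per band, detector units.
#' @return Tibble of class `resolution_bands`.
#' @export
resolution_bands <- function(d_min, d_max, max_intensity) {
  stopifnot(length(d_min) == length(d_max),
            length(d_min) == length(max_intensity),
            all(d_min > 0), all(d_min < d_max))
  b <- tibble(d_min = d_min, d_max = d_max, max_intensity = max_intensity)
  b <- dplyr::arrange(b, .data$d_min)
  if (nrow(b) > 1 &&
      any(b$d_max[-nrow(b)] > b$d_min[-1] + 1e-12)) {
    stop("resolution bands must not overlap", call. = FALSE)
  }
  class(b) <- c("resolution_bands", class(b))
  b
}

#' Build a peakogram from a stream dataset
#'
#' A 2D histogram of reflection resolution (1/d, inverse Angstrom, from each
#' reflection's own crystal cell) against log10 peak intensity. Used to
#' choose resolution-dependent intensity thresholds for salt-ring removal
#' and to confirm the powder signal is gone after filtering. Reflections
#' with non-positive peak values are excluded and counted separately.
#'
#' @param dataset A [stream_dataset()] with indexed crystals.
#' @param n_bins Length-2 integer vector: bins in (1/d, log10 intensity).
#' @param value Which intensity to histogram: `"peak"` (default, the
#'   maximum pixel value of a reflection) or `"intensity"` (integrated).
#' @return Object of class `peakogram`: `counts` matrix
#'   (resolution x intensity), `invd_edges`, `logi_edges`, `n_excluded`,
#'   and `data` (the per-reflection tibble with `invd` and `logi`).
#' @export
peakogram <- function(dataset, n_bins = c(50, 50),
                      value = c("peak", "intensity")) {
  value <- match.arg(value)
  refl <- reflections_with_d(dataset)
  refl$value <- refl[[value]]
  n_excluded <- sum(refl$value <= 0)
  refl <- refl[refl$value > 0, ]
  if (!nrow(refl)) {
    return(structure(list(counts = matrix(0, 0, 0), invd_edges = numeric(),
                          logi_edges = numeric(), n_excluded = n_excluded,
                          data = refl), class = "peakogram"))
  }
  refl$invd <- 1 / refl$d
  refl$logi <- log10(refl$value)
  xe <- seq(min(refl$invd), max(refl$invd), length.out = n_bins[1] + 1)
  ye <- seq(min(refl$logi), max(refl$logi), length.out = n_bins[2] + 1)
  # widen the top edges so max values fall in the last bin
  xe[length(xe)] <- xe[length(xe)] + 1e-9
  ye[length(ye)] <- ye[length(ye)] + 1e-9
  xi <- findInterval(refl$invd, xe, rightmost.closed = FALSE)
  yi <- findInterval(refl$logi, ye, rightmost.closed = FALSE)
  counts <- matrix(0L, n_bins[1], n_bins[2])
  for (r in seq_len(nrow(refl))) {
    counts[xi[r], yi[r]] <- counts[xi[r], yi[r]] + 1L
  }
  structure(list(counts = counts, invd_edges = xe, logi_edges = ye,
                 n_excluded = n_excluded, data = refl),
            class = "peakogram")
}

#' @export
print.peakogram <- function(x, ...) {
  cat(sprintf("<peakogram> %d reflections in %d x %d bins (%d non-positive excluded)\n",
              sum(x$counts), nrow(x$counts), ncol(x$counts), x$n_excluded))
  invisible(x)
}

# flat reflections table with per-reflection d from its crystal's cell
reflections_with_d <- function(dataset) {
  refl <- reflections_table(dataset)
  if (!nrow(refl)) {
    refl$d <- double()
    return(refl)
  }
  cells <- crystals_table(dataset)
  refl <- dplyr::left_join(refl, cells[c("crystal_id", "a", "b", "c",
                                         "alpha", "beta", "gamma")],
                           by = "crystal_id")
  refl |>
    dplyr::group_by(.data$crystal_id) |>
    dplyr::group_modify(function(g, key) {
      cell <- unit_cell(g$a[1], g$b[1], g$c[1], g$alpha[1], g$beta[1],
                        g$gamma[1])
      g$d <- d_spacing(g$h, g$k, g$l, cell)
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(c("a", "b", "c", "alpha", "beta", "gamma")))
}

#' Remove salt powder-ring reflections by resolution-dependent thresholds
#'
#' A reflection is removed iff its d-spacing lies in one of the supplied
#' bands and its peak value (or integrated intensity) exceeds that band's
#' ceiling. Crystals and chunks are retained even if emptied; retained
#' reflection values are never altered.
#'
#' @param dataset A [stream_dataset()].
#' @param bands A [resolution_bands()] tibble (non-overlapping).
#' @param value Filter on `"peak"` (default) or `"intensity"`.
#' @return List: `dataset` (filtered copy), `report` (tibble with one row
#'   per band: `d_min`, `d_max`, `max_intensity`, `n_removed`), and
#'   `removed` (tibble of the removed reflections with their origin).
#' @export
filter_salt <- function(dataset, bands, value = c("peak", "intensity")) {
  value <- match.arg(value)
  if (!inherits(bands, "resolution_bands")) {
    bands <- resolution_bands(bands$d_min, bands$d_max, bands$max_intensity)
  }
  n_removed <- rep(0L, nrow(bands))
  removed <- list()
  chunks <- lapply(dataset$chunks, function(ch) {
    ch$crystals <- lapply(ch$crystals, function(cr) {
      r <- cr$reflections
      if (!nrow(r)) return(cr)
      d <- d_spacing(r$h, r$k, r$l, cr$cell)
      v <- r[[value]]
      drop <- rep(FALSE, nrow(r))
      for (b in seq_len(nrow(bands))) {
        hit <- d >= bands$d_min[b] & d < bands$d_max[b] &
          v > bands$max_intensity[b]
        n_removed[b] <<- n_removed[b] + sum(hit)
        drop <- drop | hit
      }
      if (any(drop)) {
        removed[[length(removed) + 1L]] <<- dplyr::bind_cols(
          tibble(frame_index = ch$frame_index, d = d[drop]), r[drop, ])
        cr$reflections <- r[!drop, ]
      }
      cr
    })
    ch
  })
  report <- dplyr::bind_cols(as_tibble(bands), tibble(n_removed = n_removed))
  list(dataset = stream_dataset(chunks = chunks, header = dataset$header),
       report = report,
       removed = if (length(removed)) dplyr::bind_rows(removed) else
         dplyr::bind_cols(tibble(frame_index = integer(), d = double()),
                          reflection_table()))
}

#' Suggest a salt-filter threshold from the peakogram
#'
#' Returns the q-th quantile of reflection intensity within a resolution
#' band, as a starting point for a band ceiling; final thresholds are
#' normally picked by eye off the peakogram.
#'
#' @param dataset A [stream_dataset()].
#' @param d_min,d_max Band limits in Angstrom.
#' @param q Quantile (default 0.999).
#' @param value `"peak"` or `"intensity"`.
#' @return Suggested ceiling (numeric), or `NA` if the band is empty.
#' @export
suggest_threshold <- function(dataset, d_min, d_max, q = 0.999,
                              value = c("peak", "intensity")) {
  value <- match.arg(value)
  refl <- reflections_with_d(dataset)
  v <- refl[[value]][refl$d >= d_min & refl$d < d_max]
  if (!length(v)) return(NA_real_)
  unname(stats::quantile(v, q))
}

#' Estimate a crystal's resolution limit from signal-to-noise falloff
#'
#' Bins the crystal's reflections into shells of constant width in 1/d and
#' walks from low resolution, keeping contiguous shells whose mean
#' intensity/sigma stays at or above the cutoff; the limit is the center d
#' of the last kept shell.
#'
#' @param crystal A [crystal_record()] with reflections carrying
#'   `sigma > 0`.
#' @param snr_cutoff Mean I/sigma threshold per shell (default 1.0).
#' @param shell_width Shell width in 1/d, inverse Angstrom (default 0.05).
#' @return Resolution limit in Angstrom, or `NA` (with a warning) when no
#'   shell reaches the cutoff.
#' @export
estimate_resolution_limit <- function(crystal, snr_cutoff = 1.0,
                                      shell_width = 0.05) {
  r <- crystal$reflections
  r <- r[r$sigma > 0, ]
  if (!nrow(r)) {
    stop("crystal has no reflections with sigma > 0", call. = FALSE)
  }
  invd <- 1 / d_spacing(r$h, r$k, r$l, crystal$cell)
  shell <- floor(invd / shell_width)
  snr <- tapply(r$intensity / r$sigma, shell, mean)
  keys <- sort(as.numeric(names(snr)))
  last_ok <- NA_real_
  for (kk in keys) {
    if (snr[as.character(kk)] >= snr_cutoff) last_ok <- kk else break
  }
  if (is.na(last_ok)) {
    warning("no shell reaches the signal-to-noise cutoff; limit undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 / ((last_ok + 0.5) * shell_width)
}
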
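#' Observation table for merging
#'
#' Collects every reflection observation of a dataset, maps indices to the
#' asymmetric unit and tags each with its crystal and half-dataset
#' assignment (by parity of the chunk's frame index).
#'
#' @param dataset A [stream_dataset()].
#' @param pg A [point_group()].
#' @return Tibble: `crystal_id`, `frame_index`, `half` (1 or 2), asu
#'   `h`, `k`, `l`, `intensity`, `sigma`.
#' @export
observations <- function(dataset, pg) {
  refl <- reflections_table(dataset)
  if (!nrow(refl)) {
    return(tibble(crystal_id = character(), frame_index = integer(),
                  half = integer(), h = integer(), k = integer(),
                  l = integer(), intensity = double(), sigma = double()))
  }
  asu <- map_to_asu(refl$h, refl$k, refl$l, pg)
  tibble(crystal_id = refl$crystal_id, frame_index = refl$frame_index,
         half = as.integer(refl$frame_index %% 2L) + 1L,
         h = asu$h, k = asu$k, l = asu$l,
         intensity = refl$intensity, sigma = refl$sigma)
}

#' Determine per-crystal scale factors ("unity" partiality)
#'
#' Alternating Monte-Carlo scaling: merge with the current scales, then set
#' each crystal's scale to the least-squares ratio of its observations to
#' the consensus, s_j = sum(I_obs * Ibar) / sum(Ibar^2); scales are
#' normalised to mean 1 each round. Partiality is fixed at 1, matching the
#' "unity" model of serial merging. Iterates up to `n_rounds` or until the
#' maximum relative scale change drops below `tol`.
#'
#' @param dataset A [stream_dataset()].
#' @param pg A [point_group()].
#' @param n_rounds Maximum scaling rounds, 1 to 3 typical (default 3).
#' @param tol Convergence tolerance on relative scale change (default 1e-6).
#' @return Tibble: `crystal_id`, `scale`, `flagged` (TRUE when the crystal
#'   shares no reflection with any other crystal; its scale is left at 1).
#' @export
scale_crystals <- function(dataset, pg, n_rounds = 3, tol = 1e-6) {
  obs <- observations(dataset, pg)
  if (!nrow(obs)) {
    return(tibble(crystal_id = character(), scale = double(),
                  flagged = logical()))
  }
  obs$hkl <- paste(obs$h, obs$k, obs$l)
  cry <- sort(unique(obs$crystal_id))
  # a crystal is connected to the consensus when at least one of its hkls
  # is observed by some other crystal
  multi <- obs |>
    dplyr::distinct(.data$crystal_id, .data$hkl) |>
    dplyr::count(.data$hkl) |>
    dplyr::filter(.data$n > 1)
  connected <- obs |>
    dplyr::filter(.data$hkl %in% multi$hkl) |>
    dplyr::pull(.data$crystal_id) |>
    unique()
  flagged <- !(cry %in% connected)
  scales <- stats::setNames(rep(1, length(cry)), cry)
  if (length(cry) > 1 && any(!flagged)) {
    for (round in seq_len(n_rounds)) {
      # merged consensus under current scales
      obs$scaled <- obs$intensity / scales[obs$crystal_id]
      cons <- obs |>
        dplyr::group_by(.data$hkl) |>
        dplyr::summarise(ibar = mean(.data$scaled), .groups = "drop")
      obs$ibar <- cons$ibar[match(obs$hkl, cons$hkl)]
      new_s <- obs |>
        dplyr::group_by(.data$crystal_id) |>
        dplyr::summarise(
          s = sum(.data$intensity * .data$ibar) / sum(.data$ibar^2),
          .groups = "drop")
      s <- stats::setNames(new_s$s, new_s$crystal_id)[cry]
      s[flagged] <- NA
      s <- s / mean(s, na.rm = TRUE)
      s[flagged] <- 1
      delta <- max(abs(s - scales) / pmax(abs(scales), 1e-12))
      scales <- s
      if (delta < tol) break
    }
  }
  tibble(crystal_id = cry, scale = unname(scales), flagged = flagged)
}

#' Monte-Carlo merge of scaled observations
#'
#' Per asymmetric-unit reflection: merged intensity is the mean of the
#' scaled observations I_obs / s_j; the merged sigma is the sample standard
#' deviation over sqrt(n) for n >= 2, falling back to the single
#' observation's scaled sigma for n = 1.
#'
#' @param dataset A [stream_dataset()].
#' @param pg A [point_group()].
#' @param scales Tibble from [scale_crystals()], or `NULL` for unit scales.
#' @return Tibble of merged reflections: `h`, `k`, `l` (asu), `intensity`,
#'   `sigma`, `n_obs`.
#' @export
merge_reflections <- function(dataset, pg, scales = NULL) {
  obs <- observations(dataset, pg)
  merge_observations(obs, scales)
}

# merge an observation tibble (asu-mapped) under scales
merge_observations <- function(obs, scales = NULL) {
  if (!nrow(obs)) {
    return(tibble(h = integer(), k = integer(), l = integer(),
                  intensity = double(), sigma = double(), n_obs = integer()))
  }
  s <- if (is.null(scales)) {
    stats::setNames(rep(1, length(unique(obs$crystal_id))),
                    unique(obs$crystal_id))
  } else stats::setNames(scales$scale, scales$crystal_id)
  obs$scaled <- obs$intensity / unname(s[obs$crystal_id])
  obs$scaled_sigma <- obs$sigma / unname(s[obs$crystal_id])
  obs |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(
      intensity = mean(.data$scaled),
      sigma = if (dplyr::n() >= 2) {
        stats::sd(.data$scaled) / sqrt(dplyr::n())
      } else .data$scaled_sigma[1],
      n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$h), dplyr::desc(.data$k),
                   dplyr::desc(.data$l))
}

#' Merge the two half-datasets
#'
#' Observations are assigned to halves by the parity of their chunk's frame
#' index and merged independently; the halves feed [rsplit()] and
#' [cc_half()].
#'
#' @inheritParams merge_reflections
#' @return List of two merged tibbles, `half1` and `half2`.
#' @export
merge_halves <- function(dataset, pg, scales = NULL) {
  obs <- observations(dataset, pg)
  list(half1 = merge_observations(obs[obs$half == 1L, ], scales),
       half2 = merge_observations(obs[obs$half == 2L, ], scales))
}

#' Rsplit between two merged half-datasets
#'
#' Rsplit = 2^(-1/2) * sum|I1 - I2| / (0.5 * sum(I1 + I2)) over the common
#' reflections; the standard precision metric for Monte-Carlo-merged serial
#' data.
#'
#' @param half1,half2 Merged tibbles (columns `h`, `k`, `l`, `intensity`).
#' @return Dimensionless Rsplit; `NA` with a warning when the denominator
#'   is zero.
#' @export
rsplit <- function(half1, half2) {
  j <- dplyr::inner_join(half1, half2, by = c("h", "k", "l"),
                         suffix = c("1", "2"))
  if (!nrow(j)) stop("no common reflections between halves", call. = FALSE)
  denom <- 0.5 * sum(j$intensity1 + j$intensity2)
  if (denom == 0) {
    warning("Rsplit undefined: zero intensity sum", call. = FALSE)
    return(NA_real_)
  }
  sum(abs(j$intensity1 - j$intensity2)) / denom / sqrt(2)
}

#' CC1/2 between two merged half-datasets
#'
#' Pearson correlation of the common merged intensities of the two halves.
#'
#' @inheritParams rsplit
#' @return Correlation coefficient; `NA` with a warning when either half
#'   has zero variance.
#' @export
cc_half <- function(half1, half2) {
  j <- dplyr::inner_join(half1, half2, by = c("h", "k", "l"),
                         suffix = c("1", "2"))
  if (nrow(j) < 3) stop("need >= 3 common reflections", call. = FALSE)
  if (stats::var(j$intensity1) == 0 || stats::var(j$intensity2) == 0) {
    warning("CC1/2 undefined: zero variance in a half", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(j$intensity1, j$intensity2)
}

# enumerate all asu hkl with d >= d_min (brute-force box bounded by the
# real axis lengths over d_min)
enumerate_asu <- function(pg, cell, d_min) {
  hmax <- floor(cell$a / d_min + 1e-9)
  kmax <- floor(cell$b / d_min + 1e-9)
  lmax <- floor(cell$c / d_min + 1e-9)
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  d <- d_spacing(grid$h, grid$k, grid$l, cell)
  grid <- grid[d >= d_min, ]
  asu <- map_to_asu(grid$h, grid$k, grid$l, pg)
  dplyr::distinct(asu)
}

#' Completeness and redundancy of a merged dataset
#'
#' Completeness is the percentage of all possible unique asymmetric-unit
#' reflections with d >= `d_min` (enumerated by brute force over an index
#' box bounded by the cell axes over `d_min`) that are observed; redundancy
#' is total observations over unique observed.
#'
#' @param merged Merged tibble from [merge_reflections()].
#' @param pg A [point_group()].
#' @param cell A [unit_cell()].
#' @param d_min High-resolution cutoff in Angstrom.
#' @return Tibble: `completeness_pct`, `redundancy`, `n_unique_observed`,
#'   `n_possible`.
#' @export
completeness <- function(merged, pg, cell, d_min) {
  stopifnot(d_min > 0)
  possible <- enumerate_asu(pg, cell, d_min)
  if (nrow(merged)) {
    obs_d <- d_spacing(merged$h, merged$k, merged$l, cell)
    obs <- merged[obs_d >= d_min, ]
  } else {
    obs <- merged
  }
  n_obs_unique <- nrow(dplyr::distinct(obs[c("h", "k", "l")]))
  tibble(
    completeness_pct = 100 * n_obs_unique / nrow(possible),
    redundancy = if (n_obs_unique) sum(obs$n_obs) / n_obs_unique else NA_real_,
    n_unique_observed = n_obs_unique,
    n_possible = nrow(possible))
}

#' Per-shell figures of merit
#'
#' Divides resolution into `n_shells` equal-volume shells (linear in
#' 1/d^3 between the lowest-resolution observation and `d_min`) and
#' reports, per shell and overall: unique reflections, completeness,
#' redundancy, mean I/sigma, Rsplit and CC1/2 (half datasets by chunk
#' parity).
#'
#' @param dataset A [stream_dataset()].
#' @param pg A [point_group()].
#' @param cell A [unit_cell()] (reference cell for d and the possible-hkl
#'   enumeration).
#' @param n_shells Number of shells (>= 1).
#' @param d_min High-resolution cutoff, Angstrom.
#' @param scales Optional [scale_crystals()] output.
#' @return Object of class `shell_table`: tibble with one row per shell
#'   plus an `overall` row.
#' @export
shell_stats <- function(dataset, pg, cell, n_shells = 10, d_min,
                        scales = NULL) {
  stopifnot(n_shells >= 1, d_min > 0)
  obs <- observations(dataset, pg)
  obs$d <- d_spacing(obs$h, obs$k, obs$l, cell)
  obs <- obs[obs$d >= d_min, ]
  if (!nrow(obs)) stop("no observations at or below d_min", call. = FALSE)
  d_max <- max(obs$d)
  s3 <- seq((1 / d_max)^3, (1 / d_min)^3, length.out = n_shells + 1)
  edges_d <- 1 / s3^(1 / 3)          # descending d
  edges_d[1] <- edges_d[1] + 1e-9
  possible <- enumerate_asu(pg, cell, d_min)
  possible$d <- d_spacing(possible$h, possible$k, possible$l, cell)
  shell_of <- function(d) {
    pmin(pmax(findInterval(-d, -edges_d), 1L), n_shells)
  }
  obs$shell <- shell_of(obs$d)
  possible_in <- possible[possible$d <= edges_d[1], ]
  possible_in$shell <- shell_of(possible_in$d)
  one_shell <- function(o, n_possible) {
    merged <- merge_observations(o, scales)
    h1 <- merge_observations(o[o$half == 1L, ], scales)
    h2 <- merge_observations(o[o$half == 2L, ], scales)
    both <- nrow(h1) && nrow(h2)
    common <- if (both) {
      nrow(dplyr::inner_join(h1, h2, by = c("h", "k", "l")))
    } else 0
    tibble(
      n_unique = nrow(merged),
      completeness_pct = 100 * nrow(merged) / n_possible,
      redundancy = sum(merged$n_obs) / nrow(merged),
      mean_i_over_sigma = mean(merged$intensity / merged$sigma,
                               na.rm = TRUE),
      rsplit = if (common >= 1) rsplit(h1, h2) else NA_real_,
      cc_half = if (common >= 3) suppressWarnings(cc_half(h1, h2)) else
        NA_real_)
  }
  rows <- lapply(seq_len(n_shells), function(sh) {
    o <- obs[obs$shell == sh, ]
    npos <- sum(possible_in$shell == sh)
    lim <- tibble(shell = as.character(sh),
                  d_max = edges_d[sh], d_min = edges_d[sh + 1])
    if (!nrow(o) || npos == 0) {
      return(dplyr::bind_cols(lim, tibble(
        n_unique = 0L, completeness_pct = if (npos) 0 else NA_real_,
        redundancy = NA_real_, mean_i_over_sigma = NA_real_,
        rsplit = NA_real_, cc_half = NA_real_, empty = TRUE)))
    }
    dplyr::bind_cols(lim, one_shell(o, npos), tibble(empty = FALSE))
  })
  overall <- dplyr::bind_cols(
    tibble(shell = "overall", d_max = edges_d[1], d_min = d_min),
    one_shell(obs, nrow(possible)), tibble(empty = FALSE))
  out <- dplyr::bind_rows(c(rows, list(overall)))
  class(out) <- c("shell_table", class(out))
  out
}

#' Diffraction power across contiguous slices of a dataset
#'
#' Splits the stream into `n_parts` contiguous equal-chunk parts (as in
#' monitoring whether diffraction decays over hours of data collection) and
#' reports each part's mean and best per-crystal resolution limit.
#'
#' @param dataset A [stream_dataset()] whose crystals carry
#'   `resolution_limit`.
#' @param n_parts Number of parts (default 4).
#' @return Tibble: `part`, `n_chunks`, `n_crystals`, `mean_resolution_A`
#'   (arithmetic mean of per-crystal limits), `best_resolution_A`
#'   (minimum). Parts without crystals are flagged via `empty`.
#' @export
diffraction_power_slices <- function(dataset, n_parts = 4) {
  parts <- split_into_parts(dataset, n_parts)
  purrr::imap(parts, function(p, i) {
    lims <- unlist(lapply(p$chunks, function(ch) {
      vapply(ch$crystals, function(cr) cr$resolution_limit, numeric(1))
    }))
    tibble(part = i, n_chunks = n_chunks(p),
           n_crystals = length(lims),
           mean_resolution_A = if (length(lims)) mean(lims) else NA_real_,
           best_resolution_A = if (length(lims)) min(lims) else NA_real_,
           empty = !length(lims))
  }) |> dplyr::bind_rows()
}

#' Write merged reflections as a text hkl table
#'
#' @param merged Tibble from [merge_reflections()].
#' @param path Output path, or `NULL` to return lines.
#' @return Invisibly, the lines written (columns h k l I sigma n).
#' @export
write_hkl <- function(merged, path = NULL) {
  lines <- c("   h    k    l           I       sigma  n",
             sprintf("%4d %4d %4d %11.3f %11.3f %3d",
                     merged$h, merged$k, merged$l, merged$intensity,
                     merged$sigma, merged$n_obs))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
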
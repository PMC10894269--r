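#' Describe a serpentine helical line-scan geometry
#'
#' Fixed-target serial collection translates the sample along lines while
#' the goniometer rotates continuously; at the end of each line the mesh is
#' translated sideways and both the translation and rotation directions are
#' inverted.
#'
#' @param frames_per_line Frames collected along one line (> 0).
#' @param n_lines Number of scan lines (> 0).
#' @param rot_per_frame Magnitude of goniometer rotation per frame, degrees.
#' @param serpentine Whether direction inverts on odd lines (default TRUE).
#' @param h_step,v_step Spacing between adjacent frames within a line and
#'   between lines, micrometres (used by spatial overlap tests).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(frames_per_line, n_lines, rot_per_frame = 0.1,
                          serpentine = TRUE, h_step = 10, v_step = 10) {
  stopifnot(frames_per_line >= 1, n_lines >= 1, rot_per_frame > 0,
            h_step > 0, v_step > 0)
  structure(list(frames_per_line = as.integer(frames_per_line),
                 n_lines = as.integer(n_lines),
                 rot_per_frame = rot_per_frame,
                 serpentine = isTRUE(serpentine),
                 h_step = h_step, v_step = v_step),
            class = "scan_geometry")
}

#' Map a global frame index to its scan position
#'
#' @param frame_index 0-based global frame index (vectorised).
#' @param geometry A [scan_geometry()].
#' @return Tibble with `frame`, `line`, `index_in_line` (acquisition order
#'   within the line), `position_in_line` (spatial position: counted from
#'   the same end on every line), `rotation_deg` (resets to 0 at each line
#'   start; accumulates +rot on even lines, -rot on odd lines when
#'   serpentine), `x_um`, `y_um`.
#' @export
frame_to_position <- function(frame_index, geometry) {
  total <- geometry$frames_per_line * geometry$n_lines
  if (any(frame_index < 0) || any(frame_index >= total)) {
    stop(sprintf("frame index outside the scan (0..%d)", total - 1L),
         call. = FALSE)
  }
  fpl <- geometry$frames_per_line
  line <- frame_index %/% fpl
  idx <- frame_index %% fpl
  odd <- geometry$serpentine & (line %% 2L == 1L)
  pos <- ifelse(odd, fpl - 1L - idx, idx)
  rot <- ifelse(odd, -1, 1) * idx * geometry$rot_per_frame
  tibble(frame = as.integer(frame_index), line = as.integer(line),
         index_in_line = as.integer(idx),
         position_in_line = as.integer(pos),
         rotation_deg = rot,
         x_um = pos * geometry$h_step, y_um = line * geometry$v_step)
}

#' A per-frame spot-count series over a scan
#'
#' @param spot_counts Non-negative integer vector, one count per frame in
#'   acquisition order (e.g. from a spot-finding program such as dozor).
#' @param geometry A [scan_geometry()] covering at least these frames.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(spot_counts, geometry) {
  stopifnot(all(spot_counts >= 0),
            length(spot_counts) <= geometry$frames_per_line * geometry$n_lines)
  structure(list(spot_counts = as.numeric(spot_counts), geometry = geometry),
            class = "frame_series")
}

# local maxima (strict-then-plateau, earliest frame of a plateau) within one
# count vector; returns 1-based positions.
plateau_maxima <- function(x) {
  if (!length(x)) return(integer())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev <- c(-Inf, r$values[-length(r$values)])
  nxt <- c(r$values[-1], -Inf)
  starts[r$values > prev & r$values > nxt]
}

#' Find candidate crystal centers in a spot-count series
#'
#' A center is a local maximum of the per-frame spot count within a scan
#' line (maxima are never compared across line boundaries); a plateau
#' yields its earliest frame. Mirrors defining "the pattern with the
#' maximum spot count" as the crystal center.
#'
#' @param series A [frame_series()].
#' @param min_center_count Minimum spot count for a frame to qualify as a
#'   center (default 20).
#' @return Integer vector of 0-based global center frame indices, ascending.
#' @export
find_centers <- function(series, min_center_count = 20) {
  stopifnot(min_center_count >= 1)
  fpl <- series$geometry$frames_per_line
  counts <- series$spot_counts
  nf <- length(counts)
  centers <- integer()
  line_starts <- seq(0L, nf - 1L, by = fpl)
  for (s in line_starts) {
    e <- min(s + fpl - 1L, nf - 1L)
    seg <- counts[(s + 1L):(e + 1L)]
    loc <- plateau_maxima(seg)
    loc <- loc[seg[loc] >= min_center_count]
    centers <- c(centers, s + loc - 1L)
  }
  sort(centers)
}

#' Grow a rotational wedge around a center frame
#'
#' Extends left and right from the center while the spot count stays at or
#' above `min_spots`, stopping at line boundaries and at frames already
#' claimed by another wedge.
#'
#' @param center 0-based global center frame; its count must be >=
#'   `min_spots`.
#' @param series A [frame_series()].
#' @param min_spots Minimum spot count for a frame to join the wedge
#'   (default 10).
#' @param claimed Optional logical vector (length = frames) of frames
#'   unavailable to this wedge: claimed by a previously grown wedge or
#'   held by another pending center (see [find_wedges()]).
#' @return One-row tibble: `line`, `start_frame`, `center_frame`,
#'   `end_frame` (inclusive, global), `n_frames`, `rotation_range_deg`.
#' @export
grow_wedge <- function(center, series, min_spots = 10, claimed = NULL) {
  counts <- series$spot_counts
  geo <- series$geometry
  nf <- length(counts)
  if (is.null(claimed)) claimed <- rep(FALSE, nf)
  if (counts[center + 1L] < min_spots) {
    stop("center frame is below min_spots", call. = FALSE)
  }
  fpl <- geo$frames_per_line
  line <- center %/% fpl
  lo_bound <- line * fpl
  hi_bound <- min((line + 1L) * fpl - 1L, nf - 1L)
  s <- center
  while (s - 1L >= lo_bound && counts[s] >= min_spots && !claimed[s]) {
    s <- s - 1L
  }
  e <- center
  while (e + 1L <= hi_bound && counts[e + 2L] >= min_spots && !claimed[e + 2L]) {
    e <- e + 1L
  }
  nfr <- e - s + 1L
  tibble(line = as.integer(line), start_frame = as.integer(s),
         center_frame = as.integer(center), end_frame = as.integer(e),
         n_frames = as.integer(nfr),
         rotation_range_deg = nfr * geo$rot_per_frame)
}

#' Find all wedges in a spot-count series
#'
#' Centers are detected with [find_centers()] and wedges grown in
#' descending order of center spot count (ties broken toward the lower
#' frame index). A growing wedge never extends across another detected
#' center, and frames claimed by an earlier (stronger) wedge are
#' unavailable, so when two bumps share a qualifying frame the stronger
#' center claims it and the weaker wedge stops one frame short. The
#' returned wedges are pairwise frame-disjoint and each lies within one
#' scan line.
#'
#' @param series A [frame_series()].
#' @param min_center_count Center threshold, see [find_centers()].
#' @param min_spots Extension threshold, see [grow_wedge()].
#' @return Tibble of wedges (columns of [grow_wedge()] plus `wedge_id`),
#'   ordered by `start_frame`.
#' @export
find_wedges <- function(series, min_center_count = 20, min_spots = 10) {
  counts <- series$spot_counts
  centers <- find_centers(series, min_center_count)
  ord <- order(-counts[centers + 1L], centers)
  claimed <- rep(FALSE, length(counts))
  is_center <- rep(FALSE, length(counts))
  is_center[centers + 1L] <- TRUE
  rows <- list()
  for (ctr in centers[ord]) {
    if (claimed[ctr + 1L]) next
    blocked <- claimed | is_center
    blocked[ctr + 1L] <- FALSE
    w <- grow_wedge(ctr, series, min_spots = min_spots, claimed = blocked)
    claimed[(w$start_frame + 1L):(w$end_frame + 1L)] <- TRUE
    rows[[length(rows) + 1L]] <- w
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(wedge_id = integer(), line = integer(),
                  start_frame = integer(), center_frame = integer(),
                  end_frame = integer(), n_frames = integer(),
                  rotation_range_deg = double()))
  }
  out <- dplyr::arrange(out, .data$start_frame)
  dplyr::bind_cols(tibble(wedge_id = seq_len(nrow(out))), out)
}

#' Angle between the unique reciprocal axes of two orientations
#'
#' The angle between the chosen reciprocal-axis directions of two crystals,
#' folded as axes (theta -> min(theta, 180 - theta)) so that antiparallel
#' axes count as aligned. Crystals whose unique axes deviate by more than a
#' threshold (6 degrees in this pipeline) are treated as distinct.
#'
#' @param o1,o2 3x3 reciprocal orientation matrices (rows a*, b*, c*).
#' @param axis_label Which reciprocal axis to compare: `"a*"`, `"b*"` or
#'   `"c*"`.
#' @return Angle in degrees, in [0, 90].
#' @export
unique_axis_angle <- function(o1, o2, axis_label = "c*") {
  i <- match(axis_label, c("a*", "b*", "c*"))
  if (is.na(i)) stop("axis_label must be one of a*, b*, c*", call. = FALSE)
  u <- o1[i, ]; v <- o2[i, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length reciprocal axis", call. = FALSE)
  cosang <- abs(sum(u * v)) / (nu * nv)
  acos(min(1, cosang)) * 180 / pi
}

# default unique axis label for a lattice type (with warning where none is
# crystallographically defined)
default_axis_label <- function(lattice_type) {
  switch(lattice_type,
    hexagonal = , trigonal = , tetragonal = "c*",
    monoclinic = "b*",
    {
      warning(sprintf(
        "lattice type '%s' has no crystallographic unique axis; using c*",
        lattice_type), call. = FALSE)
      "c*"
    })
}

#' Do two wedges overlap?
#'
#' @param w1,w2 One-row wedge tibbles (as from [find_wedges()]).
#' @param geometry A [scan_geometry()] (needed for spatial mode).
#' @param mode `"frames"` (default): frame intervals intersect;
#'   `"spatial"`: any two member frames lie within
#'   `max(h_step, v_step)` micrometres of each other (captures a crystal
#'   spanning adjacent lines).
#' @return Logical scalar.
#' @export
wedges_overlap <- function(w1, w2, geometry, mode = c("frames", "spatial")) {
  mode <- match.arg(mode)
  if (mode == "frames") {
    return(w1$start_frame <= w2$end_frame && w2$start_frame <= w1$end_frame)
  }
  p1 <- frame_to_position(seq(w1$start_frame, w1$end_frame), geometry)
  p2 <- frame_to_position(seq(w2$start_frame, w2$end_frame), geometry)
  lim <- max(geometry$h_step, geometry$v_step) + 1e-9
  dx <- outer(p1$x_um, p2$x_um, "-")
  dy <- outer(p1$y_um, p2$y_um, "-")
  any(sqrt(dx^2 + dy^2) <= lim)
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

#' Deduplicate wedges into crystal identities
#'
#' Two wedges belong to the same physical crystal when they overlap (frame
#' or spatial mode) and their unique reciprocal axes agree within
#' `angle_threshold` degrees; identities are the connected components of
#' this relation. Wedges that do not overlap are never merged regardless of
#' orientation. Wedges without an orientation are excluded with a warning
#' and reported separately.
#'
#' @param wedges Tibble from [find_wedges()].
#' @param orientations List of 3x3 orientation matrices, one per wedge
#'   (typically from the indexed crystal of each wedge's center chunk);
#'   `NULL` entries mark wedges without an orientation.
#' @param geometry A [scan_geometry()].
#' @param angle_threshold Unique-axis deviation above which crystals are
#'   distinct, degrees (default 6).
#' @param mode Overlap mode, see [wedges_overlap()].
#' @param axis_label Reciprocal axis compared (default `"c*"`, the unique
#'   axis of the hexagonal/tetragonal lattices this pipeline targets).
#' @return List with `identities`: tibble (`identity_id`, `wedge_id`,
#'   `representative`: TRUE for the member with the highest center spot
#'   count when counts are supplied via `center_counts`), and `excluded`:
#'   integer vector of wedge ids without orientation.
#' @param center_counts Optional numeric vector of center spot counts per
#'   wedge used to pick each identity's representative wedge.
#' @export
deduplicate_crystals <- function(wedges, orientations, geometry,
                                 angle_threshold = 6.0,
                                 mode = c("frames", "spatial"),
                                 axis_label = "c*", center_counts = NULL) {
  mode <- match.arg(mode)
  nw <- nrow(wedges)
  has_or <- !vapply(orientations, is.null, logical(1))
  if (any(!has_or)) {
    warning(sprintf("%d wedge(s) without orientation excluded from deduplication",
                    sum(!has_or)), call. = FALSE)
  }
  keep <- which(has_or)
  parent <- uf_new(nw)
  if (length(keep) > 1) {
    for (ii in seq_along(keep)[-length(keep)]) {
      for (jj in seq((ii + 1), length(keep))) {
        i <- keep[ii]; j <- keep[jj]
        if (!wedges_overlap(wedges[i, ], wedges[j, ], geometry, mode)) next
        ang <- unique_axis_angle(orientations[[i]], orientations[[j]],
                                 axis_label)
        if (ang <= angle_threshold) parent <- uf_union(parent, i, j)
      }
    }
  }
  roots <- vapply(keep, function(i) uf_find(parent, i), integer(1))
  ids <- match(roots, unique(roots))
  identities <- tibble(identity_id = ids, wedge_id = wedges$wedge_id[keep])
  if (!is.null(center_counts)) {
    identities$center_count <- center_counts[keep]
    identities <- identities |>
      dplyr::group_by(.data$identity_id) |>
      dplyr::mutate(representative =
        dplyr::row_number(dplyr::desc(.data$center_count)) == 1L) |>
      dplyr::ungroup()
  }
  identities <- dplyr::arrange(identities, .data$identity_id, .data$wedge_id)
  list(identities = identities,
       excluded = wedges$wedge_id[!has_or])
}

#' Export a wedge manifest
#'
#' Produces the per-identity, per-wedge manifest handed to rotation
#' processing: image ids, frame range, rotation range and starting angle.
#'
#' @param identities Tibble from [deduplicate_crystals()] (`$identities`).
#' @param wedges Tibble from [find_wedges()].
#' @param dataset A [stream_dataset()] whose chunks cover all wedge frames.
#' @param geometry A [scan_geometry()].
#' @return Tibble: `identity_id`, `wedge_id`, `line`, `start_frame`,
#'   `end_frame`, `center_frame`, `start_angle_deg`, `rotation_range_deg`,
#'   `image_ids` (comma-separated).
#' @export
export_wedges <- function(identities, wedges, dataset, geometry) {
  if (!nrow(identities)) {
    return(tibble(identity_id = integer(), wedge_id = integer(),
                  line = integer(), start_frame = integer(),
                  end_frame = integer(), center_frame = integer(),
                  start_angle_deg = double(), rotation_range_deg = double(),
                  image_ids = character()))
  }
  by_frame <- stats::setNames(
    vapply(dataset$chunks, function(ch) ch$image_id, character(1)),
    vapply(dataset$chunks, function(ch) as.character(ch$frame_index),
           character(1)))
  rows <- purrr::pmap(identities[c("identity_id", "wedge_id")],
    function(identity_id, wedge_id) {
      w <- wedges[wedges$wedge_id == wedge_id, ]
      frames <- seq(w$start_frame, w$end_frame)
      miss <- setdiff(as.character(frames), names(by_frame))
      if (length(miss)) {
        stop(sprintf("frame %s missing from dataset", miss[1]), call. = FALSE)
      }
      start_angle <- frame_to_position(w$start_frame, geometry)$rotation_deg
      tibble(identity_id = identity_id, wedge_id = wedge_id,
             line = w$line, start_frame = w$start_frame,
             end_frame = w$end_frame, center_frame = w$center_frame,
             start_angle_deg = start_angle,
             rotation_range_deg = w$rotation_range_deg,
             image_ids = paste(by_frame[as.character(frames)],
                               collapse = ","))
    })
  dplyr::bind_rows(rows)
}

#' Full wedge-finding pipeline over a stream dataset
#'
#' Convenience driver: builds the spot-count series from chunk `n_peaks`,
#' finds wedges, attaches each wedge's orientation from the first indexed
#' crystal of its center chunk, and deduplicates.
#'
#' @param dataset A [stream_dataset()] whose chunk frame indices follow the
#'   scan order.
#' @param geometry A [scan_geometry()].
#' @inheritParams find_wedges
#' @inheritParams deduplicate_crystals
#' @return List: `wedges`, `identities`, `excluded`, `manifest`.
#' @export
find_crystals <- function(dataset, geometry, min_center_count = 20,
                          min_spots = 10, angle_threshold = 6.0,
                          mode = c("frames", "spatial"),
                          axis_label = "c*") {
  mode <- match.arg(mode)
  counts <- vapply(dataset$chunks, function(ch) ch$n_peaks, integer(1))
  series <- frame_series(counts, geometry)
  wedges <- find_wedges(series, min_center_count, min_spots)
  frame_of <- vapply(dataset$chunks, function(ch) ch$frame_index, integer(1))
  orientations <- lapply(seq_len(nrow(wedges)), function(i) {
    pos <- match(wedges$center_frame[i], frame_of)
    if (is.na(pos)) return(NULL)
    ch <- dataset$chunks[[pos]]
    if (length(ch$crystals)) ch$crystals[[1]]$orientation else NULL
  })
  dd <- deduplicate_crystals(wedges, orientations, geometry,
                             angle_threshold = angle_threshold, mode = mode,
                             axis_label = axis_label,
                             center_counts = counts[wedges$center_frame + 1L])
  manifest <- export_wedges(dd$identities, wedges, dataset, geometry)
  list(wedges = wedges, identities = dd$identities,
       excluded = dd$excluded, manifest = manifest)
}
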
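#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

CHUNK_BEGIN <- "----- Begin chunk -----"
CHUNK_END <- "----- End chunk -----"
CRYSTAL_BEGIN <- "--- Begin crystal"
CRYSTAL_END <- "--- End crystal"
REFL_BEGIN <- "Reflections measured after indexing"
REFL_HEADER <- "   h    k    l          I   sigma(I)       peak background  fs/px  ss/px panel"
REFL_END <- "End of reflections"

#' Construct an empty reflection table
#'
#' @return A zero-row tibble with the reflection columns: `h, k, l` (integer
#'   Miller indices), `intensity`, `sigma`, `peak`, `background` (detector
#'   units/counts), `fs`, `ss` (pixel coordinates), `panel`.
#' @export
reflection_table <- function() {
  tibble(h = integer(), k = integer(), l = integer(),
         intensity = double(), sigma = double(),
         peak = double(), background = double(),
         fs = double(), ss = double(), panel = character())
}

#' Construct a crystal record
#'
#' One indexed crystal of a stream chunk: its cell, reciprocal orientation,
#' resolution limit and reflection list.
#'
#' @param cell A [unit_cell()].
#' @param orientation 3x3 matrix of reciprocal basis rows a*, b*, c* in
#'   nm^-1; defaults to the unrotated basis of `cell`.
#' @param resolution_limit Smallest d (Angstrom) to which the crystal
#'   diffracts; must be positive.
#' @param reflections Tibble with the columns of [reflection_table()];
#'   may be empty.
#' @param extra Character vector of unrecognised stream lines carried
#'   verbatim.
#' @return An object of class `crystal_record`.
#' @export
crystal_record <- function(cell, orientation = NULL, resolution_limit = 2,
                           reflections = reflection_table(),
                           extra = character()) {
  stopifnot(inherits(cell, "unit_cell"), resolution_limit > 0)
  if (is.null(orientation)) orientation <- orientation_matrix(cell)
  stopifnot(all(dim(orientation) == c(3, 3)))
  orientation <- unname(orientation)
  reflections <- as_tibble(reflections)
  if (nrow(reflections)) {
    stopifnot(all(reflections$sigma >= 0),
              all(reflections$fs >= 0), all(reflections$ss >= 0))
  }
  structure(list(cell = cell, orientation = orientation,
                 resolution_limit = resolution_limit,
                 reflections = reflections, extra = extra),
            class = "crystal_record")
}

#' Construct a stream chunk
#'
#' One detector frame's record: identifiers, spot count and zero or more
#' indexed crystals.
#'
#' @param frame_index 0-based position in acquisition order.
#' @param image_id,event_id Free-text identifiers.
#' @param n_peaks Non-negative spot count for the frame.
#' @param crystals List of [crystal_record()]s (possibly empty).
#' @param extra Unrecognised stream lines carried verbatim.
#' @return An object of class `stream_chunk`.
#' @export
stream_chunk <- function(frame_index, image_id = "", event_id = "",
                         n_peaks = 0, crystals = list(),
                         extra = character()) {
  stopifnot(frame_index >= 0, n_peaks >= 0)
  structure(list(frame_index = as.integer(frame_index),
                 image_id = image_id, event_id = event_id,
                 n_peaks = as.integer(n_peaks), crystals = crystals,
                 extra = extra),
            class = "stream_chunk")
}

#' Construct a stream dataset
#'
#' The in-memory model of a serial-crystallography stream file: a free-text
#' header plus chunks ordered by `frame_index`.
#'
#' @param chunks List of [stream_chunk()]s; frame indices must be strictly
#'   increasing.
#' @param header Character vector of header lines preserved verbatim.
#' @return An object of class `stream_dataset`.
#' @export
stream_dataset <- function(chunks = list(), header = "Generated by incellproc") {
  fi <- vapply(chunks, function(ch) ch$frame_index, integer(1))
  if (length(fi) > 1 && any(diff(fi) <= 0)) {
    stop("chunk frame_index must be strictly increasing", call. = FALSE)
  }
  structure(list(header = header, chunks = chunks), class = "stream_dataset")
}

#' @export
print.stream_dataset <- function(x, ...) {
  nc <- vapply(x$chunks, function(ch) length(ch$crystals), integer(1))
  cat(sprintf("<stream_dataset> %d chunks, %d indexed crystals (%d chunks with >=1 crystal)\n",
              length(x$chunks), sum(nc), sum(nc > 0)))
  invisible(x)
}

#' Number of chunks in a stream dataset
#' @param dataset A [stream_dataset()].
#' @return Integer count.
#' @export
n_chunks <- function(dataset) length(dataset$chunks)

#' Flat table of all reflections in a dataset
#'
#' The tabular interface on which the peakogram, salt filtering and merging
#' operate: one row per observed reflection, tagged with its chunk and
#' crystal of origin.
#'
#' @param dataset A [stream_dataset()].
#' @return A tibble with `chunk`, `frame_index`, `crystal`, `crystal_id`
#'   plus the [reflection_table()] columns.
#' @export
reflections_table <- function(dataset) {
  rows <- purrr::imap(dataset$chunks, function(ch, i) {
    purrr::imap(ch$crystals, function(cr, j) {
      if (!nrow(cr$reflections)) return(NULL)
      dplyr::bind_cols(
        tibble(chunk = i, frame_index = ch$frame_index, crystal = j,
               crystal_id = sprintf("c%05d.%d", ch$frame_index, j)),
        cr$reflections)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (!nrow(out)) {
    out <- dplyr::bind_cols(
      tibble(chunk = integer(), frame_index = integer(), crystal = integer(),
             crystal_id = character()),
      reflection_table())
  }
  out
}

#' Flat table of all indexed crystals in a dataset
#'
#' @param dataset A [stream_dataset()].
#' @return A tibble with one row per crystal: chunk/frame identifiers, cell
#'   parameters, resolution limit and reflection count.
#' @export
crystals_table <- function(dataset) {
  rows <- purrr::imap(dataset$chunks, function(ch, i) {
    purrr::imap(ch$crystals, function(cr, j) {
      tibble(chunk = i, frame_index = ch$frame_index, crystal = j,
             crystal_id = sprintf("c%05d.%d", ch$frame_index, j),
             a = cr$cell$a, b = cr$cell$b, c = cr$cell$c,
             alpha = cr$cell$alpha, beta = cr$cell$beta,
             gamma = cr$cell$gamma,
             lattice_type = cr$cell$lattice_type,
             centering = cr$cell$centering,
             resolution_limit = cr$resolution_limit,
             n_reflections = nrow(cr$reflections))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (!nrow(out)) {
    out <- tibble(chunk = integer(), frame_index = integer(),
                  crystal = integer(), crystal_id = character(),
                  a = double(), b = double(), c = double(), alpha = double(),
                  beta = double(), gamma = double(),
                  lattice_type = character(), centering = character(),
                  resolution_limit = double(), n_reflections = integer())
  }
  out
}

parse_error <- function(line_no, msg) {
  stop(sprintf("stream parse error at line %d: %s", line_no, msg),
       call. = FALSE)
}

num_or_fail <- function(x, line_no, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) parse_error(line_no, paste("cannot parse", what))
  v
}

#' Read a serial-crystallography stream file
#'
#' Parses the documented CrystFEL-like text dialect: a free header, chunks
#' bracketed by `----- Begin chunk -----` / `----- End chunk -----`, each
#' carrying `Image filename:`, `Event:`, `num_peaks = N` and zero or more
#' crystal blocks with cell parameters (nm in the file, Angstrom in memory),
#' reciprocal basis vectors (nm^-1), a resolution limit and a reflection
#' table. Unrecognised lines inside chunks or crystals are preserved
#' verbatim and re-emitted by [write_stream()].
#'
#' @param source Path to a stream file, or a character vector of lines.
#' @return A [stream_dataset()].
#' @export
read_stream <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
               file.exists(source)) readLines(source) else source
  header <- character()
  chunks <- list()
  i <- 1L; n <- length(lines)
  frame_counter <- 0L
  # header
  while (i <= n && lines[i] != CHUNK_BEGIN) {
    header <- c(header, lines[i]); i <- i + 1L
  }
  while (i <= n) {
    if (lines[i] != CHUNK_BEGIN) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      parse_error(i, "expected chunk delimiter")
    }
    i <- i + 1L
    ch <- list(frame_index = NA_integer_, image_id = "", event_id = "",
               n_peaks = 0L, crystals = list(), extra = character())
    while (i <= n && lines[i] != CHUNK_END) {
      ln <- lines[i]
      if (ln == CHUNK_BEGIN) parse_error(i, "nested 'Begin chunk'")
      if (startsWith(ln, "Image filename: ")) {
        ch$image_id <- sub("^Image filename: ", "", ln)
      } else if (startsWith(ln, "Event: ")) {
        ch$event_id <- sub("^Event: ", "", ln)
      } else if (startsWith(ln, "Image serial number: ")) {
        ch$frame_index <- as.integer(
          num_or_fail(sub("^Image serial number: ", "", ln), i,
                      "serial number"))
      } else if (grepl("^num_peaks = ", ln)) {
        ch$n_peaks <- as.integer(num_or_fail(sub("^num_peaks = ", "", ln),
                                             i, "num_peaks"))
      } else if (startsWith(ln, CRYSTAL_BEGIN)) {
        res <- parse_crystal(lines, i + 1L)
        ch$crystals <- c(ch$crystals, list(res$crystal))
        i <- res$next_line - 1L
      } else {
        ch$extra <- c(ch$extra, ln)
      }
      i <- i + 1L
    }
    if (i > n) parse_error(n, "unterminated chunk (missing 'End chunk')")
    i <- i + 1L
    if (is.na(ch$frame_index)) {
      ch$frame_index <- frame_counter
    }
    frame_counter <- max(frame_counter, ch$frame_index) + 1L
    chunks <- c(chunks, list(structure(ch, class = "stream_chunk")))
  }
  stream_dataset(chunks = chunks, header = header)
}

parse_crystal <- function(lines, i) {
  n <- length(lines)
  cellpar <- NULL; lattice <- "triclinic"; centering <- "P"; uax <- NULL
  basis <- matrix(NA_real_, 3, 3)
  reslim <- NA_real_
  refl <- NULL; extra <- character()
  while (i <= n && lines[i] != CRYSTAL_END) {
    ln <- lines[i]
    if (startsWith(ln, "Cell parameters ")) {
      body <- sub("^Cell parameters ", "", ln)
      parts <- strsplit(gsub(",", "", body), "\\s+")[[1]]
      parts <- parts[parts != "nm" & parts != "deg"]
      v <- num_or_fail(parts, i, "cell parameters")
      if (length(v) != 6) parse_error(i, "expected six cell parameters")
      cellpar <- c(v[1:3] * 10, v[4:6])   # nm in file -> Angstrom
    } else if (grepl("^(astar|bstar|cstar) = ", ln)) {
      which_ax <- match(substr(ln, 1, 5), c("astar", "bstar", "cstar"))
      body <- sub("^[abc]star = ", "", ln)
      body <- sub(" nm\\^-1$", "", body)
      v <- num_or_fail(strsplit(trimws(body), "\\s+")[[1]], i,
                       "reciprocal vector")
      if (length(v) != 3) parse_error(i, "expected three vector components")
      basis[which_ax, ] <- v
    } else if (grepl("^lattice_type = ", ln)) {
      lattice <- sub("^lattice_type = ", "", ln)
    } else if (grepl("^centering = ", ln)) {
      centering <- sub("^centering = ", "", ln)
    } else if (grepl("^unique_axis = ", ln)) {
      uax <- sub("^unique_axis = ", "", ln)
    } else if (grepl("^diffraction_resolution_limit = ", ln)) {
      m <- regmatches(ln, regexec(
        "diffraction_resolution_limit = ([0-9.eE+-]+) nm\\^-1 or ([0-9.eE+-]+) A",
        ln))[[1]]
      if (length(m) != 3) parse_error(i, "malformed resolution limit")
      reslim <- num_or_fail(m[3], i, "resolution limit")
    } else if (ln == REFL_BEGIN) {
      i <- i + 1L
      if (i <= n && grepl("^\\s*h\\s+k\\s+l\\s", lines[i])) i <- i + 1L
      rows <- list()
      while (i <= n && lines[i] != REFL_END) {
        f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        if (length(f) < 10) parse_error(i, "short reflection row")
        hkl <- suppressWarnings(as.numeric(f[1:3]))
        if (any(is.na(hkl)) || any(hkl != round(hkl))) {
          parse_error(i, "non-integer Miller indices")
        }
        vals <- num_or_fail(f[4:9], i, "reflection values")
        rows[[length(rows) + 1L]] <-
          c(as.integer(hkl), vals)
        attr(rows[[length(rows)]], "panel") <- f[10]
        i <- i + 1L
      }
      if (i > n) parse_error(n, "unterminated reflection table")
      if (length(rows)) {
        m <- do.call(rbind, lapply(rows, as.numeric))
        refl <- tibble(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                       l = as.integer(m[, 3]), intensity = m[, 4],
                       sigma = m[, 5], peak = m[, 6], background = m[, 7],
                       fs = m[, 8], ss = m[, 9],
                       panel = vapply(rows, attr, "", which = "panel"))
      }
    } else if (nzchar(trimws(ln))) {
      extra <- c(extra, ln)
    }
    i <- i + 1L
  }
  if (i > n) parse_error(n, "unterminated crystal (missing 'End crystal')")
  if (is.null(cellpar) || anyNA(basis)) {
    parse_error(i, "crystal block missing cell parameters or basis vectors")
  }
  cell <- unit_cell(cellpar[1], cellpar[2], cellpar[3],
                    cellpar[4], cellpar[5], cellpar[6],
                    lattice_type = lattice, centering = centering,
                    unique_axis = uax)
  cr <- crystal_record(cell, orientation = basis,
                       resolution_limit = if (is.na(reslim)) 2 else reslim,
                       reflections = if (is.null(refl)) reflection_table() else refl,
                       extra = extra)
  list(crystal = cr, next_line = i + 1L)
}

fmt_refl_rows <- function(r) {
  sprintf("%4d %4d %4d %10.2f %10.2f %10.2f %10.2f %6.1f %6.1f %s",
          r$h, r$k, r$l, r$intensity, r$sigma, r$peak, r$background,
          r$fs, r$ss, r$panel)
}

#' Write a stream dataset to the text dialect
#'
#' Inverse of [read_stream()]: cells are written in nm, reciprocal vectors
#' in nm^-1, with fixed field widths. Unrecognised lines captured at read
#' time are re-emitted.
#'
#' @param dataset A [stream_dataset()].
#' @param path File path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_stream <- function(dataset, path = NULL) {
  out <- character(0)
  add <- function(...) out <<- c(out, ...)
  add(dataset$header)
  for (ch in dataset$chunks) {
    add(CHUNK_BEGIN,
        paste0("Image filename: ", ch$image_id),
        paste0("Event: ", ch$event_id),
        paste0("Image serial number: ", ch$frame_index),
        sprintf("num_peaks = %d", ch$n_peaks),
        ch$extra)
    for (cr in ch$crystals) {
      cc <- cr$cell
      add(CRYSTAL_BEGIN,
          sprintf("Cell parameters %.5f %.5f %.5f nm, %.5f %.5f %.5f deg",
                  cc$a / 10, cc$b / 10, cc$c / 10,
                  cc$alpha, cc$beta, cc$gamma),
          sprintf("astar = %+.7f %+.7f %+.7f nm^-1",
                  cr$orientation[1, 1], cr$orientation[1, 2],
                  cr$orientation[1, 3]),
          sprintf("bstar = %+.7f %+.7f %+.7f nm^-1",
                  cr$orientation[2, 1], cr$orientation[2, 2],
                  cr$orientation[2, 3]),
          sprintf("cstar = %+.7f %+.7f %+.7f nm^-1",
                  cr$orientation[3, 1], cr$orientation[3, 2],
                  cr$orientation[3, 3]),
          paste0("lattice_type = ", cc$lattice_type),
          paste0("centering = ", cc$centering),
          paste0("unique_axis = ", cc$unique_axis),
          sprintf("diffraction_resolution_limit = %.4f nm^-1 or %.4f A",
                  10 / cr$resolution_limit, cr$resolution_limit),
          cr$extra,
          REFL_BEGIN, REFL_HEADER)
      if (nrow(cr$reflections)) add(fmt_refl_rows(cr$reflections))
      add(REFL_END, CRYSTAL_END)
    }
    add(CHUNK_END)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Select chunks satisfying a predicate
#'
#' The in-memory analogue of extracting chunks from a stream with a grep
#' style tool (used e.g. to drop non-indexed frames or clean unit-cell
#' populations).
#'
#' @param dataset A [stream_dataset()].
#' @param predicate Function taking a [stream_chunk()] and returning a
#'   logical scalar.
#' @return A new [stream_dataset()] with the matching chunks, order
#'   preserved; the input is unmodified.
#' @examples
#' # keep indexed chunks only
#' # select_chunks(ds, function(ch) length(ch$crystals) >= 1)
#' @export
select_chunks <- function(dataset, predicate) {
  keep <- vapply(dataset$chunks, function(ch) isTRUE(predicate(ch)),
                 logical(1))
  stream_dataset(chunks = dataset$chunks[keep], header = dataset$header)
}

#' Partition a dataset by unit-cell population
#'
#' Assigns each chunk to the first reference cell its first indexed crystal
#' matches within tolerance; chunks without crystals, or whose first crystal
#' matches no reference, go to `unassigned`. Used to separate apparent
#' unit-cell populations (e.g. two polymorphs differing in the c axis).
#'
#' @param dataset A [stream_dataset()].
#' @param reference_cells List of [unit_cell()] reference cells (>= 1).
#' @param axis_rel_tol Relative tolerance on axis lengths (default 0.05).
#' @param angle_abs_tol Absolute tolerance on angles, degrees (default 1.5).
#' @return Named list of [stream_dataset()]s: one per reference
#'   (`ref_1`, `ref_2`, ...) plus `unassigned`. A warning is raised if any
#'   crystal matches more than one reference (first match wins).
#' @export
split_by_cell <- function(dataset, reference_cells, axis_rel_tol = 0.05,
                          angle_abs_tol = 1.5) {
  stopifnot(length(reference_cells) >= 1,
            axis_rel_tol > 0, angle_abs_tol > 0)
  nref <- length(reference_cells)
  bins <- vector("list", nref + 1L)
  overlap_seen <- FALSE
  for (ch in dataset$chunks) {
    dest <- nref + 1L
    if (length(ch$crystals)) {
      hits <- vapply(reference_cells, cells_match,
                     logical(1), cell = ch$crystals[[1]]$cell,
                     axis_rel_tol = axis_rel_tol,
                     angle_abs_tol = angle_abs_tol)
      if (sum(hits) > 1) overlap_seen <- TRUE
      if (any(hits)) dest <- which(hits)[1]
    }
    bins[[dest]] <- c(bins[[dest]], list(ch))
  }
  if (overlap_seen) {
    warning("some cells match more than one reference; first match wins",
            call. = FALSE)
  }
  out <- lapply(bins, function(b) {
    stream_dataset(chunks = if (is.null(b)) list() else b,
                   header = dataset$header)
  })
  names(out) <- c(paste0("ref_", seq_len(nref)), "unassigned")
  out
}

#' Split a dataset into contiguous equal parts
#'
#' Parts are contiguous in original order with sizes differing by at most
#' one; earlier parts take the remainder. Used to slice a sorted stream
#' into equal-chunk-count fourths for diffraction-power-over-time analysis.
#'
#' @param dataset A [stream_dataset()].
#' @param n_parts Number of parts, between 1 and the chunk count.
#' @return List of `n_parts` [stream_dataset()]s.
#' @export
split_into_parts <- function(dataset, n_parts) {
  nc <- n_chunks(dataset)
  if (n_parts < 1 || n_parts > nc) {
    stop(sprintf("n_parts must be between 1 and the chunk count (%d)", nc),
         call. = FALSE)
  }
  base <- nc %/% n_parts
  sizes <- rep(base, n_parts)
  rem <- nc %% n_parts
  if (rem > 0) sizes[seq_len(rem)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) {
    stream_dataset(chunks = dataset$chunks[s:e], header = dataset$header)
  })
}
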
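#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stream dataset into a per-chunk tibble
#'
#' @param x A [stream_dataset()].
#' @param ... Unused.
#' @return Tibble: `frame_index`, `image_id`, `event_id`, `n_peaks`,
#'   `n_crystals`.
#' @method tidy stream_dataset
#' @export
tidy.stream_dataset <- function(x, ...) {
  dplyr::bind_rows(lapply(x$chunks, function(ch) {
    tibble(frame_index = ch$frame_index, image_id = ch$image_id,
           event_id = ch$event_id, n_peaks = ch$n_peaks,
           n_crystals = length(ch$crystals))
  }))
}

#' One-row summary of a stream dataset
#'
#' @param x A [stream_dataset()].
#' @param ... Unused.
#' @return Tibble: `n_chunks`, `n_indexed_chunks`, `n_crystals`,
#'   `n_reflections`.
#' @method glance stream_dataset
#' @export
glance.stream_dataset <- function(x, ...) {
  nc <- vapply(x$chunks, function(ch) length(ch$crystals), integer(1))
  nr <- sum(vapply(x$chunks, function(ch) {
    sum(vapply(ch$crystals, function(cr) nrow(cr$reflections), integer(1)))
  }, integer(1)))
  tibble(n_chunks = length(x$chunks), n_indexed_chunks = sum(nc > 0),
         n_crystals = sum(nc), n_reflections = nr)
}

#' Tidy a shell table (per-shell rows)
#' @param x A `shell_table` from [shell_stats()].
#' @param ... Unused.
#' @return The per-shell rows as a plain tibble (overall row dropped).
#' @method tidy shell_table
#' @export
tidy.shell_table <- function(x, ...) {
  out <- as_tibble(x)[as_tibble(x)$shell != "overall", ]
  class(out) <- class(tibble())
  out
}

#' Overall figures of merit of a shell table
#' @param x A `shell_table` from [shell_stats()].
#' @param ... Unused.
#' @return One-row tibble (the overall row).
#' @method glance shell_table
#' @export
glance.shell_table <- function(x, ...) {
  out <- as_tibble(x)[as_tibble(x)$shell == "overall", ]
  class(out) <- class(tibble())
  out
}

#' Tidy a titer result
#' @param x A `titer_result` from [tcid50()].
#' @param ... Unused.
#' @return One-row tibble: `tcid50_per_ml`, `log10_endpoint_dilution`,
#'   `method`.
#' @method tidy titer_result
#' @export
tidy.titer_result <- function(x, ...) {
  tibble(tcid50_per_ml = x$tcid50_per_ml,
         log10_endpoint_dilution = x$log10_endpoint_dilution,
         method = x$method)
}

#' Per-residue deviations of a superposition
#' @param x A `superposition` from [superpose()].
#' @param ... Unused.
#' @return Tibble: `chain`, `resno`, `deviation_A`.
#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) x$deviations

#' One-row summary of a superposition
#' @param x A `superposition` from [superpose()].
#' @param ... Unused.
#' @return Tibble: `rmsd`, `n_pairs`, `max_deviation_A`.
#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
         max_deviation_A = max(x$deviations$deviation_A))
}
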
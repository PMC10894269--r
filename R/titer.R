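#' Score titration wells from fluorescent-cell counts
#'
#' A well is positive when it contains at least `threshold` fluorescent
#' (infected) cells — two by default, the standard endpoint-dilution
#' scoring for fluorescence-marked baculovirus.
#'
#' @param counts Non-negative integer vector of fluorescent cells per well,
#'   or a list of such vectors (one per dilution).
#' @param threshold Minimum count for positivity (default 2).
#' @return Number of positive wells (integer, or vector for list input).
#' @export
score_wells <- function(counts, threshold = 2) {
  if (is.list(counts)) {
    return(vapply(counts, score_wells, integer(1), threshold = threshold))
  }
  if (any(counts < 0)) stop("cell counts must be non-negative", call. = FALSE)
  sum(counts >= threshold)
}

#' Assemble an endpoint-dilution titer plate
#'
#' @param dilution_log10 Log10 total dilution per row (negative, strictly
#'   decreasing with a constant step; e.g. -2 ... -9 for a 1:10
#'   pre-dilution followed by seven serial 1:10 transfers).
#' @param positive Positive wells per dilution (0 .. `wells`).
#' @param wells Wells per dilution (default 6).
#' @param inoculum_ml Volume plated per well in mL (default 0.02).
#' @return Object of class `titer_plate` (a tibble with metadata).
#' @export
titer_plate <- function(dilution_log10, positive, wells = 6,
                        inoculum_ml = 0.02) {
  stopifnot(length(dilution_log10) == length(positive),
            all(positive >= 0), all(positive <= wells),
            inoculum_ml > 0)
  if (length(dilution_log10) > 1) {
    steps <- diff(dilution_log10)
    if (any(steps >= 0) || max(abs(steps - steps[1])) > 1e-9) {
      stop("dilutions must be strictly decreasing with a constant step",
           call. = FALSE)
    }
  }
  out <- tibble(dilution_log10 = dilution_log10,
                wells = as.integer(wells),
                positive = as.integer(positive),
                proportion = positive / wells)
  attr(out, "inoculum_ml") <- inoculum_ml
  class(out) <- c("titer_plate", class(out))
  out
}

#' TCID50 titer from an endpoint-dilution plate
#'
#' Spearman-Karber (default): with d the dilution step and S the sum of
#' positive proportions from the last fully positive row to the end, the
#' log10 endpoint dilution is `m = x100 - d * (S - 0.5)` and the titer is
#' `10^(-m) / inoculum_ml` TCID50 per mL. The Reed-Muench interpolation is
#' available as an alternative. The endpoint must be bracketed: the plate
#' needs at least one fully positive and one fully negative row.
#'
#' @param plate A [titer_plate()].
#' @param method `"spearman-karber"` (default) or `"reed-muench"`.
#' @return Object of class `titer_result`: list with `tcid50_per_ml`,
#'   `log10_endpoint_dilution`, `method`.
#' @examples
#' p <- titer_plate(-(2:9), c(6, 6, 6, 6, 3, 0, 0, 0))
#' tcid50(p)$tcid50_per_ml  # 5e7
#' @export
tcid50 <- function(plate, method = c("spearman-karber", "reed-muench")) {
  method <- match.arg(method)
  prop <- plate$proportion
  if (all(prop > 0)) {
    stop("endpoint not bracketed: no fully negative dilution", call. = FALSE)
  }
  if (all(prop < 1)) {
    stop("endpoint not bracketed: no fully positive dilution", call. = FALSE)
  }
  d <- abs(diff(plate$dilution_log10)[1])
  i100 <- max(which(prop == 1))
  m <- if (method == "spearman-karber") {
    S <- sum(prop[i100:length(prop)])
    plate$dilution_log10[i100] - d * (S - 0.5)
  } else {
    # Reed-Muench: interpolate where cumulative %infected crosses 50%
    pos <- plate$positive
    neg <- plate$wells - plate$positive
    # positives accumulated from the most dilute row upward, negatives from
    # the least dilute downward
    acc_pos <- rev(cumsum(rev(pos)))
    acc_neg <- cumsum(neg)
    pct <- 100 * acc_pos / (acc_pos + acc_neg)
    above <- max(which(pct >= 50))
    if (above == length(pct) || pct[above] == 50) {
      plate$dilution_log10[above] -
        d * (if (pct[above] == 50) 0 else 0.5)
    } else {
      pd <- (pct[above] - 50) / (pct[above] - pct[above + 1])
      plate$dilution_log10[above] - d * pd
    }
  }
  inoc <- attr(plate, "inoculum_ml")
  structure(list(tcid50_per_ml = 10^(-m) / inoc,
                 log10_endpoint_dilution = m, method = method),
            class = "titer_result")
}

#' @export
print.titer_result <- function(x, ...) {
  cat(sprintf("<titer_result> %.3g TCID50/mL (log10 endpoint dilution %.3f, %s)\n",
              x$tcid50_per_ml, x$log10_endpoint_dilution, x$method))
  invisible(x)
}

#' Volume of virus stock for a target MOI
#'
#' The dosing formula
#' `virus stock [mL] = (MOI * cell number) / (0.69 * TCID50 per mL)`,
#' where 0.69 (= ln 2) converts a TCID50 titer to infectious units.
#'
#' @param moi Target multiplicity of infection (>= 0).
#' @param cell_number Number of cells to infect (> 0).
#' @param tcid50_per_ml Stock titer in TCID50 per mL (> 0).
#' @return Volume of stock in mL.
#' @examples
#' volume_for_moi(1, 1e6, 1e7)  # 0.14493 mL
#' @export
volume_for_moi <- function(moi, cell_number, tcid50_per_ml) {
  if (tcid50_per_ml <= 0) stop("tcid50_per_ml must be > 0", call. = FALSE)
  stopifnot(moi >= 0, cell_number > 0)
  (moi * cell_number) / (0.69 * tcid50_per_ml)
}

#' Virus amplification factor
#'
#' Ratio of the harvested to the infecting titer — how much the virus
#' multiplied during an amplification passage.
#'
#' @param harvest_titer,infection_titer Titers in the same units (> 0).
#' @return Dimensionless factor.
#' @export
amplification_factor <- function(harvest_titer, infection_titer) {
  if (any(infection_titer <= 0)) {
    stop("infection titer must be > 0", call. = FALSE)
  }
  stopifnot(all(harvest_titer > 0))
  harvest_titer / infection_titer
}
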
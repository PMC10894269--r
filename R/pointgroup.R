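#' Construct a point group for reflection merging
#'
#' Builds the full set of 3x3 integer operators acting on (h, k, l) for the
#' common centrosymmetric merging point groups by closing a small generator
#' set under composition. Trigonal/hexagonal groups use hexagonal-axis
#' index conventions.
#'
#' @param name One of `"1"`, `"-1"`, `"2/m"`, `"mmm"`, `"4/m"`, `"4/mmm"`,
#'   `"-3"`, `"6/m"`, `"6/mmm"`, `"m-3"`; or `"custom"` together with
#'   `generators`.
#' @param friedel Add the inversion (Friedel) operator if absent
#'   (default TRUE; all named groups except `"1"` already contain it).
#' @param generators For `name = "custom"`: list of 3x3 integer matrices.
#' @return Object of class `point_group`: `name`, `ops` (list of 3x3
#'   integer matrices, identity first), `friedel`.
#' @examples
#' pg <- point_group("6/m")
#' length(pg$ops)  # 12
#' @export
point_group <- function(name = c("1", "-1", "2/m", "mmm", "4/m", "4/mmm",
                                 "-3", "6/m", "6/mmm", "m-3", "custom"),
                        friedel = TRUE, generators = NULL) {
  name <- match.arg(name)
  m <- function(...) matrix(as.integer(c(...)), 3, 3, byrow = TRUE)
  inv <- m(-1, 0, 0, 0, -1, 0, 0, 0, -1)
  two_z <- m(-1, 0, 0, 0, -1, 0, 0, 0, 1)
  two_y <- m(-1, 0, 0, 0, 1, 0, 0, 0, -1)
  two_x <- m(1, 0, 0, 0, -1, 0, 0, 0, -1)
  four_z <- m(0, -1, 0, 1, 0, 0, 0, 0, 1)     # (h,k,l) -> (-k, h, l)
  three_z_hex <- m(0, 1, 0, -1, -1, 0, 0, 0, 1) # (h,k,l) -> (k, -h-k, l)
  six_z_hex <- m(0, -1, 0, 1, 1, 0, 0, 0, 1)  # (h,k,l) -> (-k, h+k, l)
  two_hex_110 <- m(0, 1, 0, 1, 0, 0, 0, 0, -1) # (h,k,l) -> (k, h, -l)
  three_111 <- m(0, 0, 1, 1, 0, 0, 0, 1, 0)   # (h,k,l) -> (l, h, k)
  gens <- switch(name,
    "1" = list(),
    "-1" = list(inv),
    "2/m" = list(two_y, inv),
    "mmm" = list(two_z, two_y, inv),
    "4/m" = list(four_z, inv),
    "4/mmm" = list(four_z, two_x, inv),
    "-3" = list(three_z_hex, inv),
    "6/m" = list(six_z_hex, inv),
    "6/mmm" = list(six_z_hex, two_hex_110, inv),
    "m-3" = list(three_111, two_z, two_x, inv),
    "custom" = {
      if (is.null(generators)) {
        stop("custom point group needs generators", call. = FALSE)
      }
      lapply(generators, function(g) matrix(as.integer(g), 3, 3))
    })
  ops <- close_group(c(list(diag(3L)), gens))
  has_inv <- any(vapply(ops, function(o) all(o == inv), logical(1)))
  if (friedel && !has_inv) {
    ops <- close_group(c(ops, list(inv)))
    has_inv <- TRUE
  }
  structure(list(name = name, ops = ops, friedel = has_inv),
            class = "point_group")
}

# close a set of integer matrices under multiplication
close_group <- function(ops) {
  key <- function(o) paste(o, collapse = ",")
  seen <- new.env(parent = emptyenv())
  queue <- ops
  out <- list()
  for (o in queue) {
    k <- key(o)
    if (!exists(k, envir = seen)) {
      assign(k, TRUE, envir = seen)
      out <- c(out, list(o))
    }
  }
  repeat {
    added <- FALSE
    for (a in out) {
      for (b in out) {
        p <- a %*% b
        k <- key(p)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          out <- c(out, list(p))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  if (length(out) > 192) {
    stop("operator set did not close to a crystallographic group",
         call. = FALSE)
  }
  out
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("<point_group> %s: %d operators%s\n", x$name, length(x$ops),
              if (x$friedel) " (Friedel)" else ""))
  invisible(x)
}

#' Map reflections to the asymmetric-unit representative
#'
#' The representative of an orbit is the lexicographically greatest
#' (h, then k, then l) image over all point-group operators (including
#' Friedel mates when the group is centrosymmetric). Deterministic;
#' vectorised over reflections.
#'
#' @param h,k,l Integer Miller indices (vectorised).
#' @param pg A [point_group()].
#' @return Tibble with columns `h`, `k`, `l` of the representatives.
#' @export
map_to_asu <- function(h, k, l, pg) {
  hkl <- cbind(h, k, l)
  best <- hkl %*% t(pg$ops[[1]])
  for (op in pg$ops[-1]) {
    cand <- hkl %*% t(op)
    better <- cand[, 1] > best[, 1] |
      (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
      (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] &
         cand[, 3] > best[, 3])
    best[better, ] <- cand[better, , drop = FALSE]
  }
  tibble(h = as.integer(best[, 1]), k = as.integer(best[, 2]),
         l = as.integer(best[, 3]))
}
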
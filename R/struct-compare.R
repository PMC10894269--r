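#' Build a C-alpha coordinate set
#'
#' @param chain Chain identifiers (character).
#' @param resno Residue numbers (integer); (chain, resno) must be unique.
#' @param resname Residue names.
#' @param x,y,z Coordinates in Angstrom (finite).
#' @return Tibble of class `calpha_set`.
#' @export
calpha_set <- function(chain, resno, resname, x, y, z) {
  out <- tibble(chain = as.character(chain), resno = as.integer(resno),
                resname = as.character(resname),
                x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (anyDuplicated(out[c("chain", "resno")])) {
    stop("(chain, residue number) pairs must be unique", call. = FALSE)
  }
  if (!all(is.finite(c(out$x, out$y, out$z)))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  class(out) <- c("calpha_set", class(out))
  out
}

#' Read C-alpha atoms from a PDB or mmCIF file
#'
#' Extracts atoms named CA via bio3d; at alternate locations the highest
#' occupancy wins, ties broken toward altloc 'A'.
#'
#' @param path Coordinate file (.pdb or .cif).
#' @param chains Optional chain subset.
#' @return A [calpha_set()].
#' @export
read_calpha <- function(path, chains = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading coordinate files requires the bio3d package",
         call. = FALSE)
  }
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  at <- at[at$elety == "CA" & !is.na(at$resno), ]
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  if (!is.null(at$alt)) {
    occ <- if (!is.null(at$o)) at$o else rep(1, nrow(at))
    alt <- ifelse(is.na(at$alt) | at$alt == "", "A", at$alt)
    ord <- order(at$chain, at$resno, -occ, alt)
    at <- at[ord, ]
    at <- at[!duplicated(at[c("chain", "resno")]), ]
  }
  calpha_set(at$chain, at$resno, at$resid, at$x, at$y, at$z)
}

#' Pair residues common to two C-alpha sets
#'
#' Matches on the (chain, residue number) intersection; an optional
#' residue-number offset applied to B restores pairing of shifted
#' numbering.
#'
#' @param A,B [calpha_set()]s.
#' @param offset Added to B's residue numbers before matching (default 0).
#' @return List: `pairs` (tibble `chain`, `resno`, `i` index into A, `j`
#'   index into B), `unmatched_a`, `unmatched_b` (counts).
#' @export
pair_by_residue <- function(A, B, offset = 0L) {
  keyA <- paste(A$chain, A$resno)
  keyB <- paste(B$chain, B$resno + offset)
  j <- match(keyA, keyB)
  sel <- which(!is.na(j))
  if (!length(sel)) {
    stop("no residues in common between the two sets", call. = FALSE)
  }
  list(pairs = tibble(chain = A$chain[sel], resno = A$resno[sel],
                      i = sel, j = j[sel]),
       unmatched_a = nrow(A) - length(sel),
       unmatched_b = nrow(B) - length(sel))
}

# Kabsch: optimal proper rotation R and translation t minimising
# ||A - (B R^T + t)||; returns list(R, t)
kabsch <- function(Axyz, Bxyz) {
  ca <- colMeans(Axyz); cb <- colMeans(Bxyz)
  A0 <- sweep(Axyz, 2, ca); B0 <- sweep(Bxyz, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ca - as.numeric(R %*% cb)
  list(R = R, t = t)
}

#' Least-squares rigid-body superposition of two C-alpha sets
#'
#' Superposes B onto A over the given residue pairs (Kabsch algorithm,
#' proper rotation) and reports the RMSD after the fit.
#'
#' @param A,B [calpha_set()]s.
#' @param pairs Result of [pair_by_residue()] (computed if `NULL`).
#' @return Object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom), `n_pairs`, `pairs`,
#'   `B_fitted` (B transformed onto A's frame), and `deviations`
#'   (per-residue distances).
#' @export
superpose <- function(A, B, pairs = NULL) {
  if (is.null(pairs)) pairs <- pair_by_residue(A, B)
  p <- pairs$pairs
  if (nrow(p) < 3) stop("need at least 3 residue pairs", call. = FALSE)
  Axyz <- as.matrix(A[p$i, c("x", "y", "z")])
  Bxyz <- as.matrix(B[p$j, c("x", "y", "z")])
  # collinearity check via the rank of the centered coordinates
  sv0 <- svd(sweep(Axyz, 2, colMeans(Axyz)))$d
  if (sv0[2] < 1e-8 * max(sv0[1], 1)) {
    stop("paired atoms are collinear; superposition is degenerate",
         call. = FALSE)
  }
  kt <- kabsch(Axyz, Bxyz)
  Ball <- as.matrix(B[, c("x", "y", "z")])
  Bfit <- sweep(Ball %*% t(kt$R), 2, kt$t, "+")
  dev <- sqrt(rowSums((Axyz - Bfit[p$j, , drop = FALSE])^2))
  Bf <- B
  Bf$x <- Bfit[, 1]; Bf$y <- Bfit[, 2]; Bf$z <- Bfit[, 3]
  structure(list(rotation = kt$R, translation = kt$t,
                 rmsd = sqrt(mean(dev^2)), n_pairs = nrow(p),
                 pairs = p, B_fitted = Bf,
                 deviations = tibble(chain = p$chain, resno = p$resno,
                                     deviation_A = dev)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d C-alpha pairs, rmsd %.3f A\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Per-residue deviations after superposition
#'
#' Per-pair Euclidean C-alpha distance after the global fit; an optional
#' residue window returns the maximum deviation within it — e.g. to
#' quantify a flexible loop against an otherwise well-agreeing structure.
#'
#' @param fit A [superpose()] result.
#' @param window Optional length-2 residue-number range (inclusive).
#' @param chain Restrict the window to one chain (default: all).
#' @return Without `window`: tibble `chain`, `resno`, `deviation_A`.
#'   With `window`: list with the windowed tibble and `max_deviation_A`.
#' @export
per_residue_deviation <- function(fit, window = NULL, chain = NULL) {
  dev <- fit$deviations
  if (is.null(window)) return(dev)
  stopifnot(length(window) == 2)
  sel <- dev$resno >= window[1] & dev$resno <= window[2]
  if (!is.null(chain)) sel <- sel & dev$chain %in% chain
  if (!any(sel)) {
    stop("residue window contains no paired residues", call. = FALSE)
  }
  list(deviations = dev[sel, ], max_deviation_A = max(dev$deviation_A[sel]))
}
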
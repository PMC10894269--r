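#' Construct a unit cell
#'
#' A unit cell holds the six lattice parameters together with the lattice
#' type, centering and (where defined) the unique axis. Lengths are in
#' Angstrom, angles in degrees.
#'
#' @param a,b,c Axis lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180). The
#'   triple must define a positive-definite metric tensor.
#' @param lattice_type One of `"triclinic"`, `"monoclinic"`, `"orthorhombic"`,
#'   `"tetragonal"`, `"trigonal"`, `"hexagonal"`, `"cubic"`.
#' @param centering Lattice centering symbol, one of `P A B C I F H`.
#' @param unique_axis Unique-axis label `"a"`, `"b"`, `"c"` or `"none"`.
#'   Defaults to `"c"` for tetragonal/trigonal/hexagonal lattices, `"b"` for
#'   monoclinic, `"none"` otherwise.
#' @return An object of class `unit_cell`.
#' @examples
#' uc <- unit_cell(90, 90, 170, 90, 90, 120, "hexagonal", "P")
#' d_spacing(1, 0, 0, uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      lattice_type = "triclinic", centering = "P",
                      unique_axis = NULL) {
  lattice_type <- match.arg(lattice_type,
    c("triclinic", "monoclinic", "orthorhombic", "tetragonal",
      "trigonal", "hexagonal", "cubic"))
  centering <- match.arg(centering, c("P", "A", "B", "C", "I", "F", "H"))
  if (is.null(unique_axis)) {
    unique_axis <- switch(lattice_type,
      tetragonal = , trigonal = , hexagonal = "c",
      monoclinic = "b",
      "none")
  }
  unique_axis <- match.arg(unique_axis, c("a", "b", "c", "none"))
  lengths <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("unit cell axis lengths must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         lattice_type = lattice_type, centering = centering,
         unique_axis = unique_axis),
    class = "unit_cell")
  G <- metric_tensor(cell)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("cell parameters do not define a positive-definite metric tensor",
         call. = FALSE)
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %s %s  a=%.3f b=%.3f c=%.3f A  al=%.2f be=%.2f ga=%.2f deg  unique axis %s\n",
              x$lattice_type, x$centering, x$a, x$b, x$c,
              x$alpha, x$beta, x$gamma, x$unique_axis))
  invisible(x)
}

#' Real-space metric tensor of a unit cell
#'
#' @param cell A [unit_cell()].
#' @return 3x3 symmetric matrix G with G[i,j] = a_i . a_j in Angstrom^2.
#' @export
metric_tensor <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r)
  with(cell, matrix(c(
    a * a,      a * b * cg, a * c * cb,
    a * b * cg, b * b,      b * c * ca,
    a * c * cb, b * c * ca, c * c), 3, 3, byrow = TRUE))
}

#' Real-space basis vectors of a unit cell
#'
#' Rows are a, b, c in a standard Cartesian frame (a along x, b in the xy
#' plane), in Angstrom.
#'
#' @param cell A [unit_cell()].
#' @return 3x3 matrix, rows a, b, c.
#' @export
cell_vectors <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r); sg <- sin(cell$gamma * d2r)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz <- sqrt(max(cell$c^2 - cx^2 - cy^2, 0))
  rbind(a = c(cell$a, 0, 0),
        b = c(cell$b * cg, cell$b * sg, 0),
        c = c(cx, cy, cz))
}

#' Reciprocal basis vectors of a unit cell
#'
#' @param cell A [unit_cell()].
#' @param unit `"A^-1"` (default) or `"nm^-1"`.
#' @return 3x3 matrix, rows a*, b*, c* (no 2*pi factor).
#' @export
reciprocal_vectors <- function(cell, unit = c("A^-1", "nm^-1")) {
  unit <- match.arg(unit)
  A <- cell_vectors(cell)
  R <- t(solve(A))            # rows a*, b*, c* in A^-1
  rownames(R) <- c("astar", "bstar", "cstar")
  if (unit == "nm^-1") R <- R * 10
  R
}

#' Lattice-plane spacing d(hkl)
#'
#' Computes d = 1 / |h a* + k b* + l c*| for one or more reflections.
#' Vectorised over `h`, `k`, `l`.
#'
#' @param h,k,l Integer Miller indices; (0,0,0) is an error.
#' @param cell A [unit_cell()].
#' @return d-spacings in Angstrom.
#' @examples
#' d_spacing(1, 0, 0, unit_cell(10, 10, 10, lattice_type = "cubic"))
#' @export
d_spacing <- function(h, k, l, cell) {
  if (any(h == 0 & k == 0 & l == 0)) {
    stop("d_spacing is undefined for (0,0,0)", call. = FALSE)
  }
  R <- reciprocal_vectors(cell)
  q <- cbind(h, k, l) %*% R
  1 / sqrt(rowSums(q * q))
}

#' Recover cell lengths and angles from a reciprocal orientation matrix
#'
#' Inverts a reciprocal basis (rows a*, b*, c*, nm^-1, as carried per crystal
#' in a stream file) back to real-space lattice parameters in Angstrom.
#'
#' @param orientation 3x3 matrix, rows a*, b*, c* in nm^-1.
#' @return Named list a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @export
cell_from_orientation <- function(orientation) {
  stopifnot(is.matrix(orientation), all(dim(orientation) == c(3, 3)))
  if (abs(det(orientation)) < 1e-12) {
    stop("reciprocal orientation matrix is singular", call. = FALSE)
  }
  A <- unname(t(solve(orientation))) * 10   # rows a, b, c in Angstrom
  len <- sqrt(rowSums(A * A))
  ang <- function(u, v) {
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  list(a = len[1], b = len[2], c = len[3],
       alpha = ang(A[2, ], A[3, ]), beta = ang(A[1, ], A[3, ]),
       gamma = ang(A[1, ], A[2, ]))
}

#' Test whether a cell matches a reference within tolerances
#'
#' Axis lengths are compared relatively, angles absolutely. Used by
#' [split_by_cell()] to separate unit-cell populations (e.g. polymorphs
#' differing in the c axis).
#'
#' @param cell,reference [unit_cell()] objects.
#' @param axis_rel_tol Relative tolerance on a, b, c (default 0.05).
#' @param angle_abs_tol Absolute tolerance on angles in degrees (default 1.5).
#' @return Logical scalar.
#' @export
cells_match <- function(cell, reference, axis_rel_tol = 0.05,
                        angle_abs_tol = 1.5) {
  stopifnot(axis_rel_tol > 0, angle_abs_tol > 0)
  ax <- c(cell$a, cell$b, cell$c); rx <- c(reference$a, reference$b, reference$c)
  an <- c(cell$alpha, cell$beta, cell$gamma)
  rn <- c(reference$alpha, reference$beta, reference$gamma)
  all(abs(ax - rx) / rx <= axis_rel_tol) && all(abs(an - rn) <= angle_abs_tol)
}

#' Build an orientation matrix for a cell, optionally rotated
#'
#' Returns the reciprocal basis of `cell` (rows a*, b*, c*, nm^-1) after
#' applying a Cartesian rotation matrix.
#'
#' @param cell A [unit_cell()].
#' @param rotation 3x3 proper rotation matrix (default identity).
#' @return 3x3 orientation matrix.
#' @export
orientation_matrix <- function(cell, rotation = diag(3)) {
  reciprocal_vectors(cell, unit = "nm^-1") %*% t(rotation)
}

# Rotation about a unit axis by angle degrees (Rodrigues).
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation matrix (via QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}
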
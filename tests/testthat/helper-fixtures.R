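# shared fixtures, all generated in code

hex_cell <- function() {
  unit_cell(90, 90, 170, 90, 90, 120, "hexagonal", "P")
}

cubic_cell <- function(a = 10) {
  unit_cell(a, a, a, lattice_type = "cubic")
}

# a random valid triclinic cell (rejection-sampled for a positive-definite
# metric)
random_triclinic <- function() {
  repeat {
    cl <- try(unit_cell(runif(1, 8, 40), runif(1, 8, 40), runif(1, 8, 40),
                        runif(1, 70, 110), runif(1, 70, 110),
                        runif(1, 70, 110)),
              silent = TRUE)
    if (!inherits(cl, "try-error")) return(cl)
  }
}

# small reflection tibble with values at printed precision
rand_reflections <- function(n) {
  tibble::tibble(
    h = sample(-9:9, n, replace = TRUE),
    k = sample(-9:9, n, replace = TRUE),
    l = sample(1:9, n, replace = TRUE),
    intensity = round(runif(n, -50, 5000), 2),
    sigma = round(runif(n, 0, 100), 2),
    peak = round(runif(n, 1, 9000), 2),
    background = round(runif(n, 0, 30), 2),
    fs = round(runif(n, 0, 4000), 1),
    ss = round(runif(n, 0, 4000), 1),
    panel = sample(c("p0", "p1"), n, replace = TRUE))
}

# random dataset whose numeric fields sit exactly at the stream dialect's
# printed precision, so write -> read must reproduce them bit-identically
rand_dataset <- function(seed, max_chunks = 3) {
  set.seed(seed)
  n_ch <- sample.int(max_chunks, 1)
  chunks <- lapply(seq_len(n_ch) - 1L, function(f) {
    n_cr <- sample(0:2, 1)
    crystals <- lapply(seq_len(n_cr), function(j) {
      cl <- unit_cell(round(runif(1, 10, 200), 4), round(runif(1, 10, 200), 4),
                      round(runif(1, 10, 200), 4), round(runif(1, 80, 100), 5),
                      round(runif(1, 80, 100), 5), round(runif(1, 80, 100), 5))
      orient <- round(orientation_matrix(cl, random_rotation_test()), 7)
      crystal_record(cl, orientation = orient,
                     resolution_limit = round(runif(1, 1.5, 4), 4),
                     reflections = rand_reflections(sample(0:5, 1)))
    })
    stream_chunk(frame_index = f, image_id = sprintf("img_%03d.h5", f),
                 event_id = sprintf("//%d", f),
                 n_peaks = sample(0:200, 1), crystals = crystals)
  })
  stream_dataset(chunks = chunks, header = c("test stream", "dialect 1"))
}

random_rotation_test <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# all numeric fields of two datasets equal (exactly)
expect_dataset_equal <- function(d1, d2) {
  expect_equal(n_chunks(d1), n_chunks(d2))
  expect_equal(tidy(d1), tidy(d2))
  t1 <- crystals_table(d1); t2 <- crystals_table(d2)
  expect_equal(as.data.frame(t1), as.data.frame(t2), tolerance = 1e-12)
  r1 <- reflections_table(d1); r2 <- reflections_table(d2)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
  o1 <- lapply(d1$chunks, function(ch) lapply(ch$crystals, `[[`, "orientation"))
  o2 <- lapply(d2$chunks, function(ch) lapply(ch$crystals, `[[`, "orientation"))
  expect_equal(o1, o2, tolerance = 1e-12)
}

# hand-written two-chunk stream in the documented dialect
hand_stream_lines <- function() {
  c("test header line",
    "----- Begin chunk -----",
    "Image filename: a.h5",
    "Event: //0",
    "num_peaks = 4",
    "----- End chunk -----",
    "----- Begin chunk -----",
    "Image filename: b.h5",
    "Event: //1",
    "num_peaks = 37",
    "--- Begin crystal",
    "Cell parameters 9.00000 9.00000 17.00000 nm, 90.00000 90.00000 120.00000 deg",
    "astar = +0.1111111 +0.0641500 +0.0000000 nm^-1",
    "bstar = +0.0000000 +0.1283001 +0.0000000 nm^-1",
    "cstar = +0.0000000 +0.0000000 +0.0588235 nm^-1",
    "lattice_type = hexagonal",
    "centering = P",
    "unique_axis = c",
    "diffraction_resolution_limit = 4.0000 nm^-1 or 2.5000 A",
    "Reflections measured after indexing",
    "   h    k    l          I   sigma(I)       peak background  fs/px  ss/px panel",
    "   1    0    0     120.50       4.20     300.00      12.00  100.0  200.0 p0",
    "   0    1    0      80.25       3.10     210.00      11.50  150.0  250.0 p0",
    "  -1    1    2      42.00       2.00      90.00      10.00  300.0  400.0 p1",
    "End of reflections",
    "--- End crystal",
    "----- End chunk -----")
}

# synthetic helix-like C-alpha trace
synthetic_calpha <- function(n = 40, chain = "A", seed = 1) {
  set.seed(seed)
  t <- seq_len(n)
  calpha_set(chain = rep(chain, n), resno = t, resname = rep("ALA", n),
             x = 2.3 * cos(t / 1.75) + rnorm(n, 0, 0.05),
             y = 2.3 * sin(t / 1.75) + rnorm(n, 0, 0.05),
             z = 1.5 * t + rnorm(n, 0, 0.05))
}

# apply a rigid motion (rotation R then translation t) to a calpha_set
apply_rigid <- function(A, R, t) {
  xyz <- as.matrix(A[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  B <- A; B$x <- xyz[, 1]; B$y <- xyz[, 2]; B$z <- xyz[, 3]
  B
}
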
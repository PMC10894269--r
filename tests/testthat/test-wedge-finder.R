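test_that("frame_to_position follows the serpentine path", {
  geo <- scan_geometry(5, 4, rot_per_frame = 0.2, serpentine = TRUE,
                       h_step = 10, v_step = 8)
  p0 <- frame_to_position(0, geo)
  expect_equal(p0$line, 0)
  expect_equal(p0$index_in_line, 0)
  expect_equal(p0$rotation_deg, 0)
  # frame 7 on line 1 (odd): acquisition index 2, spatial position counted
  # from the far end
  p7 <- frame_to_position(7, geo)
  expect_equal(p7$line, 1)
  expect_equal(p7$index_in_line, 2)
  expect_equal(p7$position_in_line, 5 - 1 - 2)
  expect_equal(p7$rotation_deg, -0.4)   # rotation inverts on odd lines
  # last frame of line 0 and first of line 1: same x extremity, adjacent y
  pa <- frame_to_position(4, geo); pb <- frame_to_position(5, geo)
  expect_equal(pa$x_um, pb$x_um)
  expect_equal(pb$y_um - pa$y_um, 8)
  expect_error(frame_to_position(20, geo), "outside")
})

test_that("find_centers returns plateau-aware local maxima above threshold, within lines", {
  geo <- scan_geometry(6, 2)
  fs <- frame_series(c(0, 0, 5, 20, 7, 0,  0, 0, 0, 0, 0, 0), geo)
  expect_equal(find_centers(fs, 3), 3)
  expect_equal(find_centers(frame_series(rep(0, 12), geo), 3), integer(0))
  # plateau yields its earliest frame
  fs2 <- frame_series(c(0, 5, 5, 0, 0, 0,  0, 0, 0, 0, 0, 0), geo)
  expect_equal(find_centers(fs2, 3), 1)
  # brute-force oracle on random series
  set.seed(21)
  geo2 <- scan_geometry(20, 3)
  for (rep in 1:20) {
    counts <- rpois(60, 6)
    got <- find_centers(frame_series(counts, geo2), 5)
    oracle <- c()
    for (f in 0:59) {
      line <- f %/% 20
      if (counts[f + 1] < 5) next
      # strictly greater than the nearest non-equal neighbours on this line
      left <- f - 1
      while (left >= line * 20 && counts[left + 1] == counts[f + 1]) left <- left - 1
      right <- f + 1
      while (right <= line * 20 + 19 && counts[right + 1] == counts[f + 1]) right <- right + 1
      ok_l <- left < line * 20 || counts[left + 1] < counts[f + 1]
      ok_r <- right > line * 20 + 19 || counts[right + 1] < counts[f + 1]
      # earliest frame of its plateau
      first_of_plateau <- f == line * 20 || counts[f] != counts[f + 1]
      if (ok_l && ok_r && first_of_plateau) oracle <- c(oracle, f)
    }
    expect_equal(got, as.integer(oracle))
  }
})

test_that("grow_wedge extends while counts stay above min_spots and stops at line edges", {
  geo <- scan_geometry(7, 1)
  fs <- frame_series(c(2, 8, 15, 30, 12, 9, 1), geo)
  w <- grow_wedge(3, fs, min_spots = 5)
  expect_equal(c(w$start_frame, w$end_frame), c(1, 5))
  expect_equal(w$n_frames, 5)
  expect_equal(w$rotation_range_deg, 5 * geo$rot_per_frame)
  expect_true(w$start_frame <= w$center_frame &&
                w$center_frame <= w$end_frame)
  expect_error(grow_wedge(0, fs, min_spots = 5), "below min_spots")
  # a center at a line edge never crosses the boundary
  geo2 <- scan_geometry(4, 2)
  fs2 <- frame_series(c(9, 30, 30, 30, 30, 30, 9, 0), geo2)
  w2 <- grow_wedge(3, fs2, min_spots = 5)
  expect_equal(w2$end_frame, 3)   # line 0 ends at frame 3
})

test_that("the stronger center claims shared frames; wedges are frame-disjoint within lines", {
  geo <- scan_geometry(12, 1)
  # two bumps sharing qualifying middle frames
  counts <- c(1, 20, 40, 20, 15, 14, 20, 60, 20, 1, 0, 0)
  fs <- frame_series(counts, geo)
  wedges <- find_wedges(fs, min_center_count = 20, min_spots = 10)
  expect_equal(nrow(wedges), 2)
  strong <- wedges[wedges$center_frame == 7, ]
  weak <- wedges[wedges$center_frame == 2, ]
  # the stronger wedge reached through the shared plateau first
  expect_equal(c(strong$start_frame, strong$end_frame), c(3, 8))
  expect_equal(c(weak$start_frame, weak$end_frame), c(1, 2))
  # disjoint frames
  f1 <- seq(wedges$start_frame[1], wedges$end_frame[1])
  f2 <- seq(wedges$start_frame[2], wedges$end_frame[2])
  expect_length(intersect(f1, f2), 0)
})

test_that("raising min_spots never lengthens a wedge grown in isolation", {
  set.seed(31)
  geo <- scan_geometry(30, 2)
  for (rep in 1:10) {
    counts <- rpois(60, 8) + ifelse(runif(60) < 0.1, 40, 0)
    fs <- frame_series(counts, geo)
    centers <- find_centers(fs, 20)
    for (cf in centers) {
      w_lo <- grow_wedge(cf, fs, min_spots = 5)
      w_hi <- grow_wedge(cf, fs, min_spots = 12)
      expect_lte(w_hi$n_frames, w_lo$n_frames)
      expect_gte(w_hi$start_frame, w_lo$start_frame)
      expect_lte(w_hi$end_frame, w_lo$end_frame)
    }
  }
})

test_that("unique_axis_angle measures folded axis angles", {
  cl <- hex_cell()
  o1 <- orientation_matrix(cl)
  expect_equal(unique_axis_angle(o1, o1, "c*"), 0)
  # antiparallel c* folds to zero
  o_flip <- orientation_matrix(cl, diag(c(1, -1, -1)))
  expect_equal(unique_axis_angle(o1, o_flip, "c*"), 0, tolerance = 1e-9)
  # rotation by 10 degrees about an axis perpendicular to c*
  cstar <- o1[3, ]
  perp <- c(cstar[3], 0, -cstar[1])
  if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
  R <- incellproc:::rotation_about(perp, 10)
  o2 <- o1 %*% t(R)
  expect_equal(unique_axis_angle(o1, o2, "c*"), 10, tolerance = 1e-9)
  expect_error(unique_axis_angle(o1, o1, "q*"), "axis_label")
  o_bad <- o1; o_bad[3, ] <- 0
  expect_error(unique_axis_angle(o1, o_bad, "c*"), "zero-length")
})

test_that("wedges_overlap handles frame and spatial modes", {
  geo <- scan_geometry(10, 3, h_step = 10, v_step = 8)
  w <- function(s, e) tibble::tibble(start_frame = s, end_frame = e)
  expect_true(wedges_overlap(w(3, 7), w(6, 9), geo, "frames"))
  expect_false(wedges_overlap(w(3, 5), w(6, 9), geo, "frames"))
  # vertically adjacent frames on neighbouring lines (serpentine): frame 2
  # on line 0 is at x = 20; on line 1 the same x is frame 17
  expect_false(wedges_overlap(w(1, 3), w(16, 18), geo, "frames"))
  expect_true(wedges_overlap(w(1, 3), w(16, 18), geo, "spatial"))
  expect_error(wedges_overlap(w(1, 3), w(4, 5), geo, "bogus"))
})

test_that("deduplication merges overlapping wedges below the angle threshold", {
  geo <- scan_geometry(20, 1)
  cl <- hex_cell()
  o <- orientation_matrix(cl)
  rot_c <- function(deg) {
    ax <- c(0, 1, 0)
    o %*% t(incellproc:::rotation_about(ax, deg))
  }
  wedges <- tibble::tibble(wedge_id = 1:2, line = 0L,
                           start_frame = c(2L, 6L), center_frame = c(4L, 8L),
                           end_frame = c(7L, 10L), n_frames = c(6L, 5L),
                           rotation_range_deg = c(0.6, 0.5))
  few <- deduplicate_crystals(wedges, list(o, rot_c(3)), geo)
  expect_equal(max(few$identities$identity_id), 1)
  far <- deduplicate_crystals(wedges, list(o, rot_c(10)), geo)
  expect_equal(max(far$identities$identity_id), 2)
})

test_that("identities are connected components: chain A-B-C merges without A-C overlap", {
  geo <- scan_geometry(30, 1)
  cl <- hex_cell()
  o <- orientation_matrix(cl)
  tilt <- function(deg) o %*% t(incellproc:::rotation_about(c(0, 1, 0), deg))
  wedges <- tibble::tibble(wedge_id = 1:3, line = 0L,
                           start_frame = c(0L, 4L, 9L),
                           center_frame = c(2L, 6L, 10L),
                           end_frame = c(5L, 10L, 12L),
                           n_frames = c(6L, 7L, 4L),
                           rotation_range_deg = 0.5)
  dd <- deduplicate_crystals(wedges, list(o, tilt(2), tilt(4)), geo)
  expect_equal(max(dd$identities$identity_id), 1)
  expect_equal(nrow(dd$identities), 3)
})

test_that("deduplication equals an independent union-find oracle on random instances", {
  set.seed(41)
  geo <- scan_geometry(50, 4)
  cl <- hex_cell()
  for (rep in 1:30) {
    nw <- sample(2:12, 1)
    starts <- sort(sample(0:190, nw))
    wedges <- tibble::tibble(
      wedge_id = seq_len(nw),
      line = as.integer(starts %/% 50),
      start_frame = as.integer(starts),
      center_frame = as.integer(pmin(starts + 1, (starts %/% 50) * 50 + 49)),
      end_frame = as.integer(pmin(starts + sample(2:9, nw, replace = TRUE),
                                  (starts %/% 50) * 50 + 49)),
      n_frames = 1L, rotation_range_deg = 0.1)
    orients <- lapply(seq_len(nw), function(i) {
      orientation_matrix(cl, random_rotation_test())
    })
    dd <- deduplicate_crystals(wedges, orients, geo, angle_threshold = 30)
    # oracle: igraph components over an independently built adjacency
    adj <- matrix(FALSE, nw, nw)
    for (i in seq_len(nw - 1)) for (j in (i + 1):nw) {
      ov <- wedges$start_frame[i] <= wedges$end_frame[j] &&
        wedges$start_frame[j] <= wedges$end_frame[i]
      if (!ov) next
      ci <- orients[[i]][3, ]; cj <- orients[[j]][3, ]
      ang <- acos(min(1, abs(sum(ci * cj)) /
                        sqrt(sum(ci^2) * sum(cj^2)))) * 180 / pi
      adj[i, j] <- adj[j, i] <- ang <= 30
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- as.integer(igraph::components(g)$membership)
    got <- dd$identities$identity_id[order(dd$identities$wedge_id)]
    # same partition up to labeling: canonicalise both by first occurrence
    expect_identical(as.integer(match(got, unique(got))),
                     match(comp, unique(comp)))
  }
})

test_that("wedges without orientation are excluded with a warning", {
  geo <- scan_geometry(20, 1)
  wedges <- tibble::tibble(wedge_id = 1:2, line = 0L,
                           start_frame = c(0L, 3L), center_frame = c(1L, 4L),
                           end_frame = c(2L, 6L), n_frames = 3L,
                           rotation_range_deg = 0.3)
  o <- orientation_matrix(hex_cell())
  expect_warning(dd <- deduplicate_crystals(wedges, list(o, NULL), geo),
                 "without orientation")
  expect_equal(dd$excluded, 2L)
  expect_equal(nrow(dd$identities), 1)
})

test_that("the wedge manifest reports frame ranges, angles and image ids", {
  geo <- scan_geometry(10, 2, rot_per_frame = 0.1)
  cl <- hex_cell()
  pgrp <- point_group("6/m")
  sim <- simulate_scan(geo, 2, cl, pgrp, noise_fraction = 0, seed = 5,
                       d_min = 30, obs_fraction = 0.5)
  fc <- find_crystals(sim$dataset, geo, min_center_count = 20, min_spots = 10)
  m <- fc$manifest
  expect_equal(nrow(m), nrow(fc$wedges))
  expect_equal(m$rotation_range_deg,
               (m$end_frame - m$start_frame + 1) * 0.1)
  expect_true(all(grepl("scan_", m$image_ids)))
  # empty identity list -> empty manifest
  empty <- export_wedges(fc$identities[0, ], fc$wedges, sim$dataset, geo)
  expect_equal(nrow(empty), 0)
  # missing frame -> error naming the frame
  short_ds <- stream_dataset(chunks = sim$dataset$chunks[1:3])
  expect_error(export_wedges(fc$identities, fc$wedges, short_ds, geo),
               "missing from dataset")
})

test_that("simulated scans are recovered: centers within one frame, identity count exact", {
  geo <- scan_geometry(60, 5, rot_per_frame = 0.1)
  cl <- hex_cell()
  pgrp <- point_group("6/m")
  sim <- simulate_scan(geo, 8, cl, pgrp, noise_fraction = 0.01, seed = 2,
                       d_min = 25, obs_fraction = 0.3)
  fc <- find_crystals(sim$dataset, geo, min_center_count = 20,
                      min_spots = 10, mode = "spatial")
  tr <- sim$truth$crystals
  for (i in seq_len(nrow(tr))) {
    expect_true(any(abs(fc$wedges$center_frame - tr$center_frame[i]) <= 1))
  }
  expect_equal(max(fc$identities$identity_id), nrow(tr))
})
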
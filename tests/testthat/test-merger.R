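simple_dataset <- function(refl_list, cell = cubic_cell(10)) {
  chunks <- lapply(seq_along(refl_list) - 1L, function(f) {
    stream_chunk(f, crystals = list(
      crystal_record(cell, reflections = refl_list[[f + 1L]])))
  })
  stream_dataset(chunks = chunks)
}

mk_refl <- function(h, k, l, intensity, sigma = 1) {
  tibble::tibble(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                 intensity = intensity, sigma = sigma, peak = intensity,
                 background = 5, fs = 1, ss = 1, panel = "p0")
}

test_that("asu mapping is deterministic and matches brute-force orbit enumeration", {
  pg1 <- point_group("-1")
  expect_equal(as.integer(map_to_asu(-1, -2, -3, pg1)), c(1L, 2L, 3L))
  pgid <- point_group("1", friedel = FALSE)
  expect_equal(as.integer(map_to_asu(-1, 2, -3, pgid)), c(-1L, 2L, -3L))
  pg6 <- point_group("6/m")
  set.seed(71)
  for (rep in 1:50) {
    hkl <- sample(-4:4, 3, replace = TRUE)
    if (all(hkl == 0)) hkl <- c(1, 0, 0)
    got <- as.integer(map_to_asu(hkl[1], hkl[2], hkl[3], pg6))
    # brute-force orbit, lexicographically greatest
    orbit <- t(vapply(pg6$ops, function(op) as.integer(op %*% hkl),
                      integer(3)))
    orbit <- orbit[order(-orbit[, 1], -orbit[, 2], -orbit[, 3]), ]
    expect_equal(got, orbit[1, ])
  }
})

test_that("every member of an operator orbit maps to the same representative", {
  for (pgname in c("-1", "2/m", "mmm", "4/m", "6/m", "m-3")) {
    pg <- point_group(pgname)
    set.seed(73)
    for (rep in 1:10) {
      hkl <- sample(-4:4, 3, replace = TRUE)
      if (all(hkl == 0)) hkl <- c(2, 1, 0)
      reps <- vapply(pg$ops, function(op) {
        img <- as.integer(op %*% hkl)
        paste(as.integer(map_to_asu(img[1], img[2], img[3], pg)),
              collapse = ",")
      }, character(1))
      expect_length(unique(reps), 1)
    }
  }
})

test_that("point groups close to the expected operator counts", {
  counts <- c("1" = 1, "-1" = 2, "2/m" = 4, "mmm" = 8, "4/m" = 8,
              "4/mmm" = 16, "-3" = 6, "6/m" = 12, "6/mmm" = 24, "m-3" = 24)
  for (nm in names(counts)) {
    expect_length(point_group(nm, friedel = FALSE)$ops, counts[[nm]])
  }
})

test_that("per-crystal scaling recovers exact and noisy scale ratios", {
  base <- mk_refl(1:5, 0, 0, c(10, 20, 30, 40, 50))
  twice <- base; twice$intensity <- base$intensity * 2
  twice$peak <- twice$intensity
  ds <- simple_dataset(list(base, twice))
  pg <- point_group("1", friedel = FALSE)
  sc <- scale_crystals(ds, pg)
  expect_equal(sc$scale[2] / sc$scale[1], 2, tolerance = 1e-9)
  expect_equal(mean(sc$scale), 1, tolerance = 1e-12)
  # single crystal: scale 1 by normalisation
  one <- scale_crystals(simple_dataset(list(base)), pg)
  expect_equal(one$scale, 1)
  # invariance under chunk order relabeling
  ds_rev <- simple_dataset(list(twice, base))
  sc_rev <- scale_crystals(ds_rev, pg)
  expect_equal(sort(sc_rev$scale), sort(sc$scale), tolerance = 1e-9)
})

test_that("a crystal sharing no reflections is flagged with scale 1", {
  a <- mk_refl(1:3, 0, 0, c(10, 20, 30))
  b <- a; b$intensity <- 3 * a$intensity
  lone <- mk_refl(0, 0, 1:2, c(7, 9))
  ds <- simple_dataset(list(a, b, lone))
  pg <- point_group("1", friedel = FALSE)
  sc <- scale_crystals(ds, pg)
  expect_true(sc$flagged[3])
  expect_equal(sc$scale[3], 1)
  expect_equal(sc$scale[2] / sc$scale[1], 3, tolerance = 1e-9)
})

test_that("merging averages scaled observations with the stated sigma model", {
  pg <- point_group("1", friedel = FALSE)
  one <- simple_dataset(list(mk_refl(1, 0, 0, 10, sigma = 1)))
  m1 <- merge_reflections(one, pg)
  expect_equal(m1$intensity, 10)
  expect_equal(m1$sigma, 1)
  expect_equal(m1$n_obs, 1L)
  two <- simple_dataset(list(mk_refl(1, 0, 0, 10), mk_refl(1, 0, 0, 12)))
  m2 <- merge_reflections(two, pg)
  expect_equal(m2$intensity, 11)
  expect_equal(m2$sigma, 1)   # sd sqrt(2) / sqrt(2)
  expect_equal(m2$n_obs, 2L)
  # invariance under chunk order permutation
  two_rev <- simple_dataset(list(mk_refl(1, 0, 0, 12), mk_refl(1, 0, 0, 10)))
  expect_equal(merge_reflections(two_rev, pg)$intensity, m2$intensity)
  expect_equal(merge_reflections(stream_dataset(), pg),
               merge_reflections(stream_dataset(), pg))
})

test_that("Rsplit and CC1/2 match hand arithmetic and are scale-invariant", {
  h1 <- tibble::tibble(h = 1L, k = 0L, l = 0L, intensity = 12)
  h2 <- tibble::tibble(h = 1L, k = 0L, l = 0L, intensity = 8)
  expect_equal(rsplit(h1, h2), 4 / 10 / sqrt(2), tolerance = 1e-9)
  expect_equal(rsplit(h1, h1), 0)
  # homogeneity: scaling both halves leaves Rsplit unchanged
  h1g <- h1; h1g$intensity <- h1$intensity * 7.3
  h2g <- h2; h2g$intensity <- h2$intensity * 7.3
  expect_equal(rsplit(h1g, h2g), rsplit(h1, h2))
  # CC1/2 hand cases
  a <- tibble::tibble(h = 1:3, k = 0L, l = 0L, intensity = c(1, 2, 3))
  b <- tibble::tibble(h = 1:3, k = 0L, l = 0L, intensity = c(3, 2, 1))
  expect_equal(cc_half(a, b), -1)
  expect_equal(cc_half(a, a), 1)
  flat <- tibble::tibble(h = 1:3, k = 0L, l = 0L, intensity = c(2, 2, 2))
  expect_warning(cc <- cc_half(a, flat), "zero variance")
  expect_true(is.na(cc))
  # degenerate Rsplit denominator
  z1 <- tibble::tibble(h = 1L, k = 0L, l = 0L, intensity = 5)
  z2 <- tibble::tibble(h = 1L, k = 0L, l = 0L, intensity = -5)
  expect_warning(rs <- rsplit(z1, z2), "zero intensity")
  expect_true(is.na(rs))
})

test_that("noise-free simulated data merge to Rsplit ~ 0, CC1/2 = 1, unbiased intensities", {
  cell <- hex_cell()
  pg <- point_group("6/m")
  geo <- scan_geometry(40, 4)
  sim <- simulate_scan(geo, 6, cell, pg, noise_fraction = 0, seed = 3,
                       d_min = 22, obs_fraction = 0.5)
  sc <- scale_crystals(sim$dataset, pg, n_rounds = 100, tol = 1e-14)
  halves <- merge_halves(sim$dataset, pg, sc)
  expect_lt(rsplit(halves$half1, halves$half2), 1e-6)
  expect_equal(cc_half(halves$half1, halves$half2), 1, tolerance = 1e-12)
  merged <- merge_reflections(sim$dataset, pg, sc)
  j <- dplyr::inner_join(merged, sim$truth$intensities,
                         by = c("h", "k", "l"))
  expect_gt(cor(j$intensity, j$intensity_true), 0.999)
})

test_that("Rsplit decreases and CC1/2 increases as simulated noise shrinks", {
  cell <- hex_cell()
  pg <- point_group("6/m")
  geo <- scan_geometry(40, 3)
  rs <- c(); cc <- c()
  for (nf in c(0.10, 0.05, 0.01)) {
    sim <- simulate_scan(geo, 6, cell, pg, noise_fraction = nf, seed = 8,
                         d_min = 22, obs_fraction = 0.5)
    sc <- scale_crystals(sim$dataset, pg, n_rounds = 10)
    halves <- merge_halves(sim$dataset, pg, sc)
    rs <- c(rs, rsplit(halves$half1, halves$half2))
    cc <- c(cc, cc_half(halves$half1, halves$half2))
  }
  expect_true(all(diff(rs) < 0))
  expect_true(all(diff(cc) > 0))
})

test_that("completeness equals brute-force enumeration of the asu", {
  cell <- cubic_cell(10)
  pg <- point_group("-1")
  d_min <- 3
  possible <- incellproc:::enumerate_asu(pg, cell, d_min)
  # full synthetic dataset covering every asu reflection once
  refl <- mk_refl(possible$h, possible$k, possible$l, 100)
  ds <- simple_dataset(list(refl), cell)
  merged <- merge_reflections(ds, pg)
  comp <- completeness(merged, pg, cell, d_min)
  expect_equal(comp$completeness_pct, 100)
  expect_equal(comp$redundancy, 1)
  # deleting every second unique reflection halves it (brute-force count)
  half_idx <- seq(1, nrow(merged), by = 2)
  comp2 <- completeness(merged[half_idx, ], pg, cell, d_min)
  expect_equal(comp2$completeness_pct,
               100 * length(half_idx) / nrow(possible))
  empty <- merge_reflections(stream_dataset(), pg)
  expect_equal(completeness(empty, pg, cell, d_min)$completeness_pct, 0)
})

test_that("shell tables partition unique reflections and match recomputation", {
  cell <- hex_cell()
  pg <- point_group("6/m")
  geo <- scan_geometry(40, 4)
  sim <- simulate_scan(geo, 6, cell, pg, noise_fraction = 0.05, seed = 4,
                       d_min = 20, obs_fraction = 0.6)
  st <- shell_stats(sim$dataset, pg, cell, n_shells = 5, d_min = 20)
  per_shell <- tidy(st)
  overall <- glance(st)
  expect_equal(sum(per_shell$n_unique), overall$n_unique)
  # one shell equals the overall row
  st1 <- shell_stats(sim$dataset, pg, cell, n_shells = 1, d_min = 20)
  expect_equal(tidy(st1)$rsplit, glance(st1)$rsplit)
  expect_equal(tidy(st1)$n_unique, glance(st1)$n_unique)
  # per-shell n_unique matches an independent brute-force recount
  obs <- observations(sim$dataset, pg)
  obs$d <- d_spacing(obs$h, obs$k, obs$l, cell)
  obs <- obs[obs$d >= 20, ]
  for (i in seq_len(nrow(per_shell))) {
    sel <- obs$d <= per_shell$d_max[i] & obs$d > per_shell$d_min[i]
    n_uni <- nrow(unique(obs[sel, c("h", "k", "l")]))
    expect_equal(per_shell$n_unique[i], n_uni)
  }
  expect_true(all(per_shell$completeness_pct >= 0 &
                    per_shell$completeness_pct <= 100))
})

test_that("diffraction power slices report per-part mean and best limits", {
  cell <- cubic_cell(10)
  mk_ch <- function(f, lim) {
    stream_chunk(f, crystals = list(crystal_record(cell,
                                                   resolution_limit = lim)))
  }
  ds <- stream_dataset(chunks = list(mk_ch(0, 2), mk_ch(1, 3),
                                     mk_ch(2, 4), mk_ch(3, 5)))
  out <- diffraction_power_slices(ds, 2)
  expect_equal(out$mean_resolution_A, c(2.5, 4.5))
  expect_equal(out$best_resolution_A, c(2, 4))
  one <- diffraction_power_slices(ds, 1)
  expect_equal(one$mean_resolution_A, 3.5)
  expect_equal(one$best_resolution_A, 2)
  # brute-force recomputation on a larger simulated set
  pg <- point_group("-1")
  sim <- simulate_scan(scan_geometry(50, 4), 12, hex_cell(),
                       point_group("6/m"), 0.01, seed = 6, d_min = 30)
  parts <- diffraction_power_slices(sim$dataset, 4)
  lims <- crystals_table(sim$dataset)$resolution_limit
  sizes <- vapply(split_into_parts(sim$dataset, 4), n_chunks, integer(1))
  idx <- rep(1:4, sizes)
  ct <- crystals_table(sim$dataset)
  for (p in 1:4) {
    chunks_in <- which(idx == p)
    in_part <- ct$resolution_limit[ct$chunk %in% chunks_in]
    if (length(in_part)) {
      expect_equal(parts$mean_resolution_A[p], mean(in_part))
      expect_equal(parts$best_resolution_A[p], min(in_part))
    } else {
      expect_true(parts$empty[p])
    }
  }
})

test_that("a flagged-empty part appears when a slice holds no crystals", {
  cell <- cubic_cell(10)
  ds <- stream_dataset(chunks = list(
    stream_chunk(0, crystals = list(crystal_record(cell))),
    stream_chunk(1)))
  out <- diffraction_power_slices(ds, 2)
  expect_false(out$empty[1])
  expect_true(out$empty[2])
})
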
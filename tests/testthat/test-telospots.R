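vs <- c(0.2, 0.1, 0.1)

# a roomy nucleus without septa, so spots can spread out resolvably
telo_cell <- function(n_telomeres, seed, ...) {
  render_cell(cell_spec("H0", n_telomeres = as.integer(n_telomeres),
                        aggregate_fraction = 0, coloc_fraction = 0,
                        spot_clearance_um = 0.4,
                        n_accumulation_points = 0L, ...), seed = seed)
}

test_that("a single high-SNR blob is found within one voxel of its centre", {
  dims <- c(24, 48, 48)
  arr <- array(0, dims)
  arr[12, 24, 24] <- 1000
  arr <- laminatlas:::gauss_blur(arr, c(0.25, 0.15, 0.15), vs)
  telo <- voxel_grid(arr, vs, "TELO")
  nuc <- array(TRUE, dims)
  spots <- detect_spots(telo, nuc)
  expect_identical(nrow(spots), 1L)
  expect_lt(abs(spots$z - 11 * vs[1]), vs[1])
  expect_lt(abs(spots$y - 23 * vs[2]), vs[2])
  expect_lt(abs(spots$x - 23 * vs[3]), vs[3])
})

test_that("planted well-separated spots are counted exactly over seeds", {
  for (s in c(3, 11, 27)) {
    rc <- telo_cell(20, s)
    seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
    spots <- detect_spots(rc$stack$channels$TELO, seg$nucleus_mask)
    planted <- nrow(rc$truth$telomere_centres)
    expect_identical(nrow(spots), planted, label = sprintf("seed %d", s))
  }
})

test_that("an empty telomere channel yields zero spots", {
  telo <- voxel_grid(array(0, c(8, 16, 16)), vs, "TELO")
  nuc <- array(TRUE, c(8, 16, 16))
  expect_identical(nrow(detect_spots(telo, nuc)), 0L)
  expect_error(detect_spots(telo, array(FALSE, c(8, 16, 16))), "empty nucleus")
})

test_that("spot count is invariant under positive channel rescaling", {
  rc <- telo_cell(15, 5)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  t1 <- rc$stack$channels$TELO
  t9 <- voxel_grid(t1$data * 9.1, vs, "TELO")
  s1 <- detect_spots(t1, seg$nucleus_mask)
  s9 <- detect_spots(t9, seg$nucleus_mask)
  expect_identical(nrow(s1), nrow(s9))
  expect_equal(s1$z, s9$z)
})

test_that("aggregate flags follow proximity and volume gates", {
  base <- tibble::tibble(
    spot_id = 1:4,
    z = c(1, 1.05, 3, 5), y = c(1, 1.05, 3, 5), x = c(1, 1.08, 3, 5),
    total_intensity = rep(100, 4), volume = c(0.02, 0.02, 0.02, 0.02),
    peak = rep(1, 4)
  )
  # spots 1 and 2 are ~0.1 um apart -> both flagged at 0.2 um
  fl <- flag_aggregates(base, merge_distance_um = 0.2)
  expect_identical(fl$is_aggregate, c(TRUE, TRUE, FALSE, FALSE))
  # isolated median-sized spots: none flagged
  iso <- dplyr::mutate(base, z = c(1, 3, 5, 7), y = z, x = z)
  expect_false(any(flag_aggregates(iso, 0.2)$is_aggregate))
  # a spot much larger than the median volume is flagged
  big <- dplyr::mutate(iso, volume = c(0.02, 0.02, 0.02, 0.09))
  expect_identical(flag_aggregates(big, 0.2)$is_aggregate,
                   c(FALSE, FALSE, FALSE, TRUE))
})

test_that("planted aggregate fraction is approximately recovered", {
  hits <- 0; tot <- 0
  for (s in 1:6) {
    rc <- render_cell(cell_spec("H0", n_telomeres = 40L, coloc_fraction = 0,
                                spot_clearance_um = 0.4,
                                n_accumulation_points = 0L,
                                aggregate_fraction = 0.2), seed = 400 + s)
    seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
    spots <- detect_spots(rc$stack$channels$TELO, seg$nucleus_mask)
    spots <- flag_aggregates(spots)
    hits <- hits + sum(spots$is_aggregate)
    tot <- tot + nrow(spots)
  }
  expect_lt(abs(hits / tot - 0.2), 0.1)
})

test_that("a/c ratio has the documented limiting behaviour", {
  # 8 cube corners: perfectly isotropic covariance
  cube <- as.matrix(expand.grid(z = c(0, 1), y = c(0, 1), x = c(0, 1)))
  expect_equal(ac_ratio(cube), 1)

  # uniform ball: isotropic up to Monte-Carlo error
  set.seed(31)
  n <- 10000
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(n)^(1 / 3)
  expect_equal(ac_ratio(pts), 1, tolerance = 0.05)

  # 2:1 stretched ellipsoid surface
  sph <- matrix(rnorm(3 * n), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2))
  sph[, 1] <- sph[, 1] * 2
  expect_equal(ac_ratio(sph), 2, tolerance = 0.1)

  # invariance under rotation and uniform scaling
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(ac_ratio(5 * pts %*% rot), ac_ratio(pts), tolerance = 1e-6)

  # degenerate configurations are undefined
  expect_true(is.na(ac_ratio(cube[1:3, ])))
  plane <- cbind(runif(10), runif(10), 0.5)
  expect_true(is.na(ac_ratio(plane)))
})

test_that("binary co-localization gate hits its exact limits", {
  dims <- c(10, 20, 20)
  regions <- array(0L, dims)
  regions[3:4, 3:4, 3:4] <- 1L
  regions[7:8, 12:13, 12:13] <- 2L
  spots <- tibble::tibble(spot_id = 1:2, z = c(0.6, 1.4), y = c(0.3, 1.2),
                          x = c(0.3, 1.2), total_intensity = c(1, 1),
                          volume = c(0.01, 0.01), peak = c(1, 1))
  all_in <- array(TRUE, dims)
  expect_equal(coloc_fraction(spots, regions, all_in, vs)$fraction, 1)
  none <- array(FALSE, dims)
  expect_equal(coloc_fraction(spots, regions, none, vs)$fraction, 0)
  # half overlap, order independent
  half <- array(FALSE, dims)
  half[3:4, 3:4, 3:4] <- TRUE
  f12 <- coloc_fraction(spots, regions, half, vs)
  expect_equal(f12$fraction, 0.5)
  f21 <- coloc_fraction(spots[2:1, ], regions, half, vs)
  expect_equal(f21$fraction, 0.5)
  expect_identical(sort(f12$gates), sort(f21$gates))
  # no spots: undefined
  expect_true(is.na(coloc_fraction(spots[0, ], regions, half, vs)$fraction))
})

test_that("telomere metrics assemble the per-nucleus vector", {
  rc <- telo_cell(25, 9)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  dec <- decompose_lamin(rc$stack$channels$LAMIN, seg)
  spots <- detect_spots(rc$stack$channels$TELO, seg$nucleus_mask)
  spots <- flag_aggregates(spots)
  cl <- coloc_fraction(spots, attr(spots, "regions"), dec$internal_mask, vs)
  tm <- telomere_metrics(spots, seg, cl)
  expect_identical(tm$n_signals, nrow(spots))
  expect_lte(tm$n_aggregates, tm$n_signals)
  expect_gte(tm$ac_ratio, 1)
  expect_equal(tm$total_intensity, sum(spots$total_intensity))
  expect_gte(tm$coloc_fraction, 0)
  expect_lte(tm$coloc_fraction, 1)
})
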
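vs_iso <- c(0.1, 0.1, 0.1)

test_that("EDT-based opening equals the brute-force structuring-element oracle", {
  set.seed(5)
  for (trial in 1:6) {
    # random blobby 16^3 mask away from the border
    m <- array(FALSE, c(16, 16, 16))
    for (k in 1:3) {
      ctr <- runif(3, 0.5, 1.1)
      r <- runif(1, 0.15, 0.35)
      m <- m | make_ball_mask(dim(m), vs_iso, ctr, r)
    }
    m[c(1, 16), , ] <- FALSE; m[, c(1, 16), ] <- FALSE; m[, , c(1, 16)] <- FALSE
    for (r in c(0.1, 0.2, 0.3)) {
      fast <- laminatlas:::open_ball(m, r, vs_iso)
      expect_identical(fast, brute_open(m, r, vs_iso),
                       label = sprintf("trial %d radius %.1f", trial, r))
    }
  }
})

test_that("anisotropic opening agrees with the oracle on anisotropic voxels", {
  vs <- c(0.2, 0.1, 0.1)
  m <- array(FALSE, c(12, 16, 16))
  m <- m | make_ball_mask(dim(m), vs, c(1.1, 0.8, 0.8), 0.45)
  for (r in c(0.15, 0.3)) {
    expect_identical(laminatlas:::open_ball(m, r, vs), brute_open(m, r, vs))
  }
})

test_that("a single ball's cumulative curve jumps at its radius", {
  vs <- c(0.1, 0.1, 0.1)
  m <- make_ball_mask(c(24, 24, 24), vs, c(1.15, 1.15, 1.15), 0.5)
  g <- granulometry(m, vs, radii = seq(0.1, 1.0, by = 0.1))
  # up to surface-band discretization the ball survives openings below
  # its radius and vanishes above it
  expect_lt(max(g$cumulative_fraction[g$radius <= 0.3]), 0.1)
  expect_gt(min(g$cumulative_fraction[g$radius >= 0.6]), 0.9)
  expect_true(all(diff(g$cumulative_fraction) >= -1e-12))
})

test_that("two-ball plateau height equals the smaller ball's volume share", {
  vs <- c(0.1, 0.1, 0.1)
  m <- make_ball_mask(c(30, 30, 56), vs, c(1.45, 1.45, 1.2), 0.3) |
    make_ball_mask(c(30, 30, 56), vs, c(1.45, 1.45, 3.8), 0.6)
  v_small <- sum(make_ball_mask(c(30, 30, 56), vs, c(1.45, 1.45, 1.2), 0.3))
  share <- v_small / sum(m)
  g <- granulometry(m, vs, radii = seq(0.1, 0.9, by = 0.1))
  plateau <- g$cumulative_fraction[g$radius == 0.4]
  expect_equal(plateau, share, tolerance = 0.12)
  expect_gt(min(g$cumulative_fraction[g$radius >= 0.7]), 0.95)
})

test_that("granulometry is anti-extensive and idempotent", {
  set.seed(11)
  m <- array(FALSE, c(20, 20, 20))
  for (k in 1:4)
    m <- m | make_ball_mask(dim(m), vs_iso, runif(3, 0.5, 1.4), runif(1, 0.15, 0.4))
  g <- granulometry(m, vs_iso, radii = seq(0.05, 0.8, by = 0.05))
  expect_true(all(diff(g$retained_fraction) <= 1e-12))
  expect_true(all(g$cumulative_fraction >= 0 & g$cumulative_fraction <= 1))
  # opening at the smallest radius first, then re-sieving at that radius,
  # removes (almost) nothing more
  opened <- laminatlas:::open_ball(m, 0.2, vs_iso)
  g2 <- granulometry(opened, vs_iso, radii = c(0.2, 0.4))
  expect_lt(g2$cumulative_fraction[1], 0.02)
})

test_that("degenerate granulometry inputs are handled", {
  m <- array(FALSE, c(4, 4, 4))
  g <- granulometry(m, vs_iso, radii = c(0.1, 0.2))
  expect_true(attr(g, "undefined"))
  expect_true(all(is.na(g$cumulative_fraction)))
  expect_error(granulometry(array(TRUE, c(4, 4, 4)), vs_iso, radii = 0.1),
               "increasing")
  expect_error(granulometry(array(TRUE, c(4, 4, 4)), vs_iso,
                            radii = c(0.2, 0.1)), "increasing")
})

test_that("dna/free-space masks partition the nucleus exactly", {
  rc <- render_cell(cell_spec("H0", n_cavities = 10L), seed = 21)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  masks <- dna_and_free_masks(rc$stack$channels$DAPI, seg$nucleus_mask)
  expect_identical(masks$dna_mask | masks$free_space_mask, seg$nucleus_mask)
  expect_false(any(masks$dna_mask & masks$free_space_mask))
})

test_that("planted cavities are recovered in the free-space mask", {
  rc <- render_cell(cell_spec("H0", n_cavities = 8L), seed = 31)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  masks <- dna_and_free_masks(rc$stack$channels$DAPI, seg$nucleus_mask)
  truth_fs <- rc$truth$free_space_mask$data > 0
  recovered <- sum(masks$free_space_mask & truth_fs) / sum(truth_fs)
  expect_gte(recovered, 0.9)
})

test_that("population comparison flags the finer population decisively", {
  vs <- c(0.2, 0.1, 0.1)
  coarse <- list(means = c(0.6, 0.6), sds = c(0.05, 0.05), weights = c(0.5, 0.5))
  fine <- list(means = c(0.3, 0.3), sds = c(0.05, 0.05), weights = c(0.5, 0.5))
  curves_for <- function(radii_mix, seeds) {
    lapply(seeds, function(s) {
      rc <- render_cell(cell_spec("H0", free_space_radii = radii_mix,
                                  n_cavities = 15L, n_telomeres = 0L), seed = s)
      seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
      masks <- dna_and_free_masks(rc$stack$channels$DAPI, seg$nucleus_mask)
      granulometry(masks$free_space_mask, vs, cell_id = paste0("c", s))
    })
  }
  a <- curves_for(coarse, 1:8)
  b <- curves_for(fine, 101:108)
  cmp <- compare_populations(a, b, "coarse", "fine")
  expect_identical(cmp$finer, "fine")
  expect_lt(cmp$p_value, 0.01)
  # identical populations: D exactly 0
  same <- compare_populations(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})
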
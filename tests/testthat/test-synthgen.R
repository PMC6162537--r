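small_spec <- function(...) {
  cell_spec(semi_axes = c(1.4, 1.8, 1.8), n_cavities = 8L,
            n_telomeres = 10L, ...)
}

test_that("rendering is bit-identical under a fixed seed", {
  a <- render_cell(small_spec("HB"), seed = 77)
  b <- render_cell(small_spec("HB"), seed = 77)
  expect_identical(a$stack$channels$LAMIN$data, b$stack$channels$LAMIN$data)
  expect_identical(a$stack$channels$DAPI$data, b$stack$channels$DAPI$data)
  expect_identical(a$stack$channels$TELO$data, b$stack$channels$TELO$data)
  expect_identical(a$truth$telomere_centres, b$truth$telomere_centres)
  c <- render_cell(small_spec("HB"), seed = 78)
  expect_false(identical(a$stack$channels$LAMIN$data,
                         c$stack$channels$LAMIN$data))
})

test_that("ground-truth compartment counts match the spec", {
  for (p in c("H0", "HA", "HB", "HC", "RS2", "RS3")) {
    rc <- render_cell(cell_spec(p, n_telomeres = 0L), seed = 13)
    labs <- rc$truth$compartment_labels$data
    expect_identical(length(setdiff(unique(as.vector(labs)), 0)),
                     as.integer(rc$truth$spec$n_compartments),
                     label = p)
  }
})

test_that("an H0 cell without accumulation points has an empty internal mask", {
  rc <- render_cell(
    cell_spec("H0", n_accumulation_points = 0L, n_telomeres = 0L,
              noise = list(poisson_scale = 0, gaussian_sd = 0)),
    seed = 2)
  expect_equal(sum(rc$truth$internal_mask$data), 0)
  expect_identical(
    length(setdiff(unique(as.vector(rc$truth$compartment_labels$data)), 0)), 1L)
})

test_that("noiseless unblurred lamin integrates to the recorded truth", {
  rc <- render_cell(small_spec("HB"), seed = 5)
  clean <- rc$truth$lamin_clean
  expect_equal(sum(clean[rc$truth$shell_mask$data > 0]), rc$truth$true_Ie)
  expect_equal(sum(clean[rc$truth$internal_mask$data > 0]), rc$truth$true_Ii)
  expect_gt(rc$truth$true_Ie, 0)
  expect_gt(rc$truth$true_Ii, 0)
})

test_that("target_ratio calibration makes the truth ratio exact", {
  rc <- render_cell(cell_spec("HB", target_ratio = 3.65, n_telomeres = 0L),
                    seed = 9)
  expect_equal(rc$truth$true_Ie / rc$truth$true_Ii, 3.65, tolerance = 1e-9)
})

test_that("realized co-localization fraction is recorded exactly and near target", {
  rc <- render_cell(cell_spec("HB", n_telomeres = 40L, coloc_fraction = 0.5),
                    seed = 101)
  flags <- rc$truth$telomere_centres$coloc
  expect_identical(rc$truth$realized_coloc_fraction, mean(flags))
  # binomial 95% bounds around 0.5 at n = 40
  expect_lt(abs(mean(flags) - 0.5), 1.96 * sqrt(0.25 / 40) + 1e-9)
})

test_that("increasing read noise never decreases per-voxel variance", {
  reps <- 40
  render_lamin <- function(sd, seed) {
    render_cell(cell_spec("H0", semi_axes = c(1.0, 1.2, 1.2),
                          n_cavities = 3L, n_telomeres = 0L,
                          noise = list(poisson_scale = 1, gaussian_sd = sd)),
                seed = seed)$stack$channels$LAMIN$data
  }
  lo <- sapply(seq_len(reps), function(s) as.vector(render_lamin(1, s)))
  hi <- sapply(seq_len(reps), function(s) as.vector(render_lamin(4, s)))
  v_lo <- apply(lo, 1, var)
  v_hi <- apply(hi, 1, var)
  # compare on bright voxels (clamping at zero masks variance in the dark)
  bright <- rowMeans(lo) > 20
  expect_gt(mean(v_hi[bright]), mean(v_lo[bright]))
  expect_gt(mean(v_hi[bright] >= v_lo[bright]), 0.9)
})

test_that("population sampling is deterministic and respects overrides", {
  pop <- sample_population(c(HB = 0.5, H0 = 0.5), 4, seed = 3,
                           base_spec = list(semi_axes = c(1.2, 1.5, 1.5),
                                            n_telomeres = 0L))
  pop2 <- sample_population(c(HB = 0.5, H0 = 0.5), 4, seed = 3,
                            base_spec = list(semi_axes = c(1.2, 1.5, 1.5),
                                             n_telomeres = 0L))
  expect_identical(pop$pattern, pop2$pattern)
  expect_identical(pop$stack[[2]]$channels$LAMIN$data,
                   pop2$stack[[2]]$channels$LAMIN$data)
  expect_identical(pop$truth[[1]]$spec$semi_axes, c(1.2, 1.5, 1.5))
  expect_identical(vapply(pop$truth, function(t) t$spec$pattern, ""),
                   pop$pattern)
})

test_that("impossible septum geometry raises a clear error", {
  expect_error(
    render_cell(cell_spec("HD", semi_axes = c(0.5, 0.6, 0.6),
                          n_cavities = 0L, n_telomeres = 0L), seed = 1),
    "compartments")
})
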
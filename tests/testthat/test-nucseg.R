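noiseless <- list(poisson_scale = 0, gaussian_sd = 0)

test_that("noiseless single ellipsoid segments with Dice >= 0.95 and one lobe", {
  rc <- render_cell(cell_spec("H0", semi_axes = c(3, 4, 4), noise = noiseless,
                              n_telomeres = 0L), seed = 8)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  truth <- rc$truth$nucleus_mask$data > 0
  dice <- 2 * sum(seg$nucleus_mask & truth) / (sum(seg$nucleus_mask) + sum(truth))
  expect_gte(dice, 0.95)
  expect_identical(seg$n_lobes, 1L)
  expect_equal(seg$nuclear_volume, sum(seg$nucleus_mask) * 0.002)
})

test_that("all-zero channels raise an error", {
  z <- voxel_grid(array(0, c(8, 8, 8)), c(0.2, 0.1, 0.1), "DAPI")
  zl <- voxel_grid(array(0, c(8, 8, 8)), c(0.2, 0.1, 0.1), "LAMIN")
  expect_error(segment_nucleus(z, zl), "empty foreground")
})

test_that("a bi-lobed cell with lobe centres ~7 um apart yields two lobes", {
  rc <- render_cell(cell_spec("RS2", semi_axes = c(2, 3.6, 3.6),
                              n_telomeres = 0L), seed = 4)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  expect_identical(seg$n_lobes, 2L)
  # lobe labels partition the nucleus
  expect_identical(seg$lobe_labels > 0, seg$nucleus_mask)
})

test_that("shell and internal masks partition the lamin mask", {
  rc <- render_cell(cell_spec("HB", n_telomeres = 0L), seed = 6)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  dec <- decompose_lamin(rc$stack$channels$LAMIN, seg)
  expect_false(any(dec$shell_mask & dec$internal_mask))
  expect_identical(dec$shell_mask | dec$internal_mask, dec$lamin_mask)
  # within the nucleus the decomposition partitions lamin; the shell
  # additionally collects the blur skirt just beyond the surface
  expect_true(all(dec$internal_mask <= seg$nucleus_mask))
  expect_gte(dec$n_compartments, 1L)
})

test_that("masks are invariant under positive rescaling of the channels", {
  rc <- render_cell(cell_spec("HB", n_telomeres = 0L), seed = 14)
  d <- rc$stack$channels$DAPI
  l <- rc$stack$channels$LAMIN
  l7 <- voxel_grid(l$data * 7.3, l$voxel_size, "LAMIN")
  seg1 <- segment_nucleus(d, l)
  seg2 <- segment_nucleus(d, l7)
  expect_identical(seg1$nucleus_mask, seg2$nucleus_mask)
  dec1 <- decompose_lamin(l, seg1)
  dec2 <- decompose_lamin(l7, seg2)
  expect_identical(dec1$shell_mask, dec2$shell_mask)
  expect_identical(dec1$internal_mask, dec2$internal_mask)
  expect_identical(dec1$n_compartments, dec2$n_compartments)
})

test_that("adding septa never decreases the detected compartment count", {
  for (s in c(3, 12)) {
    counts <- vapply(c("H0", "HB", "HC"), function(p) {
      rc <- render_cell(cell_spec(p, n_telomeres = 0L), seed = s)
      seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
      decompose_lamin(rc$stack$channels$LAMIN, seg)$n_compartments
    }, 0L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("an excessive shell depth is rejected", {
  rc <- render_cell(cell_spec("H0", semi_axes = c(1.2, 1.5, 1.5),
                              n_telomeres = 0L), seed = 2)
  seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
  expect_error(decompose_lamin(rc$stack$channels$LAMIN, seg,
                               shell_depth_um = 3), "shell")
})

test_that("detected compartments match brute-force flood fill on noiseless cells", {
  for (p in c("H0", "HB", "HC")) {
    rc <- render_cell(cell_spec(p, noise = noiseless, n_telomeres = 0L),
                      seed = 20)
    seg <- segment_nucleus(rc$stack$channels$DAPI, rc$stack$channels$LAMIN)
    dec <- decompose_lamin(rc$stack$channels$LAMIN, seg)
    truth_open <- rc$truth$compartment_labels$data > 0
    expect_identical(dec$n_compartments, brute_flood_count(truth_open),
                     label = p)
  }
})
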
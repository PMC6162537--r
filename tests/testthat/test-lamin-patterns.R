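test_that("classification follows the pattern taxonomy", {
  expect_identical(classify_pattern(1, 1, 0.001, 0.01), "H0")
  expect_identical(classify_pattern(1, 1, 0.05, 0.01), "HA")
  expect_identical(classify_pattern(1, 2, 0.2, 0.01), "HB")
  expect_identical(classify_pattern(1, 3, 0.2, 0.01), "HC")
  expect_identical(classify_pattern(1, 4, 0.2, 0.01), "HD")
  expect_identical(classify_pattern(1, 7, 0.2, 0.01), "HD")
  expect_identical(classify_pattern(2, 1, 0, 0.01), "RS2")
  expect_identical(classify_pattern(3, 5, 1, 0.01), "RS3")
  expect_identical(classify_pattern(4, 1, 0.5, 0.01), "RS4")
  expect_identical(classify_pattern(5, 1, 0, 0.01), "RSmulti")
  expect_identical(classify_pattern(9, 1, 0, 0.01), "RSmulti")
})

test_that("the H branch is monotone in compartment count", {
  labels <- vapply(1:6, function(k) classify_pattern(1, k, 0.5, 0.01), "")
  ranks <- match(labels, pattern_labels())
  expect_true(all(diff(ranks) >= 0))
})

test_that("intensity ratio reduces to the analytic voxel-count ratio", {
  dims <- c(20, 40, 40)
  vs <- c(0.2, 0.1, 0.1)
  shell <- array(FALSE, dims); shell[5:9, 5:34, 5:24] <- TRUE   # 3000 voxels
  sept <- array(FALSE, dims); sept[12:16, 5:24, 5:14] <- TRUE   # 1000 voxels
  dec <- structure(list(
    lamin_mask = shell | sept, shell_mask = shell, internal_mask = sept,
    compartment_labels = array(0L, dims), n_compartments = 1L,
    internal_burden = 0, voxel_size = vs
  ), class = "lamin_decomposition")
  lam <- voxel_grid(array(1, dims), vs, "LAMIN")
  ir <- intensity_ratio(lam, dec)
  expect_equal(ir$ratio, 3)
  expect_true(ir$ratio_defined)

  # empty internal mask: flagged undefined, not a number
  dec$internal_mask <- array(FALSE, dims)
  ir2 <- intensity_ratio(lam, dec)
  expect_false(ir2$ratio_defined)
  expect_true(is.na(ir2$ratio))

  # scaling invariance: ratio(c * lamin) = ratio(lamin)
  dec$internal_mask <- sept
  lam5 <- voxel_grid(5.5 * array(1, dims), vs, "LAMIN")
  expect_equal(intensity_ratio(lam5, dec)$ratio, 3)
})

test_that("pattern table means, SDs and within-family percentages", {
  calls <- tibble::tibble(
    label = c(rep("H0", 30)),
    experiment_id = rep(c("e1", "e2", "e3"), each = 10)
  )
  tb <- pattern_table(calls)
  h0 <- tb[tb$label == "H0", ]
  expect_equal(h0$mean, 10)
  expect_equal(h0$sd, 0)
  expect_equal(h0$percentage, 100)

  # hand-computed sample SD of (5, 10, 15)
  calls2 <- tibble::tibble(
    label = rep("HB", 30),
    experiment_id = rep(c("e1", "e2", "e3"), c(5, 10, 15))
  )
  tb2 <- pattern_table(calls2)
  expect_equal(tb2$sd[tb2$label == "HB"], 5)

  # mixed families: percentages sum to 100 within each family
  calls3 <- tibble::tibble(
    label = c("H0", "HA", "HB", "RS2", "RS3", "RS2"),
    experiment_id = "e1"
  )
  tb3 <- pattern_table(calls3)
  sums <- tapply(tb3$percentage, tb3$family, sum)
  expect_equal(unname(sums["H"]), 100, tolerance = 1e-3)
  expect_equal(unname(sums["RS"]), 100, tolerance = 1e-3)
})

test_that("ratio summary excludes undefined ratios and uses sample SD", {
  calls <- tibble::tibble(
    label = c("HB", "HB", "HB", "H0"),
    ratio = c(2, 4, NA, 2),
    ratio_defined = c(TRUE, TRUE, FALSE, TRUE)
  )
  rs <- ratio_summary(calls)
  hb <- rs[rs$label == "HB", ]
  expect_equal(hb$mean_ratio, 3)
  expect_equal(hb$sd_ratio, sqrt(2))
  expect_equal(hb$n, 2L)
  expect_equal(hb$n_undefined, 1L)
  h0 <- rs[rs$label == "H0", ]
  expect_equal(h0$mean_ratio, 2)
  expect_equal(h0$sd_ratio, 0)  # n = 1 convention

  calls2 <- tibble::tibble(label = "HC", ratio = NA_real_,
                           ratio_defined = FALSE)
  expect_warning(rs2 <- ratio_summary(calls2), "omitted")
  expect_identical(nrow(rs2), 0L)
})

test_that("population sampling recovers the published frequencies", {
  freqs <- hodgkin_pattern_freqs("H")
  expect_equal(sum(freqs), 1)
  pop <- sample_population(freqs, 10000, seed = 99, render = FALSE)
  emp <- table(factor(pop$pattern, levels = names(freqs))) / nrow(pop)
  expect_true(all(abs(as.numeric(emp) - freqs) < 0.02))
  # determinism of the label sequence
  pop2 <- sample_population(freqs, 10000, seed = 99, render = FALSE)
  expect_identical(pop$pattern, pop2$pattern)
  # degenerate distribution
  pop3 <- sample_population(c(H0 = 1), 5, seed = 1, render = FALSE)
  expect_identical(unique(pop3$pattern), "H0")
  expect_error(sample_population(numeric(0), 5), "empty")
  expect_error(sample_population(c(H0 = 0.5, HA = 0.4), 5), "sum to 1")
})
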
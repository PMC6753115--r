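test_that("structure voxel counts match ellipsoid geometry and shrink with severity", {
  spec <- phantom_spec(noise_sigma = 0)
  ph0 <- make_structure_volume(spec, 0)
  # analytic ellipsoid volume, per structure
  for (s in spec$structures) {
    analytic <- 4 / 3 * pi * prod(s$baseline_radii)
    got <- sum(ph0$labels == structure_code(s$name))
    expect_lt(abs(got - analytic) / analytic, 0.02)
  }
  prof <- severity_profile(volume_loss_max = 0.3)
  ph1 <- make_structure_volume(spec, 1, prof)
  ph5 <- make_structure_volume(spec, 0.5, prof)
  n0 <- sum(ph0$labels == 1L); n1 <- sum(ph1$labels == 1L)
  expect_lt(abs(n1 / n0 - 0.7), 0.02)
  n5 <- sum(ph5$labels == 1L)
  expect_true(n1 < n5 && n5 < n0)
  expect_error(make_structure_volume(spec, 1.2), "severity")
  expect_error(make_structure_volume(spec, -0.1), "severity")
})

test_that("left/right structures are mirror symmetric at severity 0", {
  ph <- make_structure_volume(phantom_spec(noise_sigma = 0), 0)
  expect_identical(sum(ph$labels == 1L), sum(ph$labels == 2L))
  expect_identical(sum(ph$labels == 3L), sum(ph$labels == 4L))
  # exact mirror of the label field about the midsagittal plane
  flipped <- ph$labels[dim(ph$labels)[1]:1, , ]
  swap <- flipped
  swap[flipped == 1L] <- 2L; swap[flipped == 2L] <- 1L
  swap[flipped == 3L] <- 4L; swap[flipped == 4L] <- 3L
  expect_identical(swap, ph$labels)
})

test_that("structures are disjoint and strictly inside the brain mask", {
  ph <- make_structure_volume(phantom_spec(noise_sigma = 0), 0)
  counts <- table(ph$labels[ph$labels > 0])
  analytic <- sum(vapply(phantom_spec()$structures,
                         function(s) 4 / 3 * pi * prod(s$baseline_radii), 0))
  expect_lt(abs(sum(counts) - analytic) / analytic, 0.02)
  expect_true(all(ph$brain[ph$labels > 0]))
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(grid_extent = 16), "32")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise")
  expect_error(phantom_spec(bias_amplitude = 0.7), "bias_amplitude")
  big <- default_structures(64)
  big[[1]]$center <- c(2, 2, 2)
  expect_error(phantom_spec(structures = big), "inside the grid")
  expect_error(severity_profile(levels = c(CH = 0.5, SCD = 0.2, eMCI = 0.4,
                                           lMCI = 0.6, AD = 0.8)),
               "non-decreasing")
})

test_that("template library is reproducible, tagged 1/2, and guarded", {
  spec <- spec32()
  l1 <- make_template_library(3, 2, spec, seed = 7)
  l2 <- make_template_library(3, 2, spec, seed = 7)
  expect_identical(l1$meta, l2$meta)
  expect_identical(lapply(l1$templates, `[[`, "intensity"),
                   lapply(l2$templates, `[[`, "intensity"))
  expect_setequal(unique(l1$meta$group_tag), c(1L, 2L))
  cn_sev <- l1$meta$severity[l1$meta$group_tag == 1L]
  ad_sev <- l1$meta$severity[l1$meta$group_tag == 2L]
  expect_true(all(cn_sev <= 0.1) && all(ad_sev >= 0.8))
  expect_error(make_template_library(1, 0, spec), "at least one")
  expect_error(make_template_library(0, 1, spec), "at least one")
})

test_that("background noise SD matches the generative model", {
  spec <- spec32(noise_sigma = 0.05, bias_amplitude = 0)
  co <- make_cohort(c(CH = 1, SCD = 0, eMCI = 0, lMCI = 0, AD = 0),
                    spec = spec, seed = 3, apply_pose = FALSE,
                    keep_truth = TRUE)
  bg <- !dilate_mask(co$truth[[1]]$brain, 2)
  expect_gt(sum(bg), 1e4)
  emp <- sd(co$volumes[[1]][bg])
  expect_lt(abs(emp - 0.05 * spec$tissue_intensity) /
              (0.05 * spec$tissue_intensity), 0.10)
})

test_that("bias field is positive, unit-mean and has the requested range", {
  spec <- spec32(bias_amplitude = 0.2)
  ph <- make_structure_volume(spec, 0)
  set.seed(4)
  f <- make_bias_field(spec, ph$brain)
  expect_true(all(f > 0))
  expect_lt(abs(mean(f[ph$brain]) - 1), 1e-12)
  expect_lt(abs(diff(range(f)) - 0.2), 0.02)
  expect_equal(make_bias_field(spec32(bias_amplitude = 0)),
               array(1, c(32, 32, 32)))
})

test_that("default cohort has the published composition and is reproducible", {
  spec <- spec32()
  co1 <- make_cohort(spec = spec, seed = 5, apply_pose = FALSE,
                     apply_bias = FALSE, apply_noise = FALSE)
  expect_identical(nrow(co1$table), 137L)
  expect_identical(as.integer(table(co1$table$group)),
                   c(29L, 66L, 22L, 8L, 12L))
  co2 <- make_cohort(spec = spec, seed = 5, apply_pose = FALSE,
                     apply_bias = FALSE, apply_noise = FALSE)
  expect_identical(co1$table, co2$table)
  expect_identical(co1$volumes[[10]], co2$volumes[[10]])
  # severity respects the group ordering on average
  ms <- tapply(co1$table$severity, co1$table$group, mean)
  expect_true(all(diff(ms) > 0))
})

test_that("mean generated structure volume decreases across severity levels", {
  spec <- spec32(noise_sigma = 0)
  levels <- seq(0, 1, length.out = 5)
  set.seed(11)
  mean_vol <- vapply(levels, function(sv) {
    mean(vapply(1:10, function(i) {
      ph <- make_structure_volume(spec, sv, jitter_sd = 0.02)
      sum(ph$labels == 1L)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_vol) < 0))
})

test_that("cohort and library round-trip through disk formats", {
  spec <- spec32(noise_sigma = 0.01)
  dir <- withr::local_tempdir()
  lib <- make_template_library(2, 2, spec, seed = 9)
  write_library(lib, file.path(dir, "lib"))
  lib2 <- read_library(file.path(dir, "lib"), spec)
  expect_equal(lib2$meta$group_tag, lib$meta$group_tag)
  expect_equal(as.numeric(lib2$templates[[1]]$intensity),
               as.numeric(lib$templates[[1]]$intensity), tolerance = 1e-6)
  expect_identical(lib2$templates[[3]]$labels, lib$templates[[3]]$labels)

  co <- make_cohort(c(CH = 2, SCD = 0, eMCI = 0, lMCI = 0, AD = 0),
                    spec = spec, seed = 2)
  write_cohort(co, file.path(dir, "cohort"))
  tab <- read.csv(file.path(dir, "cohort", "cohort.csv"))
  expect_identical(nrow(tab), 2L)
  v <- read_volume(file.path(dir, "cohort", "s001.nii.gz"))
  expect_equal(dim(v), dim(co$volumes[[1]]))
  expect_equal(as.numeric(v), as.numeric(co$volumes[[1]]), tolerance = 1e-6)
})
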
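test_that("patch distance is an SSD with the documented properties", {
  p <- array(rnorm(343), c(7, 7, 7))
  expect_identical(patch_distance(p, p), 0)
  expect_equal(patch_distance(p, p + 1), 343)
  q <- array(rnorm(343), c(7, 7, 7))
  # elementwise loop oracle
  acc <- 0
  for (i in seq_along(p)) acc <- acc + (p[i] - q[i])^2
  expect_equal(patch_distance(p, q), acc, tolerance = 1e-12)
  expect_equal(patch_distance(p, q), patch_distance(q, p))
  expect_error(patch_distance(p, array(0, c(5, 5, 5))), "shapes")
})

test_that("optimized engine equals the exhaustive oracle", {
  lib <- tiny_library(2, 2, n = 16, seed = 3)
  subj <- as_volume(array(rnorm(16^3, 100, 10), c(16, 16, 16)))
  cfg <- patch_config(patch_radius = 1, search_radius = 2, preselect = FALSE)
  set.seed(31)
  vox <- random_voxels(40, c(16, 16, 16))
  for (r in seq_len(nrow(vox))) {
    fast <- grade_voxel(subj, lib, vox[r, ], cfg)
    slow <- brute_force_grade(subj, lib, vox[r, ], cfg)
    expect_identical(fast$label, slow$label)
    expect_equal(fast$grading, slow$grading, tolerance = 1e-10)
    expect_equal(fast$total_weight, slow$total_weight, tolerance = 1e-10)
  }
})

test_that("grading is a convex combination of the group tags", {
  lib <- tiny_library(3, 2, n = 16, seed = 5)
  subj <- as_volume(array(rnorm(16^3, 100, 10), c(16, 16, 16)))
  cfg <- patch_config(patch_radius = 1, search_radius = 2)
  set.seed(32)
  g <- grade_voxels(subj, lib, random_voxels(100, rep(16, 3)), cfg)
  expect_true(all(g$grading >= 1 & g$grading <= 2))
  # all-CN library: exactly 1
  gcn <- grade_voxels(subj, retag(lib, rep(1L, 5)),
                      random_voxels(50, rep(16, 3)), cfg)
  expect_true(all(gcn$grading == 1))
})

test_that("swapping CN/AD tags maps grading g to 3 - g exactly", {
  lib <- tiny_library(2, 2, n = 16, seed = 6)
  libsw <- retag(lib, 3L - lib$meta$group_tag)
  subj <- as_volume(array(rnorm(16^3, 100, 10), c(16, 16, 16)))
  cfg <- patch_config(patch_radius = 1, search_radius = 2)
  set.seed(33)
  vox <- random_voxels(50, rep(16, 3))
  g1 <- grade_voxels(subj, lib, vox, cfg)
  g2 <- grade_voxels(subj, libsw, vox, cfg)
  expect_equal(g1$grading + g2$grading, rep(3, 50), tolerance = 1e-12)
})

test_that("a subject present in the library grades at its own tag", {
  lib <- tiny_library(2, 2, n = 16, seed = 7)
  subj <- lib$templates[[1]]$intensity   # a CN template
  cfg <- patch_config(patch_radius = 1, search_radius = 2)
  g <- grade_voxel(subj, lib, c(8, 8, 8), cfg)
  expect_lt(abs(g$grading - 1), 0.01)
  # single-template library: tag returned exactly, both paths
  lib1 <- lib; lib1$templates <- lib1$templates[3]; lib1$meta <- lib1$meta[3, ]
  expect_identical(grade_voxel(subj, lib1, c(8, 8, 8), cfg)$grading, 2)
  expect_identical(brute_force_grade(subj, lib1, c(8, 8, 8), cfg)$grading, 2)
})

test_that("labels are invariant to a common intensity rescaling", {
  lib <- tiny_library(2, 2, n = 16, seed = 9)
  subj <- as_volume(array(rnorm(16^3, 100, 10), c(16, 16, 16)))
  libs <- lib
  for (i in 1:4)
    libs$templates[[i]]$intensity <- as_volume(lib$templates[[i]]$intensity * 7.3)
  cfg <- patch_config(patch_radius = 1, search_radius = 2)
  set.seed(34)
  vox <- random_voxels(80, rep(16, 3))
  r1 <- grade_voxels(subj, lib, vox, cfg)
  r2 <- grade_voxels(as_volume(subj * 7.3), libs, vox, cfg)
  expect_identical(r1$label, r2$label)
})

test_that("preselection falls back to exhaustive candidates instead of failing", {
  lib <- tiny_library(2, 2, n = 16, seed = 10)
  # subject wildly unlike any template: every candidate is preselected out
  subj <- as_volume(array(rnorm(16^3, 10000, 1), c(16, 16, 16)))
  cfg <- patch_config(patch_radius = 1, search_radius = 1,
                      preselect = TRUE, presel_thresh = 0.99)
  g <- grade_voxel(subj, lib, c(8, 8, 8), cfg)
  expect_true(g$fallback)
  expect_true(is.finite(g$grading))
  # and preselection never changes the fused label on phantoms at the
  # default threshold
  spec <- spec32(noise_sigma = 0.02)
  plib <- make_template_library(3, 3, spec, seed = 11)
  set.seed(35)
  ph <- make_structure_volume(spec, 0.4)
  subj2 <- as_volume(ph$volume + array(rnorm(32^3, 0, 2), c(32, 32, 32)))
  gon <- grade_region(subj2, plib, "HPC_L", cfg32(preselect = TRUE))
  goff <- grade_region(subj2, plib, "HPC_L", cfg32(preselect = FALSE))
  cand <- !is.na(gon$grading_field)
  mismatch <- mean(gon$label_field[cand] != goff$label_field[cand])
  expect_lt(mismatch, 0.01)
  expect_equal(gon$region_score, goff$region_score, tolerance = 0.02)
})

test_that("region grading is consistent, severity-sensitive and matches its definition", {
  spec <- spec32(noise_sigma = 0)
  lib <- make_template_library(4, 4, spec, seed = 12)
  ph0 <- make_structure_volume(spec, 0.05)
  ph1 <- make_structure_volume(spec, 0.95)
  cfg <- cfg32()
  g0 <- grade_region(ph0$volume, lib, "HPC_L", cfg)
  g1 <- grade_region(ph1$volume, lib, "HPC_L", cfg)
  expect_lt(g0$region_score, g1$region_score)
  expect_lt(abs(g0$region_score - 1), abs(g1$region_score - 1))
  # region score = unweighted mean over assigned voxels (cross-check)
  vox <- which(!is.na(g0$grading_field) &
                 g0$label_field == structure_code("HPC_L"), arr.ind = TRUE)
  per_vox <- grade_voxels(ph0$volume, lib, vox, cfg)
  expect_equal(g0$region_score, mean(per_vox$grading), tolerance = 1e-12)
  # fused segmentation against generator truth
  expect_gt(dice(g0$label_field == 1L, ph0$labels == 1L), 0.85)
})

test_that("grade_subject agrees with per-structure grade_region calls", {
  spec <- spec32(noise_sigma = 0.02)
  lib <- make_template_library(3, 3, spec, seed = 13)
  set.seed(36)
  ph <- make_structure_volume(spec, 0.5)
  subj <- as_volume(ph$volume + array(rnorm(32^3, 0, 2), c(32, 32, 32)))
  cfg <- cfg32()
  all4 <- grade_subject(subj, lib, names(patchgrade:::STRUCTURES), cfg)
  for (s in names(patchgrade:::STRUCTURES)) {
    one <- grade_region(subj, lib, s, cfg)
    expect_equal(all4[[s]]$region_score, one$region_score, tolerance = 1e-12)
    expect_identical(all4[[s]]$voxel_count, one$voxel_count)
  }
})

test_that("cohort grading is deterministic and order-equivariant", {
  spec <- spec32(noise_sigma = 0.02)
  lib <- make_template_library(3, 3, spec, seed = 14)
  co <- make_cohort(c(CH = 2, SCD = 0, eMCI = 0, lMCI = 0, AD = 2),
                    spec = spec, seed = 4, apply_pose = FALSE,
                    apply_bias = FALSE)
  cfg <- cfg32()
  t1 <- grade_cohort(co$volumes, lib, cfg = cfg, ids = co$table$subject_id)
  t2 <- grade_cohort(co$volumes, lib, cfg = cfg, ids = co$table$subject_id)
  expect_identical(t1, t2)
  perm <- c(3, 1, 4, 2)
  t3 <- grade_cohort(co$volumes[perm], lib, cfg = cfg,
                     ids = co$table$subject_id[perm])
  expect_equal(t3$snipe_HPC_L, t1$snipe_HPC_L[perm], tolerance = 1e-12)
})
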
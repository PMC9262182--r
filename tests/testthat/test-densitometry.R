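test_that("mean lung density is the unweighted mean of masked voxels", {
  v <- density_volume(array(c(-1000, -800, -600), c(3, 1, 1)), c(1, 1, 1))
  m <- lung_mask(array(c(1L, 1L, 2L), c(3, 1, 1)))
  expect_equal(mean_lung_density(v, m), -800)
  expect_equal(mean_lung_density(v, m, "left"), -900)
  expect_equal(mean_lung_density(v, m, "right"), -600)

  # constant field and singleton
  vc <- density_volume(array(-715, c(2, 2, 2)), c(1, 1, 1))
  mc <- lung_mask(array(1L, c(2, 2, 2)))
  expect_equal(mean_lung_density(vc, mc), -715)
  v1 <- density_volume(array(-788, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(mean_lung_density(v1, lung_mask(array(1L, c(1, 1, 1)))), -788)

  # empty selection errors
  expect_error(mean_lung_density(v, lung_mask(array(c(1L, 1L, 1L), c(3, 1, 1))),
                                 "right"), "empty lung region")
})

test_that("lung volume converts voxel counts through spacing to mL", {
  m1 <- lung_mask(array(1L, c(10, 10, 10)))
  expect_equal(lung_volume(m1, c(1, 1, 1)), 1.0)
  m2 <- lung_mask(array(c(1L, 0L), c(2, 1, 1)))
  expect_equal(lung_volume(m2, c(2, 2, 2.5)), 0.01)
  expect_error(lung_volume(m2, c(2, 2, 2.5), side = "right"),
               "empty lung region")
  expect_error(lung_mask(array(0L, c(2, 2, 2))), "no nonzero voxel")
})

test_that("MLDD is expiratory minus inspiratory, E/I is 100*exp/ins", {
  expect_identical(mldd(-788.0, -659.0), 129)
  expect_identical(mldd(-650, -650), 0)
  expect_equal(mldd(-794.6, -731.4), 63.2)
  expect_error(mldd(NA_real_, -700), "finite")

  expect_equal(ei_ratio(-788.0, -659.0), 83.63, tolerance = 1e-4)
  expect_equal(ei_ratio(-700, -700), 100)
  expect_equal(ei_ratio(2000, 1000), 50)
  expect_error(ei_ratio(0, 5), "zero")
})

test_that("attenuation fractions use strict inequalities at the threshold", {
  v <- density_volume(array(c(-1000, -800, -600), c(3, 1, 1)), c(1, 1, 1))
  m <- lung_mask(array(c(1L, 1L, 2L), c(3, 1, 1)))
  expect_equal(attenuation_fraction(v, m, -850, "below"), 100 / 3)
  expect_equal(attenuation_fraction(v, m, -650, "above"), 100 / 3)
  expect_equal(attenuation_fraction(v, m, -2000, "below"), 0)
  # a voxel exactly at the threshold counts for neither tail
  expect_equal(attenuation_fraction(v, m, -800, "below"), 100 / 3)
  expect_equal(attenuation_fraction(v, m, -800, "above"), 100 / 3)
})

test_that("threshold fractions partition and are monotone on random grids", {
  set.seed(42)
  for (rep in 1:25) {
    f <- random_tiny_fixture()
    t1 <- -900; t2 <- -700
    below <- attenuation_fraction(f$volume, f$mask, t1, "below")
    above <- attenuation_fraction(f$volume, f$mask, t2, "above")
    x <- f$volume$values[f$mask$membership != 0]
    middle <- 100 * sum(x >= t1 & x <= t2) / length(x)
    expect_equal(below + middle + above, 100)

    ths <- c(-950, -900, -850, -800)
    bel <- vapply(ths, function(t)
      attenuation_fraction(f$volume, f$mask, t, "below"), numeric(1))
    abv <- vapply(ths, function(t)
      attenuation_fraction(f$volume, f$mask, t, "above"), numeric(1))
    expect_true(all(diff(bel) >= 0))
    expect_true(all(diff(abv) <= 0))
  }
})

test_that("indices depend only on masked voxels", {
  set.seed(7)
  f <- random_tiny_fixture()
  if (!any(f$mask$membership == 0)) f$mask$membership[1] <- 0L
  outside <- which(f$mask$membership == 0)
  before <- c(mean_lung_density(f$volume, f$mask),
              attenuation_fraction(f$volume, f$mask, -850, "below"))
  v2 <- f$volume
  v2$values[outside] <- v2$values[outside] + 500
  after <- c(mean_lung_density(v2, f$mask),
             attenuation_fraction(v2, f$mask, -850, "below"))
  expect_identical(before, after)
})

test_that("whole-lung values are voxel-weighted combinations of the sides", {
  set.seed(11)
  for (rep in 1:10) {
    f <- random_tiny_fixture()
    sp <- f$volume$spacing
    expect_equal(lung_volume(f$mask, sp),
                 lung_volume(f$mask, sp, "left") + lung_volume(f$mask, sp, "right"))
    nl <- sum(f$mask$membership == 1); nr <- sum(f$mask$membership == 2)
    expect_equal(mean_lung_density(f$volume, f$mask),
                 (nl * mean_lung_density(f$volume, f$mask, "left") +
                    nr * mean_lung_density(f$volume, f$mask, "right")) / (nl + nr))
  }
})

test_that("compute_all_indices satisfies its internal identities", {
  # identity phantom: both phases equal -> all ratios 100, MLDD 0
  spec <- small_spec(expiratory_volume_ratio = 1, delta_exp = 0,
                     trapped_fraction = 1, noise_sigma = 0, seed = 2)
  ph <- quiet_phantom(spec)
  res <- compute_all_indices(ph$ins_volume, ph$exp_volume, ph$ins_mask,
                             ph$exp_mask)
  expect_equal(res$ei_volume_pct, 100)
  expect_equal(res$mldd_hu, 0)
  expect_equal(res$ei_mld_pct, 100)

  # 3-voxel fixture used as both phases
  v <- density_volume(array(c(-1000, -800, -600), c(3, 1, 1)), c(1, 1, 1))
  ve <- density_volume(array(c(-1000, -800, -600), c(3, 1, 1)), c(1, 1, 1),
                       phase = "expiratory")
  m <- lung_mask(array(c(1L, 1L, 2L), c(3, 1, 1)))
  r2 <- compute_all_indices(v, ve, m, m)
  expect_equal(r2$ei_volume_pct, 100)
  expect_equal(r2$mldd_hu, 0)
  expect_equal(unname(r2$laa_pct["E850"]), 100 / 3)

  # result invariants on a generic phantom
  ph3 <- quiet_phantom(small_spec(trapped_fraction = 0.4, seed = 5))
  r3 <- compute_all_indices(ph3$ins_volume, ph3$exp_volume, ph3$ins_mask,
                            ph3$exp_mask)
  expect_identical(r3$mldd_hu, r3$exp_mld_hu - r3$ins_mld_hu)
  pcts <- c(r3$ei_volume_pct, r3$laa_pct, r3$haa_pct)
  expect_true(all(pcts >= 0 & pcts <= 100))
  expect_true(all(diff(r3$laa_pct) <= 0))  # E850 >= E900 >= E950
  x <- ph3$exp_volume$values[ph3$exp_mask$membership != 0]
  expect_true(min(x) <= r3$exp_mld_hu && r3$exp_mld_hu <= max(x))
  expect_named(r3$per_side, c("left", "right"))
})

test_that("HU plausibility violations warn with a count, without clipping", {
  vals <- array(c(-1100, -800, -600, -700), c(4, 1, 1))
  expect_warning(v <- density_volume(vals, c(1, 1, 1)),
                 "1 voxel\\(s\\) outside")
  expect_equal(min(v$values), -1100)
})

test_that("convenience segmenter recovers phantom lungs with high Dice", {
  ph <- quiet_phantom(small_spec(seed = 13))
  seg <- simple_lung_segment(ph$ins_volume)
  gt <- ph$ins_mask$membership; sg <- seg$membership
  dice <- 2 * sum(gt != 0 & sg != 0) / (sum(gt != 0) + sum(sg != 0))
  expect_gte(dice, 0.99)
  # left/right labels follow component centroids
  expect_true(all(sg[sg != 0] == gt[sg != 0]))

  # mirroring the volume along the left-right axis swaps the labels
  mirrored <- suppressWarnings(
    density_volume(ph$ins_volume$values[dim(ph$ins_volume$values)[1]:1, , ],
                   ph$ins_volume$spacing))
  seg_m <- simple_lung_segment(mirrored)
  gt_m <- gt[dim(gt)[1]:1, , ]
  swapped <- ifelse(gt_m == 1L, 2L, ifelse(gt_m == 2L, 1L, 0L))
  agree <- mean(seg_m$membership[seg_m$membership != 0] ==
                  swapped[seg_m$membership != 0])
  expect_gte(agree, 0.99)

  # uniform soft tissue: nothing to segment
  soft <- density_volume(array(40, c(10, 10, 10)), c(1, 1, 1))
  expect_error(simple_lung_segment(soft), "segmentation failure")
})
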
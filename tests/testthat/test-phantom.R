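test_that("phantom generation is deterministic under the seed", {
  a <- quiet_phantom(small_spec(trapped_fraction = 0.3, seed = 21))
  b <- quiet_phantom(small_spec(trapped_fraction = 0.3, seed = 21))
  c <- quiet_phantom(small_spec(trapped_fraction = 0.3, seed = 22))
  expect_identical(a$ins_volume$values, b$ins_volume$values)
  expect_identical(a$exp_volume$values, b$exp_volume$values)
  expect_identical(a$ins_mask$membership, b$ins_mask$membership)
  expect_false(identical(a$ins_volume$values, c$ins_volume$values))
})

test_that("spec invariants are enforced", {
  expect_error(small_spec(trapped_fraction = 1.2), "trapped_fraction")
  expect_error(small_spec(expiratory_volume_ratio = 0), "expiratory_volume_ratio")
  expect_error(small_spec(sigma_parenchyma = 0), "sigma_parenchyma")
  expect_error(small_spec(mu_ins = -50, delta_exp = 130), "below soft tissue")
  # ellipsoid pushed outside the grid
  expect_error(small_spec(lung_centers = rbind(c(3, 20, 15), c(28, 20, 15))),
               "outside the grid")
  # overlapping ellipsoids
  expect_error(small_spec(lung_centers = rbind(c(18, 20, 15), c(22, 20, 15))),
               "overlap")
})

test_that("noise-free shift phantom: expiratory equals inspiratory + delta", {
  spec <- small_spec(trapped_fraction = 0, delta_exp = 130, noise_sigma = 0,
                     seed = 8)
  ph <- quiet_phantom(spec)
  matched <- ph$exp_mask$membership != 0
  expect_true(all(matched <= (ph$ins_mask$membership != 0)))  # exp subset of ins
  expect_equal(ph$exp_volume$values[matched],
               ph$ins_volume$values[matched] + 130)
  # masks exactly delimit the generated lung voxels
  expect_true(all(ph$ins_volume$values[ph$ins_mask$membership == 0] ==
                    spec$body_hu))
})

test_that("identity-phase phantom gives MLDD 0 and E/I volume 100", {
  ph <- quiet_phantom(small_spec(expiratory_volume_ratio = 1, delta_exp = 0,
                                 trapped_fraction = 1, seed = 9))
  expect_equal(ph$expected$mldd_hu, 0)
  expect_equal(ph$expected$ei_volume_pct, 100)
  res <- compute_all_indices(ph$ins_volume, ph$exp_volume, ph$ins_mask,
                             ph$exp_mask)
  expect_equal(res$ei_volume_pct, 100)
})

test_that("analytic expectations reduce correctly in the limits", {
  # p = 0: single-Gaussian CDF at each threshold
  s0 <- small_spec(trapped_fraction = 0, mu_ins = -880, sigma_parenchyma = 30,
                   delta_exp = 150, noise_sigma = 0)
  e0 <- analytic_expectations(s0)
  expect_equal(unname(e0$laa_pct["E900"]),
               100 * pnorm(-900, -880 + 150, 30))
  # delta = 0: no expiratory shift, MLDD expectation 0 for any p
  sd0 <- small_spec(delta_exp = 0, trapped_fraction = 0.37)
  expect_equal(analytic_expectations(sd0)$mldd_hu, 0)
})

test_that("worked two-component example matches the frozen MC oracle", {
  # mu = -880, sigma = 30, delta = +150, p = 0.3. Oracle values frozen from
  # a 10^6-draw Monte-Carlo simulation of the mixture (and its closed form):
  # E[EXP MLD] = -775, E900 = 7.5748%.
  spec <- small_spec(mu_ins = -880, sigma_parenchyma = 30, delta_exp = 150,
                     trapped_fraction = 0.3, noise_sigma = 0)
  e <- analytic_expectations(spec)
  expect_equal(e$exp_mld_hu, -775)
  expect_equal(unname(e$laa_pct["E900"]), 7.5748, tolerance = 1e-4)
  # and a fresh in-test MC draw agrees within 4 MC SEs
  set.seed(31)
  n <- 2e5
  trapped <- runif(n) < 0.3
  x <- rnorm(n, -880 + ifelse(trapped, 0, 150), 30)
  mc <- 100 * mean(x < -900)
  se <- 100 * sqrt(0.075748 * (1 - 0.075748) / n)
  expect_lt(abs(mc - unname(e$laa_pct["E900"])), 4 * se)
})

test_that("densitometry on a generated phantom recovers the expectations", {
  spec <- small_spec(mu_ins = -880, sigma_parenchyma = 30, delta_exp = 150,
                     trapped_fraction = 0.3, noise_sigma = 5, seed = 17)
  ph <- quiet_phantom(spec)
  res <- compute_all_indices(ph$ins_volume, ph$exp_volume, ph$ins_mask,
                             ph$exp_mask)
  exp_n <- sum(ph$exp_mask$membership != 0)
  e <- ph$expected
  expect_lt(abs(res$exp_mld_hu - e$exp_mld_hu),
            3 * e$sd_exp_hu / sqrt(exp_n))
  q <- e$laa_pct[["E900"]] / 100
  expect_lt(abs(res$laa_pct[["E900"]] - e$laa_pct[["E900"]]),
            3 * 100 * sqrt(q * (1 - q) / exp_n))
  expect_lt(abs(res$ei_volume_pct - e$ei_volume_pct),
            ei_volume_discretization_bound(ph$ins_mask, ph$exp_mask))
})

test_that("trapped blobs are spatially clustered, with the exact fraction", {
  spec <- small_spec(trapped_fraction = 0.3, delta_exp = 150, noise_sigma = 0,
                     n_trapped_blobs = 4, seed = 23)
  ph <- quiet_phantom(spec)
  matched <- which(ph$exp_mask$membership != 0)
  shift <- ph$exp_volume$values[matched] - ph$ins_volume$values[matched]
  trapped <- shift == 0
  expect_equal(mean(trapped), 0.3, tolerance = 0.01)
  # clustering: a trapped voxel's 6-neighbours are trapped far more often
  # than the marginal rate (mosaic, not salt-and-pepper)
  d <- dim(ph$exp_volume$values)
  tr_arr <- array(FALSE, d); tr_arr[matched[trapped]] <- TRUE
  lung <- array(FALSE, d); lung[matched] <- TRUE
  i3 <- arrayInd(matched[trapped], d)
  inside <- i3[, 1] > 1 & i3[, 1] < d[1]
  nb <- matched[trapped][inside] + 1L  # +x neighbour
  nb_rate <- mean(tr_arr[nb][lung[nb]])
  expect_gt(nb_rate, 0.7)
})
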
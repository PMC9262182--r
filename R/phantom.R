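#' Specification of a paired-phase chest phantom
#'
#' Describes a synthetic thorax used to exercise the densitometry pipeline:
#' two ellipsoidal lungs embedded in soft tissue, imaged at full inspiration
#' and at end expiration. Parenchymal density at inspiration is Gaussian,
#' `N(mu, sigma_parenchyma)`, where `mu` follows the age trend
#' `mu_ins + hu_per_year * (age_years - 12)` (12 y is the reference age).
#' On expiration the lung geometry shrinks to `expiratory_volume_ratio`
#' times its inspiratory volume and non-trapped parenchyma densifies by
#' `delta_exp` HU, while a blob-clustered fraction `trapped_fraction` of
#' voxels keeps its inspiratory density — the mosaic-attenuation pattern of
#' expiratory air trapping.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm.
#' @param lung_centers 2x3 matrix of ellipsoid centres in voxel coordinates
#'   (row 1 = left lung, row 2 = right lung).
#' @param lung_semiaxes 2x3 matrix of inspiratory semi-axes in voxels.
#' @param expiratory_volume_ratio target E/I volume as a fraction in (0, 1].
#' @param mu_ins mean parenchymal HU at inspiration at the reference age.
#' @param sigma_parenchyma parenchymal HU standard deviation (> 0).
#' @param delta_exp expiratory HU increase of non-trapped parenchyma (>= 0).
#' @param trapped_fraction fraction of parenchymal voxels that do not
#'   densify on expiration, in \[0, 1\].
#' @param n_trapped_blobs number of blob seeds per lung (spatial clustering).
#' @param noise_sigma additive HU noise SD (>= 0), independent per phase.
#' @param body_hu soft-tissue background HU.
#' @param age_years subject age; drives `mu` via `hu_per_year`.
#' @param hu_per_year HU change of `mu` per year of age (default -15).
#' @param seed top-level seed for all phantom randomness.
#' @return An object of class `phantom_spec` (validated list).
#' @seealso [generate_phantom()], [analytic_expectations()]
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 72),
                         voxel_spacing = c(2, 2, 2.5),
                         lung_centers = rbind(c(30, 48, 36), c(66, 48, 36)),
                         lung_semiaxes = rbind(c(16, 27, 28), c(16, 27, 28)),
                         expiratory_volume_ratio = 0.58,
                         mu_ins = -788,
                         sigma_parenchyma = 60,
                         delta_exp = 130,
                         trapped_fraction = 0,
                         n_trapped_blobs = 6,
                         noise_sigma = 10,
                         body_hu = 40,
                         age_years = 12,
                         hu_per_year = -15,
                         seed = 1) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing = as.numeric(voxel_spacing),
               lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
               expiratory_volume_ratio = expiratory_volume_ratio,
               mu_ins = mu_ins, sigma_parenchyma = sigma_parenchyma,
               delta_exp = delta_exp, trapped_fraction = trapped_fraction,
               n_trapped_blobs = as.integer(n_trapped_blobs),
               noise_sigma = noise_sigma, body_hu = body_hu,
               age_years = age_years, hu_per_year = hu_per_year,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  stopifnot(length(s$grid_shape) == 3L, all(s$grid_shape >= 4L),
            length(s$voxel_spacing) == 3L, all(s$voxel_spacing > 0),
            is.matrix(s$lung_centers), dim(s$lung_centers) == c(2L, 3L),
            is.matrix(s$lung_semiaxes), dim(s$lung_semiaxes) == c(2L, 3L),
            all(s$lung_semiaxes > 0), s$n_trapped_blobs >= 1L)
  if (s$trapped_fraction < 0 || s$trapped_fraction > 1)
    stop("trapped_fraction must lie in [0, 1]")
  if (s$expiratory_volume_ratio <= 0 || s$expiratory_volume_ratio > 1)
    stop("expiratory_volume_ratio must lie in (0, 1]")
  if (s$sigma_parenchyma <= 0) stop("sigma_parenchyma must be > 0")
  if (s$delta_exp < 0) stop("delta_exp must be >= 0")
  if (s$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (phantom_mu(s) + s$delta_exp >= s$body_hu)
    stop("lung density must stay below soft tissue: mu + delta_exp < body_hu")
  for (l in 1:2) {
    lo <- s$lung_centers[l, ] - s$lung_semiaxes[l, ]
    hi <- s$lung_centers[l, ] + s$lung_semiaxes[l, ]
    if (any(lo <= 1) || any(hi >= s$grid_shape))
      stop(sprintf("lung %d ellipsoid extends outside the grid", l))
  }
  # lattice-exact overlap check
  m <- ellipsoid_masks(s, 1)
  if (any(m[[1]] & m[[2]])) stop("lung ellipsoids overlap")
  if (sum(m[[1]]) == 0L || sum(m[[2]]) == 0L)
    stop("degenerate lung: ellipsoid contains no voxel")
  invisible(s)
}

# Effective inspiratory parenchymal mean, including the age trend.
phantom_mu <- function(spec) {
  spec$mu_ins + spec$hu_per_year * (spec$age_years - 12)
}

# Logical masks of the two lung ellipsoids, scaled by volume factor `ratio`
# (semi-axes scaled by ratio^(1/3)); voxel centres at integer coordinates.
ellipsoid_masks <- function(spec, ratio) {
  d <- spec$grid_shape
  s <- ratio^(1 / 3)
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  lapply(1:2, function(l) {
    c0 <- spec$lung_centers[l, ]
    se <- spec$lung_semiaxes[l, ] * s
    rx <- ((ax - c0[1]) / se[1])^2
    ry <- ((ay - c0[2]) / se[2])^2
    rz <- ((az - c0[3]) / se[3])^2
    outer(outer(rx, ry, `+`), rz, `+`) <= 1
  })
}

# Trapped-voxel selection: rank lung voxels of one phase by distance to the
# nearest blob seed (in ellipsoid-normalised coordinates, so blobs map
# consistently between phases) and take the closest `fraction` of them.
trapped_subset <- function(idx3, center, semiaxes_full, blob_u, fraction) {
  n <- nrow(idx3)
  if (fraction <= 0 || n == 0L) return(logical(n))
  if (fraction >= 1) return(rep(TRUE, n))
  u <- sweep(sweep(idx3, 2, center), 2, semiaxes_full, `/`)
  d2min <- rep(Inf, n)
  for (b in seq_len(nrow(blob_u))) {
    d2 <- (u[, 1] - blob_u[b, 1])^2 + (u[, 2] - blob_u[b, 2])^2 +
      (u[, 3] - blob_u[b, 3])^2
    d2min <- pmin(d2min, d2)
  }
  k <- round(fraction * n)
  rank(d2min, ties.method = "first") <= k
}

#' Generate a paired-phase chest phantom
#'
#' Realises a [phantom_spec()] into inspiratory and expiratory
#' [density_volume()]s with exact ground-truth [lung_mask()]s and the
#' closed-form expected densitometry result. The expiratory lung lattice is
#' a subset of the inspiratory one (same centres, shrunken semi-axes), and
#' voxels present in both phases share the same underlying parenchymal
#' density draw: a non-trapped voxel's expiratory value is its inspiratory
#' value plus `delta_exp` (plus independent per-phase noise), a trapped
#' voxel keeps its draw. Identical spec and seed give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `ins_volume`,
#'   `exp_volume`, `ins_mask`, `exp_mask`, `expected` (from
#'   [analytic_expectations()]) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 24),
#'   lung_centers = rbind(c(10, 16, 12), c(22, 16, 12)),
#'   lung_semiaxes = rbind(c(5, 9, 8), c(5, 9, 8)), seed = 7))
#' compute_all_indices(ph$ins_volume, ph$exp_volume, ph$ins_mask, ph$exp_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  mu <- phantom_mu(spec)

  ins_m <- ellipsoid_masks(spec, 1)
  exp_m <- ellipsoid_masks(spec, spec$expiratory_volume_ratio)

  ins_membership <- array(0L, d)
  ins_membership[ins_m[[1]]] <- 1L
  ins_membership[ins_m[[2]]] <- 2L
  exp_membership <- array(0L, d)
  exp_membership[exp_m[[1]]] <- 1L
  exp_membership[exp_m[[2]]] <- 2L

  # substream: blob geometry
  blob_u <- with_seed(substream_seed(spec$seed, "geometry"), {
    lapply(1:2, function(l) {
      u <- matrix(stats::runif(3 * spec$n_trapped_blobs * 4, -1, 1), ncol = 3)
      u <- u[rowSums(u^2) <= 1, , drop = FALSE]
      while (nrow(u) < spec$n_trapped_blobs) {
        extra <- matrix(stats::runif(3 * spec$n_trapped_blobs * 4, -1, 1), ncol = 3)
        u <- rbind(u, extra[rowSums(extra^2) <= 1, , drop = FALSE])
      }
      u[seq_len(spec$n_trapped_blobs), , drop = FALSE]
    })
  })

  # substream: parenchymal base density over the inspiratory lattice
  ins_idx <- which(ins_membership != 0L)
  base <- with_seed(substream_seed(spec$seed, "density"),
                    stats::rnorm(length(ins_idx), mu, spec$sigma_parenchyma))
  base_field <- array(NA_real_, d)
  base_field[ins_idx] <- base

  ins_vals <- array(spec$body_hu, d)
  ins_vals[ins_idx] <- base
  exp_idx <- which(exp_membership != 0L)
  exp_vals <- array(spec$body_hu, d)

  shift <- rep(spec$delta_exp, length(exp_idx))
  for (l in 1:2) {
    in_lung <- exp_membership[exp_idx] == l
    if (!any(in_lung)) next
    idx3 <- arrayInd(exp_idx[in_lung], d)
    trapped <- trapped_subset(idx3, spec$lung_centers[l, ],
                              spec$lung_semiaxes[l, ] *
                                spec$expiratory_volume_ratio^(1 / 3),
                              blob_u[[l]], spec$trapped_fraction)
    shift[which(in_lung)[trapped]] <- 0
  }
  exp_vals[exp_idx] <- base_field[exp_idx] + shift

  if (spec$noise_sigma > 0) {
    noise <- with_seed(substream_seed(spec$seed, "noise"), {
      list(ins = stats::rnorm(length(ins_idx), 0, spec$noise_sigma),
           exp = stats::rnorm(length(exp_idx), 0, spec$noise_sigma))
    })
    ins_vals[ins_idx] <- ins_vals[ins_idx] + noise$ins
    exp_vals[exp_idx] <- exp_vals[exp_idx] + noise$exp
  }

  structure(list(
    ins_volume = density_volume(ins_vals, spec$voxel_spacing, "inspiratory"),
    exp_volume = density_volume(exp_vals, spec$voxel_spacing, "expiratory"),
    ins_mask = lung_mask(ins_membership),
    exp_mask = lung_mask(exp_membership),
    expected = analytic_expectations(spec),
    spec = spec), class = "phantom")
}

#' Closed-form expected densitometry indices of a phantom
#'
#' The expiratory parenchymal density is a two-component Gaussian mixture:
#' with probability `p = trapped_fraction` a voxel is `N(mu, s^2)` (trapped,
#' unshifted) and with probability `1 - p` it is `N(mu + delta_exp, s^2)`,
#' where `s^2 = sigma_parenchyma^2 + noise_sigma^2`. Hence
#' `E[EXP MLD] = mu + (1 - p) * delta_exp`, `E[MLDD] = (1 - p) * delta_exp`,
#' and each threshold fraction is a mixture of Gaussian CDFs evaluated at
#' the threshold. Edge/partial-volume voxels are ignored (the phantom has
#' none: masks delimit the generated voxels exactly), and expected volumes
#' use the continuous ellipsoid volume, so the E/I volume expectation is
#' exactly `100 * expiratory_volume_ratio` up to lattice discretisation.
#'
#' @param spec a [phantom_spec()].
#' @param laa_thresholds_hu,haa_thresholds_hu thresholds as in
#'   [compute_all_indices()].
#' @return A list with elements named as in [compute_all_indices()]
#'   (`ins_mld_hu`, `exp_mld_hu`, `mldd_hu`, `ei_volume_pct`, `ei_mld_pct`,
#'   `laa_pct`, `haa_pct`, `ins_volume_ml`, `exp_volume_ml`) plus
#'   `sd_ins_hu` and `sd_exp_hu`, the per-voxel SDs needed for Monte-Carlo
#'   standard errors.
#' @export
analytic_expectations <- function(spec,
                                  laa_thresholds_hu = c(-850, -900, -950),
                                  haa_thresholds_hu = c(-600, -650)) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  mu <- phantom_mu(spec)
  p <- spec$trapped_fraction
  delta <- spec$delta_exp
  s <- sqrt(spec$sigma_parenchyma^2 + spec$noise_sigma^2)
  exp_mld <- mu + (1 - p) * delta

  mix_cdf <- function(t) p * stats::pnorm(t, mu, s) +
    (1 - p) * stats::pnorm(t, mu + delta, s)
  laa <- 100 * vapply(laa_thresholds_hu, mix_cdf, numeric(1))
  haa <- 100 * (1 - vapply(haa_thresholds_hu, mix_cdf, numeric(1)))
  names(laa) <- paste0("E", abs(laa_thresholds_hu))
  names(haa) <- paste0("E", abs(haa_thresholds_hu))

  vox_ml <- prod(spec$voxel_spacing) / 1000
  ins_ml <- sum(apply(spec$lung_semiaxes, 1, prod)) * 4 / 3 * pi * vox_ml
  # expiratory mixture SD: between-component spread adds p(1-p)*delta^2
  sd_exp <- sqrt(s^2 + p * (1 - p) * delta^2)

  list(ins_volume_ml = ins_ml,
       exp_volume_ml = ins_ml * spec$expiratory_volume_ratio,
       ins_mld_hu = mu, exp_mld_hu = exp_mld,
       mldd_hu = (1 - p) * delta,
       ei_volume_pct = 100 * spec$expiratory_volume_ratio,
       ei_mld_pct = 100 * exp_mld / mu,
       laa_pct = laa, haa_pct = haa,
       sd_ins_hu = s, sd_exp_hu = sd_exp)
}

#' Discretisation bound for the phantom E/I volume
#'
#' The lattice realisation of an ellipsoid differs from its continuous
#' volume by at most a one-voxel surface shell. This returns the resulting
#' worst-case bound, in percentage points, on
#' `|E/I volume - 100 * expiratory_volume_ratio|`: the observed ratio times
#' the sum of the two phases' surface-voxel fractions.
#'
#' @param ins_mask,exp_mask the phantom's ground-truth masks.
#' @return Bound in percentage points.
#' @export
ei_volume_discretization_bound <- function(ins_mask, exp_mask) {
  frac <- function(m) {
    a <- m$membership != 0L
    d <- dim(a)
    pad <- function(ax, off) {
      shifted <- array(FALSE, d)
      src <- lapply(1:3, function(i) seq_len(d[i]))
      dst <- src
      src[[ax]] <- src[[ax]][src[[ax]] + off >= 1 & src[[ax]] + off <= d[ax]]
      dst[[ax]] <- src[[ax]] + off
      shifted[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
      shifted
    }
    interior <- a
    for (ax in 1:3) for (off in c(-1L, 1L))
      interior <- interior & pad(ax, off)
    sum(a & !interior) / sum(a)
  }
  n_ins <- sum(ins_mask$membership != 0L)
  n_exp <- sum(exp_mask$membership != 0L)
  100 * (n_exp / n_ins) * (frac(ins_mask) + frac(exp_mask))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> seed %d, %s grid, trapped fraction %.2f, E/I volume target %.0f%%\n",
              x$spec$seed, paste(x$spec$grid_shape, collapse = "x"),
              x$spec$trapped_fraction, 100 * x$spec$expiratory_volume_ratio))
  invisible(x)
}
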
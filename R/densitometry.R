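#' Mean lung density (MLD)
#'
#' Arithmetic mean of the HU values over the selected masked voxels — no
#' weighting, no trimming. This is the MLD of classical lung densitometry,
#' computed per respiratory phase.
#'
#' @param volume a [density_volume()].
#' @param mask a [lung_mask()] aligned to `volume`.
#' @param side `"both"`, `"left"` or `"right"`.
#' @return Mean density in HU (scalar).
#' @examples
#' v <- density_volume(array(c(-1000, -800, -600), c(3, 1, 1)), c(1, 1, 1))
#' m <- lung_mask(array(c(1L, 1L, 2L), c(3, 1, 1)))
#' mean_lung_density(v, m)  # -800
#' @export
mean_lung_density <- function(volume, mask, side = c("both", "left", "right")) {
  sel <- side_selector(mask, match.arg(side), volume)
  mean(volume$values[sel])
}

#' Lung volume from a mask
#'
#' Voxel count times voxel volume, converted from mm^3 to mL
#' (1 mL = 1000 mm^3).
#'
#' @param mask a [lung_mask()].
#' @param spacing voxel spacing in mm (length 3).
#' @param side `"both"`, `"left"` or `"right"`.
#' @return Volume in mL.
#' @export
lung_volume <- function(mask, spacing, side = c("both", "left", "right")) {
  sel <- side_selector(mask, match.arg(side))
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive lengths in mm")
  sum(sel) * prod(spacing) / 1000
}

#' Mean lung density difference (MLDD)
#'
#' Expiratory minus inspiratory MLD. The sign convention is fixed so that
#' healthy lungs — which densify on expiration — give positive values;
#' small or negative MLDD indicates expiratory air trapping.
#'
#' @param ins_mld,exp_mld inspiratory and expiratory MLD in HU.
#' @return MLDD in HU.
#' @examples
#' mldd(-788.0, -659.0)  # 129
#' @export
mldd <- function(ins_mld, exp_mld) {
  if (!is.finite(ins_mld) || !is.finite(exp_mld))
    stop("both MLD values must be finite")
  exp_mld - ins_mld
}

#' Expiratory-to-inspiratory ratio (E/I), in percent
#'
#' `100 * exp_value / ins_value`. For MLD the ratio is taken on the signed
#' HU values (both negative in practice), so a lung that densifies less on
#' expiration has a *higher* E/I MLD.
#'
#' @param ins_value,exp_value paired inspiratory and expiratory values
#'   (volumes in mL or MLD in HU).
#' @return Ratio in percent.
#' @export
ei_ratio <- function(ins_value, exp_value) {
  if (any(ins_value == 0)) stop("inspiratory value is zero; E/I ratio undefined")
  100 * exp_value / ins_value
}

#' Threshold attenuation fraction (LAA / HAA percentage)
#'
#' Percentage of masked voxels strictly beyond a HU threshold. Low
#' attenuation areas (LAA, e.g. E850/E900/E950 on the expiratory phase) use
#' `direction = "below"` (HU < threshold); high attenuation areas (HAA,
#' E600/E650) use `direction = "above"` (HU > threshold). Voxels exactly
#' equal to the threshold count for neither tail.
#'
#' @param volume a [density_volume()].
#' @param mask aligned [lung_mask()].
#' @param threshold_hu threshold in HU (e.g. -900).
#' @param direction `"below"` or `"above"`.
#' @param side `"both"`, `"left"` or `"right"`.
#' @return Percentage in \[0, 100\].
#' @export
attenuation_fraction <- function(volume, mask, threshold_hu,
                                 direction = c("below", "above"),
                                 side = c("both", "left", "right")) {
  direction <- match.arg(direction)
  sel <- side_selector(mask, match.arg(side), volume)
  x <- volume$values[sel]
  n_beyond <- if (direction == "below") sum(x < threshold_hu) else sum(x > threshold_hu)
  100 * n_beyond / length(x)
}

#' Compute the full panel of lung-density indices for one subject
#'
#' Combines both phases into the densitometry result used throughout the
#' diagnostic analysis: inspiratory/expiratory volumes and MLDs, MLDD,
#' E/I volume and E/I MLD (percent), expiratory low-attenuation fractions
#' below each LAA threshold and high-attenuation fractions above each HAA
#' threshold. Whole-lung values are computed over the union of both lungs
#' (voxel-weighted); per-side values are reported alongside.
#'
#' @param ins_volume,exp_volume inspiratory and expiratory
#'   [density_volume()]s.
#' @param ins_mask,exp_mask their aligned [lung_mask()]s.
#' @param laa_thresholds_hu LAA thresholds (HU, `below` direction) applied to
#'   the expiratory phase; default -850, -900, -950.
#' @param haa_thresholds_hu HAA thresholds (HU, `above` direction), default
#'   -600, -650.
#' @return An object of class `densitometry_result`: a named list with
#'   elements `ins_volume_ml`, `exp_volume_ml`, `ins_mld_hu`, `exp_mld_hu`,
#'   `mldd_hu`, `ei_volume_pct`, `ei_mld_pct`, `laa_pct` (named by threshold),
#'   `haa_pct`, and `per_side` (the same fields for `left` and `right`).
#' @export
compute_all_indices <- function(ins_volume, exp_volume, ins_mask, exp_mask,
                                laa_thresholds_hu = c(-850, -900, -950),
                                haa_thresholds_hu = c(-600, -650)) {
  if (ins_volume$phase != "inspiratory" || exp_volume$phase != "expiratory")
    stop("volumes must be passed as (inspiratory, expiratory)")
  one_side <- function(side) {
    ins_v <- lung_volume(ins_mask, ins_volume$spacing, side)
    exp_v <- lung_volume(exp_mask, exp_volume$spacing, side)
    ins_m <- mean_lung_density(ins_volume, ins_mask, side)
    exp_m <- mean_lung_density(exp_volume, exp_mask, side)
    laa <- vapply(laa_thresholds_hu, function(t)
      attenuation_fraction(exp_volume, exp_mask, t, "below", side), numeric(1))
    haa <- vapply(haa_thresholds_hu, function(t)
      attenuation_fraction(exp_volume, exp_mask, t, "above", side), numeric(1))
    names(laa) <- paste0("E", abs(laa_thresholds_hu))
    names(haa) <- paste0("E", abs(haa_thresholds_hu))
    list(ins_volume_ml = ins_v, exp_volume_ml = exp_v,
         ins_mld_hu = ins_m, exp_mld_hu = exp_m,
         mldd_hu = mldd(ins_m, exp_m),
         ei_volume_pct = ei_ratio(ins_v, exp_v),
         ei_mld_pct = ei_ratio(ins_m, exp_m),
         laa_pct = laa, haa_pct = haa)
  }
  res <- one_side("both")
  res$per_side <- list(left = one_side("left"), right = one_side("right"))
  structure(res, class = "densitometry_result")
}

#' @export
print.densitometry_result <- function(x, ...) {
  cat("<densitometry_result>\n")
  cat(sprintf("  INS V %.1f mL  EXP V %.1f mL  E/I volume %.1f%%\n",
              x$ins_volume_ml, x$exp_volume_ml, x$ei_volume_pct))
  cat(sprintf("  INS MLD %.1f HU  EXP MLD %.1f HU  MLDD %.1f HU  E/I MLD %.1f%%\n",
              x$ins_mld_hu, x$exp_mld_hu, x$mldd_hu, x$ei_mld_pct))
  cat("  LAA%:", paste(sprintf("%s=%.2f", names(x$laa_pct), x$laa_pct),
                       collapse = "  "), "\n")
  cat("  HAA%:", paste(sprintf("%s=%.2f", names(x$haa_pct), x$haa_pct),
                       collapse = "  "), "\n")
  invisible(x)
}

#' Convenience threshold-based lung segmenter
#'
#' A deliberately simple stand-in for a clinical lung-segmentation tool,
#' intended for phantoms and quick looks: voxels with HU below
#' `air_threshold_hu` are air candidates; candidate components connected to
#' the grid border (outside-body air) are removed by 6-neighbour
#' connectivity; the largest one or two remaining components of at least
#' `min_component_voxels` voxels are kept and labelled left (1) / right (2)
#' by the component centroid along the first array axis (lower index =
#' subject-left by this package's convention).
#'
#' @param volume a [density_volume()].
#' @param air_threshold_hu HU threshold separating aerated lung from soft
#'   tissue; default -400.
#' @param min_component_voxels smallest component size kept; default 50.
#' @return A [lung_mask()].
#' @export
simple_lung_segment <- function(volume, air_threshold_hu = -400,
                                min_component_voxels = 50) {
  if (!inherits(volume, "density_volume")) stop("`volume` must be a density_volume")
  dims <- dim(volume$values)
  cand <- which(volume$values < air_threshold_hu)
  if (length(cand) == 0L)
    stop("segmentation failure: no voxel below the air threshold")
  comp <- label_components_3d(cand, dims)
  # drop components touching the grid border: outside-body air
  idx3 <- arrayInd(cand, dims)
  on_border <- idx3[, 1] == 1L | idx3[, 1] == dims[1] |
    idx3[, 2] == 1L | idx3[, 2] == dims[2] |
    idx3[, 3] == 1L | idx3[, 3] == dims[3]
  border_comps <- unique(comp[on_border])
  keep <- !(comp %in% border_comps)
  cand <- cand[keep]; comp <- comp[keep]; idx3 <- idx3[keep, , drop = FALSE]
  if (length(cand) == 0L)
    stop("segmentation failure: all low-attenuation voxels connect to the border")
  sizes <- table(comp)
  sizes <- sizes[sizes >= min_component_voxels]
  if (length(sizes) == 0L)
    stop("segmentation failure: no component reaches min_component_voxels")
  top <- names(sort(sizes, decreasing = TRUE))[seq_len(min(2L, length(sizes)))]
  membership <- array(0L, dims)
  cx <- vapply(top, function(k) mean(idx3[comp == k, 1]), numeric(1))
  labels <- if (length(top) == 2L) {
    if (cx[1] < cx[2]) c(1L, 2L) else c(2L, 1L)
  } else 1L
  for (i in seq_along(top))
    membership[cand[comp == top[i]]] <- labels[i]
  lung_mask(membership)
}

# 6-neighbour connected-component labelling on a sparse voxel set.
# Returns a component id per element of `idx` (linear indices into `dims`).
label_components_3d <- function(idx, dims) {
  if (length(idx) == 1L) return(1L)
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  i3 <- arrayInd(idx, dims)
  edges <- NULL
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (ax in 1:3) {
    ok <- i3[, ax] < dims[ax]
    nb <- idx[ok] + strides[ax]
    hit <- pos[nb] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(pos[idx[ok][hit]], pos[nb[hit]]))
  }
  if (is.null(edges)) return(seq_along(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership
}
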
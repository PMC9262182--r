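#' 3-D CT density volume
#'
#' Wraps a 3-D array of attenuation values in Hounsfield units (HU) together
#' with the voxel spacing and the respiratory phase it was acquired in.
#' HU values are expected to lie in the CT plausibility window
#' \eqn{[-1024, 3071]}; values outside it are reported with a warning (with a
#' count) but never silently clipped, since synthetic noise tails can
#' legitimately stray past the window.
#'
#' @param values numeric 3-D array of HU values.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm, all
#'   strictly positive.
#' @param phase `"inspiratory"` or `"expiratory"`.
#' @return An object of class `density_volume`: a list with elements
#'   `values`, `spacing` and `phase`.
#' @examples
#' v <- density_volume(array(-800, c(4, 4, 4)), spacing = c(1, 1, 1),
#'                     phase = "inspiratory")
#' dim(v$values)
#' @export
density_volume <- function(values, spacing, phase = c("inspiratory", "expiratory")) {
  phase <- match.arg(phase)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array of HU values")
  if (length(values) == 0L) stop("density volume grid is empty")
  if (length(spacing) != 3L || !is.numeric(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive lengths in mm")
  n_out <- sum(values < -1024 | values > 3071, na.rm = TRUE)
  if (n_out > 0L)
    warning(sprintf("%d voxel(s) outside the HU plausibility window [-1024, 3071]",
                    n_out))
  structure(list(values = values, spacing = as.numeric(spacing), phase = phase),
            class = "density_volume")
}

#' Binary/labelled lung mask aligned to a density volume
#'
#' Voxel labels: 0 = outside the lungs, 1 = left lung, 2 = right lung.
#'
#' @param membership integer-valued 3-D array with values in \{0, 1, 2\}.
#' @return An object of class `lung_mask` (list with element `membership`).
#' @export
lung_mask <- function(membership) {
  if (!is.array(membership) || length(dim(membership)) != 3L)
    stop("`membership` must be a 3-D array")
  u <- unique(as.vector(membership))
  if (!all(u %in% c(0, 1, 2)))
    stop("mask labels must be 0 (outside), 1 (left lung) or 2 (right lung)")
  if (!any(membership != 0))
    stop("lung mask has no nonzero voxel")
  structure(list(membership = membership), class = "lung_mask")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("<density_volume> %s phase, %s voxels, spacing %s mm\n",
              x$phase, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels: %d left, %d right\n",
              paste(dim(x$membership), collapse = "x"),
              sum(x$membership == 1), sum(x$membership == 2)))
  invisible(x)
}

# Checks mask/volume alignment and returns the logical selector for a side.
side_selector <- function(mask, side = c("both", "left", "right"), volume = NULL) {
  side <- match.arg(side)
  if (!inherits(mask, "lung_mask")) stop("`mask` must be a lung_mask")
  if (!is.null(volume)) {
    if (!inherits(volume, "density_volume"))
      stop("`volume` must be a density_volume")
    if (!identical(dim(volume$values), dim(mask$membership)))
      stop(sprintf("mask grid (%s) is not aligned to volume grid (%s)",
                   paste(dim(mask$membership), collapse = "x"),
                   paste(dim(volume$values), collapse = "x")))
  }
  sel <- switch(side,
                both  = mask$membership != 0,
                left  = mask$membership == 1,
                right = mask$membership == 2)
  if (!any(sel))
    stop(sprintf("empty lung region for side = '%s'", side))
  sel
}
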
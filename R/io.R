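#' Read and write density volumes and masks as NIfTI
#'
#' Volumes are stored with the voxel spacing in the NIfTI header. The
#' default on-disk datatype is `float64`, which round-trips the in-memory
#' HU values exactly; `int16` is available for compactness and matches the
#' integer HU quantisation of clinical CT, at the cost of rounding
#' (documented, not silent: choosing it is the caller's decision). Masks
#' are written as `uint8` label volumes (0/1/2).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param phase respiratory phase to tag the loaded volume with (NIfTI
#'   carries no phase field).
#' @return `read_volume()` a [density_volume()]; `read_mask()` a
#'   [lung_mask()].
#' @export
read_volume <- function(path, phase = c("inspiratory", "expiratory")) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s': expected a 3-D volume, got %d dimension(s)",
                 path, length(dim(img))))
  density_volume(array(as.numeric(img), dim(img)),
                 spacing = RNifti::pixdim(img)[1:3], phase = match.arg(phase))
}

#' @rdname read_volume
#' @param volume a [density_volume()] to write.
#' @param datatype `"float64"` (lossless) or `"int16"` (integer HU,
#'   rounded).
#' @export
write_volume <- function(volume, path, datatype = c("float64", "int16")) {
  stopifnot(inherits(volume, "density_volume"))
  datatype <- match.arg(datatype)
  vals <- volume$values
  if (datatype == "int16") vals <- round(vals)
  attr(vals, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(vals,
                         datatype = if (datatype == "int16") "int16" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s': expected a 3-D mask, got %d dimension(s)",
                 path, length(dim(img))))
  lung_mask(array(as.integer(img), dim(img)))
}

#' @rdname read_volume
#' @param mask a [lung_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lung_mask"))
  img <- RNifti::asNifti(mask$membership, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a generated phantom to a directory
#'
#' Four NIfTI files (inspiratory/expiratory volume and mask) plus a JSON
#' sidecar holding the generator spec and the closed-form ground-truth
#' expectations.
#'
#' @param phantom a `phantom` from [generate_phantom()].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_volume(phantom$ins_volume, p("ins.nii.gz"))
  write_volume(phantom$exp_volume, p("exp.nii.gz"))
  write_mask(phantom$ins_mask, p("mask_ins.nii.gz"))
  write_mask(phantom$exp_mask, p("mask_exp.nii.gz"))
  spec <- phantom$spec
  spec$lung_centers <- as.data.frame(spec$lung_centers)
  spec$lung_semiaxes <- as.data.frame(spec$lung_semiaxes)
  jsonlite::write_json(list(spec = unclass(spec),
                            expected = phantom$expected),
                       p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(vapply(c("ins.nii.gz", "exp.nii.gz", "mask_ins.nii.gz",
                     "mask_exp.nii.gz", "ground_truth.json"), p, character(1)))
}

#' Read and write cohort tables as CSV
#'
#' Round-trips values at full precision and preserves missingness (empty
#' cells become `NA`).
#'
#' @param path CSV path.
#' @return `read_cohort()` returns a `cohort_table` data.frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age_years", "sex")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("'%s': malformed cohort table, missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(tab$id))
    stop(sprintf("'%s': duplicate subject id(s)", path))
  tab$group <- factor(tab$group, levels = c("control", "BO"))
  if (any(is.na(tab$group)))
    stop(sprintf("'%s': group labels must be 'control' or 'BO'", path))
  tab$sex <- factor(tab$sex, levels = c("male", "female"))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @rdname read_cohort
#' @param table a cohort data.frame to write.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a per-subject densitometry result as JSON
#'
#' @param result a `densitometry_result`.
#' @param path output JSON path.
#' @param provenance optional named list (input paths, thresholds, ...)
#'   stored alongside the indices; package version is always included.
#' @return Invisibly, `path`.
#' @export
write_result <- function(result, path, provenance = list()) {
  stopifnot(inherits(result, "densitometry_result"))
  prov <- c(list(package = "lungdens",
                 version = as.character(utils::packageVersion("lungdens"))),
            provenance)
  jsonlite::write_json(c(list(provenance = prov), unclass(result)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
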
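#' Labeled 3D volume with voxel-to-world geometry
#'
#' Minimal container for a labeled segmentation: an integer voxel array plus
#' the 4x4 voxel-to-world affine (mm). Voxel indices are 0-based with a
#' voxel-center convention, matching the NIfTI-1 standard, and all metric
#' computation downstream happens in world millimetres so results are
#' independent of the grid resolution.
#'
#' @param voxels 3D integer (or logical) array.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   a zero origin.
#' @param spacing Per-axis voxel size in mm; derived from the affine column
#'   norms when omitted.
#' @param xform_used Which NIfTI transform the affine came from (`"sform"`,
#'   `"qform"` or `"constructed"`), kept for provenance.
#' @return A `label_volume` object.
#' @export
label_volume <- function(voxels, affine = NULL, spacing = NULL,
                         xform_used = "constructed") {
  if (length(dim(voxels)) != 3)
    stop_tortr("voxels must be a 3D array", "invalid_spec")
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (length(spacing) == 1) spacing <- rep(spacing, 3)
    affine <- diag(c(spacing, 1))
  }
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop_tortr("affine must be an invertible 4x4 matrix", "invalid_spec")
  if (is.null(spacing))
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(voxels = array(as.integer(voxels), dim(voxels)),
                 affine = unname(affine), spacing = as.numeric(spacing),
                 xform_used = xform_used),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.integer(x$voxels)))
  cat("<label_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  labels: ", paste(utils::head(labs, 10), collapse = ", "),
      if (length(labs) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read / write NIfTI-1 labelmaps
#'
#' `read_labelmap()` loads a `.nii` / `.nii.gz` segmentation and records the
#' voxel-to-world affine, using the sform when it is valid and the qform
#' otherwise (the choice is stored in `xform_used` and logged). `write_labelmap()`
#' writes a [label_volume()] back out with its affine as the sform.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A [label_volume()].
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path))
    stop_tortr(paste0("input file not found: ", path), "io")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_tortr(
                    paste0("malformed NIfTI file ", path, ": ",
                           conditionMessage(e)), "io"))
  if (length(dim(img)) > 3) img <- img[, , , 1, drop = TRUE]
  xf <- RNifti::xform(img)
  used <- attr(xf, "code")
  used <- if (!is.null(used) && used >= 1) "sform_or_qform" else "constructed"
  vol <- label_volume(array(as.integer(round(img)), dim(img)[1:3]),
                      affine = matrix(as.numeric(xf), 4, 4),
                      xform_used = used)
  message("read_labelmap: ", path, " (xform: ", used, ")")
  vol
}

#' @rdname read_labelmap
#' @param volume A [label_volume()].
#' @export
write_labelmap <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world coordinates (mm) of 0-based voxel indices (n x 3 matrix)
voxel_to_world <- function(volume, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk, 1) %*% t(volume$affine)
  h[, 1:3, drop = FALSE]
}

#' Isolate one label as a binary mask
#'
#' Keeps only the voxels equal to `label`, preserving all geometry metadata.
#' Applying it to an already-binary mask with `label = 1` is the identity.
#'
#' @param volume A [label_volume()].
#' @param label Integer label to isolate.
#' @return A binary [label_volume()] (values 0/1).
#' @export
binarize <- function(volume, label) {
  mask <- volume$voxels == as.integer(label)
  if (!any(mask))
    stop_tortr(sprintf("label %d not present in volume", as.integer(label)),
               "empty_structure")
  label_volume(array(as.integer(mask), dim(mask)), affine = volume$affine,
               spacing = volume$spacing, xform_used = volume$xform_used)
}
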
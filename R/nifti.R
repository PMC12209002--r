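#' Reduce a 4D NIfTI image to parcel time series
#'
#' Averages voxels within each atlas label at every frame. The reduction is an
#' unweighted mean, so a noiseless image assembled from known parcel signals
#' is recovered exactly. NIfTI support is optional and isolated here; the rest
#' of the pipeline consumes parcel-level TSV files and never needs an imaging
#' library.
#'
#' @param image_path Path to a 4D NIfTI image.
#' @param atlas_path Path to a 3D integer-label NIfTI atlas on the same voxel
#'   grid; label 0 is background. Labels present in the atlas header but
#'   covering zero voxels are omitted with a warning.
#' @param tr_seconds Repetition time attached to the result.
#' @param subject_id,session_id Identifiers attached to the result.
#' @return A [parcel_ts] whose columns follow ascending atlas label order,
#'   named `parcel<label>`.
#' @export
parcellate_nifti <- function(image_path, atlas_path, tr_seconds = 2,
                             subject_id = NA_character_, session_id = NA_character_) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("parcellate_nifti() requires the RNifti package.", call. = FALSE)
  }
  img <- RNifti::readNifti(image_path)
  atlas <- RNifti::readNifti(atlas_path)
  dimg <- dim(img)
  datl <- dim(atlas)
  if (length(dimg) == 3) dimg <- c(dimg, 1L)
  if (length(dimg) != 4) {
    stop(sprintf("image must be 4D, got dimensions [%s].",
      paste(dim(img), collapse = " x ")), call. = FALSE)
  }
  if (!identical(as.integer(dimg[1:3]), as.integer(datl[1:3])) || length(datl) != 3) {
    stop(sprintf(
      "voxel grid mismatch: image [%s] vs atlas [%s].",
      paste(dimg[1:3], collapse = " x "), paste(datl, collapse = " x ")
    ), call. = FALSE)
  }
  lab <- as.integer(round(as.vector(atlas)))
  if (any(lab < 0)) stop("atlas labels must be non-negative integers.", call. = FALSE)
  labels <- sort(unique(lab[lab > 0]))
  if (length(labels) == 0) stop("atlas contains no non-background labels.", call. = FALSE)

  n_frames <- dimg[4]
  n_vox <- prod(dimg[1:3])
  mat <- matrix(as.vector(img), nrow = n_vox, ncol = n_frames)
  out <- matrix(NA_real_, nrow = n_frames, ncol = length(labels))
  for (j in seq_along(labels)) {
    vox <- which(lab == labels[j])
    out[, j] <- colMeans(mat[vox, , drop = FALSE])
  }
  parcel_ts(out,
    tr_seconds = tr_seconds,
    subject_id = subject_id, session_id = session_id,
    parcel_ids = paste0("parcel", labels)
  )
}
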
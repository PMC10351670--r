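# File plumbing: NIfTI round-trips for ROI volumes, CSV conventions for
# tables (UTF-8, comma, header, missing = empty field), JSON for models.

#' Read an image/mask NIfTI pair as an ROI volume
#'
#' @param image_path Path to the intensity NIfTI-1 file.
#' @param mask_path Path to the binary mask NIfTI-1 file (same grid).
#' @param hemisphere Hemisphere label.
#' @return An [roi_volume()] with spacing taken from the image header.
#' @export
read_volume_pair <- function(image_path, mask_path, hemisphere = NA_character_) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  if (max(abs(RNifti::xform(img) - RNifti::xform(msk))) > 1e-4) {
    stop("image and mask affines differ", call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  mask <- array(as.array(msk) > 0, dim(img))
  if (!any(mask)) stop("empty ROI", call. = FALSE)
  roi_volume(array(as.numeric(as.array(img)), dim(img)), mask,
             spacing = spacing, hemisphere = hemisphere)
}

#' Write an ROI volume as an image/mask NIfTI pair
#'
#' @param roi An [roi_volume()].
#' @param image_path,mask_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_volume_pair <- function(roi, image_path, mask_path) {
  stopifnot(inherits(roi, "roi_volume"))
  img <- RNifti::asNifti(roi$intensities)
  RNifti::pixdim(img) <- roi$spacing
  msk <- RNifti::asNifti(array(as.integer(roi$mask), dim(roi$mask)))
  RNifti::pixdim(msk) <- roi$spacing
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}

#' Write a table as CSV (package conventions)
#'
#' UTF-8, comma-separated, header row, missing values as empty fields.
#'
#' @param table Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
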
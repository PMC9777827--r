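# image I/O and the chained three-stage pipeline

#' Read a grayscale image
#'
#' Reads PNG or TIFF images as a 2-D matrix on the native 0-255 scale
#' (multi-channel inputs are averaged to grayscale). The physical pixel
#' spacing, when unknown, is attached as `NA`; quantification then requires
#' an explicit `pixel_spacing_mm`. DICOM input is not supported by this
#' package; export to PNG/TIFF and pass the pixel spacing explicitly.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return numeric matrix with attribute `spacing_mm` (`NA` if unknown).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    dcm = ,
    dicom = stop("DICOM input is not supported; convert to PNG/TIFF and ",
                 "pass the pixel spacing via 'pixel_spacing_mm'"),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                           c(1, 2), mean)
  out <- img * 255
  attr(out, "spacing_mm") <- NA_real_
  out
}

#' Write / read a binary mask as PNG
#'
#' @param mask binary matrix.
#' @param path file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns an
#'   integer 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m))
}

#' Run the full quantification pipeline on one image
#'
#' Executes the three stages in order: ovary segmentation, follicle
#' segmentation, follicle counting. By default the predicted follicle mask
#' is intersected with the predicted ovary mask before quantification
#' (`restrict_to_ovary`), suppressing extra-ovarian false positives. If a
#' ground-truth follicle mask is supplied, a full counting report with
#' precision/recall is produced; otherwise the report contains the detected
#' follicles only.
#'
#' @param image 2-D grayscale matrix (0-255 or `[0, 1]`).
#' @param ovary_net,follicle_net trained [harmonic_unet()] models.
#' @param pixel_spacing_mm physical pixel size of `image` in mm (required
#'   for sizing).
#' @param gt_follicle_mask optional ground-truth follicle mask at the image
#'   resolution.
#' @param input_size side length at which the networks run; the image is
#'   resized there and the masks are resized back.
#' @param threshold probability threshold for both masks.
#' @param restrict_to_ovary intersect follicle predictions with the
#'   predicted ovary mask.
#' @return list with `ovary_mask`, `follicle_mask` (at input resolution),
#'   `report` (a `quant_report`, or a `follicle_set` when no ground truth is
#'   given) and `prob` (both probability maps).
#' @export
run_pipeline <- function(image, ovary_net, follicle_net, pixel_spacing_mm,
                         gt_follicle_mask = NULL, input_size = NULL,
                         threshold = 0.5, restrict_to_ovary = TRUE) {
  if (is.na(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("a positive 'pixel_spacing_mm' is required for quantification")
  d0 <- dim(image)
  size <- if (is.null(input_size)) max(d0) else input_size
  x <- preprocess_image(image, size)
  po <- predict_mask(ovary_net, x, threshold)
  pf <- predict_mask(follicle_net, x, threshold)
  ovary <- resize_mask(po$mask, d0[1], d0[2])
  foll <- resize_mask(pf$mask, d0[1], d0[2])
  if (restrict_to_ovary) foll <- foll * ovary
  report <- if (!is.null(gt_follicle_mask)) {
    counting_report(gt_follicle_mask, foll, pixel_spacing_mm)
  } else {
    recruitable_filter(extract_follicles(foll, pixel_spacing_mm))
  }
  list(ovary_mask = ovary, follicle_mask = foll, report = report,
       prob = list(ovary = po$prob, follicle = pf$prob))
}
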
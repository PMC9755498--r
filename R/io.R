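# PNG input/output. Images are 8-bit grayscale; masks are grayscale PNGs
# whose byte values are the class labels {0, 1, 2} directly.

#' Read / write images and label masks as PNG
#'
#' \code{read_image_png} returns intensities 0..255; \code{write_image_png}
#' accepts either that range or a normalized [-1, 1] matrix.
#' Mask files hold the literal label values, so they round-trip exactly.
#'
#' @param path file path
#' @return matrix (H x W)
#' @name png_io
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * 255
}

#' @rdname png_io
#' @param image intensity matrix, range 0..255 or [-1, 1]
#' @export
write_image_png <- function(image, path) {
  if (min(image) < 0) image <- (image + 1) * 127.5
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  out <- round(m * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname png_io
#' @param mask integer label matrix
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Write per-image AoP measurements as CSV
#' @param df data frame from \code{\link{measure_aop_batch}}
#' @param path output file
#' @export
write_aop_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report
#'
#' Per-image metrics as CSV next to a JSON aggregate with the fields
#' acc, dice_all, dice_ps, dice_fh, asd, aop_mean, aop_median, aop_std,
#' n_over_20.
#'
#' @param per_image data frame of per-image metrics
#' @param aggregate named list of summary metrics
#' @param csv_path,json_path output files
#' @export
write_eval_report <- function(per_image, aggregate, csv_path, json_path) {
  write.csv(per_image, csv_path, row.names = FALSE)
  jsonlite::write_json(aggregate, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
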
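#' Write a trimmed B-scan as an 8-bit grayscale PNG
#'
#' The image is 50 pixels wide by 256 tall (columns lateral, rows axial);
#' pixel values are rounded to the nearest 8-bit level.
#'
#' @param img a [TrimmedBScan-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBScan <- function(img, path) {
  stopifnot(is(img, "TrimmedBScan"))
  png::writePNG(round(img@pixels) / 255, path)
  invisible(path)
}

#' Read a trimmed B-scan from an 8-bit grayscale PNG
#'
#' @param path PNG path; the image must be exactly 50 x 256 pixels.
#'   Multi-channel images are reduced to their first channel.
#' @param vitreousBrightness optional known reference brightness; if
#'   `NULL` it is estimated from the innermost rows
#'   ([estimateVitreousBrightness()]).
#' @return A [TrimmedBScan-class].
#' @export
readBScan <- function(path, vitreousBrightness = NULL) {
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  if (!identical(dim(p), c(SCAN_ROWS, SCAN_COLS)))
    stop(sprintf("expected a %d x %d (tall x wide) image, got %d x %d",
                 SCAN_ROWS, SCAN_COLS, nrow(p), ncol(p)))
  TrimmedBScan(round(p * 255), vitreousBrightness)
}

#' Write a layer annotation as CSV
#'
#' One line per column with 0-based indices: columns `column`, `elm_row`,
#' `ez_row`, `rpe_row`; an empty cell marks an absent layer.
#'
#' @param ann an [AnnotationSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(ann, path) {
  stopifnot(is(ann, "AnnotationSet"))
  df <- data.frame(column = 0:(SCAN_COLS - 1L),
                   elm_row = ann@elm - 1L, ez_row = ann@ez - 1L,
                   rpe_row = ann@rpe - 1L)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a layer annotation CSV
#'
#' @param path CSV path in the format written by [writeAnnotation()].
#' @return An [AnnotationSet-class].
#' @export
readAnnotation <- function(path) {
  df <- utils::read.csv(path)
  need <- c("column", "elm_row", "ez_row", "rpe_row")
  if (!all(need %in% names(df))) stop("annotation CSV lacks required columns")
  df <- df[order(df$column), ]
  if (!identical(as.integer(df$column), 0:(SCAN_COLS - 1L)))
    stop(sprintf("annotation must cover columns 0..%d exactly", SCAN_COLS - 1L))
  AnnotationSet(df$elm_row + 1L, df$ez_row + 1L, df$rpe_row + 1L)
}
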
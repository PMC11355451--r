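#' Read a time-lapse stack from disk
#'
#' Accepts a multi-page TIFF, a glob pattern matching a numbered image
#' sequence (PNG or single-page TIFF), or a directory containing such a
#' sequence. Sequence frames are ordered by an explicit lexicographic sort
#' of their file names, independent of file-system listing order. RGB
#' frames are converted to a single channel with Rec.601 luminance weights
#' (0.299, 0.587, 0.114) and integer intensities are rescaled to `[0, 1]`
#' by the full range of the stored bit depth, so brightness drift between
#' frames is preserved.
#'
#' @param path_or_glob file path, glob pattern, or directory.
#' @param frame_interval,pixel_size optional metadata attached to the result.
#' @return a [frame_stack].
#' @seealso [save_stack()] for the inverse operation.
#' @export
load_stack <- function(path_or_glob, frame_interval = NULL, pixel_size = NULL) {
  if (!is.character(path_or_glob) || length(path_or_glob) != 1L)
    abort_validation("`path_or_glob` must be a single string")
  p <- path_or_glob
  if (file.exists(p) && !dir.exists(p)) {
    ext <- tolower(sub(".*\\.", "", p))
    if (ext %in% c("avi", "mp4", "mov", "mkv", "webm"))
      abort_capability(sprintf(
        "video container '%s' cannot be decoded in this build; convert to a multi-page TIFF or an image sequence first", p))
    if (!(ext %in% c("tif", "tiff")))
      abort_io(sprintf("single file input must be a multi-page TIFF, got '%s'", p))
    pages <- tryCatch(tiff::readTIFF(p, all = TRUE, info = FALSE),
                      error = function(e) abort_io(sprintf("cannot read TIFF '%s': %s", p, conditionMessage(e))))
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray)
    src <- p
  } else {
    files <- if (dir.exists(p)) {
      list.files(p, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                 full.names = TRUE)
    } else {
      Sys.glob(p)
    }
    if (length(files) == 0L)
      abort_io(sprintf("no readable input at '%s'", p))
    files <- files[sort.list(basename(files), method = "radix")]
    frames <- lapply(files, read_single_image)
    dims <- vapply(frames, dim, integer(2))
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
    if (length(bad))
      abort_validation(sprintf(
        "sequence frames with mismatched shape at indices: %s (%s)",
        paste(bad, collapse = ", "),
        paste(basename(files[bad]), collapse = ", ")))
    src <- p
  }
  if (length(frames) < 2L)
    abort_validation(sprintf("'%s' holds %d frame(s); at least 2 are required",
                             p, length(frames)))
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  frame_stack(frames, frame_interval = frame_interval,
              pixel_size = pixel_size, source = src)
}

read_single_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           abort_io(sprintf("unsupported image extension '%s'", ext))),
    error = function(e) abort_io(sprintf("cannot read '%s': %s", path,
                                         conditionMessage(e))))
  to_gray(img)
}

# Rec.601 luminance for RGB(A) arrays; identity for matrices
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L)
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    return(img[, , 1])
  }
  abort_validation("unsupported image layout")
}

#' Write a stack to disk
#'
#' `format = "tiff"` writes one multi-page 32-bit float TIFF, which round
#' trips intensities through [load_stack()] at single-float resolution.
#' `format = "png_sequence"` writes 8-bit files `frame_0001.png, ...` into
#' a directory, quantizing intensities to 1/255.
#'
#' @param stack a [frame_stack].
#' @param path output file (tiff) or directory (png_sequence).
#' @param format `"tiff"` or `"png_sequence"`.
#' @export
save_stack <- function(stack, path, format = c("tiff", "png_sequence")) {
  if (!inherits(stack, "frame_stack"))
    abort_validation("`stack` must be a frame_stack")
  format <- match.arg(format)
  T <- n_frames(stack)
  if (format == "tiff") {
    dir <- dirname(path)
    if (!dir.exists(dir)) abort_io(sprintf("directory '%s' does not exist", dir))
    frames <- lapply(seq_len(T), function(t) stack$frames[, , t])
    ok <- tryCatch(tiff::writeTIFF(frames, path, bits.per.sample = 32L,
                                   reduce = FALSE),
                   error = function(e) abort_io(sprintf("cannot write '%s': %s",
                                                        path, conditionMessage(e))))
    invisible(ok)
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) abort_io(sprintf("cannot create directory '%s'", path))
    }
    for (t in seq_len(T)) {
      f <- file.path(path, sprintf("frame_%04d.png", t))
      tryCatch(png::writePNG(stack$frames[, , t], f),
               error = function(e) abort_io(sprintf("cannot write '%s': %s",
                                                    f, conditionMessage(e))))
    }
    invisible(TRUE)
  }
}

#' Export / read a drift trajectory table
#'
#' Writes a delimited table with one row per frame: frame index (1-based),
#' the per-step displacement that brought the frame there (`dx`, `dy`;
#' zeros for frame 1), and the cumulative displacement (`cum_dx`,
#' `cum_dy`). `read_trajectory()` reconstructs the series and trajectory
#' from such a file.
#'
#' @param series a [translation_series] of length `T - 1`.
#' @param trajectory the matching [correction_trajectory] of length `T`.
#' @param path CSV file path.
#' @return `export_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns `list(series, trajectory)`.
#' @export
export_trajectory <- function(series, trajectory, path) {
  series <- as_translation_series(series)
  trajectory <- as_correction_trajectory(trajectory)
  if (nrow(trajectory) != nrow(series) + 1L)
    abort_validation(sprintf(
      "trajectory has %d rows but series implies %d frames",
      nrow(trajectory), nrow(series) + 1L))
  tab <- data.frame(
    frame = seq_len(nrow(trajectory)),
    dx = c(0, series[, 1]), dy = c(0, series[, 2]),
    cum_dx = trajectory[, 1], cum_dy = trajectory[, 2])
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no trajectory file at '%s'", path))
  tab <- utils::read.csv(path)
  need <- c("frame", "dx", "dy", "cum_dx", "cum_dy")
  if (!all(need %in% names(tab)))
    abort_validation(sprintf("trajectory table must have columns %s",
                             paste(need, collapse = ", ")))
  list(series = translation_series(as.matrix(tab[-1, c("dx", "dy")])),
       trajectory = correction_trajectory(as.matrix(tab[, c("cum_dx", "cum_dy")])))
}
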
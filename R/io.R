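# Thin TIFF I/O around the tiff package (16-bit multi-page stacks, one
# file per channel). Kept in Suggests: the quantification pipeline itself
# works on in-memory arrays.

require_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
}

#' Write an image stack to a multi-page 16-bit TIFF
#'
#' @param stack numeric array `rows x cols x frames` (a matrix is treated
#'   as a single frame); values must fit in 0..65535.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  require_tiff()
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (max(stack) > 65535 || min(stack) < 0)
    stop("stack values must lie in [0, 65535] for 16-bit output")
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) stack[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into an integer stack
#'
#' @param path TIFF file written by [write_stack_tiff()] (or any 16-bit
#'   grayscale multi-page TIFF).
#' @return Integer array `rows x cols x frames`.
#' @export
read_stack_tiff <- function(path) {
  require_tiff()
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- simplify2array(lapply(pages, function(p) round(p * 65535)))
  storage.mode(out) <- "integer"
  out
}

#' Write a synthetic movie (all channels) and its metadata to a directory
#'
#' One 16-bit multi-page TIFF per channel plus a `metadata.json` echoing
#' pixel size, frame interval, condition and seed.
#'
#' @param movie a `synthetic_movie`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "synthetic_movie"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(movie$channels), function(ch) {
    p <- file.path(dir, paste0(ch, ".tif"))
    write_stack_tiff(movie$channels[[ch]], p)
    p
  }, character(1))
  meta <- file.path(dir, "metadata.json")
  jsonlite::write_json(list(pixel_size = movie$pixel_size,
                            frame_interval = movie$frame_interval,
                            condition = movie$condition,
                            seed = movie$seed),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
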
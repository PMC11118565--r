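#' Multi-channel time-lapse movie container
#'
#' A `MovieStack` bundles one or more fluorescence channels of a time-lapse
#' acquisition with the acquisition metadata every downstream quantification
#' needs: the frame interval in seconds and the pixel size in micrometres per
#' pixel. Each channel is a numeric array indexed `[row, col, frame]`; all
#' channels must share the same dimensions. Channel names carry their role
#' (typically `"actin"`, `"lim"`, `"partner"`).
#'
#' @param channels named list of 3D numeric arrays `[row, col, frame]`.
#' @param frame_interval frame interval in seconds (> 0).
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @return an object of class `MovieStack`.
#' @examples
#' ch <- array(runif(16 * 16 * 4), c(16, 16, 4))
#' mv <- movie_stack(list(actin = ch), frame_interval = 3, pixel_size = 0.0653)
#' n_frames(mv)
#' @export
movie_stack <- function(channels, frame_interval, pixel_size) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named by its role (e.g. actin, lim, partner)")
  dims <- lapply(channels, function(ch) {
    if (length(dim(ch)) == 2L) ch <- array(ch, c(dim(ch), 1L))
    dim(ch)
  })
  channels <- lapply(channels, function(ch)
    if (length(dim(ch)) == 2L) array(ch, c(dim(ch), 1L)) else ch)
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all channels must share the same (row, col, frame) dimensions")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 (seconds)")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0 (um/px)")
  structure(
    list(channels = channels,
         frame_interval = as.numeric(frame_interval),
         pixel_size = as.numeric(pixel_size)),
    class = "MovieStack")
}

#' @rdname movie_stack
#' @param x a `MovieStack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "MovieStack"))
  dim(x$channels[[1]])[3]
}

#' @rdname movie_stack
#' @export
frame_dim <- function(x) {
  stopifnot(inherits(x, "MovieStack"))
  dim(x$channels[[1]])[1:2]
}

#' @rdname movie_stack
#' @param role channel role name.
#' @param frame frame index (1-based).
#' @export
get_frame <- function(x, role, frame) {
  stopifnot(inherits(x, "MovieStack"))
  ch <- x$channels[[role]]
  if (is.null(ch)) stop("channel role not present: ", role,
                        " (have: ", paste(names(x$channels), collapse = ", "), ")")
  ch[, , frame]
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("MovieStack: %d x %d px, %d frames, %d channel(s) [%s]\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  frame interval %.3g s, pixel size %.4g um/px\n",
              x$frame_interval, x$pixel_size))
  invisible(x)
}

#' Read and write movies as multi-page TIFF
#'
#' One 16-bit multi-page TIFF is written per channel
#' (`<basename>_<role>.tif`), together with a `<basename>_meta.yaml` sidecar
#' recording frame interval, pixel size, channel roles and the intensity
#' scale used for 16-bit quantization. `read_movie()` inverts the round trip.
#'
#' @param movie a `MovieStack`.
#' @param dir output directory (created if needed).
#' @param basename file name stem.
#' @return `write_movie()` returns the sidecar path invisibly; `read_movie()`
#'   returns a `MovieStack`.
#' @export
write_movie <- function(movie, dir, basename = "movie") {
  stopifnot(inherits(movie, "MovieStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- max(1, max(vapply(movie$channels, max, numeric(1))))
  for (role in names(movie$channels)) {
    ch <- movie$channels[[role]]
    pages <- lapply(seq_len(dim(ch)[3]), function(t) ch[, , t] / scale)
    tiff::writeTIFF(pages, file.path(dir, paste0(basename, "_", role, ".tif")),
                    bits.per.sample = 16L)
  }
  meta <- list(frame_interval = movie$frame_interval,
               pixel_size = movie$pixel_size,
               channels = names(movie$channels),
               intensity_scale = scale)
  path <- file.path(dir, paste0(basename, "_meta.yaml"))
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir, basename = "movie") {
  meta <- yaml::read_yaml(file.path(dir, paste0(basename, "_meta.yaml")))
  channels <- lapply(meta$channels, function(role) {
    pages <- tiff::readTIFF(file.path(dir, paste0(basename, "_", role, ".tif")),
                            all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * meta$intensity_scale
    arr
  })
  names(channels) <- meta$channels
  movie_stack(channels, meta$frame_interval, meta$pixel_size)
}
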
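#' Calibrated multi-channel time-lapse image stack
#'
#' The in-memory container for all synthetic and analysed imagery: a 4-d
#' numeric array \code{[row, col, channel, frame]} with pixel-size and
#' frame-interval calibration and a free-form \code{truth} list carrying
#' generator ground truth. Coordinates follow the image convention: origin
#' top-left, x = column, y = row, 0-based.
#'
#' @param pixels 4-d numeric array [row, col, channel, frame]
#' @param pixel_size_um physical pixel size in um
#' @param frame_interval_s time between frames in s
#' @param channels character vector naming the channels
#' @param truth list of generator ground-truth metadata
#' @return an object of class \code{ImageStack}
#' @export
image_stack <- function(pixels, pixel_size_um, frame_interval_s = 1,
                        channels = NULL, truth = list()) {
  if (length(dim(pixels)) == 2) dim(pixels) <- c(dim(pixels), 1, 1)
  if (length(dim(pixels)) == 3) dim(pixels) <- c(dim(pixels), 1)
  stopifnot(length(dim(pixels)) == 4, pixel_size_um > 0, frame_interval_s > 0)
  channels <- channels %||% paste0("ch", seq_len(dim(pixels)[3]))
  stopifnot(length(channels) == dim(pixels)[3])
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channels = channels, truth = truth),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d x %d px, %d channel(s) [%s], %d frame(s)\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "), d[4]))
  cat(sprintf("  pixel size %.4g um, frame interval %.4g s\n",
              x$pixel_size_um, x$frame_interval_s))
  if (length(x$truth)) {
    cat("  truth:", paste(names(x$truth), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract one frame of one channel as a matrix
#'
#' @param stack an ImageStack
#' @param channel channel name or index
#' @param frame frame index
#' @return numeric matrix
#' @export
get_frame <- function(stack, channel = 1, frame = 1) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) channel <- match(channel, stack$channels)
  stack$pixels[, , channel, frame]
}

#' Write / read an ImageStack as plain text
#'
#' Stacks are serialized as a long-format CSV (row, col, channel, frame,
#' value; 0-based indices) next to a JSON sidecar holding calibration,
#' channel names and ground truth. A text format stands in for multi-page
#' TIFF so that fixtures stay human-readable and portable.
#'
#' @param stack an ImageStack
#' @param path CSV path; sidecar written to \code{<path>.json}
#' @return \code{path}, invisibly (writer); an ImageStack (reader)
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$pixels)
  idx <- which(stack$pixels != 0, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                   channel = idx[, 3] - 1L, frame = idx[, 4] - 1L,
                   value = stack$pixels[idx])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(dim = d, pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               channels = stack$channels, truth = stack$truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param path CSV path written by \code{write_stack}
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  px <- array(0, dim = meta$dim)
  px[cbind(df$row + 1L, df$col + 1L, df$channel + 1L, df$frame + 1L)] <- df$value
  image_stack(px, meta$pixel_size_um, meta$frame_interval_s, meta$channels,
              as.list(meta$truth))
}
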
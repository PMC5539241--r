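# The cine loop: a timed stack of grayscale frames plus acquisition timing.

#' Cine loop container
#'
#' A contrast-enhanced ultrasound acquisition: grayscale frames on the 8-bit
#' 0-255 video-intensity scale stored as an `height x width x n_frames`
#' array, per-frame timestamps in seconds (strictly increasing), and the
#' time of the microbubble destruction pulse (`NA` when absent).
#'
#' @param frames Numeric array `c(H, W, T)` with values in [0, 255].
#' @param timestamps Numeric vector of length `T`, strictly increasing.
#' @param destruction_time Seconds, within the timestamp range, or `NA`.
#' @return An object of class `cine_loop`.
#' @export
cine_loop <- function(frames, timestamps, destruction_time = NA_real_) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    ceus_stop("frames must be an H x W x T array", "invalid_parameter")
  T_ <- dim(frames)[3]
  if (T_ < 1L) ceus_stop("cine loop needs at least one frame", "invalid_parameter")
  if (any(!is.finite(frames)) || min(frames) < 0 || max(frames) > 255)
    ceus_stop("frame intensities must be finite and within [0, 255]",
              "invalid_parameter")
  if (!is.numeric(timestamps) || length(timestamps) != T_ ||
      any(!is.finite(timestamps)) || (T_ > 1L && any(diff(timestamps) <= 0)))
    ceus_stop("timestamps must be strictly increasing, one per frame",
              "invalid_parameter")
  if (!is.na(destruction_time) &&
      (destruction_time < timestamps[1] || destruction_time > timestamps[T_]))
    ceus_stop("destruction_time must lie within the timestamp range (or be NA)",
              "invalid_parameter")
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         destruction_time = as.numeric(destruction_time)),
    class = "cine_loop"
  )
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("CEUS cine loop: %d x %d pixels, %d frames over %.3g s%s\n",
              d[1], d[2], d[3], diff(range(x$timestamps)),
              if (is.na(x$destruction_time)) ""
              else sprintf(", destruction pulse at %.3g s", x$destruction_time)))
  invisible(x)
}

#' @export
dim.cine_loop <- function(x) dim(x$frames)
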
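# Cine-loop persistence: multi-frame grayscale TIFF plus a JSON sidecar
# carrying the acquisition timing ({frame_rate, timestamps,
# destruction_time}). Frames are stored as 32-bit float samples scaled to
# [0, 1] (intensity / 255), so round trips are exact to single precision
# (~1e-5 on the 0-255 scale).

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a cine loop as multi-frame TIFF + JSON sidecar
#'
#' @param cine A [cine_loop()].
#' @param path TIFF output path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_cine_tiff <- function(cine, path) {
  stopifnot(inherits(cine, "cine_loop"))
  T_ <- dim(cine$frames)[3]
  frames <- lapply(seq_len(T_), function(k) cine$frames[, , k] / 255)
  tiff::writeTIFF(frames, path, bits.per.sample = 32)
  ts <- cine$timestamps
  fr <- if (length(ts) > 1) 1 / stats::median(diff(ts)) else NA
  jsonlite::write_json(
    list(frame_rate = fr, timestamps = ts,
         destruction_time = if (is.na(cine$destruction_time)) NULL
                            else cine$destruction_time),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cine loop written by [write_cine_tiff()]
#'
#' @param path TIFF path with its `.json` sidecar alongside.
#' @return A [cine_loop()].
#' @export
read_cine_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(sidecar_path(path))
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (length(dim(f)) == 3L) f <- f[, , 1]
    arr[, , k] <- f * 255
  }
  arr[arr < 0] <- 0; arr[arr > 255] <- 255
  dt <- if (is.null(meta$destruction_time)) NA_real_ else meta$destruction_time
  cine_loop(arr, meta$timestamps, dt)
}
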
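#' Line-scan carpet container
#'
#' A "carpet" is a line-scan time series arranged as lines x pixels (x
#' channels): each column is the intensity time trace of one position along
#' the scanned line. All physical-unit computations downstream require the
#' acquisition metadata carried here.
#'
#' @param data Numeric array `n_lines x n_pixels x n_channels` (a matrix is
#'   promoted to one channel) of non-negative counts.
#' @param pixel_size_nm Sampling pitch along the line, nm.
#' @param line_period_ms Time between successive lines, ms.
#' @param dwell_time_us Per-pixel integration time, us.
#' @param channel_names Character vector naming the channels.
#' @return An object of class `line_scan_carpet`.
#' @export
line_scan_carpet <- function(data, pixel_size_nm, line_period_ms,
                             dwell_time_us,
                             channel_names = paste0("ch", seq_len(dim(data)[3]))) {
  if (length(dim(data)) == 2) data <- array(data, dim = c(dim(data), 1))
  stopifnot(length(dim(data)) == 3, dim(data)[3] %in% 1:2,
            all(data >= 0), pixel_size_nm > 0, line_period_ms > 0,
            dwell_time_us > 0, length(channel_names) == dim(data)[3])
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 line_period_ms = line_period_ms,
                 dwell_time_us = dwell_time_us,
                 channel_names = channel_names),
            class = "line_scan_carpet")
}

#' @export
print.line_scan_carpet <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("line_scan_carpet: %d lines x %d px x %d channel(s); %.0f nm px, %.3f ms/line\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$line_period_ms))
  invisible(x)
}

#' Image time-series container
#'
#' @param data Numeric array `frames x rows x cols x channels`.
#' @param pixel_size_nm Pixel pitch, nm.
#' @param frame_period_ms Time between frames, ms.
#' @param channel_names Channel names.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm, frame_period_ms,
                        channel_names = paste0("ch", seq_len(dim(data)[4]))) {
  if (length(dim(data)) == 3) data <- array(data, dim = c(dim(data), 1))
  stopifnot(length(dim(data)) == 4, all(data >= 0), pixel_size_nm > 0,
            frame_period_ms > 0, length(channel_names) == dim(data)[4])
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 frame_period_ms = frame_period_ms,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frames x %d x %d px x %d channel(s); %.0f nm px, %.3f ms/frame\n",
              d[1], d[2], d[3], d[4], x$pixel_size_nm, x$frame_period_ms))
  invisible(x)
}

# TIFF samples are stored as 32-bit values in [0, 1]; data are written
# divided by a power-of-two scale recorded in the sidecar. The quantization
# step after rescaling is scale/2^32 (< 0.005 for counts below 2^24), so
# integer count data are recovered bit-exactly by rounding on read (the
# sidecar flags whether the source was integer).
tiff_scale <- function(x) 2^ceiling(log2(max(x, 1) + 1))

# libtiff flags 2-sample grayscale pages with a benign photometric
# warning; silence it on read
read_tiff_quiet <- function(path) {
  withCallingHandlers(tiff::readTIFF(path, all = TRUE),
                      warning = function(w) {
                        if (grepl("ExtraSamples|SamplesPerPixel",
                                  conditionMessage(w)))
                          invokeRestart("muffleWarning")
                      })
}

required_field <- function(meta, field) {
  if (is.null(meta[[field]]))
    stop(sprintf("%s required in sidecar metadata", field), call. = FALSE)
  meta[[field]]
}

#' Write a line-scan carpet as TIFF plus JSON sidecar
#'
#' The carpet is stored as one float32 TIFF page per channel (lines x
#' pixels), values divided by a power-of-two `intensity_scale` recorded in
#' the sidecar together with the full acquisition metadata.
#'
#' @param carpet A [line_scan_carpet()].
#' @param path Output TIFF path.
#' @param sidecar_path Output JSON path (default: `path` with `.json`).
#' @param extra Optional named list merged into the sidecar (e.g. a
#'   simulation ground-truth record).
#' @return Invisibly, the sidecar list.
#' @export
write_carpet <- function(carpet, path, sidecar_path = NULL, extra = NULL) {
  stopifnot(inherits(carpet, "line_scan_carpet"))
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  d <- dim(carpet$data)
  scale <- tiff_scale(carpet$data)
  pages <- lapply(seq_len(d[3]), function(ch) carpet$data[, , ch] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(kind = "line_scan_carpet",
                 n_lines = d[1], n_pixels = d[2], n_channels = d[3],
                 pixel_size_nm = carpet$pixel_size_nm,
                 line_period_ms = carpet$line_period_ms,
                 dwell_time_us = carpet$dwell_time_us,
                 channel_names = carpet$channel_names,
                 intensity_scale = scale,
                 integer_counts = all(carpet$data == round(carpet$data))),
            extra)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta)
}

#' Read a line-scan carpet written by [write_carpet()]
#'
#' Metadata are validated before any physical-unit use: a missing required
#' field is a hard error naming the field, and a mismatch between the TIFF
#' shape and the declared channel count is a format error.
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path (default: `path` + `.json`).
#' @return A [line_scan_carpet()].
#' @export
read_carpet <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("TIFF not found: ", path, call. = FALSE)
  if (!file.exists(sidecar_path))
    stop("sidecar not found: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  px <- required_field(meta, "pixel_size_nm")
  lp <- required_field(meta, "line_period_ms")
  dw <- required_field(meta, "dwell_time_us")
  nch <- required_field(meta, "n_channels")
  scale <- required_field(meta, "intensity_scale")
  pages <- read_tiff_quiet(path)
  if (length(pages) != nch)
    stop(sprintf("format error: TIFF has %d page(s) but sidecar declares %d channel(s)",
                 length(pages), nch), call. = FALSE)
  data <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (ch in seq_along(pages)) data[, , ch] <- pages[[ch]] * scale
  if (isTRUE(meta$integer_counts)) data <- round(data)
  if (!is.null(meta$n_lines) &&
      (dim(data)[1] != meta$n_lines || dim(data)[2] != meta$n_pixels))
    stop("format error: TIFF page shape disagrees with sidecar", call. = FALSE)
  cn <- meta$channel_names
  if (is.null(cn)) cn <- paste0("ch", seq_len(nch))
  line_scan_carpet(data, pixel_size_nm = px, line_period_ms = lp,
                   dwell_time_us = dw, channel_names = cn)
}

#' Write an image time series as TIFF plus JSON sidecar
#'
#' One TIFF page per frame, channels stored as samples per pixel.
#'
#' @param stack An [image_stack()].
#' @param path,sidecar_path Output paths as in [write_carpet()].
#' @param extra Optional named list merged into the sidecar.
#' @return Invisibly, the sidecar list.
#' @export
write_image_stack <- function(stack, path, sidecar_path = NULL, extra = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  d <- dim(stack$data)
  scale <- tiff_scale(stack$data)
  pages <- lapply(seq_len(d[1]), function(f) {
    pg <- stack$data[f, , , , drop = TRUE]
    if (d[4] == 1) pg <- array(pg, dim = c(d[2], d[3]))
    pg / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(kind = "image_stack", n_frames = d[1], rows = d[2],
                 cols = d[3], n_channels = d[4],
                 pixel_size_nm = stack$pixel_size_nm,
                 frame_period_ms = stack$frame_period_ms,
                 channel_names = stack$channel_names,
                 intensity_scale = scale,
                 integer_counts = all(stack$data == round(stack$data))),
            extra)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta)
}

#' Read an image time series written by [write_image_stack()]
#' @param path,sidecar_path Paths as in [read_carpet()].
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("TIFF not found: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  px <- required_field(meta, "pixel_size_nm")
  fp <- required_field(meta, "frame_period_ms")
  nch <- required_field(meta, "n_channels")
  scale <- required_field(meta, "intensity_scale")
  pages <- read_tiff_quiet(path)
  d1 <- dim(pages[[1]])
  got_ch <- if (length(d1) == 3) d1[3] else 1L
  if (got_ch != nch)
    stop(sprintf("format error: TIFF has %d sample(s)/pixel but sidecar declares %d channel(s)",
                 got_ch, nch), call. = FALSE)
  data <- array(0, dim = c(length(pages), d1[1], d1[2], nch))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 2) pg <- array(pg, dim = c(dim(pg), 1))
    data[f, , , ] <- pg * scale
  }
  if (isTRUE(meta$integer_counts)) data <- round(data)
  cn <- meta$channel_names
  if (is.null(cn)) cn <- paste0("ch", seq_len(nch))
  image_stack(data, pixel_size_nm = px, frame_period_ms = fp,
              channel_names = cn)
}

#' Write a 3D stack (one TIFF page per z slice) plus JSON sidecar
#' @param stack 3D numeric array (x, y, z).
#' @param voxel_size_nm Voxel pitch `c(x, y, z)` in nm.
#' @param path,sidecar_path Output paths.
#' @param extra Optional named list merged into the sidecar.
#' @return Invisibly, the sidecar list.
#' @export
write_stack3d <- function(stack, voxel_size_nm, path, sidecar_path = NULL,
                          extra = NULL) {
  stopifnot(length(dim(stack)) == 3, length(voxel_size_nm) == 3)
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  scale <- tiff_scale(stack)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(kind = "stack3d", dims = dim(stack),
                 voxel_size_nm = voxel_size_nm, intensity_scale = scale,
                 integer_counts = all(stack == round(stack))), extra)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta)
}

#' Read a 3D stack written by [write_stack3d()]
#' @param path,sidecar_path Paths.
#' @return A list with `stack` and `voxel_size_nm`.
#' @export
read_stack3d <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  vs <- required_field(meta, "voxel_size_nm")
  scale <- required_field(meta, "intensity_scale")
  pages <- read_tiff_quiet(path)
  stack <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]] * scale
  if (isTRUE(meta$integer_counts)) stack <- round(stack)
  list(stack = stack, voxel_size_nm = vs)
}

#' Write a results table as CSV
#'
#' Plain CSV with header, stable column order and full double precision
#' (values survive a round trip to better than 1e-12 relative).
#'
#' @param records A data.frame (possibly empty: header-only CSV).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  fmt <- records
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  utils::write.csv(fmt, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a correlation carpet as float32 TIFF plus JSON sidecar
#'
#' The sidecar records the lag grid, pixel distance `d`, mode and validity
#' mask, everything needed to re-plot the carpet on its logarithmic time
#' axis.
#'
#' @param cc A `correlation_carpet` from [pcf_carpet()].
#' @param path,sidecar_path Output paths.
#' @return Invisibly, the sidecar list.
#' @export
write_correlation_carpet <- function(cc, path, sidecar_path = NULL) {
  stopifnot(inherits(cc, "correlation_carpet"))
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  v <- cc$values
  v[!is.finite(v)] <- 0
  rng <- max(abs(v), 1e-12)
  scale <- 2^ceiling(log2(rng + 1))
  # affine map to [0,1]: stored = v/(2*scale) + 0.5
  tiff::writeTIFF(v / (2 * scale) + 0.5, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(kind = "correlation_carpet", lag_times_s = cc$lag_times_s,
               distance_px = cc$distance_px, mode = cc$mode,
               direction = cc$direction, valid = cc$valid,
               pixel_size_nm = cc$pixel_size_nm,
               separation_nm = cc$separation_nm, value_scale = scale)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta)
}
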
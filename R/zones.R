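#' Locate the nuclear lamina along the scanned line
#'
#' The lamina marker channel (e.g. lamin C-EGFP) is time-averaged into an
#' intensity profile; the lamina is the centre of a Gaussian fitted to the
#' dominant peak, rounded to the nearest column for labelling. A flat
#' profile, or two peaks of comparable prominence (ambiguity), is refused
#' with an error. A drift check compares the peak position found in the
#' first and last thirds of the acquisition and warns if they disagree by
#' more than `drift_tol_px`.
#'
#' @param carpet A [line_scan_carpet()].
#' @param lamin_channel Channel holding the lamina marker (1-based).
#' @param min_rel_prominence Peaks with prominence above this fraction of
#'   the dominant peak's prominence count as ambiguous rivals (default 0.5).
#' @param drift_tol_px Tolerated first-third/last-third drift, px.
#' @return A list: `lamina_px` (integer column), `subpixel` (Gaussian
#'   centre), `drift_px`.
#' @export
detect_lamina <- function(carpet, lamin_channel = 1,
                          min_rel_prominence = 0.5, drift_tol_px = 2) {
  stopifnot(inherits(carpet, "line_scan_carpet"))
  prof <- colMeans(carpet$data[, , lamin_channel])
  find_center <- function(p) {
    rng <- max(p) - min(p)
    if (rng <= 0 || max(p) <= 0)
      stop("lamina not found: flat profile in the lamina channel",
           call. = FALSE)
    pk <- detect_rare_peaks(p, min_prominence = 0.1 * rng,
                            min_separation = 3)
    if (nrow(pk) == 0)
      stop("lamina not found: no peak above background", call. = FALSE)
    pk <- pk[order(-pk$prominence), , drop = FALSE]
    rivals <- pk$prominence >= min_rel_prominence * pk$prominence[1]
    if (sum(rivals) > 1)
      stop(sprintf("ambiguous lamina: candidate peaks at columns %s",
                   paste(pk$position[rivals] - 1, collapse = ", ")),
           call. = FALSE)
    j0 <- pk$position[1]
    win <- max(1, j0 - 8):min(length(p), j0 + 8)
    # Gaussian fit on the local window for sub-pixel position
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + a * exp(-(x - mu)^2 / (2 * s^2)),
                        data = data.frame(x = win, y = p[win]),
                        start = list(b = min(p[win]),
                                     a = p[j0] - min(p[win]),
                                     mu = j0, s = 3),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(j0)
    mu <- unname(stats::coef(fit)["mu"])
    if (mu < win[1] || mu > win[length(win)]) j0 else mu
  }
  center <- find_center(prof)
  nl <- dim(carpet$data)[1]
  third <- max(3, floor(nl / 3))
  c1 <- tryCatch(find_center(colMeans(carpet$data[seq_len(third), ,
                                                  lamin_channel,
                                                  drop = FALSE][, , 1])),
                 error = function(e) NA_real_)
  c2 <- tryCatch(find_center(colMeans(carpet$data[(nl - third + 1):nl, ,
                                                  lamin_channel,
                                                  drop = FALSE][, , 1])),
                 error = function(e) NA_real_)
  drift <- abs(c2 - c1)
  if (is.finite(drift) && drift > drift_tol_px)
    warning(sprintf("lamina drift of %.1f px between first and last thirds",
                    drift))
  list(lamina_px = as.integer(round(center)) - 1L,   # 0-based column
       subpixel = center - 1, drift_px = drift)
}

#' Partition columns into cytoplasm / NE / nucleoplasm zones
#'
#' Columns within `ne_half_width_px` of the lamina form the nuclear
#' envelope (NE) zone; the remaining columns on the cytoplasmic side (per
#' `orientation`) are cytoplasm and the rest nucleoplasm. Zone width is
#' parameterized in pixels; the nm equivalent depends on the recorded
#' pixel size and is only reported, never used for labelling.
#'
#' @param lamina_px 0-based lamina column (or the list from
#'   [detect_lamina()]).
#' @param ne_half_width_px Half-width of the NE zone in pixels (default
#'   11, i.e. a 23-column zone).
#' @param orientation `"cyto_left"` or `"cyto_right"`: which side of the
#'   lamina is cytoplasm.
#' @param n_pixels Number of columns in the carpet.
#' @param pixel_size_nm Optional; reported as `ne_width_nm` metadata.
#' @return An object of class `zone_map`: `lamina_px`,
#'   `ne_half_width_px`, `labels` (length `n_pixels`, values
#'   `"cytoplasm"`, `"NE"`, `"nucleoplasm"`), `orientation`.
#' @export
assign_zones <- function(lamina_px, ne_half_width_px = 11,
                         orientation = c("cyto_left", "cyto_right"),
                         n_pixels, pixel_size_nm = NULL) {
  if (is.list(lamina_px)) lamina_px <- lamina_px$lamina_px
  orientation <- match.arg(orientation)
  stopifnot(lamina_px >= 0, lamina_px < n_pixels, ne_half_width_px >= 0)
  lo <- lamina_px - ne_half_width_px
  hi <- lamina_px + ne_half_width_px
  if (lo < 0 || hi > n_pixels - 1) {
    warning("NE zone truncated at the field boundary")
    lo <- max(lo, 0); hi <- min(hi, n_pixels - 1)
  }
  cols <- seq_len(n_pixels) - 1
  labels <- ifelse(cols >= lo & cols <= hi, "NE",
                   ifelse(cols < lo,
                          if (orientation == "cyto_left") "cytoplasm"
                          else "nucleoplasm",
                          if (orientation == "cyto_left") "nucleoplasm"
                          else "cytoplasm"))
  zm <- structure(list(lamina_px = as.integer(lamina_px),
                       ne_half_width_px = as.integer(ne_half_width_px),
                       labels = labels, orientation = orientation),
                  class = "zone_map")
  if (!is.null(pixel_size_nm))
    zm$ne_width_nm <- (2 * ne_half_width_px + 1) * pixel_size_nm
  zm
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("zone_map: lamina at column %d, NE half-width %d px (%s); %d cytoplasm / %d NE / %d nucleoplasm columns\n",
              x$lamina_px, x$ne_half_width_px, x$orientation,
              sum(x$labels == "cytoplasm"), sum(x$labels == "NE"),
              sum(x$labels == "nucleoplasm")))
  invisible(x)
}

#' Infer which side of the lamina is cytoplasm
#'
#' Picks the side with the higher mean particle-channel intensity
#' (cytoplasmic accumulation of particles). The inference is heuristic and
#' flagged as such in the return value.
#'
#' @param carpet A [line_scan_carpet()].
#' @param lamina_px 0-based lamina column.
#' @param particle_channel Channel holding the particle signal.
#' @return A list: `orientation` (for [assign_zones()]) and
#'   `inferred = TRUE`.
#' @export
infer_orientation <- function(carpet, lamina_px, particle_channel = 2) {
  stopifnot(inherits(carpet, "line_scan_carpet"))
  prof <- colMeans(carpet$data[, , particle_channel])
  left <- mean(prof[seq_len(max(lamina_px, 1))])
  right <- mean(prof[min(lamina_px + 2, length(prof)):length(prof)])
  list(orientation = if (left >= right) "cyto_left" else "cyto_right",
       inferred = TRUE)
}

#' Signed distance of each column from the lamina
#'
#' Negative distances are on the cytoplasmic side, matching the convention
#' of brightness-versus-distance histograms.
#'
#' @param zone_map A `zone_map`.
#' @param n_pixels Number of columns.
#' @param pixel_size_nm Pixel pitch, nm.
#' @return Numeric vector of signed distances in um, one per column.
#' @export
zone_signed_distance_um <- function(zone_map, n_pixels, pixel_size_nm) {
  stopifnot(inherits(zone_map, "zone_map"))
  cols <- seq_len(n_pixels) - 1
  d <- (cols - zone_map$lamina_px) * pixel_size_nm / 1000
  if (zone_map$orientation == "cyto_left") d else -d
}
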
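#' Number-and-brightness segmentation scheme
#'
#' The dual scheme used on 30,000-line carpets: the "fast" scheme analyses
#' raw lines in 100 segments of 300 lines each, so that fast fluctuations
#' dominate the variance; the "slow" scheme first averages lines in
#' non-overlapping 100-line windows (suppressing fast fluctuations) and
#' then analyses the averaged series as a single segment of 100 averaged
#' lines. Both knobs are configurable because the published description of
#' the segmentation does not parse uniquely.
#'
#' @param mode `"fast"` or `"slow"`.
#' @param block_lines Lines (raw or averaged) per segment. Defaults: 300
#'   (fast), 100 (slow).
#' @param average_window Raw lines averaged before analysis. Defaults: 1
#'   (fast), 100 (slow).
#' @param n_segments Number of segments; default as many as fit
#'   (fast: 100 on a 30,000-line carpet; slow: 1).
#' @return An object of class `nb_scheme`.
#' @export
nb_scheme <- function(mode = c("fast", "slow"), block_lines = NULL,
                      average_window = NULL, n_segments = NULL) {
  mode <- match.arg(mode)
  if (is.null(block_lines)) block_lines <- if (mode == "fast") 300L else 100L
  if (is.null(average_window)) average_window <- if (mode == "fast") 1L else 100L
  stopifnot(block_lines >= 2, average_window >= 1)
  structure(list(mode = mode, block_lines = as.integer(block_lines),
                 average_window = as.integer(average_window),
                 n_segments = if (is.null(n_segments)) NULL
                              else as.integer(n_segments)),
            class = "nb_scheme")
}

#' Number and brightness analysis of a carpet
#'
#' Moment analysis per column and segment: apparent number
#' `N = <k>^2 / sigma^2` and apparent brightness `B = <k> / N =
#' sigma^2 / <k>`, where `<k>` and `sigma^2` are the temporal mean and
#' variance of the (possibly window-averaged) intensity. Under the
#' photon-counting convention pure shot noise gives `B = 1` and `N = <k>`;
#' `B` above 1 signals number fluctuations of particles brighter than one
#' count per sampling. Zero-variance columns are flagged (`N` undefined,
#' `B = 0`).
#'
#' @param carpet A [line_scan_carpet()].
#' @param scheme An [nb_scheme()].
#' @param channel Channel to analyse (1-based).
#' @return Data.frame of class `nb_map`: `segment_id, column, mean_k,
#'   var_k, N_apparent, B_apparent, scheme, defined`.
#' @export
nb_compute <- function(carpet, scheme = nb_scheme("fast"), channel = 1) {
  stopifnot(inherits(carpet, "line_scan_carpet"),
            inherits(scheme, "nb_scheme"))
  A <- carpet$data[, , channel]
  nl <- nrow(A); np <- ncol(A)
  aw <- scheme$average_window
  if (aw > 1) {
    nwin <- floor(nl / aw)
    if (nwin < 2) stop("average_window leaves fewer than 2 lines", call. = FALSE)
    grp <- rep(seq_len(nwin), each = aw)
    A <- rowsum(A[seq_len(nwin * aw), , drop = FALSE], grp) / aw
    nl <- nwin
  }
  bl <- scheme$block_lines
  nseg <- if (is.null(scheme$n_segments)) floor(nl / bl) else scheme$n_segments
  if (nseg < 1 || nseg * bl > nl)
    stop(sprintf("scheme overruns the carpet: %d segments x %d lines > %d available",
                 nseg, bl, nl), call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nseg), function(s) {
    seg <- A[((s - 1) * bl + 1):(s * bl), , drop = FALSE]
    m <- colMeans(seg)
    v <- apply(seg, 2, stats::var)
    defined <- v > 0 & m > 0
    data.frame(segment_id = s, column = seq_len(np) - 1L,
               mean_k = m, var_k = v,
               N_apparent = ifelse(defined, m^2 / v, NA_real_),
               B_apparent = ifelse(v > 0 & m > 0, v / m, 0),
               scheme = scheme$mode, defined = defined,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("nb_map", class(out))
  attr(out, "scheme") <- scheme
  out
}

#' Across-segment aggregate of an N&B map
#'
#' Per-column mean and SEM of N and B over segments (only segments where
#' the moments are defined).
#'
#' @param nb An `nb_map` from [nb_compute()].
#' @return Data.frame: `column, n_segments, mean_N, sem_N, mean_B, sem_B,
#'   scheme`.
#' @export
nb_aggregate <- function(nb) {
  cols <- sort(unique(nb$column))
  out <- do.call(rbind, lapply(cols, function(cl) {
    s <- nb[nb$column == cl & nb$defined, , drop = FALSE]
    n <- nrow(s)
    data.frame(column = cl, n_segments = n,
               mean_N = if (n) mean(s$N_apparent) else NA_real_,
               sem_N = if (n > 1) stats::sd(s$N_apparent) / sqrt(n) else NA_real_,
               mean_B = if (n) mean(s$B_apparent) else NA_real_,
               sem_B = if (n > 1) stats::sd(s$B_apparent) / sqrt(n) else NA_real_,
               scheme = nb$scheme[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Join N&B maps with per-column speed classification
#'
#' Each column's diffusion class (from the ACF fit) selects the matching
#' N&B scheme: fast columns report the fast-scheme moments, slow columns
#' the slow-scheme moments; invalid fits are excluded. This is the
#' column-wise classification used to build per-zone fast/slow N and B
#' aggregates.
#'
#' @param nb_fast,nb_slow `nb_map`s from [nb_compute()] under the fast and
#'   slow schemes of the same carpet/channel.
#' @param fcs_results A `fcs_fit_result` for the same columns.
#' @return Data.frame: `column, speed_class, D_um2_s, N_apparent,
#'   B_apparent, scheme`.
#' @export
joint_speed_partition <- function(nb_fast, nb_slow, fcs_results) {
  agg_f <- nb_aggregate(nb_fast)
  agg_s <- nb_aggregate(nb_slow)
  cols_nb <- sort(unique(agg_f$column))
  if (!all(fcs_results$column %in% cols_nb))
    stop("column mismatch between N&B maps and fit results", call. = FALSE)
  res <- fcs_results[fcs_results$valid &
                       fcs_results$speed_class %in% c("fast", "slow"), ,
                     drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    cl <- res$column[i]
    src <- if (res$speed_class[i] == "fast") agg_f else agg_s
    row <- src[src$column == cl, , drop = FALSE]
    data.frame(column = cl, speed_class = res$speed_class[i],
               D_um2_s = res$D_um2_s[i],
               N_apparent = row$mean_N, B_apparent = row$mean_B,
               scheme = row$scheme, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Brightness as a function of distance from the lamina
#'
#' Bins the per-column mean brightness by signed distance from the lamina
#' (negative = cytoplasmic side) and reports mean B with SEM per bin; the
#' histogram used to locate bright, slow particle accumulations relative
#' to the nuclear envelope.
#'
#' @param nb An `nb_map` (typically the slow scheme).
#' @param zone_map A `zone_map` from [assign_zones()].
#' @param pixel_size_nm Pixel pitch, nm.
#' @param bin_width_um Bin width, um (default 0.25).
#' @return Data.frame: `bin_lo_um, bin_hi_um, bin_mid_um, n, mean_B,
#'   sem_B`.
#' @export
brightness_vs_distance <- function(nb, zone_map, pixel_size_nm,
                                   bin_width_um = 0.25) {
  stopifnot(bin_width_um > 0)
  agg <- nb_aggregate(nb)
  agg <- agg[!is.na(agg$mean_B), , drop = FALSE]
  if (nrow(agg) == 0)
    return(data.frame(bin_lo_um = numeric(0), bin_hi_um = numeric(0),
                      bin_mid_um = numeric(0), n = integer(0),
                      mean_B = numeric(0), sem_B = numeric(0)))
  dist <- zone_signed_distance_um(zone_map, max(agg$column) + 1,
                                  pixel_size_nm)[agg$column + 1]
  bins <- floor(dist / bin_width_um)
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    bvals <- agg$mean_B[sel]
    data.frame(bin_lo_um = b * bin_width_um,
               bin_hi_um = (b + 1) * bin_width_um,
               bin_mid_um = (b + 0.5) * bin_width_um,
               n = sum(sel), mean_B = mean(bvals),
               sem_B = if (sum(sel) > 1) stats::sd(bvals) / sqrt(sum(sel))
                       else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Prominence-based peak detection
#'
#' Local maxima whose topographic prominence (height above the higher of
#' the two bounding valleys toward equal-or-higher terrain) exceeds
#' `min_prominence`, kept at least `min_separation` samples apart
#' (greedily, most prominent first). Used to surface rare bright particle
#' transits in otherwise quiet traces.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence.
#' @param min_separation Minimum distance between reported peaks, samples.
#' @return Data.frame: `position` (1-based index), `height`, `prominence`;
#'   zero rows when nothing qualifies.
#' @export
detect_rare_peaks <- function(x, min_prominence, min_separation = 1) {
  n <- length(x)
  empty <- data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  is_max <- which(x[2:(n - 1)] > x[1:(n - 2)] &
                    x[2:(n - 1)] >= x[3:n]) + 1
  if (length(is_max) == 0) return(empty)
  prom <- vapply(is_max, function(i) {
    h <- x[i]
    # walk left until terrain >= h (or the edge); valley = min en route
    left <- x[seq_len(i - 1)]
    hi_l <- which(left >= h)
    vmin_l <- if (length(hi_l)) min(left[(max(hi_l)):(i - 1)]) else min(left)
    right <- x[(i + 1):n]
    hi_r <- which(right >= h)
    vmin_r <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(right)
    h - max(vmin_l, vmin_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  pos <- is_max[keep]; hgt <- x[pos]; prom <- prom[keep]
  if (length(pos) == 0) return(empty)
  ord <- order(-prom, pos)
  chosen <- integer(0)
  for (i in ord)
    if (!length(chosen) || all(abs(pos[i] - pos[chosen]) >= min_separation))
      chosen <- c(chosen, i)
  chosen <- chosen[order(pos[chosen])]
  data.frame(position = pos[chosen], height = hgt[chosen],
             prominence = prom[chosen])
}
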
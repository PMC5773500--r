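#' Quasi-logarithmic (multi-tau style) lag grid
#'
#' Lags in units of lines/frames, approximately `points_per_octave` per
#' factor of two, from 1 up to `max_lag` (default one eighth of the series
#' length, bounding the variance of the long-lag estimates).
#'
#' @param n Series length (lines or frames).
#' @param points_per_octave Grid density (default 8).
#' @param max_lag Largest lag, in samples.
#' @return Strictly increasing integer vector of lags (>= 1).
#' @export
multitau_lags <- function(n, points_per_octave = 8,
                          max_lag = floor(n / 8)) {
  stopifnot(n >= 16, points_per_octave >= 1, max_lag >= 1, max_lag < n)
  ex <- seq(0, log2(max_lag), by = 1 / points_per_octave)
  sort(unique(pmin(round(2^ex), max_lag)))
}

#' Brute-force pair-correlation oracle
#'
#' Evaluates the pair correlation
#' `pCF(tau) = <F_a(t) F_b(t+tau)> / (<F_a(t)> <F_b(t+tau)>) - 1`
#' by explicit O(T*L) summation, with all three means taken over the same
#' overlapping support `t in [1, T-tau]`. This is the reference the
#' FFT-based production path is tested against; `tau = 0` is allowed here.
#'
#' @param series_a,series_b Equal-length numeric vectors.
#' @param lags Integer lags (>= 0), each < length of the series.
#' @return Numeric vector of pCF values at `lags`.
#' @export
direct_correlation_oracle <- function(series_a, series_b, lags) {
  stopifnot(length(series_a) == length(series_b),
            all(lags >= 0), all(lags < length(series_a)))
  n <- length(series_a)
  vapply(lags, function(tau) {
    m <- n - tau
    num <- 0
    for (t in seq_len(m)) num <- num + series_a[t] * series_b[t + tau]
    num <- num / m
    ma <- sum(series_a[seq_len(m)]) / m
    mb <- sum(series_b[seq_len(m) + tau]) / m
    if (ma <= 0 || mb <= 0) return(NA_real_)
    num / (ma * mb) - 1
  }, numeric(1))
}

# Linear (zero-padded, non-circular) cross-correlation sums for paired
# columns of A and B: S[tau+1, p] = sum_t A[t, p] * B[t + tau, p].
cross_corr_sums_matrix <- function(A, B) {
  n <- nrow(A)
  nfft <- stats::nextn(2 * n, 2)
  pad <- matrix(0, nfft - n, ncol(A))
  FA <- stats::mvfft(rbind(A, pad))
  FB <- stats::mvfft(rbind(B, pad))
  S <- Re(stats::mvfft(Conj(FA) * FB, inverse = TRUE)) / nfft
  S[seq_len(n), , drop = FALSE]
}

# pCF curves for paired columns of A and B at integer lags (>= 1 or 0).
# Returns list(values = P x L matrix, valid = length-P logical).
pcf_pairs_fft <- function(A, B, lags) {
  n <- nrow(A)
  stopifnot(all(lags >= 0), all(lags < n))
  S <- cross_corr_sums_matrix(A, B)
  csa <- apply(A, 2, cumsum)
  csb <- apply(B, 2, cumsum)
  if (!is.matrix(csa)) { csa <- matrix(csa, ncol = 1); csb <- matrix(csb, ncol = 1) }
  P <- ncol(A)
  vals <- matrix(NA_real_, P, length(lags))
  for (li in seq_along(lags)) {
    tau <- lags[li]
    m <- n - tau
    ma <- csa[m, ] / m
    mb <- (csb[n, ] - if (tau > 0) csb[tau, ] else 0) / m
    den <- ma * mb
    v <- (S[tau + 1, ] / m) / den - 1
    v[den <= 0] <- NA_real_
    vals[, li] <- v
  }
  valid <- colMeans(A) > 0 & colMeans(B) > 0
  list(values = vals, valid = valid)
}

#' Pair correlation of one carpet column
#'
#' Temporal cross-correlation between the intensity trace at `column` and
#' the trace `d` pixels downstream (Glossary: a delayed positive peak means
#' molecules travel between the two positions). `d = 0` with equal channels
#' is the autocorrelation (same code path); different channels give the
#' cross-channel pair correlation used for co-transport.
#'
#' @param carpet A [line_scan_carpet()].
#' @param column 0-based column index.
#' @param d Pixel offset (may be negative for the upstream direction).
#' @param channel_a,channel_b Channel indices (1-based).
#' @param lags Integer lag grid in lines (default [multitau_lags()]).
#' @return A list of class `correlation_curve`: `lag_times_s`, `values`,
#'   `valid`, `distance_px`, `separation_nm`, `mode`.
#' @export
pcf_column <- function(carpet, column, d = 0, channel_a = 1,
                       channel_b = channel_a, lags = NULL) {
  stopifnot(inherits(carpet, "line_scan_carpet"))
  np <- dim(carpet$data)[2]
  if (column < 0 || column >= np || column + d < 0 || column + d >= np)
    stop("column or column + d outside the carpet", call. = FALSE)
  if (is.null(lags)) lags <- multitau_lags(dim(carpet$data)[1])
  a <- carpet$data[, column + 1, channel_a]
  b <- carpet$data[, column + d + 1, channel_b]
  r <- pcf_pairs_fft(cbind(a), cbind(b), lags)
  structure(list(
    lag_times_s = lags * carpet$line_period_ms / 1000,
    lags = lags,
    values = as.numeric(r$values),
    valid = r$valid[1],
    distance_px = d,
    separation_nm = abs(d) * carpet$pixel_size_nm,
    mode = if (channel_a != channel_b) "cross_channel_pair"
           else if (d == 0) "auto" else "pair"),
    class = "correlation_curve")
}

#' Correlation carpet: per-column ACF / pCF / cross-channel pCF
#'
#' Stacks [pcf_column()] over every column for which `column + d` is inside
#' the carpet; out-of-range or zero-mean columns are flagged invalid (an
#' explicit mask, not NaN propagation). The physical pixel-pair separation
#' `|d| * pixel_size_nm` is recorded.
#'
#' @inheritParams pcf_column
#' @param detrend Optional detrending applied per column before
#'   correlation: `"none"` (default), `"additive"` or `"multiplicative"`
#'   (see [detrend_column()]).
#' @param detrend_window Window for the detrend moving average, lines.
#' @param columns Optional 0-based source columns to compute (others stay
#'   flagged invalid); by default all columns.
#' @return An object of class `correlation_carpet`: `values`
#'   (n_pixels x n_lags), `lag_times_s`, `lags`, `valid`, `distance_px`,
#'   `separation_nm`, `mode`, `direction`, `pixel_size_nm`,
#'   `line_period_ms`.
#' @export
pcf_carpet <- function(carpet, d = 0, channel_a = 1, channel_b = channel_a,
                       lags = NULL, detrend = c("none", "additive",
                                                "multiplicative"),
                       detrend_window = 1000, columns = NULL) {
  stopifnot(inherits(carpet, "line_scan_carpet"))
  detrend <- match.arg(detrend)
  nl <- dim(carpet$data)[1]; np <- dim(carpet$data)[2]
  if (abs(d) >= np) stop("d out of bounds", call. = FALSE)
  if (is.null(lags)) lags <- multitau_lags(nl)
  A <- carpet$data[, , channel_a]
  B <- carpet$data[, , channel_b]
  if (detrend != "none") {
    A <- apply(A, 2, detrend_column, method = detrend,
               window = detrend_window)
    B <- apply(B, 2, detrend_column, method = detrend,
               window = detrend_window)
  }
  cols <- seq_len(np) - 1                       # 0-based source columns
  tgt <- cols + d
  ok <- tgt >= 0 & tgt < np
  if (!is.null(columns)) ok <- ok & cols %in% columns
  vals <- matrix(NA_real_, np, length(lags))
  valid <- rep(FALSE, np)
  if (any(ok)) {
    r <- pcf_pairs_fft(A[, cols[ok] + 1, drop = FALSE],
                       B[, tgt[ok] + 1, drop = FALSE], lags)
    vals[ok, ] <- r$values
    valid[ok] <- r$valid
  }
  structure(list(
    values = vals,
    lag_times_s = lags * carpet$line_period_ms / 1000,
    lags = lags, valid = valid, distance_px = d,
    separation_nm = abs(d) * carpet$pixel_size_nm,
    mode = if (channel_a != channel_b) "cross_channel_pair"
           else if (d == 0) "auto" else "pair",
    direction = sign(d),
    pixel_size_nm = carpet$pixel_size_nm,
    line_period_ms = carpet$line_period_ms),
    class = "correlation_carpet")
}

#' @export
print.correlation_carpet <- function(x, ...) {
  cat(sprintf("correlation_carpet (%s): %d columns x %d lags, d = %d px (%.0f nm), %d valid\n",
              x$mode, nrow(x$values), ncol(x$values), x$distance_px,
              x$separation_nm, sum(x$valid)))
  invisible(x)
}

#' Remove a slow intensity trend from a time trace
#'
#' Guards correlation and N&B analysis against bleaching or stage drift: a
#' running local-linear (first-order Savitzky-Golay) smooth estimates the
#' slow trend — exact for linear drifts, including at the trace ends —
#' which is removed either additively (`x - trend + mean`) or
#' multiplicatively (`x * mean / trend`), preserving the overall mean.
#' Disabled by default throughout the package.
#'
#' @param series Numeric vector.
#' @param method `"additive"` or `"multiplicative"`.
#' @param window Boxcar length in samples (`1 < window < length(series)`).
#' @return Detrended series of the same length.
#' @export
detrend_column <- function(series, method = c("additive", "multiplicative"),
                           window = 1000) {
  method <- match.arg(method)
  n <- length(series)
  if (window <= 1) stop("window must be > 1", call. = FALSE)
  if (window >= n) stop("window must be smaller than the series", call. = FALSE)
  w <- as.integer(window)
  # running local-linear fit over centred (edge-truncated) windows, all
  # moments via cumulative sums (O(n)); reproduces linear trends exactly
  i <- seq_len(n)
  half <- w %/% 2
  lo <- pmax(i - half, 1)
  hi <- pmin(i + (w - half - 1), n)
  cs <- c(0, cumsum(series))
  cst <- c(0, cumsum(series * i))
  ct <- c(0, cumsum(as.numeric(i)))
  ct2 <- c(0, cumsum(as.numeric(i)^2))
  m <- hi - lo + 1
  sy <- cs[hi + 1] - cs[lo]
  sty <- cst[hi + 1] - cst[lo]
  st <- ct[hi + 1] - ct[lo]
  st2 <- ct2[hi + 1] - ct2[lo]
  denom <- m * st2 - st^2
  b <- ifelse(m > 1 & denom > 0, (m * sty - st * sy) / denom, 0)
  a <- (sy - b * st) / m
  trend <- a + b * i
  mu <- mean(series)
  if (method == "additive") {
    series - trend + mu
  } else {
    if (any(trend <= 0))
      stop("multiplicative detrend requires a strictly positive trend",
           call. = FALSE)
    series * (mu / trend)
  }
}

#' Scalar amplitude of a correlation curve
#'
#' Mean of the correlation values over a lag-time window; the summary used
#' for barrier-crossing contrast and amplitude maps.
#'
#' @param curve A `correlation_curve`, or a list with `lag_times_s` and
#'   `values`.
#' @param lag_range Length-2 numeric, seconds; default spans all lags.
#' @return Mean correlation over the window (NA if no lags fall inside).
#' @export
pcf_amplitude <- function(curve, lag_range = NULL) {
  lt <- curve$lag_times_s
  v <- curve$values
  if (is.null(lag_range)) lag_range <- range(lt)
  sel <- lt >= lag_range[1] & lt <= lag_range[2]
  if (!any(sel)) return(NA_real_)
  mean(v[sel], na.rm = TRUE)
}

#' Lag time of the correlation peak
#'
#' Position of the maximum of a correlation curve, optionally after a short
#' moving-average smooth; used to compare barrier-delayed translocation
#' against the barrier-free case.
#'
#' @param curve A `correlation_curve`-like list.
#' @param smooth Odd moving-average span in lag points (1 = none).
#' @return Lag time (s) of the maximum value.
#' @export
pcf_peak_lag <- function(curve, smooth = 3) {
  v <- curve$values
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    vs <- as.numeric(stats::filter(v, k, sides = 2))
    v <- ifelse(is.na(vs), v, vs)
  }
  curve$lag_times_s[which.max(v)]
}
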
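#' FCS model configuration
#'
#' Parameters of the single-component diffusion model fitted to column
#' ACFs: `G(tau) = G0 / ((1 + tau/tau_D) * sqrt(1 + tau/(kappa^2 tau_D)))`,
#' which for `kappa = Inf` reduces to the 2D form `G0 / (1 + tau/tau_D)`.
#' The diffusion coefficient follows as `D = w0^2 / (4 tau_D)`.
#'
#' The lateral waist `w0` scales D quadratically and must reflect the
#' actual instrument; the default 0.25 um is typical for a 60x/1.2 NA
#' water-immersion objective but is a stand-in, not a calibrated value.
#'
#' @param psf_waist_um Lateral 1/e^2 beam radius w0, um.
#' @param structure_parameter Axial/lateral ratio kappa; `Inf` selects the
#'   pure 2D model (default, appropriate for line scans).
#' @param d_range_um2_s Admissible diffusion range; fits outside are marked
#'   invalid and excluded from aggregates (default 0-100 um^2/s).
#' @param fast_slow_threshold_um2_s Boundary between "slow" and "fast"
#'   diffusion (default 2; strictly greater is fast).
#' @param chi2_max Maximum acceptable reduced chi-square when per-point
#'   noise estimates are available (default 5).
#' @param fit_offset Also fit an additive baseline G_inf (default TRUE).
#'   A finite trace, slow drift, or a closed particle reservoir all leave
#'   the long-lag correlation slightly offset from zero; fitting the
#'   baseline keeps those artefacts out of tau_D.
#' @return An object of class `fcs_model_config`.
#' @export
fcs_model_config <- function(psf_waist_um = 0.25,
                             structure_parameter = Inf,
                             d_range_um2_s = c(0, 100),
                             fast_slow_threshold_um2_s = 2,
                             chi2_max = 5,
                             fit_offset = TRUE) {
  stopifnot(psf_waist_um > 0, structure_parameter > 0,
            length(d_range_um2_s) == 2, d_range_um2_s[1] >= 0,
            d_range_um2_s[2] > d_range_um2_s[1],
            fast_slow_threshold_um2_s >= d_range_um2_s[1],
            fast_slow_threshold_um2_s <= d_range_um2_s[2],
            chi2_max > 0)
  structure(list(psf_waist_um = psf_waist_um,
                 structure_parameter = structure_parameter,
                 d_range_um2_s = d_range_um2_s,
                 fast_slow_threshold_um2_s = fast_slow_threshold_um2_s,
                 chi2_max = chi2_max, fit_offset = isTRUE(fit_offset)),
            class = "fcs_model_config")
}

#' Single-component FCS model curve
#' @param tau Lag times, s.
#' @param G0 Amplitude.
#' @param tau_D Dwell time, s.
#' @param kappa Structure parameter (Inf = 2D).
#' @return Model correlation values.
#' @export
fcs_model_curve <- function(tau, G0, tau_D, kappa = Inf) {
  g <- G0 / (1 + tau / tau_D)
  if (is.finite(kappa)) g <- g / sqrt(1 + tau / (kappa^2 * tau_D))
  g
}

empty_fit <- function(column = NA_integer_) {
  data.frame(column = column, G0 = NA_real_, tau_D_s = NA_real_,
             D_um2_s = NA_real_, chi2 = NA_real_, dof = NA_integer_,
             valid = FALSE, speed_class = "invalid",
             N_apparent = NA_real_, stringsAsFactors = FALSE)
}

#' Fit a single-component FCS model to a correlation curve
#'
#' Weighted least squares (Levenberg-Marquardt) fit of the model in
#' [fcs_model_config()]. Initialization is derivative-free: G0 from the
#' mean of the first three lags, tau_D from the lag at which the curve
#' first falls to G0/2. Non-convergence, fewer than 8 finite lag points, a
#' non-positive early amplitude, a diffusion coefficient outside the
#' admissible range, or an unacceptable reduced chi-square all yield an
#' invalid result rather than an error.
#'
#' @param lag_times_s Lag times, s (or a `correlation_curve` in which case
#'   `values` is taken from it).
#' @param values Correlation values at the lags.
#' @param model An [fcs_model_config()].
#' @param weights Optional per-lag weights (1/variance). When supplied,
#'   `chi2` is the weighted residual sum of squares and the reduced
#'   chi-square gate applies.
#' @param column Optional 0-based column index carried into the result.
#' @return One-row data.frame: `column, G0, tau_D_s, D_um2_s, chi2, dof,
#'   valid, speed_class, N_apparent`.
#' @export
fit_single_component <- function(lag_times_s, values = NULL, model,
                                 weights = NULL, column = NA_integer_) {
  if (is.list(lag_times_s) && !is.null(lag_times_s$lag_times_s)) {
    values <- lag_times_s$values
    lag_times_s <- lag_times_s$lag_times_s
  }
  stopifnot(inherits(model, "fcs_model_config"),
            length(lag_times_s) == length(values))
  keep <- is.finite(lag_times_s) & is.finite(values)
  if (!is.null(weights)) keep <- keep & is.finite(weights) & weights > 0
  tau <- lag_times_s[keep]; y <- values[keep]
  w <- if (is.null(weights)) NULL else weights[keep]
  if (length(y) < 8) return(empty_fit(column))
  g0_init <- mean(y[seq_len(min(3, length(y)))])
  if (!is.finite(g0_init) || g0_init <= 0) return(empty_fit(column))
  below <- which(y < g0_init / 2)
  tau_init <- if (length(below) > 0) tau[below[1]] else stats::median(tau)
  tau_init <- max(tau_init, tau[1] / 2)
  kappa <- model$structure_parameter
  df <- data.frame(tau = tau, y = y)
  form <- if (is.finite(kappa))
    y ~ G0 / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD)))
  else y ~ G0 / (1 + tau / tauD)
  start <- list(G0 = g0_init, tauD = tau_init)
  lower <- c(1e-12, 1e-9)
  if (model$fit_offset) {
    form <- stats::as.formula(
      paste(paste(deparse(form), collapse = " "), "+ Ginf"))
    start$Ginf <- 0
    lower <- c(lower, -Inf)
  }
  call_args <- list(form, data = df, start = start, lower = lower,
                    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(w)) call_args$weights <- w
  fit <- tryCatch(do.call(minpack.lm::nlsLM, call_args),
                  error = function(e) NULL)
  if (is.null(fit)) return(empty_fit(column))
  p <- stats::coef(fit)
  G0 <- unname(p["G0"]); tauD <- unname(p["tauD"])
  Ginf <- if (model$fit_offset) unname(p["Ginf"]) else 0
  D <- model$psf_waist_um^2 / (4 * tauD)
  n_par <- length(start)
  dof <- length(y) - as.integer(n_par)
  res <- y - fcs_model_curve(tau, G0, tauD, kappa) - Ginf
  chi2 <- if (is.null(w)) NA_real_ else sum(w * res^2)
  chi2_ok <- is.na(chi2) || dof < 1 || chi2 / dof < model$chi2_max
  in_range <- D >= model$d_range_um2_s[1] & D <= model$d_range_um2_s[2]
  valid <- is.finite(D) && G0 > 0 && in_range && chi2_ok
  data.frame(column = column, G0 = G0, tau_D_s = tauD, D_um2_s = D,
             chi2 = chi2, dof = dof, valid = valid,
             speed_class = classify_speed(D, model$fast_slow_threshold_um2_s,
                                          valid),
             N_apparent = 1 / G0, stringsAsFactors = FALSE)
}

#' Classify diffusion as fast or slow
#'
#' `D` strictly above the threshold is "fast"; `0 <= D <= threshold` is
#' "slow" (the boundary value itself is slow); invalid fits propagate as
#' "invalid".
#'
#' @param D Diffusion coefficient(s), um^2/s.
#' @param threshold Boundary, um^2/s (default 2).
#' @param valid Logical validity flag(s), recycled.
#' @return Character vector: `"fast"`, `"slow"` or `"invalid"`.
#' @export
classify_speed <- function(D, threshold = 2, valid = TRUE) {
  out <- ifelse(D > threshold, "fast", "slow")
  out[!valid | !is.finite(D) | D < 0] <- "invalid"
  out
}

#' Fit all columns of a carpet ACF
#'
#' Computes the per-column ACF (optionally with block-estimated weights)
#' and fits each column with [fit_single_component()].
#'
#' Weights: when `n_blocks >= 4`, the carpet is split into `n_blocks`
#' temporal blocks, the ACF is computed per block, and the inverse
#' empirical variance of the block mean is used as the per-lag weight;
#' otherwise the fit is unweighted.
#'
#' @param carpet A [line_scan_carpet()].
#' @param model An [fcs_model_config()].
#' @param channel Channel to analyse (1-based).
#' @param lags Lag grid (default [multitau_lags()]).
#' @param n_blocks Temporal blocks for weight estimation (0 or < 4
#'   disables weighting).
#' @return Data.frame of per-column fit results (class `fcs_fit_result`),
#'   with the ACF `correlation_carpet` attached as attribute `"acf"`.
#' @export
fit_carpet_acf <- function(carpet, model = fcs_model_config(), channel = 1,
                           lags = NULL, n_blocks = 8) {
  stopifnot(inherits(carpet, "line_scan_carpet"))
  nl <- dim(carpet$data)[1]
  if (is.null(lags)) lags <- multitau_lags(nl)
  cc <- pcf_carpet(carpet, d = 0, channel_a = channel, lags = lags)
  np <- nrow(cc$values)
  wmat <- NULL
  if (n_blocks >= 4) {
    bl <- floor(nl / n_blocks)
    blags <- lags[lags < bl / 2]
    if (length(blags) >= 8) {
      block_vals <- array(NA_real_, dim = c(np, length(blags), n_blocks))
      A <- carpet$data[, , channel]
      for (b in seq_len(n_blocks)) {
        seg <- A[((b - 1) * bl + 1):(b * bl), , drop = FALSE]
        r <- pcf_pairs_fft(seg, seg, blags)
        block_vals[, , b] <- r$values
      }
      v <- apply(block_vals, c(1, 2), stats::var) / n_blocks
      wmat <- matrix(NA_real_, np, length(lags))
      wmat[, seq_along(blags)] <- 1 / pmax(v, 1e-12)
    }
  }
  out <- do.call(rbind, lapply(seq_len(np), function(i) {
    if (!cc$valid[i]) return(empty_fit(i - 1L))
    fit_single_component(cc$lag_times_s, cc$values[i, ], model,
                         weights = if (is.null(wmat)) NULL else wmat[i, ],
                         column = i - 1L)
  }))
  class(out) <- c("fcs_fit_result", class(out))
  attr(out, "acf") <- cc
  attr(out, "model") <- model
  out
}

#' File-averaged diffusion estimate
#'
#' Combines repeated acquisitions ("files") of the same field. Default
#' interpretation: average the per-column ACF curves across files, then fit
#' the averaged curves; the alternative averages the per-file fitted D
#' values. Both are provided because either reading of "file averaged" is
#' defensible.
#'
#' @param carpets List of [line_scan_carpet()] with identical geometry.
#' @param model An [fcs_model_config()].
#' @param method `"average_curves"` (default) or `"average_fits"`.
#' @param channel Channel to analyse.
#' @param lags Lag grid.
#' @return A `fcs_fit_result` data.frame (per column).
#' @export
file_averaged_diffusion <- function(carpets, model = fcs_model_config(),
                                    method = c("average_curves",
                                               "average_fits"),
                                    channel = 1, lags = NULL) {
  method <- match.arg(method)
  stopifnot(length(carpets) >= 1)
  if (is.null(lags)) lags <- multitau_lags(dim(carpets[[1]]$data)[1])
  if (method == "average_curves") {
    ccs <- lapply(carpets, pcf_carpet, d = 0, channel_a = channel,
                  lags = lags)
    avg <- ccs[[1]]
    avg$values <- Reduce(`+`, lapply(ccs, `[[`, "values")) / length(ccs)
    avg$valid <- Reduce(`&`, lapply(ccs, `[[`, "valid"))
    out <- do.call(rbind, lapply(seq_len(nrow(avg$values)), function(i) {
      if (!avg$valid[i]) return(empty_fit(i - 1L))
      fit_single_component(avg$lag_times_s, avg$values[i, ], model,
                           column = i - 1L)
    }))
    class(out) <- c("fcs_fit_result", class(out))
    attr(out, "acf") <- avg
    out
  } else {
    fits <- lapply(carpets, fit_carpet_acf, model = model,
                   channel = channel, lags = lags, n_blocks = 0)
    base <- fits[[1]]
    dmat <- sapply(fits, function(f) ifelse(f$valid, f$D_um2_s, NA_real_))
    base$D_um2_s <- rowMeans(dmat, na.rm = TRUE)
    base$valid <- rowSums(!is.na(dmat)) > 0
    base$speed_class <- classify_speed(base$D_um2_s,
                                       model$fast_slow_threshold_um2_s,
                                       base$valid)
    base$G0 <- base$tau_D_s <- base$chi2 <- base$N_apparent <- NA_real_
    base
  }
}

#' Per-zone summary statistics of fitted diffusion
#'
#' Boxplot-style statistics (n, mean, SEM, median, quartiles) of the valid
#' fitted D values per zone, optionally split by speed class. Empty zones
#' are reported with `n = 0` and null statistics.
#'
#' @param results A `fcs_fit_result` data.frame.
#' @param zone_map A `zone_map` from [assign_zones()] covering the same
#'   columns.
#' @param by_class Also split by fast/slow speed class (default FALSE).
#' @return Data.frame with columns `zone` (and `speed_class`), `n`,
#'   `mean_D`, `sem_D`, `median_D`, `q25_D`, `q75_D`.
#' @export
zone_statistics <- function(results, zone_map, by_class = FALSE) {
  stopifnot(inherits(zone_map, "zone_map"),
            length(zone_map$labels) > max(results$column, 0))
  zl <- zone_map$labels[results$column + 1]
  zones <- c("cytoplasm", "NE", "nucleoplasm")
  groups <- if (by_class)
    expand.grid(zone = zones, speed_class = c("fast", "slow"),
                stringsAsFactors = FALSE)
  else data.frame(zone = zones, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- results$valid & zl == groups$zone[g]
    if (by_class) sel <- sel & results$speed_class == groups$speed_class[g]
    d <- results$D_um2_s[sel]
    n <- length(d)
    row <- data.frame(zone = groups$zone[g], n = n,
                      mean_D = if (n) mean(d) else NA_real_,
                      sem_D = if (n > 1) stats::sd(d) / sqrt(n) else NA_real_,
                      median_D = if (n) stats::median(d) else NA_real_,
                      q25_D = if (n) unname(stats::quantile(d, 0.25)) else NA_real_,
                      q75_D = if (n) unname(stats::quantile(d, 0.75)) else NA_real_,
                      stringsAsFactors = FALSE)
    if (by_class) row <- cbind(row[1], speed_class = groups$speed_class[g],
                               row[-1])
    row
  }))
  rownames(out) <- NULL
  out
}
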
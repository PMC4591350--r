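#' Kinetic curve objects
#'
#' One well's OmniLog time series: metadata plus a strictly increasing
#' time grid (hours) and non-negative signals (OmniLog color units).
#'
#' @param strain_id,plate_id,well_id,substrate,replicate Metadata.
#' @param times Hours, strictly increasing.
#' @param signals Signal values, same length as `times`.
#' @return An object of class `KineticCurve`.
#' @export
kinetic_curve <- function(strain_id, plate_id, well_id, substrate,
                          replicate, times, signals) {
  if (length(times) != length(signals))
    stop_("times and signals must have equal length")
  if (any(diff(times) <= 0)) stop_("times must be strictly increasing")
  structure(list(strain_id = strain_id, plate_id = plate_id,
                 well_id = well_id, substrate = substrate,
                 replicate = as.integer(replicate),
                 times = as.numeric(times), signals = as.numeric(signals)),
            class = "KineticCurve")
}

#' @export
print.KineticCurve <- function(x, ...) {
  cat(sprintf("KineticCurve %s/%s/%s (%s, rep %d): %d points over %.2g h\n",
              x$strain_id, x$plate_id, x$well_id, x$substrate, x$replicate,
              length(x$times), max(x$times)))
  invisible(x)
}

#' Read and write OmniLog-style kinetics files
#'
#' The kinetics CSV has a `time_h` column plus one column per well; the
#' sidecar manifest TSV maps well columns to metadata with columns
#' `well_id`, `strain_id`, `plate_id`, `substrate`, `replicate`.
#' Negative signals are clipped to zero (the number of clipped values
#' is attached as attribute `n_clipped` with a warning); a non-monotone
#' time column is a format error.
#'
#' @param path Kinetics CSV path.
#' @param manifest_path Manifest TSV path.
#' @return `read_kinetics()`: a list of `KineticCurve`; `write_kinetics()`
#'   writes both files and returns `path` invisibly.
#' @export
read_kinetics <- function(path, manifest_path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(df)) stop_("kinetics CSV lacks a time_h column")
  times <- df$time_h
  if (any(diff(times) <= 0)) stop_("time_h column is not strictly increasing")
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("well_id", "strain_id", "plate_id", "substrate", "replicate")
  if (!all(need %in% names(man)))
    stop_("manifest lacks column(s): %s",
          paste(setdiff(need, names(man)), collapse = ", "))
  wells <- setdiff(names(df), "time_h")
  orphan <- setdiff(wells, man$well_id)
  if (length(orphan))
    stop_("wells missing from manifest: %s", paste(orphan, collapse = ", "))
  n_clipped <- 0L
  curves <- lapply(wells, function(w) {
    y <- df[[w]]
    neg <- y < 0
    if (any(neg)) { n_clipped <<- n_clipped + sum(neg); y[neg] <- 0 }
    m <- man[man$well_id == w, ][1, ]
    kinetic_curve(m$strain_id, m$plate_id, w, m$substrate, m$replicate,
                  times, y)
  })
  if (n_clipped > 0)
    warning(sprintf("%d negative signal value(s) clipped to 0", n_clipped))
  attr(curves, "n_clipped") <- n_clipped
  curves
}

#' @rdname read_kinetics
#' @param curves List of `KineticCurve` sharing one time grid.
#' @export
write_kinetics <- function(curves, path, manifest_path) {
  if (!length(curves)) stop_("no curves to write")
  times <- curves[[1]]$times
  for (kc in curves)
    if (!isTRUE(all.equal(kc$times, times)))
      stop_("all curves must share the same time grid")
  df <- data.frame(time_h = times)
  man <- list()
  for (kc in curves) {
    df[[kc$well_id]] <- kc$signals
    man[[length(man) + 1L]] <- data.frame(
      well_id = kc$well_id, strain_id = kc$strain_id, plate_id = kc$plate_id,
      substrate = kc$substrate, replicate = kc$replicate,
      stringsAsFactors = FALSE)
  }
  write_atomic(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
  write_tsv_atomic(do.call(rbind, man), manifest_path)
  invisible(path)
}

#' Nine characteristic curve parameters
#'
#' Summarizes one kinetic curve with nine values:
#' \describe{
#'   \item{y0}{baseline, mean of the first 3 points;}
#'   \item{min_s, max_s}{raw signal extremes;}
#'   \item{span}{`max_s - min_s`;}
#'   \item{avg_height}{mean raw signal;}
#'   \item{lag_lambda}{lag time in hours, from the tangent at the point
#'     of maximum slope: `t* - (y(t*) - y0)/mu`, clamped to
#'     `[0, last time]`; equals the last time when `mu = 0`;}
#'   \item{max_slope_mu}{maximum first difference of the
#'     moving-average-smoothed signal divided by the time step
#'     (units/hour), floored at 0;}
#'   \item{plateau}{mean of the last `plateau_tail` points;}
#'   \item{auc}{trapezoidal integral of the baseline-subtracted signal
#'     clamped below at 0 (units x hours) — the activity measure.}
#' }
#'
#' @param curve A `KineticCurve`, or any list with `times` and `signals`.
#' @param smooth_window Odd moving-average window in points (default 5).
#' @param plateau_tail Number of tail points averaged for the plateau.
#' @return Named numeric vector of the nine parameters.
#' @export
curve_parameters <- function(curve, smooth_window = 5L, plateau_tail = 8L) {
  t <- curve$times; y <- curve$signals
  n <- length(y)
  if (n < smooth_window)
    stop_("curve has %d points, fewer than smooth_window = %d", n, smooth_window)
  if (smooth_window %% 2L == 0L) stop_("smooth_window must be odd")
  y0 <- mean(y[seq_len(min(3L, n))])
  sm <- as.numeric(stats::filter(y, rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  ok <- which(!is.na(sm))
  slopes <- diff(sm[ok]) / diff(t[ok])
  if (!length(slopes) || max(slopes) <= 0) {
    mu <- 0
    lag <- t[n]
  } else {
    i <- which.max(slopes)
    mu <- slopes[i]
    t_star <- (t[ok][i] + t[ok][i + 1L]) / 2          # slope midpoint time
    y_star <- (sm[ok][i] + sm[ok][i + 1L]) / 2
    lag <- min(max(t_star - (y_star - y0) / mu, 0), t[n])
  }
  h <- pmax(y - y0, 0)
  c(y0 = y0, min_s = min(y), max_s = max(y), span = max(y) - min(y),
    avg_height = mean(y), lag_lambda = lag, max_slope_mu = mu,
    plateau = mean(y[seq.int(max(1L, n - plateau_tail + 1L), n)]),
    auc = pracma::trapz(t, h))
}

#' Fit a sigmoid model to a kinetic curve
#'
#' Least-squares fit (Levenberg-Marquardt via \pkg{minpack.lm}) of one
#' of the three sigmoid models, initialized from [curve_parameters()]
#' (`A` from the span, `mu` from the maximum slope, `lambda` from the
#' lag, `y0` from the baseline; `nu = 1` for Richards). Parameters are
#' bounded: `A, mu, lambda >= 0`, `nu` in `[0.05, 20]`. Fits are
#' diagnostic only — activity scoring always uses the direct area, never
#' the fitted curve. Non-convergence is reported as `converged = FALSE`
#' with `rss = Inf`.
#'
#' @param curve A `KineticCurve`.
#' @param model One of `"logistic"`, `"gompertz"`, `"richards"`.
#' @return A list of class `SigmoidFit`: `model`, `params` (named),
#'   `rss`, `converged`.
#' @export
fit_sigmoid <- function(curve, model = c("logistic", "gompertz", "richards")) {
  model <- match.arg(model)
  t <- curve$times; y <- curve$signals
  if (length(y) <= sigmoid_n_params[[model]])
    stop_("curve must have more points than model parameters")
  cp <- curve_parameters(curve,
                         smooth_window = min(5L, length(y) - (1 - length(y) %% 2L)))
  start <- list(A = max(cp[["span"]], 1e-3),
                mu = max(cp[["max_slope_mu"]], 1e-3),
                lambda = max(cp[["lag_lambda"]], 0),
                y0 = cp[["y0"]])
  lower <- c(A = 0, mu = 0, lambda = 0, y0 = -Inf)
  upper <- c(A = Inf, mu = Inf, lambda = Inf, y0 = Inf)
  if (model == "richards") {
    start$nu <- 1
    lower <- c(lower, nu = 0.05)
    upper <- c(upper, nu = 20)
  }
  fit <- tryCatch({
    f <- if (model == "richards")
      minpack.lm::nlsLM(y ~ sigmoid_value(model, t, A, mu, lambda, y0, nu),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ sigmoid_value(model, t, A, mu, lambda, y0),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    list(params = stats::coef(f), rss = sum(stats::resid(f)^2),
         converged = f$convInfo$isConv %||% TRUE)
  }, error = function(e) list(params = setNames(rep(NA_real_, length(start)),
                                                names(start)),
                              rss = Inf, converged = FALSE))
  structure(list(model = model, params = fit$params, rss = fit$rss,
                 converged = fit$converged), class = "SigmoidFit")
}

#' @export
print.SigmoidFit <- function(x, ...) {
  cat(sprintf("SigmoidFit[%s] rss = %.4g, converged = %s\n",
              x$model, x$rss, x$converged))
  if (all(is.finite(x$params))) print(round(x$params, 4))
  invisible(x)
}

#' Best-fitting sigmoid model for a curve
#'
#' Fits all three models and returns the converged fit with the lowest
#' residual sum of squares. RSS values within a small relative
#' tolerance are treated as tied; ties go to the model with fewer
#' parameters, then to the fixed order logistic, Gompertz, Richards
#' (relevant because the Richards model at `nu = 1` reproduces the
#' logistic exactly). If no model converges the least-bad attempt is
#' returned with `converged = FALSE`.
#'
#' @param curve A `KineticCurve`.
#' @return A `SigmoidFit`.
#' @export
best_fit <- function(curve) {
  fits <- lapply(sigmoid_models, function(m) fit_sigmoid(curve, m))
  conv <- vapply(fits, `[[`, logical(1), "converged")
  pool <- if (any(conv)) fits[conv] else fits
  rss <- vapply(pool, `[[`, numeric(1), "rss")
  best <- min(rss)
  tol <- 1e-6 * (1 + abs(best))
  tied <- which(rss <= best + tol)
  npar <- sigmoid_n_params[vapply(pool, `[[`, character(1), "model")[tied]]
  tied <- tied[npar == min(npar)]
  pool[[tied[1]]]
}

#' Activity of one strain x substrate from replicate curves
#'
#' Activity is the mean replicate AUC of the baseline-subtracted signal
#' (the direct activity area). Replicates are checked for consistency:
#' the record is flagged inconsistent when the relative spread
#' `(max - min)/mean` of the replicate AUCs exceeds `consistency_tol`
#' (records with zero mean activity are trivially consistent).
#' Inconsistent records are flagged, never dropped.
#'
#' @param curves List of replicate `KineticCurve`s for one
#'   strain x substrate (>= 1).
#' @param consistency_tol Relative spread tolerance (default 0.25).
#' @return A one-row data.frame: `strain_id`, `plate_id`, `substrate`,
#'   `n_replicates`, `activity`, `consistent`.
#' @export
activity <- function(curves, consistency_tol = 0.25) {
  if (!length(curves)) stop_("at least one replicate curve is required")
  aucs <- vapply(curves, function(kc) curve_parameters(kc)[["auc"]], numeric(1))
  m <- mean(aucs)
  consistent <- if (m > 0) (max(aucs) - min(aucs)) / m <= consistency_tol else TRUE
  data.frame(strain_id = curves[[1]]$strain_id,
             plate_id = curves[[1]]$plate_id,
             substrate = curves[[1]]$substrate,
             n_replicates = length(curves),
             activity = m, consistent = consistent,
             stringsAsFactors = FALSE)
}

PM_LEVELS <- c("low", "lower-middle", "upper-middle", "high")

#' Four-level activity categories per plate
#'
#' Thresholds are set per plate as fractions of that plate's maximum
#' activity `M`: `low` below `cut[1]*M`, `lower-middle` below
#' `cut[2]*M`, `upper-middle` below `cut[3]*M`, else `high`. An
#' all-zero plate is entirely `low`.
#'
#' @param activities Numeric activity values of one plate (>= 1).
#' @param cutpoints Increasing fractions of the plate maximum
#'   (default `c(0.25, 0.50, 0.75)`).
#' @return An ordered factor over
#'   `low < lower-middle < upper-middle < high`.
#' @export
categorize_activities <- function(activities, cutpoints = c(0.25, 0.50, 0.75)) {
  if (!length(activities)) stop_("at least one activity is required")
  if (length(cutpoints) != 3L || any(diff(cutpoints) <= 0))
    stop_("cutpoints must be three increasing fractions")
  M <- max(activities)
  lev <- if (M <= 0) rep("low", length(activities)) else
    PM_LEVELS[1L + findInterval(activities / M, cutpoints)]
  factor(lev, levels = PM_LEVELS, ordered = TRUE)
}

#' Min-max normalization for activity heat maps
#'
#' Maps a plate's activities linearly onto `[0, 1]`; a constant input
#' maps to all zeros.
#'
#' @param activities Numeric vector (>= 1 value).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_heatmap <- function(activities) {
  if (!length(activities)) stop_("at least one activity is required")
  rng <- range(activities)
  if (diff(rng) == 0) return(rep(0, length(activities)))
  (activities - rng[1]) / diff(rng)
}
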
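## Viability normalization and Hill-sigmoid IC50 estimation.
##
## The model chain is: raw plate fluorescence -> background subtraction ->
## normalization to the untreated reference (percent viability) -> replicate
## averaging -> four-parameter Hill fit -> per-panel normalized/ranked IC50
## profile. Each step is exposed on its own so intermediate results can be
## inspected and tested.

#' Hill sigmoid dose-response function
#'
#' Decreasing four-parameter log-logistic (Hill) viability curve
#' \deqn{anI(D) = min + \frac{max - min}{1 + (D/IC_{50})^H}}
#' where `D` is the dose, `min`/`max` the lower/upper viability plateaus (in
#' percent of untreated), `ic50` the half-maximal inhibitory concentration and
#' `hill` the Hill coefficient controlling steepness. Strictly decreasing in
#' `D` for `hill > 0`.
#'
#' @param dose Dose (same units as `ic50`, typically uM); non-negative,
#'   vectorized.
#' @param min,max Lower and upper plateaus (percent viability), `min < max`.
#' @param ic50 Half-maximal inhibitory concentration, `> 0`.
#' @param hill Hill coefficient, `> 0`.
#' @return Predicted viability (percent of untreated), same length as `dose`.
#' @examples
#' hill_function(0, min = 10, max = 100, ic50 = 50, hill = 1.5)   # = max
#' hill_function(50, min = 10, max = 100, ic50 = 50, hill = 1.5)  # midpoint 55
#' @export
hill_function <- function(dose, min, max, ic50, hill) {
  check_scalar_number(ic50, "ic50", lower = 0, strict_lower = TRUE)
  check_scalar_number(hill, "hill", lower = 0, strict_lower = TRUE)
  check_scalar_number(min, "min")
  check_scalar_number(max, "max")
  if (min >= max) stop_field("min", "must be smaller than 'max'")
  if (any(dose < 0)) stop_field("dose", "doses must be non-negative")
  min + (max - min) / (1 + (dose / ic50)^hill)
}

#' Subtract plate background from raw intensities
#'
#' Subtracts the blank-well background signal from raw fluorescence readings.
#' Values that would fall at or below zero are clipped to a small positive
#' floor (with a warning) so that downstream normalization stays well-defined.
#'
#' @param raw Numeric matrix (or vector) of raw intensities, replicates in
#'   rows, doses in columns.
#' @param background Scalar blank-well intensity, `>= 0`.
#' @param floor Clipping floor for background-subtracted values (default
#'   `1e-6`).
#' @return Background-subtracted intensities, same shape as `raw`.
#' @export
subtract_background <- function(raw, background, floor = 1e-6) {
  check_scalar_number(background, "background", lower = 0)
  check_scalar_number(floor, "floor", lower = 0, strict_lower = TRUE)
  if (!is.numeric(raw) || anyNA(raw)) {
    stop_field("raw", "must be numeric without missing values")
  }
  out <- raw - background
  n_clip <- sum(out < floor)
  if (n_clip > 0L) {
    warning(sprintf(
      "%d intensit%s at or below background; clipped to floor %g",
      n_clip, if (n_clip == 1L) "y" else "ies", floor
    ), call. = FALSE)
    out[out < floor] <- floor
  }
  out
}

#' Construct a dose-response series for one cell line / compound / timepoint
#'
#' Bundles the raw per-replicate intensity readings of one dose ladder with
#' the plate background and the untreated reference intensity.
#'
#' @param cell_line,compound Labels.
#' @param timepoint_h Exposure duration in hours.
#' @param doses Dose vector in uM, strictly increasing, may include 0.
#' @param raw_intensities Numeric matrix, replicates x doses.
#' @param background Scalar blank-well intensity (default 0).
#' @param reference_intensity Untreated reference intensity I0, already
#'   background-subtracted; must be `> 0` (otherwise the untreated signal sits
#'   below background and normalization is meaningless).
#' @return Object of class `dose_response_series`.
#' @export
dose_response_series <- function(cell_line, compound = "compound",
                                 timepoint_h = NA_real_, doses,
                                 raw_intensities, background = 0,
                                 reference_intensity) {
  check_doses(doses, "doses")
  if (is.vector(raw_intensities)) {
    raw_intensities <- matrix(raw_intensities, nrow = 1L)
  }
  if (!is.matrix(raw_intensities) || !is.numeric(raw_intensities)) {
    stop_field("raw_intensities", "must be a numeric replicate x dose matrix")
  }
  if (ncol(raw_intensities) != length(doses)) {
    stop_field("raw_intensities",
               sprintf("has %d columns but there are %d doses",
                       ncol(raw_intensities), length(doses)))
  }
  check_scalar_number(background, "background", lower = 0)
  if (!is.numeric(reference_intensity) || length(reference_intensity) != 1L ||
      !is.finite(reference_intensity) || reference_intensity <= 0) {
    stop("reference signal below background", call. = FALSE)
  }
  structure(
    list(cell_line = as.character(cell_line),
         compound = as.character(compound),
         timepoint_h = as.numeric(timepoint_h),
         doses = as.numeric(doses),
         raw_intensities = raw_intensities,
         background = as.numeric(background),
         reference_intensity = as.numeric(reference_intensity)),
    class = "dose_response_series"
  )
}

#' Normalize a dose-response series to percent of untreated
#'
#' Background-subtracts the raw readings and expresses each replicate as a
#' percentage of the untreated reference intensity,
#' \eqn{nI_i = 100 \, I_i / I_0}, then averages the replicates at each dose
#' into the mean normalized pattern \eqn{anI_i = \frac{1}{N}\sum_j nI_i(j)}.
#'
#' @param series A [dose_response_series()].
#' @param floor Clipping floor passed to [subtract_background()].
#' @return Object of class `normalized_response` with fields `doses`, `nI`
#'   (replicate x dose percent-viability matrix), `anI` (replicate-averaged
#'   pattern) and `n_replicates`.
#' @export
normalize_viability <- function(series, floor = 1e-6) {
  stopifnot(inherits(series, "dose_response_series"))
  corrected <- subtract_background(series$raw_intensities, series$background,
                                   floor = floor)
  nI <- 100 * corrected / series$reference_intensity
  anI <- colMeans(nI)
  structure(
    list(cell_line = series$cell_line, compound = series$compound,
         timepoint_h = series$timepoint_h, doses = series$doses,
         nI = nI, anI = anI, n_replicates = nrow(nI)),
    class = "normalized_response"
  )
}

## Shared fitting core used by fit_hill(); exported surface is fit_hill().
fit_hill_core <- function(d, y, range_factor, max_restarts) {
  min0 <- min(y); max0 <- max(y)
  mid <- (min0 + max0) / 2
  pos <- d > 0
  ic50_0 <- d[pos][which.min(abs(y[pos] - mid))]
  lower <- c(vmin = 0, vmax = 0, ic50 = 1e-12, hill = 1e-3)
  upper <- c(vmin = 200, vmax = 200, ic50 = Inf, hill = 20)

  one_fit <- function(ic50_start) {
    start <- list(vmin = base::max(min0, 0), vmax = base::min(max0, 200),
                  ic50 = ic50_start, hill = 1)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ vmin + (vmax - vmin) / (1 + (d / ic50)^hill),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
      ),
      error = function(e) NULL
    )
  }

  ## Deterministic restart ladder over the prescribed x[0.1, 10] interval.
  starts <- ic50_0 * c(1, 10^seq(-1, 1, length.out = max_restarts))
  best <- NULL; best_rss <- Inf
  for (s in starts) {
    fit <- one_fit(s)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }

  if (is.null(best)) {
    return(list(par = c(vmin = min0, vmax = max0, ic50 = ic50_0, hill = 1),
                rss = NA_real_, optimizer_ok = FALSE))
  }
  par <- stats::coef(best)
  ## Decreasing-sigmoid branch: a fit with vmax <= vmin is a degenerate or
  ## increasing curve and is flagged as non-converged.
  ok <- par[["vmax"]] > par[["vmin"]]
  dr <- range(d[pos])
  in_range <- par[["ic50"]] >= dr[1] / range_factor &&
    par[["ic50"]] <= dr[2] * range_factor
  list(par = par, rss = best_rss, optimizer_ok = ok && in_range)
}

#' Fit the Hill sigmoid to a normalized dose-response pattern
#'
#' Nonlinear least squares of [hill_function()] to the replicate-averaged
#' pattern `anI` (default) or to the pooled per-replicate points. Starting
#' values are taken from the data (plateaus from the extreme responses, IC50
#' from the dose nearest the midpoint, Hill coefficient 1) and the fit is
#' restarted over a deterministic ladder of IC50 starting values spanning
#' 0.1x-10x before giving up. Box constraints keep the decreasing branch:
#' `min` in \[0, 200\], `max` in \[0, 200\], `hill` in (0, 20\], `ic50 > 0`.
#'
#' A fit is reported as non-converged (parameters still returned) when the
#' optimizer fails, the fitted curve is not decreasing (`max <= min`), or the
#' fitted IC50 falls outside the non-zero dose range by more than
#' `range_factor`.
#'
#' @param response A [normalize_viability()] result.
#' @param pooled If `TRUE`, fit all replicate points rather than the averaged
#'   pattern.
#' @param include_zero_dose Include the untreated (dose 0) point in the fit
#'   (default `TRUE`; the model is defined at `D = 0`).
#' @param range_factor Factor by which the fitted IC50 may exceed the
#'   observed dose range while still counting as converged (default 100).
#' @param max_restarts Number of IC50 restart values beyond the data-driven
#'   start (default 10).
#' @return Object of class `hill_fit` with fields `min`, `max`, `ic50`,
#'   `hill`, `rss`, `converged`, `n_points`.
#' @export
fit_hill <- function(response, pooled = FALSE, include_zero_dose = TRUE,
                     range_factor = 100, max_restarts = 10) {
  stopifnot(inherits(response, "normalized_response"))
  check_scalar_number(range_factor, "range_factor", lower = 1)
  max_restarts <- check_count(max_restarts, "max_restarts", lower = 1L)

  keep <- if (include_zero_dose) rep(TRUE, length(response$doses))
          else response$doses > 0
  doses <- response$doses[keep]
  if (sum(unique(doses) > 0) < 4L) {
    stop("at least 4 distinct non-zero doses are required for fitting",
         call. = FALSE)
  }
  if (pooled) {
    d <- rep(doses, each = nrow(response$nI))
    y <- as.vector(response$nI[, keep, drop = FALSE])
  } else {
    d <- doses
    y <- response$anI[keep]
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop_field("anI", "normalized responses must be finite")
  }
  if (diff(range(y)) == 0) stop("no dose dependence", call. = FALSE)

  core <- fit_hill_core(d, y, range_factor, max_restarts)
  par <- core$par
  structure(
    list(cell_line = response$cell_line, compound = response$compound,
         timepoint_h = response$timepoint_h,
         min = unname(par[["vmin"]]), max = unname(par[["vmax"]]),
         ic50 = unname(par[["ic50"]]), hill = unname(par[["hill"]]),
         rss = core$rss, converged = isTRUE(core$optimizer_ok),
         n_points = length(y)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit [%s, %s, %s h]: min=%.3g max=%.3g IC50=%.4g uM H=%.3g (rss=%.3g, %s)\n",
    x$cell_line, x$compound,
    if (is.na(x$timepoint_h)) "?" else format(x$timepoint_h),
    x$min, x$max, x$ic50, x$hill, x$rss,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Build a normalized, ranked IC50 profile across cell lines
#'
#' Collects fitted IC50 values \eqn{V_i} over a panel of cell lines and
#' derives the normalized values
#' \eqn{nV_i = (V_i - V_{min}) / (V_{max} - V_{min}) \in [0, 1]}
#' and their ascending ranks \eqn{R_i} (rank 1 = lowest IC50 = most
#' sensitive; ties receive average ranks). This normalized profile is the
#' "IC50 signature" correlated against expression patterns downstream.
#'
#' Non-converged fits are excluded with a warning. If all retained IC50
#' values are equal, `n_ic50` is set to 0 for every line (with a warning) and
#' ranks are tied.
#'
#' @param fits Named list of [fit_hill()] results (names = cell lines), or a
#'   named numeric vector of IC50 values.
#' @return Object of class `ic50_profile`: a data.frame with columns
#'   `cell_line`, `ic50`, `n_ic50`, `rank`.
#' @export
build_profile <- function(fits) {
  if (is.numeric(fits)) {
    if (is.null(names(fits))) stop_field("fits", "must be named by cell line")
    v <- fits
  } else {
    stopifnot(is.list(fits))
    if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
      stop_field("fits", "must be named by cell line")
    }
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (any(!conv)) {
      warning(sprintf("excluding non-converged fits: %s",
                      paste(names(fits)[!conv], collapse = ", ")),
              call. = FALSE)
      fits <- fits[conv]
    }
    v <- vapply(fits, function(f) f$ic50, numeric(1))
  }
  if (length(v) < 2L) {
    stop("at least 2 cell lines with converged fits are required",
         call. = FALSE)
  }
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("all IC50 values equal; normalized values set to 0",
            call. = FALSE)
    nv <- rep(0, length(v))
  } else {
    nv <- (v - rng[1]) / (rng[2] - rng[1])
  }
  out <- data.frame(cell_line = names(v), ic50 = unname(v),
                    n_ic50 = unname(nv),
                    rank = unname(rank(v)),  # average ranks on ties
                    stringsAsFactors = FALSE)
  class(out) <- c("ic50_profile", "data.frame")
  out
}

#' Average IC50 profiles over timepoints
#'
#' Averages the normalized IC50 values of per-timepoint profiles line by
#' line, then re-normalizes to \[0, 1\] and re-ranks, yielding the
#' timepoint-averaged susceptibility profile of the panel. For the averaged
#' profile the `ic50` column carries the per-line mean of the input
#' normalized values (unitless), since absolute concentrations are not
#' comparable across timepoints after normalization.
#'
#' @param profiles List of [build_profile()] results with identical cell-line
#'   sets and order.
#' @return An `ic50_profile`.
#' @export
aggregate_timepoints <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  lines <- profiles[[1]]$cell_line
  for (p in profiles) {
    stopifnot(inherits(p, "ic50_profile"))
    if (!identical(p$cell_line, lines)) {
      stop("profiles have mismatched cell-line sets or order", call. = FALSE)
    }
  }
  mean_nv <- rowMeans(vapply(profiles, function(p) p$n_ic50,
                             numeric(length(lines))))
  names(mean_nv) <- lines
  build_profile(mean_nv)
}
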
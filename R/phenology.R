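#' Phenology extraction configuration
#'
#' Asymptotic growth curves never literally start or stop, so the onset and
#' termination dates are defined by threshold fractions of the seasonal
#' maximum: `D_o` is the earliest time the fitted curve reaches
#' `theta_o * W_max` and `D_t` the earliest time it reaches
#' `theta_t * W_max`.
#'
#' @param theta_o Onset threshold fraction (default 0.05).
#' @param theta_t Termination threshold fraction (default 0.95).
#' @param grid_step Search grid resolution in days (default 0.1).
#' @param season_window Optional DOY interval; defaults to the fitted
#'   series' observed range.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(theta_o = 0.05, theta_t = 0.95,
                              grid_step = 0.1, season_window = NULL) {
  if (!(theta_o > 0 && theta_o < theta_t && theta_t < 1))
    stop("need 0 < theta_o < theta_t < 1", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be positive", call. = FALSE)
  structure(list(theta_o = theta_o, theta_t = theta_t,
                 grid_step = grid_step, season_window = season_window),
            class = "extraction_config")
}

#' Extract growth-characteristic parameters from a fitted curve
#'
#' From a converged [fit_series()] result, extracts the phenological
#' parameter set: `W_max` (maximum of the fitted curve over the season
#' window), `V_max`/`D_vmax` (maximum growth rate and its date, from the
#' first rate peak), `D_o`/`D_t` (threshold onset and termination dates),
#' `D_r`/`D_st` (onset and end of rapid growth, defined as the acceleration
#' maximum before and the acceleration minimum after the rate peak), the
#' growth periods `GD_sl = D_r - D_o`, `GD_r = D_st - D_r`,
#' `GD = D_t - D_o`, `GD_st` (unimodal: `D_t - D_st`; bimodal:
#' `D_t - D_st2`), and `V_mean = W_max / GD`.
#'
#' A `bidoseresp` fit whose rate has two maxima is treated as bimodal: the
#' window is split at the interior rate minimum and a second-phase set
#' (`V_max2`, `D_r2`, `D_vmax2`, `D_st2`, `GD_sl2 = D_r2 - D_st`,
#' `GD_r2 = D_st2 - D_r2`) is extracted on the second segment. If only one
#' rate maximum is found, the phase-2 fields stay `NA` and a warning is
#' recorded.
#'
#' @param fit A converged `growth_fit`.
#' @param config An [extraction_config()].
#' @return An object of class `phenology_params`.
#' @export
extract_phenology <- function(fit, config = extraction_config()) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged))
    stop("phenology requires a converged fit", call. = FALSE)
  win <- config$season_window %||% fit$season_window
  if (length(win) != 2 || win[1] >= win[2])
    stop("invalid season window", call. = FALSE)
  fam <- fit$family; par <- fit$params; h <- config$grid_step

  grid <- seq(win[1], win[2], by = h)
  yv <- grow_eval(fam, par, grid)

  # W_max: fitted-curve maximum over the window (refined off the grid)
  i <- which.max(yv)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  if (lo < hi) {
    opt <- stats::optimize(function(x) grow_eval(fam, par, x),
                           c(lo, hi), maximum = TRUE, tol = 1e-8)
    W_max <- max(opt$objective, yv[i])
  } else W_max <- yv[i]

  ex <- rate_extrema(fam, par, win, grid_step = h)
  maxima <- ex[ex$type == "max", , drop = FALSE]
  if (nrow(maxima) == 0)
    stop("extraction failure: no rate maximum inside the window (D_vmax)",
         call. = FALSE)
  bimodal <- fam == "bidoseresp" && nrow(maxima) >= 2
  if (fam == "bidoseresp" && !bimodal)
    warning("bidoseresp fit has a single rate peak; phase-2 fields left NA",
            call. = FALSE)

  D_vmax <- maxima$time[1]
  V_max <- maxima$rate[1]

  cross_up <- function(thr, label) {
    j <- which(yv >= thr)[1]
    if (is.na(j))
      stop(sprintf("extraction failure: threshold never crossed inside window (%s)",
                   label), call. = FALSE)
    if (j == 1) return(grid[1])
    stats::uniroot(function(x) grow_eval(fam, par, x) - thr,
                   c(grid[j - 1], grid[j]), tol = 1e-8)$root
  }
  D_o <- cross_up(config$theta_o * W_max, "D_o")
  D_t <- cross_up(config$theta_t * W_max, "D_t")

  # acceleration extremum on (a, b); maximum if `maximum`
  accel_extremum <- function(a, b, maximum) {
    g <- seq(a, b, by = min(h, (b - a) / 50))
    av <- grow_accel(fam, par, g)
    j <- if (maximum) which.max(av) else which.min(av)
    lo <- g[max(j - 1, 1)]; hi <- g[min(j + 1, length(g))]
    if (lo >= hi) return(g[j])
    opt <- stats::optimize(function(x) grow_accel(fam, par, x),
                           c(lo, hi), maximum = maximum, tol = 1e-8)
    if (maximum) opt$maximum else opt$minimum
  }

  split_t <- if (bimodal) {
    mins <- ex[ex$type == "min" & ex$time > maxima$time[1] &
                 ex$time < maxima$time[2], , drop = FALSE]
    if (nrow(mins)) mins$time[1] else mean(maxima$time[1:2])
  } else win[2]

  D_r <- accel_extremum(win[1], D_vmax, maximum = TRUE)
  D_st <- accel_extremum(D_vmax, split_t, maximum = FALSE)

  phase2 <- list(V_max2 = NA_real_, D_r2 = NA_real_, D_vmax2 = NA_real_,
                 D_st2 = NA_real_, GD_sl2 = NA_real_, GD_r2 = NA_real_)
  if (bimodal) {
    phase2$D_vmax2 <- maxima$time[2]
    phase2$V_max2 <- maxima$rate[2]
    phase2$D_r2 <- accel_extremum(split_t, phase2$D_vmax2, maximum = TRUE)
    phase2$D_st2 <- accel_extremum(phase2$D_vmax2, win[2], maximum = FALSE)
    phase2$GD_sl2 <- phase2$D_r2 - D_st
    phase2$GD_r2 <- phase2$D_st2 - phase2$D_r2
  }

  out <- structure(
    c(list(W_max = W_max, V_max = V_max, V_mean = NA_real_,
           D_o = D_o, D_r = D_r, D_vmax = D_vmax, D_st = D_st, D_t = D_t,
           GD_sl = NA_real_, GD_r = NA_real_, GD_st = NA_real_,
           GD = NA_real_, bimodal = bimodal),
      phase2,
      list(family = fam, series_id = fit$series_id, trait = fit$trait,
           patch_area_m2 = fit$patch_area_m2,
           reproductive_type = fit$reproductive_type)),
    class = "phenology_params")
  out <- derive_periods(out)
  check_phenology_order(out)
  out
}

#' Fill in the growth-period durations from the extracted dates
#'
#' Applies the duration identities `GD_sl = D_r - D_o`, `GD_r = D_st - D_r`,
#' `GD = D_t - D_o`, `GD_st = D_t - D_st` (unimodal) or `D_t - D_st2`
#' (bimodal), the phase-2 identities `GD_sl2 = D_r2 - D_st` and
#' `GD_r2 = D_st2 - D_r2`, and `V_mean = W_max / GD`. Accepts either a
#' `phenology_params` object or a plain named list carrying the dates, so
#' durations can also be recomputed from published mean dates.
#'
#' @param params A `phenology_params` object or a list with at least `D_o`,
#'   `D_r`, `D_st`, `D_t` (optionally `D_st2`, `W_max`).
#' @return The input with all duration fields (and `V_mean`, when `W_max`
#'   and `GD > 0` are available) populated.
#' @export
derive_periods <- function(params) {
  need <- c("D_o", "D_r", "D_st", "D_t")
  if (!all(need %in% names(params)) ||
      any(!is.finite(unlist(params[need]))))
    stop("dates D_o, D_r, D_st, D_t must all be populated", call. = FALSE)
  params$GD_sl <- params$D_r - params$D_o
  params$GD_r <- params$D_st - params$D_r
  params$GD <- params$D_t - params$D_o
  bim <- isTRUE(params$bimodal) ||
    (!is.null(params$D_st2) && is.finite(params$D_st2))
  params$GD_st <- if (bim) params$D_t - params$D_st2 else params$D_t - params$D_st
  if (bim && !is.null(params$D_r2) && is.finite(params$D_r2)) {
    params$GD_sl2 <- params$D_r2 - params$D_st
    if (is.finite(params$D_st2 %||% NA_real_))
      params$GD_r2 <- params$D_st2 - params$D_r2
  }
  if (!is.null(params$W_max) && is.finite(params$W_max) && params$GD > 0)
    params$V_mean <- mean_growth_rate(params$W_max, params$GD)
  params
}

#' Mean growth rate
#'
#' The growth increment per day, `W_max / GD`.
#'
#' @param W_max Maximum growth increment (trait units).
#' @param GD Total growth period in days; must be positive.
#' @return `W_max / GD` in trait units per day.
#' @examples
#' mean_growth_rate(76, 73)  # 1.04 cm/day, rounds to 1.0
#' @export
mean_growth_rate <- function(W_max, GD) {
  if (any(GD <= 0)) stop("GD must be positive", call. = FALSE)
  W_max / GD
}

#' @export
print.phenology_params <- function(x, ...) {
  cat(sprintf("<phenology_params> %s (%s)%s\n", x$series_id, x$trait,
              if (isTRUE(x$bimodal)) " [bimodal]" else ""))
  cat(sprintf("  W_max=%.2f  V_max=%.3f  V_mean=%.3f\n",
              x$W_max, x$V_max, x$V_mean))
  cat(sprintf("  D_o=%.1f D_r=%.1f D_vmax=%.1f D_st=%.1f D_t=%.1f\n",
              x$D_o, x$D_r, x$D_vmax, x$D_st, x$D_t))
  cat(sprintf("  GD_sl=%.1f GD_r=%.1f GD_st=%.1f GD=%.1f\n",
              x$GD_sl, x$GD_r, x$GD_st, x$GD))
  if (isTRUE(x$bimodal))
    cat(sprintf("  phase 2: V_max2=%.3f D_r2=%.1f D_vmax2=%.1f D_st2=%.1f\n",
                x$V_max2, x$D_r2, x$D_vmax2, x$D_st2))
  invisible(x)
}

check_phenology_order <- function(p) {
  ok <- p$D_o < p$D_r && p$D_r < p$D_vmax && p$D_vmax < p$D_st &&
    p$D_st <= p$D_t + 1e-8
  if (isTRUE(p$bimodal))
    ok <- ok && p$D_st < p$D_r2 && p$D_r2 < p$D_vmax2 &&
      p$D_vmax2 < p$D_st2 && p$D_st2 <= p$D_t + 1e-8
  if (!ok)
    stop("extraction failure: phenological date ordering violated",
         call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
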
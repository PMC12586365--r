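#' Construct a trait increment series
#'
#' A `trait_series` holds one monitored cluster's (or rhizome's) cumulative
#' growth-increment series for one trait, indexed by day of year. Aboveground
#' traits start from zero each spring; rhizome series must be
#' baseline-corrected with [rhizome_baseline_correct()] before fitting.
#'
#' @param series_id Identifier of the monitored cluster or rhizome.
#' @param patch_area_m2 Positive patch area in square metres.
#' @param trait One of `"plant_height"` (cm), `"leaf_area"` (cm^2),
#'   `"rhizome_length"` (cm).
#' @param reproductive_type `"asexual"`, `"sexual"`, or `"not_applicable"`
#'   (rhizomes are shared by the whole patch and carry no type).
#' @param doys Strictly increasing positive integers (day of year).
#' @param increments Non-negative numeric increments, same length as `doys`.
#' @return An object of class `trait_series`.
#' @export
trait_series <- function(series_id, patch_area_m2, trait, reproductive_type,
                         doys, increments) {
  trait <- match.arg(trait, c("plant_height", "leaf_area", "rhizome_length"))
  reproductive_type <- match.arg(reproductive_type,
                                 c("asexual", "sexual", "not_applicable"))
  if (!is.numeric(patch_area_m2) || patch_area_m2 <= 0)
    stop("`patch_area_m2` must be positive", call. = FALSE)
  if (length(doys) != length(increments))
    stop("`doys` and `increments` must have equal length", call. = FALSE)
  if (any(diff(doys) <= 0) || any(doys <= 0))
    stop("`doys` must be strictly increasing and positive", call. = FALSE)
  if (any(!is.finite(increments)) || any(increments < 0))
    stop("`increments` must be finite and non-negative", call. = FALSE)
  structure(
    list(series_id = as.character(series_id),
         patch_area_m2 = as.numeric(patch_area_m2),
         trait = trait, reproductive_type = reproductive_type,
         doys = as.numeric(doys), increments = as.numeric(increments)),
    class = "trait_series")
}

#' @export
print.trait_series <- function(x, ...) {
  cat(sprintf("<trait_series> %s | %s | %s | patch %.2f m2 | %d surveys (DOY %d-%d)\n",
              x$series_id, x$trait, x$reproductive_type, x$patch_area_m2,
              length(x$doys), min(x$doys), max(x$doys)))
  invisible(x)
}

#' Fitting configuration
#'
#' @param n_starts Number of local least-squares starts; the first uses the
#'   data-driven initialisation, the rest jitter it (log-uniform within
#'   +/-25% on positive parameters).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param seed Integer seed making the jittered restarts reproducible.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 8, max_iter = 200, seed = 1L) {
  stopifnot(n_starts >= 1, max_iter >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Data-driven starting values for a growth family
#'
#' Heuristics: logistic — `A1 = 0`, `A2 = max(y)`, `x0` at the half-maximum
#' crossing, `p` from the slope of `log(y/(A2 - y))` against `log(t)` over
#' mid-range points; bihill — `Pm = max(y)`, `Ka` at the half-rise,
#' `Ki = 1.5 x` DOY of the maximum, `Ha = Hi = 4`; bidoseresp — the series
#' is split at the interior minimum of a smoothed empirical rate, `L1`/`L2`
#' are the within-segment half-rise DOYs, `P` the first segment's share of
#' the total rise, `h1 = h2 = 0.05`.
#'
#' @param series A [trait_series()].
#' @param family Model family tag.
#' @return Named numeric parameter vector satisfying the family invariants.
#' @export
initialize_params <- function(series, family) {
  family <- match_family(family)
  x <- series$doys; y <- series$increments
  if (max(y) <= 0 || stats::sd(y) == 0)
    stop("degenerate series: constant or all-zero increments", call. = FALSE)
  ymax <- max(y)
  half_rise <- function(xx, yy, lo, hi) {
    thr <- lo + 0.5 * (hi - lo)
    i <- which(yy >= thr)[1]
    if (is.na(i)) xx[length(xx)] else xx[i]
  }
  switch(family,
    logistic = {
      A2 <- ymax
      x0 <- half_rise(x, y, 0, A2)
      mid <- y > 0.2 * A2 & y < 0.8 * A2 & y > 0
      p <- 6
      if (sum(mid) >= 2) {
        A2s <- 1.05 * A2  # keep the logit finite at the top
        z <- log(y[mid] / (A2s - y[mid]))
        sl <- stats::coef(stats::lm(z ~ log(x[mid])))[2]
        if (is.finite(sl) && sl > 0) p <- sl
      }
      c(A1 = 0, A2 = A2, x0 = x0, p = min(max(p, 1), 30))
    },
    bihill = {
      c(Pm = ymax, Ka = half_rise(x, y, 0, ymax),
        Ha = 4, Ki = 1.5 * x[which.max(y)], Hi = 4)
    },
    bidoseresp = {
      # empirical rate at interval midpoints, 3-point moving average
      emp <- diff(y) / diff(x)
      mids <- (x[-1] + x[-length(x)]) / 2
      if (length(emp) >= 3)
        emp <- stats::filter(emp, rep(1 / 3, 3), sides = 2)
      emp[is.na(emp)] <- 0
      pk <- which(diff(sign(diff(emp))) < 0) + 1
      split_i <- if (length(pk) >= 2) {
        top2 <- pk[order(emp[pk], decreasing = TRUE)][1:2]
        seg <- seq(min(top2), max(top2))
        seg[which.min(emp[seg])]
      } else {
        which.min(abs(mids - stats::median(x)))
      }
      t_split <- mids[split_i]
      i_split <- findInterval(t_split, x)
      y_split <- y[i_split]
      L1 <- half_rise(x[seq_len(i_split)], y[seq_len(i_split)], y[1], y_split)
      L2 <- half_rise(x[-seq_len(i_split)], y[-seq_len(i_split)], y_split, y[length(y)])
      P <- (y_split - y[1]) / max(y[length(y)] - y[1], .Machine$double.eps)
      c(A1 = min(y), A2 = ymax, L1 = L1, L2 = max(L2, L1 + 1),
        h1 = 0.05, h2 = 0.05, P = min(max(P, 0.05), 0.95))
    }
  )
}

default_bounds <- function(series, family) {
  x <- series$doys; y <- series$increments
  span <- max(y) - min(y)
  switch(family,
    logistic = list(
      lower = c(A1 = min(y) - 0.5 * span, A2 = 0.2 * max(y),
                x0 = min(x) / 3, p = 0.5),
      upper = c(A1 = 0.5 * max(y), A2 = 3 * max(y), x0 = 3 * max(x), p = 50)),
    bihill = list(
      lower = c(Pm = 0.2 * max(y), Ka = min(x) / 3, Ha = 0.5,
                Ki = min(x) / 3, Hi = 0.5),
      upper = c(Pm = 10 * max(y), Ka = 5 * max(x), Ha = 30,
                Ki = 10 * max(x), Hi = 30)),
    bidoseresp = list(
      lower = c(A1 = min(y) - 0.5 * span, A2 = 0.2 * max(y),
                L1 = min(x) - 30, L2 = min(x), h1 = 1e-3, h2 = 1e-3, P = 0),
      upper = c(A1 = 0.5 * max(y), A2 = 3 * max(y),
                L1 = max(x), L2 = max(x) + 60, h1 = 1, h2 = 1, P = 1))
  )
}

#' Fit a growth family to a trait series
#'
#' Bounded Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]) from
#' the data-driven initialisation plus `n_starts - 1` jittered restarts; the
#' best (lowest residual sum of squares) successful start is kept. The
#' bimodal family is invariant under swapping its two phases, so a fit with
#' `L1 > L2` is relabelled (`L1`/`h1` exchanged with `L2`/`h2`, `P` mapped to
#' `1 - P`) before being returned.
#'
#' @param series A [trait_series()]; rhizome series should already be
#'   baseline-corrected.
#' @param family Model family tag (by convention: logistic for plant height,
#'   bihill for leaf area, bidoseresp for rhizome length).
#' @param config A [fit_config()].
#' @return An object of class `growth_fit` with elements `family`, `params`,
#'   `adj_r2`, `rss`, `n_obs`, `converged`, `season_window`, plus provenance
#'   (`series_id`, `trait`, `patch_area_m2`, `reproductive_type`, `seed`,
#'   `n_starts`).
#' @export
fit_series <- function(series, family, config = fit_config()) {
  family <- match_family(family)
  stopifnot(inherits(series, "trait_series"))
  x <- series$doys; y <- series$increments
  k <- length(param_names(family))
  if (length(x) < k + 2)
    stop("series too short for a ", k, "-parameter family", call. = FALSE)
  init <- initialize_params(series, family)  # errors on degenerate series
  b <- default_bounds(series, family)
  init <- pmin(pmax(init, b$lower), b$upper)

  resid_fun <- function(par) {
    pv <- stats::setNames(par, names(init))
    grow_eval(family, pv, x) - y
  }

  starts <- with_preserved_rng(config$seed, {
    s <- list(init)
    for (i in seq_len(config$n_starts - 1)) {
      jit <- init
      pos <- jit > 0 & names(jit) != "P"
      jit[pos] <- jit[pos] * exp(stats::runif(sum(pos), -1, 1) * log(1.25))
      if ("P" %in% names(jit))
        jit[["P"]] <- min(max(jit[["P"]] + stats::runif(1, -0.2, 0.2), 0), 1)
      s[[i + 1]] <- pmin(pmax(jit, b$lower), b$upper)
    }
    s
  })

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = b$lower, upper = b$upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iter)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- res$deviance
    ok <- res$info %in% 1:4 && all(is.finite(res$par))
    if (is.null(best) || (ok && !best$ok) || (ok == best$ok && rss < best$rss))
      best <- list(fit = res, rss = rss, ok = ok)
  }
  if (is.null(best))
    stop("no start converged for series ", series$series_id, call. = FALSE)

  params <- stats::setNames(unlist(best$fit$par), names(init))
  if (family == "bidoseresp" && params[["L1"]] > params[["L2"]]) {
    params <- c(A1 = params[["A1"]], A2 = params[["A2"]],
                L1 = params[["L2"]], L2 = params[["L1"]],
                h1 = params[["h2"]], h2 = params[["h1"]],
                P = 1 - params[["P"]])
  }
  tss <- sum((y - mean(y))^2)
  structure(
    list(family = family, params = params,
         adj_r2 = adjusted_r2(best$rss, tss, length(y), k),
         rss = best$rss, n_obs = length(y), converged = best$ok,
         season_window = range(x),
         series_id = series$series_id, trait = series$trait,
         patch_area_m2 = series$patch_area_m2,
         reproductive_type = series$reproductive_type,
         seed = config$seed, n_starts = config$n_starts),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s on %s (%s)\n", x$family, x$series_id, x$trait))
  cat("  params: ", paste(sprintf("%s=%.4g", names(x$params), x$params),
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  adj R2 = %.4f | RSS = %.4g | n = %d | converged: %s\n",
              x$adj_r2, x$rss, x$n_obs, x$converged))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - k - 1)` with `R^2 = 1 - rss/tss`, the
#' fit-quality statistic reported for nonlinear growth fits.
#'
#' @param rss Residual sum of squares (non-negative).
#' @param tss Total sum of squares (positive).
#' @param n_obs Number of observations; must exceed `k_params + 1`.
#' @param k_params Number of fitted parameters.
#' @return Adjusted R-squared, at most 1 (equal to 1 iff `rss = 0`).
#' @export
adjusted_r2 <- function(rss, tss, n_obs, k_params) {
  if (rss < 0 || tss <= 0) stop("need rss >= 0 and tss > 0", call. = FALSE)
  if (n_obs <= k_params + 1)
    stop("n_obs must exceed k_params + 1", call. = FALSE)
  1 - (rss / tss) * (n_obs - 1) / (n_obs - k_params - 1)
}

#' Scale a series' increments to a unit maximum
#'
#' Used for display only (growth curves of different traits on one panel);
#' fitting is always done on raw increments.
#'
#' @param series A [trait_series()] with a positive maximum increment.
#' @return The series with `increments` divided by their maximum.
#' @export
standardize_series <- function(series) {
  stopifnot(inherits(series, "trait_series"))
  m <- max(series$increments)
  if (m <= 0)
    stop("degenerate series: cannot standardize an all-zero series",
         call. = FALSE)
  series$increments <- series$increments / m
  series
}

# Run `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
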
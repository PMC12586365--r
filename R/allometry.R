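#' Pair and log-transform two trait series for allometry
#'
#' Allometric relationships are established on early-season surveys only
#' (aboveground traits stabilise after mid-July), so observations after
#' `cutoff_doy` are dropped when survey dates are supplied. Pairs in which
#' either value is zero or negative cannot be log-transformed and are
#' dropped pair-wise; the number dropped is reported.
#'
#' @param x_values,y_values Patch-mean trait values over surveys (equal
#'   length); `x` is the independent trait, `y` the dependent one.
#' @param doys Optional survey dates (DOY) used to apply the cutoff.
#' @param cutoff_doy Last DOY retained (default 196, mid-July).
#' @return A list of class `log_pairs` with `lg_x`, `lg_y` (base-10 logs),
#'   `n` and `n_dropped`.
#' @export
prepare_log_pairs <- function(x_values, y_values, doys = NULL,
                              cutoff_doy = 196) {
  if (length(x_values) != length(y_values))
    stop("x and y must have equal length", call. = FALSE)
  keep <- rep(TRUE, length(x_values))
  if (!is.null(doys)) {
    if (length(doys) != length(x_values))
      stop("doys must match the series length", call. = FALSE)
    keep <- doys <= cutoff_doy
  }
  x <- x_values[keep]; y <- y_values[keep]
  pos <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_dropped <- sum(!pos)
  x <- x[pos]; y <- y[pos]
  if (length(x) < 3)
    stop("insufficient data: fewer than 3 positive pairs before the cutoff",
         call. = FALSE)
  structure(list(lg_x = log10(x), lg_y = log10(y),
                 n = length(x), n_dropped = n_dropped),
            class = "log_pairs")
}

#' Standardized major axis (SMA) allometric fit
#'
#' Fits `lg y = lg a + b lg x` by standardized major axis: the slope is
#' `sign(r) * sd(lg y) / sd(lg x)` and the intercept passes through the
#' centroid. SMA symmetrises measurement error in both variables, the
#' appropriate line for allometry where neither trait is controlled. The
#' correlation t-test (n - 2 df) gives the significance of the fit, and
#' [test_slope()] with `B = 1` tests departure from isometry: `b > 1` means
#' the `y` trait grows proportionally faster than the `x` trait.
#'
#' @param pairs A [prepare_log_pairs()] result (or any list with numeric
#'   `lg_x`, `lg_y`).
#' @return An object of class `sma_fit` with `slope_b`, `intercept`, `r2`,
#'   `p_fit`, `r2_1`, `p_1`, `n`.
#' @export
sma_fit <- function(pairs) {
  x <- pairs$lg_x; y <- pairs$lg_y
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a coordinate", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (slope == 0) slope <- stats::sd(y) / stats::sd(x)  # r exactly 0: sign convention +
  intercept <- mean(y) - slope * mean(x)
  r2 <- r^2
  tstat <- r * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  p_fit <- 2 * stats::pt(-abs(tstat), df = n - 2)
  st <- test_slope(pairs, B = 1)
  structure(list(slope_b = slope, intercept = intercept, r2 = r2,
                 p_fit = p_fit, r2_1 = st$r2_1, p_1 = st$p_1, n = n),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("<sma_fit> lg y = %.3f + %.3f lg x  (n = %d)\n",
              x$intercept, x$slope_b, x$n))
  cat(sprintf("  R2 = %.3f (p = %.3g); slope vs 1: R2_1 = %.3f (p_1 = %.3g)\n",
              x$r2, x$p_fit, x$r2_1, x$p_1))
  invisible(x)
}

#' Test an SMA slope against a hypothesised value
#'
#' Uses the rotation trick: with scores `u = y - B x` and `v = y + B x`,
#' the SMA slope equals `B` exactly when `u` and `v` are uncorrelated, so
#' `r2_1 = cor(u, v)^2` measures departure from slope `B` and
#' `F = r2_1 (n - 2) / (1 - r2_1)` on (1, n - 2) df gives its significance.
#'
#' @inheritParams sma_fit
#' @param B Hypothesised slope (1 tests isometry).
#' @return A list with `r2_1` and `p_1`.
#' @export
test_slope <- function(pairs, B = 1) {
  x <- pairs$lg_x; y <- pairs$lg_y
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  u <- y - B * x
  v <- y + B * x
  scale <- abs(B) * stats::sd(x) + stats::sd(y)
  if (stats::sd(u) <= 1e-10 * scale || stats::sd(v) <= 1e-10 * scale)
    return(list(r2_1 = 0, p_1 = 1))  # sample slope equals B exactly
  r2_1 <- stats::cor(u, v)^2
  Fstat <- r2_1 * (n - 2) / max(1 - r2_1, .Machine$double.eps)
  list(r2_1 = r2_1,
       p_1 = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE))
}

#' Trait-pair ratios of maximum growth increments
#'
#' Resource-allocation ratios between trait pairs, one per patch: leaf area
#' to plant height (`LA-PH`), rhizome length to leaf area (`RL-LA`) and
#' rhizome length to plant height (`RL-PH`), each computed from the
#' patch-mean maximum growth increments. In the `"Y-X"` labels the first
#' trait is the numerator (dependent) trait.
#'
#' @param summaries Data frame with columns `patch_area_m2`, `trait` and
#'   `W_max` (patch-mean maximum growth increment).
#' @return Data frame with columns `pair`, `patch_area_m2`, `ratio`.
#'   Patches missing one trait of a pair are skipped with a warning.
#' @export
increment_ratios <- function(summaries) {
  stopifnot(all(c("patch_area_m2", "trait", "W_max") %in% names(summaries)))
  pairs <- list(`LA-PH` = c("leaf_area", "plant_height"),
                `RL-LA` = c("rhizome_length", "leaf_area"),
                `RL-PH` = c("rhizome_length", "plant_height"))
  out <- list()
  for (area in unique(summaries$patch_area_m2)) {
    sub <- summaries[summaries$patch_area_m2 == area, , drop = FALSE]
    for (nm in names(pairs)) {
      num <- sub$W_max[sub$trait == pairs[[nm]][1]]
      den <- sub$W_max[sub$trait == pairs[[nm]][2]]
      if (length(num) != 1 || length(den) != 1) {
        warning(sprintf("patch %.2f m2: missing trait for pair %s; skipped",
                        area, nm), call. = FALSE)
        next
      }
      out[[length(out) + 1]] <- data.frame(
        pair = nm, patch_area_m2 = area, ratio = num / den,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pair = character(0), patch_area_m2 = numeric(0),
                      ratio = numeric(0)))
  do.call(rbind, out)
}
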
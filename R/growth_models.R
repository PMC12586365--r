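#' Growth model families
#'
#' Three nonlinear families describe one season of cumulative trait growth:
#'
#' * `"logistic"` — power logistic in day of year (DOY),
#'   `y = A2 + (A1 - A2) / (1 + (t/x0)^p)`, used for unimodal plant-height
#'   increments. Parameters: `A1` (initial asymptote), `A2` (final
#'   asymptote), `x0` (center, DOY), `p` (power).
#' * `"bihill"` — product of an activating and an inhibitory Hill term,
#'   `y = Pm / ((1 + (Ka/t)^Ha) * (1 + (t/Ki)^Hi))`, a rise followed by a
#'   plateau/decline, used for leaf-area increments. Parameters: `Pm`
#'   (maximum), `Ka`/`Ha` (half-maximal activating DOY, Hill coefficient),
#'   `Ki`/`Hi` (half-maximal inhibitory DOY, Hill coefficient).
#' * `"bidoseresp"` — mixture of two base-10 sigmoids,
#'   `y = A1 + (A2 - A1) * (P / (1 + 10^((L1 - t) h1)) +
#'   (1 - P) / (1 + 10^((L2 - t) h2)))`, a bimodal rise with two rate
#'   peaks, used for rhizome-length increments. Parameters: `A1` (bottom),
#'   `A2` (top), `L1`/`L2` (half-rise locations, DOY), `h1`/`h2` (slopes,
#'   per day), `P` (proportion of phase 1 in the total rise).
#'
#' All three are evaluated on the DOY axis directly. `grow_eval()` returns
#' the curve, `grow_rate()` its analytic first time-derivative (the growth
#' rate, trait units per day) and `grow_accel()` the analytic second
#' derivative used to locate the onset and end of rapid growth.
#'
#' @param family One of `"logistic"`, `"bihill"`, `"bidoseresp"`.
#' @param params Named numeric vector of parameters for `family` (see
#'   Details).
#' @param t Numeric vector of times (DOY). Must be strictly positive for
#'   `"bihill"` and non-negative for `"logistic"`.
#' @return Numeric vector, same length as `t`.
#' @examples
#' grow_eval("logistic", c(A1 = 0, A2 = 100, x0 = 110, p = 8), 110)  # 50
#' grow_rate("logistic", c(A1 = 0, A2 = 100, x0 = 110, p = 8), 110)  # 800/440
#' @export
grow_eval <- function(family, params, t) {
  family <- match_family(family)
  check_params(family, params)
  check_domain(family, t)
  switch(family,
    logistic = {
      u <- (t / params[["x0"]])^params[["p"]]
      params[["A2"]] + (params[["A1"]] - params[["A2"]]) / (1 + u)
    },
    bihill = {
      a <- (params[["Ka"]] / t)^params[["Ha"]]
      b <- (t / params[["Ki"]])^params[["Hi"]]
      params[["Pm"]] / ((1 + a) * (1 + b))
    },
    bidoseresp = {
      s1 <- sigmoid10((t - params[["L1"]]) * params[["h1"]])
      s2 <- sigmoid10((t - params[["L2"]]) * params[["h2"]])
      dA <- params[["A2"]] - params[["A1"]]
      params[["A1"]] + dA * (params[["P"]] * s1 + (1 - params[["P"]]) * s2)
    }
  )
}

#' @rdname grow_eval
#' @export
grow_rate <- function(family, params, t) {
  family <- match_family(family)
  check_params(family, params)
  check_domain(family, t)
  switch(family,
    logistic = {
      p <- params[["p"]]
      u <- (t / params[["x0"]])^p
      r <- (params[["A2"]] - params[["A1"]]) * p * u / (t * (1 + u)^2)
      # limit at t = 0 is 0 for p > 1
      r[t == 0] <- if (p > 1) 0 else NaN
      r
    },
    bihill = {
      a <- (params[["Ka"]] / t)^params[["Ha"]]
      b <- (t / params[["Ki"]])^params[["Hi"]]
      da <- -params[["Ha"]] * a / t
      db <- params[["Hi"]] * b / t
      D <- (1 + a) * (1 + b)
      dD <- da * (1 + b) + db * (1 + a)
      -params[["Pm"]] * dD / D^2
    },
    bidoseresp = {
      s1 <- sigmoid10((t - params[["L1"]]) * params[["h1"]])
      s2 <- sigmoid10((t - params[["L2"]]) * params[["h2"]])
      dA <- params[["A2"]] - params[["A1"]]
      ln10 <- log(10)
      dA * (params[["P"]] * ln10 * params[["h1"]] * s1 * (1 - s1) +
        (1 - params[["P"]]) * ln10 * params[["h2"]] * s2 * (1 - s2))
    }
  )
}

#' @rdname grow_eval
#' @export
grow_accel <- function(family, params, t) {
  family <- match_family(family)
  check_params(family, params)
  check_domain(family, t)
  switch(family,
    logistic = {
      p <- params[["p"]]
      u <- (t / params[["x0"]])^p
      a <- (params[["A2"]] - params[["A1"]]) * p * u *
        ((p - 1) - (p + 1) * u) / (t^2 * (1 + u)^3)
      a[t == 0] <- if (p > 2) 0 else NaN
      a
    },
    bihill = {
      a <- (params[["Ka"]] / t)^params[["Ha"]]
      b <- (t / params[["Ki"]])^params[["Hi"]]
      Ha <- params[["Ha"]]; Hi <- params[["Hi"]]
      da <- -Ha * a / t
      db <- Hi * b / t
      d2a <- Ha * (Ha + 1) * a / t^2
      d2b <- Hi * (Hi - 1) * b / t^2
      D <- (1 + a) * (1 + b)
      dD <- da * (1 + b) + db * (1 + a)
      d2D <- d2a * (1 + b) + 2 * da * db + d2b * (1 + a)
      params[["Pm"]] * (2 * dD^2 - d2D * D) / D^3
    },
    bidoseresp = {
      s1 <- sigmoid10((t - params[["L1"]]) * params[["h1"]])
      s2 <- sigmoid10((t - params[["L2"]]) * params[["h2"]])
      dA <- params[["A2"]] - params[["A1"]]
      c1 <- (log(10) * params[["h1"]])^2
      c2 <- (log(10) * params[["h2"]])^2
      dA * (params[["P"]] * c1 * s1 * (1 - s1) * (1 - 2 * s1) +
        (1 - params[["P"]]) * c2 * s2 * (1 - s2) * (1 - 2 * s2))
    }
  )
}

#' Locate the local extrema of the growth rate
#'
#' Scans the rate curve on a fine grid over `window` and refines every
#' interior local maximum and minimum with [stats::optimize()]. For the
#' logistic and BiHill families the rate is unimodal (one maximum); a
#' two-component `bidoseresp` fit with well-separated phases yields two
#' maxima separated by one interior minimum — the signature of bimodal
#' rhizome growth.
#'
#' @inheritParams grow_eval
#' @param window Numeric length-2 vector, the DOY interval to search.
#' @param grid_step Grid resolution in days for bracketing extrema.
#' @return A data frame with columns `time`, `rate` and `type`
#'   (`"max"`/`"min"`), ordered by time. Zero rows if the rate is monotone
#'   on the window.
#' @export
rate_extrema <- function(family, params, window, grid_step = 0.1) {
  family <- match_family(family)
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2])
    stop("`window` must be a finite increasing interval", call. = FALSE)
  check_domain(family, window)
  grid <- seq(window[1], window[2], by = grid_step)
  if (length(grid) < 3) stop("window too narrow for the grid step", call. = FALSE)
  r <- grow_rate(family, params, grid)
  d <- diff(r)
  # interior indices where the discrete slope changes sign
  s <- sign(d)
  idx <- which(s[-1] * s[-length(s)] < 0) + 1
  if (!length(idx)) {
    return(data.frame(time = numeric(0), rate = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(idx, function(i) {
    lo <- grid[i - 1]; hi <- grid[i + 1]
    maximum <- d[i - 1] > 0
    opt <- stats::optimize(function(x) grow_rate(family, params, x),
                           interval = c(lo, hi), maximum = maximum,
                           tol = 1e-8)
    data.frame(time = if (maximum) opt$maximum else opt$minimum,
               rate = opt$objective,
               type = if (maximum) "max" else "min",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$time), , drop = FALSE]
}

# ---- internal helpers -------------------------------------------------------

match_family <- function(family) {
  match.arg(family, c("logistic", "bihill", "bidoseresp"))
}

param_names <- function(family) {
  switch(family,
    logistic = c("A1", "A2", "x0", "p"),
    bihill = c("Pm", "Ka", "Ha", "Ki", "Hi"),
    bidoseresp = c("A1", "A2", "L1", "L2", "h1", "h2", "P")
  )
}

check_params <- function(family, params) {
  need <- param_names(family)
  if (!is.numeric(params) || !all(need %in% names(params)))
    stop(sprintf("'%s' parameters must be a named numeric vector with %s",
                 family, paste(need, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(params[need])))
    stop("all parameters must be finite", call. = FALSE)
  bad <- switch(family,
    logistic = params[["x0"]] <= 0 || params[["p"]] <= 0,
    bihill = any(params[need] <= 0),
    bidoseresp = params[["h1"]] <= 0 || params[["h2"]] <= 0 ||
      params[["P"]] < 0 || params[["P"]] > 1
  )
  if (bad) stop(sprintf("invalid '%s' parameters", family), call. = FALSE)
  invisible(TRUE)
}

check_domain <- function(family, t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  if (family == "bihill" && any(t <= 0))
    stop("bihill is undefined at t <= 0 (Ka/t term)", call. = FALSE)
  if (family == "logistic" && any(t < 0))
    stop("logistic power term is undefined for t < 0", call. = FALSE)
  invisible(TRUE)
}

# 1 / (1 + 10^(-z)), numerically stable in both tails
sigmoid10 <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + 10^(-z[pos]))
  e <- 10^(z[!pos])
  out[!pos] <- e / (1 + e)
  out
}
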
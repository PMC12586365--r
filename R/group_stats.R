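#' Brown-Forsythe test of variance homogeneity
#'
#' Median-centred Levene test (via [car::leveneTest()]), robust to
#' non-normal growth parameters. Its p-value decides between the classic
#' ANOVA + LSD route (homogeneous variances) and the Welch ANOVA +
#' Games-Howell route.
#'
#' @param values Numeric response.
#' @param groups Group labels, same length.
#' @return The homogeneity p-value.
#' @export
variance_homogeneity <- function(values, groups) {
  groups <- factor(groups)
  check_groups(values, groups)
  if (all(tapply(values, groups, stats::sd) == 0)) return(1)
  res <- car::leveneTest(values ~ groups, center = stats::median)
  res[["Pr(>F)"]][1]
}

#' One-way ANOVA F test, classic or Welch
#'
#' @inheritParams variance_homogeneity
#' @param welch If `TRUE`, use Welch's heteroscedastic F
#'   (no pooled-variance assumption).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
oneway_f <- function(values, groups, welch = FALSE) {
  groups <- factor(groups)
  check_groups(values, groups)
  k <- nlevels(groups)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  if (all(vars == 0)) {
    # degenerate: no within-group variability
    if (max(means) - min(means) == 0)
      return(list(F = 0, df1 = k - 1, df2 = length(values) - k, p = 1))
    return(list(F = Inf, df1 = k - 1, df2 = length(values) - k, p = 0))
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = !welch)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = unname(ht$p.value))
}

#' Pairwise post hoc comparisons with a compact letter display
#'
#' `"lsd"` performs Fisher's LSD: pooled-variance pairwise t tests using the
#' ANOVA mean squared error and its residual degrees of freedom. The
#' `"games_howell"` method drops the pooled-variance assumption: pairwise
#' Welch-Satterthwaite statistics referred to the studentized-range
#' distribution, the standard companion to a significant Welch F. Letters
#' are assigned by insert-and-absorb, starting from `"a"` at the largest
#' group mean; groups sharing a letter do not differ at `alpha`.
#'
#' @inheritParams variance_homogeneity
#' @param method `"lsd"` or `"games_howell"`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `p_matrix` (symmetric pairwise p-values), `letters`
#'   (named character vector) and `means`.
#' @export
posthoc_letters <- function(values, groups, method = c("lsd", "games_howell"),
                            alpha = 0.05) {
  method <- match.arg(method)
  groups <- factor(groups)
  check_groups(values, groups)
  lev <- levels(groups)
  k <- length(lev)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  N <- length(values)

  p_mat <- matrix(1, k, k, dimnames = list(lev, lev))
  if (method == "lsd") {
    mse <- sum((n - 1) * v) / (N - k)
    df <- N - k
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
      p <- if (se == 0) as.numeric(m[i] != m[j]) * 0 + (m[i] == m[j]) else
        2 * stats::pt(-abs(m[i] - m[j]) / se, df)
      p_mat[i, j] <- p_mat[j, i] <- p
    }
  } else {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      se2 <- v[i] / n[i] + v[j] / n[j]
      if (se2 == 0) {
        p <- as.numeric(m[i] == m[j])
      } else {
        q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
        df <- se2^2 / (v[i]^2 / (n[i]^2 * (n[i] - 1)) +
                       v[j]^2 / (n[j]^2 * (n[j] - 1)))
        p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      }
      p_mat[i, j] <- p_mat[j, i] <- p
    }
  }

  letters <- letter_display(p_mat, m, alpha)
  list(p_matrix = p_mat, letters = letters, means = m)
}

#' Full group-comparison stage for one growth parameter
#'
#' Runs the homogeneity check, picks classic ANOVA + LSD when variances are
#' homogeneous (`homogeneity_p > 0.05`) and Welch ANOVA + Games-Howell
#' otherwise, and builds the compact letter display. Groups with fewer than
#' 3 observations are flagged low-power rather than suppressed, and
#' `0.05 < p < marginal` is reported as marginal significance.
#'
#' @inheritParams variance_homogeneity
#' @param parameter Name of the growth parameter being compared (label).
#' @param alpha Significance level (default 0.05).
#' @param marginal Upper bound of the marginal-significance band (default
#'   0.10).
#' @return An object of class `group_comparison`.
#' @export
group_comparison <- function(values, groups, parameter = "parameter",
                             alpha = 0.05, marginal = 0.10) {
  groups <- factor(groups)
  check_groups(values, groups)
  hp <- variance_homogeneity(values, groups)
  welch <- hp <= alpha
  ov <- oneway_f(values, groups, welch = welch)
  ph <- posthoc_letters(values, groups,
                        method = if (welch) "games_howell" else "lsd",
                        alpha = alpha)
  n <- tapply(values, groups, length)
  structure(
    list(parameter = parameter, groups = levels(groups),
         n_per_group = as.integer(n),
         means = as.numeric(ph$means),
         sds = as.numeric(tapply(values, groups, stats::sd)),
         homogeneity_p = hp,
         method = if (welch) "welch+games_howell" else "classic_anova+LSD",
         F = ov$F, df1 = ov$df1, df2 = ov$df2, p = ov$p,
         significant = ov$p <= alpha,
         marginal = ov$p > alpha && ov$p < marginal,
         low_power = any(n < 3),
         letters = ph$letters, p_matrix = ph$p_matrix),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s [%s]\n", x$parameter, x$method))
  for (i in seq_along(x$groups))
    cat(sprintf("  %-16s %6.2f +/- %.2f %s (n=%d)\n", x$groups[i],
                x$means[i], x$sds[i], x$letters[i], x$n_per_group[i]))
  cat(sprintf("  F = %.3f (df %g, %.1f), p = %.4g%s%s\n", x$F, x$df1, x$df2,
              x$p, if (x$significant) " *" else "",
              if (x$marginal) " (marginal)" else ""))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

check_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  invisible(TRUE)
}

# Insert-and-absorb compact letter display. `p_mat` is a symmetric pairwise
# p-value matrix; letters are ordered "a", "b", ... starting from the group
# with the largest mean.
letter_display <- function(p_mat, means, alpha = 0.05) {
  lev <- rownames(p_mat)
  ord <- order(means, decreasing = TRUE)
  sets <- list(seq_along(lev))  # start: everyone shares one letter
  for (a in seq_len(length(lev) - 1)) for (b in seq(a + 1, length(lev))) {
    i <- ord[a]; j <- ord[b]
    if (p_mat[i, j] > alpha) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    new_sets <- unique(lapply(new_sets, sort))
    new_sets <- new_sets[lengths(new_sets) > 0]
    # absorb: drop sets strictly contained in another
    keep <- vapply(seq_along(new_sets), function(u) {
      !any(vapply(seq_along(new_sets), function(w) {
        w != u && all(new_sets[[u]] %in% new_sets[[w]]) &&
          length(new_sets[[w]]) > length(new_sets[[u]])
      }, logical(1)))
    }, logical(1))
    sets <- new_sets[keep]
  }
  # order sets by the best-ranked (largest-mean) member so "a" goes with
  # the largest mean
  rank_of <- function(s) min(match(s, ord))
  sets <- sets[order(vapply(sets, rank_of, numeric(1)))]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (si in seq_along(sets))
    for (g in sets[[si]]) out[g] <- paste0(out[g], letters[si])
  out
}
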
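test_that("Brown-Forsythe homogeneity matches hand-computed arithmetic", {
  # two groups {1,2,3}, {4,5,6}: absolute deviations from group medians are
  # identical across groups, so the one-way F on them is exactly 0
  v <- c(1, 2, 3, 4, 5, 6); g <- rep(c("a", "b"), each = 3)
  z <- abs(v - ave(v, g, FUN = median))
  Fz <- anova(lm(z ~ factor(g)))$`F value`[1]
  expect_equal(Fz, 0)
  expect_equal(variance_homogeneity(v, g), 1)

  # degenerate equal-spread groups
  expect_equal(variance_homogeneity(c(5, 5, 9, 9), rep(c("a", "b"), each = 2)), 1)
  expect_error(variance_homogeneity(c(1, 2, 3), c("a", "a", "b")),
               "at least 2")

  # widening one group's spread drives the p-value down
  set.seed(13)
  base <- rnorm(20); wide <- rnorm(20)
  g2 <- rep(c("a", "b"), each = 20)
  p_equal <- variance_homogeneity(c(base, wide), g2)
  p_wide <- variance_homogeneity(c(base, wide * 10), g2)
  expect_lt(p_wide, p_equal)
  expect_lt(p_wide, 0.001)
})

test_that("classic F equals the pooled t-squared for two groups", {
  set.seed(9)
  v <- c(rnorm(8, 0), rnorm(8, 1)); g <- rep(c("a", "b"), each = 8)
  f <- oneway_f(v, g, welch = FALSE)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(f$p, tt$p.value, tolerance = 1e-10)
  # identical groups: F = 0, p = 1
  f0 <- oneway_f(rep(c(3, 3, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(f0$F, 0)
  expect_equal(f0$p, 1)
})

test_that("Welch F coincides with classic F for two balanced equal-variance groups", {
  # for k = 2 the Welch denominator correction vanishes, so with equal n
  # and equal sample variances the two statistics are numerically identical
  # (for k > 2 Welch's F carries a 1 + 1/(3(n-1)) style correction even
  # under homoscedasticity, so only the two-group identity is exact)
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  g <- rep(c("a", "b"), each = 4)
  expect_equal(var(v[1:4]), var(v[5:8]))  # construction check
  expect_equal(oneway_f(v, g, welch = TRUE)$F,
               oneway_f(v, g, welch = FALSE)$F, tolerance = 1e-10)
})

test_that("LSD pairwise p equals the pooled-MSE t-test closed form", {
  set.seed(14)
  v <- c(rnorm(6, 0), rnorm(6, 2), rnorm(6, 4))
  g <- rep(c("a", "b", "c"), each = 6)
  ph <- posthoc_letters(v, g, method = "lsd")
  mse <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (18 - 3)
  m <- tapply(v, g, mean)
  t_ab <- (m["a"] - m["b"]) / sqrt(mse * (1 / 6 + 1 / 6))
  expect_equal(ph$p_matrix["a", "b"], 2 * pt(-abs(t_ab), df = 15),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("compact letters partition consistently with the pairwise tests", {
  # well-separated means with tiny variance: all letters distinct,
  # "a" on the largest mean
  v <- c(0, 0.1, 10, 10.1, 20, 20.1)
  g <- rep(c("g1", "g2", "g3"), each = 2)
  ph <- posthoc_letters(v, g, method = "lsd")
  expect_equal(unname(ph$letters[c("g3", "g2", "g1")]), c("a", "b", "c"))
  # all groups equal: one shared letter
  ph0 <- posthoc_letters(rep(c(1, 2), 3), rep(c("x", "y", "z"), each = 2),
                         method = "games_howell")
  expect_true(all(ph0$letters == "a"))
  # random data: letters share a character iff the pair is non-significant
  set.seed(15)
  for (rep in 1:10) {
    vv <- rnorm(24, rep(sample(0:3, 4), each = 6), 1.5)
    gg <- rep(paste0("g", 1:4), each = 6)
    res <- posthoc_letters(vv, gg, method = sample(c("lsd", "games_howell"), 1))
    for (i in 1:3) for (j in (i + 1):4) {
      share <- any(strsplit(res$letters[i], "")[[1]] %in%
                     strsplit(res$letters[j], "")[[1]])
      expect_identical(share, res$p_matrix[i, j] > 0.05)
    }
  }
})

test_that("group_comparison routes by homogeneity and flags marginal cases", {
  set.seed(16)
  hom <- c(rnorm(8, 0, 1), rnorm(8, 3, 1))
  het <- c(rnorm(8, 0, 0.2), rnorm(8, 3, 4))
  g <- rep(c("a", "b"), each = 8)
  gc_hom <- group_comparison(hom, g)
  gc_het <- group_comparison(het, g)
  expect_equal(gc_hom$method, "classic_anova+LSD")
  expect_equal(gc_het$method, "welch+games_howell")
  expect_true(gc_het$homogeneity_p <= 0.05)
  # two-observation groups are flagged low-power, not dropped
  gc_lp <- group_comparison(c(1, 2, 5, 6, 7), c("m", "m", "b", "b", "b"))
  expect_true(gc_lp$low_power)
})

test_that("null type-I error is calibrated for both ANOVA variants", {
  set.seed(18)
  n_rep <- 800
  rej <- matrix(FALSE, n_rep, 2)
  g <- rep(c("a", "b", "c"), each = 8)
  for (r in seq_len(n_rep)) {
    v <- rnorm(24)
    rej[r, 1] <- oneway_f(v, g, welch = FALSE)$p <= 0.05
    rej[r, 2] <- oneway_f(v, g, welch = TRUE)$p <= 0.05
  }
  # 800 reps: MC sd ~ 0.0077, allow ~3 sd
  expect_lt(abs(mean(rej[, 1]) - 0.05), 0.025)
  expect_lt(abs(mean(rej[, 2]) - 0.05), 0.025)
})
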
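fit_from_true <- function(family, params, doys, trait = "plant_height") {
  fit_series(sim_series(family, params, doys, 0, trait), family)
}

test_that("extraction agrees with dense-grid brute force for all families", {
  cases <- list(
    list(fam = "logistic", par = c(A1 = 0, A2 = 100, x0 = 110, p = 8),
         win = c(60, 330)),
    list(fam = "bihill", par = c(Pm = 249, Ka = 140, Ha = 6, Ki = 320,
                                 Hi = 8), win = c(60, 330)),
    list(fam = "bidoseresp",
         par = c(A1 = 0, A2 = 200, L1 = 162, L2 = 256, h1 = 0.05,
                 h2 = 0.08, P = 0.6), win = c(56, 349)))
  for (cs in cases) {
    doys <- seq(cs$win[1], cs$win[2], by = 5)
    trait <- c(logistic = "plant_height", bihill = "leaf_area",
               bidoseresp = "rhizome_length")[[cs$fam]]
    fit <- fit_from_true(cs$fam, cs$par, doys, trait)
    ph <- suppressWarnings(
      extract_phenology(fit, extraction_config(season_window = cs$win)))
    bf <- brute_phenology(cs$fam, cs$par, cs$win)
    for (nm in c("D_o", "D_r", "D_vmax", "D_st", "D_t"))
      expect_lt(abs(ph[[nm]] - bf[[nm]]), 0.1 + 0.01,
                label = sprintf("%s %s", cs$fam, nm))
    expect_equal(ph$W_max, bf$W_max, tolerance = 1e-4)
    expect_equal(ph$V_max, bf$V_max, tolerance = 1e-4)
    if (isTRUE(bf$bimodal)) {
      expect_true(ph$bimodal)
      for (nm in c("D_r2", "D_vmax2", "D_st2"))
        expect_lt(abs(ph[[nm]] - bf[[nm]]), 0.1 + 0.01)
    }
  }
})

test_that("logistic inflection dates are near-symmetric about the rate peak", {
  fit <- fit_from_true("logistic", c(A1 = 0, A2 = 100, x0 = 110, p = 8),
                       seq(60, 330, by = 5))
  ph <- extract_phenology(fit, extraction_config(season_window = c(60, 330)))
  # the inflection-based rapid-growth window is near-symmetric about the
  # rate peak for a steep power logistic (the signature visible in the
  # published plant-height dates)
  expect_lt(abs((ph$D_vmax - ph$D_r) - (ph$D_st - ph$D_vmax)), 1)
})

test_that("bimodal rhizome extraction recovers both published peak dates", {
  par <- c(A1 = 0, A2 = 200, L1 = 162, L2 = 256, h1 = 0.05, h2 = 0.08,
           P = 0.6)
  fit <- fit_from_true("bidoseresp", par, doys_rhizome(), "rhizome_length")
  ph <- extract_phenology(fit, extraction_config(season_window = c(56, 349)))
  expect_true(ph$bimodal)
  expect_lt(abs(ph$D_vmax - 162), 2)
  expect_lt(abs(ph$D_vmax2 - 256), 2)
  expect_true(ph$D_st < ph$D_r2 && ph$D_r2 < ph$D_vmax2 &&
                ph$D_vmax2 < ph$D_st2 && ph$D_st2 <= ph$D_t)
  expect_equal(ph$GD_sl2, ph$D_r2 - ph$D_st)
  expect_equal(ph$GD_r2, ph$D_st2 - ph$D_r2)
  expect_equal(ph$GD_st, ph$D_t - ph$D_st2)
})

test_that("date ordering and duration identities hold over random draws", {
  set.seed(3)
  for (rep in 1:25) {
    fam <- sample(c("logistic", "bihill", "bidoseresp"), 1)
    par <- rand_params(fam)
    win <- if (fam == "bihill") c(60, 330) else c(56, 349)
    doys <- seq(win[1], win[2], by = if (fam == "bidoseresp") 10 else 5)
    trait <- c(logistic = "plant_height", bihill = "leaf_area",
               bidoseresp = "rhizome_length")[[fam]]
    ph <- tryCatch(suppressWarnings(extract_phenology(
      fit_from_true(fam, par, doys, trait),
      extraction_config(season_window = win))), error = function(e) NULL)
    if (is.null(ph)) next  # a draw whose thresholds fall outside the window
    expect_true(ph$D_o < ph$D_r && ph$D_r < ph$D_vmax &&
                  ph$D_vmax < ph$D_st && ph$D_st <= ph$D_t)
    expect_equal(ph$GD_sl, ph$D_r - ph$D_o)
    expect_equal(ph$GD_r, ph$D_st - ph$D_r)
    expect_equal(ph$GD, ph$D_t - ph$D_o)
    if (!ph$bimodal)
      expect_equal(ph$GD_sl + ph$GD_r + ph$GD_st, ph$GD, tolerance = 1e-8)
    expect_equal(ph$V_mean, ph$W_max / ph$GD)
  }
})

test_that("derive_periods reproduces duration arithmetic from mean dates", {
  # leaf-area population mean dates
  la <- derive_periods(list(D_o = 86, D_r = 122, D_st = 161, D_t = 209))
  expect_equal(la$GD_sl, 36)
  expect_equal(la$GD_r, 39)
  expect_equal(la$GD_st, 48)
  expect_equal(la$GD, 123)
  # rhizome population mean dates
  rl <- derive_periods(list(D_o = 77, D_r = 141, D_st = 182, D_t = 316))
  expect_equal(rl$GD, 239)
  expect_equal(rl$GD_sl, 64)
  expect_error(derive_periods(list(D_o = 1, D_r = 2)), "populated")
})

test_that("threshold monotonicity: later thresholds give later dates", {
  fit <- fit_from_true("logistic", c(A1 = 0, A2 = 100, x0 = 110, p = 8),
                       seq(60, 330, by = 5))
  win <- c(60, 330)
  base <- extract_phenology(fit, extraction_config(season_window = win))
  hi_t <- extract_phenology(fit, extraction_config(theta_t = 0.99,
                                                   season_window = win))
  hi_o <- extract_phenology(fit, extraction_config(theta_o = 0.10,
                                                   season_window = win))
  expect_gte(hi_t$D_t, base$D_t)
  expect_gte(hi_o$D_o, base$D_o)
})

test_that("round-trip simulate-fit-extract recovers the rate-peak date", {
  set.seed(17)
  par <- c(A1 = 0, A2 = 100, x0 = 110, p = 8)
  truth <- brute_phenology("logistic", par, c(60, 330), step = 0.01)
  for (rep in 1:3) {
    s <- sim_series("logistic", par, doys_aboveground(), sigma = 2)
    ph <- extract_phenology(fit_series(s, "logistic"),
                            extraction_config(season_window = c(60, 330)))
    expect_lt(abs(ph$D_vmax - truth$D_vmax), 3)
  }
})

test_that("mean growth rate identities and contracts", {
  expect_equal(mean_growth_rate(76, 73), 76 / 73)
  expect_equal(round(mean_growth_rate(76, 73), 1), 1.0)
  expect_equal(mean_growth_rate(0, 10), 0)
  expect_equal(mean_growth_rate(2 * 76, 73), 2 * mean_growth_rate(76, 73))
  expect_error(mean_growth_rate(10, 0), "positive")
  ec <- extraction_config
  expect_error(ec(theta_o = 0.5, theta_t = 0.4), "theta")
})

test_that("non-converged fits are refused", {
  fit <- fit_from_true("logistic", c(A1 = 0, A2 = 100, x0 = 110, p = 8),
                       seq(60, 330, by = 5))
  fit$converged <- FALSE
  expect_error(extract_phenology(fit), "converged")
})
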
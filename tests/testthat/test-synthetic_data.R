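test_that("survey schedules reproduce the field calendar", {
  rh <- survey_schedule("2021-02-25", "2021-12-15", 10)
  expect_length(rh, 30)
  expect_equal(rh[1], 56L)        # Feb 25 = 31 + 25
  expect_equal(diff(rh), rep(10L, 29))
  ag <- survey_schedule("2021-03-25", "2021-11-05", 5)
  expect_equal(ag[1], 84L)        # Mar 25 = 31 + 28 + 25
  expect_length(ag, 46)           # inclusive rule
  expect_length(survey_schedule("2021-03-25", "2021-03-25", 5), 1)
  expect_error(survey_schedule("2021-05-01", "2021-04-01", 5), "after")
})

test_that("cluster parameter draws are seeded and centered on the means", {
  cc <- campaign_config()
  set.seed(42); a <- draw_cluster_params(cc, 3, "leaf_area", "asexual")
  set.seed(42); b <- draw_cluster_params(cc, 3, "leaf_area", "asexual")
  expect_identical(a, b)
  expect_error(draw_cluster_params(cc, 1, "stem_width"), "unknown trait")

  set.seed(43)
  mu <- cc$trait_mean_params$leaf_area[[3]][["Pm"]]
  draws <- replicate(10000,
    draw_cluster_params(cc, 3, "leaf_area", "asexual")[["Pm"]])
  expect_lt(abs(mean(draws) - mu) / mu, 0.02)
  expect_lt(abs(sd(draws) / mean(draws) - cc$between_cluster_cv), 0.02)

  # sexual clusters scale the aboveground asymptote and advance the center
  set.seed(44)
  sex <- replicate(2000,
    draw_cluster_params(cc, 5, "leaf_area", "sexual")[["Pm"]])
  set.seed(45)
  asex <- replicate(2000,
    draw_cluster_params(cc, 5, "leaf_area", "asexual")[["Pm"]])
  expect_lt(abs(mean(sex) / mean(asex) - cc$sexual_Wmax_multiplier_leaf), 0.1)
})

test_that("campaign table has the designed shape and determinism", {
  cc <- campaign_config(seed = 6)
  camp <- simulate_campaign(cc)
  n_ag_series <- sum(cc$asexual_clusters_per_patch) +
    cc$sexual_clusters_largest_patch
  expected_rows <- n_ag_series * 2 * 46 + sum(cc$rhizomes_per_patch) * 30
  expect_equal(nrow(camp), expected_rows)
  expect_setequal(unique(camp$trait),
                  c("plant_height", "leaf_area", "rhizome_length"))
  # sexual clusters only in the largest patch
  sex <- camp[camp$type == "sexual", ]
  expect_true(all(sex$patch_area_m2 == max(cc$patch_areas_m2)))
  # all randomness flows from the seed
  camp2 <- simulate_campaign(campaign_config(seed = 6))
  expect_identical(camp, camp2)
  expect_false(identical(camp$value,
                         simulate_campaign(campaign_config(seed = 7))$value))
})

test_that("noiseless aboveground series start near zero; rhizomes are monotone", {
  cc <- campaign_config(noise_sd_fraction = 0, seed = 8)
  camp <- simulate_campaign(cc)
  first_ag <- camp[camp$doy == 84 & camp$trait != "rhizome_length", ]
  max_ag <- aggregate(value ~ series_id + trait,
                      camp[camp$trait != "rhizome_length", ], max)
  key <- paste(first_ag$series_id, first_ag$trait)
  mkey <- paste(max_ag$series_id, max_ag$trait)
  # "near zero": early-centered (sexual, jittered) clusters can reach ~20%
  # of their seasonal maximum by the first survey
  expect_true(all(first_ag$value <=
                    0.25 * max_ag$value[match(key, mkey)]))
  expect_lt(median(first_ag$value / max_ag$value[match(key, mkey)]), 0.12)
  rh <- camp[camp$trait == "rhizome_length", ]
  for (sid in unique(rh$series_id)) {
    v <- rh$value[rh$series_id == sid]
    expect_true(all(diff(v) >= -1e-9))
    expect_gt(v[1], 0)  # positive pre-season baseline
  }
})

test_that("refitting a noiseless campaign recovers the generator parameters", {
  cc <- campaign_config(noise_sd_fraction = 0, seed = 9)
  camp <- simulate_campaign(cc)
  gp <- attr(camp, "generator_params")
  fam <- c(plant_height = "logistic", leaf_area = "bihill",
           rhizome_length = "bidoseresp")
  picks <- c("P1_C01 plant_height", "P3_C01 leaf_area",
             "P5_R01 rhizome_length")
  for (nm in picks) {
    parts <- strsplit(nm, " ")[[1]]
    sub <- camp[camp$series_id == parts[1] & camp$trait == parts[2], ]
    vals <- sub$value
    # subtract the known baseline (not the first measurement, which already
    # contains a little early growth) so recovery is checked against the
    # exact generator curve
    if (parts[2] == "rhizome_length")
      vals <- vals - gp[[nm]][["baseline"]]
    s <- trait_series(parts[1], sub$patch_area_m2[1], parts[2],
                      sub$type[1], sub$doy, vals)
    f <- fit_series(s, fam[[parts[2]]])
    tru <- gp[[nm]]
    for (pn in setdiff(names(f$params), c("A1")))
      expect_lt(abs(f$params[[pn]] - tru[[pn]]) / abs(tru[[pn]]), 1e-3,
                label = paste(nm, pn))
  }
})

test_that("noisy campaign keeps the rhizome phase-1 peak near the generator's", {
  cc <- campaign_config(seed = 10)  # default 2% noise
  camp <- simulate_campaign(cc)
  gp <- attr(camp, "generator_params")
  rh <- camp[camp$trait == "rhizome_length" & camp$patch_area_m2 == 201.11, ]
  dvmax <- c(); l1 <- c()
  for (sid in unique(rh$series_id)) {
    sub <- rh[rh$series_id == sid, ]
    s <- trait_series(sid, 201.11, "rhizome_length", "not_applicable",
                      sub$doy, pmax(sub$value - sub$value[1], 0))
    ph <- suppressWarnings(
      extract_phenology(fit_series(s, "bidoseresp")))
    dvmax <- c(dvmax, ph$D_vmax)
    l1 <- c(l1, gp[[paste(sid, "rhizome_length")]][["L1"]])
  }
  # generator phase-1 rate peak sits at L1 for the two-sigmoid family
  expect_lt(abs(mean(dvmax) - mean(l1)), 5)
})
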
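#' Default per-patch generator means
#'
#' Family parameters for the three traits in each of the five monitored
#' patches, calibrated so the implied phenology matches the published
#' per-patch means: the asymptotes equal the patch-mean maximum increments,
#' the centers equal the patch-mean peak-rate dates, and the shape
#' parameters are solved from the printed onset/termination dates via the
#' 5%/95% threshold closed forms (see the methods vignette).
#'
#' @return Named list (`plant_height`, `leaf_area`, `rhizome_length`), each
#'   a list of five named parameter vectors, one per patch in increasing
#'   area order.
#' @export
default_trait_params <- function() {
  d_o_rhizome <- c(129, 84, 72, 72, 73)
  l1 <- c(171, 177, 164, 156, 161)
  list(
    plant_height = lapply(1:5, function(i)
      c(A1 = 0,
        A2 = c(76, 70, 71, 76, 74)[i],
        x0 = c(110, 111, 106, 111, 107)[i],
        p = 9)),
    leaf_area = lapply(1:5, function(i)
      c(Pm = c(249, 221, 208, 229, 266)[i],
        Ka = c(151, 158, 147, 132, 142)[i],
        Ha = 6, Ki = 330, Hi = 8)),
    rhizome_length = lapply(1:5, function(i)
      c(A1 = 0,
        A2 = c(94, 153, 200, 202, 173)[i],
        L1 = l1[i],
        L2 = c(251, 258, 259, 262, 256)[i],
        # h1 set so the 5% onset of phase 1 lands on the printed D_o:
        # P/(1 + 10^((L1 - D_o) h1)) = 0.05 with P = 0.6
        h1 = log10(11) / (l1[i] - d_o_rhizome[i]),
        h2 = 0.08, P = 0.6))
  )
}

#' Synthetic monitoring-campaign configuration
#'
#' Defaults emulate the field design: five patches spanning four orders of
#' magnitude in area; 2, 3, 7, 5 and 8 asexual clusters (plus 6 sexual
#' clusters in the largest patch) monitored for plant height and leaf area
#' every 5 days from 25 March to 5 November 2021; 2, 3, 7, 5 and 17
#' rhizomes monitored every 10 days from 25 February to 15 December 2021.
#' Between-cluster variability is lognormal around the per-patch means;
#' sexual clusters get multiplicative boosts on the aboveground asymptotes
#' and slightly earlier centers; measurement noise is additive Gaussian
#' (a fraction of each series' span) floored at zero.
#'
#' @param patch_areas_m2 Patch areas (m^2).
#' @param asexual_clusters_per_patch Aboveground asexual clusters per patch.
#' @param sexual_clusters_largest_patch Sexual clusters in the largest patch.
#' @param rhizomes_per_patch Monitored rhizomes per patch.
#' @param aboveground_schedule,rhizome_schedule Lists with `start`, `end`
#'   (Dates) and `step_days`.
#' @param noise_sd_fraction Measurement noise SD as a fraction of the
#'   series' generator span.
#' @param sexual_Wmax_multiplier_leaf,sexual_Wmax_multiplier_height
#'   Multiplicative effect of sexual reproduction on the aboveground
#'   asymptotes.
#' @param sexual_center_shift_days Days by which sexual clusters' centers
#'   are advanced (`leaf_area`, `plant_height`).
#' @param rhizome_baseline_range_cm Uniform range for the pre-season rhizome
#'   baseline length.
#' @param trait_mean_params Per-trait, per-patch generator means
#'   (default [default_trait_params()]).
#' @param between_cluster_cv Lognormal coefficient of variation of the
#'   amplitude parameters between clusters (date/shape parameters use a
#'   quarter of it).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(
    patch_areas_m2 = c(0.51, 2.29, 201.11, 312.93, 36075),
    asexual_clusters_per_patch = c(2, 3, 7, 5, 8),
    sexual_clusters_largest_patch = 6,
    rhizomes_per_patch = c(2, 3, 7, 5, 17),
    aboveground_schedule = list(start = as.Date("2021-03-25"),
                                end = as.Date("2021-11-05"), step_days = 5),
    rhizome_schedule = list(start = as.Date("2021-02-25"),
                            end = as.Date("2021-12-15"), step_days = 10),
    noise_sd_fraction = 0.02,
    sexual_Wmax_multiplier_leaf = 1.8,
    sexual_Wmax_multiplier_height = 1.7,
    sexual_center_shift_days = c(leaf_area = 13, plant_height = 6),
    rhizome_baseline_range_cm = c(30, 60),
    trait_mean_params = default_trait_params(),
    between_cluster_cv = 0.15,
    seed = 1L) {
  np <- length(patch_areas_m2)
  stopifnot(length(asexual_clusters_per_patch) == np,
            length(rhizomes_per_patch) == np,
            sexual_Wmax_multiplier_leaf > 1,
            sexual_Wmax_multiplier_height > 1,
            noise_sd_fraction >= 0, between_cluster_cv >= 0)
  for (tr in c("plant_height", "leaf_area", "rhizome_length"))
    stopifnot(length(trait_mean_params[[tr]]) == np)
  structure(list(
    patch_areas_m2 = patch_areas_m2,
    asexual_clusters_per_patch = asexual_clusters_per_patch,
    sexual_clusters_largest_patch = sexual_clusters_largest_patch,
    rhizomes_per_patch = rhizomes_per_patch,
    aboveground_schedule = aboveground_schedule,
    rhizome_schedule = rhizome_schedule,
    noise_sd_fraction = noise_sd_fraction,
    sexual_Wmax_multiplier_leaf = sexual_Wmax_multiplier_leaf,
    sexual_Wmax_multiplier_height = sexual_Wmax_multiplier_height,
    sexual_center_shift_days = sexual_center_shift_days,
    rhizome_baseline_range_cm = rhizome_baseline_range_cm,
    trait_mean_params = trait_mean_params,
    between_cluster_cv = between_cluster_cv,
    seed = as.integer(seed)), class = "campaign_config")
}

#' Survey schedule as days of the year
#'
#' Dates `start`, `start + step`, ... up to `end` (inclusive rule),
#' returned as DOY (January 1 = 1; the 2021 study calendar is non-leap).
#'
#' @param start,end Dates (or strings coercible to Date).
#' @param step_days Positive integer step.
#' @return Integer vector of DOYs.
#' @examples
#' length(survey_schedule("2021-02-25", "2021-12-15", 10))  # 30 surveys
#' @export
survey_schedule <- function(start, end, step_days) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("start must not be after end", call. = FALSE)
  if (step_days < 1) stop("step_days must be >= 1", call. = FALSE)
  dates <- seq(start, end, by = step_days)
  as.integer(format(dates, "%j"))
}

#' Draw one cluster's growth-curve parameters
#'
#' Parameters are drawn lognormally around the configured per-patch means:
#' amplitude parameters (`A2`, `Pm`) with coefficient of variation
#' `between_cluster_cv`, date and shape parameters with a quarter of it
#' (matching the much smaller relative spread of the published dates).
#' Sexual clusters receive the aboveground `W_max` multipliers and a
#' forward shift of the center parameter (earlier rapid growth). Draws
#' consume the current RNG stream, so they are deterministic after
#' `set.seed()`.
#'
#' @param config A [campaign_config()].
#' @param patch_index Patch index (1 = smallest).
#' @param trait Trait name.
#' @param reproductive_type `"asexual"`, `"sexual"` or `"not_applicable"`.
#' @return Named parameter vector for the trait's model family.
#' @export
draw_cluster_params <- function(config, patch_index, trait,
                                reproductive_type = "asexual") {
  if (!trait %in% names(config$trait_mean_params))
    stop("unknown trait: ", trait, call. = FALSE)
  stopifnot(patch_index >= 1,
            patch_index <= length(config$patch_areas_m2))
  mu <- config$trait_mean_params[[trait]][[patch_index]]
  amp <- intersect(names(mu), c("A2", "Pm"))
  cv_amp <- config$between_cluster_cv
  cv_oth <- config$between_cluster_cv / 4
  draw1 <- function(m, cv) {
    if (m <= 0 || cv == 0) return(m)
    sdl <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
  }
  out <- mu
  for (nm in names(mu)) {
    if (nm %in% c("A1", "P")) next  # A1 pinned at 0, P jittered below
    out[nm] <- draw1(mu[[nm]], if (nm %in% amp) cv_amp else cv_oth)
  }
  if ("P" %in% names(mu))
    out["P"] <- min(max(mu[["P"]] + stats::rnorm(1, 0, 0.03), 0.05), 0.95)
  if (identical(reproductive_type, "sexual")) {
    if (trait == "leaf_area") {
      out["Pm"] <- out[["Pm"]] * config$sexual_Wmax_multiplier_leaf
      out["Ka"] <- out[["Ka"]] - config$sexual_center_shift_days[["leaf_area"]]
    } else if (trait == "plant_height") {
      out["A2"] <- out[["A2"]] * config$sexual_Wmax_multiplier_height
      out["x0"] <- out[["x0"]] - config$sexual_center_shift_days[["plant_height"]]
    }
  }
  # keep the bimodal ordering intact under jitter
  if (all(c("L1", "L2") %in% names(out)) && out[["L2"]] <= out[["L1"]] + 5)
    out["L2"] <- out[["L1"]] + 5
  out
}

#' Simulate a full monitoring campaign
#'
#' Generates the long-format monitoring table the readers consume: one row
#' per series and survey with the calendar date, DOY, patch area, series
#' id, reproductive type, trait and measured value. Aboveground values are
#' model increments (starting near zero at the first survey); rhizome
#' values are the positive pre-season baseline plus the model increment, so
#' they are non-decreasing in the noiseless case. Noise is additive
#' truncated Gaussian (floored at 0) with SD `noise_sd_fraction` times the
#' series' generator span.
#'
#' @param config A [campaign_config()].
#' @return A `data.frame` with columns `date`, `doy`, `patch_area_m2`,
#'   `series_id`, `type`, `trait`, `value`, plus an attribute
#'   `"generator_params"` (the drawn per-series parameters, for recovery
#'   checks).
#' @export
simulate_campaign <- function(config = campaign_config()) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed)
  ag <- config$aboveground_schedule
  rh <- config$rhizome_schedule
  doy_ag <- survey_schedule(ag$start, ag$end, ag$step_days)
  doy_rh <- survey_schedule(rh$start, rh$end, rh$step_days)
  date_ag <- seq(as.Date(ag$start), as.Date(ag$end), by = ag$step_days)
  date_rh <- seq(as.Date(rh$start), as.Date(rh$end), by = rh$step_days)
  fam_of <- c(plant_height = "logistic", leaf_area = "bihill",
              rhizome_length = "bidoseresp")

  rows <- list()
  gen <- list()
  noise <- function(mu, span) {
    if (config$noise_sd_fraction == 0) return(mu)
    pmax(mu + stats::rnorm(length(mu), 0, config$noise_sd_fraction * span), 0)
  }
  for (i in seq_along(config$patch_areas_m2)) {
    area <- config$patch_areas_m2[i]
    n_sex <- if (i == which.max(config$patch_areas_m2))
      config$sexual_clusters_largest_patch else 0
    types <- c(rep("asexual", config$asexual_clusters_per_patch[i]),
               rep("sexual", n_sex))
    for (j in seq_along(types)) {
      sid <- sprintf("P%d_C%02d", i, j)
      for (trait in c("plant_height", "leaf_area")) {
        par <- draw_cluster_params(config, i, trait, types[j])
        span <- if (trait == "plant_height") par[["A2"]] else par[["Pm"]]
        vals <- noise(grow_eval(fam_of[[trait]], par, doy_ag), span)
        gen[[paste(sid, trait)]] <- par
        rows[[length(rows) + 1]] <- data.frame(
          date = date_ag, doy = doy_ag, patch_area_m2 = area,
          series_id = sid, type = types[j], trait = trait, value = vals,
          stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(config$rhizomes_per_patch[i])) {
      sid <- sprintf("P%d_R%02d", i, j)
      par <- draw_cluster_params(config, i, "rhizome_length", "not_applicable")
      baseline <- stats::runif(1, config$rhizome_baseline_range_cm[1],
                               config$rhizome_baseline_range_cm[2])
      vals <- noise(baseline + grow_eval("bidoseresp", par, doy_rh),
                    par[["A2"]])
      gen[[paste(sid, "rhizome_length")]] <- c(par, baseline = baseline)
      rows[[length(rows) + 1]] <- data.frame(
        date = date_rh, doy = doy_rh, patch_area_m2 = area,
        series_id = sid, type = "not_applicable",
        trait = "rhizome_length", value = vals,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generator_params") <- gen
  out
}
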
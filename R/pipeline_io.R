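#' Read a long-format monitoring table into trait series
#'
#' Expects the tidy long layout the simulator writes: columns `date`,
#' `patch_area_m2`, `series_id`, `type`, `trait`, `value` (an optional
#' `doy` column is ignored and recomputed). Calendar dates are converted to
#' day of year (January 1 = 1) and one [trait_series()] is built per
#' `(series_id, trait)` with rows sorted by DOY.
#'
#' @param path CSV file path.
#' @return Named list of `trait_series` (names `"<series_id>.<trait>"`).
#' @export
read_monitoring_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("date", "patch_area_m2", "series_id", "type", "trait", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(df$date)
  bad <- which(is.na(dates))
  if (length(bad))
    stop("unparseable date at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  neg <- which(!is.finite(df$value) | df$value < 0)
  if (length(neg))
    stop("negative or non-finite value at row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  df$doy <- as.integer(format(dates, "%j"))
  key <- paste(df$series_id, df$trait, df$doy)
  if (anyDuplicated(key))
    stop("duplicate (series, trait, date) row(s), e.g. row ",
         which(duplicated(key))[1], call. = FALSE)
  split_key <- paste(df$series_id, df$trait, sep = ".")
  out <- lapply(split(df, split_key), function(sub) {
    sub <- sub[order(sub$doy), , drop = FALSE]
    trait_series(series_id = sub$series_id[1],
                 patch_area_m2 = sub$patch_area_m2[1],
                 trait = sub$trait[1],
                 reproductive_type = sub$type[1],
                 doys = sub$doy, increments = sub$value)
  })
  out
}

#' Write a monitoring table to CSV
#'
#' @param df Long-format monitoring data frame (as from
#'   [simulate_campaign()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_monitoring_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert raw rhizome lengths to growth increments
#'
#' Rhizomes grow from an existing pre-season base, so the first measurement
#' is the baseline and the growth increment is each measurement minus that
#' baseline (the first increment is 0 by construction).
#'
#' @param series A rhizome-length [trait_series()] of raw measurements.
#' @return The series with baseline-subtracted increments.
#' @export
rhizome_baseline_correct <- function(series) {
  stopifnot(inherits(series, "trait_series"))
  if (series$trait != "rhizome_length")
    stop("baseline correction applies to rhizome_length series only",
         call. = FALSE)
  if (!length(series$increments)) stop("empty series", call. = FALSE)
  series$increments <- series$increments - series$increments[1]
  series$increments[series$increments < 0] <- 0  # measurement noise floor
  series
}

#' Patch-level means of per-series values
#'
#' @param df Data frame of per-series values with grouping columns.
#' @param value_col Name of the value column to aggregate.
#' @param by Character vector of grouping columns (default patch and trait).
#' @return Data frame with the grouping columns plus `mean`, `sd`, `n`.
#' @export
patch_means <- function(df, value_col, by = c("patch_area_m2", "trait")) {
  stopifnot(value_col %in% names(df), all(by %in% names(df)))
  g <- interaction(df[by], drop = TRUE)
  out <- do.call(rbind, lapply(split(df, g), function(sub) {
    v <- sub[[value_col]]
    v <- v[is.finite(v)]
    res <- sub[1, by, drop = FALSE]
    res$mean <- mean(v)
    res$sd <- if (length(v) > 1) stats::sd(v) else 0
    res$n <- length(v)
    res
  }))
  rownames(out) <- NULL
  out[order(out[[by[1]]]), , drop = FALSE]
}

#' Smooth trend of a quantity along the lg-area gradient
#'
#' Interpolating natural cubic spline through the patch-level means, used
#' to visualise trait trends along the logarithmic patch-area gradient.
#' With fewer than 4 points the interpolant degenerates to a lower degree
#' and a warning is issued.
#'
#' @param lg_areas Distinct, sorted base-10 log patch areas.
#' @param values Patch-level means, same length.
#' @param n_grid Number of grid points for the returned curve.
#' @return List with `x`, `y` (the sampled curve) and `fun` (the spline
#'   function).
#' @export
spline_trend <- function(lg_areas, values, n_grid = 100) {
  if (length(lg_areas) != length(values))
    stop("lg_areas and values must have equal length", call. = FALSE)
  if (any(duplicated(lg_areas)) || is.unsorted(lg_areas))
    stop("lg_areas must be distinct and sorted", call. = FALSE)
  if (length(lg_areas) < 2) stop("need at least 2 points", call. = FALSE)
  if (length(lg_areas) < 4)
    warning("fewer than 4 points: spline degree reduced", call. = FALSE)
  f <- stats::splinefun(lg_areas, values, method = "natural")
  x <- seq(min(lg_areas), max(lg_areas), length.out = n_grid)
  list(x = x, y = f(x), fun = f)
}

#' Pipeline configuration
#'
#' @param theta_o,theta_t Phenology onset/termination threshold fractions.
#' @param cutoff_doy Last survey DOY used for allometry (mid-July = 196).
#' @param alpha Significance level.
#' @param marginal Marginal-significance band upper bound.
#' @param grid_step Phenology search grid (days).
#' @param n_starts Least-squares multistarts per series.
#' @param seed Master seed for simulation and fitting.
#' @param campaign A [campaign_config()] used when simulating (defaults to
#'   the study design with this `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(theta_o = 0.05, theta_t = 0.95,
                            cutoff_doy = 196, alpha = 0.05, marginal = 0.10,
                            grid_step = 0.1, n_starts = 8, seed = 1L,
                            campaign = NULL) {
  structure(list(theta_o = theta_o, theta_t = theta_t,
                 cutoff_doy = cutoff_doy, alpha = alpha, marginal = marginal,
                 grid_step = grid_step, n_starts = n_starts,
                 seed = as.integer(seed),
                 campaign = campaign %||% campaign_config(seed = seed)),
            class = "pipeline_config")
}

family_for_trait <- function(trait) {
  switch(trait,
    plant_height = "logistic",
    leaf_area = "bihill",
    rhizome_length = "bidoseresp",
    stop("no model family assigned to trait ", trait, call. = FALSE))
}

#' Run the full growth-dynamics analysis
#'
#' Orchestrates the stages: read (or simulate) the monitoring table,
#' baseline-correct rhizome series, fit each series with its trait's model
#' family, extract phenology, aggregate patch-level means, compare growth
#' parameters across traits (population level) and between sexual and
#' asexual clusters in the largest patch, compute trait-pair increment
#' ratios, fit SMA allometries per trait pair and patch on pre-cutoff
#' patch-mean survey values, and smooth key parameters along the lg-area
#' gradient. Belowground-aboveground SMA pairs match each rhizome survey to
#' the nearest aboveground survey within 3 days.
#'
#' @param config A [pipeline_config()].
#' @param input Path to a monitoring CSV, or `NULL` to simulate a campaign
#'   from `config$campaign`.
#' @param out_dir Optional directory; when given, all report tables are
#'   written there as CSV plus a JSON run manifest.
#' @return A list of class `pipeline_result` with elements `phenology`
#'   (per-series data frame), `patch_summary`, `trait_comparison`,
#'   `sexual_comparison`, `ratios`, `sma`, `trends` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  # --- input ---------------------------------------------------------------
  if (is.null(input)) {
    campaign <- simulate_campaign(config$campaign)
  } else {
    campaign <- NULL
  }
  series_list <- if (is.null(input)) {
    df <- campaign
    split_key <- paste(df$series_id, df$trait, sep = ".")
    lapply(split(df, split_key), function(sub) {
      sub <- sub[order(sub$doy), , drop = FALSE]
      trait_series(sub$series_id[1], sub$patch_area_m2[1], sub$trait[1],
                   sub$type[1], sub$doy, sub$value)
    })
  } else read_monitoring_table(input)

  # --- preprocess + fit + phenology ---------------------------------------
  fc <- fit_config(n_starts = config$n_starts, seed = config$seed)
  ec <- extraction_config(theta_o = config$theta_o, theta_t = config$theta_t,
                          grid_step = config$grid_step)
  n_in <- length(series_list)
  n_failed <- 0L
  phen_rows <- list()
  for (s in series_list) {
    if (s$trait == "rhizome_length") s <- rhizome_baseline_correct(s)
    res <- tryCatch({
      fit <- fit_series(s, family_for_trait(s$trait), fc)
      ph <- suppressWarnings(extract_phenology(fit, ec))
      cbind(data.frame(series_id = s$series_id, trait = s$trait,
                       patch_area_m2 = s$patch_area_m2,
                       reproductive_type = s$reproductive_type,
                       adj_r2 = fit$adj_r2, converged = fit$converged,
                       stringsAsFactors = FALSE),
            as.data.frame(ph[c("W_max", "V_max", "V_mean", "D_o", "D_r",
                               "D_vmax", "D_st", "D_t", "GD_sl", "GD_r",
                               "GD_st", "GD", "bimodal", "V_max2", "D_r2",
                               "D_vmax2", "D_st2", "GD_sl2", "GD_r2")]))
    }, error = function(e) {
      note("series %s (%s) failed: %s", s$series_id, s$trait,
           conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else
      phen_rows[[length(phen_rows) + 1]] <- res
  }
  if (!length(phen_rows))
    stop("pipeline failure at fitting stage: no series could be fitted",
         call. = FALSE)
  phen <- do.call(rbind, phen_rows)
  rownames(phen) <- NULL

  # --- patch-level summaries ----------------------------------------------
  # aboveground comparisons across patches use asexual clusters only
  phen_cmp <- phen[phen$reproductive_type != "sexual", , drop = FALSE]
  patch_summary <- patch_means(phen_cmp, "W_max")
  for (col in c("V_max", "V_mean", "GD", "D_vmax", "D_o", "D_t")) {
    pm <- patch_means(phen_cmp, col)
    patch_summary[[paste0(col, "_mean")]] <- pm$mean
    patch_summary[[paste0(col, "_sd")]] <- pm$sd
  }
  names(patch_summary)[names(patch_summary) == "mean"] <- "W_max_mean"
  names(patch_summary)[names(patch_summary) == "sd"] <- "W_max_sd"
  patch_summary$lg_area <- log10(patch_summary$patch_area_m2)

  # --- population-level comparison across traits ---------------------------
  cmp_params <- c("D_o", "D_r", "D_vmax", "D_st", "D_t",
                  "GD_sl", "GD_r", "GD_st", "GD")
  trait_comparison <- lapply(cmp_params, function(pn) {
    group_comparison(phen[[pn]], phen$trait, parameter = pn,
                     alpha = config$alpha, marginal = config$marginal)
  })
  names(trait_comparison) <- cmp_params

  # --- sexual vs asexual in the largest patch ------------------------------
  big <- max(phen$patch_area_m2)
  ab <- phen[phen$patch_area_m2 == big & phen$trait != "rhizome_length", ,
             drop = FALSE]
  sexual_comparison <- NULL
  if (length(unique(ab$reproductive_type)) == 2) {
    sex_params <- c("V_mean", "V_max", "W_max", cmp_params)
    sexual_comparison <- list()
    for (tr in unique(ab$trait)) {
      sub <- ab[ab$trait == tr, , drop = FALSE]
      sexual_comparison[[tr]] <- lapply(sex_params, function(pn) {
        group_comparison(sub[[pn]], sub$reproductive_type,
                         parameter = paste(tr, pn),
                         alpha = config$alpha, marginal = config$marginal)
      })
      names(sexual_comparison[[tr]]) <- sex_params
    }
  } else note("single reproductive type in the largest patch; sexual/asexual comparison skipped")

  # --- increment ratios ----------------------------------------------------
  wmax_by_patch <- patch_means(phen_cmp, "W_max")
  names(wmax_by_patch)[names(wmax_by_patch) == "mean"] <- "W_max"
  ratios <- increment_ratios(wmax_by_patch)

  # --- SMA allometry on pre-cutoff patch-mean survey values ----------------
  sma <- sma_stage(series_list, config, note)

  # --- lg-area trends ------------------------------------------------------
  trends <- list()
  for (tr in unique(patch_summary$trait)) {
    sub <- patch_summary[patch_summary$trait == tr, , drop = FALSE]
    sub <- sub[order(sub$lg_area), , drop = FALSE]
    if (nrow(sub) >= 4)
      trends[[tr]] <- spline_trend(sub$lg_area, sub$W_max_mean)[c("x", "y")]
  }

  manifest <- list(
    seed = config$seed,
    config = config[c("theta_o", "theta_t", "cutoff_doy", "alpha",
                      "marginal", "grid_step", "n_starts")],
    simulated = is.null(input),
    n_series_in = n_in,
    n_converged = nrow(phen),
    n_failed = n_failed,
    warnings = warnings_log)

  out <- structure(list(phenology = phen, patch_summary = patch_summary,
                        trait_comparison = trait_comparison,
                        sexual_comparison = sexual_comparison,
                        ratios = ratios, sma = sma, trends = trends,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

# SMA stage: build patch-mean survey series per trait and fit each pair/patch
sma_stage <- function(series_list, config, note) {
  traits <- c("plant_height", "leaf_area", "rhizome_length")
  areas <- sort(unique(vapply(series_list, function(s) s$patch_area_m2, 0)))
  mean_series <- function(area, trait) {
    sel <- Filter(function(s) s$patch_area_m2 == area && s$trait == trait &&
                    s$reproductive_type != "sexual", series_list)
    if (!length(sel)) return(NULL)
    sel <- lapply(sel, function(s)
      if (trait == "rhizome_length") rhizome_baseline_correct(s) else s)
    doys <- sel[[1]]$doys
    vals <- rowMeans(do.call(cbind, lapply(sel, function(s) s$increments)))
    list(doys = doys, values = vals)
  }
  pair_defs <- list(`LA-PH` = c(y = "leaf_area", x = "plant_height"),
                    `RL-LA` = c(y = "rhizome_length", x = "leaf_area"),
                    `RL-PH` = c(y = "rhizome_length", x = "plant_height"))
  rows <- list()
  for (area in areas) {
    ms <- lapply(traits, function(tr) mean_series(area, tr))
    names(ms) <- traits
    for (nm in names(pair_defs)) {
      ys <- ms[[pair_defs[[nm]][["y"]]]]
      xs <- ms[[pair_defs[[nm]][["x"]]]]
      if (is.null(ys) || is.null(xs)) next
      if (identical(xs$doys, ys$doys)) {
        doys <- xs$doys; xv <- xs$values; yv <- ys$values
      } else {
        # match each belowground survey to the nearest aboveground one
        idx <- vapply(ys$doys, function(d) {
          i <- which.min(abs(xs$doys - d))
          if (abs(xs$doys[i] - d) <= 3) i else NA_integer_
        }, 1L)
        ok <- !is.na(idx)
        doys <- ys$doys[ok]; xv <- xs$values[idx[ok]]; yv <- ys$values[ok]
      }
      fit <- tryCatch({
        lp <- prepare_log_pairs(xv, yv, doys = doys,
                                cutoff_doy = config$cutoff_doy)
        sma_fit(lp)
      }, error = function(e) {
        note("SMA %s at patch %.2f m2 failed: %s", nm, area,
             conditionMessage(e))
        NULL
      })
      if (is.null(fit)) next
      rows[[length(rows) + 1]] <- data.frame(
        pair = nm, patch_area_m2 = area, slope = fit$slope_b,
        intercept = fit$intercept, r2 = fit$r2, p = fit$p_fit,
        r2_1 = fit$r2_1, p_1 = fit$p_1, n = fit$n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pair = character(0), patch_area_m2 = numeric(0),
                      slope = numeric(0), intercept = numeric(0),
                      r2 = numeric(0), p = numeric(0), r2_1 = numeric(0),
                      p_1 = numeric(0), n = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$phenology, file.path(out_dir, "phenology.csv"),
                   row.names = FALSE)
  utils::write.csv(result$patch_summary,
                   file.path(out_dir, "patch_summary.csv"), row.names = FALSE)
  utils::write.csv(result$ratios, file.path(out_dir, "ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(result$sma, file.path(out_dir, "sma.csv"),
                   row.names = FALSE)
  cmp <- do.call(rbind, lapply(result$trait_comparison, function(gc)
    data.frame(parameter = gc$parameter, method = gc$method, F = gc$F,
               p = gc$p,
               groups = paste(sprintf("%s:%.1f%s", gc$groups, gc$means,
                                      gc$letters), collapse = "; "),
               stringsAsFactors = FALSE)))
  utils::write.csv(cmp, file.path(out_dir, "trait_comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result>\n")
  cat(sprintf("  series: %d in, %d converged, %d failed\n",
              m$n_series_in, m$n_converged, m$n_failed))
  cat(sprintf("  seed %d | simulated: %s\n", m$seed, m$simulated))
  cat(sprintf("  tables: phenology (%d rows), sma (%d rows), ratios (%d rows)\n",
              nrow(x$phenology), nrow(x$sma), nrow(x$ratios)))
  invisible(x)
}
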
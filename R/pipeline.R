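# End-to-end orchestration: simulate/load -> detect -> select definition ->
# fit vulnerability -> fit hazard -> Monte Carlo risk -> optional projection,
# with serialized intermediate artifacts and a run report.

default_run_config <- function() {
  list(
    simulate = TRUE,
    sim = list(),                 # overrides to sim_config()
    data = NULL,                  # CSV path when simulate = FALSE
    catalogue = NULL,             # YAML path; NULL = packaged default
    age_groups = c("0-64", "65+"),
    age_shares = c("0-64" = 0.9, "65+" = 0.1),
    selection_group = "all",
    spec = list(df_var = 2L, df_lag = 3L, max_lag = 3L),
    mc = list(n_years = 10000L, seed = 7L),
    return_periods = c(50, 100),
    future = list(enabled = FALSE, warming = 3, spell_rate_factor = 2,
                  elder_share = 0.3153, n_years = 10000L),
    seed = 42L
  )
}

#' Load a run configuration
#'
#' Reads a YAML run configuration and fills unset fields with the package
#' defaults. A list is accepted in place of a path.
#'
#' @param config path to a YAML file, or a list of overrides, or `NULL` for
#'   the defaults.
#' @return the completed configuration list.
#' @export
run_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(base, config)
  if (!is.null(cfg$age_shares)) cfg$age_shares <- unlist(cfg$age_shares)
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

group_file_tag <- function(g) {
  c("0-64" = "0_64", "65+" = "65plus", "all" = "all")[[g]]
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", na = "null")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or loading), heat-wave definition
#' selection by minimum AIC over the catalogue, per-age-group vulnerability
#' fitting with data-driven centering, hazard (Poisson frequency + Gamma
#' intensity) fitting with chi-square goodness of fit, the Monte Carlo loss
#' simulation, and -- when enabled -- a future projection with a warmer
#' simulated climate and an aged population structure. Every stage writes a
#' self-describing artifact (CSV for series/tables, JSON for fitted
#' objects) into `out_dir`, plus a markdown run report. Deterministic given
#' the configuration and seed.
#'
#' @param config a [run_config()] input (path, list, or `NULL`).
#' @param out_dir output directory.
#' @param seed optional master seed overriding the configuration's seeds
#'   (simulation uses `seed`, the Monte Carlo `seed + 1`, the projection
#'   `seed + 2`).
#' @return invisibly, a list with every stage's in-memory result.
#' @export
run_all <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- run_config(config)
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg$mc$seed <- as.integer(seed) + 1L
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # -- data ------------------------------------------------------------
  sim_cfg <- NULL
  data <- run_stage("data", {
    if (isTRUE(cfg$simulate)) {
      sim_args <- cfg$sim
      sim_args$seed <- cfg$seed
      sim_cfg <- do.call(sim_config, sim_args)
      ds <- generate_dataset(sim_cfg)
      write_dataset(ds, out_dir, name = "data")
      say("data: simulated %d years (%d records), seed %d",
          sim_cfg$n_years, nrow(ds$records), cfg$seed)
      ds$records
    } else {
      d <- read_daily_records(cfg$data)
      say("data: loaded %d records from %s", nrow(d), cfg$data)
      d
    }
  })
  if (isTRUE(cfg$simulate)) {
    cfg$age_shares <- sim_cfg$age_shares
  }
  structure_now <- age_structure(cfg$age_shares, label = "baseline")

  # -- definition selection --------------------------------------------
  spec <- crossbasis_spec(cfg$spec$df_var, cfg$spec$df_lag, cfg$spec$max_lag)
  catalogue <- hw_catalogue(cfg$catalogue)
  sel <- run_stage("select", {
    s <- select_definition(data, catalogue, spec,
                           age_group = cfg$selection_group)
    utils::write.csv(s$table, file.path(out_dir, "aic_table.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(s$events),
                     file.path(out_dir, "events.csv"),
                     row.names = FALSE, quote = FALSE)
    say("select: %d/%d definitions fittable; winner %s (%d events, AIC %.2f)",
        sum(s$table$fittable), nrow(s$table), s$best$id,
        nrow(s$events), min(s$table$aic[s$table$fittable]))
    s
  })
  events <- sel$events
  hwii <- daily_hwii_series(data, events)
  threshold <- attr(events, "threshold")

  # -- vulnerability fits ----------------------------------------------
  fits <- run_stage("vulnerability", {
    out <- list()
    for (g in cfg$age_groups) {
      v <- fit_vulnerability(data, hwii, spec, age_group = g,
                             definition_id = sel$best$id)
      curve <- percentile_axis(v$curve, events$hwii)
      tag <- group_file_tag(g)
      write_json_artifact(
        list(age_group = g, definition_id = sel$best$id,
             threshold = threshold, center = v$center,
             aic = v$fit$aic, n_obs = v$fit$n_obs,
             coefficients = as.list(v$fit$coef),
             covariance = unname(v$fit$vcov),
             spec = list(df_var = spec$df_var, df_lag = spec$df_lag,
                         max_lag = spec$max_lag,
                         var_knots = v$fit$spec$var_knots,
                         var_boundary = v$fit$spec$var_boundary)),
        file.path(out_dir, sprintf("fit_%s.json", tag)))
      utils::write.csv(as.data.frame(curve),
                       file.path(out_dir, sprintf("curve_%s.csv", tag)),
                       row.names = FALSE, quote = FALSE)
      say("vulnerability[%s]: center %.3g, AIC %.2f", g, v$center, v$fit$aic)
      out[[g]] <- v
    }
    out
  })
  curves <- lapply(fits, `[[`, "curve")

  # -- hazard ----------------------------------------------------------
  period <- as.integer(format(range(as.Date(data$date)), "%Y"))
  hazard <- run_stage("hazard", {
    st <- annual_stats(events, period)
    freq <- fit_poisson(st$annual$frequency)
    intens <- fit_gamma(st$intensities)
    # short records may not support the chi-square binning; record that
    # rather than aborting the run
    gof_safe <- function(model, x) {
      tryCatch(gof_chisq(model, x), error = function(e) {
        structure(list(statistic = NA_real_, dof = NA_integer_,
                       p_value = NA_real_, pass = NA,
                       note = conditionMessage(e)),
                  class = "gof_result")
      })
    }
    gof_f <- gof_safe(freq, st$annual$frequency)
    gof_i <- gof_safe(intens, st$intensities)
    write_json_artifact(
      list(period = period, lambda = freq$lambda,
           shape = intens$shape, scale = intens$scale,
           n_events = intens$n_events,
           gof = list(
             frequency = list(statistic = gof_f$statistic, dof = gof_f$dof,
                              p_value = gof_f$p_value, pass = gof_f$pass),
             intensity = list(statistic = gof_i$statistic, dof = gof_i$dof,
                              p_value = gof_i$p_value, pass = gof_i$pass))),
      file.path(out_dir, "hazard.json"))
    say("hazard: lambda %.3f/yr, Gamma(shape %.3f, scale %.3f); GOF p = %.3g / %.3g",
        freq$lambda, intens$shape, intens$scale, gof_f$p_value, gof_i$p_value)
    list(freq = freq, intens = intens, stats = st,
         gof = list(frequency = gof_f, intensity = gof_i))
  })

  # -- risk ------------------------------------------------------------
  risk <- run_stage("risk", {
    r <- simulate_losses(hazard$freq, hazard$intens, curves, structure_now,
                         n_years = cfg$mc$n_years, seed = cfg$mc$seed)
    summ <- risk_summary(r, cfg$return_periods)
    utils::write.csv(summ, file.path(out_dir, "risk_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    write_json_artifact(
      list(n_years = r$n_years, seed = r$seed,
           units = "deaths per million per year", summary = summ),
      file.path(out_dir, "risk.json"))
    crude <- Reduce(`+`, lapply(r$annual, function(m) m[, "central"]))
    utils::write.csv(ep_curve(crude), file.path(out_dir, "ep_curve.csv"),
                     row.names = FALSE, quote = FALSE)
    for (g in names(r$annual)) {
      say("risk[%s]: CMR AAL %.4g, ASMR AAL %.4g per million", g,
          aal(r$annual[[g]][, "central"]),
          cmr_to_asmr(aal(r$annual[[g]][, "central"]), structure_now, g))
    }
    list(result = r, summary = summ)
  })

  # -- future projection ------------------------------------------------
  projection <- NULL
  if (isTRUE(cfg$future$enabled)) {
    projection <- run_stage("project", {
      if (!isTRUE(cfg$simulate)) {
        stop("future projection requires a simulated baseline in this workflow")
      }
      fut_cfg <- sim_cfg
      fut_cfg$t_mean_annual <- fut_cfg$t_mean_annual + cfg$future$warming
      fut_cfg$spell_rate <- fut_cfg$spell_rate * cfg$future$spell_rate_factor
      fut_cfg$start_year <- sim_cfg$start_year + 50L
      fut_cfg$seed <- cfg$seed + 3L
      fut_t <- generate_temperature(fut_cfg)
      elder <- cfg$future$elder_share
      fut_struct <- age_structure(
        c("0-64" = 1 - elder, "65+" = elder), label = "projected")
      p <- project_future(curves, fut_struct, future_series = fut_t,
                          defn = sel$best, threshold = threshold,
                          n_years = cfg$future$n_years,
                          seed = cfg$mc$seed + 1L)
      summ <- risk_summary(p$risk, cfg$return_periods)
      write_json_artifact(
        list(warming = cfg$future$warming, elder_share = elder,
             lambda = p$annual_frequency, mean_hwii = p$mean_hwii,
             shape = p$intens$shape, scale = p$intens$scale,
             units = "deaths per million per year", summary = summ),
        file.path(out_dir, "projection.json"))
      say("project: lambda %.3f/yr, mean HWII %.2f; elder ASMR AAL %.4g per million",
          p$annual_frequency, p$mean_hwii,
          summ$aal[summ$group == "65+" & summ$metric == "ASMR" &
                     summ$band == "central"])
      list(projection = p, summary = summ)
    })
  }

  writeLines(c("# heatrisk run report", "", paste0("- ", log_lines)),
             file.path(out_dir, "report.md"))
  invisible(list(config = cfg, data = data, selection = sel, fits = fits,
                 curves = curves, hazard = hazard, risk = risk,
                 projection = projection, log = log_lines))
}
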
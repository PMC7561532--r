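#' Pipeline run configuration
#'
#' All tunables default to the analysis protocol: 2-h rarefaction at a
#' 15-min grain, bursts of at least 8 days with at most 4 consecutive
#' missed fixes, CTCRW single imputation, 2/3/4-state candidate models
#' with the scale-spanning multistart grid, the 0.85 predictive-power
#' threshold, 95% home-range isopleths on 7-h rarefied data, and 10
#' random steps per stratum.
#'
#' @param landscape a [landscape_spec()] (synthetic input), or `NULL`
#'   when `tracks`/raster paths are supplied.
#' @param tracks either a list of [track_spec()]s (synthetic input) or a
#'   path to a track CSV.
#' @param seed global seed; per-stage seeds are derived from it by
#'   stable hashing of stage names.
#' @param out_dir output directory for artifacts (`NULL`: no files).
#' @param rarefy_interval_h,rarefy_grain_min rarefaction target/grain.
#' @param min_burst_days,max_missing burst criteria.
#' @param n_states candidate state counts.
#' @param hmm_grid_means,hmm_grid_rhos multistart grid.
#' @param pred_threshold predictive-power threshold.
#' @param mean_ratio plausibility separation ratio.
#' @param isopleth home-range isopleth percent.
#' @param homerange_interval_h rarefaction interval for home ranges.
#' @param n_random random steps per stratum.
#' @param min_strata minimum strata per selection dataset.
#' @param ref_latlon study reference lat/lon for solar computations.
#' @return a `run_config` list.
#' @export
run_config <- function(landscape = landscape_spec(),
                       tracks = list(track_spec()),
                       seed = 1L, out_dir = NULL,
                       rarefy_interval_h = 2, rarefy_grain_min = 15,
                       min_burst_days = 8, max_missing = 4,
                       n_states = 2:4,
                       hmm_grid_means = c(5, 50, 200, 500, 1500),
                       hmm_grid_rhos = c(0.2, 0.7),
                       pred_threshold = 0.85, mean_ratio = 3,
                       isopleth = 95, homerange_interval_h = 7,
                       n_random = 10, min_strata = 20,
                       ref_latlon = c(46.7, -60.6)) {
  structure(as.list(environment()), class = "run_config")
}

behavior_labels <- function(N) {
  if (N == 3) c("encamped", "foraging", "traveling")
  else paste0("state", seq_len(N))
}

#' Run the full movement-analysis pipeline
#'
#' Sequences the stages end to end: track generation or ingestion,
#' speed screening, rarefaction, burst extraction, CTCRW imputation of
#' missing slots, HMM fitting over the candidate state counts with
#' sequential model selection, behavior decoding, season/light
#' assignment, time budgets, seasonal home ranges, and the stratified
#' step-selection fits. Artifacts are written to `config$out_dir` when
#' set; a structured report is returned and any stage error aborts with
#' the stage name.
#'
#' @param config a [run_config()].
#' @return a run report list (seeds, per-stage counts, the selected
#'   movement model and criteria report, budget table, home-range
#'   summary, selection results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(seed = config$seed, counts = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, file, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }

  # -- input: synthetic generation or CSV ingestion
  truth <- NULL
  if (is.character(config$tracks)) {
    fixes <- stage("read_tracks", read_track_csv(config$tracks))
    stack <- stage("read_landscape", config$landscape)
    stopifnot(inherits(stack, "landscape_stack"))
  } else {
    stack <- stage("synth_landscape", make_landscape(config$landscape))
    fixes_list <- list(); truth <- list()
    for (i in seq_along(config$tracks)) {
      ts <- config$tracks[[i]]
      ts$seed <- stage_seed(config$seed, paste0("track", i))
      sim <- stage("synth_track", simulate_track(ts, stack,
                                                 id = sprintf("A%02d", i)))
      f <- sim$fixes
      f <- stage("synth_gaps",
                 drop_fixes(f, ts$missingness,
                            max_gap = config$max_missing,
                            seed = stage_seed(config$seed,
                                              paste0("gaps", i))))
      fixes_list[[i]] <- f
      truth[[sprintf("A%02d", i)]] <- sim$states
    }
    fixes <- do.call(rbind, fixes_list)
    emit(stack$landcover, "landcover.asc", write_ascii_grid)
    emit(stack$dem, "dem.asc", write_ascii_grid)
    emit(stack$corridors, "corridors.geojson", write_lines_geojson)
    emit(fixes, "tracks_raw.csv", write_track_csv)
  }
  report$counts$fixes_raw <- nrow(fixes)

  # -- preprocess
  scr <- stage("speed_filter", filter_speed(fixes))
  report$counts$fixes_removed_speed <- nrow(scr$removed)
  rar <- stage("rarefy", rarefy(scr$fixes, config$rarefy_interval_h,
                                config$rarefy_grain_min))
  report$counts$fixes_rarefied <- sum(!is.na(rar$x))
  bursts <- stage("extract_bursts",
                  extract_bursts(rar, config$rarefy_interval_h,
                                 config$min_burst_days, config$max_missing))
  report$counts$bursts <- length(bursts)
  if (length(bursts) == 0) stop("pipeline stage 'extract_bursts' failed: ",
                                "no burst satisfies the criteria",
                                call. = FALSE)

  # -- ctcrw imputation
  n_imputed <- 0
  bursts <- stage("ctcrw", lapply(seq_along(bursts), function(i) {
    b <- bursts[[i]]
    if (!any(!b$observed)) return(b)
    pars <- fit_ctcrw(b)
    b2 <- impute_missing(b, pars,
                         seed = stage_seed(config$seed, paste0("impute", i)))
    n_imputed <<- n_imputed + sum(b2$source == "imputed")
    b2
  }))
  report$counts$imputed_fixes <- n_imputed

  # -- steps + temporal context
  steps <- stage("steps", lapply(bursts, function(b) {
    s <- steps_from_burst(b)
    s$id <- attr(b, "id")
    ctx <- assign_temporal(
      data.frame(id = s$id, time = s$time, x = s$x1, y = s$y1),
      stack, config$ref_latlon)
    s$season <- ctx$season
    s$light <- ctx$light
    s
  }))
  report$counts$steps <- sum(vapply(steps, nrow, 0L))

  # -- hmm fit + selection
  grids <- lapply(config$n_states, function(N)
    start_grid(N, config$hmm_grid_means, config$hmm_grid_rhos))
  fits <- stage("hmm_fit", lapply(seq_along(config$n_states), function(k) {
    multistart_fit(steps, config$n_states[k], grid = grids[[k]])
  }))
  decs <- stage("hmm_decode", lapply(fits, state_posteriors, steps = steps))
  sel <- stage("hmm_select",
               select_model(fits, decs, mean_ratio = config$mean_ratio,
                            pred_threshold = config$pred_threshold))
  report$model_selection <- sel$report
  model <- sel$model
  report$selected_states <- model$N
  report$state_step_means <- model$mean
  dec <- decs[[which(config$n_states == model$N)]]
  emit(model, "movement_model.json", write_movement_model)

  labels <- behavior_labels(model$N)
  flat <- do.call(rbind, steps)
  flat$behavior <- labels[dec$viterbi]
  flat$state_prob <- dec$max_posterior
  report$counts$steps_decoded <- nrow(flat)
  retained <- flat[!flat$imputed & !is.na(flat$length), , drop = FALSE]
  report$counts$steps_non_imputed <- nrow(retained)
  emit(data.frame(id = flat$id, timestamp = flat$time, x = flat$x1,
                  y = flat$y1, season = flat$season, light = flat$light,
                  state = flat$behavior, state_prob = flat$state_prob),
       "decoded_steps.csv",
       function(obj, p) write.csv(obj, p, row.names = FALSE))

  # -- time budget
  budget <- stage("budget", time_budget(retained, config$ref_latlon[1],
                                        config$ref_latlon[2]))
  report$budget <- budget
  emit(budget, "time_budget.csv",
       function(obj, p) write.csv(obj, p, row.names = FALSE))

  # -- home ranges on 7-h rarefied data
  hr_fixes <- stage("homerange_rarefy",
                    rarefy(scr$fixes, config$homerange_interval_h,
                           config$rarefy_grain_min))
  hr_fixes <- hr_fixes[!is.na(hr_fixes$x), , drop = FALSE]
  hr_fixes <- stage("homerange_temporal",
                    assign_temporal(hr_fixes, stack, config$ref_latlon))
  hr <- stage("homerange", seasonal_ranges(hr_fixes, config$isopleth))
  report$homeranges <- homerange_summary(hr)
  report$counts$fixes_homerange <- nrow(hr_fixes)
  emit(hr, "homeranges.geojson", write_homeranges_geojson)
  if (!is.null(report$homeranges)) {
    emit(report$homeranges, "homerange_summary.csv",
         function(obj, p) write.csv(obj, p, row.names = FALSE))
  }

  # -- issa
  dists <- stage("issa_distributions",
                 empirical_distributions(retained))
  strata <- stage("issa_strata",
                  make_strata(retained, stack, dists,
                              n_random = config$n_random,
                              seed = stage_seed(config$seed, "issa")))
  report$counts$strata <- if (is.null(strata)) 0L else
    length(unique(strata$stratum))
  issa <- stage("issa_fit", fit_issa(strata, min_strata = config$min_strata))
  report$issa <- issa_results_table(issa)
  report$issa_skipped <- issa$skipped
  if (!is.null(report$issa)) {
    emit(report$issa, "issa_results.csv",
         function(obj, p) write.csv(obj, p, row.names = FALSE))
    emit(issa_wide_table(issa), "issa_table.csv",
         function(obj, p) write.csv(obj, p, row.names = FALSE))
  }

  if (!is.null(truth)) report$truth_states <- truth
  if (!is.null(out_dir)) {
    rep_json <- report
    rep_json$truth_states <- NULL
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows")
  }
  report
}
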
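# End-to-end pipeline: structured configuration plus the three stages
# prepare -> train -> evaluate.  Every stage is a pure function of
# (config, input files, seed): re-running never changes outputs.

default_config <- function() {
  list(
    paths = list(series = NULL, spectral = NULL, action_spectrum = NULL,
                 cloud = NULL, out_dir = "uvcast-out"),
    grid = list(start = "05:00", end = "19:00", step = 10),
    imputation = list(slot_window = 2, day_window = 5, year_window = 2),
    quality = list(max_abs_skewness = 0.3, max_ratio = 15,
                   ceiling = 400, floor = 150),
    smoothing = list(window = 11, polyorder = 3),
    windows = list(K = 14, lead = 1),
    splits = list(train_years = integer(0), val_years = integer(0),
                  test_years = integer(0), excluded_years = integer(0)),
    model = list(encoder_hidden = c(128, 256), dense_hidden = 160,
                 dropout = 0.2, quantile_q = 0.33),
    train = list(lr_init = 5e-4, lr_decay = 1e-7, epochs = 2000,
                 batch_size = 256, seed = 1),
    evaluate = list(window = c("08:00", "16:00"), floor = 1),
    filter_training = FALSE
  )
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      modify_list(base[[nm]], new[[nm]])
    } else new[[nm]]
  }
  base
}

#' Pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list) and merges it over
#' the package defaults.  Recognised keys:
#' `paths.{series,spectral,action_spectrum,cloud,out_dir}`,
#' `grid.{start,end,step}`,
#' `imputation.{slot_window,day_window,year_window}`,
#' `quality.{max_abs_skewness,max_ratio,ceiling,floor}`,
#' `smoothing.{window,polyorder}`, `windows.{K,lead}`,
#' `splits.{train_years,val_years,test_years,excluded_years}`,
#' `model.{encoder_hidden,dense_hidden,dropout,quantile_q}`,
#' `train.{lr_init,lr_decay,epochs,batch_size,seed}`,
#' `evaluate.{window,floor}` and `filter_training`.
#'
#' @param config Path to a YAML file, or a (possibly partial) config
#'   list.
#' @return The completed configuration list (class `uv_config`).
#' @export
uv_config <- function(config = list()) {
  if (inherits(config, "uv_config")) return(config)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modify_list(default_config(), config)
  sp <- cfg$splits
  years <- c(sp$train_years, sp$val_years, sp$test_years)
  if (anyDuplicated(years)) {
    stop("train/validation/test year sets must be pairwise disjoint")
  }
  structure(cfg, class = "uv_config")
}

cfg_path <- function(cfg, name) {
  p <- cfg$paths[[name]]
  if (is.null(p)) stop(sprintf("config: paths.%s is required here", name))
  p
}

cfg_grid <- function(cfg) uv_grid(cfg$grid$start, cfg$grid$end, cfg$grid$step)

split_dates <- function(series, years) {
  series$dates[year_of(series$dates) %in% years]
}

#' Prepare the modelling dataset
#'
#' Reads the input series (weighting spectral scans first when a
#' spectral file and action spectrum are configured), drops excluded
#' years, imputes missing cells, and applies the quality filter to the
#' validation- and test-year days (training days are kept in full; set
#' `filter_training: true` to filter them too).  Writes
#' `cleaned_series.csv` and `cleaning_report.json` to `paths.out_dir`.
#'
#' @param config See [uv_config()].
#' @return Invisibly, a list with the cleaned `series` and the cleaning
#'   `report`.
#' @export
uv_prepare <- function(config) {
  cfg <- uv_config(config)
  grid <- cfg_grid(cfg)
  if (!is.null(cfg$paths$spectral)) {
    days <- read_spectral_csv(cfg$paths$spectral, grid)
    spectrum <- read_action_spectrum(cfg_path(cfg, "action_spectrum"))
    series <- apply_action_spectrum(days, spectrum)
  } else {
    series <- read_series_csv(cfg_path(cfg, "series"), grid)
  }
  series <- complete_calendar(series)
  excl <- cfg$splits$excluded_years
  if (length(excl)) {
    keep <- !(year_of(series$dates) %in% excl)
    if (!any(keep)) stop("all days excluded by splits.excluded_years")
    series <- series[which(keep)]
  }
  n_missing_before <- sum(!series$observed)
  series <- uv_impute(series, cfg$imputation$slot_window,
                      cfg$imputation$day_window, cfg$imputation$year_window)
  n_imputed <- sum(series$imputed)

  filter_years <- c(cfg$splits$val_years, cfg$splits$test_years,
                    if (isTRUE(cfg$filter_training)) cfg$splits$train_years)
  rejected <- data.frame(date = as.Date(character()), rules = character())
  if (length(filter_years)) {
    in_scope <- year_of(series$dates) %in% filter_years
    if (any(in_scope)) {
      qf <- uv_quality_filter(series[which(in_scope)],
                              cfg$quality$max_abs_skewness,
                              cfg$quality$max_ratio, cfg$quality$ceiling,
                              cfg$quality$floor)
      rejected <- qf$rejected
    }
  }
  for (split in c("val", "test")) {
    yrs <- cfg$splits[[paste0(split, "_years")]]
    if (length(yrs) &&
        !length(setdiff(split_dates(series, yrs), rejected$date))) {
      stop(sprintf("%s split is empty after quality filtering", split))
    }
  }

  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_series_csv(series, file.path(out_dir, "cleaned_series.csv"))
  report <- list(
    n_days = nrow(series$values),
    n_missing_before = n_missing_before,
    n_imputed = n_imputed,
    n_unimputable = sum(!series$observed),
    rejected_days = if (nrow(rejected)) {
      lapply(seq_len(nrow(rejected)), function(i) {
        list(date = as.character(rejected$date[i]),
             rules = rejected$rules[i])
      })
    } else list(),
    splits = cfg$splits
  )
  jsonlite::write_json(report, file.path(out_dir, "cleaning_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(series = series, report = report))
}

read_prepared <- function(cfg) {
  out_dir <- cfg$paths$out_dir
  series <- read_series_csv(file.path(out_dir, "cleaned_series.csv"),
                            cfg_grid(cfg))
  report <- jsonlite::read_json(file.path(out_dir, "cleaning_report.json"))
  rejected <- as.Date(vapply(report$rejected_days,
                             function(r) r$date, character(1)))
  list(series = series, report = report, rejected = rejected)
}

#' Train the forecaster on the prepared dataset
#'
#' Builds training windows over the training years (validation-year
#' targets, minus quality-rejected days, monitor the loss and select the
#' retained parameters), fits [uvnet()], and writes `model.rds` (a
#' versioned checkpoint) and `loss_log.csv` to `paths.out_dir`.
#'
#' @param config See [uv_config()].
#' @return The fitted [uvnet()], invisibly.
#' @export
uv_train <- function(config) {
  cfg <- uv_config(config)
  prep <- read_prepared(cfg)
  series <- prep$series
  train_targets <- split_dates(series, cfg$splits$train_years)
  if (!length(train_targets)) stop("no training-year days in the prepared series")
  val_targets <- setdiff(split_dates(series, cfg$splits$val_years),
                         prep$rejected)
  model <- uvnet(
    series, K = cfg$windows$K, targets = train_targets,
    val_series = if (length(val_targets)) series else NULL,
    val_targets = if (length(val_targets)) {
      as.Date(val_targets, origin = "1970-01-01")
    } else NULL,
    lead = cfg$windows$lead,
    control = uvnet_control(encoder_hidden = cfg$model$encoder_hidden,
                            dense_hidden = cfg$model$dense_hidden,
                            dropout = cfg$model$dropout,
                            quantile = cfg$model$quantile_q,
                            smoothing_window = cfg$smoothing$window,
                            smoothing_polyorder = cfg$smoothing$polyorder),
    training = uvnet_training(lr_init = cfg$train$lr_init,
                              lr_decay = cfg$train$lr_decay,
                              epochs = cfg$train$epochs,
                              batch_size = cfg$train$batch_size),
    seed = cfg$train$seed
  )
  uvnet_save(model, file.path(cfg$paths$out_dir, "model.rds"))
  utils::write.csv(model$loss_log,
                   file.path(cfg$paths$out_dir, "loss_log.csv"),
                   row.names = FALSE)
  invisible(model)
}

#' Evaluate the trained forecaster on the test years
#'
#' Makes a next-day forecast for every eligible test-year date (complete
#' input history, previous-year donor available, not quality-rejected),
#' evaluates MAPE against the prepared series, compares with the
#' previous-day persistence baseline, and writes `report.json` to
#' `paths.out_dir`.
#'
#' @param config See [uv_config()].
#' @return The report list, invisibly.
#' @export
uv_evaluate <- function(config) {
  cfg <- uv_config(config)
  prep <- read_prepared(cfg)
  series <- prep$series
  model <- uvnet_load(file.path(cfg$paths$out_dir, "model.rds"))
  test_dates <- setdiff(split_dates(series, cfg$splits$test_years),
                        prep$rejected)
  if (!length(test_dates)) stop("no eligible test dates")
  ws <- build_windows(series, K = model$K,
                      targets = as.Date(test_dates, origin = "1970-01-01"),
                      lead = model$lead, scale = model$scale,
                      smoothing_window = model$control$smoothing_window,
                      smoothing_polyorder = model$control$smoothing_polyorder,
                      with_target = FALSE)
  eligible <- as.Date(vapply(ws$windows, function(w) as.character(w$date),
                             character(1)))
  if (!length(eligible)) stop("no eligible test dates")
  cloud <- NULL
  if (!is.null(cfg$paths$cloud)) {
    covs <- read_covariate_csv(cfg$paths$cloud)
    cloud <- covs[["cloud"]]
    if (is.null(cloud)) cloud <- covs[[1]]
  }
  fc <- forecast_next_day(model, series, eligible)
  ev <- uv_mape(fc, series, window = cfg$evaluate$window,
                floor = cfg$evaluate$floor, cloud = cloud)
  bl <- baseline_previous_day(series, eligible)
  ev_bl <- uv_mape(bl, series, window = cfg$evaluate$window,
                   floor = cfg$evaluate$floor, cloud = cloud)
  report <- list(
    n_days = ev$n_days,
    eligible_dates = as.character(eligible),
    skipped = if (nrow(ws$skipped)) {
      lapply(seq_len(nrow(ws$skipped)), function(i) {
        list(date = as.character(ws$skipped$date[i]),
             reason = ws$skipped$reason[i])
      })
    } else list(),
    mape_overall = ev$mape_overall,
    mape_by_hour = as.list(ev$mape_by_hour),
    mape_by_cloud_bin = if (!is.null(ev$mape_by_cloud_bin)) {
      as.list(ev$mape_by_cloud_bin)
    } else NULL,
    spearman_cloud = if (is.finite(ev$spearman_cloud)) ev$spearman_cloud
                     else NULL,
    excluded_slots = ev$excluded_slots,
    baseline = list(mape_overall = ev_bl$mape_overall,
                    excluded_slots = ev_bl$excluded_slots)
  )
  jsonlite::write_json(report, file.path(cfg$paths$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
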
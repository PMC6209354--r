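#' Read a long-format seasonal CPUE table
#'
#' Reads and validates the long CSV layout (`year`, `season`, `bay`,
#' `species`, `cpue`). This is also the documented import path for the
#' study's supplementary CPUE spreadsheet: export it to CSV with one row per
#' year x season x bay x species and these column names.
#'
#' @param path CSV file path.
#' @return validated data frame, sorted by species, bay, season, year.
#' @export
read_cpue_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "season", "bay", "species", "cpue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$cpue)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$cpue))))[1]
    stop("non-numeric cpue at data row ", bad)
  }
  if (any(!is.finite(df$cpue)) || any(df$cpue < 0)) {
    bad <- which(!is.finite(df$cpue) | df$cpue < 0)[1]
    stop("cpue must be finite and non-negative (data row ", bad, ")")
  }
  df$season <- tolower(df$season)
  if (!all(df$season %in% c("spring", "fall")))
    stop("season must be 'spring' or 'fall' (data row ",
         which(!df$season %in% c("spring", "fall"))[1], ")")
  key <- paste(df$year, df$season, df$bay, df$species, sep = "|")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate (year, season, bay, species) key at data row ", bad)
  }
  df <- df[order(df$species, df$bay, df$season, df$year), ]
  rownames(df) <- NULL
  # per-series gap check
  for (k in split(df, list(df$species, df$bay, df$season), drop = TRUE)) {
    yrs <- sort(k$year)
    if (length(yrs) > 1L && any(diff(yrs) != 1L))
      stop(sprintf("series %s/%s/%s has year gaps", k$species[1], k$bay[1],
                   k$season[1]))
  }
  df
}

#' Write and read a seasonal panel CSV
#'
#' The panel dialect: a comment header carrying the stage and species tags,
#' then a `t` column (1, 1.5, ...) followed by one column per bay.
#'
#' @param panel a [cpue_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s species=%s", attr(panel, "stage"),
                     attr(panel, "species")), con)
  df <- data.frame(t = attr(panel, "t"), unclass(panel),
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  stage <- sub(".*stage=(\\S+).*", "\\1", header)
  species <- sub(".*species=(\\S+).*", "\\1", header)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1] != "t") stop("panel CSV must start with a 't' column")
  cpue_panel(as.matrix(df[, -1, drop = FALSE]), stage = stage,
             species = species, bays = names(df)[-1])
}

#' Serialize a fitted periodic VARM as JSON
#'
#' Stores the inclusion mask, coefficient estimates and standard errors,
#' log-likelihood and BIC; [read_model_json()] reconstructs a `pvarm`
#' object usable for simulation.
#'
#' @param fit a [pvarm()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  obj <- list(included = names(fit$spec)[fit$spec],
              n_bays = attr(fit$spec, "n_bays"),
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              loglik = fit$loglik, bic = fit$bic, n_obs = fit$n_obs,
              converged = fit$converged, start_index = fit$start_index)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- varm_spec(obj$included, n_bays = obj$n_bays)
  incl <- names(spec)[spec]
  fit <- list(spec = spec, n_obs = obj$n_obs,
              n_params = length(incl), converged = obj$converged,
              start_index = obj$start_index,
              coefficients = unlist(obj$coefficients)[incl],
              se = unlist(obj$se)[incl],
              loglik = obj$loglik, bic = obj$bic, init = "stationary",
              call = NULL)
  class(fit) <- "pvarm"
  fit
}

#' Read a base effort/harvest CSV
#'
#' Mirrors the published base table layout: columns `season` (high/low),
#' `bay`, `trips`, `harvest_red_drum`, `harvest_seatrout`, seven bays per
#' season in coastal order.
#'
#' @param path CSV path.
#' @return list with `high`/`low` [base_season_table()]s (seasons present in
#'   the file).
#' @export
read_base_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("season", "bay", "trips", "harvest_red_drum", "harvest_seatrout")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (season in unique(df$season)) {
    sub <- df[df$season == season, ]
    sub <- sub[match(bay_codes(), sub$bay), ]
    if (any(is.na(sub$bay)))
      stop("season ", season, " must contain all 7 bays ",
           paste(bay_codes(), collapse = ", "))
    out[[season]] <- base_season_table(season, sub$trips,
                                       sub$harvest_red_drum,
                                       sub$harvest_seatrout)
  }
  out
}

#' Write a base effort/harvest CSV
#'
#' @param base list with `high`/`low` [base_season_table()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_base_table_csv <- function(base, path) {
  rows <- lapply(names(base), function(season) {
    b <- base[[season]]
    data.frame(season = season, bay = b$bay, trips = b$trips,
               harvest_red_drum = b$harvest_red_drum,
               harvest_seatrout = b$harvest_seatrout,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a run-configuration YAML file
#'
#' Strict schema: unknown keys are errors (to prevent silent constant
#' drift), constants must be positive, referenced paths must exist.
#'
#' @param path YAML path.
#' @return named list of validated settings merged over defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(input = NULL, base_table = NULL, species = "red_drum",
                   sweep = "reduced", max_models = 20L, n_starts = 5L,
                   seed = 1L, wtp = 30, cost_per_mile = c(0.5, 1, 2),
                   annual_days = 20, days_high = 189, days_low = 176,
                   d1 = 100, out_dir = ".", log_level = "info")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  cfg$cost_per_mile <- as.numeric(unlist(cfg$cost_per_mile))
  for (key in c("wtp", "annual_days", "days_high", "days_low", "d1"))
    if (!is.numeric(cfg[[key]]) || any(cfg[[key]] <= 0))
      stop("configuration key '", key, "' must be positive")
  if (any(cfg$cost_per_mile <= 0)) stop("cost_per_mile values must be positive")
  for (key in c("input", "base_table"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured path does not exist: ", cfg[[key]])
  cfg
}

# line-oriented key=value log records on stderr
log_kv <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0("stage=", stage,
                if (length(kv)) paste0(" ", paste(names(kv), unlist(kv),
                                                  sep = "=", collapse = " ")))
  message(msg)
}
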
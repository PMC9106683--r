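# Delimited-text I/O: profile tables, literature tables, stage mappings,
# results, and run configuration.
#
# One dialect only: comma-separated, decimal point, UTF-8.  Units are fixed
# by the column schema (g/kg, g/cm3, cm, permil); nothing is unit-guessed.

# condition helpers: the CLI maps these classes to exit codes
soc_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "pastureSOC_error")))
}
schema_error <- function(fmt, ...) soc_stop("schema_error", fmt, ...)
data_error   <- function(fmt, ...) soc_stop("data_error", fmt, ...)
config_error <- function(fmt, ...) soc_stop("config_error", fmt, ...)

profile_required_cols <- c("stage", "replicate", "horizon", "top_cm",
                           "bottom_cm", "soc_g_kg", "bd_g_cm3", "crack_cm")
profile_optional_cols <- c(n_g_kg = "n", d13c_permil = "d13c",
                           vsc_frac = "vsc", clay_pct = "clay",
                           root_mg_cm3 = "root")

#' Read a horizon-level profile table into stage ensembles
#'
#' One row per horizon.  Required columns: `stage`, `replicate`, `horizon`,
#' `top_cm`, `bottom_cm`, `soc_g_kg`, `bd_g_cm3`, `crack_cm`; recognized
#' optional columns: `n_g_kg`, `d13c_permil`, `vsc_frac`, `clay_pct`,
#' `root_mg_cm3`.  Unrecognized columns are ignored with a warning.  Rows
#' are grouped into profiles by (stage, replicate) and every profile is
#' validated; any invariant violation aborts the read, naming the profile.
#'
#' @param path CSV file path.
#' @return Named list of [stage_ensemble()] objects, ordered S0..S5.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) schema_error("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(profile_required_cols, names(d))
  if (length(missing) > 0L) {
    schema_error("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(d),
                   c(profile_required_cols, names(profile_optional_cols)))
  if (length(extra) > 0L) {
    warning("ignoring unrecognized column(s): ", paste(extra, collapse = ", "))
  }
  key <- paste(d$stage, d$replicate, d$horizon, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    data_error("data error: duplicate (stage, replicate, horizon) at row %d (%s/%s/%s)",
               i, d$stage[i], d$replicate[i], d$horizon[i])
  }
  groups <- split(d, list(stage = d$stage, replicate = d$replicate),
                  drop = TRUE)
  profiles <- lapply(groups, function(g) {
    if (length(unique(g$crack_cm)) != 1L) {
      data_error("data error: crack_cm not constant within profile %s/%s",
                 g$stage[1], g$replicate[1])
    }
    h <- data.frame(label = as.character(g$horizon),
                    top = g$top_cm, bottom = g$bottom_cm,
                    soc = g$soc_g_kg, bd = g$bd_g_cm3)
    for (col in names(profile_optional_cols)) {
      if (!is.null(g[[col]])) h[[profile_optional_cols[[col]]]] <- g[[col]]
    }
    soil_profile(g$stage[1], g$replicate[1], h, crack_depth = g$crack_cm[1])
  })
  for (p in profiles) {
    v <- validate_profile(p)
    if (length(v) > 0L) {
      data_error("data error in profile %s/%s: %s",
                 p$stage, p$replicate, paste(v, collapse = "; "))
    }
  }
  stages <- vapply(profiles, function(p) p$stage, character(1))
  ens <- lapply(split(unname(profiles), stages), stage_ensemble)
  ens[order(match(names(ens), degradation_stages()))]
}

#' Write stage ensembles back to the standard profile CSV
#'
#' Inverse of [read_profiles()]; the write -> read round trip reproduces
#' every field.
#'
#' @param ensembles List of [stage_ensemble()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(ensembles, path) {
  rows <- lapply(ensembles, function(ens) {
    do.call(rbind, lapply(ens$profiles, function(p) {
      h <- p$horizons
      data.frame(stage = p$stage, replicate = p$replicate,
                 horizon = h$label, top_cm = h$top, bottom_cm = h$bottom,
                 soc_g_kg = h$soc, bd_g_cm3 = h$bd, crack_cm = p$crack_depth,
                 n_g_kg = h$n, d13c_permil = h$d13c, vsc_frac = h$vsc,
                 clay_pct = h$clay, root_mg_cm3 = h$root)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

literature_required_cols <- c("study_id", "degradation_label", "depth_top_cm",
                              "depth_bottom_cm")
literature_numeric_cols <- c("depth_top_cm", "depth_bottom_cm", "carbon_g_kg",
                             "n_g_kg", "bd_g_cm3", "year")

#' Read a literature-record table
#'
#' One observation per row.  Required columns: `study_id`,
#' `degradation_label`, `depth_top_cm`, `depth_bottom_cm`; recognized
#' optional columns: `carbon_kind` ("SOC" or "SOM"), `carbon_g_kg`,
#' `n_g_kg`, `bd_g_cm3`, `region`, `year`.  Degradation labels are carried
#' verbatim; mapping onto stages happens later ([regroup_stage()]).  A
#' non-numeric cell in a numeric column, a missing depth interval, or a
#' carbon content without a `carbon_kind` is a data error naming the row.
#'
#' @param path CSV file path.
#' @return `data.frame` of literature records with a `mapped_stage` column
#'   initialized to `NA`.
#' @export
read_literature <- function(path) {
  if (!file.exists(path)) schema_error("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       colClasses = "character")
  missing <- setdiff(literature_required_cols, names(d))
  if (length(missing) > 0L) {
    schema_error("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", "))
  }
  for (col in c("carbon_kind", "carbon_g_kg", "n_g_kg", "bd_g_cm3",
                "region", "year")) {
    if (is.null(d[[col]])) d[[col]] <- rep(NA_character_, nrow(d))
  }
  for (col in intersect(literature_numeric_cols, names(d))) {
    raw <- trimws(d[[col]])
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0L) {
      data_error("data error: unparseable numeric cell '%s' in column %s, row %d",
                 raw[bad[1]], col, bad[1])
    }
    d[[col]] <- num
  }
  bad <- which(is.na(d$depth_top_cm) | is.na(d$depth_bottom_cm))
  if (length(bad) > 0L) {
    data_error("data error: missing depth interval at row %d", bad[1])
  }
  bad <- which(d$depth_bottom_cm <= d$depth_top_cm)
  if (length(bad) > 0L) {
    data_error("data error: depth_bottom_cm <= depth_top_cm at row %d", bad[1])
  }
  bad <- which(!is.na(d$carbon_g_kg) &
                 !(toupper(trimws(d$carbon_kind)) %in% c("SOC", "SOM")))
  if (length(bad) > 0L) {
    data_error("data error: carbon_g_kg without carbon_kind SOC/SOM at row %d",
               bad[1])
  }
  d$carbon_kind <- toupper(trimws(d$carbon_kind))
  d$carbon_kind[d$carbon_kind %in% c("", "NA")] <- NA_character_
  d$region[!is.na(d$region) & trimws(d$region) == ""] <- NA_character_
  d$mapped_stage <- rep(NA_character_, nrow(d))
  d
}

#' Read a stage-mapping table (degradation label to stage code)
#'
#' @param path CSV with columns `label`, `stage`.
#' @return `data.frame(label, stage)` with stage codes validated.
#' @export
read_stage_mapping <- function(path) {
  if (!file.exists(path)) schema_error("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("label", "stage") %in% names(d))) {
    schema_error("schema error: stage mapping needs columns label, stage")
  }
  bad <- setdiff(d$stage, degradation_stages())
  if (length(bad) > 0L) {
    data_error("data error: unknown stage code(s) in mapping: %s",
               paste(bad, collapse = ", "))
  }
  d[, c("label", "stage")]
}

#' Write a results table as CSV
#'
#' Numeric columns are rounded to a fixed number of decimal places so that
#' a write -> read round trip is lossless at the declared precision.
#' Optional header lines (config echo) are written as `#`-prefixed comments
#' that [utils::read.csv()] with `comment.char = "#"` skips.
#'
#' @param results `data.frame` from the stocks/partitioning/meta modules.
#' @param path Output CSV path.
#' @param digits Decimal places kept for numeric columns (default 6).
#' @param header_lines Optional character vector written as `# ` comments.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, digits = 6, header_lines = NULL) {
  stopifnot(is.data.frame(results))
  out <- results
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- round(out[[col]], digits)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0L) {
    writeLines(paste("#", header_lines), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable constants of the pipeline: the integration depth
#' limit (cm), the SOM:SOC conversion factor, the VSC lignin-recovery
#' fraction, the lignin delta-13C depletion (permil), the degradation-label
#' to stage mapping table, the significance level of the closure test, and
#' the random seed.
#'
#' @param depth_limit Stock integration depth, cm (default 30).
#' @param som_to_soc_factor SOM:SOC conversion factor (default 2.0).
#' @param vsc_recovery Fraction of lignin C recovered as VSC phenols
#'   (default 0.38).
#' @param lignin_depletion Lignin delta-13C depletion below bulk plant
#'   material, permil (default 4.3).
#' @param stage_mapping `data.frame(label, stage)`; defaults to
#'   [default_stage_mapping()].
#' @param alpha Significance level for the closure test (default 0.05).
#' @param seed Optional integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(depth_limit = 30, som_to_soc_factor = 2.0,
                       vsc_recovery = 0.38, lignin_depletion = 4.3,
                       stage_mapping = default_stage_mapping(),
                       alpha = 0.05, seed = NULL) {
  if (!is.numeric(depth_limit) || depth_limit <= 0) {
    config_error("config error: depth_limit must be > 0")
  }
  if (!is.numeric(som_to_soc_factor) || som_to_soc_factor <= 0) {
    config_error("config error: som_to_soc_factor must be > 0")
  }
  if (!is.numeric(vsc_recovery) || vsc_recovery <= 0 || vsc_recovery > 1) {
    config_error("config error: vsc_recovery must be in (0, 1]")
  }
  if (!is.numeric(lignin_depletion) || lignin_depletion < 0) {
    config_error("config error: lignin_depletion must be >= 0")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    config_error("config error: alpha must be in (0, 1)")
  }
  stopifnot(is.data.frame(stage_mapping),
            all(c("label", "stage") %in% names(stage_mapping)))
  structure(list(depth_limit = depth_limit,
                 som_to_soc_factor = som_to_soc_factor,
                 vsc_recovery = vsc_recovery,
                 lignin_depletion = lignin_depletion,
                 stage_mapping = stage_mapping,
                 alpha = alpha,
                 seed = seed),
            class = "run_config")
}

#' Read a YAML run configuration file
#'
#' Recognized keys match the [run_config()] arguments; `stage_mapping` may
#' be a path to a mapping CSV (resolved relative to the config file).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config error: file not found: %s", path)
  y <- yaml::read_yaml(path)
  known <- c("depth_limit", "som_to_soc_factor", "vsc_recovery",
             "lignin_depletion", "stage_mapping", "alpha", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    config_error("config error: unknown key(s): %s",
                 paste(unknown, collapse = ", "))
  }
  if (!is.null(y$stage_mapping) && is.character(y$stage_mapping)) {
    mp <- y$stage_mapping
    if (!file.exists(mp)) mp <- file.path(dirname(path), y$stage_mapping)
    y$stage_mapping <- read_stage_mapping(mp)
  }
  do.call(run_config, y)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config> depth_limit %g cm, SOM:SOC %g, ",
                     "VSC recovery %g, lignin depletion %g permil, alpha %g, ",
                     "%d stage-mapping entries\n"),
              x$depth_limit, x$som_to_soc_factor, x$vsc_recovery,
              x$lignin_depletion, x$alpha, nrow(x$stage_mapping)))
  invisible(x)
}

#' Echo a run configuration as header lines for result files
#' @param config A [run_config()].
#' @return Character vector suitable for `write_results(header_lines=)`.
#' @keywords internal
config_echo <- function(config) {
  c(sprintf("pastureSOC %s",
            as.character(utils::packageVersion("pastureSOC"))),
    sprintf("depth_limit=%g som_to_soc_factor=%g vsc_recovery=%g lignin_depletion=%g alpha=%g seed=%s",
            config$depth_limit, config$som_to_soc_factor, config$vsc_recovery,
            config$lignin_depletion, config$alpha,
            if (is.null(config$seed)) "NA" else format(config$seed)))
}
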
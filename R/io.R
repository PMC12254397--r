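#' Read and write cohort tables
#'
#' Cohorts are interchanged as tab-separated values with a header row,
#' matching biobank-style phenotype exports: missing values are empty fields,
#' no quoting, no binary formats.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a tibble with `subject_id` as character and all other columns numeric.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", na.strings = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  tibble::as_tibble(df)
}

#' Write a run manifest
#'
#' Every output directory gets a JSON manifest sufficient to re-run the
#' analysis bit-identically: the configuration echo, all seeds, package and R
#' versions, and the numerical conventions in force (propensity truncation,
#' probability clipping, winsorization quantile type).
#'
#' @param dir Output directory.
#' @param config Configuration list to echo.
#' @param extra Named list of additional entries.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, extra = list()) {
  cfg <- config
  # learner objects are closures; record their names only
  if (!is.null(cfg$library) && is.list(cfg$library) &&
      all(vapply(cfg$library, inherits, logical(1), "learner_spec"))) {
    cfg$library <- vapply(cfg$library, `[[`, character(1), "name")
  }
  cfg$beta <- NULL # trait coefficient tables echoed separately if needed
  manifest <- c(
    list(
      package = "mediscreen",
      package_version = as.character(utils::packageVersion("mediscreen")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      conventions = list(
        winsorization_quantile_type = 1,
        missing_value_encoding = "empty field",
        p_value_reference = "normal"
      ),
      config = cfg
    ),
    extra
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Run configurations are YAML files binding the pipeline together: input
#' path, trait specs, mediators, confounders, strata, estimands, Super
#' Learner library and folds, truncation, winsorization, FDR threshold,
#' multiplicity family mode, seeds and the output directory. Unknown learner
#' names error. See the packaged example
#' `system.file("examples", "run-config.yaml", package = "mediscreen")`.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

learner_by_name <- function(nm) {
  switch(nm,
         mean = lrn_mean(),
         glm = lrn_glm(),
         glm_interaction = lrn_glm_interaction(),
         glmnet = lrn_glmnet(),
         xgboost = lrn_xgboost(),
         gam = lrn_gam(),
         saturated = lrn_saturated(),
         abort(paste0("unknown learner name: ", nm),
               class = "mediscreen_config_error"))
}

as_run_config <- function(raw) {
  defaults <- list(
    input = NULL, traits = NULL, mediators = "activity",
    confounders = c("age", "sex"),
    strata = c("combined", "female", "male"),
    estimands = c("TE", "NDE", "NIE"),
    library = c("gam", "glmnet", "glm_interaction", "xgboost"),
    K = 10, cross_fit = TRUE, delta = 0.025, winsor = 0, fdr = 0.05,
    family_mode = "per-analysis", special_codes = c(-1, -3),
    seed = 1L, out_dir = "mediscreen-output"
  )
  unknown <- setdiff(names(raw), c(names(defaults), "simulate"))
  if (length(unknown)) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")),
          class = "mediscreen_config_error")
  }
  cfg <- utils::modifyList(defaults, raw)
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    abort("seed must be an integer", class = "mediscreen_config_error")
  }
  if (cfg$fdr <= 0 || cfg$fdr >= 1) {
    abort("fdr must lie in (0, 1)", class = "mediscreen_config_error")
  }
  structure(cfg, class = "run_config")
}

run_config_screen_config <- function(cfg, no_sl = FALSE,
                                     no_cross_fit = FALSE) {
  lib_names <- if (no_sl) "glmnet" else cfg$library
  screen_config(
    library = lapply(lib_names, learner_by_name),
    K = cfg$K,
    cross_fit = cfg$cross_fit && !no_cross_fit,
    delta = cfg$delta,
    winsor = cfg$winsor,
    fdr = cfg$fdr,
    family_mode = cfg$family_mode,
    special_codes = cfg$special_codes,
    seed = as.integer(cfg$seed)
  )
}

config_trait_specs <- function(cfg, cohort) {
  if (is.null(cfg$traits)) {
    reserved <- c("subject_id", "age", "sex", "A", "pem_flag", cfg$mediators)
    nm <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                  reserved)
    if (!length(nm)) {
      abort("no trait columns found in input", class = "mediscreen_config_error")
    }
    return(nm)
  }
  if (is.character(cfg$traits)) return(cfg$traits)
  # list form: each element a list(name, kind, composite, components, ...)
  lapply(cfg$traits, function(t) {
    do.call(trait_spec, t)
  })
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort (see [generate_cohort()]) and writes
#' `cohort.tsv`, `truth.tsv` (trait, TE, NDE, NIE) and a run manifest to the
#' output directory.
#'
#' @param sem A [sem_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
cmd_simulate <- function(sem = sem_config(), out_dir = "mediscreen-output") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(sem)
  cohort_path <- file.path(out_dir, "cohort.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_cohort(sim$cohort, cohort_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  sem_echo <- unclass(sem)
  sem_echo$beta <- NULL
  sem_echo$gamma <- as.list(sem$gamma)
  sem_echo$alpha <- as.list(sem$alpha)
  manifest <- write_manifest(out_dir, sem_echo,
                             extra = list(command = "simulate",
                                          n_rows = nrow(sim$cohort),
                                          n_traits = nrow(sim$truth)))
  inform(sprintf("wrote %d subjects, %d traits to %s",
                 nrow(sim$cohort), nrow(sim$truth), out_dir))
  invisible(list(cohort = cohort_path, truth = truth_path,
                 manifest = manifest))
}

#' Run the screening workflow from a configuration
#'
#' Reads the input cohort, validates that every configured column exists,
#' runs [run_screen()], and writes `results.tsv` plus a manifest. Traits
#' that fail to estimate appear as rows with missing estimates; the manifest
#' counts the warnings.
#'
#' @param config A `run_config` (from [read_run_config()]) or path to a YAML
#'   config file.
#' @param no_sl Reduce the learner library to the penalised GLM alone (the
#'   no-Super-Learner baseline).
#' @param no_cross_fit Disable cross-fitting.
#' @param out_dir Override the config's output directory.
#' @return The `trait_results` tibble, invisibly.
#' @export
cmd_screen <- function(config, no_sl = FALSE, no_cross_fit = FALSE,
                       out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) {
    abort("config must name an input cohort file",
          class = "mediscreen_config_error")
  }
  cohort <- read_cohort(config$input)
  needed <- c(config$confounders, "A", config$mediators)
  if (any(c("NDE", "NIE") %in% config$estimands)) {
    missing_cols <- setdiff(needed, names(cohort))
  } else {
    missing_cols <- setdiff(c(config$confounders, "A"), names(cohort))
  }
  if (length(missing_cols)) {
    abort(paste0("input is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mediscreen_config_error")
  }
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  specs <- config_trait_specs(config, cohort)
  scfg <- run_config_screen_config(config, no_sl = no_sl,
                                   no_cross_fit = no_cross_fit)
  n_warn <- 0L
  results <- withCallingHandlers(
    run_screen(cohort, specs, mediators = config$mediators,
               strata = config$strata, estimands = config$estimands,
               config = scfg, confounders = config$confounders),
    warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    }
  )
  utils::write.table(results, file.path(out_dir, "results.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)
  cfg_echo <- unclass(config)
  write_manifest(out_dir, c(cfg_echo, unclass(scfg)["delta"],
                            list(no_sl = no_sl, no_cross_fit = no_cross_fit)),
                 extra = list(command = "screen", n_rows = nrow(results),
                              n_warnings = n_warn))
  inform(sprintf("wrote %d result rows to %s (%d warnings)",
                 nrow(results), out_dir, n_warn))
  invisible(results)
}

#' Summarise one or more screening result tables
#'
#' With one table, reports significant-trait counts per multiplicity family.
#' With two or more, additionally computes pairwise z-score concordance
#' (tables must share their trait set) and effect-fraction summaries.
#'
#' @param results_paths Character vector of `results.tsv` paths, or a list of
#'   `trait_results` tibbles.
#' @param estimand Estimand used for the concordance pairing.
#' @return List with `counts` (significant traits per family per table),
#'   `concordance` (tibble of pairwise Pearson r, or `NULL` for one table)
#'   and `fractions` (per-table mean |NDE|/|NIE| fraction summary).
#' @export
cmd_report <- function(results_paths, estimand = "TE") {
  tables <- lapply(results_paths, function(x) {
    if (is.character(x)) {
      tibble::as_tibble(utils::read.delim(x, sep = "\t", na.strings = "",
                                          stringsAsFactors = FALSE))
    } else {
      x
    }
  })
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("table_", seq_along(tables))
  }
  schema <- c("trait", "stratum", "mediator", "estimand", "z", "p_adj",
              "significant")
  for (nm in names(tables)) {
    missing_cols <- setdiff(schema, names(tables[[nm]]))
    if (length(missing_cols)) {
      abort(paste0(nm, " is missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            class = "mediscreen_input_error")
    }
  }
  counts <- dplyr::bind_rows(lapply(names(tables), function(nm) {
    tables[[nm]] |>
      dplyr::group_by(.data$stratum, .data$estimand, .data$mediator) |>
      dplyr::summarise(n_significant = sum(.data$significant, na.rm = TRUE),
                       n_traits = dplyr::n_distinct(.data$trait),
                       .groups = "drop") |>
      dplyr::mutate(table = nm, .before = 1)
  }))
  concordance <- NULL
  if (length(tables) >= 2) {
    pairs <- utils::combn(names(tables), 2, simplify = FALSE)
    concordance <- dplyr::bind_rows(lapply(pairs, function(pr) {
      a <- tables[[pr[1]]]
      b <- tables[[pr[2]]]
      if (!setequal(unique(a$trait), unique(b$trait))) {
        abort(sprintf("tables '%s' and '%s' have disjoint or mismatched trait sets",
                      pr[1], pr[2]),
              class = "mediscreen_input_error")
      }
      conc <- zscore_concordance(a, b, estimand = estimand, labels = pr)
      dplyr::mutate(glance(conc), table_a = pr[1], table_b = pr[2],
                    .before = 1)
    }))
  }
  fractions <- dplyr::bind_rows(lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    if (!"nde_fraction" %in% names(tb)) return(NULL)
    tb |>
      dplyr::filter(.data$estimand == "NDE", !is.na(.data$nde_fraction)) |>
      dplyr::summarise(
        table = nm,
        n_traits = dplyr::n(),
        mean_nde_fraction = mean(.data$nde_fraction),
        mean_nie_fraction = mean(.data$nie_fraction)
      )
  }))
  list(counts = counts, concordance = concordance, fractions = fractions)
}
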
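well_columns <- c("fish_id", "compound", "well_role", "time_h", "replicate",
                  "concentration_ug_per_L")
well_roles <- c("exposure", "solvent_control", "medium_control")

#' Read a tidy well-measurement CSV
#'
#' Expects the schema written by [write_wells()] /
#' `simulate`: one row per well per time point with columns `fish_id`,
#' `compound`, `well_role`, `time_h`, `replicate`,
#' `concentration_ug_per_L`. Extra columns are preserved untouched.
#' Validation errors name the offending data row.
#'
#' @param path CSV file path.
#' @return Tibble of typed well measurements.
#' @export
read_wells <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(well_columns, names(w))
  if (length(missing) > 0L) {
    stop("wells file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w$fish_id <- as.character(w$fish_id)
  w$compound <- as.character(w$compound)
  w$well_role <- as.character(w$well_role)
  w$time_h <- suppressWarnings(as.numeric(w$time_h))
  w$concentration_ug_per_L <- suppressWarnings(as.numeric(w$concentration_ug_per_L))

  fail_row <- function(cond, what) {
    if (any(cond)) {
      stop("wells file '", path, "': ", what, " on row ", which(cond)[1],
           call. = FALSE)
    }
  }
  fail_row(!is.finite(w$time_h) | w$time_h < 0, "unparseable or negative time_h")
  fail_row(!is.finite(w$concentration_ug_per_L) | w$concentration_ug_per_L < 0,
           "negative or unparseable concentration")
  fail_row(!(w$well_role %in% well_roles),
           paste0("well_role not one of {", paste(well_roles, collapse = ", "), "}"))
  w
}

#' Write well measurements to CSV
#'
#' @param wells Well-measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  readr::write_csv(wells[, c(well_columns, setdiff(names(wells), well_columns))],
                   path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param out_dir Directory for all output artifacts (created if needed).
#' @param wells_path Input wells CSV; `NULL` to simulate instead.
#' @param sim_config [simulation_config()] used when simulating.
#' @param factors [scaling_factors()].
#' @param alpha Significance level for NSD classification and Tukey HSD.
#' @param clearance_mode `"paper_literal"` or `"volume_corrected"`.
#' @param compounds_path Optional compound-profile CSV for read-across
#'   (default: the packaged seven-compound table; `NA` disables the stage).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            wells_path = NULL,
                            sim_config = simulation_config(),
                            factors = scaling_factors(),
                            alpha = 0.05,
                            clearance_mode = "paper_literal",
                            compounds_path = system.file("extdata", "compounds.csv",
                                                         package = "spheroclear")) {
  structure(
    list(out_dir = out_dir, wells_path = wells_path, sim_config = sim_config,
         factors = factors, alpha = alpha, clearance_mode = clearance_mode,
         compounds_path = compounds_path),
    class = "pipeline_config"
  )
}

#' Run the full substrate-depletion analysis pipeline
#'
#' Simulate (or read) well measurements, fit per-fish depletion kinetics
#' with NSD classification, scale to intrinsic clearance, summarise the
#' cohort with ANOVA/Tukey compact letters per compound, optionally score
#' read-across concordance, and write every artifact plus a JSON run
#' manifest to `config$out_dir`. Re-running on identical inputs reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list of the in-memory artifacts: `wells`, `fits`,
#'   `clearance`, `summary`, `tukey`, `concordance`, `manifest`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  if (is.null(config$wells_path)) {
    sim <- simulate_cohort(config$sim_config)
    wells <- sim$wells
    write_wells(wells, out("wells.csv"))
    readr::write_csv(sim$truth, out("true_parameters.csv"), progress = FALSE)
  } else {
    wells <- read_wells(config$wells_path)
  }

  fits <- fit_all(wells, alpha = config$alpha)
  readr::write_csv(fits, out("fits.csv"), progress = FALSE)

  cl <- clearance_table(fits, config$factors, config$clearance_mode)
  readr::write_csv(cl, out("clearance.csv"), progress = FALSE)

  summary_tbl <- summarize_cohort(fits)
  readr::write_csv(summary_tbl, out("summary.csv"), progress = FALSE)

  tukey <- list()
  for (cmp in unique(fits$compound[!(fits$nsd %in% TRUE)])) {
    pw <- per_well_depletion(wells, cmp)
    pw <- pw[pw$percent_depletion > 0, , drop = FALSE]
    if (length(unique(pw$fish_id)) >= 2L && all(table(pw$fish_id) >= 2L)) {
      tukey[[cmp]] <- anova_ln_depletion(pw, alpha = config$alpha)
    }
  }
  if (length(tukey) > 0L) {
    letters_tbl <- dplyr::bind_rows(
      lapply(names(tukey), function(cmp) {
        dplyr::mutate(tukey[[cmp]]$letters, compound = cmp, .before = 1)
      })
    )
    pairwise_tbl <- dplyr::bind_rows(
      lapply(names(tukey), function(cmp) {
        dplyr::mutate(tukey[[cmp]]$pairwise, compound = cmp, .before = 1)
      })
    )
    readr::write_csv(letters_tbl, out("tukey_letters.csv"), progress = FALSE)
    readr::write_csv(pairwise_tbl, out("tukey_pairwise.csv"), progress = FALSE)
  }

  conc <- NULL
  if (!is.null(config$compounds_path) && !is.na(config$compounds_path) &&
      nzchar(config$compounds_path) && file.exists(config$compounds_path)) {
    profiles <- read_compound_profiles(config$compounds_path)
    conc <- concordance_table(profiles, species_cyp_inventory())
    readr::write_csv(conc$table, out("concordance.csv"), progress = FALSE)
  }

  manifest <- list(
    package = "spheroclear",
    version = as.character(utils::packageVersion("spheroclear")),
    simulated = is.null(config$wells_path),
    seed = if (is.null(config$wells_path)) config$sim_config$seed else NULL,
    alpha = config$alpha,
    clearance_mode = config$clearance_mode,
    n_wells = nrow(wells),
    n_fits = nrow(fits),
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(wells = wells, fits = fits, clearance = cl,
                 summary = summary_tbl, tukey = tukey, concordance = conc,
                 manifest = manifest))
}

# Stable fingerprint of the pipeline configuration (md5 of its canonical
# JSON serialisation); changes iff the configuration changes.
config_hash <- function(config) {
  ser <- jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                          digits = NA, null = "null")
  unname(tools::md5sum(textConnection_md5(ser)))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

# md5sum() wants a file; spool the string through a tempfile
textConnection_md5 <- function(txt) {
  f <- tempfile(fileext = ".json")
  writeLines(txt, f)
  f
}
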
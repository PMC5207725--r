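#' Simulation configuration for a plate-based substrate-depletion experiment
#'
#' Builds and validates the configuration object that drives
#' [simulate_fish()] and [simulate_cohort()]. Defaults emulate a 96-well
#' spheroid depletion assay: rows of 6 exposure + 3 solvent-control +
#' 3 medium-control wells quenched at 0, 0.5, 1, 2, 4 and 24 h, 100 spheroids
#' (about 50,000 hepatocytes) per well in 75 uL, a measured time-zero dose of
#' 98 +/- 4 ug/L against a 100 ug/L nominal dose, per-fish first-order
#' depletion rate constants with mean 0.022 h^-1 and SD 0.010 h^-1
#' (propranolol-like inter-individual spread), and 10% multiplicative
#' measurement noise.
#'
#' Per-fish rate constants are drawn from a lognormal distribution
#' moment-matched to `k_mean_h` and `k_sd_h`, which keeps every draw
#' positive. Measurement error is multiplicative lognormal with unit mean
#' and coefficient of variation `measurement_cv`, the usual error structure
#' for LC-MS/MS quantification where error scales with signal.
#'
#' @param n_fish Number of fish (one independent spheroid batch each).
#' @param time_points_h Strictly increasing sampling times in hours; must
#'   include 0.
#' @param n_exposure_wells,n_solvent_wells,n_medium_wells Replicate wells per
#'   time point for each well role.
#' @param nominal_dose_ug_per_L Nominal dose (ug/L), recorded for provenance.
#' @param dose_mean_ug_per_L,dose_sd_ug_per_L Mean and SD of the measured
#'   time-zero concentration (ug/L); per-fish true C0 is Normal with these
#'   moments.
#' @param k_mean_h,k_sd_h Mean and SD (h^-1) of the per-fish true depletion
#'   rate constant.
#' @param measurement_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise; in `[0, 1)`.
#' @param abiotic_loss_rate_h First-order loss rate (h^-1) applied to
#'   cell-free medium-control wells (evaporation/sorption); default 0 for
#'   sealed plates.
#' @param compound Compound name carried on every simulated well.
#' @param seed Integer root seed. Each fish consumes an independent
#'   sub-stream derived by stable hashing of `(seed, fish_id)`, so fish `i`
#'   is reproducible regardless of how many fish are simulated.
#'
#' @return A list of class `"simulation_config"`.
#' @export
#' @examples
#' cfg <- simulation_config(n_fish = 2, seed = 1)
#' sim <- simulate_cohort(cfg)
#' head(sim$wells)
simulation_config <- function(n_fish = 12,
                              time_points_h = c(0, 0.5, 1, 2, 4, 24),
                              n_exposure_wells = 6,
                              n_solvent_wells = 3,
                              n_medium_wells = 3,
                              nominal_dose_ug_per_L = 100,
                              dose_mean_ug_per_L = 98,
                              dose_sd_ug_per_L = 4,
                              k_mean_h = 0.022,
                              k_sd_h = 0.010,
                              measurement_cv = 0.10,
                              abiotic_loss_rate_h = 0,
                              compound = "propranolol",
                              seed = 1L) {
  cfg <- list(
    n_fish = as.integer(n_fish),
    time_points_h = as.numeric(time_points_h),
    n_exposure_wells = as.integer(n_exposure_wells),
    n_solvent_wells = as.integer(n_solvent_wells),
    n_medium_wells = as.integer(n_medium_wells),
    nominal_dose_ug_per_L = as.numeric(nominal_dose_ug_per_L),
    dose_mean_ug_per_L = as.numeric(dose_mean_ug_per_L),
    dose_sd_ug_per_L = as.numeric(dose_sd_ug_per_L),
    k_mean_h = as.numeric(k_mean_h),
    k_sd_h = as.numeric(k_sd_h),
    measurement_cv = as.numeric(measurement_cv),
    abiotic_loss_rate_h = as.numeric(abiotic_loss_rate_h),
    compound = as.character(compound),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  counts <- c(cfg$n_fish, cfg$n_exposure_wells, cfg$n_solvent_wells, cfg$n_medium_wells)
  if (any(!is.finite(counts)) || any(counts < 1L)) {
    stop_cfg("all well/fish counts must be >= 1")
  }
  tp <- cfg$time_points_h
  if (length(tp) < 2L || any(!is.finite(tp)) || any(diff(tp) <= 0) || tp[1] != 0) {
    stop_cfg("time points must be strictly increasing, start at 0, length >= 2")
  }
  if (!is.finite(cfg$k_mean_h) || cfg$k_mean_h < 0) stop_cfg("k_mean_h must be >= 0")
  if (!is.finite(cfg$k_sd_h) || cfg$k_sd_h < 0) stop_cfg("k_sd_h must be >= 0")
  if (!is.finite(cfg$measurement_cv) || cfg$measurement_cv < 0 || cfg$measurement_cv >= 1) {
    stop_cfg("measurement_cv must lie in [0, 1)")
  }
  if (!is.finite(cfg$dose_mean_ug_per_L) || cfg$dose_mean_ug_per_L <= 0) {
    stop_cfg("dose_mean_ug_per_L must be positive")
  }
  if (!is.finite(cfg$dose_sd_ug_per_L) || cfg$dose_sd_ug_per_L < 0) {
    stop_cfg("dose_sd_ug_per_L must be >= 0")
  }
  if (!is.finite(cfg$abiotic_loss_rate_h) || cfg$abiotic_loss_rate_h < 0) {
    stop_cfg("abiotic_loss_rate_h must be >= 0")
  }
  if (!is.finite(cfg$seed)) stop_cfg("seed must be a finite integer")
  invisible(cfg)
}

# Stable 31-ary string hash folded with the root seed, kept below 2^31 - 1.
# Gives each (seed, fish_id) pair its own reproducible RNG sub-stream.
substream_seed <- function(seed, fish_id) {
  m <- 2147483647
  h <- (as.double(seed) %% m + 5381) %% m
  for (ch in utf8ToInt(as.character(fish_id))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so simulation never perturbs user code.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Lognormal (meanlog, sdlog) matched to an arithmetic mean and SD.
lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Draw repeatedly from `draw()` until the value is finite and positive;
# deterministic given the RNG state.
draw_positive <- function(draw, what) {
  for (i in 1:100) {
    x <- draw()
    if (is.finite(x) && x > 0) return(x)
  }
  stop("could not draw a finite positive value for ", what, call. = FALSE)
}

#' Simulate all wells for one fish
#'
#' Draws the fish's true depletion rate constant and true time-zero
#' concentration, then generates every well of the plate design in
#' `config`: exposure wells follow `C0 * exp(-k * t)` under multiplicative
#' lognormal noise, medium controls (compound, no spheroids) decay at
#' `abiotic_loss_rate_h` under the same noise model, and solvent controls
#' (spheroids, no compound) are emitted with concentration 0 so that real
#' plate exports with this layout parse identically.
#'
#' @param config A [simulation_config()].
#' @param fish_id Identifier for the fish; also selects the RNG sub-stream.
#'
#' @return A list with `wells` (tibble, one row per well per time point:
#'   `fish_id`, `compound`, `well_role`, `time_h`, `replicate`,
#'   `concentration_ug_per_L`) and `truth` (one-row tibble of
#'   `fish_id`, `true_k_h`, `true_C0_ug_per_L`, kept for
#'   parameter-recovery tests).
#' @export
simulate_fish <- function(config, fish_id) {
  validate_simulation_config(config)
  with_local_seed(substream_seed(config$seed, fish_id), {
    true_k <- if (config$k_sd_h == 0) {
      config$k_mean_h
    } else {
      lp <- lognormal_params(config$k_mean_h, config$k_sd_h)
      draw_positive(function() stats::rlnorm(1, lp$meanlog, lp$sdlog), "true_k")
    }
    true_c0 <- if (config$dose_sd_ug_per_L == 0) {
      config$dose_mean_ug_per_L
    } else {
      draw_positive(
        function() stats::rnorm(1, config$dose_mean_ug_per_L, config$dose_sd_ug_per_L),
        "true_C0"
      )
    }

    noise <- if (config$measurement_cv == 0) {
      function(n) rep(1, n)
    } else {
      np <- lognormal_params(1, config$measurement_cv)
      function(n) stats::rlnorm(n, np$meanlog, np$sdlog)
    }

    n_e <- config$n_exposure_wells
    n_s <- config$n_solvent_wells
    n_m <- config$n_medium_wells
    tp <- config$time_points_h
    # one noise draw per measured well, in plate order (per time point:
    # exposure wells first, then medium controls)
    eps <- matrix(noise((n_e + n_m) * length(tp)), nrow = n_e + n_m)
    per_t <- function(i) {
      t <- tp[i]
      expo <- true_c0 * exp(-true_k * t) * eps[seq_len(n_e), i]
      med <- true_c0 * exp(-config$abiotic_loss_rate_h * t) * eps[n_e + seq_len(n_m), i]
      c(expo, rep(0, n_s), med)
    }
    conc <- unlist(lapply(seq_along(tp), per_t))
    wells <- tibble::tibble(
      fish_id = as.character(fish_id),
      compound = config$compound,
      well_role = rep(
        rep(c("exposure", "solvent_control", "medium_control"), c(n_e, n_s, n_m)),
        length(tp)
      ),
      time_h = rep(tp, each = n_e + n_s + n_m),
      replicate = rep(c(seq_len(n_e), seq_len(n_s), seq_len(n_m)), length(tp)),
      concentration_ug_per_L = conc
    )

    list(
      wells = wells,
      truth = tibble::tibble(
        fish_id = as.character(fish_id),
        true_k_h = true_k,
        true_C0_ug_per_L = true_c0
      )
    )
  })
}

#' Simulate a cohort of fish
#'
#' Concatenates [simulate_fish()] over `config$n_fish` fish with ids
#' `"fish_01"`, `"fish_02"`, ... Each fish uses its own RNG sub-stream, so
#' the wells of fish `i` are identical whether 1 or 1000 fish are simulated.
#'
#' @param config A [simulation_config()].
#' @return A list with `wells` (all fish stacked) and `truth` (one row per
#'   fish).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  ids <- cohort_fish_ids(config$n_fish)
  sims <- lapply(ids, function(id) simulate_fish(config, id))
  list(
    wells = dplyr::bind_rows(lapply(sims, `[[`, "wells")),
    truth = dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  )
}

cohort_fish_ids <- function(n_fish) {
  sprintf("fish_%02d", seq_len(n_fish))
}
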
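#' Fit first-order depletion kinetics for one fish x compound
#'
#' Nonlinear least-squares fit of the two-parameter exponential decay
#' `C(t) = a * exp(-k * t)` to all individual exposure-well measurements
#' (not per-time-point means), with `k` constrained non-negative: the
#' biology admits no negative depletion, and apparently increasing time
#' courses are handled by NSD classification rather than by a negative rate.
#'
#' Initialisation uses the time-zero mean for `a` and the negated slope of
#' `ln(mean concentration)` versus time for `k` (floored at a small
#' positive value), with a fixed fallback of `k0 = 0.01` h^-1 if the
#' log-linear start is unusable. Fitting is bounded Levenberg-Marquardt
#' (`minpack.lm::nlsLM`).
#'
#' @param wells Tibble of well measurements (see [simulate_fish()] /
#'   [read_wells()] for the schema). Only `well_role == "exposure"` rows for
#'   the requested fish and compound are used.
#' @param fish_id,compound Select the time course to fit.
#'
#' @return A one-row tibble of class `"depletion_fit"`: fitted
#'   `a_ug_per_L`, `k_h`, `k_se_h`, derived `t_half_h` (`ln 2 / k`; `NA`
#'   when `k = 0`), `percent_depletion` over the incubation,
#'   `incubation_end_h`, `rss`, `n_points`, and `nsd = NA` (set by
#'   [classify_nsd()]).
#' @export
#' @examples
#' cfg <- simulation_config(n_fish = 1, measurement_cv = 0, dose_sd_ug_per_L = 0,
#'                          k_sd_h = 0, k_mean_h = 0.02, seed = 7)
#' sim <- simulate_fish(cfg, "fish_01")
#' fit_depletion(sim$wells, "fish_01", "propranolol")
fit_depletion <- function(wells, fish_id, compound) {
  ew <- wells[wells$well_role == "exposure" &
                wells$fish_id == fish_id &
                wells$compound == compound, , drop = FALSE]
  if (nrow(ew) == 0L) {
    stop("no exposure wells for fish '", fish_id, "', compound '", compound, "'",
         call. = FALSE)
  }
  tp <- sort(unique(ew$time_h))
  if (length(tp) < 3L) {
    stop("need >= 3 distinct time points to fit depletion (got ", length(tp), ")",
         call. = FALSE)
  }
  if (min(tp) != 0) stop("time 0 must be present in the exposure wells", call. = FALSE)

  t <- ew$time_h
  y <- ew$concentration_ug_per_L
  means <- tapply(y, t, mean)
  mt <- as.numeric(names(means))
  a0 <- unname(means[mt == 0])

  # log-linear start: OLS slope of ln(mean C) vs t over positive means
  pos <- means > 0
  k0 <- 0.01
  if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(means[pos]) ~ mt[pos]))[2]
    if (is.finite(sl)) k0 <- max(1e-6, -sl)
  }
  if (!is.finite(a0) || a0 <= 0) a0 <- max(mean(y), 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-k * t),
      start = list(a = a0, k = k0),
      lower = c(a = 1e-12, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-k * t),
        start = list(a = max(mean(y), 1e-6), k = 0.01),
        lower = c(a = 1e-12, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) {
        stop("depletion fit failed for fish '", fish_id, "', compound '",
             compound, "': ", conditionMessage(e), call. = FALSE)
      }
    )
  }

  cf <- stats::coef(fit)
  k_se <- tryCatch(sqrt(stats::vcov(fit)["k", "k"]), error = function(e) NA_real_)
  end_h <- max(tp)
  pct <- percent_depletion(wells, fish_id, compound, end_h)

  tibble::new_tibble(
    tibble::tibble(
      fish_id = as.character(fish_id),
      compound = as.character(compound),
      a_ug_per_L = unname(cf["a"]),
      k_h = unname(cf["k"]),
      k_se_h = k_se,
      t_half_h = if (cf["k"] > 0) log(2) / unname(cf["k"]) else NA_real_,
      percent_depletion = pct,
      nsd = NA,
      incubation_end_h = end_h,
      rss = sum(stats::resid(fit)^2),
      n_points = length(y)
    ),
    class = "depletion_fit"
  )
}

#' Fit every fish x compound time course in a well table
#'
#' @param wells Well-measurement tibble.
#' @param alpha Significance level for NSD classification; `NULL` skips
#'   classification.
#' @return Tibble with one [fit_depletion()] row per fish x compound, with
#'   `nsd` filled in via [classify_nsd()] when `alpha` is given.
#' @export
fit_all <- function(wells, alpha = 0.05) {
  combos <- unique(wells[wells$well_role == "exposure", c("fish_id", "compound")])
  fits <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    f <- fit_depletion(wells, combos$fish_id[i], combos$compound[i])
    if (!is.null(alpha)) {
      mc <- wells[wells$well_role == "medium_control" &
                    wells$fish_id == combos$fish_id[i] &
                    wells$compound == combos$compound[i], , drop = FALSE]
      f$nsd <- classify_nsd(f, wells, medium_controls = mc, alpha = alpha)
    }
    f
  }))
  fits
}

#' Half-life under first-order kinetics
#'
#' @param k_h Depletion rate constant (h^-1), strictly positive.
#' @return `ln(2) / k_h`, in hours.
#' @export
#' @examples
#' half_life(0.022)
half_life <- function(k_h) {
  if (!is.numeric(k_h) || any(!is.finite(k_h)) || any(k_h <= 0)) {
    stop("half_life() requires k_h > 0; check the NSD flag first", call. = FALSE)
  }
  log(2) / k_h
}

#' Percent depletion over the incubation window
#'
#' `100 * (1 - mean C(end) / mean C(0))` over exposure wells. May be
#' negative on noisy null data; it is then reported as computed.
#'
#' @param wells Well-measurement tibble.
#' @param fish_id,compound Time course selector.
#' @param end_h End of the incubation window (hours); defaults to the last
#'   exposure time point present.
#' @return Percent loss of parent compound.
#' @export
percent_depletion <- function(wells, fish_id, compound, end_h = NULL) {
  ew <- wells[wells$well_role == "exposure" &
                wells$fish_id == fish_id &
                wells$compound == compound, , drop = FALSE]
  if (is.null(end_h)) end_h <- max(ew$time_h)
  c0 <- ew$concentration_ug_per_L[ew$time_h == 0]
  cend <- ew$concentration_ug_per_L[ew$time_h == end_h]
  if (length(c0) == 0L || length(cend) == 0L) {
    stop("exposure wells required at time 0 and at end_h = ", end_h, call. = FALSE)
  }
  100 * (1 - mean(cend) / mean(c0))
}

#' Classify a fit as "no substrate depletion" (NSD)
#'
#' A compound is flagged NSD for a fish when the fitted rate constant is not
#' significantly greater than zero (one-sided Wald t-test at `alpha`), or
#' when the loss in exposure wells does not exceed the abiotic loss in
#' cell-free medium-control wells over the same window (one-sided Welch
#' t-test on per-well endpoint fractional loss at `alpha`). Without medium
#' controls only the rate-significance criterion is applied, with a
#' warning.
#'
#' @param fit A [fit_depletion()] row.
#' @param wells Well table holding the exposure wells behind `fit`.
#' @param medium_controls Medium-control rows for the same fish x compound
#'   (may be empty).
#' @param alpha Significance level (default 0.05).
#' @return Logical: `TRUE` when no depletion is demonstrable.
#' @export
classify_nsd <- function(fit, wells, medium_controls = NULL, alpha = 0.05) {
  # criterion 1: k significantly > 0
  k_sig <- FALSE
  if (fit$k_h > 0 && is.finite(fit$k_se_h) && fit$k_se_h > 0) {
    tstat <- fit$k_h / fit$k_se_h
    p_k <- stats::pt(tstat, df = max(fit$n_points - 2L, 1L), lower.tail = FALSE)
    k_sig <- p_k < alpha
  } else if (fit$k_h > 0 && is.finite(fit$k_se_h) && fit$k_se_h == 0) {
    k_sig <- TRUE # noise-free fit: depletion exact
  }
  if (!k_sig) return(TRUE)

  if (is.null(medium_controls) || nrow(medium_controls) == 0L) {
    warning("no medium controls: NSD classification uses the k-significance ",
            "criterion alone", call. = FALSE)
    return(FALSE)
  }

  # criterion 2: exposure loss must exceed medium-control (abiotic) loss
  end_h <- fit$incubation_end_h
  ew <- wells[wells$well_role == "exposure" &
                wells$fish_id == fit$fish_id &
                wells$compound == fit$compound, , drop = FALSE]
  exp_loss <- endpoint_fractional_loss(ew, end_h)
  med_loss <- endpoint_fractional_loss(medium_controls, end_h)
  if (is.null(exp_loss) || is.null(med_loss)) {
    warning("medium controls lack both endpoints: NSD classification uses ",
            "the k-significance criterion alone", call. = FALSE)
    return(FALSE)
  }
  v <- stats::var(exp_loss) + stats::var(med_loss)
  if (!is.finite(v) || v == 0) {
    return(!(mean(exp_loss) > mean(med_loss)))
  }
  p_w <- stats::t.test(exp_loss, med_loss, alternative = "greater")$p.value
  !(p_w < alpha)
}

# Per-well fractional loss at end_h relative to the group's time-zero mean.
endpoint_fractional_loss <- function(w, end_h) {
  c0 <- w$concentration_ug_per_L[w$time_h == 0]
  cend <- w$concentration_ug_per_L[w$time_h == end_h]
  if (length(c0) == 0L || length(cend) == 0L || mean(c0) <= 0) return(NULL)
  1 - cend / mean(c0)
}
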
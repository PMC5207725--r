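#' Cohort summary of per-fish depletion fits
#'
#' Mean and sample SD (n - 1 denominator) of percent depletion, rate
#' constant and half-life across the non-NSD fish of each compound. The
#' mean half-life is the mean of the per-fish half-lives, not
#' `ln(2) / mean(k)` — the two differ whenever k varies between fish.
#'
#' @param fits Tibble of depletion fits ([fit_all()] output, or any tibble
#'   with `compound`, `percent_depletion`, `k_h`, `t_half_h` and optionally
#'   `nsd`).
#' @return Tibble, one row per compound: `n_fish`, `mean_percent`,
#'   `sd_percent`, `mean_k_h`, `sd_k_h`, `mean_t_half_h`, `sd_t_half_h`,
#'   `all_nsd`. Compounds where every fish is NSD carry `all_nsd = TRUE`
#'   and `NA` kinetic aggregates.
#' @export
summarize_cohort <- function(fits) {
  if (!"nsd" %in% names(fits)) fits$nsd <- FALSE
  fits$nsd[is.na(fits$nsd)] <- FALSE
  dplyr::group_by(fits, .data$compound) |>
    dplyr::summarise(
      n_fish = sum(!.data$nsd),
      all_nsd = all(.data$nsd),
      mean_percent = if (all(.data$nsd)) NA_real_ else mean(.data$percent_depletion[!.data$nsd]),
      sd_percent = if (all(.data$nsd)) NA_real_ else stats::sd(.data$percent_depletion[!.data$nsd]),
      mean_k_h = if (all(.data$nsd)) NA_real_ else mean(.data$k_h[!.data$nsd]),
      sd_k_h = if (all(.data$nsd)) NA_real_ else stats::sd(.data$k_h[!.data$nsd]),
      mean_t_half_h = if (all(.data$nsd)) NA_real_ else mean(.data$t_half_h[!.data$nsd]),
      sd_t_half_h = if (all(.data$nsd)) NA_real_ else stats::sd(.data$t_half_h[!.data$nsd]),
      .groups = "drop"
    )
}

#' Per-well percent depletion for inter-individual comparison
#'
#' Computes, for each exposure well at the end of the incubation, the
#' percent loss relative to that fish's time-zero exposure mean. This is
#' the per-well observational unit fed into [anova_ln_depletion()].
#'
#' @param wells Well-measurement tibble.
#' @param compound Compound to extract.
#' @param end_h Endpoint (hours); default: last exposure time point.
#' @return Tibble with `fish_id` and `percent_depletion` (one row per
#'   endpoint exposure well).
#' @export
per_well_depletion <- function(wells, compound, end_h = NULL) {
  ew <- wells[wells$well_role == "exposure" & wells$compound == compound, ,
              drop = FALSE]
  if (is.null(end_h)) end_h <- max(ew$time_h)
  dplyr::group_by(ew, .data$fish_id) |>
    dplyr::reframe(
      percent_depletion = 100 *
        (1 - .data$concentration_ug_per_L[.data$time_h == end_h] /
           mean(.data$concentration_ug_per_L[.data$time_h == 0]))
    )
}

#' One-way ANOVA with Tukey HSD and compact letters on ln(% depletion)
#'
#' Tests inter-individual (fish-to-fish) differences in metabolic rate:
#' one-way ANOVA on the natural log of per-well percent depletion, followed
#' by all pairwise Tukey HSD comparisons at `alpha`, summarised as a
#' compact letter display. Two fish share a letter if and only if their
#' Tukey-adjusted difference is not significant; letters run A, B, ... in
#' decreasing order of group mean. Non-positive percent values cannot be
#' log-transformed and are dropped with a warning (the count is recorded).
#'
#' The ANOVA and Tukey comparisons use `stats::aov()`/`stats::TukeyHSD()`
#' (Tukey-Kramer on unbalanced data); the letter display is built by
#' insertion-absorption from the pairwise significance matrix, so it is
#' deterministic given the data.
#'
#' @param per_well Tibble with `fish_id` and `percent_depletion`
#'   (see [per_well_depletion()]).
#' @param alpha Familywise significance level (default 0.05).
#' @return A list of class `"tukey_grouping"`: `letters` (tibble of
#'   `fish_id`, `group_letters`, `mean_ln_percent`), `pairwise` (long
#'   tibble of Tukey-adjusted p-values), `F_statistic`, `anova_p`,
#'   `n_excluded_nonpositive`, `alpha`.
#' @export
anova_ln_depletion <- function(per_well, alpha = 0.05) {
  bad <- !is.finite(per_well$percent_depletion) | per_well$percent_depletion <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive %-depletion value(s) excluded from the ",
            "ln-scale ANOVA", call. = FALSE)
    per_well <- per_well[!bad, , drop = FALSE]
  }
  fish <- unique(per_well$fish_id)
  if (length(fish) < 2L) stop("need >= 2 fish for the ANOVA", call. = FALSE)
  counts <- table(per_well$fish_id)
  if (any(counts < 2L)) {
    stop("need >= 2 wells per fish for the ANOVA; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }

  d <- data.frame(
    ln_pct = log(per_well$percent_depletion),
    fish = factor(per_well$fish_id, levels = fish)
  )
  fit <- stats::aov(ln_pct ~ fish, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$fish

  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- tibble::tibble(
    fish_a = vapply(pairs, `[`, character(1), 1),
    fish_b = vapply(pairs, `[`, character(1), 2),
    diff_ln = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )

  means <- tapply(d$ln_pct, d$fish, mean)
  sig <- pairwise_significance_matrix(fish, pairwise, alpha)
  letters <- compact_letter_display(means[fish], sig)

  structure(
    list(
      letters = tibble::tibble(
        fish_id = fish,
        group_letters = letters,
        mean_ln_percent = as.numeric(means[fish])
      ),
      pairwise = pairwise,
      F_statistic = an[["F value"]][1],
      anova_p = an[["Pr(>F)"]][1],
      n_excluded_nonpositive = sum(bad),
      alpha = alpha
    ),
    class = "tukey_grouping"
  )
}

# Symmetric logical matrix: TRUE where the Tukey-adjusted pairwise
# difference is significant at alpha.
pairwise_significance_matrix <- function(groups, pairwise, alpha) {
  n <- length(groups)
  sig <- matrix(FALSE, n, n, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$fish_a[i]
    b <- pairwise$fish_b[i]
    s <- is.finite(pairwise$p_adj[i]) && pairwise$p_adj[i] < alpha
    sig[a, b] <- s
    sig[b, a] <- s
  }
  sig
}

#' Compact letter display by insertion-absorption
#'
#' Builds the letter assignment from a pairwise significance matrix:
#' starting from a single letter spanning all groups, each significant pair
#' splits every letter containing both members into two columns (one
#' without each member), redundant columns that are subsets of others are
#' absorbed, and letters are finally ordered so that "A" is carried by the
#' group with the largest mean. Guarantees that two groups share a letter
#' if and only if their pairwise difference is not significant.
#'
#' @param means Named numeric vector of group means (used only to order the
#'   letters; ties broken by position).
#' @param sig Symmetric logical matrix, `TRUE` = significantly different.
#' @return Character vector of letter strings (e.g. `"A,B"`), one per
#'   group, in the order of `means`.
#' @export
compact_letter_display <- function(means, sig) {
  n <- length(means)
  groups <- names(means)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  stopifnot(nrow(sig) == n, ncol(sig) == n)

  # columns: logical membership vectors, start with one letter for everyone
  cols <- list(rep(TRUE, n))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          new_cols <- c(new_cols, list(c1), list(c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a == b || !keep[a]) next
          sub_ab <- all(!new_cols[[a]] | new_cols[[b]])
          if (sub_ab && (!all(!new_cols[[b]] | new_cols[[a]]) || b < a)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- unique(cols)

  # order letters: "A" goes to the column whose best (largest-mean) member
  # ranks highest; ties by column content for determinism
  ord <- order(vapply(cols, function(col) -max(means[col]), numeric(1)),
               vapply(cols, function(col) paste(which(col), collapse = ","),
                      character(1)))
  cols <- cols[ord]
  vapply(seq_len(n), function(g) {
    paste(LETTERS[which(vapply(cols, `[`, logical(1), g))], collapse = ",")
  }, character(1))
}
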
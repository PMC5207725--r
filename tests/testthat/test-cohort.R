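test_that("cohort summary reproduces textbook mean/SD arithmetic", {
  set.seed(1)
  fits <- tibble::tibble(
    fish_id = sprintf("f%02d", 1:9), compound = "drug",
    percent_depletion = stats::runif(9, 10, 70),
    k_h = stats::runif(9, 0.005, 0.05), nsd = FALSE
  )
  fits$t_half_h <- log(2) / fits$k_h
  s <- summarize_cohort(fits)
  # two-pass reference computation
  two_pass_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(s$mean_k_h, mean(fits$k_h))
  expect_lt(abs(s$sd_k_h - two_pass_sd(fits$k_h)) / s$sd_k_h, 1e-12)
  expect_lt(abs(s$sd_percent - two_pass_sd(fits$percent_depletion)) / s$sd_percent, 1e-12)
  # mean half-life is the mean of per-fish half-lives, not ln2/mean(k)
  expect_equal(s$mean_t_half_h, mean(fits$t_half_h))
  expect_false(isTRUE(all.equal(s$mean_t_half_h, log(2) / s$mean_k_h)))
})

test_that("identical fits summarise with zero variance", {
  fits <- tibble::tibble(
    fish_id = c("a", "b"), compound = "drug", percent_depletion = 40,
    k_h = 0.02, t_half_h = log(2) / 0.02, nsd = FALSE
  )
  s <- summarize_cohort(fits)
  expect_equal(s$mean_k_h, 0.02)
  expect_equal(s$sd_k_h, 0)
})

test_that("NSD fish are excluded and all-NSD compounds flagged", {
  fits <- tibble::tibble(
    fish_id = c("a", "b", "c", "d"),
    compound = c("drug", "drug", "inert", "inert"),
    percent_depletion = c(40, 44, 1, -2),
    k_h = c(0.02, 0.024, 0, 0),
    t_half_h = c(log(2) / 0.02, log(2) / 0.024, NA, NA),
    nsd = c(FALSE, FALSE, TRUE, TRUE)
  )
  s <- summarize_cohort(fits)
  drug <- s[s$compound == "drug", ]
  inert <- s[s$compound == "inert", ]
  expect_equal(drug$n_fish, 2L)
  expect_false(drug$all_nsd)
  expect_equal(drug$mean_k_h, 0.022)
  expect_true(inert$all_nsd)
  expect_true(is.na(inert$mean_k_h))
})

test_that("degenerate separations give the expected letter displays", {
  # three widely separated tight groups: three distinct letters
  pw <- tibble::tibble(
    fish_id = rep(c("a", "b", "c"), each = 4),
    percent_depletion = rep(c(60, 30, 5), each = 4) + rep(c(-.1, 0, .1, .2), 3)
  )
  g <- anova_ln_depletion(pw)
  expect_equal(g$letters$group_letters, c("A", "B", "C"))
  # indistinguishable groups: everyone shares "A"
  pw2 <- tibble::tibble(
    fish_id = rep(c("a", "b", "c"), each = 4),
    percent_depletion = rep(40, 12)
  )
  g2 <- anova_ln_depletion(pw2)
  expect_equal(g2$letters$group_letters, c("A", "A", "A"))
})

test_that("letter sharing equals Tukey non-significance on simulated cohorts", {
  for (seed in 1:4) {
    cfg <- simulation_config(n_fish = 6, seed = seed)
    sim <- simulate_cohort(cfg)
    pw <- per_well_depletion(sim$wells, "propranolol")
    pw <- pw[pw$percent_depletion > 0, ]
    g <- anova_ln_depletion(pw)
    share <- sharing_matrix(g$letters$group_letters)
    ids <- g$letters$fish_id
    for (r in seq_len(nrow(g$pairwise))) {
      i <- match(g$pairwise$fish_a[r], ids)
      j <- match(g$pairwise$fish_b[r], ids)
      expect_identical(share[i, j], !(g$pairwise$p_adj[r] < g$alpha))
    }
  }
})

test_that("compact letters match the exhaustive oracle on all 4-group patterns", {
  n <- 4
  pair_idx <- utils::combn(n, 2)
  for (mask in 0:(2^ncol(pair_idx) - 1)) {
    sig <- matrix(FALSE, n, n)
    for (p in seq_len(ncol(pair_idx))) {
      if (bitwAnd(mask, 2^(p - 1)) > 0) {
        sig[pair_idx[1, p], pair_idx[2, p]] <- TRUE
        sig[pair_idx[2, p], pair_idx[1, p]] <- TRUE
      }
    }
    means <- c(a = 4, b = 3, c = 2, d = 1)
    letters <- compact_letter_display(means, sig)
    expect_identical(unname(sharing_matrix(letters)), !sig,
                     label = paste("pattern", mask))
    n_letters <- length(unique(unlist(strsplit(letters, ","))))
    expect_equal(n_letters, min_letters_bruteforce(sig),
                 label = paste("letter count, pattern", mask))
  }
})

test_that("letters start at A for the largest group mean", {
  sig <- matrix(TRUE, 3, 3); diag(sig) <- FALSE
  means <- c(low = 1, high = 9, mid = 5)
  expect_equal(compact_letter_display(means, sig), c("C", "A", "B"))
})

test_that("adjusted p-values agree with an independent multiple-comparison route", {
  skip_if_not_installed("multcomp")
  cfg <- simulation_config(n_fish = 5, seed = 9)
  sim <- simulate_cohort(cfg)
  pw <- per_well_depletion(sim$wells, "propranolol")
  g <- anova_ln_depletion(pw)
  d <- data.frame(y = log(pw$percent_depletion),
                  fish = factor(pw$fish_id, levels = unique(pw$fish_id)))
  glht_fit <- multcomp::glht(stats::aov(y ~ fish, d),
                             linfct = multcomp::mcp(fish = "Tukey"))
  p_mc <- summary(glht_fit, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(length(p_mc), nrow(g$pairwise))
  expect_lt(max(abs(sort(as.numeric(p_mc)) - sort(g$pairwise$p_adj))), 0.02)
})

test_that("ANOVA F is invariant under rescaling all percent values", {
  cfg <- simulation_config(n_fish = 4, seed = 12)
  sim <- simulate_cohort(cfg)
  pw <- per_well_depletion(sim$wells, "propranolol")
  g1 <- anova_ln_depletion(pw)
  pw2 <- pw
  pw2$percent_depletion <- pw2$percent_depletion * 2.5 # constant shift on ln scale
  g2 <- anova_ln_depletion(pw2)
  expect_equal(g2$F_statistic, g1$F_statistic, tolerance = 1e-10)
})

test_that("an outlier slow fish receives an unshared letter", {
  # per-well % depletion regenerated from the printed per-fish means/SDs
  tab <- table4_fixture()
  set.seed(104)
  pw <- tibble::tibble(
    fish_id = rep(as.character(tab$fish_id), each = 6),
    percent_depletion = stats::rnorm(
      6 * nrow(tab),
      rep(tab$percent_depletion, each = 6),
      rep(tab$percent_depletion_sd, each = 6)
    )
  )
  pw <- pw[pw$percent_depletion > 0, ]
  g <- anova_ln_depletion(pw)
  expect_lt(g$anova_p, 0.001)
  slow <- strsplit(g$letters$group_letters[g$letters$fish_id == "12"], ",")[[1]]
  others <- unlist(strsplit(g$letters$group_letters[g$letters$fish_id != "12"], ","))
  expect_length(intersect(slow, others), 0)
})

test_that("non-positive percent values are excluded with a warning", {
  pw <- tibble::tibble(
    fish_id = rep(c("a", "b"), each = 4),
    percent_depletion = c(40, 42, 38, -1, 20, 22, 19, 21)
  )
  expect_warning(g <- anova_ln_depletion(pw), "non-positive")
  expect_equal(g$n_excluded_nonpositive, 1L)
  expect_error(anova_ln_depletion(tibble::tibble(fish_id = "a", percent_depletion = 4)),
               ">= 2")
})
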
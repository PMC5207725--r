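# Build noise-free exposure/medium wells directly (independent of the
# package's simulator) from an exact first-order time course.
noise_free_wells <- function(k, c0 = 100, times = c(0, 0.5, 1, 2, 4, 24),
                             n_exposure = 6, n_medium = 3,
                             fish_id = "f1", compound = "drug") {
  rows <- lapply(times, function(t) {
    tibble::tibble(
      fish_id = fish_id,
      compound = compound,
      well_role = rep(c("exposure", "medium_control"), c(n_exposure, n_medium)),
      time_h = t,
      replicate = c(seq_len(n_exposure), seq_len(n_medium)),
      concentration_ug_per_L = c(rep(c0 * exp(-k * t), n_exposure), rep(c0, n_medium))
    )
  })
  dplyr::bind_rows(rows)
}

# Residual sum of squares of a two-parameter exponential decay.
expdecay_rss <- function(a, k, t, y) sum((y - a * exp(-k * t))^2)

# Brute-force 2-D grid search over (a, k) minimising RSS; the independent
# oracle for the nonlinear fit.
grid_search_fit <- function(t, y, a_range, k_range, n_grid = 201) {
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  k_grid <- seq(k_range[1], k_range[2], length.out = n_grid)
  best <- c(a = NA, k = NA, rss = Inf)
  for (a in a_grid) {
    rss <- vapply(k_grid, function(k) expdecay_rss(a, k, t, y), numeric(1))
    i <- which.min(rss)
    if (rss[i] < best["rss"]) best <- c(a = a, k = k_grid[i], rss = rss[i])
  }
  best
}

# All letter-column covers of a significance pattern, brute-forced for
# small group counts: a valid display is a set of group subsets such that
# (a) no subset contains a significantly-different pair, (b) every
# non-significant pair shares at least one subset, (c) every group appears.
# Returns the minimal number of letters needed.
min_letters_bruteforce <- function(sig) {
  n <- nrow(sig)
  stopifnot(n <= 4)
  subsets <- lapply(1:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  valid <- Filter(function(s) {
    if (length(s) < 2) return(TRUE)
    prs <- utils::combn(s, 2)
    all(!sig[cbind(prs[1, ], prs[2, ])])
  }, subsets)
  nonsig_pairs <- which(upper.tri(sig) & !sig, arr.ind = TRUE)
  covers <- function(cols) {
    if (!all(seq_len(n) %in% unlist(cols))) return(FALSE)
    if (nrow(nonsig_pairs) == 0) return(TRUE)
    all(apply(nonsig_pairs, 1, function(pr) {
      any(vapply(cols, function(s) all(pr %in% s), logical(1)))
    }))
  }
  for (k in 1:length(valid)) {
    combos <- utils::combn(seq_along(valid), k, simplify = FALSE)
    for (cm in combos) {
      if (covers(valid[cm])) return(k)
    }
  }
  stop("no valid letter cover found")
}

# Shared-letter matrix induced by a compact letter display string vector.
sharing_matrix <- function(letters) {
  sets <- strsplit(letters, ",", fixed = TRUE)
  n <- length(sets)
  outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    length(intersect(sets[[i]], sets[[j]])) > 0
  }))
}

table4_fixture <- function() {
  path <- system.file("extdata", "propranolol_fish.csv", package = "spheroclear")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
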
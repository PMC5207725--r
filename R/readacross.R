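#' Load compound metabolism profiles for read-across
#'
#' Reads a compound-profile table (default: the seven packaged reference
#' pharmaceuticals) holding each compound's BDDCS class, percent of dose
#' metabolised in humans, the major human CYP enzymes believed responsible,
#' and the observed trout-spheroid depletion outcome.
#'
#' A compound is treated as extensively metabolised in humans when
#' `percent_metabolised_human >= threshold` (default 50% of dose); all
#' packaged compounds sit far from that boundary (6% versus >= 99%).
#'
#' @param path CSV path; defaults to the packaged `compounds.csv`.
#' @param threshold Percent-of-dose cut-off for human extensive metabolism.
#' @return Tibble with `name`, `bddcs_class`, `percent_metabolised_human`,
#'   `major_cyps` (list-column of CYP names), `cyp_note`,
#'   `human_metabolised`, `trout_observed_metabolised` (logical, `NA` =
#'   unknown).
#' @export
read_compound_profiles <- function(path = system.file("extdata", "compounds.csv",
                                                      package = "spheroclear"),
                                   threshold = 50) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("name", "bddcs_class", "percent_metabolised_human", "major_cyps",
           "trout_observed_metabolised")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0L) {
    stop("compound profile file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$name)) {
    stop("duplicate compound names in profile table: ",
         paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    name = raw$name,
    bddcs_class = as.integer(raw$bddcs_class),
    percent_metabolised_human = as.numeric(raw$percent_metabolised_human),
    major_cyps = lapply(strsplit(as.character(raw$major_cyps), ";", fixed = TRUE),
                        trimws),
    cyp_note = if ("cyp_note" %in% names(raw)) raw$cyp_note else NA_character_,
    human_metabolised = as.numeric(raw$percent_metabolised_human) >= threshold,
    trout_observed_metabolised = as.logical(raw$trout_observed_metabolised)
  )
}

#' Known-absent CYP inventory for a species
#'
#' @param species Species name.
#' @param absent_cyps CYPs demonstrated absent in the species' genome.
#' @param present_cyps CYPs known present (optional).
#' @return A list of class `"species_cyp_inventory"`.
#' @export
species_cyp_inventory <- function(species = "rainbow trout",
                                  absent_cyps = c("2D6", "3A4"),
                                  present_cyps = character()) {
  if (length(intersect(absent_cyps, present_cyps)) > 0L) {
    stop("present and absent CYP sets must be disjoint", call. = FALSE)
  }
  structure(
    list(species = species,
         absent_cyps = as.character(absent_cyps),
         present_cyps = as.character(present_cyps)),
    class = "species_cyp_inventory"
  )
}

#' Read-across concordance for one compound
#'
#' A read-across prediction is concordant when the human
#' extensive-metabolism status matches the observed trout-spheroid
#' depletion outcome: a compound metabolised in humans and depleted by
#' spheroids, or not metabolised in either.
#'
#' @param human_metabolised Logical.
#' @param trout_observed_metabolised Logical, or `NA` when untested.
#' @return `"concordant"`, `"discordant"`, or `"unknown"`. Vectorised.
#' @export
#' @examples
#' concordance(FALSE, FALSE) # atenolol: not metabolised in either species
concordance <- function(human_metabolised, trout_observed_metabolised) {
  ifelse(is.na(trout_observed_metabolised), "unknown",
         ifelse(human_metabolised == trout_observed_metabolised,
                "concordant", "discordant"))
}

#' Concordance table over a set of compound profiles
#'
#' Scores each compound with [concordance()] and, when a CYP inventory is
#' given, flags compounds whose major human CYPs include an enzyme
#' demonstrated absent in the target species — the mechanistic explanation
#' for discordant cases such as CYP2D6 substrates in trout.
#'
#' @param profiles Tibble from [read_compound_profiles()].
#' @param inventory Optional [species_cyp_inventory()].
#' @return A list with `table` (per-compound concordance and mechanistic
#'   flag) and `counts` (named totals of concordant / discordant /
#'   unknown).
#' @export
concordance_table <- function(profiles, inventory = NULL) {
  if (anyDuplicated(profiles$name)) {
    stop("duplicate compound names: ",
         paste(unique(profiles$name[duplicated(profiles$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profiles) == 0L) {
    return(list(
      table = tibble::tibble(name = character(), concordance = character(),
                             major_cyp_absent_in_species = logical()),
      counts = c(concordant = 0L, discordant = 0L, unknown = 0L)
    ))
  }
  conc <- concordance(profiles$human_metabolised,
                      profiles$trout_observed_metabolised)
  flag <- if (is.null(inventory)) {
    rep(NA, nrow(profiles))
  } else {
    vapply(profiles$major_cyps,
           function(cyps) length(intersect(cyps, inventory$absent_cyps)) > 0L,
           logical(1))
  }
  tab <- tibble::tibble(
    name = profiles$name,
    human_metabolised = profiles$human_metabolised,
    trout_observed_metabolised = profiles$trout_observed_metabolised,
    concordance = conc,
    major_cyp_absent_in_species = flag
  )
  counts <- c(
    concordant = sum(conc == "concordant"),
    discordant = sum(conc == "discordant"),
    unknown = sum(conc == "unknown")
  )
  list(table = tab, counts = counts)
}
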
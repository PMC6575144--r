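#' Published surveillance counts used for agreement replays
#'
#' The restricted-access corpus behind the published LTC-suicide analysis
#' cannot ship with this package, but its validation arithmetic is fully
#' determined by the printed cross-tabulations, which this function returns
#' as machine-readable inputs.
#'
#' * `table_srf`: the SRF injury-location code against the algorithm's
#'   three-way classification (living in LTC / transitioning-or-otherwise /
#'   non-LTC) over the N = 47 759 analytic deaths.
#' * `table_deathloc`: death-location codes among the 428
#'   algorithm-identified in-facility deaths, split by SRF injury coding.
#' * `totals`: printed margins and stage counts (the LTC/nursing-home death
#'   code total is printed as 569 in the methods and 567 in the results;
#'   both are carried, with 569 the default used in replays).
#'
#' @return A list of matrices and named totals.
#' @export
reference_counts <- function() {
  table_srf <- matrix(
    c(106, 8, 149,
      322, 601, 46573),
    nrow = 2, byrow = TRUE,
    dimnames = list(srf = c("yes", "no"),
                    nlp = c("in_ltc", "trans_or_otherwise", "non_ltc")))
  table_deathloc <- matrix(
    c(18, 39,
      17, 26,
      30, 58,
      22, 131,
      19, 68),
    nrow = 5, byrow = TRUE,
    dimnames = list(death_location = c("inpatient", "outpatient_ed",
                                       "ltc_nursing_home", "decedents_home",
                                       "other_undetermined"),
                    injury = c("srf", "non_srf")))
  totals <- c(
    analytic_n = 47759,
    suicides = 42576,
    accidental_firearm = 279,
    undetermined = 4904,
    excluded_blank_narrative = 2578,
    srf_coded = 263,
    deathloc_ltc_methods = 569,
    deathloc_ltc_results = 567,
    nlp_in_ltc = 428,
    nlp_transitioning = 449,
    nlp_otherwise = 160,
    nlp_total_ltc = 1037,
    seed_positives = 103,
    seed_negatives = 264,
    band_batch = 41,
    band_positives = 14,
    band_negatives = 27,
    final_positive_pool = 1200,
    final_in_ltc = 331,
    final_transitioning = 432,
    final_otherwise = 157,
    final_false_positive = 280
  )
  list(table_srf = table_srf, table_deathloc = table_deathloc,
       totals = totals)
}

#' Replay the published code-validation arithmetic
#'
#' Assembles the 2x2 agreement tables from [reference_counts()] and
#' recomputes the published validation statistics: Cohen's kappa for the
#' SRF injury code and for the LTC/nursing-home death code against the
#' algorithm's living-in-LTC classification, the share of SRF-coded
#' injuries the algorithm places in LTC, the LTC-associated share of all
#' deaths, and the SRF code's sensitivity/specificity with the algorithm as
#' criterion standard.
#'
#' @param deathloc_total Which printed margin to use for the LTC/nursing-
#'   home death-location code (default the methods figure, 569).
#' @return List of computed statistics (unrounded) and the 2x2 tables used.
#' @export
replay_code_validation <- function(deathloc_total = NULL) {
  ref <- reference_counts()
  tot <- ref$totals
  if (is.null(deathloc_total)) deathloc_total <- tot[["deathloc_ltc_methods"]]
  n <- tot[["analytic_n"]]
  in_ltc <- tot[["nlp_in_ltc"]]

  srf_yes_in_ltc <- ref$table_srf["yes", "in_ltc"]
  srf_total <- sum(ref$table_srf["yes", ])
  t_srf <- crosstab_2x2(
    a = srf_yes_in_ltc,
    b = srf_total - srf_yes_in_ltc,
    c = in_ltc - srf_yes_in_ltc,
    d = n - in_ltc - (srf_total - srf_yes_in_ltc))

  dl_overlap <- sum(ref$table_deathloc["ltc_nursing_home", ])
  t_dl <- crosstab_2x2(
    a = dl_overlap,
    b = deathloc_total - dl_overlap,
    c = in_ltc - dl_overlap,
    d = n - in_ltc - (deathloc_total - dl_overlap))

  ss <- sensitivity_specificity(t_srf, gold_margin = "cols")
  list(
    kappa_srf = cohens_kappa(t_srf),
    kappa_deathloc = cohens_kappa(t_dl),
    srf_overlap_pct = 100 * srf_yes_in_ltc / srf_total,
    ltc_share_pct = 100 * tot[["nlp_total_ltc"]] / n,
    srf_sensitivity_pct = 100 * ss$sensitivity,
    srf_specificity_pct = 100 * ss$specificity,
    table_srf_2x2 = t_srf,
    table_deathloc_2x2 = t_dl
  )
}
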
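# National five-year budget impact of adopting testing plus prevention,
# under sequencing-throughput constraints.

#' Epidemiology and throughput inputs for the budget projection
#'
#' Defaults are the national figures for Thailand: breast-cancer incidence
#' 22,158 cases/year and prevalence 76,440 cases, 30% of patients meeting
#' high-risk testing criteria by expert consensus, the 18.6% carrier
#' detection rate, 16.43% cascade-testing uptake with four eligible
#' first-degree relatives per proband and 50% expected positivity, and a
#' national sequencing throughput of 3,500 samples in year 1 growing 55%
#' annually.
#'
#' @param annual_incidence New breast-cancer cases per year.
#' @param prevalence Existing breast-cancer cases.
#' @param high_risk_rate Fraction meeting high-risk testing criteria.
#' @param detection_rate P/LP carrier fraction among the tested high-risk.
#' @param family_uptake Cascade-testing uptake among relatives within 1 year.
#' @param relatives_per_proband Eligible first-degree relatives per proband.
#' @param family_positivity Expected carrier fraction among tested relatives.
#' @param throughput_year1 Sequencing capacity in year 1 (samples).
#' @param throughput_growth Annual capacity growth fraction.
#' @param horizon_years Projection horizon.
#' @return List of class `brca_epi`.
#' @export
budget_epidemiology <- function(annual_incidence = 22158,
                                prevalence = 76440,
                                high_risk_rate = 0.30,
                                detection_rate = 0.186,
                                family_uptake = 0.1643,
                                relatives_per_proband = 4,
                                family_positivity = 0.5,
                                throughput_year1 = 3500,
                                throughput_growth = 0.55,
                                horizon_years = 5L) {
  epi <- as.list(environment())
  num <- vapply(epi, is.numeric, logical(1))
  if (!all(num) || any(unlist(epi) < 0)) stop("all inputs must be non-negative numbers",
                                              call. = FALSE)
  for (f in c("high_risk_rate", "detection_rate", "family_uptake", "family_positivity",
              "throughput_growth"))
    if (epi[[f]] > 1 && f != "throughput_growth")
      stop(f, " must lie in [0, 1]", call. = FALSE)
  class(epi) <- "brca_epi"
  epi
}

#' Nationally eligible and detected patient counts
#'
#' Annual counts feeding the budget projection. Eligibility and carrier
#' detection use ceiling rounding (a part-patient still needs a test slot);
#' the derived family-tester count uses nearest rounding. Each mode is
#' explicit so the arithmetic is auditable.
#'
#' @param epi A `brca_epi`.
#' @return List with `new_eligible` (new high-risk patients/year),
#'   `existing_eligible` (prevalent backlog), `new_plp` (new carriers
#'   detected/year at full coverage) and `family_testers_positive`
#'   (positive relatives tested/year).
#' @export
eligible_counts <- function(epi) {
  new_eligible <- ceiling(epi$annual_incidence * epi$high_risk_rate)
  existing_eligible <- round(epi$prevalence * epi$high_risk_rate)
  new_plp <- ceiling(new_eligible * epi$detection_rate)
  family_testers_positive <- round(new_plp * epi$family_uptake *
                                     epi$relatives_per_proband * epi$family_positivity)
  list(new_eligible = new_eligible, existing_eligible = existing_eligible,
       new_plp = new_plp, family_testers_positive = family_testers_positive)
}

#' Sequencing volumes by programme year
#'
#' Patient tests follow the national throughput, `3500 * (1 + growth)^(k-1)`
#' in year k, capped by the remaining eligible pool (prevalent backlog plus
#' accumulated incident patients). Family cascade tests scale with the
#' patient testing volume from the year-1 positive-relative count.
#'
#' @param epi A `brca_epi`.
#' @param years Integer vector of programme years (default full horizon).
#' @return `data.frame` with `year`, `patient_tests`, `family_tests`.
#' @export
testing_volume <- function(epi, years = seq_len(epi$horizon_years)) {
  ec <- eligible_counts(epi)
  kmax <- max(years)
  pool <- ec$existing_eligible
  tested <- numeric(kmax)
  for (k in seq_len(kmax)) {
    pool <- pool + ec$new_eligible
    cap <- epi$throughput_year1 * (1 + epi$throughput_growth)^(k - 1)
    tested[k] <- min(cap, pool)
    pool <- pool - tested[k]
  }
  fam <- if (tested[1L] > 0) round(ec$family_testers_positive * tested / tested[1L])
         else numeric(kmax)
  data.frame(year = years, patient_tests = tested[years], family_tests = fam[years])
}

#' Five-year national budget-impact table
#'
#' Compares two strategies for the population reached by the testing
#' programme: strategy 1 (no genetic testing; everyone managed by carrier
#' status unknown) and strategy 2 (testing plus subsequent prevention).
#' Each programme year enrols the year's tested cohort, which then accrues
#' the per-person undiscounted annual cost stream of its strategy arm from
#' the Markov model; per budget-impact convention the streams are nominal
#' (undiscounted). Testing costs are charged in the year of testing. The
#' budget impact is the strategy 2 minus strategy 1 total by year.
#'
#' @param epi A `brca_epi`.
#' @param ps A `brca_params` object.
#' @return A `brca_budget`: `data.frame` in million USD with one row per
#'   cost line, one column per year plus `total`.
#' @export
annual_budget <- function(epi, ps) {
  vol <- testing_volume(epi)
  values <- param_values(ps)
  # override the model's decision-tree inputs that the projection fixes
  values[["p_detect"]] <- epi$detection_rate
  values[["p_family_uptake"]] <- epi$family_uptake
  values[["p_family_positive"]] <- epi$family_positivity
  st <- ps$settings
  streams <- list(
    p_test = run_arm("proband", "testing", values, st)$cost_stream,
    p_ref  = run_arm("proband", "no_testing", values, st)$cost_stream,
    f_test = run_arm("family", "testing", values, st)$cost_stream,
    f_ref  = run_arm("family", "no_testing", values, st)$cost_stream)
  # testing costs are accounted in their own rows
  streams$p_test[1L] <- streams$p_test[1L] - values[["cost_test_ngs"]]
  streams$f_test[1L] <- streams$f_test[1L] -
    epi$family_uptake * values[["cost_test_targeted"]]

  ny <- epi$horizon_years
  care <- function(stream, counts) {
    sapply(seq_len(ny), function(y)
      sum(counts[seq_len(y)] * stream[y - seq_len(y) + 1L]))
  }
  # family cohort reached per programme year: relatives of newly found
  # carriers (tested or not, their care differs only through the cascade)
  fam_cohort <- vol$family_tests / epi$family_positivity

  test_cost_patient <- vol$patient_tests * values[["cost_test_ngs"]]
  test_cost_family <- vol$family_tests * values[["cost_test_targeted"]]
  rows <- rbind(
    s1_care_patient = care(streams$p_ref, vol$patient_tests),
    s1_care_family  = care(streams$f_ref, fam_cohort),
    s2_test_patient = test_cost_patient,
    s2_test_family  = test_cost_family,
    s2_care_patient = care(streams$p_test, vol$patient_tests),
    s2_care_family  = care(streams$f_test, fam_cohort))
  rows <- rbind(rows,
                s1_total = rows["s1_care_patient", ] + rows["s1_care_family", ],
                s2_test_total = rows["s2_test_patient", ] + rows["s2_test_family", ],
                s2_care_total = rows["s2_care_patient", ] + rows["s2_care_family", ])
  rows <- rbind(rows, s2_total = rows["s2_test_total", ] + rows["s2_care_total", ])
  rows <- rbind(rows, budget_impact = rows["s2_total", ] - rows["s1_total", ])
  out <- as.data.frame(rows / 1e6)
  names(out) <- paste0("year", seq_len(ny))
  out$total <- rowSums(out)
  out <- cbind(line = rownames(out), out)
  rownames(out) <- NULL
  class(out) <- c("brca_budget", "data.frame")
  out
}

#' @export
print.brca_budget <- function(x, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 2)
  cat("National budget impact (million USD)\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
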
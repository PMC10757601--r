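# Full pipeline: decision-tree allocation -> per-group Markov traces ->
# allocation-weighted economic outcomes -> incremental comparison.

.one_time_surgery <- function(group, values) {
  switch(group,
         M2 = values[["cost_rrm"]] + values[["cost_rrso"]],
         M3 = values[["cost_rrm"]],
         M4 = values[["cost_rrso"]],
         0)
}

#' Lifetime economic outcome of one strategy arm
#'
#' Allocates the cohort over risk groups via the decision tree, runs each
#' occupied group through the Markov model (probands enter at breast-cancer
#' diagnosis, family members enter well), accumulates discounted cost and
#' QALYs, and weights by the allocation. One-time costs charged at cycle 0:
#' risk-reducing surgery for M2/M3/M4 occupants (M2 pays both), the NGS
#' panel for every tested proband, and the targeted test for the tested
#' fraction of family members.
#'
#' @param perspective `"proband"` or `"family"`.
#' @param arm `"testing"` or `"no_testing"`.
#' @param values Named parameter vector.
#' @param settings Settings list from a `brca_params` object.
#' @return A `brca_outcome` with an added `allocation` element.
#' @export
run_arm <- function(perspective = c("proband", "family"),
                    arm = c("testing", "no_testing"),
                    values, settings) {
  perspective <- match.arg(perspective)
  arm <- match.arg(arm)
  alloc <- if (perspective == "proband") allocate_proband(arm, values)
           else allocate_family(arm, values)
  entry <- if (perspective == "proband") "BC" else "Well"
  n_cycles <- settings$terminal_age - settings$entry_age + 1L

  # groups with identical incidence share one trace (M6/M1, and M5 pairs)
  cache <- list()
  cost <- 0; qaly <- 0
  cost_stream <- numeric(n_cycles); qaly_stream <- numeric(n_cycles)
  for (g in RISK_GROUPS) {
    w <- alloc$weights[[g]]
    if (w <= 0) next
    key <- paste(group_incidence(g, values), collapse = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- run_group_trace(values, g, entry, n_cycles = n_cycles)
    out <- accumulate_outcomes(cache[[key]], values, settings,
                               one_time_cost = .one_time_surgery(g, values))
    cost <- cost + w * out$cost
    qaly <- qaly + w * out$qaly
    cost_stream <- cost_stream + w * out$cost_stream
    qaly_stream <- qaly_stream + w * out$qaly_stream
  }
  if (arm == "testing") {
    test_cost <- if (perspective == "proband") values[["cost_test_ngs"]]
                 else values[["p_family_uptake"]] * values[["cost_test_targeted"]]
    cost <- cost + test_cost
    cost_stream[1L] <- cost_stream[1L] + test_cost
  }
  structure(list(cost = cost, qaly = qaly, cost_stream = cost_stream,
                 qaly_stream = qaly_stream, allocation = alloc),
            class = "brca_outcome")
}

#' Base-case cost-utility analysis for one perspective
#'
#' Runs the testing and no-testing arms at the supplied parameter values
#' (point estimates by default) and compares them.
#'
#' @param ps A `brca_params` object.
#' @param perspective `"proband"` or `"family"`.
#' @param values Optional named parameter vector; defaults to the point
#'   estimates.
#' @param wtp Willingness-to-pay; defaults to the set's threshold.
#' @return A `brca_base_case`: list with `testing`, `no_testing`
#'   (`brca_outcome`s) and `comparison` (`brca_comparison`).
#' @export
run_base_case <- function(ps, perspective = c("proband", "family"),
                          values = NULL, wtp = NULL) {
  perspective <- match.arg(perspective)
  if (is.null(values)) values <- param_values(ps)
  if (is.null(wtp)) wtp <- ps$settings$wtp
  test <- run_arm(perspective, "testing", values, ps$settings)
  ref <- run_arm(perspective, "no_testing", values, ps$settings)
  structure(list(perspective = perspective, testing = test, no_testing = ref,
                 comparison = compare(test, ref, wtp)),
            class = "brca_base_case")
}

#' @export
print.brca_base_case <- function(x, ...) {
  cat("Base-case cost-utility analysis (", x$perspective, " perspective)\n", sep = "")
  df <- base_case_table(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate a base-case result
#'
#' @param bc A `brca_base_case`.
#' @return `data.frame` with arm, cost, QALY rows plus the increment and
#'   ICER, mirroring the usual CUA results layout.
#' @export
base_case_table <- function(bc) {
  cmp <- bc$comparison
  data.frame(arm = c("testing", "no_testing", "increment"),
             cost_usd = round(c(bc$testing$cost, bc$no_testing$cost, cmp$delta_cost), 2),
             qaly = round(c(bc$testing$qaly, bc$no_testing$qaly, cmp$delta_qaly), 4),
             icer_usd_per_qaly = c(NA, NA, cmp$icer_rounded),
             stringsAsFactors = FALSE)
}
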
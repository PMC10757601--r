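test_that("transition rows are proper probability distributions for every group", {
  for (g in c("M1", "M2", "M3", "M4", "M5", "M6")) {
    tm <- build_transition_matrix(base_values, g)
    expect_equal(unname(rowSums(tm$P)), rep(1, nrow(tm$P)), tolerance = 1e-12)
    expect_true(all(tm$P >= 0))
    # the stay matrix is a sub-stochastic part of P
    expect_true(all(tm$S <= tm$P + 1e-15))
  }
})

test_that("Well transitions carry the strategy-specific incidences", {
  tm <- build_transition_matrix(base_values, "M2")
  iw <- which(tm$states$id == "Well.0")
  expect_equal(tm$P[iw, "BC.1"], 0.0037)
  expect_equal(tm$P[iw, "OC.1"], 0.0018)
  expect_equal(tm$P[iw, "Well.0"], 1 - 0.0037 - 0.0018)
})

test_that("first-year breast cancer row matches the published wiring", {
  # with no elevated germline ovarian risk the ovarian hazard is the
  # sporadic ovarian-in-breast-patient rate alone
  v <- base_values
  v[c("oc_dev_surv", "oc_dev_neg")] <- 0
  tm <- build_transition_matrix(v, "M5")
  i <- which(tm$states$id == "BC.1")
  expect_equal(tm$P[i, "Death.0"], 0.15)
  expect_equal(tm$P[i, "MetBC.1"], 0.0211)
  expect_equal(tm$P[i, "BrOv.1"], 0.0007)
  expect_equal(tm$P[i, "PostBC.2"], 1 - 0.15 - 0.0211 - 0.0007)
})

test_that("band clocks saturate and recurrence resets the clock", {
  tm <- build_transition_matrix(base_values, "M6")
  st <- tm$states
  # top band maps to itself
  i16 <- which(st$id == "PostBC.16")
  expect_gt(tm$P[i16, "PostBC.16"], 0)
  expect_identical(sum(tm$P[i16, grep("^PostBC", st$id)] > 0), 1L)
  # recurrence from any post year re-enters active cancer at clock 1
  for (k in c(1, 5, 9, 16)) {
    i <- which(st$id == paste0("PostBC.", k))
    bc_targets <- st$id[grep("^BC\\.", st$id)][tm$P[i, grep("^BC\\.", st$id)] > 0]
    expect_identical(bc_targets, "BC.1")
  }
})

test_that("all-zero hazards freeze the cohort in place", {
  tr <- run_group_trace(zero_values, "M5", "Well", n_cycles = 30)
  expect_equal(tr$occ[, "Well"], rep(1, 30))
  expect_equal(sum(tr$occ[, "Death"]), 0)
})

test_that("a forced 50% annual death probability decays geometrically", {
  v <- zero_values
  # each band's cumulative value chosen so the per-cycle probability is 1/2
  v[["mort_bc_1"]] <- 0.5
  v[c("mort_bc_2_3", "mort_bc_4_5")] <- 1 - 0.5^2
  v[c("mort_bc_6_10", "mort_bc_11_15", "mort_bc_16p")] <- 1 - 0.5^5
  tr <- run_group_trace(v, "M5", "BC", n_cycles = 12)
  alive <- 1 - tr$occ[, "Death"]
  expect_equal(alive, 0.5^(0:11), tolerance = 1e-12)
})

test_that("mass is conserved and death is monotone under random parameter draws", {
  for (seed in 1:10) {
    v <- perturb_values(seed + 100)
    g <- sample(c("M1", "M4", "M5", "M6"), 1)
    tr <- run_group_trace(v, g, sample(c("BC", "Well"), 1), n_cycles = 56)
    expect_lt(max(abs(rowSums(tr$occ) - 1)), 1e-10)
    expect_true(all(diff(tr$occ[, "Death"]) >= -1e-12))
    expect_true(all(tr$entry >= -1e-12))
  }
})

test_that("cohort trace matches an independent 1e5-walker microsimulation", {
  n_cycles <- 56
  for (case in list(list(g = "M6", entry = "BC"), list(g = "M1", entry = "Well"))) {
    tr <- run_group_trace(base_values, case$g, case$entry, n_cycles = n_cycles)
    ms <- microsimulate_group(base_values, case$g, case$entry,
                              n_cycles = n_cycles, n_walkers = 1e5, seed = 42)
    se <- sqrt(pmax(tr$occ * (1 - tr$occ), 0) / 1e5)
    outside <- abs(ms - tr$occ) > 3 * se + 1e-9
    # 3 binomial SEs per state per cycle; allow the expected rare excursions
    expect_lt(mean(outside), 0.01)
  }
})

test_that("more surgery means less cancer: group incidence ordering", {
  inflow <- function(g) {
    tr <- run_group_trace(base_values, g, "Well", n_cycles = 56)
    sum(tr$entry[, c("BC", "OC", "BrOv")]) - sum(tr$entry[1, c("BC", "OC", "BrOv")])
  }
  expect_lt(inflow("M2"), inflow("M3"))
  expect_lt(inflow("M2"), inflow("M4"))
  expect_lt(inflow("M3"), inflow("M1"))
  expect_lt(inflow("M4"), inflow("M1"))
})

test_that("testing reduces cumulative breast-cancer recurrence in probands", {
  recurrence_mass <- function(arm) {
    alloc <- allocate_proband(arm, base_values)
    tot <- 0
    for (g in names(alloc$weights)) {
      w <- alloc$weights[[g]]
      if (w == 0) next
      tr <- run_group_trace(base_values, g, "BC", n_cycles = 56)
      tot <- tot + w * (sum(tr$entry[-1, "BC"]))
    }
    tot
  }
  expect_gt(recurrence_mass("no_testing"), recurrence_mass("testing"))
})

test_that("discounting and accumulation follow the cycle-start convention", {
  st <- base_ps$settings
  # constant occupancy in Well for 10 cycles at zero discount
  stz <- st
  stz$discount_rate_cost <- 0
  stz$discount_rate_outcome <- 0
  tr <- run_group_trace(zero_values, "M5", "Well", n_cycles = 10)
  out <- accumulate_outcomes(tr, base_values, stz)
  expect_equal(out$qaly, 10 * 0.89)
  expect_equal(out$cost, sum(out$cost_stream))
  # two $100 cycles at 3%: 100 + 100/1.03
  v <- zero_values
  v[grep("^cost_|^u_", names(v))] <- 0
  v[["u_well"]] <- 1
  v[["cost_visit_transport"]] <- 100  # Well gets one visit per year
  tr2 <- run_group_trace(v, "M5", "Well", n_cycles = 2)
  out2 <- accumulate_outcomes(tr2, v, st)
  expect_equal(out2$cost, 100 + 100 / 1.03, tolerance = 1e-12)
  expect_equal(out2$qaly, 1 + 1 / 1.03, tolerance = 1e-12)
})

test_that("zero discount rates reproduce the undiscounted stream sums exactly", {
  st <- base_ps$settings
  st$discount_rate_cost <- 0
  st$discount_rate_outcome <- 0
  tr <- run_group_trace(base_values, "M6", "BC", n_cycles = 56)
  out <- accumulate_outcomes(tr, base_values, st, one_time_cost = 666.88)
  expect_equal(out$cost, sum(out$cost_stream))
  expect_equal(out$qaly, sum(out$qaly_stream))
})

test_that("outcome bounds hold: QALY cap and testing-arm cost floor", {
  st <- base_ps$settings
  horizon <- st$terminal_age - st$entry_age + 1L
  for (persp in c("proband", "family")) {
    out <- run_arm(persp, "testing", base_values, st)
    expect_lte(out$qaly, horizon * max(base_values[grep("^u_", names(base_values))]))
    floor_cost <- if (persp == "proband") base_values[["cost_test_ngs"]]
                  else base_values[["p_family_uptake"]] * base_values[["cost_test_targeted"]]
    expect_gte(out$cost, floor_cost)
  }
})

test_that("infeasible probability combinations raise a named error", {
  v <- base_values
  v[["p_met"]] <- 0.9
  v[["rec_1_5"]] <- 0.9
  expect_error(build_transition_matrix(v, "M6"), "infeasible.*BC")
  expect_error(run_group_trace(base_values, "M6", "BC", n_cycles = 0), "horizon")
})

test_that("trace exports tidily", {
  tr <- run_group_trace(base_values, "M6", "BC", n_cycles = 5)
  df <- trace_as_data_frame(tr)
  expect_identical(nrow(df), 5L * 9L)
  expect_equal(sum(df$occupancy[df$cycle == 3]), 1, tolerance = 1e-12)
})
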
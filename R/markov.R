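# Markov cohort engine: 8 health states plus Death, with year-since-diagnosis
# tunnel clocks carrying the banded recurrence and mortality probabilities.

STATE_LABELS <- c("Well", "BC", "PostBC", "MetBC", "BrOv",
                  "OC", "PostOC", "MetOC", "Death")
CLOCKED_STATES <- c("BC", "PostBC", "MetBC", "BrOv", "OC", "PostOC", "MetOC")
CLOCK_MAX <- 16L

#' Health-state labels of the Markov model
#'
#' `Well`, breast cancer (`BC`, active treatment year), post-breast cancer
#' (`PostBC`), metastatic breast cancer (`MetBC`), combined breast and
#' ovarian cancer (`BrOv`), ovarian cancer (`OC`), post-ovarian cancer
#' (`PostOC`), metastatic ovarian cancer (`MetOC`), and absorbing `Death`.
#' @return Character vector of the nine state labels.
#' @export
health_states <- function() STATE_LABELS

# expanded state space: Well and Death are unclocked; the cancer states carry
# a years-since-diagnosis clock saturating at CLOCK_MAX (top year band).
expanded_states <- function() {
  df <- rbind(data.frame(label = "Well", clock = 0L),
              do.call(rbind, lapply(CLOCKED_STATES, function(s)
                data.frame(label = s, clock = seq_len(CLOCK_MAX)))),
              data.frame(label = "Death", clock = 0L))
  df$id <- paste0(df$label, ".", df$clock)
  df
}

.EXP <- expanded_states()
.NEXP <- nrow(.EXP)
.EIDX <- stats::setNames(seq_len(.NEXP), .EXP$id)
# indicator matrix aggregating expanded states to the nine labels
.AGG <- local({
  A <- matrix(0, .NEXP, length(STATE_LABELS),
              dimnames = list(.EXP$id, STATE_LABELS))
  A[cbind(seq_len(.NEXP), match(.EXP$label, STATE_LABELS))] <- 1
  A
})

eix <- function(label, clock = 0L) .EIDX[[paste0(label, ".", clock)]]

#' Per-group breast and ovarian cancer incidence
#'
#' Maps each risk group to its annual breast and ovarian cancer incidence
#' under the corresponding prevention strategy: M1 carriers under
#' intensified surveillance, M2 after both RRM and RRSO, M3 after RRM only,
#' M4 after RRSO only, M5 non-carriers/VUS under routine surveillance, and
#' M6 undiagnosed carriers, who follow untreated carrier natural history
#' (identical incidence to M1 but with no option of risk-reducing surgery).
#'
#' @param group One of `"M1"` to `"M6"`.
#' @param values Named parameter vector.
#' @return Numeric `c(bc = , oc = )` annual probabilities.
#' @export
group_incidence <- function(group, values) {
  key <- switch(group,
                M1 = c("bc_dev_surv", "oc_dev_surv"),
                M2 = c("bc_dev_both", "oc_dev_both"),
                M3 = c("bc_dev_rrm", "oc_dev_rrm"),
                M4 = c("bc_dev_rrso", "oc_dev_rrso"),
                M5 = c("bc_dev_neg", "oc_dev_neg"),
                M6 = c("bc_dev_surv", "oc_dev_surv"),
                stop("unknown risk group '", group, "'", call. = FALSE))
  c(bc = values[[key[1]]], oc = values[[key[2]]])
}

# Year-band expansions (index = years since the latest diagnosis event,
# saturating in the top band). The published band values are within-band
# cumulative risks from follow-up studies (e.g. recurrence "in 1-5 yr",
# mortality "in the 2-3 year"); each is converted to the per-cycle
# probability 1 - (1 - q)^(1/w) for a band of width w years. Read as raw
# annual probabilities they would imply five-year survival near 50%,
# inconsistent with the survival literature they summarise. Open-ended
# top bands are treated as five-year blocks.
.annualise <- function(q, w) 1 - (1 - q)^(1 / w)

.band_mort_bc <- function(v) c(.annualise(v[["mort_bc_1"]], 1),
                               rep(.annualise(v[["mort_bc_2_3"]], 2), 2),
                               rep(.annualise(v[["mort_bc_4_5"]], 2), 2),
                               rep(.annualise(v[["mort_bc_6_10"]], 5), 5),
                               rep(.annualise(v[["mort_bc_11_15"]], 5), 5),
                               .annualise(v[["mort_bc_16p"]], 5))
.band_rec <- function(v) c(rep(.annualise(v[["rec_1_5"]], 5), 5),
                           rep(.annualise(v[["rec_6_10"]], 5), 5),
                           rep(.annualise(v[["rec_11_15"]], 5), 5),
                           .annualise(v[["rec_16p"]], 5))
.band_mort_brov <- function(v) c(rep(.annualise(v[["mort_brov_1_5"]], 5), 5),
                                 rep(.annualise(v[["mort_brov_6p"]], 5), 11))
.band_mort_oc <- function(v) c(rep(.annualise(v[["mort_oc_1_5"]], 5), 5),
                               rep(.annualise(v[["mort_oc_6p"]], 5), 11))

#' Build the expanded-state transition matrix for one risk group
#'
#' Produces the annual transition matrix over the clock-expanded state
#' space. Annual probabilities are combined additively within a row, with
#' the stay/progression probability as the remainder; a row whose listed
#' probabilities exceed 1 raises an error naming the state. The topology:
#'
#' * `Well` develops breast or ovarian cancer at the group incidence.
#' * `BC(k)` (active year): dies at the year-`k` banded breast mortality,
#'   metastasises (`p_met`), develops ovarian cancer
#'   (`oc_in_bc` plus the group ovarian incidence, entering `BrOv`),
#'   else moves to `PostBC(k+1)`.
#' * `PostBC(k)`: banded mortality; recurs/develops a new breast primary
#'   at banded recurrence plus the group breast incidence (back to active
#'   `BC`); develops ovarian cancer as above; else stays.
#' * `OC(k)` / `PostOC(k)`: mirror the breast pathway with the ovarian
#'   mortality bands, `p_met_oc`, and breast-in-ovarian development
#'   (`bc_in_oc` plus group breast incidence, entering `BrOv`).
#' * `MetBC`/`MetOC` die at the banded breast mortality; `BrOv` dies at
#'   the combined-state banded mortality. `Death` is absorbing.
#'
#' @param values Named parameter vector.
#' @param group Risk group `"M1"`..`"M6"`.
#' @return List with `P` (transition matrix), `S` (its within-label "stay"
#'   part, used to separate newly entered mass) and the expanded-state
#'   table.
#' @export
build_transition_matrix <- function(values, group) {
  inc <- group_incidence(group, values)
  b <- inc[["bc"]]; o <- inc[["oc"]]
  breast_intact <- !group %in% c("M2", "M3")
  ovary_intact <- !group %in% c("M2", "M4")
  m_bc <- .band_mort_bc(values)
  m_bo <- .band_mort_brov(values)
  m_oc <- .band_mort_oc(values)
  # Breast events after a first breast cancer: banded recurrence of the
  # original tumour applies while breast tissue is intact, and the group's
  # strategy-specific incidence adds the contralateral/new-primary risk that
  # risk-reducing mastectomy removes. After RRM the literature post-RRM rate
  # is the whole breast-event hazard.
  rec <- if (breast_intact) .band_rec(values) + b else rep(b, CLOCK_MAX)
  pmet <- values[["p_met"]]
  pmet_oc <- values[["p_met_oc"]]
  # second-site hazards: group incidence plus the sporadic in-state base
  # while the organ is intact; after its risk-reducing surgery the group
  # rate (which already reflects the operated state) stands alone
  oc_in_bc <- o + if (ovary_intact) values[["oc_in_bc"]] else 0
  bc_in_oc <- b + if (breast_intact) values[["bc_in_oc"]] else 0

  P <- matrix(0, .NEXP, .NEXP, dimnames = list(.EXP$id, .EXP$id))
  S <- matrix(0, .NEXP, .NEXP, dimnames = list(.EXP$id, .EXP$id))
  idx_death <- eix("Death")

  fill <- function(i, targets, label) {
    ps <- vapply(targets, `[[`, numeric(1), 2L)
    if (any(ps < 0)) stop("negative transition probability leaving ", label, call. = FALSE)
    if (sum(ps) > 1 + 1e-12)
      stop("infeasible parameters: outgoing probabilities from ", label,
           " sum to ", format(sum(ps), digits = 4), call. = FALSE)
    for (t in targets) P[i, t[[1]]] <<- P[i, t[[1]]] + t[[2]]
  }

  iw <- eix("Well")
  fill(iw, list(list(eix("BC", 1L), b), list(eix("OC", 1L), o)), "Well")
  P[iw, iw] <- S[iw, iw] <- 1 - b - o

  for (k in seq_len(CLOCK_MAX)) {
    kn <- min(k + 1L, CLOCK_MAX)
    # active breast cancer: exactly one treatment year unless death/progression
    i <- eix("BC", k)
    d <- m_bc[k]
    fill(i, list(list(idx_death, d), list(eix("MetBC", 1L), pmet),
                 list(eix("BrOv", 1L), oc_in_bc)), .EXP$id[i])
    P[i, eix("PostBC", kn)] <- 1 - d - pmet - oc_in_bc

    # recurrence is a new active cancer: the diagnosis clock resets, so the
    # first-year mortality band applies to the recurrence year
    i <- eix("PostBC", k)
    d <- m_bc[k]; rr <- rec[k]
    fill(i, list(list(idx_death, d), list(eix("BC", 1L), rr),
                 list(eix("BrOv", 1L), oc_in_bc)), .EXP$id[i])
    P[i, eix("PostBC", kn)] <- S[i, eix("PostBC", kn)] <- 1 - d - rr - oc_in_bc

    # metastatic progression restarts the survival-band clock: progression
    # is a new, advanced disease event, not year k of disease-free follow-up
    i <- eix("MetBC", k)
    P[i, idx_death] <- m_bc[k]
    P[i, eix("MetBC", kn)] <- S[i, eix("MetBC", kn)] <- 1 - m_bc[k]

    # ovarian-side states follow the same banded cancer-survival curve with
    # the published combined-state values as excess mortality; taken alone
    # those excess terms would leave ovarian cancer patients near-immortal
    i <- eix("OC", k)
    d <- min(m_bc[k] + m_oc[k], 1)
    fill(i, list(list(idx_death, d), list(eix("MetOC", 1L), pmet_oc),
                 list(eix("BrOv", 1L), bc_in_oc)), .EXP$id[i])
    P[i, eix("PostOC", kn)] <- 1 - d - pmet_oc - bc_in_oc

    i <- eix("PostOC", k)
    fill(i, list(list(idx_death, d), list(eix("BrOv", 1L), bc_in_oc)), .EXP$id[i])
    P[i, eix("PostOC", kn)] <- S[i, eix("PostOC", kn)] <- 1 - d - bc_in_oc

    i <- eix("MetOC", k)
    d <- min(m_bc[k] + m_oc[k], 1)
    P[i, idx_death] <- d
    P[i, eix("MetOC", kn)] <- S[i, eix("MetOC", kn)] <- 1 - d

    # combined-state mortality is an excess hazard on top of the banded
    # breast-cancer mortality (a new active cancer restarts the band clock);
    # taken alone it would sit below post-breast mortality and make ovarian
    # cancer protective
    i <- eix("BrOv", k)
    d <- min(m_bc[k] + m_bo[k], 1)
    P[i, idx_death] <- d
    P[i, eix("BrOv", kn)] <- S[i, eix("BrOv", kn)] <- 1 - d
  }
  P[idx_death, idx_death] <- S[idx_death, idx_death] <- 1
  list(P = P, S = S, states = .EXP)
}

#' Run a unit cohort of one risk group through its lifetime
#'
#' Propagates a unit cohort from the entry state through annual cycles from
#' entry age to terminal age (cycle 0 at entry age). The trace records, per
#' cycle, the start-of-cycle occupancy of each health state and the mass
#' newly entering each state that cycle (used for first-year-in-state
#' costs). Mass is conserved to 1e-10 every cycle and Death is absorbing.
#'
#' @param values Named parameter vector.
#' @param group Risk group `"M1"`..`"M6"`.
#' @param entry_state `"BC"` for probands, who enter the model at breast
#'   cancer diagnosis, or `"Well"` for family members.
#' @param n_cycles Number of annual cycles including cycle 0; defaults to
#'   `terminal_age - entry_age + 1` when `settings` is given.
#' @param settings Settings list from a `brca_params` object.
#' @return A `brca_trace`: list with `occ` and `entry` (cycles x 9 state
#'   matrices) and `n_cycles`.
#' @export
run_group_trace <- function(values, group, entry_state = c("BC", "Well"),
                            n_cycles = NULL, settings = NULL) {
  entry_state <- match.arg(entry_state)
  if (is.null(n_cycles)) {
    if (is.null(settings)) stop("give n_cycles or settings", call. = FALSE)
    n_cycles <- settings$terminal_age - settings$entry_age + 1L
  }
  if (n_cycles < 1L) stop("horizon must cover at least one cycle", call. = FALSE)
  tm <- build_transition_matrix(values, group)
  v <- numeric(.NEXP)
  v[eix(entry_state, if (entry_state == "Well") 0L else 1L)] <- 1
  occ <- matrix(0, n_cycles, length(STATE_LABELS),
                dimnames = list(NULL, STATE_LABELS))
  entry <- occ
  occ[1L, ] <- v %*% .AGG
  entry[1L, ] <- occ[1L, ]
  if (n_cycles > 1L) for (t in 2:n_cycles) {
    cont <- drop((v %*% tm$S) %*% .AGG)
    v <- drop(v %*% tm$P)
    ol <- drop(v %*% .AGG)
    occ[t, ] <- ol
    entry[t, ] <- pmax(ol - cont, 0)
  }
  structure(list(occ = occ, entry = entry, n_cycles = n_cycles,
                 group = group, entry_state = entry_state),
            class = "brca_trace")
}

#' @export
print.brca_trace <- function(x, ...) {
  cat("<brca_trace> group ", x$group, ", entry ", x$entry_state, ", ",
      x$n_cycles, " cycles; terminal death mass ",
      round(x$occ[x$n_cycles, "Death"], 4), "\n", sep = "")
  invisible(x)
}

#' Export a cohort trace as a tidy data frame
#'
#' @param trace A `brca_trace`.
#' @return `data.frame` with columns `cycle`, `state`, `occupancy`,
#'   `entering` (mass newly in the state that cycle).
#' @export
trace_as_data_frame <- function(trace) {
  data.frame(cycle = rep(seq_len(trace$n_cycles) - 1L, times = length(STATE_LABELS)),
             state = rep(STATE_LABELS, each = trace$n_cycles),
             occupancy = as.vector(trace$occ),
             entering = as.vector(trace$entry))
}

# per-label annual recurring cost and the first-year-only cost vectors
.state_cost_vectors <- function(values, settings) {
  visit_sum <- values[["cost_visit_transport"]] + values[["cost_visit_meal"]] +
    values[["cost_visit_accom"]] + values[["cost_visit_opportunity"]]
  vpy <- settings$visits_per_year
  visits <- c(Well = vpy$well, BC = vpy$active, PostBC = vpy$post, MetBC = vpy$active,
              BrOv = vpy$active, OC = vpy$active, PostOC = vpy$post, MetOC = vpy$active,
              Death = 0)
  key <- c(BC = "bc", PostBC = "postbc", MetBC = "metbc", BrOv = "brov",
           OC = "oc", PostOC = "postoc", MetOC = "metoc")
  annual <- stats::setNames(numeric(length(STATE_LABELS)), STATE_LABELS)
  firsty <- annual
  for (s in STATE_LABELS) {
    if (s %in% names(key)) {
      # hospitalisation attaches to the admission episode on entering the
      # state; outpatient, recurring non-medical and visit costs accrue
      # annually. For the one-year active states the two are equivalent.
      annual[s] <- values[[paste0("cost_op_", key[s])]] +
        values[[paste0("cost_rec_", key[s])]]
      firsty[s] <- values[[paste0("cost_fy_", key[s])]] +
        values[[paste0("cost_ip_", key[s])]]
    }
    annual[s] <- annual[s] + visit_sum * visits[s]
  }
  firsty["Well"] <- values[["cost_fy_well"]]
  list(annual = annual, first_year = firsty)
}

.state_utilities <- function(values) {
  c(Well = values[["u_well"]], BC = values[["u_bc"]], PostBC = values[["u_postbc"]],
    MetBC = values[["u_metbc"]], BrOv = values[["u_brov"]], OC = values[["u_oc"]],
    PostOC = values[["u_postoc"]], MetOC = values[["u_metoc"]], Death = 0)
}

#' Discounted lifetime cost and QALYs of a cohort trace
#'
#' Applies cycle-start accounting: each cycle charges the start-of-cycle
#' occupancy with the state's annual cost (outpatient + inpatient +
#' recurring non-medical + annualised per-visit costs) and credits its
#' utility; mass newly entering a state additionally pays that state's
#' first-year-only cost. One-time costs (testing, risk-reducing surgery)
#' are charged at cycle 0. Cycle 0 is undiscounted; cycle t is discounted
#' by `1/(1+r)^t` with separate cost and outcome rates.
#'
#' @param trace A `brca_trace`.
#' @param values Named parameter vector.
#' @param settings Settings list from a `brca_params` object.
#' @param one_time_cost USD charged once at cycle 0 (per person in this
#'   cohort).
#' @return A `brca_outcome`: list with discounted `cost` and `qaly`, and
#'   the undiscounted per-cycle `cost_stream` and `qaly_stream`.
#' @export
accumulate_outcomes <- function(trace, values, settings, one_time_cost = 0) {
  cv <- .state_cost_vectors(values, settings)
  ut <- .state_utilities(values)
  tt <- seq_len(trace$n_cycles) - 1L
  cost_stream <- drop(trace$occ %*% cv$annual) + drop(trace$entry %*% cv$first_year)
  cost_stream[1L] <- cost_stream[1L] + one_time_cost
  qaly_stream <- drop(trace$occ %*% ut)
  dc <- (1 + settings$discount_rate_cost)^(-tt)
  do <- (1 + settings$discount_rate_outcome)^(-tt)
  structure(list(cost = sum(cost_stream * dc), qaly = sum(qaly_stream * do),
                 cost_stream = cost_stream, qaly_stream = qaly_stream),
            class = "brca_outcome")
}

#' @export
print.brca_outcome <- function(x, ...) {
  cat("<brca_outcome> discounted lifetime cost $", format(round(x$cost, 2), big.mark = ","),
      ", QALYs ", round(x$qaly, 3), "\n", sep = "")
  invisible(x)
}

#' Simulate the cohort walker-by-walker (validation oracle)
#'
#' Independent count-level microsimulation of the same transition matrix:
#' `n_walkers` individuals advance cycle by cycle with multinomially drawn
#' transitions. Used to validate the deterministic cohort trace, which it
#' should match within binomial sampling error per state per cycle.
#'
#' @inheritParams run_group_trace
#' @param n_walkers Number of simulated individuals.
#' @param seed Optional integer seed.
#' @return Matrix of occupancy proportions, cycles x 9 states.
#' @export
microsimulate_group <- function(values, group, entry_state = c("BC", "Well"),
                                n_cycles, n_walkers = 1e5, seed = NULL) {
  entry_state <- match.arg(entry_state)
  if (!is.null(seed)) set.seed(seed)
  tm <- build_transition_matrix(values, group)
  counts <- integer(.NEXP)
  counts[eix(entry_state, if (entry_state == "Well") 0L else 1L)] <- n_walkers
  occ <- matrix(0, n_cycles, length(STATE_LABELS), dimnames = list(NULL, STATE_LABELS))
  occ[1L, ] <- drop(counts %*% .AGG) / n_walkers
  if (n_cycles > 1L) for (t in 2:n_cycles) {
    nxt <- integer(.NEXP)
    for (i in which(counts > 0L)) {
      row <- tm$P[i, ]
      nz <- which(row > 0)
      nxt[nz] <- nxt[nz] + drop(stats::rmultinom(1L, counts[i], row[nz]))
    }
    counts <- nxt
    occ[t, ] <- drop(counts %*% .AGG) / n_walkers
  }
  occ
}
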
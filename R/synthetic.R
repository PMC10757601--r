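# Synthetic interview microdata: per-health-state cost and utility
# observations with the statistical structure of the study's 264-person
# EQ-5D-5L/cost survey, plus re-estimation of parameter means and SEs.

.INTERVIEW_STATES <- c("Well", "BC", "PostBC", "MetBC", "BrOv", "OC", "PostOC", "MetOC")

#' Design of a synthetic interview survey
#'
#' Picks out the interview-derived parameters of the base-case table — the
#' per-state utilities and the outpatient, inpatient, first-year and
#' recurring cost items — and treats each one's moment-matched Beta or
#' Gamma distribution as the true distribution of individual observations.
#' Per-state sample sizes default to `n_per_state`; individual utilities
#' come out heavy-tailed on \[0, 1\] and costs right-skewed, emulating
#' interview microdata.
#'
#' @param n_per_state Observations per health state (at least 2, so a
#'   standard error can be estimated).
#' @param seed Integer seed stored with the design.
#' @param ps Parameter set supplying the true means/SEs; defaults to the
#'   base-case table.
#' @return A `brca_synth_design`: `data.frame` with one row per simulated
#'   quantity (`name`, `health_state`, `family`, `mean`, `se`, `n`) plus a
#'   `seed` attribute.
#' @export
synth_design <- function(n_per_state = 500L, seed = 1L, ps = default_parameters()) {
  if (n_per_state < 2L) stop("need at least 2 observations per state", call. = FALSE)
  key <- c(Well = "well", BC = "bc", PostBC = "postbc", MetBC = "metbc",
           BrOv = "brov", OC = "oc", PostOC = "postoc", MetOC = "metoc")
  rows <- list()
  for (s in .INTERVIEW_STATES) {
    for (prefix in c("u_", "cost_op_", "cost_ip_", "cost_fy_", "cost_rec_")) {
      nm <- paste0(prefix, key[[s]])
      i <- match(nm, ps$specs$name)
      if (is.na(i) || ps$specs$se[i] == 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(name = nm, health_state = s, family = ps$specs$family[i],
                   mean = ps$specs$mean[i], se = ps$specs$se[i],
                   n = as.integer(n_per_state), stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, rows)
  attr(design, "seed") <- as.integer(seed)
  class(design) <- c("brca_synth_design", "data.frame")
  design
}

#' Generate synthetic interview records
#'
#' Draws `n` i.i.d. observations per designed quantity from its true
#' distribution; reproducible given the design's seed.
#'
#' @param design A `brca_synth_design`.
#' @return `data.frame` with columns `subject`, `health_state`, `quantity`,
#'   `value`.
#' @export
generate_interviews <- function(design) {
  if (!inherits(design, "brca_synth_design")) stop("not a synth design", call. = FALSE)
  set.seed(attr(design, "seed"))
  recs <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    x <- if (d$family == "beta") {
      mm <- moment_match_beta(d$mean, d$se, d$name)
      stats::rbeta(d$n, mm$alpha, mm$beta)
    } else {
      mm <- moment_match_gamma(d$mean, d$se, d$name)
      stats::rgamma(d$n, shape = mm$shape, scale = mm$scale)
    }
    data.frame(subject = paste0(d$health_state, "_", seq_len(d$n)),
               health_state = d$health_state, quantity = d$name, value = x,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Re-estimate parameter means and standard errors from interview records
#'
#' For each quantity: mean = sample mean, SE = sample SD / sqrt(n). A
#' quantity with fewer than 2 records is dropped with a warning.
#'
#' @param records Output of [generate_interviews()] (or real microdata in
#'   the same layout).
#' @return `data.frame` with `name`, `mean`, `se`, `n`.
#' @export
estimate_parameters <- function(records) {
  split_q <- split(records$value, records$quantity)
  keep <- vapply(split_q, length, integer(1)) >= 2L
  if (any(!keep))
    warning("dropped quantities with fewer than 2 observations: ",
            paste(names(split_q)[!keep], collapse = ", "), call. = FALSE)
  split_q <- split_q[keep]
  data.frame(name = names(split_q),
             mean = vapply(split_q, mean, numeric(1)),
             se = vapply(split_q, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
             n = vapply(split_q, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold re-estimated quantities back into a parameter set
#'
#' Replaces the mean and SE of every matching parameter; estimated
#' utilities are clipped into the open unit interval if a sample mean
#' falls outside it.
#'
#' @param ps A `brca_params` object.
#' @param estimates Output of [estimate_parameters()].
#' @return The updated `brca_params`.
#' @export
update_parameters <- function(ps, estimates) {
  i <- match(estimates$name, ps$specs$name)
  if (anyNA(i))
    stop("estimates refer to unknown parameters: ",
         paste(estimates$name[is.na(i)], collapse = ", "), call. = FALSE)
  m <- estimates$mean
  util <- ps$specs$role[i] %in% c("probability", "utility")
  m[util] <- pmin(pmax(m[util], 1e-9), 1 - 1e-9)
  ps$specs$mean[i] <- m
  ps$specs$se[i] <- estimates$se
  ps
}
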
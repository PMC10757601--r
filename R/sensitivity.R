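# One-way (tornado) and probabilistic sensitivity analyses.

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full decision-tree + Markov pipeline with each parameter in
#' turn set to the ends of its range (explicit `low`/`high`, otherwise
#' `mean +/- 1.96 se` clipped to the domain), holding all other parameters
#' at their point estimates, and records the ICER at each end. The outcome
#' discount rate is varied over 0 to 6% alongside the distributional
#' parameters. Entries are returned sorted by descending bar width
#' `|icer_high - icer_low|`, the tornado ordering.
#'
#' @param ps A `brca_params` object.
#' @param perspective `"proband"` or `"family"`.
#' @param parameters Character vector of parameter names to vary; defaults
#'   to every non-degenerate parameter plus `"discount_rate_outcome"`.
#' @param wtp Willingness-to-pay used for the NMB column.
#' @return A `data.frame` (class `brca_tornado`) with one row per
#'   parameter: `parameter`, `low`, `high`, `icer_low`, `icer_high`,
#'   `width`, sorted by `width`.
#' @export
owsa <- function(ps, perspective = c("proband", "family"),
                 parameters = NULL, wtp = NULL) {
  perspective <- match.arg(perspective)
  if (is.null(wtp)) wtp <- ps$settings$wtp
  if (is.null(parameters))
    parameters <- c(ps$specs$name[ps$specs$se > 0 & ps$specs$family != "fixed"],
                    "discount_rate_outcome")
  base_values <- param_values(ps)
  icer_at <- function(name, x) {
    v <- base_values
    st <- ps$settings
    if (name == "discount_rate_outcome") st$discount_rate_outcome <- x
    else if (name == "discount_rate_cost") st$discount_rate_cost <- x
    else v[[name]] <- x
    ps2 <- ps
    ps2$settings <- st
    bc <- run_base_case(ps2, perspective, values = v, wtp = wtp)
    bc$comparison$icer
  }
  rows <- lapply(parameters, function(nm) {
    rng <- if (nm %in% c("discount_rate_outcome", "discount_rate_cost")) c(0, 0.06)
           else owsa_range(ps, nm)
    data.frame(parameter = nm, low = rng[1], high = rng[2],
               icer_low = icer_at(nm, rng[1]), icer_high = icer_at(nm, rng[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("brca_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of the whole parameter set: each iteration draws
#' every non-degenerate parameter from its moment-matched distribution,
#' reruns both strategy arms, and records the incremental cost and QALYs.
#' The run is reproducible given `seed`.
#'
#' @param ps A `brca_params` object.
#' @param perspective `"proband"` or `"family"`.
#' @param n_iter Number of iterations (default 2000).
#' @param seed Integer seed for the whole run.
#' @return A `brca_psa`: list with `iterations` (a `data.frame` of
#'   `delta_cost`, `delta_qaly`, `icer`), `perspective`, `n_iter`, `seed`.
#' @export
psa <- function(ps, perspective = c("proband", "family"),
                n_iter = 2000, seed = 1L) {
  perspective <- match.arg(perspective)
  if (n_iter < 1) stop("n_iter must be at least 1", call. = FALSE)
  set.seed(seed)
  dc <- dq <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    v <- suppressWarnings(sample_parameter_set(ps))
    bc <- run_base_case(ps, perspective, values = v)
    dc[i] <- bc$comparison$delta_cost
    dq[i] <- bc$comparison$delta_qaly
  }
  structure(list(iterations = data.frame(delta_cost = dc, delta_qaly = dq,
                                         icer = ifelse(dq == 0, NA_real_, dc / dq)),
                 perspective = perspective, n_iter = n_iter, seed = seed),
            class = "brca_psa")
}

#' @export
print.brca_psa <- function(x, ...) {
  cat("<brca_psa> ", x$perspective, ", ", x$n_iter, " iterations (seed ", x$seed, ")\n",
      "mean Δcost $", round(mean(x$iterations$delta_cost), 2),
      ", mean ΔQALY ", round(mean(x$iterations$delta_qaly), 4), "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability
#'
#' Fraction of PSA iterations with positive incremental net monetary
#' benefit, `wtp * delta_qaly - delta_cost > 0`, at each willingness-to-pay
#' value.
#'
#' @param psa_result A `brca_psa`.
#' @param wtp Numeric vector of willingness-to-pay thresholds (USD/QALY).
#' @return `data.frame` with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa_result, wtp = seq(0, 20000, by = 500)) {
  it <- psa_result$iterations
  p <- vapply(wtp, function(w) mean(w * it$delta_qaly - it$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp, prob_cost_effective = p)
}
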
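PARAM_FAMILIES <- c("beta", "gamma", "fixed")
PARAM_ROLES <- c("probability", "cost", "utility")

#' Declare a single model parameter
#'
#' A parameter is a mean together with the standard error used for
#' distributional (probabilistic) sensitivity analysis, a sampling family
#' and a role that fixes its valid domain. Probabilities and utilities live
#' on \[0, 1\] and are sampled from moment-matched Beta distributions; costs
#' are non-negative USD and are sampled from moment-matched Gamma
#' distributions. A parameter with `se = 0` (or `family = "fixed"`) is
#' degenerate: sampling always returns the mean.
#'
#' @param name Unique identifier.
#' @param mean Point estimate (base-case value).
#' @param se Standard error used for distribution matching; `0` for fixed
#'   parameters.
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param role One of `"probability"`, `"cost"`, `"utility"`.
#' @param low,high Optional explicit one-way sensitivity range. When `NA`
#'   the range defaults to `mean +/- 1.96 * se`, clipped to the domain.
#' @return A one-row `data.frame` spec.
#' @export
param_spec <- function(name, mean, se, family, role, low = NA_real_, high = NA_real_) {
  family <- match.arg(family, PARAM_FAMILIES)
  role <- match.arg(role, PARAM_ROLES)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(mean) || !is.finite(se) || se < 0)
    stop("parameter '", name, "': mean must be finite and se >= 0", call. = FALSE)
  if (role %in% c("probability", "utility") && (mean < 0 || mean > 1))
    stop("parameter '", name, "': role '", role, "' requires mean in [0, 1]", call. = FALSE)
  if (role == "cost" && mean < 0)
    stop("parameter '", name, "': costs must be >= 0", call. = FALSE)
  if (family == "beta" && role == "cost")
    stop("parameter '", name, "': beta family is only valid for probabilities/utilities",
         call. = FALSE)
  if (family == "gamma" && role != "cost")
    stop("parameter '", name, "': gamma family is only valid for costs", call. = FALSE)
  data.frame(name = name, mean = mean, se = se, family = family, role = role,
             low = low, high = high, stringsAsFactors = FALSE)
}

#' Assemble a parameter set
#'
#' Bundles the parameter table with the global model settings: discount
#' rates, model entry/terminal age, the willingness-to-pay threshold and the
#' THB/USD conversion used to express all monetary values in USD.
#'
#' @param specs `data.frame` of stacked [param_spec()] rows.
#' @param discount_rate_cost,discount_rate_outcome Annual discount rates in
#'   `[0, 1)`; both default to 0.03.
#' @param entry_age,terminal_age Model entry and terminal age in years.
#' @param wtp Willingness-to-pay threshold in USD per QALY.
#' @param currency_conversion THB per USD.
#' @param visits_per_year Named list giving annual hospital-visit counts by
#'   state class, used to annualise the per-visit non-medical costs.
#' @return An object of class `brca_params`.
#' @export
parameter_set <- function(specs,
                          discount_rate_cost = 0.03,
                          discount_rate_outcome = 0.03,
                          entry_age = 45L,
                          terminal_age = 100L,
                          wtp = 5000,
                          currency_conversion = 32.0,
                          visits_per_year = list(active = 12, post = 4, well = 1)) {
  if (anyDuplicated(specs$name))
    stop("duplicate parameter names: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "), call. = FALSE)
  for (r in c(discount_rate_cost, discount_rate_outcome))
    if (r < 0 || r >= 1) stop("discount rates must lie in [0, 1)", call. = FALSE)
  if (terminal_age <= entry_age) stop("terminal_age must exceed entry_age", call. = FALSE)
  ps <- list(specs = specs,
             settings = list(discount_rate_cost = discount_rate_cost,
                             discount_rate_outcome = discount_rate_outcome,
                             entry_age = as.integer(entry_age),
                             terminal_age = as.integer(terminal_age),
                             wtp = wtp,
                             currency_conversion = currency_conversion,
                             visits_per_year = visits_per_year))
  class(ps) <- "brca_params"
  ps
}

#' @export
print.brca_params <- function(x, ...) {
  cat("<brca_params> ", nrow(x$specs), " parameters; entry age ",
      x$settings$entry_age, ", terminal age ", x$settings$terminal_age,
      ", discount ", x$settings$discount_rate_cost * 100, "%/",
      x$settings$discount_rate_outcome * 100, "%, WTP $",
      format(x$settings$wtp, big.mark = ","), "/QALY\n", sep = "")
  invisible(x)
}

#' Point-estimate values of a parameter set
#'
#' @param ps A `brca_params` object.
#' @return Named numeric vector of parameter means.
#' @export
param_values <- function(ps) {
  stats::setNames(ps$specs$mean, ps$specs$name)
}

#' Moment-match a Beta distribution from mean and standard error
#'
#' Solves the two moment equations so that `Beta(alpha, beta)` has exactly
#' the requested mean and variance `se^2`:
#' `alpha = m * (m (1 - m) / se^2 - 1)`, `beta = (1 - m) * (same factor)`.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error, with `0 < se^2 < mean * (1 - mean)`.
#' @param name Optional parameter name used in error messages.
#' @return List with elements `alpha` and `beta`.
#' @export
moment_match_beta <- function(mean, se, name = NULL) {
  lbl <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (any(mean <= 0) || any(mean >= 1))
    stop("beta moment matching", lbl, " requires mean strictly inside (0, 1)", call. = FALSE)
  if (any(se <= 0))
    stop("beta moment matching", lbl, " requires se > 0", call. = FALSE)
  if (any(se^2 >= mean * (1 - mean)))
    stop("invalid variance", lbl, ": se^2 must be < mean * (1 - mean)", call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Moment-match a Gamma distribution from mean and standard error
#'
#' `shape = mean^2 / se^2`, `scale = se^2 / mean`; shapes below 1 are valid
#' and arise for the heavy-tailed interview cost items.
#'
#' @inheritParams moment_match_beta
#' @return List with elements `shape` and `scale`.
#' @export
moment_match_gamma <- function(mean, se, name = NULL) {
  lbl <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (any(mean <= 0)) stop("gamma moment matching", lbl, " requires mean > 0", call. = FALSE)
  if (any(se <= 0)) stop("gamma moment matching", lbl, " requires se > 0", call. = FALSE)
  list(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Draw one realisation of every parameter
#'
#' Each non-degenerate parameter is drawn independently from its
#' moment-matched Beta (probabilities, utilities) or Gamma (costs)
#' distribution. Parameters with `family = "fixed"` or `se = 0` return
#' their mean. A Beta row whose variance is infeasible
#' (`se^2 >= mean (1 - mean)`) falls back to its mean with a warning so a
#' full-set probabilistic analysis always runs. The three proband surgery
#' uptakes (and the family triple) are rescaled proportionally, with a
#' warning, in the rare event their sampled sum exceeds 1.
#'
#' @param ps A `brca_params` object.
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible on its own. Leave `NULL` inside a loop that manages the
#'   RNG stream itself.
#' @return Named numeric vector of realised values.
#' @export
sample_parameter_set <- function(ps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- ps$specs
  out <- sp$mean
  for (i in seq_len(nrow(sp))) {
    if (sp$family[i] == "fixed" || sp$se[i] == 0) next
    m <- sp$mean[i]; s <- sp$se[i]
    if (sp$family[i] == "beta") {
      if (m <= 0 || m >= 1 || s^2 >= m * (1 - m)) {
        warning("parameter '", sp$name[i],
                "': infeasible beta variance; held fixed at its mean", call. = FALSE)
        next
      }
      mm <- moment_match_beta(m, s)
      out[i] <- stats::rbeta(1L, mm$alpha, mm$beta)
    } else {
      mm <- moment_match_gamma(m, s, sp$name[i])
      out[i] <- stats::rgamma(1L, shape = mm$shape, scale = mm$scale)
    }
  }
  names(out) <- sp$name
  out <- .renormalise_uptakes(out, c("p_uptake_both", "p_uptake_rrm", "p_uptake_rrso"))
  out <- .renormalise_uptakes(out, c("p_fam_uptake_both", "p_fam_uptake_rrm", "p_fam_uptake_rrso"))
  # guard against representable rounding just outside the unit interval
  dom <- sp$role %in% c("probability", "utility")
  out[dom] <- pmin(pmax(out[dom], 0), 1)
  out
}

.renormalise_uptakes <- function(values, triple) {
  if (!all(triple %in% names(values))) return(values)
  s <- sum(values[triple])
  if (s > 1) {
    warning("sampled surgery uptakes sum to ", format(s, digits = 4),
            " > 1; rescaled proportionally", call. = FALSE)
    values[triple] <- values[triple] / s
  }
  values
}

#' One-way sensitivity range of a parameter
#'
#' Explicit `low`/`high` columns win. Probabilities and utilities default
#' to `mean +/- 1.96 se` clipped to \[0, 1\]. Costs default to
#' `mean +/- 25%`, the usual health-technology-assessment convention: the
#' interview cost items are heavy-tailed with standard errors exceeding
#' their means, so a normal-approximation interval would degenerate to
#' `[0, several times the mean]` and say nothing about the parameter's
#' leverage. A degenerate parameter gets a zero-width range.
#'
#' @param ps A `brca_params` object.
#' @param name Parameter name.
#' @return Numeric `c(low, high)`.
#' @export
owsa_range <- function(ps, name) {
  i <- match(name, ps$specs$name)
  if (is.na(i)) stop("unknown parameter '", name, "'", call. = FALSE)
  sp <- ps$specs[i, ]
  if (!is.na(sp$low) && !is.na(sp$high)) return(c(sp$low, sp$high))
  if (sp$se == 0) return(c(sp$mean, sp$mean))
  if (sp$role == "cost") return(c(0.75 * sp$mean, 1.25 * sp$mean))
  c(max(sp$mean - 1.96 * sp$se, 0), min(sp$mean + 1.96 * sp$se, 1))
}

# ---- config round-trip -------------------------------------------------

.SETTING_KEYS <- c("discount_rate_cost", "discount_rate_outcome", "entry_age",
                   "terminal_age", "wtp", "currency_conversion", "visits_per_year")

#' Write a parameter set to a YAML config file
#'
#' @param ps A `brca_params` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(ps, path) {
  rows <- lapply(seq_len(nrow(ps$specs)), function(i) {
    r <- as.list(ps$specs[i, c("name", "mean", "se", "family", "role")])
    if (!is.na(ps$specs$low[i])) r$low <- ps$specs$low[i]
    if (!is.na(ps$specs$high[i])) r$high <- ps$specs$high[i]
    r
  })
  yaml::write_yaml(list(settings = ps$settings, parameters = rows), path,
                   precision = 12L)
  invisible(path)
}

#' Load a parameter set from a YAML config file
#'
#' The schema has two top-level sections: `settings` (discount rates, ages,
#' WTP, currency conversion, visit counts) and `parameters` (a list of
#' name/mean/se/family/role records, optional low/high). Unknown keys and
#' domain violations raise an error naming the offending keys; the file
#' must contain every parameter the model requires.
#'
#' @param path File path.
#' @return A `brca_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("settings", "parameters"))
  if (length(bad)) stop("unknown top-level config keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  st <- cfg$settings
  bad <- setdiff(names(st), .SETTING_KEYS)
  if (length(bad)) stop("unknown settings keys: ", paste(bad, collapse = ", "), call. = FALSE)
  specs <- do.call(rbind, lapply(cfg$parameters, function(r) {
    extra <- setdiff(names(r), c("name", "mean", "se", "family", "role", "low", "high"))
    if (length(extra)) stop("unknown parameter fields for '", r$name %||% "?",
                            "': ", paste(extra, collapse = ", "), call. = FALSE)
    param_spec(r$name, r$mean, r$se, r$family, r$role,
               low = r$low %||% NA_real_, high = r$high %||% NA_real_)
  }))
  ps <- do.call(parameter_set, c(list(specs = specs), st))
  missing <- setdiff(required_parameter_names(), ps$specs$name)
  if (length(missing))
    stop("config is missing required parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Names of the parameters every downstream module requires
#' @return Character vector.
#' @export
required_parameter_names <- function() default_parameters()$specs$name

#' Base-case parameter set
#'
#' The full published input table for the Thai BRCA1/2 testing cost-utility
#' model: gBRCA detection and VUS rates, surgery and cascade-testing
#' uptakes, per-strategy breast/ovarian cancer incidences, recurrence and
#' mortality probabilities by year band, sequencing costs, per-state annual
#' outpatient/inpatient costs, per-visit and first-year non-medical costs,
#' recurring out-of-pocket costs, EQ-5D-5L utilities, and the one-time
#' risk-reducing surgery costs. All monetary values are USD.
#'
#' Ovarian-side progression and mortality are not separately published;
#' they default to the corresponding breast/combined-state values and are
#' ordinary named parameters so they can be revised or varied.
#'
#' @return A `brca_params` object.
#' @export
default_parameters <- function() {
  p <- function(...) param_spec(..., role = "probability")
  co <- function(name, mean, se) param_spec(name, mean, se,
                                            family = if (se > 0) "gamma" else "fixed",
                                            role = "cost")
  u <- function(name, mean, se) param_spec(name, mean, se, family = "beta", role = "utility")
  specs <- rbind(
    # decision tree: probands
    p("p_detect",            0.1860, 0.0186, "beta"),
    p("p_vus",               0.0631, 0.0063, "beta"),
    p("p_family_uptake",     0.1643, 0.0164, "beta"),
    p("p_family_positive",   0.5,    0,      "fixed"),
    p("p_uptake_both",       0.1897, 0.0190, "beta"),
    p("p_uptake_rrm",        0.1034, 0.0103, "beta"),
    p("p_uptake_rrso",       0.1897, 0.0190, "beta"),
    p("p_fam_uptake_both",   0,      0,      "fixed"),
    p("p_fam_uptake_rrm",    0,      0,      "fixed"),
    p("p_fam_uptake_rrso",   0.2727, 0.0273, "beta"),
    # breast / ovarian cancer incidence by prevention strategy
    p("bc_dev_surv",         0.0364, 0.00364, "beta"),
    p("bc_dev_both",         0.0037, 0.00037, "beta"),
    p("bc_dev_rrm",          0.0072, 0.00072, "beta"),
    p("bc_dev_rrso",         0.0178, 0.00026, "beta"),
    p("bc_dev_neg",          0.0072, 0.00072, "beta"),
    p("oc_dev_surv",         0.0128, 0.01282, "beta"),
    p("oc_dev_both",         0.0018, 0.00065, "beta"),
    p("oc_dev_rrm",          0.0036, 0.00005, "beta"),
    p("oc_dev_rrso",         0.0027, 0.00059, "beta"),
    p("oc_dev_neg",          0.0006, 0.00062, "beta"),
    # within-model health-state change
    p("p_met",               0.0211, 0.0021, "beta"),
    p("rec_1_5",             0.2432, 0.0243, "beta"),
    p("rec_6_10",            0.0749, 0.0075, "beta"),
    p("rec_11_15",           0.0383, 0.0038, "beta"),
    p("rec_16p",             0.0445, 0.0045, "beta"),
    p("oc_in_bc",            0.0007, 0.0001, "beta"),
    p("bc_in_oc",            0.0040, 0.0004, "beta"),
    p("mort_bc_1",           0.1500, 0.0230, "beta"),
    p("mort_bc_2_3",         0.1391, 0.0383, "beta"),
    p("mort_bc_4_5",         0.1091, 0.0383, "beta"),
    p("mort_bc_6_10",        0.0758, 0.0076, "beta"),
    p("mort_bc_11_15",       0.0390, 0.0039, "beta"),
    p("mort_bc_16p",         0.0465, 0.0047, "beta"),
    p("mort_brov_1_5",       0.0195, 0.0510, "beta"),
    p("mort_brov_6p",        0.0069, 0.0612, "beta"),
    # ovarian-side defaults (reuse published breast/combined values)
    p("mort_oc_1_5",         0.0195, 0,      "fixed"),
    p("mort_oc_6p",          0.0069, 0,      "fixed"),
    p("p_met_oc",            0.0211, 0,      "fixed"),
    # direct medical costs
    co("cost_test_ngs",       666.88, 133.375),
    co("cost_test_targeted",  78.13,  78.125),
    co("cost_op_bc",          902.31, 2310.5),
    co("cost_op_postbc",      350.13, 1258.5),
    co("cost_op_metbc",      1824.50, 4539.344),
    co("cost_op_brov",       1331.81, 3106.219),
    co("cost_op_oc",          448.63, 1153.69),
    co("cost_op_postoc",      199.78, 954.56),
    co("cost_op_metoc",      1193.22, 2688.53),
    co("cost_ip_bc",         2354.44, 2527.09),
    co("cost_ip_postbc",     2289.41, 3615.91),
    co("cost_ip_metbc",      3469.19, 5828.94),
    co("cost_ip_brov",       3533.81, 4247.16),
    co("cost_ip_oc",         2543.50, 1648.91),
    co("cost_ip_postoc",     2515.59, 2139.38),
    co("cost_ip_metoc",      4087.28, 5087),
    # direct non-medical, per visit
    co("cost_visit_transport",   17,    27.97),
    co("cost_visit_meal",        3.97,  8.94),
    co("cost_visit_accom",       3.22,  21.97),
    co("cost_visit_opportunity", 19.53, 43.38),
    # first-year-only: supportive equipment / house renovation
    co("cost_fy_well",        126.19, 321.28),
    co("cost_fy_bc",          282.72, 1201.28),
    co("cost_fy_postbc",        3.13, 10.16),
    co("cost_fy_metbc",       209.59, 631.13),
    co("cost_fy_brov",         96.88, 247.56),
    co("cost_fy_oc",           97.09, 130.09),
    co("cost_fy_postoc",        5.22, 15.63),
    co("cost_fy_metoc",       260.41, 247.56),
    # recurring: supplements, caregiver, private clinic
    co("cost_rec_bc",        1289.56, 2359.03),
    co("cost_rec_postbc",     466.47, 1609),
    co("cost_rec_metbc",     1980.34, 3954.06),
    co("cost_rec_brov",       992.50, 2025.72),
    co("cost_rec_oc",         756.78, 1469.97),
    co("cost_rec_postoc",     223.78, 373.06),
    co("cost_rec_metoc",     3250.00, 5629.16),
    # one-time risk-reducing surgery costs
    co("cost_rrm",           1239, 0),
    co("cost_rrso",           631, 0),
    # EQ-5D-5L utilities
    u("u_well",   0.89, 0.13),
    u("u_bc",     0.84, 0.18),
    u("u_postbc", 0.90, 0.09),
    u("u_metbc",  0.80, 0.16),
    u("u_brov",   0.86, 0.11),
    u("u_oc",     0.76, 0.18),
    u("u_postoc", 0.88, 0.13),
    u("u_metoc",  0.71, 0.39)
  )
  parameter_set(specs)
}
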
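RISK_GROUPS <- c("M1", "M2", "M3", "M4", "M5", "M6")

new_allocation <- function(perspective, arm, weights) {
  w <- stats::setNames(rep(0, 6L), RISK_GROUPS)
  w[names(weights)] <- unlist(weights)
  if (any(w < -1e-12)) stop("negative allocation weight", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12)
    stop("allocation weights must sum to 1 (got ", format(sum(w), digits = 15), ")",
         call. = FALSE)
  structure(list(perspective = perspective, arm = arm, weights = w),
            class = "brca_allocation")
}

#' @export
print.brca_allocation <- function(x, ...) {
  cat("<brca_allocation> ", x$perspective, "/", x$arm, "\n", sep = "")
  print(round(x$weights, 6))
  invisible(x)
}

#' Risk-group allocation for high-risk breast-cancer probands
#'
#' Converts the testing decision into a probability allocation over the six
#' risk groups. Under testing, detected carriers (`p_detect`) split by the
#' observed 1-year surgery uptakes into intensified surveillance (M1), both
#' RRM and RRSO (M2), RRM only (M3) and RRSO only (M4); probands testing
#' negative, together with VUS results (whose cancer risk is taken as equal
#' to the negative group), resume routine surveillance as M5. Without
#' testing, carriers remain undiagnosed (M6) and the rest are M5. Testing
#' therefore reallocates carriers across management groups but never
#' changes carrier prevalence.
#'
#' @param arm `"testing"` or `"no_testing"`.
#' @param values Named numeric vector of realised parameter values (from
#'   [param_values()] or [sample_parameter_set()]).
#' @return A `brca_allocation`.
#' @export
allocate_proband <- function(arm = c("testing", "no_testing"), values) {
  arm <- match.arg(arm)
  p <- values[["p_detect"]]
  b <- values[["p_uptake_both"]]
  m <- values[["p_uptake_rrm"]]
  s <- values[["p_uptake_rrso"]]
  if (b + m + s > 1 + 1e-12)
    stop("invalid surgery uptakes: both + RRM + RRSO = ", format(b + m + s, digits = 4),
         " exceeds 1", call. = FALSE)
  if (arm == "testing") {
    new_allocation("proband", arm,
                   list(M1 = p * (1 - b - m - s), M2 = p * b, M3 = p * m,
                        M4 = p * s, M5 = 1 - p))
  } else {
    new_allocation("proband", arm, list(M5 = 1 - p, M6 = p))
  }
}

#' Risk-group allocation for first-degree relatives of carriers
#'
#' Cascade (targeted-variant) testing is taken up by a fraction
#' `p_family_uptake` of relatives within a year; half are expected to carry
#' the familial variant (`p_family_positive`). Tested carriers opt for
#' surgery per the family uptake rates (in the source data only RRSO, at
#' 27.27%) or stay under intensified surveillance (M1); tested non-carriers
#' are M5. Relatives who decline testing — and everyone in the no-testing
#' arm — reach M6 if they carry the variant and M5 otherwise.
#'
#' @inheritParams allocate_proband
#' @return A `brca_allocation`.
#' @export
allocate_family <- function(arm = c("testing", "no_testing"), values) {
  arm <- match.arg(arm)
  u <- values[["p_family_uptake"]]
  q <- values[["p_family_positive"]]
  b <- values[["p_fam_uptake_both"]]
  m <- values[["p_fam_uptake_rrm"]]
  s <- values[["p_fam_uptake_rrso"]]
  if (b + m + s > 1 + 1e-12)
    stop("invalid family surgery uptakes: sum exceeds 1", call. = FALSE)
  if (arm == "testing") {
    new_allocation("family", arm,
                   list(M1 = u * q * (1 - b - m - s), M2 = u * q * b,
                        M3 = u * q * m, M4 = u * q * s,
                        M5 = 1 - q, M6 = (1 - u) * q))
  } else {
    new_allocation("family", arm, list(M5 = 1 - q, M6 = q))
  }
}
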
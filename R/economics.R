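#' Incremental comparison of two strategy arms
#'
#' Computes incremental cost and QALYs (`test - ref`), the ICER, the net
#' monetary benefit at a willingness-to-pay threshold, and the standard
#' cost-effectiveness-plane dominance classification: an intervention that
#' saves money while gaining QALYs is `"dominant"` (cost-saving; its
#' negative ratio is still reported), one that costs more while losing
#' QALYs is `"dominated"`. A zero QALY difference with a nonzero cost
#' difference leaves the ICER undefined (`NA`) rather than dividing by
#' zero.
#'
#' @param test,ref `brca_outcome` objects (or any list with `cost` and
#'   `qaly`).
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A `brca_comparison`: `delta_cost`, `delta_qaly`, `icer`,
#'   `icer_rounded` (whole USD/QALY), `nmb`, `dominance`.
#' @export
compare <- function(test, ref, wtp = 5000) {
  dc <- test$cost - ref$cost
  dq <- test$qaly - ref$qaly
  if (dq == 0) {
    icer <- if (dc == 0) 0 else NA_real_
    dominance <- if (dc == 0) "equivalent" else if (dc < 0) "dominant" else "dominated"
  } else {
    icer <- dc / dq
    dominance <- if (dc < 0 && dq > 0) "dominant"
      else if (dc > 0 && dq < 0) "dominated"
      else "none"
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 icer_rounded = if (is.na(icer)) NA_real_ else round(icer),
                 nmb = wtp * dq - dc, wtp = wtp, dominance = dominance),
            class = "brca_comparison")
}

#' @export
print.brca_comparison <- function(x, ...) {
  cat("<brca_comparison> Δcost $", round(x$delta_cost, 2),
      ", ΔQALY ", round(x$delta_qaly, 4), sep = "")
  if (is.na(x$icer)) cat(", ICER undefined")
  else cat(", ICER $", x$icer_rounded, "/QALY", sep = "")
  cat(", NMB $", round(x$nmb, 2), " at WTP $", x$wtp, sep = "")
  if (x$dominance %in% c("dominant", "dominated"))
    cat(" [", x$dominance, "]", sep = "")
  cat("\n")
  invisible(x)
}
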
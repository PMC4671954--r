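#' Differential-expression validation of ceRNA candidates
#'
#' Tests each nominated candidate with the same pooled two-sided t engine
#' as the haploinsufficiency screen and assigns a three-way call: `DOWN` or
#' `UP` when `p < alpha` (direction from the sign of case minus control
#' mean), `NS` otherwise. Unlike the in-region screen, direction is not
#' constrained — released miRNAs are expected to repress, but indirect
#' network effects (and miRNA-mediated activation) can raise a candidate,
#' so up-regulated candidates are reported as found. A candidate absent
#' from the expression input yields an explicit `untested` row, never a
#' silent drop.
#'
#' @param candidates a `cerna_candidates` (or plain character vector of
#'   gene ids).
#' @param summary_table summary-statistics table covering the candidates
#'   (alternative to `expr`/`sheet`).
#' @param expr,sheet expression matrix and sample sheet (alternative to
#'   `summary_table`).
#' @param alpha significance level.
#' @return a `candidate_report` data.frame: one row per candidate with the
#'   group statistics, test result, `call` in `{DOWN, UP, NS}` (`NA` when
#'   untested) and `tested` flag.
#' @export
validate_candidates <- function(candidates, summary_table = NULL,
                                expr = NULL, sheet = NULL, alpha = 0.05) {
  check_alpha(alpha)
  genes <- if (inherits(candidates, "cerna_candidates"))
    candidates$candidates else as.character(candidates)
  use_summary <- !is.null(summary_table)
  if (!use_summary && (is.null(expr) || is.null(sheet)))
    stop("provide either summary_table or expr + sheet")
  rows <- lapply(genes, function(g) {
    if (use_summary) {
      i <- match(g, summary_table$gene_id)
      if (is.na(i) || !isTRUE(summary_table$available[i]))
        return(report_row(g, rep(NA_real_, 6), untestable_result(g)))
      r <- summary_table[i, ]
      st <- c(r$mean_case, r$sd_case, r$n_case, r$mean_ctrl, r$sd_ctrl, r$n_ctrl)
    } else {
      gs <- group_stats(expr, sheet, g)
      if (is.null(gs) || gs$CASE$n < 2 || gs$CONTROL$n < 2)
        return(report_row(g, rep(NA_real_, 6), untestable_result(g)))
      st <- c(gs$CASE$mean, gs$CASE$sd, gs$CASE$n,
              gs$CONTROL$mean, gs$CONTROL$sd, gs$CONTROL$n)
    }
    de <- t_test_from_summary(st[1], st[2], st[3], st[4], st[5], st[6],
                              gene_id = g, alpha = alpha)
    report_row(g, st, de)
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("candidate_report", class(rep))
  rep
}

report_row <- function(gene, st, de) {
  call <- if (!de$testable) NA_character_
          else if (!de$significant) "NS" else de$direction
  data.frame(gene_id = gene,
             mean_case = st[1], sd_case = st[2], n_case = st[3],
             mean_ctrl = st[4], sd_ctrl = st[5], n_ctrl = st[6],
             t_statistic = de$t_statistic, df = de$df, p_value = de$p_value,
             call = call, tested = de$testable,
             low_expression = FALSE, stringsAsFactors = FALSE)
}

#' Annotate non-significant candidates with very low expression
#'
#' Candidates that fail to reach significance while both group means sit in
#' the bottom tail of the expression distribution are flagged: near the
#' array noise floor a real shift is hard to detect, so their `NS` call is
#' weak evidence of no effect. The floor defaults to the
#' `quantile_floor` quantile (10th percentile) of a reference mean
#' distribution — typically all group means of the tables under study — or
#' can be given as an absolute intensity. Annotation-only: candidates are
#' never filtered by it.
#'
#' @param report a `candidate_report`.
#' @param reference_means numeric pool of group means defining the
#'   percentile floor (ignored when `floor` is given).
#' @param quantile_floor percentile used with `reference_means`
#'   (default 0.1).
#' @param floor absolute intensity floor; `0` disables annotation.
#' @return the report with `low_expression` set on NS rows whose two group
#'   means are both below the floor; the floor used is in
#'   `attr(, "low_expression_floor")`.
#' @export
low_expression_note <- function(report, reference_means = NULL,
                                quantile_floor = 0.1, floor = NULL) {
  if (is.null(floor)) {
    if (is.null(reference_means))
      stop("need reference_means or an absolute floor")
    floor <- stats::quantile(reference_means[is.finite(reference_means)],
                             quantile_floor, names = FALSE)
  }
  if (floor < 0) stop("floor must be >= 0")
  report$low_expression <- !is.na(report$call) & report$call == "NS" &
    is.finite(report$mean_case) & is.finite(report$mean_ctrl) &
    report$mean_case < floor & report$mean_ctrl < floor
  attr(report, "low_expression_floor") <- floor
  report
}
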
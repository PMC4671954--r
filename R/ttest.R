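#' Two-group Student's t-test from summary statistics
#'
#' The workhorse of both the haploinsufficiency screen and the candidate
#' validation: a pooled-variance (equal-variance) two-sample Student's
#' t-test computed from per-group (mean, sd, n), two-sided, with
#' `df = n1 + n2 - 2`. The pooled form is used deliberately — it is what
#' reproduces the published p-values — and direction (sign of case minus
#' control mean) is reported separately from significance.
#'
#' Degenerate inputs are resolved explicitly: zero variance in both groups
#' with equal means gives `t = 0, p = 1`; zero variance with unequal means
#' is the infinite-t limit, reported as `p = 0` with a warning.
#'
#' @param mean_case,sd_case,n_case case-group mean, SD and size.
#' @param mean_ctrl,sd_ctrl,n_ctrl control-group mean, SD and size.
#' @param gene_id identifier carried into the result.
#' @param alpha two-sided significance level in (0, 1).
#' @return one-row data.frame: `gene_id`, `t_statistic`, `df`, `p_value`,
#'   `direction` (`DOWN` if case < control else `UP`), `significant`,
#'   `testable`.
#' @export
t_test_from_summary <- function(mean_case, sd_case, n_case,
                                mean_ctrl, sd_ctrl, n_ctrl,
                                gene_id = NA_character_, alpha = 0.05) {
  check_alpha(alpha)
  if (anyNA(c(mean_case, sd_case, n_case, mean_ctrl, sd_ctrl, n_ctrl)) ||
      n_case < 2 || n_ctrl < 2 || sd_case < 0 || sd_ctrl < 0)
    return(untestable_result(gene_id))
  df <- n_case + n_ctrl - 2
  sp2 <- ((n_case - 1) * sd_case^2 + (n_ctrl - 1) * sd_ctrl^2) / df
  delta <- mean_case - mean_ctrl
  if (sp2 == 0) {
    if (delta == 0) {
      t <- 0; p <- 1
    } else {
      warning("zero variance with unequal means for '", gene_id,
              "': reporting the p = 0 limit", call. = FALSE)
      t <- sign(delta) * Inf; p <- 0
    }
  } else {
    t <- delta / sqrt(sp2 * (1 / n_case + 1 / n_ctrl))
    p <- 2 * stats::pt(-abs(t), df)
  }
  data.frame(gene_id = gene_id, t_statistic = t, df = df, p_value = p,
             direction = if (delta < 0) "DOWN" else "UP",
             significant = p < alpha, testable = TRUE,
             stringsAsFactors = FALSE)
}

# pooled two-sided p only; shared with the suspect-row detector
pooled_t_p <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  2 * stats::pt(-abs((m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))), df)
}

untestable_result <- function(gene_id)
  data.frame(gene_id = gene_id, t_statistic = NA_real_, df = NA_real_,
             p_value = NA_real_, direction = NA_character_,
             significant = FALSE, testable = FALSE, stringsAsFactors = FALSE)

check_alpha <- function(alpha) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("alpha must be a single number in (0, 1)")
  invisible(alpha)
}

#' Differential expression over a summary-statistics table
#'
#' Applies [t_test_from_summary()] to every row of a table read by
#' [read_summary_table()]. Unavailable rows yield explicit non-testable
#' results (never a silent skip).
#'
#' @param table summary table data.frame.
#' @param alpha two-sided significance level.
#' @param p_adjust multiple-testing correction applied across the testable
#'   rows before thresholding (`"none"` by default — the screen's published
#'   rule is raw `p < 0.05` — or any method of [stats::p.adjust()], e.g.
#'   `"BH"`).
#' @return data.frame of per-gene test results, one row per input row, with
#'   a `p_adjusted` column (equal to `p_value` when `p_adjust = "none"`);
#'   `significant` thresholds the adjusted value.
#' @export
de_from_summary <- function(table, alpha = 0.05, p_adjust = "none") {
  check_alpha(alpha)
  out <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (!isTRUE(r$available)) return(untestable_result(r$gene_id))
    t_test_from_summary(r$mean_case, r$sd_case, r$n_case,
                        r$mean_ctrl, r$sd_ctrl, r$n_ctrl,
                        gene_id = r$gene_id, alpha = alpha)
  })
  apply_p_adjust(do.call(rbind, out), alpha, p_adjust)
}

apply_p_adjust <- function(de, alpha, method) {
  de$p_adjusted <- de$p_value
  if (method != "none")
    de$p_adjusted[de$testable] <- stats::p.adjust(de$p_value[de$testable],
                                                  method = method)
  de$significant <- de$testable & !is.na(de$p_adjusted) &
    de$p_adjusted < alpha
  de
}

#' Differential expression from a raw expression matrix
#'
#' Computes per-gene per-group (mean, sd, n) over non-missing values and
#' feeds them to the same pooled-t engine as the summary path, so the two
#' paths coincide exactly when the matrix matches the summary. Missing
#' values are excluded pairwise per gene; a gene is testable only if each
#' group retains at least 2 non-missing samples.
#'
#' @param expr an [expression_matrix()].
#' @param sheet a [sample_sheet()] covering every matrix column.
#' @param genes genes to test (default: all matrix rows).
#' @param alpha two-sided significance level.
#' @param p_adjust multiple-testing correction, as in [de_from_summary()].
#' @return data.frame of per-gene test results.
#' @export
de_from_matrix <- function(expr, sheet, genes = rownames(expr), alpha = 0.05,
                           p_adjust = "none") {
  check_alpha(alpha)
  if (!all(sheet$sample_id %in% colnames(expr)))
    stop("sample sheet names samples absent from the matrix: ",
         paste(setdiff(sheet$sample_id, colnames(expr)), collapse = ", "))
  for (g in c("CASE", "CONTROL"))
    if (sum(sheet$group == g) < 2)
      stop("need at least 2 samples in group ", g)
  out <- lapply(genes, function(g) {
    st <- group_stats(expr, sheet, g)
    if (is.null(st) || st$CASE$n < 2 || st$CONTROL$n < 2)
      return(untestable_result(g))
    t_test_from_summary(st$CASE$mean, st$CASE$sd, st$CASE$n,
                        st$CONTROL$mean, st$CONTROL$sd, st$CONTROL$n,
                        gene_id = g, alpha = alpha)
  })
  apply_p_adjust(do.call(rbind, out), alpha, p_adjust)
}

#' Call haploinsufficient genes within the deleted region
#'
#' A gene is called haploinsufficient when it lies in the deleted region and
#' shows a statistically significant *reduction* in the deleted samples:
#' two-sided `p < alpha` and direction `DOWN`. Significantly up-regulated
#' in-region genes are never returned — hemizygous loss cannot raise copy
#' number, so the call is one-directional by design even though the test is
#' two-sided.
#'
#' @param de test results from [de_from_summary()] or [de_from_matrix()].
#' @param region a [region_annotation()]; its gene list is the in-region
#'   universe.
#' @param alpha significance level for the call.
#' @return sorted character vector of haploinsufficient gene ids.
#' @export
call_haploinsufficient <- function(de, region, alpha = 0.05) {
  check_alpha(alpha)
  if (!inherits(region, "region_annotation"))
    stop("region must be a region_annotation")
  p <- if ("p_adjusted" %in% names(de)) de$p_adjusted else de$p_value
  hit <- de$testable & de$gene_id %in% region$genes &
    !is.na(p) & p < alpha & de$direction == "DOWN"
  sort(unique(de$gene_id[hit]))
}
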
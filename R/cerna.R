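#' Rank miRNAs by haploinsufficient-target count and select released ones
#'
#' Each miRNA's count is the number of distinct haploinsufficient genes it
#' is predicted to target in the collapsed graph. miRNAs are ordered from
#' most to least represented (ties broken lexicographically by id, zero
#' counts omitted) and those regulating at least `threshold` genes are
#' selected as putatively "released": the deletion removes a share of their
#' binding sites, so their free availability — hence their activity on
#' remaining targets — is expected to increase.
#'
#' @param graph a `target_graph` from [collapse_to_graph()].
#' @param haplo_genes non-empty character vector of haploinsufficient genes.
#' @param threshold inclusive minimum count for selection (default 5).
#' @return a `mirna_ranking`: list with `ranking` (data.frame `mirna_id`,
#'   `n_haplo_targets`, non-increasing), `threshold`, and `selected`
#'   (character vector).
#' @export
rank_released_mirnas <- function(graph, haplo_genes, threshold = 5) {
  if (length(haplo_genes) == 0L)
    stop("haplo_genes is empty: nothing was lost, nothing is released")
  if (nrow(graph) == 0L) stop("target graph is empty")
  stopifnot(threshold >= 1)
  sub <- graph[graph$gene_id %in% haplo_genes, , drop = FALSE]
  counts <- table(sub$mirna_id)
  rk <- data.frame(mirna_id = as.character(names(counts)),
                   n_haplo_targets = as.integer(counts),
                   stringsAsFactors = FALSE)
  rk <- rk[order(-rk$n_haplo_targets, rk$mirna_id), , drop = FALSE]
  rownames(rk) <- NULL
  structure(list(ranking = rk, threshold = threshold,
                 selected = rk$mirna_id[rk$n_haplo_targets >= threshold]),
            class = "mirna_ranking")
}

#' @export
print.mirna_ranking <- function(x, ...) {
  cat(sprintf("mirna_ranking: %d miRNAs with >=1 haplo target, %d selected at threshold >= %d\n",
              nrow(x$ranking), length(x$selected), x$threshold))
  invisible(x)
}

#' Nominate ceRNA candidates by all-miRNA target intersection
#'
#' A candidate is a gene predicted to be targeted by *every* selected
#' (released) miRNA — the transcripts competing for the whole released pool
#' are those most exposed to its increased activity. The candidate universe
#' is the gene side of the target graph (genes with at least one filtered
#' prediction), and in-region genes are excluded by default since the
#' screen looks for effects outside the deletion. `min_fraction` relaxes
#' the all-miRNA rule (fraction of selected miRNAs required) for
#' sensitivity analysis; the published rule is 1.0.
#'
#' @param graph a `target_graph`.
#' @param ranking a `mirna_ranking` with non-empty `selected`.
#' @param region a [region_annotation()] (used for the exclusion), or
#'   `NULL` when `exclude_in_region = FALSE`.
#' @param exclude_in_region drop candidates inside the deleted region
#'   (default `TRUE`).
#' @param min_fraction minimum fraction of selected miRNAs that must target
#'   a candidate (default 1 = all).
#' @return a `cerna_candidates`: list with `candidates` (sorted character),
#'   `evidence` (edge data.frame restricted to candidates x selected
#'   miRNAs), `excluded_in_region` (candidates dropped by the exclusion),
#'   `selected_mirnas`.
#' @export
find_cerna_candidates <- function(graph, ranking, region = NULL,
                                  exclude_in_region = TRUE,
                                  min_fraction = 1) {
  stopifnot(inherits(ranking, "mirna_ranking"),
            min_fraction > 0, min_fraction <= 1)
  sel <- ranking$selected
  if (length(sel) == 0L)
    stop("no selected miRNAs: the target intersection is undefined")
  if (exclude_in_region && !inherits(region, "region_annotation"))
    stop("exclude_in_region = TRUE needs a region_annotation")
  sub <- graph[graph$mirna_id %in% sel, , drop = FALSE]
  n_per_gene <- tapply(sub$mirna_id, sub$gene_id,
                       function(m) length(unique(m)))
  need <- ceiling(min_fraction * length(sel))
  cand <- sort(names(n_per_gene)[n_per_gene >= need])
  excluded <- character()
  if (exclude_in_region) {
    excluded <- intersect(cand, region$genes)
    cand <- setdiff(cand, region$genes)
  }
  structure(list(candidates = cand,
                 evidence = sub[sub$gene_id %in% cand, , drop = FALSE],
                 excluded_in_region = excluded,
                 selected_mirnas = sel),
            class = "cerna_candidates")
}

#' @export
print.cerna_candidates <- function(x, ...) {
  cat(sprintf("cerna_candidates: %d candidate(s) targeted by all %d selected miRNAs\n",
              length(x$candidates), length(x$selected_mirnas)))
  if (length(x$candidates)) cat(" ", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full deletion-wide ceRNA pipeline
#'
#' Chains the five stages: differential expression of in-region genes ->
#' haploinsufficiency call -> target-site filtering and collapse ->
#' released-miRNA ranking -> all-miRNA intersection -> candidate
#' validation. Expression evidence comes either from a summary-statistics
#' table (`summary_table`; validation reuses it) or from a raw matrix
#' (`expr` + `sheet`). When `out_dir` is given, every stage writes a TSV
#' and a JSON run manifest records configuration, input digests and stage
#' counts, sufficient to reproduce the run.
#'
#' @param region a [region_annotation()].
#' @param target_records unfiltered target-site records.
#' @param summary_table summary-statistics table for the in-region screen
#'   (alternative to `expr`/`sheet`).
#' @param validation_summary summary-statistics table covering the
#'   candidates; defaults to `summary_table`, but out-of-region candidates
#'   are usually published in a separate table.
#' @param expr,sheet expression matrix and sample sheet (alternative to
#'   `summary_table`; the matrix serves both DE stages).
#' @param alpha significance level for both DE stages.
#' @param cfg a [filter_config()].
#' @param threshold released-miRNA selection threshold.
#' @param exclude_in_region drop in-region candidates.
#' @param low_expr_quantile quantile of the mean distribution used to
#'   annotate low-expressed non-significant candidates.
#' @param out_dir optional output directory for stage TSVs and manifest.
#' @param seed optional integer recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return list with `de`, `haplo_genes`, `graph`, `ranking`, `candidates`,
#'   `report`, `counts`.
#' @export
run_cerna_pipeline <- function(region, target_records,
                               summary_table = NULL,
                               validation_summary = summary_table,
                               expr = NULL, sheet = NULL,
                               alpha = 0.05, cfg = filter_config(),
                               threshold = 5, exclude_in_region = TRUE,
                               low_expr_quantile = 0.1,
                               out_dir = NULL, seed = NULL) {
  stage <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  use_summary <- !is.null(summary_table)
  if (!use_summary && (is.null(expr) || is.null(sheet)))
    stop("[io_model] provide either summary_table or expr + sheet")

  de <- stage("haplo_stats", function() {
    if (use_summary) de_from_summary(summary_table, alpha = alpha)
    else de_from_matrix(expr, sheet,
                        genes = intersect(region$genes, rownames(expr)),
                        alpha = alpha)
  })
  haplo <- stage("haplo_stats", function()
    call_haploinsufficient(de, region, alpha = alpha))
  graph <- stage("target_db", function()
    collapse_to_graph(filter_sites(target_records, cfg)))
  ranking <- stage("cerna_core", function()
    rank_released_mirnas(graph, haplo, threshold = threshold))
  candidates <- stage("cerna_core", function()
    find_cerna_candidates(graph, ranking, region,
                          exclude_in_region = exclude_in_region))
  report <- stage("candidate_validation", function() {
    rep <- if (use_summary)
      validate_candidates(candidates, summary_table = validation_summary,
                          alpha = alpha)
    else
      validate_candidates(candidates, expr = expr, sheet = sheet,
                          alpha = alpha)
    low_expression_note(rep, reference_means = if (use_summary)
      c(summary_table$mean_case, summary_table$mean_ctrl,
        validation_summary$mean_case, validation_summary$mean_ctrl)
      else rowMeans(expr, na.rm = TRUE),
      quantile_floor = low_expr_quantile)
  })

  counts <- list(genes_tested = sum(de$testable),
                 genes_haploinsufficient = length(haplo),
                 mirnas_ranked = nrow(ranking$ranking),
                 mirnas_selected = length(ranking$selected),
                 candidates = length(candidates$candidates),
                 calls = as.list(table(report$call)))
  res <- list(de = de, haplo_genes = haplo, graph = graph,
              ranking = ranking, candidates = candidates,
              report = report, counts = counts)
  if (!is.null(out_dir))
    write_pipeline_outputs(res, out_dir,
                           config = list(alpha = alpha, threshold = threshold,
                                         exclude_in_region = exclude_in_region,
                                         low_expr_quantile = low_expr_quantile,
                                         filter = unclass(cfg)),
                           seed = seed)
  res
}

write_pipeline_outputs <- function(res, out_dir, config, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    file
  }
  files <- c(tsv(res$de, "de_results.tsv"),
             tsv(data.frame(gene_id = res$haplo_genes), "haplo_genes.tsv"),
             tsv(as.data.frame(res$graph), "target_graph.tsv"),
             tsv(res$ranking$ranking, "mirna_ranking.tsv"),
             tsv(data.frame(gene_id = res$candidates$candidates),
                 "cerna_candidates.tsv"),
             tsv(res$report, "candidate_report.tsv"))
  manifest <- list(
    tool = "cernadel",
    version = as.character(utils::packageVersion("cernadel")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    stage_counts = res$counts,
    output_digests = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$output_digests) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
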
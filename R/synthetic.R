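#' Configuration of the synthetic deletion-cohort generator
#'
#' Defaults mirror the shape of the motivating 5q- study: 29 deleted
#' patients vs 17 controls, a 43-gene deleted region of which ~40% carry a
#' detectable hemizygous reduction (matching the 16/41 testable genes
#' called in the published screen), 9 planted released miRNAs and 4 planted
#' ceRNA genes. Intensities are log-normal — array signal is positive and
#' right-skewed — with `noise_sigma` the log-scale SD (0.3 gives
#' coefficients of variation in the range of the published per-gene SDs).
#' The deletion halves the case-group mean of affected genes
#' (`deletion_effect` 0.5); planted ceRNAs shift by `cerna_effect_down` /
#' `cerna_effect_up` (alternating per gene, so both directions occur).
#'
#' The sizes without a study analogue are fixed conventions: 300 background
#' genes and 50 miRNAs with ~20 background targets each keep the chance
#' that an unplanted gene is hit by all 9 released miRNAs negligible while
#' giving the ranking plenty of true-negative miRNAs.
#'
#' @param n_case,n_ctrl group sizes.
#' @param n_region_genes genes in the deleted region.
#' @param haplo_fraction fraction of region genes with a planted deletion
#'   effect.
#' @param n_background_genes out-of-region genes.
#' @param n_mirnas total miRNAs in the target table.
#' @param n_released_mirnas planted released miRNAs.
#' @param n_planted_cernas planted ceRNA genes (out-of-region).
#' @param deletion_effect multiplicative case-mean factor for haplo genes.
#' @param cerna_effect_down,cerna_effect_up multiplicative case-mean
#'   factors for planted ceRNAs (alternating).
#' @param noise_sigma log-normal noise SD (log scale).
#' @param baseline_meanlog,baseline_sdlog log-normal law of per-gene
#'   baseline means.
#' @param threshold released-miRNA selection threshold the wiring must
#'   support.
#' @param decoy_gene_targets background targets per miRNA (approximate).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_case = 29, n_ctrl = 17,
                             n_region_genes = 43, haplo_fraction = 0.4,
                             n_background_genes = 300, n_mirnas = 50,
                             n_released_mirnas = 9, n_planted_cernas = 4,
                             deletion_effect = 0.5,
                             cerna_effect_down = 0.7, cerna_effect_up = 1.4,
                             noise_sigma = 0.3,
                             baseline_meanlog = log(60), baseline_sdlog = 1,
                             threshold = 5, decoy_gene_targets = 20) {
  cfg <- list(n_case = n_case, n_ctrl = n_ctrl,
              n_region_genes = n_region_genes,
              haplo_fraction = haplo_fraction,
              n_background_genes = n_background_genes, n_mirnas = n_mirnas,
              n_released_mirnas = n_released_mirnas,
              n_planted_cernas = n_planted_cernas,
              deletion_effect = deletion_effect,
              cerna_effect_down = cerna_effect_down,
              cerna_effect_up = cerna_effect_up,
              noise_sigma = noise_sigma,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              threshold = threshold,
              decoy_gene_targets = decoy_gene_targets)
  counts <- cfg[grep("^n_", names(cfg))]
  if (any(unlist(counts) < 1)) stop("all counts must be >= 1")
  if (any(c(deletion_effect, cerna_effect_down, cerna_effect_up) <= 0))
    stop("effect factors must be > 0")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  if (n_released_mirnas > n_mirnas)
    stop("more released miRNAs than miRNAs")
  if (n_planted_cernas > n_background_genes)
    stop("more planted ceRNAs than background genes")
  n_haplo <- round(haplo_fraction * n_region_genes)
  if (n_haplo < threshold)
    stop("planted haplo genes (", n_haplo,
         ") cannot support the selection threshold (", threshold, ")")
  cfg$n_haplo <- n_haplo
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic deletion cohort with planted ceRNA structure
#'
#' Draws per-gene baseline means from a log-normal law, multiplies planted
#' effects into the case group (deletion effect on haplo genes, ceRNA
#' effect on planted candidates), and wires a target table in which every
#' planted released miRNA hits at least `threshold` planted haplo genes
#' and *all* planted ceRNAs, while decoy miRNAs stay below the threshold
#' and decoy genes miss at least one released miRNA. All target records
#' pass the default [filter_config()]. Every random draw flows from the
#' single `seed` (one stream, scoped with [withr::with_seed()]), so a rerun
#' with the same seed is bit-identical.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed for the single RNG stream.
#' @return list: `expr` ([expression_matrix()]), `sheet` ([sample_sheet()]),
#'   `region` ([region_annotation()]), `targets` (target-site data.frame),
#'   `truth` (list: `haplo_genes`, `released_mirnas`, `cerna_genes`,
#'   `cerna_direction`, `edges`), `config`.
#' @export
generate_synthetic <- function(cfg = synthetic_config(), seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(seed, generate_synthetic_impl(cfg))
}

generate_synthetic_impl <- function(cfg) {
  region_genes <- sprintf("REG%03d", seq_len(cfg$n_region_genes))
  bg_genes <- sprintf("BG%03d", seq_len(cfg$n_background_genes))
  mirnas <- sprintf("syn-miR-%03d", seq_len(cfg$n_mirnas))
  haplo <- sort(sample(region_genes, cfg$n_haplo))
  cernas <- sort(sample(bg_genes, cfg$n_planted_cernas))
  released <- sort(sample(mirnas, cfg$n_released_mirnas))
  cerna_dir <- stats::setNames(
    rep(c("DOWN", "UP"), length.out = cfg$n_planted_cernas), cernas)

  genes <- c(region_genes, bg_genes)
  baseline <- stats::setNames(
    stats::rlnorm(length(genes), cfg$baseline_meanlog, cfg$baseline_sdlog),
    genes)
  case_factor <- stats::setNames(rep(1, length(genes)), genes)
  case_factor[haplo] <- cfg$deletion_effect
  case_factor[cernas] <- ifelse(cerna_dir == "DOWN",
                                cfg$cerna_effect_down, cfg$cerna_effect_up)

  sids <- c(sprintf("CASE%02d", seq_len(cfg$n_case)),
            sprintf("CTRL%02d", seq_len(cfg$n_ctrl)))
  groups <- rep(c("CASE", "CONTROL"), c(cfg$n_case, cfg$n_ctrl))
  mean_mat <- baseline %o% rep(1, length(sids))
  mean_mat[, groups == "CASE"] <-
    mean_mat[, groups == "CASE"] * case_factor[genes]
  vals <- mean_mat * exp(matrix(stats::rnorm(length(mean_mat),
                                             sd = cfg$noise_sigma),
                                nrow = length(genes)))
  dimnames(vals) <- list(genes, sids)
  expr <- expression_matrix(vals)
  sheet <- sample_sheet(sids, groups)
  region <- region_annotation("SYN_CDR", "chr5", 131e6, 139e6, region_genes)

  # wiring: planted structure first, then decoys
  edges <- list()
  add_edges <- function(m, gs) {
    if (length(gs)) edges[[length(edges) + 1L]] <<-
        data.frame(mirna_id = m, gene_id = gs, stringsAsFactors = FALSE)
  }
  decoy_pool <- setdiff(bg_genes, cernas)
  for (m in released) {
    k <- sample(cfg$threshold:cfg$n_haplo, 1)
    add_edges(m, sample(haplo, k))
    add_edges(m, cernas)
    add_edges(m, sample(decoy_pool, min(cfg$decoy_gene_targets,
                                        length(decoy_pool))))
  }
  for (m in setdiff(mirnas, released)) {
    k <- sample(0:min(cfg$threshold - 2L, cfg$n_haplo), 1)
    if (k > 0) add_edges(m, sample(haplo, k))
    add_edges(m, sample(decoy_pool, min(cfg$decoy_gene_targets,
                                        length(decoy_pool))))
  }
  edge_df <- unique(do.call(rbind, edges))
  # a fraction of interactions get a second predicted site, exercising the
  # multi-hit collapse downstream
  dup <- edge_df[stats::runif(nrow(edge_df)) < 0.1, , drop = FALSE]
  site_df <- rbind(edge_df, dup)
  n <- nrow(site_df)
  targets <- data.frame(
    mirna_id = site_df$mirna_id, gene_id = site_df$gene_id,
    site_region = "3UTR",
    seed_length = sample(7:8, n, replace = TRUE),
    seed_start = 1L,
    p_miRWalk = stats::runif(n, 0, 0.05),
    p_miRanda = stats::runif(n, 0, 0.05),
    p_RNA22 = stats::runif(n, 0, 0.05),
    p_TargetScan = stats::runif(n, 0, 0.05),
    stringsAsFactors = FALSE)
  targets <- targets[order(targets$mirna_id, targets$gene_id), , drop = FALSE]
  rownames(targets) <- NULL

  list(expr = expr, sheet = sheet, region = region, targets = targets,
       truth = list(haplo_genes = haplo, released_mirnas = released,
                    cerna_genes = cernas, cerna_direction = cerna_dir,
                    edges = edge_df),
       config = cfg)
}

#' Write a synthetic cohort to a directory in the standard formats
#'
#' Emits the TSV/BED formats of the readers in this package plus
#' `truth.tsv` tables so a cohort can be archived and re-read.
#'
#' @param sim output of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_sample_sheet(sim$sheet, file.path(dir, "samples.tsv"))
  r <- sim$region
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", r$chrom, r$start, r$end,
                     r$region_id), file.path(dir, "region.bed"))
  utils::write.table(data.frame(gene_id = r$genes),
                     file.path(dir, "region_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$targets, file.path(dir, "target_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- rbind(
    data.frame(kind = "haplo_gene", id = sim$truth$haplo_genes,
               direction = "DOWN", stringsAsFactors = FALSE),
    data.frame(kind = "released_mirna", id = sim$truth$released_mirnas,
               direction = NA_character_, stringsAsFactors = FALSE),
    data.frame(kind = "cerna_gene", id = sim$truth$cerna_genes,
               direction = unname(sim$truth$cerna_direction),
               stringsAsFactors = FALSE))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' Build an expression matrix that reproduces a summary table exactly
#'
#' Bridges printed per-group summary statistics to the raw-matrix code
#' path: per gene and group, `n` log-normal draws (the package's positive,
#' right-skewed intensity model; the base CV is matched to the target
#' SD/mean ratio) are affinely rescaled to hit the printed mean and SD
#' exactly (sample SD, denominator `n - 1`), and redrawn whenever rescaling
#' would still produce a negative intensity — no clipping, so the moments
#' are exact. Unavailable rows become all-`NA` (untestable) rows.
#'
#' @param table summary table as from [read_summary_table()].
#' @param seed integer seed.
#' @param max_tries redraw attempts per gene/group before giving up.
#' @return list: `expr` ([expression_matrix()]), `sheet` ([sample_sheet()]).
#' @export
matrix_from_summary <- function(table, seed = 1, max_tries = 10000) {
  if (any(table$n_case < 2, na.rm = TRUE) ||
      any(table$n_ctrl < 2, na.rm = TRUE))
    stop("group sizes must be >= 2")
  nc <- max(table$n_case, na.rm = TRUE)
  nt <- max(table$n_ctrl, na.rm = TRUE)
  sids <- c(sprintf("CASE%02d", seq_len(nc)), sprintf("CTRL%02d", seq_len(nt)))
  groups <- rep(c("CASE", "CONTROL"), c(nc, nt))
  withr::with_seed(seed, {
    vals <- matrix(NA_real_, nrow = nrow(table), ncol = length(sids),
                   dimnames = list(table$gene_id, sids))
    for (i in seq_len(nrow(table))) {
      r <- table[i, ]
      if (!isTRUE(r$available)) next
      vals[i, seq_len(r$n_case)] <-
        rescale_to(r$mean_case, r$sd_case, r$n_case, max_tries, r$gene_id)
      vals[i, nc + seq_len(r$n_ctrl)] <-
        rescale_to(r$mean_ctrl, r$sd_ctrl, r$n_ctrl, max_tries, r$gene_id)
    }
    list(expr = expression_matrix(vals), sheet = sample_sheet(sids, groups))
  })
}

rescale_to <- function(m, s, n, max_tries, gene) {
  if (s == 0) return(rep(m, n))
  if (m <= 0)
    stop("non-positive mean with non-zero SD for ", gene,
         ": cannot build a non-negative sample")
  # log-normal base draws bound the studentized minimum near -mean/sd of the
  # base law; matching the base CV to ~1.25 x the target SD/mean ratio keeps
  # the rescaled sample non-negative even for low-mean, high-variance rows
  # (where normal draws would require astronomically many redraws)
  sigma0 <- sqrt(log1p((1.25 * s / m)^2))
  for (i in seq_len(max_tries)) {
    x <- stats::rlnorm(n, 0, sigma0)
    sx <- stats::sd(x)
    if (sx == 0) next
    y <- m + (x - mean(x)) * s / sx
    if (all(y >= 0)) return(y)
  }
  stop("could not draw non-negative values matching mean/SD for ", gene)
}

#' Planted-structure recovery benchmark
#'
#' Runs the full pipeline on freshly generated synthetic cohorts and scores
#' recovery of the planted released-miRNA set and the planted ceRNA set
#' against the generator's truth. Precision is `NA` when the pipeline
#' selects nothing (no positive calls to be wrong about).
#'
#' @param n_seeds number of replicate cohorts.
#' @param cfg a [synthetic_config()].
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param alpha significance level passed to the pipeline.
#' @return data.frame with one row per replicate: precision/recall for
#'   miRNAs and ceRNAs, and the in-region significant fraction
#'   (`region_sig_rate`, the type-I proxy under a null configuration).
#' @export
recovery_experiment <- function(n_seeds = 50, cfg = synthetic_config(),
                                seed = 1, alpha = 0.05) {
  one <- function(i) {
    sim <- generate_synthetic(cfg, seed = seed + i)
    de <- de_from_matrix(sim$expr, sim$sheet, genes = sim$region$genes,
                         alpha = alpha)
    haplo <- call_haploinsufficient(de, sim$region, alpha = alpha)
    sel <- character(); cand <- character()
    if (length(haplo)) {
      graph <- collapse_to_graph(filter_sites(sim$targets))
      ranking <- rank_released_mirnas(graph, haplo,
                                      threshold = cfg$threshold)
      sel <- ranking$selected
      if (length(sel))
        cand <- find_cerna_candidates(graph, ranking, sim$region)$candidates
    }
    pr <- function(called, truth) c(
      precision = if (length(called)) length(intersect(called, truth)) /
        length(called) else NA_real_,
      recall = length(intersect(called, truth)) / length(truth))
    m <- pr(sel, sim$truth$released_mirnas)
    g <- pr(cand, sim$truth$cerna_genes)
    data.frame(seed = seed + i,
               mirna_precision = m[["precision"]],
               mirna_recall = m[["recall"]],
               cerna_precision = g[["precision"]],
               cerna_recall = g[["recall"]],
               region_sig_rate = mean(de$p_value[de$testable] < alpha),
               n_haplo_called = length(haplo))
  }
  do.call(rbind, lapply(seq_len(n_seeds), one))
}
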
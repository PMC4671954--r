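PREDICTORS <- c("miRWalk", "miRanda", "RNA22", "TargetScan")
SITE_REGIONS <- c("3UTR", "5UTR", "CDS", "promoter")

#' Read a miRNA-target prediction table
#'
#' One row per predicted binding site: miRNA, gene, transcript region of
#' the site, seed length (nt), 1-based seed start within the miRNA, and one
#' p-value per prediction algorithm (miRWalk, miRanda, RNA22, TargetScan).
#' All records load unfiltered; stringency filtering is a separate,
#' explicit step ([filter_sites()]).
#'
#' @param path TSV with columns `mirna_id`, `gene_id`, `site_region`,
#'   `seed_length`, `seed_start`, `p_miRWalk`, `p_miRanda`, `p_RNA22`,
#'   `p_TargetScan`.
#' @return data.frame of site records.
#' @export
read_target_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_target_records(df)
}

validate_target_records <- function(df) {
  needed <- c("mirna_id", "gene_id", "site_region", "seed_length",
              "seed_start", paste0("p_", PREDICTORS))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("target table missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  bad_region <- setdiff(unique(df$site_region), SITE_REGIONS)
  if (length(bad_region))
    stop("unknown site_region label(s) ", paste(bad_region, collapse = ", "),
         "; allowed: ", paste(SITE_REGIONS, collapse = ", "))
  if (any(df$seed_length < 1, na.rm = TRUE))
    stop("seed_length must be >= 1")
  if (any(df$seed_start < 1, na.rm = TRUE))
    stop("seed_start must be >= 1")
  for (p in paste0("p_", PREDICTORS)) {
    v <- df[[p]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop(p, " outside [0, 1] at row(s) ",
           paste(which(!is.na(v) & (v < 0 | v > 1)), collapse = ", "))
  }
  df
}

#' Stringency filter for predicted target sites
#'
#' `filter_config()` captures the published stringency rule and reproduces
#' it with its defaults: sites in the 3'UTR, seed at least `min_seed_length`
#' nucleotides starting exactly at miRNA position 1, and p <= 0.05 in *all
#' four* prediction algorithms (the bound is inclusive). A record missing a
#' required predictor's p-value fails that predictor — consensus requires
#' detection by every algorithm, so absence of evidence is treated as
#' failure.
#'
#' @param required_region site region kept (default `"3UTR"`).
#' @param min_seed_length minimum seed length in nt (default 7).
#' @param required_seed_start exact required seed start (default 1).
#' @param max_predictor_p inclusive per-predictor p cutoff (default 0.05).
#' @param required_predictors predictors that must all pass (default all 4).
#' @return a `filter_config` list.
#' @export
filter_config <- function(required_region = "3UTR", min_seed_length = 7,
                          required_seed_start = 1, max_predictor_p = 0.05,
                          required_predictors = PREDICTORS) {
  stopifnot(required_region %in% SITE_REGIONS, min_seed_length >= 1,
            required_seed_start >= 1,
            max_predictor_p >= 0, max_predictor_p <= 1,
            all(required_predictors %in% PREDICTORS))
  structure(list(required_region = required_region,
                 min_seed_length = min_seed_length,
                 required_seed_start = required_seed_start,
                 max_predictor_p = max_predictor_p,
                 required_predictors = required_predictors),
            class = "filter_config")
}

#' @rdname filter_config
#' @param records target-site data.frame from [read_target_table()].
#' @param cfg a `filter_config`.
#' @return the records passing the filter, input order preserved.
#' @export
filter_sites <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  records <- validate_target_records(records)
  if (nrow(records) == 0L) return(records)
  keep <- records$site_region == cfg$required_region &
    records$seed_length >= cfg$min_seed_length &
    records$seed_start == cfg$required_seed_start
  for (p in cfg$required_predictors) {
    v <- records[[paste0("p_", p)]]
    keep <- keep & !is.na(v) & v <= cfg$max_predictor_p
  }
  records[keep, , drop = FALSE]
}

#' Collapse filtered sites to a bipartite miRNA-gene graph
#'
#' A gene recognised multiple times by the same miRNA counts as a single
#' hit: the graph has one unweighted edge per distinct (miRNA, gene) pair,
#' with the number of collapsed sites retained as provenance.
#'
#' @param records *filtered* site records.
#' @return a `target_graph`: data.frame `mirna_id`, `gene_id`, `n_sites`,
#'   one row per edge, sorted by miRNA then gene.
#' @export
collapse_to_graph <- function(records) {
  if (nrow(records) == 0L) {
    g <- data.frame(mirna_id = character(), gene_id = character(),
                    n_sites = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(n_sites = records$mirna_id),
                            by = list(mirna_id = records$mirna_id,
                                      gene_id = records$gene_id),
                            FUN = length)
    g <- agg[order(agg$mirna_id, agg$gene_id), , drop = FALSE]
    rownames(g) <- NULL
  }
  class(g) <- c("target_graph", class(g))
  g
}

#' @export
print.target_graph <- function(x, ...) {
  cat(sprintf("target_graph: %d edges, %d miRNAs, %d genes\n",
              nrow(x), length(unique(x$mirna_id)), length(unique(x$gene_id))))
  invisible(x)
}

graph_neighbors <- function(graph, mirna) graph$gene_id[graph$mirna_id == mirna]

#' Built-in seed-match target predictor
#'
#' A deliberately simple, database-free predictor used to make the pipeline
#' self-contained: a site is reported wherever the reverse complement of
#' the miRNA 5' seed (positions 1..`min_seed_len`) occurs in the UTR, read
#' 5'->3' on both molecules (the duplex is antiparallel, so miRNA position
#' 1 pairs with the 3'-most base of the site). Each minimal-seed occurrence
#' is extended greedily towards the 5' end of the UTR while Watson-Crick
#' complementarity to successive miRNA positions continues; the extended
#' length is reported as `seed_length`. Exact A:U / G:C pairing only — no
#' G:U wobble, no free-energy model. Per-predictor p-values are set to 0 so
#' the records always pass [filter_sites()], and the `source` column marks
#' them `seed_match` to keep them distinguishable from database evidence.
#'
#' @param mirna_seq miRNA sequence, 5'->3', over A/C/G/U (T accepted).
#' @param utr_seq UTR sequence, 5'->3', over A/C/G/T (U accepted).
#' @param min_seed_len minimum (and initial) seed length, >= 1.
#' @param mirna_id,gene_id identifiers carried into the records.
#' @return target-site data.frame (possibly 0-row) in the
#'   [read_target_table()] schema plus `utr_start` (1-based position of the
#'   site's 5' end in the UTR) and `source` columns.
#' @export
seed_match_predict <- function(mirna_seq, utr_seq, min_seed_len = 7,
                               mirna_id = "miRNA", gene_id = "gene") {
  stopifnot(min_seed_len >= 1)
  mirna <- toupper(gsub("T", "U", mirna_seq, fixed = TRUE))
  utr <- toupper(gsub("T", "U", utr_seq, fixed = TRUE))
  if (!grepl("^[ACGU]*$", mirna) || !grepl("^[ACGU]*$", utr))
    stop("sequences must be over the A/C/G/U(T) alphabet")
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      site_region = character(), seed_length = integer(),
                      seed_start = integer(), p_miRWalk = numeric(),
                      p_miRanda = numeric(), p_RNA22 = numeric(),
                      p_TargetScan = numeric(), utr_start = integer(),
                      source = character(), stringsAsFactors = FALSE)
  if (nchar(mirna) < min_seed_len || nchar(utr) < min_seed_len) return(empty)
  seed_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::RNAString(
      substr(mirna, 1L, min_seed_len))))
  hits <- Biostrings::matchPattern(seed_rc, Biostrings::RNAString(utr))
  if (length(hits) == 0L) return(empty)
  mirna_chars <- strsplit(mirna, "")[[1]]
  utr_chars <- strsplit(utr, "")[[1]]
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  starts <- Biostrings::start(hits)
  rows <- lapply(starts, function(s) {
    # extend the duplex: miRNA position k pairs with UTR position s - (k - min_seed_len)
    k <- min_seed_len
    while (k < length(mirna_chars)) {
      u <- s - (k + 1L - min_seed_len)
      if (u < 1L || utr_chars[u] != comp[[mirna_chars[k + 1L]]]) break
      k <- k + 1L
    }
    data.frame(mirna_id = mirna_id, gene_id = gene_id, site_region = "3UTR",
               seed_length = k, seed_start = 1L,
               p_miRWalk = 0, p_miRanda = 0, p_RNA22 = 0, p_TargetScan = 0,
               utr_start = s - (k - min_seed_len), source = "seed_match",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
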
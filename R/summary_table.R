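#' Read a per-gene per-group summary-statistics table
#'
#' The table layout mirrors published two-group expression tables: per gene,
#' mean / SD / SE and sample size for the case (deleted) and control groups,
#' the p-value as printed, and an optional direction flag (`DOWN`/`UP`).
#' Rows published as "Data not available" load with `available = FALSE` and
#' are excluded from testing downstream rather than dropped.
#'
#' Printed tables carry typos. Each row is screened by
#' [detect_suspect_rows()]; rows failing the screen are flagged
#' `suspect = TRUE` with a warning, but still loaded. Where the packaged
#' fixtures store a corrected value, the original printed string is kept in
#' the `provenance` column (format `field=printed_value`), and the screen
#' runs against the printed values so the correction remains auditable.
#'
#' @param path TSV with columns `gene_id`, `mean_case`, `sd_case`,
#'   `se_case`, `n_case`, `mean_ctrl`, `sd_ctrl`, `se_ctrl`, `n_ctrl`,
#'   `p_printed`, `flag`, `available` and optionally `provenance`.
#' @param quiet suppress the suspect-row warning.
#' @return data.frame of summary rows with logical `available` and
#'   `suspect` columns.
#' @export
read_summary_table <- function(path, quiet = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  needed <- c("gene_id", "mean_case", "sd_case", "se_case", "n_case",
              "mean_ctrl", "sd_ctrl", "se_ctrl", "n_ctrl")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("summary table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"flag" %in% names(df)) df$flag <- NA_character_
  if (!"p_printed" %in% names(df)) df$p_printed <- NA_real_
  if (!"available" %in% names(df)) df$available <- TRUE
  if (!"provenance" %in% names(df)) df$provenance <- NA_character_
  df$available <- as.logical(df$available)
  for (col in setdiff(needed, "gene_id")) df[[col]] <- as.numeric(df[[col]])

  av <- which(df$available)
  bad_sd <- av[!is.na(df$sd_case[av]) & df$sd_case[av] < 0 |
               !is.na(df$sd_ctrl[av]) & df$sd_ctrl[av] < 0]
  if (length(bad_sd))
    stop("negative SD for: ", paste(df$gene_id[bad_sd], collapse = ", "))
  bad_n <- av[df$n_case[av] < 2 | df$n_ctrl[av] < 2]
  if (length(bad_n))
    stop("group size < 2 for: ", paste(df$gene_id[bad_n], collapse = ", "))

  df$suspect <- detect_suspect_rows(df)
  if (any(df$suspect, na.rm = TRUE) && !quiet)
    warning("suspect printed values (kept, see provenance): ",
            paste(df$gene_id[df$suspect], collapse = ", "), call. = FALSE)
  df
}

#' Detect internally inconsistent printed summary rows
#'
#' Printed tables are screened with two redundancy checks on the values *as
#' printed* (reconstructed from the `provenance` column where a correction
#' has been applied):
#'
#' * SE identity: each group's standard error must satisfy
#'   `|se - sd/sqrt(n)| / se < rel_tol` — SE columns are derivable from SD
#'   and n, so a violation pinpoints a misprinted SD or SE.
#' * p reproduction: where a p-value is printed, the pooled two-sided t-test
#'   recomputed from (mean, sd, n) must fall within a factor of 2 of it
#'   (printed p's are rounded, so order-of-magnitude agreement is the
#'   strongest safe check); this catches a misprinted *mean*, which the SE
#'   identity cannot see.
#'
#' @param df summary table as from [read_summary_table()].
#' @param rel_tol relative tolerance of the SE identity (default 0.02).
#' @return logical vector, `TRUE` for suspect rows (`FALSE` for unavailable
#'   rows).
#' @export
detect_suspect_rows <- function(df, rel_tol = 0.02) {
  vapply(seq_len(nrow(df)), function(i) {
    if (!isTRUE(df$available[i])) return(FALSE)
    row <- as.list(df[i, ])
    # restore printed values recorded as "field=value" (";"-separated)
    if (!is.na(row$provenance) && nzchar(row$provenance)) {
      for (item in strsplit(row$provenance, ";", fixed = TRUE)[[1]]) {
        kv <- strsplit(item, "=", fixed = TRUE)[[1]]
        row[[trimws(kv[1])]] <- as.numeric(kv[2])
      }
    }
    se_bad <- function(se, sd, n)
      is.finite(se) && se > 0 && abs(se - sd / sqrt(n)) / se >= rel_tol
    if (se_bad(row$se_case, row$sd_case, row$n_case) ||
        se_bad(row$se_ctrl, row$sd_ctrl, row$n_ctrl)) return(TRUE)
    if (is.finite(row$p_printed) && row$p_printed > 0) {
      p <- pooled_t_p(row$mean_case, row$sd_case, row$n_case,
                      row$mean_ctrl, row$sd_ctrl, row$n_ctrl)
      ratio <- p / row$p_printed
      if (is.finite(ratio) && (ratio < 0.5 || ratio > 2)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Write a summary table as canonical TSV
#' @param df summary table data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Packaged study fixtures
#'
#' Accessors for the plain-text fixtures shipped with the package: the
#' in-region haploinsufficiency screen table (43 genes of the 5q common
#' deleted region, 29 case vs 17 control), the candidate-gene validation
#' table, the deleted-region annotation, and a *constructed* miRNA-target
#' site table wiring the 9 selected miRNAs to the in-region and candidate
#' genes (the original prediction-database snapshot is not redistributable,
#' so this wiring is synthetic and the 9-miRNA / 4-candidate counts are
#' fixture-conditional).
#'
#' @return `fixture_table1()`/`fixture_table2()`: summary-table data.frames;
#'   `fixture_region()`: a [region_annotation()]; `fixture_target_sites()`:
#'   a target-site data.frame as from [read_target_table()].
#' @name fixtures
NULL

fixture_path <- function(file)
  system.file("extdata", file, package = "cernadel", mustWork = TRUE)

#' @rdname fixtures
#' @param quiet suppress the suspect-row warning.
#' @export
fixture_table1 <- function(quiet = TRUE)
  read_summary_table(fixture_path("table1_summary.tsv"), quiet = quiet)

#' @rdname fixtures
#' @export
fixture_table2 <- function(quiet = TRUE)
  read_summary_table(fixture_path("table2_summary.tsv"), quiet = quiet)

#' @rdname fixtures
#' @export
fixture_region <- function()
  read_region(fixture_path("deleted_region.bed"),
              fixture_path("deleted_region_genes.tsv"))

#' @rdname fixtures
#' @export
fixture_target_sites <- function()
  read_target_table(fixture_path("target_sites_synthetic.tsv"))
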
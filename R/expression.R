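#' Construct and validate an expression matrix
#'
#' An expression matrix holds non-negative gene-level intensities (e.g.
#' microarray signal for bone-marrow CD34+ cells), genes in rows and samples
#' in columns. Missing values are `NA`; negative intensities and duplicated
#' gene or sample identifiers are rejected outright because every downstream
#' statistic assumes a clean, uniquely keyed matrix.
#'
#' @param values numeric matrix with unique, non-empty rownames (gene ids)
#'   and colnames (sample ids); `NA` marks missingness.
#' @return the validated matrix with class `"expression_matrix"` prepended.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid)))
    stop("expression matrix needs non-empty rownames (genes) and colnames (samples)")
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative intensity at gene '%s', sample '%s' (%g)",
                 gid[neg[1, 1]], sid[neg[1, 2]], values[neg[1, , drop = FALSE]]))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' The TSV dialect is canonical for this package: tab-separated, UTF-8, '.'
#' decimal, first column gene ids, remaining columns one per sample. GCT 1.2
#' files ("#1.2" header, dimension line, `Name`/`Description` columns) are
#' accepted as produced by GEO-style exports; the `Description` column is
#' dropped.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; guessed from the extension by default.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || trimws(header[1]) != "#1.2")
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- suppressWarnings(as.integer(strsplit(header[2], "\t")[[1]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimension line in ", path)
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) != dims[1] || (ncol(df) - 2L) != dims[2])
      stop(sprintf("GCT dimension line says %d x %d but body is %d x %d",
                   dims[1], dims[2], nrow(df), ncol(df) - 2L))
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  expression_matrix(vals)
}

#' Write an expression matrix as canonical TSV
#'
#' Inverse of [read_expression()] for the TSV dialect: a `gene_id` column
#' then one column per sample, full precision, no quoting.
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-group sample sheet
#'
#' Two-column TSV `sample_id`, `group`; group labels must be `CASE` or
#' `CONTROL` and both groups must be non-empty.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_sheet(df[[1]], df[[2]])
}

#' @rdname read_sample_sheet
#' @param sample_id character vector of sample identifiers.
#' @param group matching vector of `"CASE"`/`"CONTROL"` labels.
#' @export
sample_sheet <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- toupper(as.character(group))
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(group), c("CASE", "CONTROL"))
  if (length(bad))
    stop("unknown group labels (allowed CASE, CONTROL): ",
         paste(bad, collapse = ", "))
  if (!all(c("CASE", "CONTROL") %in% group))
    stop("both CASE and CONTROL groups must be non-empty")
  data.frame(sample_id = sample_id, group = group, stringsAsFactors = FALSE)
}

#' Write a sample sheet as TSV
#' @param sheet a sample sheet data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deleted-region annotation
#'
#' The commonly deleted region is a fixed genomic interval (BED convention:
#' 0-based half-open) together with an explicit in-region gene list. Gene
#' membership is carried as the list, not recomputed from coordinates,
#' because the screen works from a fixed published gene universe.
#'
#' @param region_id short identifier, e.g. `"5q_CDR"`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval bounds, `start < end`.
#' @param genes non-empty, duplicate-free character vector of member genes.
#' @return a `region_annotation` list.
#' @export
region_annotation <- function(region_id, chrom, start, end, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("region gene list must be non-empty")
  if (anyDuplicated(genes))
    stop("duplicate genes in region list: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (!(is.numeric(start) && is.numeric(end) && start >= 0 && end > start))
    stop("region needs 0 <= start < end")
  structure(list(region_id = region_id, chrom = chrom,
                 start = as.numeric(start), end = as.numeric(end),
                 genes = genes),
            class = "region_annotation")
}

#' Read a region annotation from BED6 plus a companion gene list
#'
#' @param bed_path BED6 file; the first record defines the region.
#' @param genes_path one-column TSV of member gene ids (header `gene_id`).
#' @return a [region_annotation()].
#' @export
read_region <- function(bed_path, genes_path) {
  bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED file needs at least 4 columns: ", bed_path)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)[[1]]
  region_annotation(region_id = bed[1, 4], chrom = bed[1, 1],
                    start = bed[1, 2], end = bed[1, 3], genes = genes)
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("Region %s (%s:%d-%d, 0-based half-open), %d member genes\n",
              x$region_id, x$chrom, x$start, x$end, length(x$genes)))
  invisible(x)
}

# per-gene per-group (mean, sd, n) over non-missing entries; used by the
# matrix t-test path and by pipeline reporting
group_stats <- function(expr, sheet, gene) {
  if (!gene %in% rownames(expr)) return(NULL)
  v <- expr[gene, sheet$sample_id]
  out <- lapply(c(CASE = "CASE", CONTROL = "CONTROL"), function(g) {
    x <- v[sheet$group == g]
    x <- x[!is.na(x)]
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  })
  out
}
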
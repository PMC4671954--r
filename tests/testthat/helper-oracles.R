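# Independent oracles and small generators used across the suite. Each is a
# deliberately naive alternative route to a quantity the package computes.

# two-sided p by numerically integrating the t density over |T| > |t|
quadrature_p <- function(t_stat, df) {
  if (!is.finite(t_stat)) return(0)
  2 * stats::integrate(function(x) stats::dt(x, df), lower = abs(t_stat),
                       upper = Inf, rel.tol = 1e-12)$value
}

# quadratic brute-force seed matcher: for every UTR position j (the base
# pairing miRNA position 1), extend complementarity towards the UTR 5' end
brute_seed_sites <- function(mirna_seq, utr_seq, min_len) {
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  mi <- strsplit(toupper(gsub("T", "U", mirna_seq)), "")[[1]]
  ut <- strsplit(toupper(gsub("T", "U", utr_seq)), "")[[1]]
  lens <- integer(0)
  for (j in seq_along(ut)) {
    k <- 0L
    while (k < length(mi) && j - k >= 1L && ut[j - k] == comp[[mi[k + 1L]]])
      k <- k + 1L
    if (k >= min_len) lens <- c(lens, k)
  }
  lens
}

# random unfiltered target-site table mixing passing and failing records
random_target_table <- function(n, n_mirna = 6, n_gene = 12) {
  data.frame(
    mirna_id = sprintf("miR-%02d", sample.int(n_mirna, n, replace = TRUE)),
    gene_id = sprintf("G%02d", sample.int(n_gene, n, replace = TRUE)),
    site_region = sample(c("3UTR", "5UTR", "CDS", "promoter"), n,
                         replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    seed_length = sample(5:9, n, replace = TRUE),
    seed_start = sample(1:3, n, replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    p_miRWalk = stats::runif(n, 0, 0.06),
    p_miRanda = stats::runif(n, 0, 0.06),
    p_RNA22 = stats::runif(n, 0, 0.06),
    p_TargetScan = stats::runif(n, 0, 0.06),
    stringsAsFactors = FALSE)
}

# brute-force edge set: distinct (miRNA, gene) pairs via set construction
brute_edges <- function(records)
  unique(paste(records$mirna_id, records$gene_id, sep = "\r"))

# brute-force per-miRNA haploinsufficient-target counts
brute_counts <- function(graph, haplo) {
  mirnas <- unique(graph$mirna_id)
  counts <- vapply(mirnas, function(m)
    length(unique(graph$gene_id[graph$mirna_id == m &
                                  graph$gene_id %in% haplo])), integer(1))
  counts[counts > 0]
}

# brute-force intersection: every gene adjacent to every selected miRNA
brute_candidates <- function(graph, selected, region_genes = character()) {
  genes <- unique(graph$gene_id)
  hit <- vapply(genes, function(g) all(vapply(selected, function(m)
    any(graph$mirna_id == m & graph$gene_id == g), logical(1))), logical(1))
  sort(setdiff(genes[hit], region_genes))
}

# minimal valid target record, overridable field by field
one_record <- function(...) {
  rec <- data.frame(mirna_id = "miR-01", gene_id = "G01",
                    site_region = "3UTR", seed_length = 7L, seed_start = 1L,
                    p_miRWalk = 0.01, p_miRanda = 0.01, p_RNA22 = 0.01,
                    p_TargetScan = 0.01, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}
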
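test_that("generator is deterministic and honors the study-shaped defaults", {
  sim1 <- generate_synthetic(seed = 1)
  sim2 <- generate_synthetic(seed = 1)
  expect_identical(sim1, sim2)
  expect_false(identical(unclass(sim1$expr),
                         unclass(generate_synthetic(seed = 2)$expr)))
  expect_equal(length(sim1$truth$released_mirnas), 9)
  expect_equal(length(sim1$truth$cerna_genes), 4)
  expect_equal(sum(sim1$sheet$group == "CASE"), 29)
  expect_equal(sum(sim1$sheet$group == "CONTROL"), 17)
  expect_equal(length(sim1$region$genes), 43)
  expect_equal(length(sim1$truth$haplo_genes), round(0.4 * 43))
})

test_that("generator output passes the container invariants and the filter", {
  sim <- generate_synthetic(seed = 5)
  expect_s3_class(sim$expr, "expression_matrix")
  expect_true(all(sim$expr > 0))
  # every record passes the default stringency filter
  expect_equal(nrow(filter_sites(sim$targets)), nrow(sim$targets))
  g <- collapse_to_graph(sim$targets)
  # planted wiring: every released miRNA targets >= threshold haplo genes
  for (m in sim$truth$released_mirnas)
    expect_gte(length(intersect(g$gene_id[g$mirna_id == m],
                                sim$truth$haplo_genes)), 5)
  # and every planted ceRNA is targeted by all released miRNAs
  for (ce in sim$truth$cerna_genes)
    expect_true(all(sim$truth$released_mirnas %in%
                      g$mirna_id[g$gene_id == ce]))
  # no decoy miRNA reaches the threshold by planted wiring
  decoys <- setdiff(unique(g$mirna_id), sim$truth$released_mirnas)
  for (m in decoys)
    expect_lt(length(intersect(g$gene_id[g$mirna_id == m],
                               sim$truth$haplo_genes)), 5)
})

test_that("impossible planted structure is rejected at configuration time", {
  expect_error(synthetic_config(n_released_mirnas = 10, n_mirnas = 9),
               "more released")
  expect_error(synthetic_config(haplo_fraction = 0.05), "threshold")
  expect_error(synthetic_config(deletion_effect = 0), "> 0")
  expect_error(synthetic_config(n_planted_cernas = 500,
                                n_background_genes = 100), "ceRNAs")
})

test_that("written cohorts re-read into equivalent objects", {
  sim <- generate_synthetic(synthetic_config(n_background_genes = 30,
                                             n_mirnas = 12,
                                             n_released_mirnas = 2,
                                             n_planted_cernas = 2,
                                             decoy_gene_targets = 5),
                            seed = 8)
  dir <- withr::local_tempdir()
  write_synthetic(sim, dir)
  expect_equal(unclass(read_expression(file.path(dir, "expression.tsv"))),
               unclass(sim$expr))
  expect_equal(read_sample_sheet(file.path(dir, "samples.tsv")), sim$sheet)
  region <- read_region(file.path(dir, "region.bed"),
                        file.path(dir, "region_genes.tsv"))
  expect_equal(region$genes, sim$region$genes)
  back <- read_target_table(file.path(dir, "target_sites.tsv"))
  expect_equal(nrow(back), nrow(sim$targets))
})

test_that("rescaled matrices hit printed moments exactly", {
  t2 <- fixture_table2()
  mm <- matrix_from_summary(t2, seed = 11)
  for (i in seq_len(nrow(t2))) {
    case <- mm$expr[t2$gene_id[i], mm$sheet$group == "CASE"]
    ctrl <- mm$expr[t2$gene_id[i], mm$sheet$group == "CONTROL"]
    expect_equal(mean(case), t2$mean_case[i], tolerance = 1e-12)
    expect_equal(sd(case), t2$sd_case[i], tolerance = 1e-12)
    expect_equal(mean(ctrl), t2$mean_ctrl[i], tolerance = 1e-12)
    expect_equal(sd(ctrl), t2$sd_ctrl[i], tolerance = 1e-12)
    expect_true(all(c(case, ctrl) >= 0))
  }
  # unavailable rows become untestable all-NA rows, not dropped
  t1 <- fixture_table1()
  mm1 <- matrix_from_summary(t1, seed = 12)
  expect_true(all(is.na(mm1$expr["SLC36A3", ])))
  expect_error(matrix_from_summary(transform(t2, n_case = 1), seed = 1),
               ">= 2")
})

test_that("pipeline recovers planted structure on a handful of cohorts", {
  rec <- recovery_experiment(n_seeds = 5, seed = 500)
  expect_gte(mean(rec$mirna_recall), 0.9)
  expect_gte(mean(rec$cerna_recall), 0.9)
  expect_gte(mean(rec$mirna_precision, na.rm = TRUE), 0.9)
  expect_gte(mean(rec$cerna_precision, na.rm = TRUE), 0.9)
})

test_that("recovery degrades on average as log-normal noise grows", {
  sig <- c(0.3, 1.0, 2.5)
  score <- vapply(sig, function(s) {
    rec <- recovery_experiment(n_seeds = 6,
                               cfg = synthetic_config(noise_sigma = s),
                               seed = 900)
    mean(rec$mirna_recall + rec$cerna_recall) / 2
  }, numeric(1))
  # a trend over the grid, not a strict per-seed inequality
  expect_gt(score[1], score[3])
  expect_gte(score[1], score[2])
})
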
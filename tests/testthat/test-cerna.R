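toy_graph <- function(edges) {
  g <- collapse_to_graph(do.call(rbind, lapply(seq_len(nrow(edges)),
    function(i) one_record(mirna_id = edges$m[i], gene_id = edges$g[i]))))
  g
}

test_that("ranking counts haplo targets and selects at an inclusive threshold", {
  edges <- expand.grid(m = "miR-A", g = paste0("H", 1:6),
                       stringsAsFactors = FALSE)
  edges <- rbind(edges, expand.grid(m = "miR-B", g = paste0("H", 1:4),
                                    stringsAsFactors = FALSE),
                 data.frame(m = "miR-C", g = "X1"),
                 data.frame(m = "miR-D", g = paste0("H", 1:5)))
  g <- toy_graph(edges)
  rk <- rank_released_mirnas(g, paste0("H", 1:6), threshold = 5)
  expect_equal(rk$ranking$mirna_id, c("miR-A", "miR-D", "miR-B"))
  expect_equal(rk$ranking$n_haplo_targets, c(6L, 5L, 4L))
  # count exactly 5 is selected; zero-count miRNAs are omitted entirely
  expect_equal(rk$selected, c("miR-A", "miR-D"))
  expect_false("miR-C" %in% rk$ranking$mirna_id)
  expect_error(rank_released_mirnas(g, character()), "nothing is released")
})

test_that("equal counts order lexicographically", {
  edges <- expand.grid(m = c("miR-z", "miR-a", "miR-m"), g = paste0("H", 1:5),
                       stringsAsFactors = FALSE)
  rk <- rank_released_mirnas(toy_graph(edges), paste0("H", 1:5))
  expect_equal(rk$ranking$mirna_id, c("miR-a", "miR-m", "miR-z"))
})

test_that("ranking counts equal brute force on random graphs", {
  withr::local_seed(21)
  for (i in 1:30) {
    g <- collapse_to_graph(filter_sites(random_target_table(150)))
    if (nrow(g) == 0) next
    haplo <- sample(unique(g$gene_id), min(5, length(unique(g$gene_id))))
    rk <- rank_released_mirnas(g, haplo, threshold = 2)
    oracle <- brute_counts(g, haplo)
    expect_setequal(rk$ranking$mirna_id, names(oracle))
    expect_equal(rk$ranking$n_haplo_targets,
                 unname(oracle[rk$ranking$mirna_id]))
    expect_true(all(diff(rk$ranking$n_haplo_targets) <= 0))
  }
})

test_that("candidate intersection equals brute-force enumeration", {
  withr::local_seed(22)
  region <- region_annotation("r", "chr1", 0, 10, c("G01", "G02", "G03"))
  n_checked <- 0
  for (i in 1:100) {
    g <- collapse_to_graph(filter_sites(random_target_table(200, 5, 10)))
    if (nrow(g) == 0) next
    haplo <- sample(unique(g$gene_id), min(4, length(unique(g$gene_id))))
    rk <- rank_released_mirnas(g, haplo, threshold = 1)
    cand <- find_cerna_candidates(g, rk, region)
    expect_equal(cand$candidates,
                 brute_candidates(g, rk$selected, region$genes))
    # evidence covers every candidate x selected-miRNA pair
    if (length(cand$candidates))
      expect_equal(nrow(cand$evidence),
                   length(cand$candidates) * length(rk$selected))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 90)
})

test_that("single selected miRNA yields its whole out-of-region neighborhood", {
  edges <- data.frame(m = "miR-A", g = c("H1", "H2", "H3", "X1", "X2"))
  g <- toy_graph(edges)
  region <- region_annotation("r", "chr1", 0, 10, c("H1", "H2", "H3"))
  rk <- rank_released_mirnas(g, c("H1", "H2", "H3"), threshold = 3)
  cand <- find_cerna_candidates(g, rk, region)
  expect_equal(cand$candidates, c("X1", "X2"))
  expect_equal(cand$excluded_in_region, c("H1", "H2", "H3"))
  # without the exclusion, in-region genes stay in
  keep <- find_cerna_candidates(g, rk, region, exclude_in_region = FALSE)
  expect_equal(keep$candidates, c("H1", "H2", "H3", "X1", "X2"))
})

test_that("an empty selected set is an error, never 'all genes'", {
  g <- toy_graph(data.frame(m = "miR-A", g = "H1"))
  rk <- rank_released_mirnas(g, "H1", threshold = 5)
  expect_equal(length(rk$selected), 0)
  expect_error(find_cerna_candidates(g, rk, NULL, exclude_in_region = FALSE),
               "undefined")
})

test_that("threshold and selected-set monotonicity hold on random graphs", {
  withr::local_seed(23)
  for (i in 1:20) {
    g <- collapse_to_graph(filter_sites(random_target_table(200, 6, 12)))
    if (nrow(g) == 0) next
    haplo <- sample(unique(g$gene_id), min(5, length(unique(g$gene_id))))
    rks <- lapply(1:4, function(th) rank_released_mirnas(g, haplo, th))
    for (th in 2:4) {
      # lowering the threshold never shrinks the selection
      expect_true(all(rks[[th]]$selected %in% rks[[th - 1]]$selected))
      # enlarging the selected set never grows the intersection
      if (length(rks[[th]]$selected) && length(rks[[th - 1]]$selected)) {
        c_hi <- find_cerna_candidates(g, rks[[th]], NULL,
                                      exclude_in_region = FALSE)$candidates
        c_lo <- find_cerna_candidates(g, rks[[th - 1]], NULL,
                                      exclude_in_region = FALSE)$candidates
        expect_true(all(c_lo %in% c_hi))
      }
    }
    # removing a haplo gene never increases any miRNA's count
    rk_full <- rks[[1]]$ranking
    sub <- rank_released_mirnas(g, haplo[-1], threshold = 1)$ranking
    for (m in sub$mirna_id)
      expect_lte(sub$n_haplo_targets[sub$mirna_id == m],
                 rk_full$n_haplo_targets[rk_full$mirna_id == m])
  }
})

test_that("candidate set is invariant under input record order", {
  withr::local_seed(24)
  recs <- random_target_table(200, 5, 10)
  region <- region_annotation("r", "chr1", 0, 10, "G01")
  run <- function(r) {
    g <- collapse_to_graph(filter_sites(r))
    rk <- rank_released_mirnas(g, c("G02", "G03", "G04"), threshold = 1)
    find_cerna_candidates(g, rk, region)$candidates
  }
  expect_equal(run(recs), run(recs[sample(nrow(recs)), ]))
})
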
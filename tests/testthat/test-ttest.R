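test_that("pooled summary t-test reproduces the published candidate p", {
  de <- t_test_from_summary(173.15608, 48.10625, 29,
                            217.83253, 40.57191, 17, gene_id = "GRAMD1B")
  expect_lt(abs(de$p_value - 0.00245), 1e-5)   # one unit in the last digit
  expect_equal(de$df, 44)
  expect_equal(de$direction, "DOWN")
  expect_true(de$significant)
})

test_that("identical groups give t = 0, p = 1; degenerate SDs are explicit", {
  de <- t_test_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(de$t_statistic, 0)
  expect_equal(de$p_value, 1)
  # zero variance both groups, equal means
  de0 <- t_test_from_summary(5, 0, 10, 5, 0, 10)
  expect_equal(de0$p_value, 1)
  # zero variance, unequal means: the p = 0 limit, with a warning
  expect_warning(de1 <- t_test_from_summary(5, 0, 10, 6, 0, 10),
                 "zero variance")
  expect_equal(de1$p_value, 0)
  # incomplete rows are reported untestable, never silently skipped
  deNA <- t_test_from_summary(5, NA, 10, 6, 1, 10, gene_id = "g")
  expect_false(deNA$testable)
  expect_false(deNA$significant)
})

test_that("summary p agrees with quadrature of the t density to 1e-9", {
  t1 <- fixture_table1()
  rows <- t1[t1$available, ][c(1, 5, 10, 20, 31, 41), ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    de <- t_test_from_summary(r$mean_case, r$sd_case, r$n_case,
                              r$mean_ctrl, r$sd_ctrl, r$n_ctrl)
    expect_equal(de$p_value, quadrature_p(de$t_statistic, de$df),
                 tolerance = 1e-9)
  }
})

test_that("recomputed p matches every printed non-suspect p at printed precision", {
  for (tab in list(fixture_table1(), fixture_table2())) {
    rows <- tab[tab$available & !tab$suspect & is.finite(tab$p_printed), ]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      de <- t_test_from_summary(r$mean_case, r$sd_case, r$n_case,
                                r$mean_ctrl, r$sd_ctrl, r$n_ctrl,
                                gene_id = r$gene_id)
      ratio <- de$p_value / r$p_printed
      expect_gt(ratio, 0.5)
      expect_lt(ratio, 2)
      # where >= 3 significant figures are printed, agree within 5%
      sig_digits <- nchar(gsub("^[0.]+", "", format(r$p_printed,
                                                    scientific = FALSE)))
      if (sig_digits >= 3)
        expect_equal(de$p_value, r$p_printed, tolerance = 0.05,
                     label = r$gene_id)
    }
  }
})

test_that("matrix path equals summary path when the matrix matches the summary", {
  t2 <- fixture_table2()
  mm <- matrix_from_summary(t2, seed = 7)
  de_m <- de_from_matrix(mm$expr, mm$sheet)
  de_s <- de_from_summary(t2)
  expect_equal(de_m$p_value, de_s$p_value, tolerance = 1e-10)
  expect_equal(de_m$t_statistic, de_s$t_statistic, tolerance = 1e-10)
  expect_lt(abs(de_m$p_value[de_m$gene_id == "GRAMD1B"] - 0.00245), 1e-5)
  # permuting sample order changes nothing
  perm <- sample(colnames(mm$expr))
  expr_p <- expression_matrix(unclass(mm$expr)[, perm])
  expect_equal(de_from_matrix(expr_p, mm$sheet)$p_value, de_m$p_value)
})

test_that("matrix t p agrees with a label-permutation null within MC error", {
  withr::local_seed(42)
  n1 <- 29; n2 <- 17
  x <- 60 * exp(rnorm(n1 + n2, sd = 0.3))   # one null gene
  expr <- expression_matrix(matrix(x, nrow = 1,
                                   dimnames = list("g", sprintf("s%02d",
                                                                1:(n1 + n2)))))
  sheet <- sample_sheet(colnames(expr), rep(c("CASE", "CONTROL"), c(n1, n2)))
  de <- de_from_matrix(expr, sheet)
  obs_t <- abs(de$t_statistic)
  perm_t <- replicate(1000, {
    g <- sample(sheet$group)
    a <- x[g == "CASE"]; b <- x[g == "CONTROL"]
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    abs((mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2)))
  })
  p_perm <- mean(perm_t >= obs_t)
  mc_se <- sqrt(de$p_value * (1 - de$p_value) / 1000)
  expect_lt(abs(p_perm - de$p_value), 4 * mc_se + 0.01)
})

test_that("missing values are excluded pairwise with a 2-per-group floor", {
  m <- matrix(abs(rnorm(24, 50, 5)), nrow = 2,
              dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:12)))
  m[2, 1:5] <- NA                       # leaves 1 CASE value for g2
  expr <- expression_matrix(m)
  sheet <- sample_sheet(colnames(expr),
                        rep(c("CASE", "CONTROL"), each = 6))
  de <- de_from_matrix(expr, sheet)
  expect_true(de$testable[de$gene_id == "g1"])
  expect_false(de$testable[de$gene_id == "g2"])
})

test_that("haploinsufficiency call returns exactly the printed DOWN set", {
  t1 <- fixture_table1()
  de <- de_from_summary(t1)
  region <- fixture_region()
  expect_equal(call_haploinsufficient(de, region),
               c("AFAP1L1", "CCDC69", "CSF1R", "CSNK1A1", "DCTN4", "G3BP1",
                 "GM2A", "GRPEL2", "HMGXB3", "PCYOX1L", "PPARGC1B", "RBM22",
                 "RPS14", "SLC26A2", "SMIM3", "TCOF1"))
  # the call is one-directional: no in-region gene is significant-UP
  expect_equal(sum(de$significant & de$direction == "UP", na.rm = TRUE), 0)
  # alpha boundary: CSF1R (p ~ 0.0475) in at 0.05, out at 0.04
  expect_true("CSF1R" %in% call_haploinsufficient(de, region, alpha = 0.05))
  expect_false("CSF1R" %in% call_haploinsufficient(de, region, alpha = 0.04))
  # the call matches the printed flags row for row
  expect_setequal(call_haploinsufficient(de, region),
                  t1$gene_id[!is.na(t1$flag) & t1$flag == "DOWN"])
  expect_error(call_haploinsufficient(de, region, alpha = 0), "alpha")
})

test_that("the optional BH correction only ever shrinks the call set", {
  t1 <- fixture_table1()
  region <- fixture_region()
  raw <- call_haploinsufficient(de_from_summary(t1), region)
  bh <- call_haploinsufficient(de_from_summary(t1, p_adjust = "BH"), region)
  expect_true(all(bh %in% raw))
  # BH-adjusted p's are never smaller than raw p's
  de_bh <- de_from_summary(t1, p_adjust = "BH")
  expect_true(all(de_bh$p_adjusted[de_bh$testable] >=
                    de_bh$p_value[de_bh$testable]))
  # default is the raw rule: p_adjusted coincides with p_value
  de_raw <- de_from_summary(t1)
  expect_identical(de_raw$p_adjusted, de_raw$p_value)
})
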
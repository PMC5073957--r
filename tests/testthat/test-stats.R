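# direct O/E formula, independent of chisq.test
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

test_that("chi_square_independence matches closed forms and the O/E oracle", {
  perfect <- chi_square_independence(rbind(c(5, 5), c(5, 5)))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  diag20 <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(diag20$statistic, 20)
  expect_equal(diag20$df, 1L)

  set.seed(8)
  for (i in 1:20) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, 20) + 1, nrow = nr)
    res <- chi_square_independence(tab)
    expect_equal(res$statistic, oracle_chi2(tab), tolerance = 1e-10)
    expect_equal(res$df, (nrow(tab) - 1) * (ncol(tab) - 1))
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               "degenerate")
})

test_that("Monte Carlo p agrees with the analytic p within 3 standard errors", {
  # a large-count table, where the continuous chi-square tail is a valid
  # description of the discrete fixed-margin null
  tab <- rbind(c(120, 100, 95), c(100, 110, 105), c(95, 100, 110))
  analytic <- chi_square_independence(tab)$p_value
  mc <- chi_square_independence(tab, method = "monte_carlo",
                                mc_reps = 1e5, mc_seed = 42)
  se <- sqrt(analytic * (1 - analytic) / 1e5)
  expect_lt(abs(mc$p_value - analytic), 3 * se + 2 / 1e5)
  # seeded Monte Carlo is reproducible
  mc2 <- chi_square_independence(tab, method = "monte_carlo",
                                 mc_reps = 1e5, mc_seed = 42)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("compare_two_groups runs Welch t with a rank-test companion", {
  same <- compare_two_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$t_p, 1)
  far <- compare_two_groups(c(1, 2, 3), c(101, 102, 103))
  expect_lt(far$t_p, 0.01)
  expect_lt(far$mw_p, 0.2)   # n = 3 exact rank test cannot go below 0.1
  expect_error(compare_two_groups(5, c(1, 2)), "group A")
  expect_error(compare_two_groups(c(1, 2), c(3, 3)[1]), "group B")
})

test_that("anova_lengths reproduces hand-computed sums of squares", {
  res <- anova_lengths(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$F_statistic, 13.5)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  ident <- anova_lengths(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$F_statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(anova_lengths(list(a = c(1, 2, 3))), "2 groups")
  expect_error(anova_lengths(list(a = c(1, 2), b = 3)), "fewer than 2")
})

test_that("two-group ANOVA F equals the pooled-variance t squared", {
  set.seed(19)
  for (i in 1:10) {
    a <- rnorm(sample(4:12, 1), mean = 3)
    b <- rnorm(sample(4:12, 1), mean = 5)
    f <- anova_lengths(list(a = a, b = b))
    t_pooled <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(f$F_statistic, unname(t_pooled$statistic)^2,
                 tolerance = 1e-9)
    expect_equal(f$p_value, t_pooled$p.value, tolerance = 1e-9)
  }
})

test_that("summarize_screen computes fractions, ratios and per-key rows", {
  recs <- make_records(c(strrep("A", 50), strrep("A", 60), strrep("A", 70),
                         strrep("A", 80)), ids = c("a", "b", "c", "d"))
  classification <- data.frame(
    protein_id = c("a", "b", "c", "d"),
    label = c("pcc_only", "ncc_only", "mixed", "cc_free"))
  clusters <- rbind(make_cluster("a", "positive", 1, 10),
                    make_cluster("b", "negative", 1, 10),
                    make_cluster("c", "positive", 1, 10),
                    make_cluster("c", "negative", 20, 30))
  s <- summarize_screen(clusters, classification, recs)
  expect_equal(s$overall$cc_free_fraction, 0.25)
  expect_equal(s$overall$n_mixed, 1L)
  expect_equal(s$overall$n_pcc, 2L)
  expect_equal(s$overall$n_ncc, 2L)
  expect_equal(s$by_key$key, "all")
  expect_equal(s$by_key$ncc_pcc_ratio, 1.0)
})

test_that("NCC:PCC ratio follows counts and flags the undefined case", {
  recs <- make_records(rep(strrep("A", 30), 2), ids = c("a", "b"))
  classification <- data.frame(protein_id = c("a", "b"),
                               label = c("mixed", "cc_free"))
  clusters <- do.call(rbind, c(
    lapply(1:30, function(i) make_cluster("a", "negative", i * 2, i * 2)),
    lapply(1:10, function(i) make_cluster("a", "positive", i * 2, i * 2))))
  s <- summarize_screen(clusters, classification, recs)
  expect_equal(s$by_key$ncc_pcc_ratio[s$by_key$key == "all"], 3.0)

  empty <- summarize_screen(make_cluster()[0, ],
                            data.frame(protein_id = c("a", "b"),
                                       label = c("cc_free", "cc_free")),
                            recs)
  expect_true(is.na(empty$by_key$ncc_pcc_ratio))
  expect_equal(empty$overall$n_clusters, 0L)
})

test_that("per-family counts are additive to the all row", {
  plants <- c(lapply(1:6, function(i) plant_spec("positive", 15)),
              lapply(1:9, function(i) plant_spec("negative", 15)))
  sim <- generate_proteome(sim_config(40, seed = 13, plant_specs = plants))
  res <- scan_proteome(sim$records, scan_config())
  s <- summarize_screen(res$clusters, res$classification, sim$records,
                        sim$metadata)
  fam <- s$by_key[s$by_key$kind == "family", ]
  all_row <- s$by_key[s$by_key$kind == "all", ]
  expect_equal(sum(fam$n_pcc), all_row$n_pcc)
  expect_equal(sum(fam$n_ncc), all_row$n_ncc)
  expect_equal(sum(fam$n_proteins), all_row$n_proteins)
  grp <- s$by_key[s$by_key$kind == "group", ]
  expect_equal(sum(grp$n_ncc), all_row$n_ncc)
  # summaries are invariant under input permutation
  perm <- sample(nrow(res$clusters))
  s2 <- summarize_screen(res$clusters[perm, ], res$classification,
                         sim$records, sim$metadata)
  expect_equal(s2$by_key, s$by_key)
})

test_that("cluster ids missing from metadata are grouped as unknown", {
  recs <- make_records(c(strrep("A", 30), strrep("A", 30)),
                       ids = c("a", "b"))
  classification <- data.frame(protein_id = c("a", "b"),
                               label = c("pcc_only", "cc_free"))
  clusters <- make_cluster("a", "positive", 1, 10)
  meta <- data.frame(protein_id = "b", virus = "v", family = "f",
                     group = "dsDNA")
  expect_warning(s <- summarize_screen(clusters, classification, recs, meta),
                 "unknown")
  expect_true("unknown" %in% s$by_key$key)
})
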
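test_that("encode_charge maps only the polarity alphabet to 1", {
  expect_equal(encode_charge("KRDEA", "positive"), c(1L, 1L, 0L, 0L, 0L))
  expect_equal(encode_charge("KRDEA", "negative"), c(0L, 0L, 1L, 1L, 0L))
  # histidine and ambiguity codes are neutral
  expect_equal(encode_charge("HXHX", "positive"), rep(0L, 4))
  expect_equal(encode_charge("BZXUOJ", "negative"), rep(0L, 6))
})

test_that("estimate_background pools, splits per protein, or passes through", {
  expect_equal(estimate_background(make_records("KKAA"), "positive",
                                   scan_config()), 0.5)
  recs <- make_records(c("KA", "AA"))
  expect_equal(estimate_background(recs, "positive", scan_config()), 0.25)
  pp <- estimate_background(recs, "positive",
                            scan_config(background_mode = "per_protein"))
  expect_equal(unname(pp), c(0.5, 0))
  expect_equal(estimate_background(recs, "positive", fixed_config(0.1)), 0.1)
  cfg_nofix <- scan_config(background_mode = "fixed", fixed_p0_neg = 0.1)
  expect_error(estimate_background(recs, "positive", cfg_nofix), "fixed_p0_pos")
})

test_that("binomial_tail matches closed forms and the pmf-summation oracle", {
  expect_equal(binomial_tail(0, 20, 0.3), 1.0)
  expect_equal(binomial_tail(20, 20, 0.5), 0.5^20)
  expect_equal(binomial_tail(10, 20, 0.1), 7.150904021079e-06,
               tolerance = 1e-10)
  for (k in c(0, 3, 10, 47, 100))
    for (p0 in c(0.02, 0.1, 0.5))
      expect_equal(binomial_tail(k, 100, p0), oracle_tail(k, 100, p0),
                   tolerance = 1e-10)
  expect_error(binomial_tail(21, 20, 0.1), "k")
  expect_error(binomial_tail(5, 20, 1.2), "p0")
})

test_that("critical_count finds the smallest significant count", {
  expect_equal(critical_count(20, 0.0, 1e-5), 1L)
  expect_equal(critical_count(20, 0.1, 1e-5), 10L)
  expect_equal(critical_count(20, 0.5, 1e-5), 20L)
  # oracle bracketing for the two nontrivial values
  expect_lte(oracle_tail(10, 20, 0.1), 1e-5)
  expect_gt(oracle_tail(9, 20, 0.1), 1e-5)
  expect_lte(oracle_tail(20, 20, 0.5), 1e-5)
  expect_gt(oracle_tail(19, 20, 0.5), 1e-5)
  # unattainable: even an all-charged short window is not significant
  expect_identical(critical_count(3, 0.9, 1e-5), NA_integer_)
})

test_that("critical_count is monotone in alpha and p0", {
  p0_grid <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5)
  alpha_grid <- 10^(-(3:8))
  for (p0 in p0_grid) {
    ks <- vapply(alpha_grid, function(a) critical_count(20, p0, a),
                 integer(1))
    expect_true(all(diff(ks[!is.na(ks)]) >= 0))   # smaller alpha, larger k*
  }
  for (a in alpha_grid) {
    ks <- vapply(p0_grid, function(p0) critical_count(20, p0, a), integer(1))
    expect_true(all(diff(ks[!is.na(ks)]) >= 0))   # larger p0, larger k*
  }
})

test_that("scan_protein detects a planted run and trims to charged bounds", {
  seq <- paste0(strrep("A", 10), strrep("K", 12), strrep("A", 10))
  cl <- scan_protein(make_records(seq)[1, ], "positive", 0.05,
                     fixed_config())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 11L)
  expect_equal(cl$end, 22L)
  expect_equal(cl$length, 12L)
  expect_equal(cl$charged_count, 12L)
  expect_equal(cl$net_charge, 12L)
  expect_equal(cl$sequence, strrep("K", 12))
  # agrees with the all-window brute force
  orc <- oracle_scan(seq, "positive", 0.05)
  expect_equal(cl[, c("start", "end")], orc$intervals)
})

test_that("scan_protein returns nothing on neutral sequence", {
  rec <- make_records(strrep("A", 40))[1, ]
  expect_equal(nrow(scan_protein(rec, "positive", 0.05, fixed_config())), 0L)
  expect_equal(nrow(scan_protein(rec, "negative", 0.05, fixed_config())), 0L)
})

test_that("proteins shorter than the window are scanned as one window", {
  # length 10 < w = 20: single window of width 10; k*(10, 0.05, 1e-5) applies
  rec <- make_records(strrep("K", 10))[1, ]
  cl <- scan_protein(rec, "positive", 0.05, fixed_config())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 1L)
  expect_equal(cl$end, 10L)
  expect_equal(cl$min_window_p, 0.05^10)
})

test_that("scan matches the brute-force oracle on random sequences", {
  set.seed(42)
  cfg <- fixed_config(0.08)
  for (i in 1:60) {
    L <- sample(10:200, 1)
    f <- runif(1, 0.02, 0.3)
    seq <- random_aa_seq(L, f)
    cl <- scan_protein(make_records(seq)[1, ], "positive", 0.08, cfg)
    orc <- oracle_scan(seq, "positive", 0.08)
    expect_equal(cl[, c("start", "end")], orc$intervals)
  }
})

test_that("reported clusters respect boundary, disjointness and p-value invariants", {
  set.seed(7)
  cfg <- fixed_config(0.06)
  for (i in 1:40) {
    seq <- random_aa_seq(sample(30:300, 1), runif(1, 0.05, 0.35))
    cl <- scan_protein(make_records(seq)[1, ], "positive", 0.06, cfg)
    if (nrow(cl) == 0) next
    first <- substr(cl$sequence, 1, 1)
    last <- substr(cl$sequence, cl$length, cl$length)
    expect_true(all(first %in% c("K", "R")))
    expect_true(all(last %in% c("K", "R")))
    expect_true(all(cl$min_window_p <= cfg$alpha))
    expect_true(all(cl$charged_count >= 1))
    if (nrow(cl) > 1)
      expect_true(all(cl$start[-1] > cl$end[-nrow(cl)])) # disjoint, sorted
  }
})

test_that("scan_proteome labels proteins and is deterministic", {
  recs <- make_records(c(
    paste0(strrep("A", 10), strrep("K", 12), strrep("A", 10),
           strrep("D", 12), strrep("A", 10)),
    paste0(strrep("A", 10), strrep("R", 12), strrep("A", 10)),
    strrep("A", 60)))
  res <- scan_proteome(recs, fixed_config())
  expect_equal(res$classification$label, c("mixed", "pcc_only", "cc_free"))
  expect_setequal(unique(res$clusters$polarity), c("positive", "negative"))
  res2 <- scan_proteome(recs, fixed_config())
  expect_identical(res, res2)
})

test_that("mixed label equals the intersection of PCC and NCC protein sets", {
  plants <- c(lapply(1:6, function(i) plant_spec("positive", 15)),
              lapply(1:6, function(i) plant_spec("negative", 15)))
  sim <- generate_proteome(sim_config(25, seed = 31, plant_specs = plants))
  res <- scan_proteome(sim$records, scan_config())
  pcc <- unique(res$clusters$protein_id[res$clusters$polarity == "positive"])
  ncc <- unique(res$clusters$protein_id[res$clusters$polarity == "negative"])
  mixed <- res$classification$protein_id[res$classification$label == "mixed"]
  expect_setequal(mixed, intersect(pcc, ncc))
  free <- res$classification$protein_id[res$classification$label == "cc_free"]
  expect_setequal(free, setdiff(sim$records$id, union(pcc, ncc)))
})

test_that("planted clusters are recovered by the proteome scan", {
  bg <- default_background()
  bg[c("K", "R", "D", "E")] <- 0.025
  bg[!names(bg) %in% c("K", "R", "D", "E")] <- (1 - 0.1) / 16
  plants <- c(lapply(1:10, function(i) plant_spec("positive", 15)),
              lapply(1:5, function(i) plant_spec("negative", 15)))
  sim <- generate_proteome(sim_config(40, seed = 5, plant_specs = plants,
                                      background = bg))
  res <- scan_proteome(sim$records, fixed_config(0.05))
  rec <- evaluate_recovery(sim$truths, res$clusters)
  expect_equal(rec$recall, 1.0)
  expect_equal(sum(sim$truths$polarity == "positive"), 10L)
  expect_equal(sum(sim$truths$polarity == "negative"), 5L)
})

test_that("CPP candidates are positive clusters of 7-30 residues", {
  cl <- rbind(make_cluster("a", "positive", 1, 15),
              make_cluster("b", "positive", 1, 61),
              make_cluster("c", "negative", 1, 15),
              make_cluster("d", "positive", 1, 6),
              make_cluster("e", "positive", 1, 7),
              make_cluster("f", "positive", 1, 30))
  out <- flag_cpp_candidates(cl)
  expect_equal(out$cpp_candidate, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
})
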
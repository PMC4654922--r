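test_that("crosstab_pair counts cells and drops incomplete individuals", {
  d <- explicit_dataset(g1 = c(0, 0, 1, NA), g2 = c(0, 0, 2, 0),
                        trait = c(1, 0, 1, 0))
  ct <- crosstab_pair(d, c(1, 2))
  expect_equal(ct$n[1, 1], 2)
  expect_equal(ct$cases[1, 1], 1)
  expect_equal(ct$n[2, 3], 1)
  expect_equal(ct$cases[2, 3], 1)
  expect_equal(sum(ct$n), 3)          # 4th individual dropped
  expect_equal(ct$n_used, 3)
})

test_that("crosstab_pair handles an all-missing SNP and rejects self-pairs", {
  d <- explicit_dataset(g1 = c(NA, NA, NA), g2 = c(0, 1, 2),
                        trait = c(1, 0, 1))
  ct <- crosstab_pair(d, c(1, 2))
  expect_equal(sum(ct$n), 0)
  expect_error(crosstab_pair(d, c(2, 2)), "self-pair")
})

test_that("crosstab totals match an independent recount on simulated data", {
  d <- toy_dataset(20, 500, seed = 3, missing_rate = 0.1)
  for (pair in list(c(1, 2), c(5, 19))) {
    ct <- crosstab_pair(d, pair)
    both_ok <- sum(!is.na(d$genotypes[, pair[1]]) &
                     !is.na(d$genotypes[, pair[2]]))
    expect_equal(sum(ct$n), both_ok)
    expect_equal(sum(ct$cases) + sum(ct$controls), both_ok)
  }
})

test_that("cell labelling follows the one-vs-rest chi-squared rule", {
  # cell (0,0): 10 cases / 0 controls; rest at (1,1): 90 cases / 100 controls
  # hand chi-squared: 200*(10*100 - 0*90)^2 / (10*190*100*100) = 10.526 > 2.706
  g <- c(rep(0, 10), rep(1, 190))
  trait <- c(rep(1, 10), rep(1, 90), rep(0, 100))
  d <- explicit_dataset(g, g, trait)
  ct <- crosstab_pair(d, c(1, 2))
  hlo <- categorize_cells(ct, alpha_cell = 0.1)
  expect_equal(hlo[1, 1], "H")
  expect_equal(hlo[2, 2], "L")        # complementary cell is lower risk
  expect_true(all(hlo[ct$n == 0] == "O"))
})

test_that("degenerate continuous cells are undecided", {
  # one cell whose values equal the rest's mean with no contrast
  d <- explicit_dataset(g1 = c(0, 0, 1, 1, 1, 1), g2 = c(0, 0, 1, 1, 1, 1),
                        trait = c(0, 0, -1, 1, -1, 1),
                        trait_type = "continuous")
  hlo <- categorize_cells(crosstab_pair(d, c(1, 2)))
  expect_equal(hlo[1, 1], "O")
})

test_that("mbmdr_statistic is zero iff all cells are undecided", {
  d <- toy_dataset(4, 200, seed = 5)
  ct <- crosstab_pair(d, c(1, 2))
  all_o <- matrix("O", 3, 3)
  expect_identical(mbmdr_statistic(all_o, ct), 0)
  # single H cell holding all its subjects' cases: equals the hand 2x2 chi2
  g <- c(rep(0, 10), rep(1, 190))
  trait <- c(rep(1, 10), rep(1, 90), rep(0, 100))
  dh <- explicit_dataset(g, g, trait)
  cth <- crosstab_pair(dh, c(1, 2))
  hlo <- matrix("O", 3, 3); hlo[1, 1] <- "H"
  expect_equal(mbmdr_statistic(hlo, cth),
               200 * (10 * 100)^2 / (10 * 190 * 100 * 100))
})

test_that("statistic takes the max over the H and L branches", {
  set.seed(8)
  for (tt in c("binary", "continuous")) {
    d <- toy_dataset(6, 300, tt, seed = 11)
    ct <- crosstab_pair(d, c(2, 5))
    hlo <- categorize_cells(ct)
    h_only <- hlo; h_only[h_only == "L"] <- "O"
    l_only <- hlo; l_only[l_only == "H"] <- "O"
    expect_equal(mbmdr_statistic(hlo, ct),
                 max(mbmdr_statistic(h_only, ct),
                     mbmdr_statistic(l_only, ct)))
  }
})

test_that("pair_statistic is symmetric in the pair and non-negative", {
  for (tt in c("binary", "continuous")) {
    d <- toy_dataset(8, 150, tt, seed = 21, missing_rate = 0.05)
    for (p in list(c(1, 2), c(3, 7), c(5, 8))) {
      t1 <- pair_statistic(d, p)
      expect_gte(t1, 0)
      expect_equal(t1, pair_statistic(d, rev(p)))
    }
  }
})

test_that("compiled kernel agrees with the pure-R reference on every pair", {
  for (tt in c("binary", "continuous")) {
    for (adj in c(FALSE, TRUE)) {
      d <- toy_dataset(12, 120, tt, seed = 42, missing_rate = 0.05)
      top <- scan_all_pairs(d, n = n_pairs(d), adjust_main = adj)
      ref <- vapply(seq_len(nrow(top)), function(k)
        pair_statistic(d, c(top$snp_a[k], top$snp_b[k]), adjust_main = adj),
        numeric(1))
      expect_equal(top$statistic, ref, tolerance = 1e-9)
    }
  }
})

test_that("global main-effect correction residualizes the trait", {
  d <- toy_dataset(5, 400, "continuous", seed = 31)
  dc <- correct_main_effects(d)
  expect_equal(dc$trait_type, "continuous")
  for (j in 1:5) for (lev in 1:2) {
    dum <- as.numeric(d$genotypes[, j] == lev)
    expect_lt(abs(stats::cor(dc$trait, dum)), 1e-8)
  }
  # trait exactly linear in one SNP's dummies vanishes after correction
  d2 <- d
  d2$trait <- 2 * (d$genotypes[, 1] == 1) - 3 * (d$genotypes[, 1] == 2) + 1
  expect_lt(max(abs(correct_main_effects(d2)$trait)), 1e-10)
  d3 <- d
  d3$trait <- rep(1, length(d$trait))
  expect_error(correct_main_effects(d3), "degenerate trait")
})

test_that("pair-local correction demotes a main-effect SNP in the scan", {
  set.seed(17)
  d <- simulate_null(15, 600, "continuous", seed = 91)
  d$trait <- d$trait + 1.0 * d$genotypes[, 7]   # strong additive main effect
  plain <- scan_all_pairs(d, n = 5)
  expect_true(7 %in% c(plain$snp_a[1], plain$snp_b[1]))
  adj <- scan_all_pairs(d, n = 5, adjust_main = TRUE)
  expect_false(7 %in% c(adj$snp_a[1], adj$snp_b[1]))
})

test_that("scan_all_pairs matches an exhaustive sort (oracle equivalence)", {
  for (tt in c("binary", "continuous")) {
    d <- toy_dataset(9, 120, tt, seed = 55, missing_rate = 0.05)
    bf <- brute_force_scan(d)
    ord <- order(-bf$statistic, bf$snp_a, bf$snp_b)
    top <- scan_all_pairs(d, n = 10)
    expect_equal(top$statistic, bf$statistic[ord][1:10], tolerance = 1e-9)
    expect_equal(top$snp_a, bf$snp_a[ord][1:10])
    expect_equal(top$snp_b, bf$snp_b[ord][1:10])
  }
})

test_that("scan visits all pairs, bounds n, and tie-breaks by pair index", {
  d <- toy_dataset(3, 50, seed = 2)
  top <- scan_all_pairs(d, n = 3)
  expect_equal(attr(top, "m"), 3)
  expect_equal(nrow(top), 3)
  expect_warning(top2 <- scan_all_pairs(d, n = 10), "exceeds")
  expect_equal(nrow(top2), 3)
  # duplicated SNP columns force exact ties; lowest pair index must win
  g <- toy_dataset(2, 80, seed = 9)$genotypes
  dd <- mbmdr_dataset(cbind(g, g), toy_dataset(2, 80, seed = 9)$trait)
  top3 <- scan_all_pairs(dd, n = 6)
  ties <- top3[duplicated(top3$statistic) |
                 duplicated(top3$statistic, fromLast = TRUE), ]
  if (nrow(ties) > 1) {
    lin <- (ties$snp_a - 1) * 4 - (ties$snp_a - 1) * ties$snp_a / 2 +
      (ties$snp_b - ties$snp_a - 1)
    grp <- split(lin, ties$statistic)
    for (g_ in grp) expect_equal(g_, sort(g_))
  }
})
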
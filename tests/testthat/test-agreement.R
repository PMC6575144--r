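# brute-force agreement oracle: po/pe by explicit counting loops
brute_kappa <- function(m) {
  n <- sum(m)
  po <- 0
  for (i in seq_len(nrow(m))) po <- po + m[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(m))) {
    ri <- sum(m[i, ]) / n
    ci <- sum(m[, i]) / n
    pe <- pe + ri * ci
  }
  (po - pe) / (1 - pe)
}

test_that("crosstabs match a naive pairwise count", {
  set.seed(11)
  ids <- sprintf("i%03d", 1:100)
  a <- setNames(sample(c("x", "y", "z"), 100, TRUE), ids)
  b <- setNames(sample(c("p", "q"), 100, TRUE), ids)
  tab <- build_crosstab(a, b)
  for (av in c("x", "y", "z")) {
    for (bv in c("p", "q")) {
      brute <- sum(vapply(ids, function(i) a[i] == av && b[i] == bv,
                          logical(1)))
      expect_identical(tab[av, bv], as.integer(brute))
    }
  }
  # mismatched universes error; ids are matched by name, not position
  expect_error(build_crosstab(a, b[1:99]), "universes differ")
  perm <- b[sample(ids)]
  expect_identical(build_crosstab(a, perm), tab)
})

test_that("collapsing pools categories without losing mass", {
  labs <- setNames(c("IN_LTC", "TRANSITIONING", "OTHERWISE_ASSOCIATED",
                     "NOT_ASSOCIATED"), c("a", "b", "c", "d"))
  pooled <- collapse_labels(labs, c(TRANSITIONING = "other_ltc",
                                    OTHERWISE_ASSOCIATED = "other_ltc"))
  expect_identical(unname(pooled),
                   c("IN_LTC", "other_ltc", "other_ltc", "NOT_ASSOCIATED"))
  expect_identical(length(pooled), length(labs))
})

test_that("published SRF cross-tabulation replays exactly", {
  ref <- reference_counts()
  expect_equal(unname(ref$table_srf["yes", ]), c(106, 8, 149))
  expect_equal(sum(ref$table_srf), 47759)
  expect_equal(unname(colSums(ref$table_srf)), c(428, 609, 46722))
})

test_that("Cohen's kappa reproduces the published agreement statistics", {
  rep <- replay_code_validation()
  # SRF injury code vs algorithm living-in-LTC: kappa 0.30 (CI 0.26-0.35)
  expect_identical(round(rep$kappa_srf$kappa, 2), 0.30)
  expect_identical(round(rep$kappa_srf$ci95, 2), c(0.26, 0.35))
  # LTC/nursing-home death code: kappa 0.17 (CI 0.14-0.20), both margins
  expect_identical(round(rep$kappa_deathloc$kappa, 2), 0.17)
  expect_identical(round(rep$kappa_deathloc$ci95, 2), c(0.14, 0.20))
  rep567 <- replay_code_validation(deathloc_total = 567)
  expect_identical(round(rep567$kappa_deathloc$kappa, 2), 0.17)
  # overlap share and sensitivity
  expect_identical(round(rep$srf_overlap_pct, 1), 40.3)
  expect_identical(round(rep$srf_sensitivity_pct), 25)
})

test_that("kappa limiting cases behave", {
  perfect <- crosstab_2x2(50, 0, 0, 50)
  expect_equal(cohens_kappa(perfect)$kappa, 1)
  # independent margins (outer product) give kappa 0
  indep <- matrix(c(6, 14, 24, 56), 2, 2, byrow = TRUE)  # 100*[.2,.8]x[.3,.7]
  expect_equal(cohens_kappa(indep)$kappa, 0)
  degen <- crosstab_2x2(100, 0, 0, 0)
  expect_true(cohens_kappa(degen)$degenerate)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "positive")
})

test_that("kappa matches the brute-force po/pe oracle on random tables", {
  set.seed(21)
  for (rep in 1:250) {
    k <- sample(2:4, 1)
    m <- matrix(rpois(k * k, lambda = sample(c(2, 10, 60), 1)) + 1, k, k)
    got <- cohens_kappa(m)
    expect_equal(got$kappa, brute_kappa(m), tolerance = 1e-12)
    # transpose invariance
    expect_equal(cohens_kappa(t(m))$kappa, got$kappa, tolerance = 1e-12)
    # CI contains the point estimate
    expect_true(got$ci95[1] <= got$kappa && got$kappa <= got$ci95[2])
  }
})

test_that("sensitivity and specificity follow the direct formulas", {
  set.seed(31)
  for (rep in 1:50) {
    truth <- rbinom(200, 1, 0.3)
    test <- ifelse(rbinom(200, 1, 0.8) == 1, truth, 1 - truth)
    ids <- sprintf("s%03d", 1:200)
    tab <- build_crosstab(
      setNames(ifelse(test == 1, "yes", "no"), ids),
      setNames(ifelse(truth == 1, "yes", "no"), ids))[c("yes", "no"),
                                                      c("yes", "no")]
    ss <- sensitivity_specificity(tab, gold_margin = "cols")
    tp <- sum(test == 1 & truth == 1); fn <- sum(test == 0 & truth == 1)
    tn <- sum(test == 0 & truth == 0); fp <- sum(test == 1 & truth == 0)
    expect_equal(ss$sensitivity, tp / (tp + fn))
    expect_equal(ss$specificity, tn / (tn + fp))
  }
  perfect <- crosstab_2x2(40, 0, 0, 60)
  ssp <- sensitivity_specificity(perfect)
  expect_equal(ssp$sensitivity, 1)
  expect_equal(ssp$specificity, 1)
  none <- crosstab_2x2(0, 10, 0, 90)
  expect_true("no gold positives" %in%
                sensitivity_specificity(none)$flags)
})
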
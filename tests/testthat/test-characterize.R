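# brute-force chi-square oracle
brute_chisq <- function(m) {
  total <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / total
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  stat
}

test_that("group summaries match hand computation on a small fixture", {
  rec <- data.frame(
    id = sprintf("c%d", 1:6),
    age = c(60, 70, 80, 90, 75, 65),
    sex = c("male", "female", "male", "male", "female", "male"),
    stringsAsFactors = FALSE)
  cats <- setNames(c("IN_LTC", "IN_LTC", "TRANSITIONING", "NOT_ASSOCIATED",
                     "NOT_ASSOCIATED", "NOT_ASSOCIATED"), rec$id)
  tab <- summarize_groups(rec, cats, variables = "sex")
  gn <- attr(tab, "group_n")
  expect_equal(unname(gn[c("non_ltc", "all_ltc", "in_ltc")]), c(3, 3, 2))
  age_non <- tab[tab$variable == "age" & tab$group == "non_ltc", ]
  expect_equal(age_non$n, median(c(90, 75, 65)))          # 75
  expect_equal(age_non$pct, diff(quantile(c(90, 75, 65), c(.25, .75))),
               ignore_attr = TRUE)                         # IQR 12.5
  male_inltc <- tab[tab$variable == "sex" & tab$level == "male" &
                      tab$group == "in_ltc", ]
  expect_equal(male_inltc$n, 1)
  expect_equal(male_inltc$pct, 50)
  # percentages within a categorical block sum to 100 per group
  sex_rows <- tab[tab$variable == "sex" & tab$group == "all_ltc", ]
  expect_equal(sum(sex_rows$pct), 100)
  expect_error(summarize_groups(rec[1:2, ], cats[4:5]), "category")
})

test_that("published Table-1 chi-square statistics reproduce", {
  ref <- reference_counts()$totals
  n_sub <- c(ref[["nlp_in_ltc"]], ref[["nlp_transitioning"]],
             ref[["nlp_otherwise"]])
  published <- list(
    list(yes = c(277, 360, 128), stat = 31),    # male
    list(yes = c(217, 351, 64), stat = 104),    # physical health problem
    list(yes = c(168, 202, 98), stat = 23)      # depressed mood
  )
  for (case in published) {
    m <- rbind(case$yes, n_sub - case$yes)
    res <- chisq_stat(m)
    expect_identical(round(res$statistic), case$stat)
    expect_identical(res$df, 2L)
    expect_lt(res$p, 0.001)
  }
})

test_that("chi-square matches the brute-force loop on random tables", {
  set.seed(41)
  for (rep in 1:250) {
    r <- sample(2:4, 1); k <- sample(2:4, 1)
    m <- matrix(rpois(r * k, 8) + 1, r, k)
    res <- chisq_stat(m)
    expect_equal(res$statistic, brute_chisq(m), tolerance = 1e-12)
    expect_identical(res$df, (r - 1L) * (k - 1L))
  }
  # identical distributions across groups -> statistic 0
  same <- cbind(c(10, 20), c(10, 20), c(10, 20))
  expect_equal(chisq_stat(same)$statistic, 0)
  # tiny expected cells flag but still compute
  flagged <- chisq_stat(matrix(c(1, 0, 0, 9), 2, 2) + c(0, 1, 1, 0))
  expect_false(is.null(chisq_stat(matrix(c(1, 1, 1, 30), 2, 2))$flag))
})

test_that("Kruskal-Wallis equals the rank closed form and handles ties", {
  # untied toy data: closed form H = 12/(N(N+1)) * sum R_j^2/n_j - 3(N+1)
  x <- c(1, 3, 5, 7, 9, 11, 2, 4, 6)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  H_manual <- 12 / (9 * 10) * sum(rs^2 / 3) - 3 * 10
  res <- kruskal_wallis(x, g)
  expect_equal(res$statistic, H_manual)
  expect_identical(res$df, 2L)
  # against stats::kruskal.test with ties
  xt <- c(1, 1, 2, 2, 3, 3, 4, 5, 5, 6)
  gt <- rep(c("a", "b"), 5)
  ref <- stats::kruskal.test(xt, factor(gt))
  got <- kruskal_wallis(xt, gt)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two nonempty")
})

test_that("group_test dispatches and excludes the missing category", {
  corp <- mid_corpus()
  s <- mid_sample()
  truth <- setNames(corp$truth$category, corp$truth$id)
  age_res <- group_test(s$records, truth, "age")
  expect_identical(age_res$method, "kruskal-wallis")
  sex_res <- group_test(s$records, truth, "sex")
  expect_identical(sex_res$method, "pearson-chisq")
  means_res <- group_test(s$records, truth, "means")
  sel <- truth[s$records$id] %in% ltc_positive_categories()
  lv <- setdiff(unique(s$records$means[sel]), "missing")
  expect_identical(means_res$df, (length(lv) - 1L) * 2L)
  aov_res <- group_test(s$records, truth, "age", type = "anova")
  expect_identical(aov_res$method, "anova")
})

test_that("suppression masks small cells and recoverable complements", {
  m <- matrix(c(3, 40, 100,
                0, 25, 7,
                12, 2, 30), 3, 3, byrow = TRUE)
  out <- suppress_cells(m, threshold = 6, margins_published = FALSE)
  expect_identical(out[1, 1], "S")     # 3 suppressed
  expect_identical(out[2, 1], "0")     # zero shown
  expect_identical(out[2, 3], "7")     # at-threshold kept (1-5 masked)
  out2 <- suppress_cells(m, threshold = 6, margins_published = TRUE)
  # row 1 has one primary suppression; next-smallest open cell masked too
  expect_identical(out2[1, 2], "S")
  expect_identical(out2[1, 3], "100")
  # row 3: primary on the 2, complementary on the 12
  expect_identical(out2[3, 2], "S")
  expect_identical(out2[3, 1], "S")
  # unsuppressed values never altered
  expect_identical(out2[2, 2], "25")
})
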
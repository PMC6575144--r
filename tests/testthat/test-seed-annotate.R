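test_that("keyword matching finds terms under both match modes", {
  rec <- ten_records()
  rec$narrative[1] <- "resident of a convalescent center"
  rec$narrative[2] <- "suffered from depression"
  hits <- keyword_search(rec, keyword_set(c("convalescent")))
  expect_identical(hits, "F01")
  # substring mode matches inside words, word-boundary mode does not
  rec$narrative[2] <- "attended a rehabilitation session"
  expect_identical(keyword_search(rec, keyword_set("rehab")), "F02")
  expect_identical(keyword_search(rec, keyword_set("rehab", "word-boundary")),
                   character(0))
  expect_identical(keyword_search(rec[0, ], keyword_set()), character(0))
  expect_error(keyword_set(character()), "nonempty")
  expect_error(keyword_set(c("a", "a")), "duplicate")
})

test_that("keyword_search is monotone in the term set", {
  s <- mid_sample()
  base <- keyword_search(s, keyword_set(c("nursing home", "convalescent")))
  wider <- keyword_search(s, keyword_set(c("nursing home", "convalescent",
                                           "long-term", "residential")))
  expect_true(all(base %in% wider))
})

test_that("default keywords achieve high recall and imperfect precision", {
  corp <- mid_corpus()
  s <- mid_sample()
  cand <- keyword_search(s, keyword_set())
  truth_pos <- corp$truth$id[corp$truth$category != "NOT_ASSOCIATED"]
  truth_pos <- intersect(truth_pos, s$records$id)
  recall <- mean(truth_pos %in% cand)
  precision <- mean(cand %in% truth_pos)
  expect_gte(recall, 0.9)
  expect_lt(precision, 0.8)  # distractors keep precision well below 1
})

test_that("annotation sampling is reproducible and hypergeometric", {
  pool <- sprintf("id%04d", 1:1000)
  s1 <- sample_for_annotation(pool, 100, seed = 3)
  s2 <- sample_for_annotation(pool, 100, seed = 3)
  expect_identical(s1, s2)
  expect_identical(sort(sample_for_annotation(pool, 1000, seed = 1)), pool)
  expect_error(sample_for_annotation(pool, 1001), "pool")
  # overlap of independent samples: hypergeometric mean 10, sd ~ 2.9
  overlaps <- vapply(1:20, function(k) {
    a <- sample_for_annotation(pool, 100, seed = 2 * k)
    b <- sample_for_annotation(pool, 100, seed = 2 * k + 1)
    length(intersect(a, b))
  }, numeric(1))
  expect_lt(abs(mean(overlaps) - 10), 3 * 3 / sqrt(20))
})

test_that("record_annotations splits unanimous and adjudicated items", {
  ids <- sprintf("x%02d", 1:41)
  truth <- rep(c(1L, 0L), length.out = 41)
  m <- cbind(truth, truth)
  rownames(m) <- ids
  # force disagreement on 4 items
  m[1:4, 2] <- 1L - m[1:4, 2]
  res <- record_annotations(labeled_set(), m, round = 1L)
  expect_identical(sum(res$concordance$adjudicated), 4L)
  expect_identical(sum(res$concordance$agreed), 37L)
  expect_identical(nrow(res$labeled), 41L)  # conservation
  expect_identical(sum(res$labeled$source == "adjudication"), 4L)
  # tie falls to the designated rater (column 1) without adjudicator
  expect_identical(res$labeled$label[match(ids[1:4], res$labeled$id)],
                   truth[1:4])
  # consensus adjudication overrides the tie-breaker where provided
  res2 <- record_annotations(labeled_set(), m, round = 1L,
                             adjudicated_labels = setNames(1L - truth[1:4],
                                                           ids[1:4]))
  expect_identical(res2$labeled$label[match(ids[1:4], res2$labeled$id)],
                   1L - truth[1:4])
  # append-only
  expect_error(record_annotations(res$labeled, m), "append-only")
})

test_that("noiseless oracle raters reconstruct ground truth labels", {
  corp <- mid_corpus()
  ids <- corp$records$id[1:60]
  ann <- oracle_annotate(corp, ids, oracle_config(error_rate = 0))
  res <- record_annotations(labeled_set(), ann)
  truth <- as.integer(corp$truth$category[match(ids, corp$truth$id)] !=
                        "NOT_ASSOCIATED")
  expect_identical(res$labeled$label[match(ids, res$labeled$id)], truth)
  expect_identical(sum(res$concordance$adjudicated), 0L)
})

test_that("build_seed_labels fills the published quotas", {
  corp <- mid_corpus()
  s <- mid_sample()
  lab <- build_seed_labels(s, corp, n_pos = 30L, n_neg = 70L, seed = 2L)
  expect_identical(sum(lab$label == 1L), 30L)
  expect_identical(sum(lab$label == 0L), 70L)
  expect_true(all(lab$source == "keyword-seed"))
  expect_error(build_seed_labels(s, corp, n_pos = 10000L),
               "seed pool too small")
})

test_that("labeled sets round-trip through CSV", {
  lab <- add_labels(labeled_set(), c("a", "b"), c(1L, 0L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labeled_set(lab, path)
  back <- read_labeled_set(path)
  expect_equal(as.data.frame(back), as.data.frame(lab), ignore_attr = TRUE)
})
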
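# closed-form expected inter-rater kappa for two raters flipping a binary
# truth with probability e at positive prevalence pi; verified against
# brute-force Monte Carlo (n = 2e5) before freezing:
#   e=0.085 pi=0.50 -> closed 0.6889, MC 0.6895
#   e=0.200 pi=0.34 -> closed 0.3355, MC 0.3347
expected_rater_kappa <- function(e, pi) {
  po <- (1 - e)^2 + e^2
  q <- pi * (1 - e) + (1 - pi) * e
  pe <- q^2 + (1 - q)^2
  (po - pe) / (1 - pe)
}

test_that("config validation rejects bad inputs", {
  expect_error(generator_config(prevalence = c(IN_LTC = 0.5,
                                               TRANSITIONING = 0.2,
                                               OTHERWISE_ASSOCIATED = 0.2,
                                               NOT_ASSOCIATED = 0.2)),
               "sum to 1")
  expect_error(generator_config(srf_sensitivity = 1.3), "rates")
  expect_error(generator_config(narrative_length_mean = -5), "> 0")
  bad <- c(A = 1)
  expect_error(generator_config(prevalence = bad), "named")
})

test_that("empty corpus and determinism contracts hold", {
  empty <- generate_corpus(generator_config(n_records = 0L))
  expect_identical(nrow(empty$records), 0L)
  expect_identical(nrow(empty$truth), 0L)

  a <- generate_corpus(generator_config(n_records = 300L, seed = 5L))
  b <- generate_corpus(generator_config(n_records = 300L, seed = 5L))
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_corpus(generator_config(n_records = 300L, seed = 6L))
  expect_false(identical(a$records$narrative, c$records$narrative))
})

test_that("corpus ids are unique and truth covers every record", {
  corp <- mid_corpus()
  expect_false(anyDuplicated(corp$records$id) > 0)
  expect_setequal_chr(corp$records$id, corp$truth$id)
})

test_that("category counts follow the configured multinomial", {
  # 20 seeded replicates at n=1500, chi-square goodness of fit at alpha=.01
  prev <- c(IN_LTC = 0.01, TRANSITIONING = 0.01,
            OTHERWISE_ASSOCIATED = 0.005, NOT_ASSOCIATED = 0.975)
  total <- setNames(numeric(4), names(prev))
  n_rep <- 20L
  n <- 1500L
  for (s in seq_len(n_rep)) {
    corp <- generate_corpus(generator_config(n_records = n, seed = 9000L + s,
                                             prevalence = prev))
    cnt <- table(factor(corp$truth$category, levels = names(prev)))
    total <- total + as.numeric(cnt)
  }
  expected <- prev * n * n_rep
  stat <- sum((total - expected)^2 / expected)
  expect_lt(stat, qchisq(0.99, df = 3))
})

test_that("paper-calibrated default reproduces the published subtype counts", {
  corp <- cached("full_corpus",
                 generate_corpus(generator_config(seed = 20260911L)))
  cnt <- table(corp$truth$category)
  # binomial sampling error: +/- 4 sd around the published expectations
  for (chk in list(c("IN_LTC", 428), c("TRANSITIONING", 449),
                   c("OTHERWISE_ASSOCIATED", 160))) {
    expected <- as.numeric(chk[2])
    sdv <- sqrt(expected * (1 - expected / 47759))
    expect_lt(abs(cnt[[chk[1]]] - expected), 4 * sdv)
  }
  expect_identical(sum(cnt), 47759L)
})

test_that("narrative length moments and blank fraction match the config", {
  corp <- cached("len_corpus",
                 generate_corpus(generator_config(n_records = 10000L,
                                                  seed = 77L)))
  len <- nchar(corp$records$narrative)
  blank_frac <- mean(len == 0)
  expect_lt(abs(blank_frac - 2578 / 50337), 0.01)
  nb <- len[len > 0]
  expect_lt(abs(mean(nb) - 513.8) / 513.8, 0.05)
  expect_lt(abs(sd(nb) - 344.2) / 344.2, 0.05)
  expect_gte(min(nb), 40)
})

test_that("SRF code error structure matches the configured rates", {
  corp <- cached("len_corpus",
                 generate_corpus(generator_config(n_records = 10000L,
                                                  seed = 77L)))
  truth <- corp$truth$category
  srf <- corp$records$injury_location_code == "SRF"
  in_ltc <- truth == "IN_LTC"
  sens <- mean(srf[in_ltc])
  fpr <- mean(srf[!in_ltc])
  n1 <- sum(in_ltc)
  expect_lt(abs(sens - 0.25), 4 * sqrt(0.25 * 0.75 / n1))
  p0 <- 157 / 47331
  expect_lt(abs(fpr - p0), 4 * sqrt(p0 * (1 - p0) / sum(!in_ltc)))
})

test_that("death-location and covariate marginals track the config", {
  corp <- cached("len_corpus",
                 generate_corpus(generator_config(n_records = 10000L,
                                                  seed = 77L)))
  rec <- corp$records
  truth <- corp$truth$category
  dl <- default_deathloc <- generator_config()$deathloc_distribution
  in_ltc <- truth == "IN_LTC"
  p_ltc_code <- mean(rec$death_location_code[in_ltc] == "ltc_nursing_home")
  expect_lt(abs(p_ltc_code - 88 / 428), 4 * sqrt(0.2 * 0.8 / sum(in_ltc)))
  # sex marginal for the dominant class
  not <- truth == "NOT_ASSOCIATED"
  expect_lt(abs(mean(rec$sex[not] == "male") - 0.776), 0.02)
  expect_true(all(rec$age >= 55))
})

test_that("noiseless oracle returns ground truth; errors on unknown ids", {
  corp <- mid_corpus()
  ids <- corp$records$id[1:50]
  ann <- oracle_annotate(corp, ids, oracle_config(error_rate = 0,
                                                  n_raters = 3L))
  truth <- as.integer(corp$truth$category[match(ids, corp$truth$id)] !=
                        "NOT_ASSOCIATED")
  for (j in 1:3) expect_identical(unname(ann[, j]), truth)
  expect_error(oracle_annotate(corp, "NOPE", oracle_config()), "unknown")
  expect_error(oracle_config(error_rate = 0.5), "error_rate")
})

test_that("oracle raters reproduce the calibrated inter-rater kappa", {
  # balanced labels: equal parts positive and negative records
  corp <- cached("len_corpus",
                 generate_corpus(generator_config(n_records = 10000L,
                                                  seed = 77L)))
  pos <- corp$truth$id[corp$truth$category != "NOT_ASSOCIATED"]
  neg <- corp$truth$id[corp$truth$category == "NOT_ASSOCIATED"]
  m <- min(length(pos), length(neg))
  ids <- c(pos[seq_len(m)], neg[seq_len(m)])
  # replicate annotation rounds to reach ~1e4 rated items
  k_emp <- local({
    tabs <- matrix(0, 2, 2)
    for (s in seq_len(ceiling(10000 / length(ids)))) {
      ann <- oracle_annotate(corp, ids, oracle_config(seed = s), salt = s)
      tabs <- tabs + table(factor(ann[, 1], 0:1), factor(ann[, 2], 0:1))
    }
    cohens_kappa(tabs)$kappa
  })
  expect_lt(abs(k_emp - expected_rater_kappa(0.085, 0.5)), 0.05)
  expect_lt(abs(k_emp - 0.69), 0.05)
})

test_that("oracle_categorize is the identity on truth and conserves counts", {
  corp <- mid_corpus()
  got <- oracle_categorize(corp, corp$truth$id)
  expect_identical(unname(got), corp$truth$category)
  expect_identical(as.vector(table(got)), as.vector(table(corp$truth$category)))
  one <- corp$truth$id[corp$truth$category == "IN_LTC"][1]
  expect_identical(unname(oracle_categorize(corp, one)), "IN_LTC")
  expect_error(oracle_categorize(corp, "missing-id"), "unknown")
})
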
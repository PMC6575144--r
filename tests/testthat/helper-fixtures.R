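# Shared fixtures, built in code and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# mid-size corpus for classifier/loop unit tests
mid_corpus <- function() {
  cached("mid_corpus", generate_corpus(generator_config(n_records = 4000L,
                                                        seed = 421L)))
}

mid_sample <- function() {
  cached("mid_sample", {
    suppressWarnings(build_analytic_sample(recode_records(mid_corpus()$records)))
  })
}

mid_features <- function() {
  cached("mid_features", {
    s <- mid_sample()
    vec <- fit_vectorizer(s$records$narrative)
    list(vectorizer = vec,
         matrix = transform_texts(vec, s$records$narrative, s$records$id))
  })
}

# hand-written ten-record fixture for exclusion logic
ten_records <- function() {
  data.frame(
    id = sprintf("F%02d", 1:10),
    state = "S01", year = 2010L,
    age = c(60, 70, 40, 65, 80, 55, 62, 75, 68, 90),
    sex = "male", race_eth = "non-Hispanic white",
    marital = "married",
    manner = c("suicide", "suicide", "suicide", "other", "undetermined",
               "suicide", "accidental_firearm", "suicide", "suicide",
               "suicide"),
    means = "firearm",
    injury_location_code = "house_apartment",
    death_location_code = "decedents_home",
    narrative = c("note found at scene", "history of depression", "ok",
                  "ok", "", "chronic pain", "ok", "", "ok", "ok"),
    stringsAsFactors = FALSE
  )
}

# tiny separable corpus: positives say "ltcword", negatives "otherword"
separable_texts <- function(n_pos = 20L, n_neg = 40L) {
  texts <- c(
    sprintf("the decedent lived at ltcword number %d with a history", 1:n_pos),
    sprintf("the decedent stayed near otherword number %d with a history",
            1:n_neg)
  )
  ids <- sprintf("T%03d", seq_along(texts))
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  lab <- add_labels(labeled_set(), ids, labels)
  vec <- fit_vectorizer(texts, min_df = 2L)
  list(matrix = transform_texts(vec, texts, ids), labels = lab,
       ids = ids, y = labels, vectorizer = vec, texts = texts)
}

expect_setequal_chr <- function(a, b) {
  expect_true(setequal(a, b))
}

# reproducible permutation without touching the caller's RNG
with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x[sample.int(length(x))]
}
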
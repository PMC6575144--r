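#' Configuration for the synthetic NVDRS-style corpus generator
#'
#' Builds a validated generator configuration.  Defaults are calibrated to
#' the published surveillance corpus this package emulates: 47 759 analytic
#' deaths among adults 55 and older, narratives with mean (SD) length
#' 513.8 (344.2) characters, roughly 2.2% of deaths associated with
#' residential LTC split across three subtypes (428 living in LTC, 449
#' transitioning, 160 otherwise associated), a "supervised residential
#' facility" (SRF) injury-location code with 25% sensitivity for in-facility
#' cases, and covariate/death-location marginals matching the published
#' characterization tables.
#'
#' @param n_records Number of decedent records to generate.
#' @param prevalence Named numeric vector over [ltc_categories()] summing
#'   to 1: the category mixture.
#' @param narrative_length_mean,narrative_length_sd Target narrative length
#'   moments in characters (truncated normal, floor 40).
#' @param srf_sensitivity P(SRF injury code | living in LTC).
#' @param srf_false_positive_rate P(SRF injury code | any other category).
#' @param deathloc_distribution Matrix (category x death-location code) of
#'   row-stochastic death-location probabilities.
#' @param covariate_marginals List of per-category covariate distributions;
#'   see the package vignette.  Any element you supply replaces the default.
#' @param states Data frame with columns `state` and `first_year` (first
#'   year the state reports to the surveillance system).
#' @param year_range Inclusive integer range of data years.
#' @param blank_fraction Fraction of records with a blank narrative, to
#'   exercise the exclusion step (default 2578/50337).
#' @param distractor_fraction Fraction of NOT_ASSOCIATED narratives seeded
#'   with keyword-bearing distractor clauses.
#' @param phrase_bank Phrase bank as returned by [load_phrase_bank()].
#' @param seed Integer master seed; every stream derives from it.
#' @return An object of class `ltc_generator_config`.
#' @export
generator_config <- function(n_records = 47759,
                             prevalence = NULL,
                             narrative_length_mean = 513.8,
                             narrative_length_sd = 344.2,
                             srf_sensitivity = 0.25,
                             srf_false_positive_rate = 157 / 47331,
                             deathloc_distribution = NULL,
                             covariate_marginals = list(),
                             states = NULL,
                             year_range = c(2003L, 2015L),
                             blank_fraction = 2578 / 50337,
                             distractor_fraction = 0.14,
                             phrase_bank = NULL,
                             seed = 1L) {
  cats <- ltc_categories()
  if (is.null(prevalence)) {
    prevalence <- c(428, 449, 160, 47759 - 428 - 449 - 160) / 47759
    names(prevalence) <- cats
  }
  if (is.null(names(prevalence)) || !setequal(names(prevalence), cats)) {
    stop("prevalence must be named over ltc_categories()")
  }
  prevalence <- prevalence[cats]
  if (any(prevalence < 0) || abs(sum(prevalence) - 1) > 1e-9) {
    stop("prevalence values must be nonnegative and sum to 1 (within 1e-9)")
  }
  if (narrative_length_mean <= 0) stop("narrative_length_mean must be > 0")
  for (p in c(srf_sensitivity, srf_false_positive_rate,
              blank_fraction, distractor_fraction)) {
    if (p < 0 || p > 1) stop("rates must lie in [0, 1]")
  }
  if (is.null(deathloc_distribution)) deathloc_distribution <- default_deathloc()
  deathloc_distribution <- deathloc_distribution /
    rowSums(deathloc_distribution)
  cm <- default_covariate_marginals()
  cm[names(covariate_marginals)] <- covariate_marginals
  if (is.null(states)) states <- default_states()
  stopifnot(all(c("state", "first_year") %in% names(states)))
  if (is.null(phrase_bank)) phrase_bank <- load_phrase_bank()
  structure(
    list(n_records = as.integer(n_records),
         prevalence = prevalence,
         narrative_length_mean = narrative_length_mean,
         narrative_length_sd = narrative_length_sd,
         srf_sensitivity = srf_sensitivity,
         srf_false_positive_rate = srf_false_positive_rate,
         deathloc_distribution = deathloc_distribution,
         covariate_marginals = cm,
         states = states,
         year_range = as.integer(year_range),
         blank_fraction = blank_fraction,
         distractor_fraction = distractor_fraction,
         phrase_bank = phrase_bank,
         seed = as.integer(seed)),
    class = "ltc_generator_config"
  )
}

# Death-location codes: in-LTC row from the published cross-tabulation of
# death-location codes for algorithm-identified facility deaths
# ((57, 43, 88, 153, 87)/428); other rows reflect that only ~1% of other
# deaths carry the LTC/nursing-home death code.
default_deathloc <- function() {
  codes <- c("inpatient", "outpatient_ed", "ltc_nursing_home",
             "decedents_home", "other")
  m <- rbind(
    IN_LTC = c(57, 43, 88, 153, 87) / 428,
    TRANSITIONING = c(0.14, 0.12, 0.010, 0.57, 0.16),
    OTHERWISE_ASSOCIATED = c(0.14, 0.12, 0.010, 0.57, 0.16),
    NOT_ASSOCIATED = c(0.15, 0.12, 0.0102, 0.55, 0.17)
  )
  colnames(m) <- codes
  m / rowSums(m)
}

# Covariate marginals per category (order IN_LTC, TRANSITIONING,
# OTHERWISE_ASSOCIATED, NOT_ASSOCIATED), calibrated to the published
# decedent-characteristics table.  Ages are truncated normal on [55, 105];
# parameters chosen so medians/IQRs land near the published 79(19)/80(13)/
# 75(20)/64(15).
default_covariate_marginals <- function() {
  cats <- ltc_categories()
  mat <- function(...) {
    m <- rbind(...)
    rownames(m) <- cats
    m / rowSums(m)
  }
  marital <- mat(
    c(0.234, 0.136, 0.393, 0.231, 0.004, 0.002),
    c(0.261, 0.062, 0.454, 0.218, 0.004, 0.001),
    c(0.725, 0.075, 0.088, 0.106, 0.004, 0.002),
    c(0.443, 0.108, 0.152, 0.279, 0.016, 0.001)
  )
  colnames(marital) <- c("married", "single", "widowed", "divorced",
                         "unknown", "missing")
  manner <- mat(
    c(0.897, 0.103, 0.000),
    c(0.978, 0.022, 0.000),
    c(0.981, 0.019, 0.000),
    c(0.890, 0.104, 0.006)
  )
  colnames(manner) <- c("suicide", "undetermined", "accidental_firearm")
  means <- mat(
    c(0.243, 0.020, 0.227, 0.080, 0.030, 0.010, 0.304),
    c(0.710, 0.020, 0.138, 0.020, 0.030, 0.010, 0.094),
    c(0.662, 0.020, 0.169, 0.030, 0.030, 0.010, 0.106),
    c(0.573, 0.026, 0.204, 0.017, 0.033, 0.019, 0.128)
  )
  colnames(means) <- c("firearm", "sharp_blunt", "poisoning", "fall",
                       "other", "unknown", "missing")
  flags <- rbind(
    depressed_mood = c(0.393, 0.450, 0.613, 0.359),
    physical_health_problem = c(0.507, 0.782, 0.400, 0.377),
    suicidal_ideation_history = c(0.093, 0.169, 0.088, 0.120),
    recent_crisis = c(0.119, 0.269, 0.206, 0.113),
    any_crisis = c(0.196, 0.361, 0.281, 0.202),
    crisis_eviction = c(0.023, 0.091, 0.062, 0.023),
    crisis_death_of_friend = c(0.100, 0.127, 0.062, 0.077),
    crisis_financial = c(0.035, 0.031, 0.150, 0.093),
    crisis_family = c(0.019, 0.085, 0.244, 0.041)
  )
  colnames(flags) <- cats
  list(
    age = list(IN_LTC = c(mean = 79, sd = 13),
               TRANSITIONING = c(mean = 80, sd = 10),
               OTHERWISE_ASSOCIATED = c(mean = 75, sd = 14),
               NOT_ASSOCIATED = c(mean = 62, sd = 13),
               bounds = c(55, 105)),
    sex_male = c(IN_LTC = 0.647, TRANSITIONING = 0.802,
                 OTHERWISE_ASSOCIATED = 0.800, NOT_ASSOCIATED = 0.776),
    race_nhw = c(IN_LTC = 0.925, TRANSITIONING = 0.953,
                 OTHERWISE_ASSOCIATED = 0.962, NOT_ASSOCIATED = 0.898),
    marital = marital,
    manner = manner,
    means = means,
    flags = flags
  )
}

# 27 synthetic reporting states; the first 13 begin reporting in 2003-2004
# (the subset used for trend analysis), the rest join later.
default_states <- function() {
  first <- c(rep(2003L, 8), rep(2004L, 5),
             rep(2005L, 4), rep(2008L, 3), rep(2010L, 4), rep(2013L, 3))
  data.frame(state = sprintf("S%02d", seq_along(first)),
             first_year = first,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic NVDRS-style corpus with known ground truth
#'
#' Draws `n_records` decedent records.  Category labels come from a
#' multinomial over the configured prevalence; narratives are assembled from
#' category-specific clause banks plus filler until a truncated-normal
#' target length is reached; structured fields (SRF injury code,
#' death-location code, demographics, circumstance flags) are drawn from the
#' configured per-category marginals.  A configurable fraction of narratives
#' is blanked to exercise the analytic-sample exclusion step.  Every concern
#' draws from its own seeded stream, so generation is fully reproducible and
#' individual knobs can change without perturbing unrelated draws.
#'
#' @param config An [generator_config()] object.
#' @return An object of class `ltc_corpus`: a list with `records` (a
#'   data.frame, one row per decedent, including the free-text `narrative`)
#'   and `truth` (a data.frame mapping `id` to the hidden true
#'   `category`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "ltc_generator_config"))
  n <- config$n_records
  cats <- ltc_categories()
  if (n == 0L) {
    rec <- empty_records()
    return(structure(list(records = rec,
                          truth = data.frame(id = character(),
                                             category = character(),
                                             stringsAsFactors = FALSE),
                          config = config),
                     class = "ltc_corpus"))
  }
  seed <- config$seed
  ids <- sprintf("R%07d", seq_len(n))

  category <- with_stream(seed, 101, {
    sample(cats, n, replace = TRUE, prob = config$prevalence)
  })
  ci <- match(category, cats)

  lengths <- with_stream(seed, 102, {
    # lognormal matched to the configured mean/SD: narrative lengths are
    # right-skewed in practice, and unlike a floor-censored normal this
    # reproduces both configured moments (mass below the 40-char floor is
    # negligible, ~5e-5, so the floor is only a guard)
    mu <- config$narrative_length_mean
    sdlog2 <- log(1 + (config$narrative_length_sd / mu)^2)
    pmax(40, round(exp(rnorm(n, log(mu) - sdlog2 / 2, sqrt(sdlog2)))))
  })
  blank <- with_stream(seed, 103, runif(n) < config$blank_fraction)

  narrative <- with_stream(seed, 104, {
    assemble_narratives(category, lengths, config$phrase_bank,
                        config$distractor_fraction)
  })
  narrative[blank] <- ""

  cm <- config$covariate_marginals
  bounds <- cm$age$bounds
  age <- with_stream(seed, 105, {
    mu <- vapply(cm$age[cats], `[[`, numeric(1), "mean")[ci]
    sg <- vapply(cm$age[cats], `[[`, numeric(1), "sd")[ci]
    round(pmin(bounds[2], pmax(bounds[1], rnorm(n, mu, sg))))
  })
  sex <- with_stream(seed, 106, {
    ifelse(runif(n) < cm$sex_male[category], "male", "female")
  })
  race_eth <- with_stream(seed, 107, {
    nhw <- runif(n) < cm$race_nhw[category]
    other_pool <- c("non-Hispanic black", "Hispanic", "Asian/Pacific Islander",
                    "American Indian/Alaska Native", "other/unknown")
    out <- sample(other_pool, n, replace = TRUE,
                  prob = c(0.35, 0.3, 0.15, 0.1, 0.1))
    out[nhw] <- "non-Hispanic white"
    out
  })
  marital <- with_stream(seed, 108, sample_rows(cm$marital, ci))
  manner <- with_stream(seed, 109, sample_rows(cm$manner, ci))
  means <- with_stream(seed, 110, sample_rows(cm$means, ci))

  srf <- with_stream(seed, 111, {
    p <- ifelse(category == "IN_LTC", config$srf_sensitivity,
                config$srf_false_positive_rate)
    runif(n) < p
  })
  injury_location_code <- with_stream(seed, 112, {
    alt <- sample(c("house_apartment", "street", "natural_area",
                    "motor_vehicle", "other"),
                  n, replace = TRUE, prob = c(0.72, 0.05, 0.06, 0.05, 0.12))
    ifelse(srf, "SRF", alt)
  })
  death_location_code <- with_stream(seed, 113, {
    sample_rows(config$deathloc_distribution, ci)
  })

  flags <- with_stream(seed, 114, {
    f <- cm$flags
    out <- matrix(FALSE, n, nrow(f),
                  dimnames = list(NULL, rownames(f)))
    for (k in rownames(f)) out[, k] <- runif(n) < f[k, category]
    out
  })

  state_year <- with_stream(seed, 115, {
    si <- sample(nrow(config$states), n, replace = TRUE)
    fy <- pmax(config$states$first_year[si], config$year_range[1])
    yr <- fy + floor(runif(n) * (config$year_range[2] - fy + 1))
    list(state = config$states$state[si], year = as.integer(yr))
  })

  records <- data.frame(
    id = ids, state = state_year$state, year = state_year$year,
    age = age, sex = sex, race_eth = race_eth, marital = marital,
    manner = manner, means = means,
    injury_location_code = injury_location_code,
    death_location_code = death_location_code,
    stringsAsFactors = FALSE
  )
  records <- cbind(records, as.data.frame(flags))
  records$narrative <- narrative
  structure(list(records = records,
                 truth = data.frame(id = ids, category = category,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "ltc_corpus")
}

empty_records <- function() {
  flags <- rownames(default_covariate_marginals()$flags)
  cols <- c("id", "state", "year", "age", "sex", "race_eth", "marital",
            "manner", "means", "injury_location_code", "death_location_code",
            flags, "narrative")
  rec <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  rec$year <- integer(); rec$age <- numeric()
  for (f in flags) rec[[f]] <- logical()
  rec
}

# Sample one level per row from a row-stochastic matrix, rows indexed by ci.
sample_rows <- function(probmat, ci) {
  lv <- colnames(probmat)
  cum <- t(apply(probmat, 1, cumsum))
  u <- runif(length(ci))
  idx <- rowSums(u > cum[ci, , drop = FALSE]) + 1L
  lv[pmin(idx, length(lv))]
}

#' @export
print.ltc_corpus <- function(x, ...) {
  cat("<ltc_corpus> ", nrow(x$records), " records\n", sep = "")
  if (nrow(x$truth)) print(table(x$truth$category))
  invisible(x)
}

# Assemble narratives: positive categories get 2-4 signal clauses, a
# configurable fraction of NOT_ASSOCIATED narratives get 1-2 keyword-bearing
# distractor clauses, then filler clauses pad to the target length.
assemble_narratives <- function(category, lengths, bank, distractor_fraction) {
  n <- length(category)
  role <- c(IN_LTC = "in_ltc", TRANSITIONING = "transitioning",
            OTHERWISE_ASSOCIATED = "otherwise")[category]
  n_signal <- ifelse(is.na(role), 0L, sample(2:4, n, replace = TRUE))
  use_distract <- is.na(role) & runif(n) < distractor_fraction
  n_distract <- ifelse(use_distract, sample(1:2, n, replace = TRUE), 0L)

  filler <- bank$filler
  avg_filler <- mean(nchar(filler)) + 2  # ". " separator

  parts <- vector("list", n)
  # signal clause draws, per record, without replacement within a record
  for (i in which(n_signal > 0L)) {
    pool <- bank[[role[i]]]
    parts[[i]] <- pool[sample.int(length(pool), n_signal[i])]
  }
  for (i in which(n_distract > 0L)) {
    pool <- bank$distractor
    parts[[i]] <- pool[sample.int(length(pool), n_distract[i])]
  }
  base_len <- vapply(parts, function(p) {
    if (is.null(p)) 0 else sum(nchar(p)) + 2 * length(p)
  }, numeric(1))
  n_fill <- pmax(0L, as.integer(round((lengths - base_len) / avg_filler)))
  fill_idx <- sample.int(length(filler), sum(n_fill), replace = TRUE)
  fill_split <- split(filler[fill_idx], rep(seq_len(n), n_fill))
  fill_by_rec <- vector("list", n)
  fill_by_rec[as.integer(names(fill_split))] <- fill_split
  out <- character(n)
  for (i in seq_len(n)) {
    clauses <- c(parts[[i]], fill_by_rec[[i]])
    if (is.null(clauses) || !length(clauses)) clauses <- filler[1]
    # signal clauses are shuffled into the narrative, not always leading
    if (length(clauses) > 1L) clauses <- clauses[sample.int(length(clauses))]
    out[i] <- paste0(paste(clauses, collapse = ". "), ".")
  }
  # enforce the 40-character floor on assembled text
  short <- which(nchar(out) < 40L)
  for (i in short) {
    while (nchar(out[i]) < 40L) {
      out[i] <- paste0(substr(out[i], 1, nchar(out[i]) - 1L), ". ",
                       filler[sample.int(length(filler), 1L)], ".")
    }
  }
  out
}

#' Configuration for simulated annotators
#'
#' Simulated raters return the true binary LTC-association label,
#' independently flipped with probability `error_rate`.  The default error
#' rate 0.085 is calibrated so that two raters on a balanced item set show
#' chance-corrected agreement (Cohen's kappa) of about 0.69, matching the
#' inter-rater agreement reported for the human annotation round this
#' simulates: with flip probability e and balanced labels,
#' kappa = (1 - 2e)^2, and (1 - 2 * 0.085)^2 = 0.6889.
#'
#' @param error_rate Per-rater label flip probability, in [0, 0.5).
#' @param n_raters Number of independent raters.
#' @param seed Integer seed.
#' @return An object of class `ltc_oracle_config`.
#' @export
oracle_config <- function(error_rate = 0.085, n_raters = 2L, seed = 1L) {
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (n_raters < 1L) stop("need at least one rater")
  structure(list(error_rate = error_rate, n_raters = as.integer(n_raters),
                 seed = as.integer(seed)),
            class = "ltc_oracle_config")
}

#' Simulated annotation of records by noisy raters
#'
#' @param corpus An `ltc_corpus`.
#' @param ids Record ids to annotate.
#' @param oracle An [oracle_config()].
#' @param salt Integer mixed into the seed so successive annotation rounds
#'   draw fresh noise.
#' @return Integer matrix (ids x raters) of 0/1 labels, 1 = associated with
#'   LTC.
#' @export
oracle_annotate <- function(corpus, ids, oracle = oracle_config(), salt = 0L) {
  stopifnot(inherits(corpus, "ltc_corpus"))
  truth <- corpus$truth$category[match(ids, corpus$truth$id)]
  if (anyNA(truth)) {
    stop("unknown record id(s): ",
         paste(head(ids[is.na(truth)], 5), collapse = ", "))
  }
  y <- as.integer(truth %in% ltc_positive_categories())
  n <- length(ids)
  out <- with_stream(oracle$seed, 201 + salt, {
    flips <- matrix(runif(n * oracle$n_raters) < oracle$error_rate,
                    n, oracle$n_raters)
    (matrix(y, n, oracle$n_raters) + flips) %% 2L
  })
  dimnames(out) <- list(ids, paste0("rater", seq_len(oracle$n_raters)))
  storage.mode(out) <- "integer"
  out
}

#' Ground-truth four-way categories for a set of records
#'
#' The simulated stand-in for the manual four-group annotation of classifier
#' positives: returns each record's true category.
#'
#' @inheritParams oracle_annotate
#' @return Named character vector id -> category.
#' @export
oracle_categorize <- function(corpus, ids) {
  stopifnot(inherits(corpus, "ltc_corpus"))
  truth <- corpus$truth$category[match(ids, corpus$truth$id)]
  if (anyNA(truth)) {
    stop("unknown record id(s): ",
         paste(head(ids[is.na(truth)], 5), collapse = ", "))
  }
  setNames(truth, ids)
}
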
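#' Configuration for the iterative retraining loop
#'
#' Each round, narratives whose predicted probability falls inside the
#' ambiguity band (default 0.10 to 0.90, endpoints inclusive) are sampled
#' for annotation, stratified across probability deciles so the batch spans
#' the band, annotated by the (simulated) raters, adjudicated, added to the
#' labeled set, and the forest is retrained.
#'
#' @param band_low,band_high Ambiguity band endpoints (inclusive).
#' @param batch_size Narratives annotated per round (default 41).
#' @param max_rounds Maximum augmentation rounds.
#' @param stop_rule `"fixed_rounds"` (always run `max_rounds`) or
#'   `"stable_positives"` (stop early once the positive set changes by less
#'   than 1% between rounds).
#' @param seed Integer seed.
#' @return Object of class `ltc_loop_config`.
#' @export
loop_config <- function(band_low = 0.10, band_high = 0.90, batch_size = 41L,
                        max_rounds = 5L,
                        stop_rule = c("stable_positives", "fixed_rounds"),
                        seed = 1L) {
  stop_rule <- match.arg(stop_rule)
  if (!(band_low >= 0 && band_low < band_high && band_high <= 1)) {
    stop("need 0 <= band_low < band_high <= 1")
  }
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(band_low = band_low, band_high = band_high,
                 batch_size = as.integer(batch_size),
                 max_rounds = as.integer(max_rounds),
                 stop_rule = stop_rule, seed = as.integer(seed)),
            class = "ltc_loop_config")
}

#' Select an annotation batch from the probability band
#'
#' From unlabeled ids with `band_low <= p <= band_high`, draws up to
#' `batch_size` ids stratified across ten equal probability strata spanning
#' the band, so the batch covers the whole ambiguous range rather than
#' clustering at the threshold.  Already-labeled ids are never selected.
#'
#' @param probs Named probability vector.
#' @param labeled_ids Ids already in the labeled set.
#' @param config An [loop_config()].
#' @param salt Integer mixed into the seed per round.
#' @return Character vector of selected ids (possibly empty).
#' @export
select_band_sample <- function(probs, labeled_ids, config = loop_config(),
                               salt = 0L) {
  p <- probs[!(names(probs) %in% labeled_ids)]
  p <- p[p >= config$band_low & p <= config$band_high]
  if (!length(p)) return(character())
  n_strata <- 10L
  edges <- seq(config$band_low, config$band_high, length.out = n_strata + 1L)
  stratum <- pmin(findInterval(p, edges, rightmost.closed = TRUE), n_strata)
  by_stratum <- split(names(p), stratum)
  with_stream(config$seed, 601 + salt, {
    by_stratum <- lapply(by_stratum, function(ids) ids[sample.int(length(ids))])
    # round-robin over nonempty strata until the batch is filled
    take <- character()
    while (length(take) < config$batch_size && any(lengths(by_stratum) > 0)) {
      for (s in seq_along(by_stratum)) {
        if (length(take) >= config$batch_size) break
        if (length(by_stratum[[s]])) {
          take <- c(take, by_stratum[[s]][1])
          by_stratum[[s]] <- by_stratum[[s]][-1]
        }
      }
    }
    take
  })
}

#' Run the iterative human-in-the-loop retraining procedure
#'
#' Trains the forest on the initial labeled set, then repeats: predict all
#' narratives, draw a band sample, annotate it with the simulated raters
#' (discordant items adjudicated), augment the labeled set, retrain.  Stops
#' after `max_rounds` rounds, when the band is empty, or -- under the
#' `stable_positives` rule -- when the positive set (p > 0.50) changes by
#' less than 1% between consecutive rounds.
#'
#' @param matrix Feature matrix for the full analytic sample.
#' @param labeled Initial `ltc_labeled_set` (must contain both classes).
#' @param corpus The generating `ltc_corpus` (source of oracle annotations).
#' @param oracle An [oracle_config()].
#' @param config An [loop_config()].
#' @param n_trees Trees per forest (default 1500).
#' @param cv_k Folds for the per-round cross-validation entry in the log
#'   (0 disables CV logging).
#' @return List with `model`, `probs`, `labeled`, and `log` (one row per
#'   round: labeled-set size, positive count, mean CV F1).
#' @export
run_loop <- function(matrix, labeled, corpus, oracle = oracle_config(),
                     config = loop_config(), n_trees = 1500L, cv_k = 5L) {
  stopifnot(inherits(labeled, "ltc_labeled_set"))
  if (length(unique(labeled$label)) < 2L) {
    stop("initial labeled set must contain both classes")
  }
  log <- data.frame(round = integer(), n_labeled = integer(),
                    n_positive = integer(), cv_f1 = numeric(),
                    n_annotated = integer())
  fit_round <- function(round, lab) {
    model <- train_forest(matrix, lab, n_trees = n_trees,
                          seed = derive_seed(config$seed, 700 + round))
    probs <- predict_proba(model, matrix)
    f1 <- if (cv_k >= 2L) {
      cross_validate(matrix[lab$id, , drop = FALSE], lab, k = cv_k,
                     n_trees = min(n_trees, 300L),
                     seed = derive_seed(config$seed, 800 + round))$mean[["f1"]]
    } else {
      NA_real_
    }
    list(model = model, probs = probs, f1 = f1)
  }

  state <- fit_round(0L, labeled)
  pos_prev <- names(state$probs)[state$probs > 0.5]
  log <- rbind(log, data.frame(round = 0L, n_labeled = nrow(labeled),
                               n_positive = length(pos_prev),
                               cv_f1 = state$f1, n_annotated = 0L))
  round <- 0L
  while (round < config$max_rounds) {
    round <- round + 1L
    batch <- select_band_sample(state$probs, labeled$id, config,
                                salt = round)
    if (!length(batch)) break
    ann <- oracle_annotate(corpus, batch, oracle, salt = round)
    cons <- consensus_adjudication(corpus, ann, oracle, salt = 1000L + round)
    rec <- record_annotations(labeled, ann, round = round,
                              source = "band-sample",
                              adjudicated_labels = cons)
    labeled <- rec$labeled
    state <- fit_round(round, labeled)
    pos_now <- names(state$probs)[state$probs > 0.5]
    log <- rbind(log, data.frame(round = round, n_labeled = nrow(labeled),
                                 n_positive = length(pos_now),
                                 cv_f1 = state$f1,
                                 n_annotated = length(batch)))
    if (config$stop_rule == "stable_positives") {
      delta <- length(union(setdiff(pos_now, pos_prev),
                            setdiff(pos_prev, pos_now)))
      if (delta / max(1L, length(pos_prev)) < 0.01) {
        pos_prev <- pos_now
        break
      }
    }
    pos_prev <- pos_now
  }
  list(model = state$model, probs = state$probs, labeled = labeled,
       log = log)
}
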
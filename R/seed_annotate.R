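#' Keyword set for candidate discovery
#'
#' The initial labeled set is seeded by searching narratives for
#' LTC-related keywords.  Matching is on lowercased text; the default
#' `"substring"` mode means "long-term" matches both "long-term care" and
#' "long-term illness" -- deliberately high-recall, low-precision, since
#' candidates go to annotation, not straight into the labeled set.
#'
#' @param terms Character vector of lowercase terms; duplicates are an error.
#' @param match_mode `"substring"` or `"word-boundary"`.
#' @return Object of class `ltc_keyword_set`.
#' @export
keyword_set <- function(terms = default_keywords(),
                        match_mode = c("substring", "word-boundary")) {
  match_mode <- match.arg(match_mode)
  terms <- tolower(terms)
  if (length(terms) == 0L) stop("keyword set must be nonempty")
  if (anyDuplicated(terms)) stop("duplicate keyword terms")
  structure(list(terms = terms, match_mode = match_mode),
            class = "ltc_keyword_set")
}

#' @rdname keyword_set
#' @export
default_keywords <- function() {
  c("long-term", "convalescent", "residential", "nursing home",
    "assisted living", "care facility", "rehab")
}

#' Find candidate narratives by keyword match
#'
#' @param sample An `ltc_analytic_sample` (or plain records data frame).
#' @param keywords An [keyword_set()].
#' @return Character vector of matching record ids, sorted.
#' @export
keyword_search <- function(sample, keywords = keyword_set()) {
  records <- if (inherits(sample, "ltc_analytic_sample")) sample$records else sample
  if (!nrow(records)) return(character())
  text <- tolower(records$narrative)
  hit <- rep(FALSE, length(text))
  for (term in keywords$terms) {
    if (keywords$match_mode == "substring") {
      hit <- hit | grepl(term, text, fixed = TRUE)
    } else {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term), "\\b")
      hit <- hit | grepl(pat, text, perl = TRUE)
    }
  }
  sort(records$id[hit])
}

#' Draw a simple random sample of candidates for annotation
#'
#' @param candidates Character vector of candidate ids.
#' @param n Sample size (without replacement).
#' @param seed Integer seed.
#' @return Character vector of `n` sampled ids.
#' @export
sample_for_annotation <- function(candidates, n, seed = 1L) {
  if (n > length(candidates)) {
    stop("requested sample of ", n, " from pool of ", length(candidates))
  }
  with_stream(seed, 301, candidates[sample.int(length(candidates), n)])
}

#' Construct an empty labeled set
#'
#' A labeled set maps record ids to binary LTC-association labels with
#' provenance: the annotation round and the source of the label
#' (`keyword-seed`, `band-sample`, or `adjudication`).
#'
#' @return Object of class `ltc_labeled_set` (data frame id/label/round/source).
#' @export
labeled_set <- function() {
  structure(data.frame(id = character(), label = integer(),
                       round = integer(), source = character(),
                       stringsAsFactors = FALSE),
            class = c("ltc_labeled_set", "data.frame"))
}

#' Merge multi-rater annotations into the labeled set
#'
#' Items on which all raters agree enter the labeled set directly;
#' discordant items are flagged and adjudicated, entering with
#' `source = "adjudication"`.  Adjudication is by majority vote; exact ties
#' fall to `adjudicated_labels` when supplied (a consensus determination,
#' e.g. a fresh oracle read -- see the vignette) and otherwise to the
#' designated tie-breaking rater.  Labels are append-only: re-annotating an
#' id already in the labeled set is an error.
#'
#' @param labeled An `ltc_labeled_set`.
#' @param rater_labels Integer matrix (ids x raters) of 0/1 labels, as
#'   returned by [oracle_annotate()]; all raters must cover the same ids.
#' @param round Annotation round number recorded as provenance.
#' @param source Provenance for unanimous items.
#' @param tie_breaker Column index of the designated tie-breaking rater.
#' @param adjudicated_labels Optional named 0/1 vector giving consensus
#'   determinations for (a superset of) the tied ids.
#' @return List: `labeled` (updated set) and `concordance` (data frame with
#'   per-item agreement and the adjudicated ids flagged).
#' @export
record_annotations <- function(labeled, rater_labels, round = 1L,
                               source = "band-sample", tie_breaker = 1L,
                               adjudicated_labels = NULL) {
  stopifnot(inherits(labeled, "ltc_labeled_set"), is.matrix(rater_labels))
  ids <- rownames(rater_labels)
  if (is.null(ids)) stop("rater_labels must carry ids as rownames")
  dup <- intersect(ids, labeled$id)
  if (length(dup)) {
    stop("labels are append-only; already labeled: ",
         paste(head(dup, 5), collapse = ", "))
  }
  pos <- rowSums(rater_labels)
  r <- ncol(rater_labels)
  unanimous <- pos == 0L | pos == r
  final <- integer(length(ids))
  final[unanimous] <- as.integer(pos[unanimous] > 0)
  if (any(!unanimous)) {
    disc <- which(!unanimous)
    maj <- pos[disc] / r
    tie_fallback <- rater_labels[disc, tie_breaker]
    if (!is.null(adjudicated_labels)) {
      got <- adjudicated_labels[ids[disc]]
      tie_fallback <- ifelse(is.na(got), tie_fallback, got)
    }
    adj <- ifelse(maj > 0.5, 1L, ifelse(maj < 0.5, 0L, tie_fallback))
    final[disc] <- as.integer(adj)
  }
  new <- data.frame(id = ids, label = final, round = as.integer(round),
                    source = ifelse(unanimous, source, "adjudication"),
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(labeled), new)
  class(out) <- c("ltc_labeled_set", "data.frame")
  list(labeled = out,
       concordance = data.frame(id = ids, agreed = unanimous,
                                adjudicated = !unanimous, label = final,
                                stringsAsFactors = FALSE))
}

#' Add externally determined labels (e.g. the keyword-seed stage)
#'
#' @param labeled An `ltc_labeled_set`.
#' @param ids Record ids.
#' @param labels Binary labels (0/1).
#' @inheritParams record_annotations
#' @return Updated `ltc_labeled_set`.
#' @export
add_labels <- function(labeled, ids, labels, round = 0L,
                       source = "keyword-seed") {
  stopifnot(length(ids) == length(labels))
  dup <- intersect(ids, labeled$id)
  if (length(dup)) {
    stop("labels are append-only; already labeled: ",
         paste(head(dup, 5), collapse = ", "))
  }
  out <- rbind(as.data.frame(labeled),
               data.frame(id = as.character(ids), label = as.integer(labels),
                          round = as.integer(round), source = source,
                          stringsAsFactors = FALSE))
  class(out) <- c("ltc_labeled_set", "data.frame")
  out
}

#' Build the initial keyword-seeded labeled set
#'
#' Mirrors the seeding stage of the published pipeline: keyword candidates
#' are sampled in random order and annotated (here by the simulated raters,
#' with adjudication of discordant pairs) until quotas of positives and
#' negatives are filled -- by default 103 deaths associated with LTC and
#' 264 not associated.
#'
#' @param sample An `ltc_analytic_sample`.
#' @param corpus The generating `ltc_corpus` (annotation oracle source).
#' @param keywords An [keyword_set()].
#' @param oracle An [oracle_config()].
#' @param n_pos,n_neg Target numbers of positive / negative seed labels.
#' @param seed Integer seed for the candidate ordering.
#' @return An `ltc_labeled_set` with `source = "keyword-seed"`.
#' @export
build_seed_labels <- function(sample, corpus, keywords = keyword_set(),
                              oracle = oracle_config(), n_pos = 103L,
                              n_neg = 264L, seed = 1L) {
  candidates <- keyword_search(sample, keywords)
  if (!length(candidates)) stop("no keyword candidates to seed from")
  ordering <- sample_for_annotation(candidates, length(candidates), seed)
  ann <- oracle_annotate(corpus, ordering, oracle, salt = 0L)
  cons <- consensus_adjudication(corpus, ann, oracle, salt = 1000L)
  rec <- record_annotations(labeled_set(), ann, round = 0L,
                            source = "keyword-seed",
                            adjudicated_labels = cons)
  lab <- rec$labeled
  pos_ids <- lab$id[lab$label == 1L]
  neg_ids <- lab$id[lab$label == 0L]
  if (length(pos_ids) < n_pos || length(neg_ids) < n_neg) {
    stop(sprintf("seed pool too small: found %d positives / %d negatives",
                 length(pos_ids), length(neg_ids)))
  }
  keep <- c(head(pos_ids, n_pos), head(neg_ids, n_neg))
  out <- lab[match(keep, lab$id), , drop = FALSE]
  out$source <- "keyword-seed"
  rownames(out) <- NULL
  class(out) <- c("ltc_labeled_set", "data.frame")
  out
}

#' Consensus adjudication draws for discordant items
#'
#' For oracle-simulated annotation, discordant items are resolved by a
#' fresh independent consensus determination at the same error rate (a
#' deliberative re-read, not a coin-flip to one rater); see the vignette.
#'
#' @param corpus An `ltc_corpus`.
#' @param rater_labels Rater matrix from [oracle_annotate()].
#' @param oracle The [oracle_config()] in use.
#' @param salt Stream salt (keep distinct from the rater draw).
#' @return Named 0/1 vector over the discordant ids, or `NULL` if none.
#' @export
consensus_adjudication <- function(corpus, rater_labels, oracle, salt = 1000L) {
  pos <- rowSums(rater_labels)
  r <- ncol(rater_labels)
  disc <- rownames(rater_labels)[pos > 0L & pos < r]
  if (!length(disc)) return(NULL)
  one <- oracle_config(oracle$error_rate, 1L, oracle$seed)
  setNames(as.integer(oracle_annotate(corpus, disc, one, salt = salt)[, 1]),
           disc)
}

#' Persist / load a labeled set as CSV
#'
#' @param labeled An `ltc_labeled_set`.
#' @param path CSV path.
#' @export
write_labeled_set <- function(labeled, path) {
  data.table::fwrite(as.data.frame(labeled), path)
  invisible(path)
}

#' @rdname write_labeled_set
#' @export
read_labeled_set <- function(path) {
  out <- data.table::setDF(data.table::fread(path, showProgress = FALSE,
                                             colClasses = c(id = "character")))
  class(out) <- c("ltc_labeled_set", "data.frame")
  out
}
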
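#' Load the narrative phrase bank
#'
#' The synthetic-narrative generator assembles coroner/medical-examiner style
#' narratives from a fixed, versioned bank of clauses.  Real narrative
#' corpora of this kind cannot be redistributed, so lexical realism is
#' approximated by construction: each LTC-association category has its own
#' bank of signal clauses (facility residence, placement/transition,
#' third-party/fear/financial), there is a bank of distractor clauses that
#' contain seed keywords without any LTC association (e.g. "group home",
#' "long-term unemployment"), and a bank of neutral filler clauses used to
#' pad narratives to their sampled target length.
#'
#' @param path Optional path to an alternative phrase bank CSV with columns
#'   `role` (one of `in_ltc`, `transitioning`, `otherwise`, `distractor`,
#'   `filler`) and `phrase`.
#' @return A named list of character vectors, one per role.
#' @export
load_phrase_bank <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phrase_bank.csv", package = "ltcsuicide")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("phrase bank file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("role", "phrase") %in% names(df)))
  roles <- c("in_ltc", "transitioning", "otherwise", "distractor", "filler")
  missing <- setdiff(roles, unique(df$role))
  if (length(missing)) stop("phrase bank missing roles: ", paste(missing, collapse = ", "))
  bank <- split(df$phrase, factor(df$role, levels = roles))
  lapply(bank, as.character)
}
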
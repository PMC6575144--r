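#' Case categories for LTC association
#'
#' The four-way classification of a death's relationship to residential
#' long-term care: living in a facility at the time of injury, transitioning
#' into or out of one, otherwise associated (caregivers, financial strain,
#' fear of placement), or not associated.
#'
#' @return Character vector of the four category codes, in canonical order.
#' @export
ltc_categories <- function() {
  c("IN_LTC", "TRANSITIONING", "OTHERWISE_ASSOCIATED", "NOT_ASSOCIATED")
}

# Categories counted as "associated with LTC" in binary analyses.
ltc_positive_categories <- function() {
  c("IN_LTC", "TRANSITIONING", "OTHERWISE_ASSOCIATED")
}

# Deterministic sub-seed derivation so each generation concern (lengths,
# categories, codes, oracle, ...) has its own stream and changing one knob
# does not perturb the others.  Arithmetic stays below 2^53 so it is exact
# in doubles; result is a valid 32-bit seed.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + salt * 11939) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, salt),
# restoring the caller's state afterwards.
with_stream <- function(seed, salt, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, salt))
  expr
}

# Cheap stable fingerprint of a character vector (vocabulary binding for
# the classifier).  Polynomial rolling hash over UTF-8 bytes, mod a prime.
vocab_fingerprint <- function(vocab) {
  if (length(vocab) == 0L) return("v0:0")
  bytes <- utf8ToInt(paste(vocab, collapse = "\x1f"))
  h <- 0
  p <- 1048573
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    # Horner scheme in exact double arithmetic
    for (b in chunk) h <- (h * 131 + b) %% p
  }
  sprintf("v%d:%d", length(vocab), as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# let data.table resolve .N / by= inside this package
.datatable.aware <- TRUE
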
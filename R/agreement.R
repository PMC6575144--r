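#' Cross-tabulate two labelings of the same records
#'
#' @param labels_a,labels_b Named vectors (or factors) over the *same* id
#'   universe; names are matched, not positions.
#' @return Object of class `ltc_crosstab`: an integer matrix (levels of a x
#'   levels of b) with margin attributes.
#' @export
build_crosstab <- function(labels_a, labels_b) {
  ids_a <- names(labels_a)
  ids_b <- names(labels_b)
  if (is.null(ids_a) || is.null(ids_b)) stop("labelings must carry ids as names")
  if (!setequal(ids_a, ids_b) || length(ids_a) != length(ids_b)) {
    stop("id universes differ between the two labelings")
  }
  b <- labels_b[ids_a]
  tab <- table(a = as.character(labels_a), b = as.character(b))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  structure(m, class = c("ltc_crosstab", class(m)))
}

#' Collapse categories of a labeling
#'
#' Pools categories before cross-tabulation, e.g. transitioning and
#' otherwise-associated into a single column, or the three LTC-associated
#' categories into a binary indicator.
#'
#' @param labels Named character vector.
#' @param mapping Named character vector old level -> new level; unmapped
#'   levels pass through.
#' @return Named character vector with pooled levels.
#' @export
collapse_labels <- function(labels, mapping) {
  out <- as.character(labels)
  hit <- out %in% names(mapping)
  out[hit] <- mapping[out[hit]]
  setNames(out, names(labels))
}

#' Construct a 2x2 table from its four cells
#'
#' Convenience for agreement arithmetic on published tables: `a` both
#' positive, `b` row-positive only, `c` column-positive only, `d` both
#' negative.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param labels Dimension names.
#' @return An `ltc_crosstab`.
#' @export
crosstab_2x2 <- function(a, b, c, d, labels = c("yes", "no")) {
  m <- matrix(as.integer(c(a, c, b, d)), 2, 2,
              dimnames = list(a = labels, b = labels))
  structure(m, class = c("ltc_crosstab", class(m)))
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement for a square contingency table:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed diagonal agreement
#' and `pe` the agreement expected from the margins.  The standard error is
#' the large-sample (Fleiss-Cohen-Everitt) formula, and the 95% CI is
#' `kappa +/- 1.96 se`.  Degenerate margins (`pe = 1`) yield a flagged
#' result with `kappa = NA`.
#'
#' @param table A square `ltc_crosstab` (or plain matrix) of counts.
#' @return Object of class `ltc_agreement`: list with `kappa`, `se`,
#'   `ci95`, `po`, `pe`, `n`, `degenerate`.
#' @export
cohens_kappa <- function(table) {
  m <- unclass(table)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- sum(m)
  if (n <= 0) stop("table total must be positive")
  p <- m / n
  po <- sum(diag(p))
  rs <- rowSums(p)
  cs <- colSums(p)
  pe <- sum(rs * cs)
  if (abs(1 - pe) < 1e-12) {
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          ci95 = c(NA_real_, NA_real_), po = po, pe = pe,
                          n = n, degenerate = TRUE),
                     class = "ltc_agreement"))
  }
  kappa <- (po - pe) / (1 - pe)
  t1 <- sum(diag(p) * (1 - (rs + cs) * (1 - kappa))^2)
  t2 <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (i != j) t2 <- t2 + p[i, j] * (cs[i] + rs[j])^2
    }
  }
  t2 <- (1 - kappa)^2 * t2
  t3 <- (kappa - pe * (1 - kappa))^2
  kappa <- unname(kappa)
  se <- unname(sqrt((t1 + t2 - t3) / (n * (1 - pe)^2)))
  structure(list(kappa = kappa, se = se,
                 ci95 = c(kappa - 1.96 * se, kappa + 1.96 * se),
                 po = po, pe = pe, n = n, degenerate = FALSE),
            class = "ltc_agreement")
}

#' @export
print.ltc_agreement <- function(x, ...) {
  if (x$degenerate) {
    cat("kappa undefined (degenerate margins, pe = 1)\n")
  } else {
    cat(sprintf("kappa %.2f (95%% CI %.2f-%.2f), po %.3f, pe %.3f, n %d\n",
                x$kappa, x$ci95[1], x$ci95[2], x$po, x$pe, as.integer(x$n)))
  }
  invisible(x)
}

#' Sensitivity and specificity against a criterion standard
#'
#' Treats one dimension of a 2x2 table as the criterion ("gold") standard
#' -- in the published comparison, the NLP algorithm -- and evaluates the
#' other labeling against it.  The first row/column level is taken as
#' positive.  Exact (Clopper-Pearson) 95% binomial CIs accompany both
#' proportions.  Zero gold positives (or negatives) flag the corresponding
#' estimate as undefined.
#'
#' @param table A 2x2 `ltc_crosstab`, positive level first.
#' @param gold_margin `"cols"` if the criterion standard is the column
#'   labeling (default), `"rows"` if it is the rows.
#' @return List with `sensitivity`, `specificity`, their `ci95`, the cell
#'   counts, and `flags`.
#' @export
sensitivity_specificity <- function(table, gold_margin = c("cols", "rows")) {
  gold_margin <- match.arg(gold_margin)
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == c(2, 2)))
  if (gold_margin == "rows") m <- t(m)
  tp <- m[1, 1]; fn <- m[2, 1]; fp <- m[1, 2]; tn <- m[2, 2]
  flags <- character()
  sens <- if (tp + fn == 0) {
    flags <- c(flags, "no gold positives"); NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    flags <- c(flags, "no gold negatives"); NA_real_
  } else tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       sensitivity_ci95 = exact_binom_ci(tp, tp + fn),
       specificity_ci95 = exact_binom_ci(tn, tn + fp),
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       flags = flags)
}

# Clopper-Pearson interval; NA for n = 0.
exact_binom_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  alpha <- 1 - level
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}
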
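#' Summarize decedent characteristics by LTC-association group
#'
#' Produces the standard characterization layout: one column per group
#' (all non-LTC deaths, all LTC-associated deaths, and the three LTC
#' subgroups), age as median (IQR), every categorical variable as
#' count (%) computed within column.
#'
#' @param records Data frame of analytic records.
#' @param categories Named vector id -> category covering the records.
#' @param variables Character vector of categorical/logical columns to
#'   tabulate (defaults to the standard demographic and circumstance set
#'   present in generated corpora).
#' @return Data frame in long form: variable, level, group, n, pct (NA for
#'   the age row, which instead fills median/iqr), plus per-group totals as
#'   the `"group_n"` attribute.
#' @export
summarize_groups <- function(records, categories, variables = NULL) {
  cat_vec <- categories[records$id]
  if (anyNA(cat_vec)) stop("every record needs an assigned category")
  pos <- ltc_positive_categories()
  grp_of <- ifelse(cat_vec %in% pos, cat_vec, "NOT_ASSOCIATED")
  member <- list(
    non_ltc = grp_of == "NOT_ASSOCIATED",
    all_ltc = grp_of %in% pos,
    in_ltc = grp_of == "IN_LTC",
    transitioning = grp_of == "TRANSITIONING",
    otherwise = grp_of == "OTHERWISE_ASSOCIATED"
  )
  if (is.null(variables)) {
    candidates <- c("sex", "race_dichotomy", "marital", "manner", "means",
                    rownames(default_covariate_marginals()$flags))
    variables <- intersect(candidates, names(records))
  }
  rows <- list()
  group_n <- vapply(member, sum, integer(1))
  for (g in names(member)) {
    age <- records$age[member[[g]]]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "age", level = "median_iqr", group = g,
      n = if (length(age)) stats::median(age) else NA_real_,
      pct = if (length(age)) unname(diff(quantile(age, c(0.25, 0.75))))
            else NA_real_,
      stringsAsFactors = FALSE)
  }
  for (v in variables) {
    col <- records[[v]]
    if (is.logical(col)) col <- ifelse(col, "yes", "no")
    col <- as.character(col)
    levels <- sort(unique(col))
    for (g in names(member)) {
      sel <- member[[g]]
      denom <- sum(sel)
      for (lv in levels) {
        cnt <- sum(sel & col == lv)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, group = g, n = cnt,
          pct = if (denom > 0) 100 * cnt / denom else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "group_n") <- group_n
  out
}

#' Pearson chi-square test of association (no continuity correction)
#'
#' Hand-rolled `sum((O - E)^2 / E)` with `df = (r - 1)(c - 1)`.  Expected
#' cells below 1 flag the result rather than blocking it.
#'
#' @param m Matrix of observed counts.
#' @return List: `statistic`, `df`, `p`, `flag`.
#' @export
chisq_stat <- function(m) {
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2x2 table")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       flag = if (any(E < 1)) "expected cell < 1" else NULL)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' @param x Numeric response.
#' @param g Group labels aligned with `x`.
#' @return List: `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(x, g) {
  g <- as.factor(g)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) stop("need at least two nonempty groups")
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / corr
  df <- k - 1L
  list(statistic = H, df = df, p = pchisq(H, df, lower.tail = FALSE))
}

#' Compare a variable across the three LTC subgroups
#'
#' The published characterization tests differences across the three
#' LTC-associated subgroups only (living in LTC vs transitioning vs
#' otherwise associated), using Kruskal-Wallis for continuous variables and
#' Pearson chi-square for categorical ones, with the `missing` category
#' excluded from categorical tests.
#'
#' @param records Analytic records.
#' @param categories Named id -> category vector.
#' @param variable Column name to test.
#' @param type `"auto"` (numeric -> Kruskal-Wallis, otherwise chi-square),
#'   `"kruskal"`, `"chisq"`, or `"anova"` (one-way ANOVA, provided for
#'   comparability, not the default).
#' @param exclude_levels Category levels dropped before a chi-square test
#'   (default `"missing"`).
#' @return List: `statistic`, `df`, `p`, `method`, and any `flag`.
#' @export
group_test <- function(records, categories, variable,
                       type = c("auto", "kruskal", "chisq", "anova"),
                       exclude_levels = "missing") {
  type <- match.arg(type)
  cat_vec <- categories[records$id]
  sel <- cat_vec %in% ltc_positive_categories()
  x <- records[[variable]][sel]
  g <- cat_vec[sel]
  if (length(unique(g[!is.na(x)])) < 2L) stop("need >= 2 nonempty groups")
  if (type == "auto") {
    type <- if (is.numeric(x)) "kruskal" else "chisq"
  }
  if (type == "kruskal") {
    res <- kruskal_wallis(x, g)
    c(res, method = "kruskal-wallis")
  } else if (type == "anova") {
    fit <- stats::aov(x ~ factor(g))
    s <- summary(fit)[[1]]
    list(statistic = s[1, "F value"], df = s[1, "Df"],
         p = s[1, "Pr(>F)"], method = "anova")
  } else {
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    keep <- !(as.character(x) %in% exclude_levels)
    m <- table(as.character(x)[keep], g[keep])
    res <- chisq_stat(m)
    c(res, method = "pearson-chisq")
  }
}

#' Small-cell suppression for disclosure control
#'
#' Replaces counts strictly between 0 and `threshold` with the marker
#' `"S"`; zero is not disclosive and is shown as 0.  When row margins are
#' published, a single suppressed cell in a row would be recoverable by
#' subtraction, so complementary suppression masks the next-smallest cell
#' in any row with exactly one primary suppression.
#'
#' @param m Integer matrix of counts.
#' @param threshold Counts in `(0, threshold)` are suppressed (default 6,
#'   i.e. counts 1-5 masked).
#' @param margins_published If `TRUE` (default) apply the complementary
#'   row rule.
#' @return Character matrix with `"S"` markers; unsuppressed entries keep
#'   their count verbatim.
#' @export
suppress_cells <- function(m, threshold = 6L, margins_published = TRUE) {
  m <- as.matrix(m)
  primary <- m > 0 & m < threshold
  out <- matrix(as.character(m), nrow(m), ncol(m), dimnames = dimnames(m))
  out[primary] <- "S"
  if (margins_published && ncol(m) > 1L) {
    for (i in seq_len(nrow(m))) {
      if (sum(primary[i, ]) == 1L) {
        open <- which(!primary[i, ] & m[i, ] > 0)
        if (length(open)) {
          out[i, open[which.min(m[i, open])]] <- "S"
        }
      }
    }
  }
  out
}
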
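#' Annual counts of LTC-associated deaths in early-reporting states
#'
#' Counts LTC-associated deaths per calendar year, restricted to states
#' that began reporting by `early_cutoff` (the published analysis used the
#' 13 states reporting from 2003-2004, over 2005-2015, to avoid artifacts
#' of abstractor inexperience in late-joining states).  Years with no
#' events are zero-filled.
#'
#' @param records Analytic records (needs `id`, `state`, `year`).
#' @param categories Named id -> category vector.
#' @param states Data frame `state`,`first_year` (reporting metadata).
#' @param years Integer vector of analysis years (inclusive, default
#'   2005:2015).
#' @param early_cutoff Latest first reporting year that qualifies a state
#'   (default 2004).
#' @return Data frame: `year`, one column per LTC subgroup, and `all_ltc`.
#' @export
annual_counts <- function(records, categories, states,
                          years = 2005:2015, early_cutoff = 2004L) {
  years <- as.integer(years)
  if (!length(years) || any(diff(years) != 1L)) {
    stop("years must be a consecutive inclusive range")
  }
  if (anyNA(records$year)) stop("records with missing year")
  qualifying <- states$state[states$first_year <= early_cutoff]
  cat_vec <- categories[records$id]
  pos <- ltc_positive_categories()
  sel <- records$state %in% qualifying & cat_vec %in% pos &
    records$year %in% years
  out <- data.frame(year = years)
  for (g in pos) {
    cnt <- table(factor(records$year[sel & cat_vec == g], levels = years))
    out[[tolower(g)]] <- as.integer(cnt)
  }
  out$all_ltc <- as.integer(rowSums(out[, tolower(pos), drop = FALSE]))
  out
}

#' Poisson trend regression by iteratively reweighted least squares
#'
#' Fits `log E[count] = alpha + beta * year` by hand-coded IRLS: the year
#' covariate is centered at its mean for numerical stability, coefficients
#' start from the log of the mean count, and weighted normal equations are
#' iterated to relative tolerance 1e-10 (max 50 iterations).  `beta` is the
#' log-rate change per year and its Wald p-value tests for temporal trend.
#'
#' @param counts Nonnegative integer counts, one per year.
#' @param years Corresponding years (default `seq_along(counts)`).
#' @return Object of class `ltc_trendfit`: list with `beta_year`, `se`,
#'   `p_value`, `alpha` (on the centered scale), `fitted`, `deviance`,
#'   `converged`, `iterations`, `flags`.
#' @export
poisson_trend <- function(counts, years = seq_along(counts)) {
  if (length(counts) < 3L) stop("need at least 3 years of counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (all(counts == 0)) {
    return(structure(list(beta_year = NA_real_, se = NA_real_,
                          p_value = NA_real_, alpha = NA_real_,
                          fitted = rep(0, length(counts)),
                          deviance = NA_real_, converged = FALSE,
                          iterations = 0L,
                          flags = "all-zero series: no finite fit"),
                     class = "ltc_trendfit"))
  }
  y <- as.numeric(counts)
  x <- years - mean(years)
  X <- unname(cbind(1, x))
  beta <- c(log(mean(y)), 0)
  dev <- function(mu) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  deviance_path <- numeric()
  converged <- FALSE
  it <- 0L
  for (it in seq_len(50L)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    deviance_path <- c(deviance_path, dev(mu))
    W <- mu                       # Poisson: var = mu, weight = mu
    z <- eta + (y - mu) / mu      # working response
    XtWX <- crossprod(X, W * X)
    XtWz <- crossprod(X, W * z)
    beta_new <- drop(solve(XtWX, XtWz))
    if (max(abs(beta_new - beta)) <= 1e-10 * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  deviance_path <- c(deviance_path, dev(mu))
  vcov <- solve(crossprod(X, mu * X))
  se <- sqrt(diag(vcov))[2]
  z_stat <- beta[2] / se
  structure(list(beta_year = beta[2], se = unname(se),
                 p_value = 2 * pnorm(-abs(z_stat)),
                 alpha = beta[1], fitted = mu,
                 deviance = tail(deviance_path, 1),
                 deviance_path = deviance_path,
                 converged = converged, iterations = it,
                 flags = if (converged) NULL else
                   sprintf("did not converge in %d iterations", it)),
            class = "ltc_trendfit")
}

#' @export
print.ltc_trendfit <- function(x, ...) {
  if (is.na(x$beta_year)) {
    cat("<ltc_trendfit> no finite fit (", x$flags, ")\n", sep = "")
  } else {
    cat(sprintf("<ltc_trendfit> beta = %.4f (se %.4f), p = %.3g, %s in %d iter\n",
                x$beta_year, x$se, x$p_value,
                if (x$converged) "converged" else "NOT converged",
                x$iterations))
  }
  invisible(x)
}
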
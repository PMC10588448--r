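# Exact 2x2 inference: central/noncentral hypergeometric machinery for
# collapsing burden tests. Everything is computed in log space via lchoose so
# that margins of gnomAD size (~2.7e5 alleles) never touch a factorial.

.check_counts <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop("contingency counts must be non-negative integers; got (",
         paste(x, collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' Build a 2x2 allele-count contingency table
#'
#' The table compares alternate-allele counts between a case cohort and a
#' population control, with fixed margins under the conditional model:
#' `a` case alt alleles, `b` case comparison alleles, `c` control alt
#' alleles, `d` control comparison alleles.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_table` (a named list with the four
#'   cells plus the margins `m1 = a + b`, `m2 = c + d`, `k = a + c` and the
#'   grand total `n`).
#' @examples
#' contingency_table(35, 11951, 466, 267908)
#' @export
contingency_table <- function(a, b, c, d) {
  .check_counts(a, b, c, d)
  structure(
    list(a = a, b = b, c = c, d = d,
         m1 = a + b, m2 = c + d, k = a + c, n = a + b + c + d),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("alt", "other")))
  print(m)
  invisible(x)
}

.tab_cells <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_table")) return(a[c("a", "b", "c", "d")])
  list(a = a, b = b, c = c, d = d)
}

#' Log hypergeometric probability mass
#'
#' Log of `choose(m1, x) * choose(n_total - m1, k - x) / choose(n_total, k)`,
#' the central hypergeometric pmf underlying Fisher's exact test. Out-of-support
#' `x` returns `-Inf`.
#'
#' @param x Number of successes drawn (vectorised).
#' @param k Number of draws (the `a + c` margin).
#' @param m1 Number of successes in the population (the `a + b` margin).
#' @param n_total Population size (table grand total).
#' @return Log probabilities, same length as `x`.
#' @examples
#' exp(log_hypergeom_pmf(1, k = 2, m1 = 2, n_total = 4))  # 2/3
#' @export
log_hypergeom_pmf <- function(x, k, m1, n_total) {
  stopifnot(length(k) == 1, length(m1) == 1, length(n_total) == 1)
  if (k < 0 || m1 < 0 || k > n_total || m1 > n_total) {
    stop("margins must satisfy 0 <= k, m1 <= n_total", call. = FALSE)
  }
  lp <- lchoose(m1, x) + lchoose(n_total - m1, k - x) - lchoose(n_total, k)
  lo <- max(0, k - (n_total - m1))
  hi <- min(k, m1)
  lp[x < lo | x > hi | x != floor(x)] <- -Inf
  lp
}

# Support and log-pmf for the margins of a table. Internal, unchecked.
.hyper_support <- function(m1, k, n) {
  lo <- max(0, k - (n - m1))
  hi <- min(k, m1)
  x <- lo:hi
  list(x = x,
       lp = lchoose(m1, x) + lchoose(n - m1, k - x) - lchoose(n, k),
       lo = lo, hi = hi)
}

#' One-sided (greater) Fisher exact p-value
#'
#' Upper-tail probability `P(X >= a)` under the central hypergeometric
#' distribution with the table's margins: the test of case enrichment.
#'
#' @param a,b,c,d Cell counts, or a `contingency_table` as the single first
#'   argument.
#' @return A p-value in (0, 1].
#' @examples
#' fisher_p_greater(35, 11951, 466, 267908)
#' @export
fisher_p_greater <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .tab_cells(a, b, c, d)
  .check_counts(t$a, t$b, t$c, t$d)
  m1 <- t$a + t$b; k <- t$a + t$c; n <- m1 + t$c + t$d
  s <- .hyper_support(m1, k, n)
  if (t$a <= s$lo) return(1)  # whole support: analytically certain
  tail <- s$lp[s$x >= t$a]
  mx <- max(tail)
  min(1, exp(mx) * sum(exp(tail - mx)))
}

#' Two-sided Fisher exact p-value (pmf-summation convention)
#'
#' Sums the central hypergeometric pmf over every support point whose
#' probability does not exceed the observed one by more than a relative
#' tolerance of 1e-7 -- the summation convention of `stats::fisher.test`,
#' which is what published burden tables are computed with.
#'
#' @inheritParams fisher_p_greater
#' @return A p-value in (0, 1].
#' @export
fisher_p_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .tab_cells(a, b, c, d)
  .check_counts(t$a, t$b, t$c, t$d)
  m1 <- t$a + t$b; k <- t$a + t$c; n <- m1 + t$c + t$d
  s <- .hyper_support(m1, k, n)
  if (length(s$x) == 1L) return(1)
  lp_obs <- s$lp[s$x == t$a]
  keep <- s$lp <= lp_obs + log1p(1e-7)
  mx <- max(s$lp[keep])
  min(1, exp(mx) * sum(exp(s$lp[keep] - mx)))
}

#' Sample (cross-product) odds ratio
#'
#' `a*d / (b*c)`, the unconditional descriptive odds ratio. Degenerate cells
#' follow the conventions: 0 when the numerator alone vanishes, `Inf` when the
#' denominator alone vanishes, and 1 (with a warning) when both do.
#'
#' @inheritParams fisher_p_greater
#' @return A non-negative ratio, possibly `Inf`.
#' @export
or_sample <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .tab_cells(a, b, c, d)
  .check_counts(t$a, t$b, t$c, t$d)
  num <- t$a * t$d
  den <- t$b * t$c
  if (num == 0 && den == 0) {
    warning("degenerate table: both cross products are zero; returning 1")
    return(1)
  }
  if (den == 0) return(Inf)
  num / den
}

# Mean and variance of the noncentral (Fisher) hypergeometric distribution at
# log-odds t, given the central log-pmf over the support.
.nchyper_moments <- function(x, lp0, t) {
  w <- lp0 + x * t
  mx <- max(w)
  ew <- exp(w - mx)
  sw <- sum(ew)
  m <- sum(x * ew) / sw
  v <- sum(x * x * ew) / sw - m * m
  c(mean = m, var = v)
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds ratio maximising the noncentral hypergeometric likelihood of the
#' table conditional on all margins -- the estimate reported by
#' `stats::fisher.test`, found as the root of `E_psi[X] = a` on the log-odds
#' scale by safeguarded Newton iteration. Returns 0 when `a` sits at the
#' support minimum and `Inf` at the maximum.
#'
#' @inheritParams fisher_p_greater
#' @param tol Convergence tolerance on `|E_psi[X] - a|`.
#' @return The conditional MLE of the odds ratio.
#' @examples
#' or_conditional_mle(35, 11951, 466, 267908)  # 1.6837
#' @export
or_conditional_mle <- function(a, b = NULL, c = NULL, d = NULL, tol = 1e-10) {
  tc <- .tab_cells(a, b, c, d)
  .check_counts(tc$a, tc$b, tc$c, tc$d)
  m1 <- tc$a + tc$b; k <- tc$a + tc$c; n <- m1 + tc$c + tc$d
  s <- .hyper_support(m1, k, n)
  if (tc$a <= s$lo) return(0)
  if (tc$a >= s$hi) return(Inf)

  f <- function(t) .nchyper_moments(s$x, s$lp, t)["mean"] - tc$a

  # bracket the root; E_psi[X] is strictly increasing in t
  t0 <- log((tc$a + 0.5) * (tc$d + 0.5) / ((tc$b + 0.5) * (tc$c + 0.5)))
  tl <- t0 - 1; th <- t0 + 1
  it <- 0L
  while (f(tl) > 0 && it < 200L) { tl <- tl - 2 * (th - tl); it <- it + 1L }
  while (f(th) < 0 && it < 200L) { th <- th + 2 * (th - tl); it <- it + 1L }
  if (it >= 200L) {
    stop("conditional MLE failed to bracket for table (",
         paste(unlist(tc), collapse = ", "), ")", call. = FALSE)
  }

  t <- max(tl, min(th, t0))
  for (iter in seq_len(200L)) {
    mo <- .nchyper_moments(s$x, s$lp, t)
    err <- unname(mo["mean"] - tc$a)
    if (abs(err) < tol) return(exp(unname(t)))
    if (err > 0) th <- t else tl <- t
    step <- if (mo["var"] > 0) err / mo["var"] else NA_real_
    t_new <- t - step
    if (!is.finite(t_new) || t_new <= tl || t_new >= th) t_new <- (tl + th) / 2
    t <- t_new
  }
  stop("conditional MLE did not converge within 200 iterations for table (",
       paste(unlist(tc), collapse = ", "), ")", call. = FALSE)
}

#' Benjamini-Hochberg adjustment with an explicit family size
#'
#' Step-up false-discovery-rate adjustment `min_{j: p_j >= p_i} p_j * m / rank_j`
#' where the family size `m_total` may exceed the number of observed p-values
#' (untested family members are implicitly p = 1). Input order is preserved.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param m_total Family size, at least `length(pvals)`.
#' @return Adjusted p-values in input order, capped at 1.
#' @examples
#' bh_adjust(c(0.00350858, 0.024524772, 0.083930393, 0.231331347), m_total = 8)
#' @export
bh_adjust <- function(pvals, m_total = length(pvals)) {
  .check_pvals(pvals, m_total)
  n <- length(pvals)
  if (n == 0L) return(numeric(0))
  o <- order(pvals)
  q <- pvals[o] * m_total / seq_len(n)
  adj <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

#' Bonferroni adjustment with an explicit family size
#'
#' @inheritParams bh_adjust
#' @return `pmin(1, pvals * m_total)` in input order.
#' @export
bonferroni_adjust <- function(pvals, m_total = length(pvals)) {
  .check_pvals(pvals, m_total)
  pmin(1, pvals * m_total)
}

.check_pvals <- function(pvals, m_total) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m_total < length(pvals)) {
    stop("family size m_total (", m_total, ") is smaller than the number of ",
         "observed p-values (", length(pvals), ")", call. = FALSE)
  }
}

#' Run the full exact-test battery on one 2x2 table
#'
#' @inheritParams fisher_p_greater
#' @return A one-row tibble with `p_greater`, `p_two_sided`, `or_sample` and
#'   `or_cmle`.
#' @export
exact_table_test <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .tab_cells(a, b, c, d)
  tibble::tibble(
    p_greater = fisher_p_greater(t$a, t$b, t$c, t$d),
    p_two_sided = fisher_p_two_sided(t$a, t$b, t$c, t$d),
    or_sample = suppressWarnings(or_sample(t$a, t$b, t$c, t$d)),
    or_cmle = or_conditional_mle(t$a, t$b, t$c, t$d)
  )
}
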
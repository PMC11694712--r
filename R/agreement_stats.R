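# Inter-method agreement statistics, implemented from first principles:
# unweighted Cohen's kappa, two-way mixed single-measures intraclass
# correlation for consistency (ICC(3,1)), Spearman rank correlation with
# average ranks for ties, and the Pearson chi-square test. No continuity
# corrections; two-sided p-values.

#' Unweighted Cohen's kappa
#'
#' Chance-corrected categorical agreement `kappa = (p_o - p_e) / (1 - p_e)`
#' with observed agreement `p_o = sum(diag) / N` and chance agreement
#' `p_e = sum(row_i * col_i) / N^2`, computed from integer sums so the
#' result is exact to floating precision.
#'
#' @param table square matrix of counts (rows = rater A categories,
#'   columns = rater B, same ordered category set).
#' @return list: `kappa`, `p_o`, `p_e`, `n`.
#' @export
cohen_kappa <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m))
    stop_hprfd("kappa requires a square table", "hprfd_parameter_error")
  if (any(m < 0) || sum(m) <= 0)
    stop_hprfd("counts must be non-negative with N > 0",
               "hprfd_parameter_error")
  n <- sum(m)
  # exact integer numerators: kappa = (N*sum(diag) - S) / (N^2 - S),
  # with S = sum(row_i * col_i)
  s <- sum(rowSums(m) * colSums(m))
  po <- sum(diag(m)) / n
  pe <- s / n^2
  if (abs(n^2 - s) < .Machine$double.eps * n^2) {
    warning("degenerate single-category table: kappa undefined")
    return(list(kappa = NA_real_, p_o = po, p_e = pe, n = n))
  }
  list(kappa = (n * sum(diag(m)) - s) / (n^2 - s), p_o = po, p_e = pe,
       n = n)
}

#' Intraclass correlation, two-way mixed, consistency, single measures
#'
#' ICC(3,1) = `(MS_R - MS_E) / (MS_R + (k - 1) MS_E)` from the two-way
#' ANOVA decomposition of an N x k subjects-by-raters matrix, with the
#' subject-by-rater interaction as the error term. Consistency agreement is
#' insensitive to fixed per-rater offsets.
#'
#' @param data numeric matrix, N subjects x k raters, no missing cells.
#' @return list: `icc`, `ms_r` (between-subject mean square), `ms_e`
#'   (residual mean square), `n`, `k`.
#' @export
icc_consistency <- function(data) {
  m <- as.matrix(data)
  if (any(is.na(m))) stop_hprfd("no missing cells allowed",
                                "hprfd_parameter_error")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop_hprfd("need at least 2 subjects and 2 raters",
               "hprfd_parameter_error")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r + (k - 1) * ms_e <= .Machine$double.eps * ss_tot + 0) {
    warning("zero variance: ICC undefined")
    return(list(icc = NA_real_, ms_r = ms_r, ms_e = ms_e, n = n, k = k))
  }
  list(icc = (ms_r - ms_e) / (ms_r + (k - 1) * ms_e),
       ms_r = ms_r, ms_e = ms_e, n = n, k = k)
}

# average ranks with ties (midranks)
midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  sorted <- x[o]
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && sorted[j + 1L] == sorted[i]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Spearman rank correlation with average-rank ties
#'
#' Assigns average ranks to ties and returns the Pearson product-moment
#' correlation of the two rank vectors.
#'
#' @param x,y numeric vectors of equal length >= 3 (ties allowed).
#' @return list: `rho`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_hprfd("need equal-length vectors of length >= 3",
               "hprfd_parameter_error")
  rx <- midranks(x); ry <- midranks(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den <= 0) {
    warning("constant vector: rho undefined")
    return(list(rho = NA_real_, n = length(x)))
  }
  list(rho = sum(dx * dy) / den, n = length(x))
}

#' Pearson chi-square test of independence
#'
#' `chi2 = sum (O - E)^2 / E` with `E = row * col / N`,
#' `df = (r - 1)(c - 1)`, p-value from the chi-square survival function.
#' No continuity correction.
#'
#' @param table matrix of counts.
#' @return list: `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  n <- sum(m)
  if (n <= 0) stop_hprfd("N must be positive", "hprfd_parameter_error")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    stop_hprfd("zero margin in contingency table", "hprfd_parameter_error")
  E <- outer(rs, cs) / n
  chi2 <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
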
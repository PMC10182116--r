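# Cohort-level statistics: ordinal correlation, group comparison with
# multiplicity control, reader agreement, reliability and auxiliary tests.
#
# Kruskal-Wallis H and the rank-sum statistic are computed with tie
# correction; for small samples their p-values come from exhaustive
# permutation enumeration, otherwise from the usual asymptotic
# approximations (chi-squared / normal via stats::wilcox.test).

#' Code ACR categories A-D as ordinal 1-4
#'
#' @param x character/factor vector with values in `A`..`D`.
#' @return integer vector (NA preserved).
#' @export
acr_code <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% c("A", "B", "C", "D")
  if (any(bad)) stop("ACR categories must be in {A, B, C, D}")
  match(x, c("A", "B", "C", "D"))
}

# Tie-corrected Kruskal-Wallis H from a rank vector and group index.
kw_H <- function(ranks, g, N, tie_corr) {
  R <- rowsum(ranks, g)
  n_i <- tabulate(g)
  H0 <- 12 / (N * (N + 1)) * sum(R^2 / n_i) - 3 * (N + 1)
  if (tie_corr <= 0) 0 else H0 / tie_corr
}

tie_correction <- function(values, N) {
  t_ <- table(values)
  1 - sum(t_^3 - t_) / (N^3 - N)
}

# Exhaustive permutation distribution of H over all distinct assignments
# of the observations to groups of the observed sizes.
kw_exact_p <- function(ranks, sizes, H_obs, tie_corr) {
  N <- length(ranks)
  count <- 0L
  total <- 0L
  recurse <- function(avail, gi, acc_g) {
    if (gi == length(sizes)) {
      g <- integer(N)
      g[unlist(acc_g)] <- rep(seq_along(acc_g), lengths(acc_g))
      g[avail] <- gi
      H <- kw_H(ranks, g, N, tie_corr)
      total <<- total + 1L
      if (H >= H_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    cmb <- combn(avail, sizes[gi])
    for (j in seq_len(ncol(cmb))) {
      recurse(setdiff(avail, cmb[, j]), gi + 1L, c(acc_g, list(cmb[, j])))
    }
  }
  recurse(seq_len(N), 1L, list())
  count / total
}

# Two-sided exact rank-sum p for group 1 of size n1 within a pooled rank
# vector (enumeration over all subsets).
ranksum_exact_p <- function(ranks, n1) {
  N <- length(ranks)
  cmb <- combn(N, n1)
  sums <- colSums(matrix(ranks[cmb], nrow = n1))
  E <- n1 * mean(ranks)
  obs <- sum(ranks[seq_len(n1)])
  mean(abs(sums - E) >= abs(obs - E) - 1e-12)
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation (Pearson correlation of mid-ranks)
#' with a two-sided p-value from the t approximation.  Ordinal `y` given
#' as ACR letters is coded A=1 .. D=4.
#'
#' @param x numeric vector.
#' @param y numeric vector, or character/factor of ACR categories.
#' @return list with `rho`, `p_value` and `n`.
#' @export
spearman_rho <- function(x, y) {
  if (is.character(y) || is.factor(y)) y <- acr_code(y)
  keep <- complete.cases(x, y)
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " incomplete pair(s) dropped")
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("Spearman correlation undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Kruskal-Wallis test with Holm-adjusted pairwise comparisons
#'
#' Global tie-corrected Kruskal-Wallis H across the groups, followed by
#' all pairwise two-sided Wilcoxon rank-sum comparisons adjusted with
#' Holm's step-down procedure.  For small samples (pooled n at or below
#' `exact_max_n` globally, pair size at or below `exact_max_pair` per
#' comparison) p-values are exact permutation probabilities; otherwise the
#' chi-squared / normal approximations are used.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @param exact_max_n largest pooled n for the exact global test.
#' @param exact_max_pair largest pooled pair size for exact rank-sum tests.
#' @return list with `H`, `p_global`, `method_global`, and a `pairwise`
#'   data.frame (`group1`, `group2`, `p_raw`, `p_holm`).
#' @export
kruskal_wallis_holm <- function(values, groups, exact_max_n = 10,
                                exact_max_pair = 12) {
  keep <- complete.cases(values, groups)
  if (any(!keep)) message(sum(!keep), " incomplete observation(s) dropped")
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  N <- length(values)
  ranks <- rank(values)
  g <- as.integer(groups)
  tc <- tie_correction(values, N)
  H <- kw_H(ranks, g, N, tc)
  if (N <= exact_max_n) {
    p_global <- kw_exact_p(ranks, tabulate(g), H, tc)
    method_global <- "exact permutation"
  } else {
    p_global <- if (tc <= 0) 1 else pchisq(H, df = nlevels(groups) - 1,
                                           lower.tail = FALSE)
    method_global <- "chi-squared approximation"
  }

  lv <- levels(groups)
  pairs <- combn(lv, 2)
  p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    v1 <- values[groups == pairs[1, j]]
    v2 <- values[groups == pairs[2, j]]
    if (length(v1) + length(v2) <= exact_max_pair) {
      r <- rank(c(v1, v2))
      p_raw[j] <- ranksum_exact_p(r, length(v1))
    } else {
      p_raw[j] <- suppressWarnings(
        wilcox.test(v1, v2, exact = FALSE, correct = FALSE)$p.value)
    }
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         p_raw = p_raw, p_holm = p.adjust(p_raw, "holm"),
                         stringsAsFactors = FALSE)
  list(H = H, p_global = p_global, method_global = method_global,
       pairwise = pairwise)
}

#' Cohen's kappa for two raters
#'
#' Unweighted kappa with the standard asymptotic 95% confidence interval
#' (`se = sqrt(po (1 - po) / (n (1 - pe)^2))`).
#'
#' @param r1,r2 categorical vectors of equal length over the same set of
#'   categories.
#' @return list with `kappa`, `ci` (length-2), `po`, `pe`, `n`.
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("raters must have equal length")
  keep <- complete.cases(r1, r2)
  r1 <- factor(r1[keep]); r2 <- factor(r2[keep])
  lev <- union(levels(r1), levels(r2))
  r1 <- factor(r1, levels = lev); r2 <- factor(r2, levels = lev)
  n <- length(r1)
  if (n < 2L) stop("need at least 2 paired ratings")
  tab <- table(r1, r2)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) stop("kappa undefined: a single shared category in both raters")
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kappa, ci = kappa + c(-1, 1) * qnorm(0.975) * se,
       po = po, pe = pe, n = n)
}

#' Intraclass correlation for paired left/right measurements
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation, ICC(2,1), from the standard mean squares decomposition.
#'
#' @param left,right paired numeric vectors, n >= 3.
#' @return list with `icc` and `n`.
#' @export
icc_paired <- function(left, right) {
  keep <- complete.cases(left, right)
  left <- left[keep]; right <- right[keep]
  n <- length(left)
  if (n < 3L) stop("need at least 3 complete pairs")
  x <- cbind(left, right)
  k <- 2
  m <- mean(x)
  subj <- rowMeans(x)
  rater <- colMeans(x)
  ss_total <- sum((x - m)^2)
  ss_rows <- k * sum((subj - m)^2)
  ss_cols <- n * sum((rater - m)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total == 0) stop("zero total variance: ICC undefined")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = max(-1, min(1, icc)), n = n)
}

#' Auxiliary cohort tests
#'
#' Chi-squared test of independence on the mammography-vs-MRI ACR
#' cross-tabulation (first readers, no continuity correction) and a paired
#' t-test on left/right mean breast PDFF.
#'
#' @param table cohort data.frame.
#' @param mammo_col,mri_col ACR columns for the cross-tabulation.
#' @param left_col,right_col paired numeric columns.
#' @return list with `chi_squared` (`statistic`, `p_value`, `df`) and
#'   `paired_t` (`t`, `p_value`, `n`); elements are `NULL` when the
#'   corresponding columns are absent.
#' @export
auxiliary_tests <- function(table, mammo_col = "acr_mammo_reader1",
                            mri_col = "acr_mri_reader1",
                            left_col = "mean_pdff_breast_left",
                            right_col = "mean_pdff_breast_right") {
  out <- list(chi_squared = NULL, paired_t = NULL)
  if (all(c(mammo_col, mri_col) %in% names(table))) {
    tab <- base::table(table[[mammo_col]], table[[mri_col]])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (sum(tab) == 0 || nrow(tab) < 2 || ncol(tab) < 2) {
      stop("cross-tabulation needs at least 2 non-empty rows and columns")
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out$chi_squared <- list(statistic = unname(ct$statistic),
                            p_value = ct$p.value, df = unname(ct$parameter))
  }
  if (all(c(left_col, right_col) %in% names(table))) {
    l <- table[[left_col]]; r <- table[[right_col]]
    keep <- complete.cases(l, r)
    l <- l[keep]; r <- r[keep]
    if (length(l) < 2L) stop("paired t-test needs at least 2 complete pairs")
    d <- l - r
    if (sd(d) == 0) {
      out$paired_t <- if (mean(d) == 0) list(t = 0, p_value = 1, n = length(d))
                      else list(t = sign(mean(d)) * Inf, p_value = 0, n = length(d))
    } else {
      tt <- t.test(l, r, paired = TRUE)
      out$paired_t <- list(t = unname(tt$statistic), p_value = tt$p.value,
                           n = length(d))
    }
  }
  out
}

#' Full statistics report for a cohort table
#'
#' Runs the cohort analysis set on a table with recovered per-subject
#' summaries and ACR categories: Spearman correlation of mean breast PDFF
#' with the mammographic ACR grade, Kruskal-Wallis with Holm-adjusted
#' pairwise comparisons across grades, inter-reader Cohen's kappa for
#' mammography and MRI, left/right ICC, and the auxiliary chi-squared and
#' paired t-tests.
#'
#' @param table cohort data.frame (see [run_cohort()]).
#' @param acr_col ACR column used for correlation/grouping.
#' @param pdff_col mean breast PDFF column.
#' @param json_path optional path; when given the report is also written
#'   as JSON.
#' @return a list of test results.
#' @export
cohort_report <- function(table, acr_col = "acr_mammo_reader1",
                          pdff_col = "mean_pdff_breast",
                          json_path = NULL) {
  res <- list()
  res$spearman_pdff_acr <- spearman_rho(table[[pdff_col]], table[[acr_col]])
  res$kruskal_wallis <- kruskal_wallis_holm(table[[pdff_col]], table[[acr_col]])
  if (all(c("acr_mammo_reader1", "acr_mammo_reader2") %in% names(table))) {
    res$kappa_mammo <- cohens_kappa(table$acr_mammo_reader1, table$acr_mammo_reader2)
  }
  if (all(c("acr_mri_reader1", "acr_mri_reader2") %in% names(table))) {
    res$kappa_mri <- cohens_kappa(table$acr_mri_reader1, table$acr_mri_reader2)
  }
  if (all(c("mean_pdff_breast_left", "mean_pdff_breast_right") %in% names(table))) {
    res$icc_left_right <- icc_paired(table$mean_pdff_breast_left,
                                     table$mean_pdff_breast_right)
  }
  res$auxiliary <- tryCatch(auxiliary_tests(table), error = function(e) NULL)
  if (!is.null(json_path)) {
    jsonlite::write_json(res, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  res
}
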
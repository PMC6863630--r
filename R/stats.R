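#' Significance stars at Bonferroni-corrected levels
#'
#' Annotation convention for families of 4 planned comparisons:
#' `***` p < 0.00025, `**` p < 0.0025, `*` p < 0.0125 (the base
#' 0.001/0.01/0.05 levels divided by the family size).
#'
#' @param p P-value(s).
#' @param m Family size.
#' @param alpha_levels Uncorrected star levels.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p, m = 4, alpha_levels = c(0.001, 0.01, 0.05)) {
  lv <- sort(alpha_levels) / m
  dplyr::case_when(
    p < lv[1] ~ "***",
    p < lv[2] ~ "**",
    p < lv[3] ~ "*",
    TRUE ~ "ns"
  )
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Nominal familywise level.
#' @param m Number of planned comparisons.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni(0.05, 4) # 0.0125
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

test_report <- function(test, statistic, p_value, n = NA_integer_, ...) {
  tibble::tibble(test = test, statistic = statistic,
                 p_value = p_value, n = n, ...)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities (margins fixed) of all tables at most
#' as probable as the observed one. Invariant under transposition and
#' row/column swaps.
#'
#' @param a,b,c,d Cell counts (responders/non-responders x group), or a
#'   2x2 matrix as `a`.
#' @return One-row tibble: `test`, `statistic` (odds ratio estimate),
#'   `p_value`, `n`.
#' @export
#' @examples
#' fisher_exact_2x2(28, 7, 17, 34)
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), nrow = 2)
  if (any(m < 0) || any(m != round(m))) {
    stop_arg("cell counts must be non-negative integers")
  }
  if (all(rowSums(m) == 0) || all(colSums(m) == 0)) {
    warn("degenerate table (empty margin); p = 1")
    return(test_report("fisher_exact", NA_real_, 1, sum(m)))
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    # one empty margin: only one table is possible
    return(test_report("fisher_exact", NA_real_, 1, sum(m)))
  }
  ft <- stats::fisher.test(m, alternative = "two.sided")
  test_report("fisher_exact", unname(ft$estimate), ft$p.value, sum(m))
}

#' Wilcoxon rank-sum test for two groups
#'
#' Exact null distribution when the combined sample size is at most 20
#' and there are no ties; normal approximation with tie correction
#' otherwise.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble report.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = n <= 20 && !ties, correct = ties)
  )
  test_report("wilcoxon_rank_sum", unname(wt$statistic), wt$p.value, n,
              n_x = length(x), n_y = length(y))
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based one-way test with tie correction. For small samples
#' (combined n of 10 or fewer, no ties) the p-value is the exact
#' permutation probability `P(H >= H_obs)` by full enumeration;
#' otherwise the usual chi-square reference is used.
#'
#' @param groups List of numeric vectors (one per group).
#' @return One-row tibble report (`method` records which null was
#'   used).
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop_arg("need at least 2 non-empty groups")
  if (length(unique(unlist(groups))) == 1) {
    # degenerate all-tied data: H = 0 by convention
    return(test_report("kruskal_wallis", 0, 1, sum(lengths(groups)),
                       method = "degenerate"))
  }
  kt <- stats::kruskal.test(groups)
  n <- sum(lengths(groups))
  ties <- anyDuplicated(unlist(groups)) > 0
  if (n <= 10 && !ties) {
    p <- kw_perm_p(groups)
    method <- "exact_permutation"
  } else {
    p <- kt$p.value
    method <- "chi_square"
  }
  test_report("kruskal_wallis", unname(kt$statistic), p, n, method = method)
}

# exact permutation p for the KW statistic (no ties), by recursive
# enumeration of the rank sets assigned to each group
kw_perm_p <- function(groups) {
  sizes <- lengths(groups)
  n <- sum(sizes)
  stat <- function(parts) {
    12 / (n * (n + 1)) *
      sum(vapply(parts, function(r) sum(r)^2 / length(r), numeric(1))) -
      3 * (n + 1)
  }
  obs <- stat(split(rank(unlist(groups)), rep(seq_along(groups), sizes)))
  hits <- 0L
  total <- 0L
  recurse <- function(avail, gi, parts) {
    if (gi == length(sizes)) {
      parts[[gi]] <- avail
      total <<- total + 1L
      if (stat(parts) >= obs - 1e-9) hits <<- hits + 1L
      return(invisible())
    }
    for (p in combn(avail, sizes[gi], simplify = FALSE)) {
      parts[[gi]] <- p
      recurse(setdiff(avail, p), gi + 1L, parts)
    }
  }
  recurse(seq_len(n), 1L, vector("list", length(sizes)))
  hits / total
}

#' All-pairs Tukey-HSD comparisons
#'
#' One-way ANOVA followed by Tukey's honest significant difference on
#' every pair of groups (studentized-range reference).
#'
#' @param groups Named list of numeric vectors.
#' @return Tibble with one row per pair: `comparison`, `diff`,
#'   `p_value`.
#' @export
tukey_hsd <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop_arg("need at least 2 non-empty groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  df <- tibble::tibble(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  tibble::tibble(
    test = "tukey_hsd",
    comparison = rownames(tk),
    diff = tk[, "diff"],
    p_value = tk[, "p adj"]
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum gap between the two empirical CDFs; the p-value is
#' exact for small samples without ties and asymptotic otherwise.
#'
#' @param x,y Numeric samples.
#' @param exact Force or forbid the exact p; `NULL` lets sample size
#'   decide.
#' @return One-row tibble report (statistic = D).
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  test_report("ks_two_sample", unname(kt$statistic), kt$p.value,
              length(x) + length(y), n_x = length(x), n_y = length(y))
}

#' Wilcoxon signed-rank test against a reference value
#'
#' Tests whether values (e.g. amplitudes normalized to a reference
#' structure) differ from `mu` (default 1). Zero differences are
#' dropped, with n adjusted, per the usual convention; the null is
#' exact for 20 or fewer non-zero differences without ties.
#'
#' @param x Numeric sample.
#' @param mu Reference value.
#' @return One-row tibble report.
#' @export
signed_rank_vs_value <- function(x, mu = 1) {
  d <- x - mu
  x_nz <- x[d != 0] # drop zero differences up front so the exact null applies
  nz <- length(x_nz)
  if (nz == 0) {
    return(test_report("signed_rank", NA_real_, 1, 0L))
  }
  ties <- anyDuplicated(abs(x_nz - mu)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(x_nz, mu = mu, exact = nz <= 20 && !ties,
                       correct = ties)
  )
  test_report("signed_rank", unname(wt$statistic), wt$p.value, nz)
}

#' Connection-probability analysis of a recorded cohort
#'
#' Builds responder counts per (cortical source, projection class) and
#' runs the four planned two-sided Fisher's exact comparisons --
#' GP_CPu vs GP_STN within each cortical source, and M1 vs M2 within
#' each projection class -- with a Bonferroni family of 4 and star
#' annotations at the corrected levels.
#'
#' @param x Either a per-cell tibble with `cortical_source`,
#'   `projection_class` and a logical `responsive` column (see
#'   [summarise_oepsc_cells()]), or a pre-tabulated tibble with
#'   `cortical_source`, `projection_class`, `n_responsive`, `n_total`.
#' @param alpha Nominal familywise level.
#' @return List with `counts` (tibble incl. responder fractions) and
#'   `comparisons` (one row per planned test, with `p_value`,
#'   `adjusted_alpha`, `significant`, `stars`).
#' @export
connection_table_analysis <- function(x, alpha = 0.05) {
  x <- tibble::as_tibble(x)
  if (all(c("n_responsive", "n_total") %in% names(x))) {
    counts <- x
  } else {
    if (!"responsive" %in% names(x)) {
      stop_arg("need either a `responsive` column or n_responsive/n_total")
    }
    counts <- dplyr::summarise(
      dplyr::group_by(x, .data$cortical_source, .data$projection_class),
      n_responsive = sum(.data$responsive),
      n_total = dplyr::n(), .groups = "drop"
    )
  }
  counts <- dplyr::mutate(counts, fraction = .data$n_responsive / .data$n_total)
  planned <- list(
    list(fix = "cortical_source", at = "M1", vary = "projection_class",
         lev = c("GP_CPu", "GP_STN")),
    list(fix = "cortical_source", at = "M2", vary = "projection_class",
         lev = c("GP_CPu", "GP_STN")),
    list(fix = "projection_class", at = "GP_CPu", vary = "cortical_source",
         lev = c("M1", "M2")),
    list(fix = "projection_class", at = "GP_STN", vary = "cortical_source",
         lev = c("M1", "M2"))
  )
  m_family <- length(planned)
  a_adj <- bonferroni(alpha, m_family)
  rows <- purrr::map(planned, function(pl) {
    g1 <- counts[counts[[pl$fix]] == pl$at & counts[[pl$vary]] == pl$lev[1], ]
    g2 <- counts[counts[[pl$fix]] == pl$at & counts[[pl$vary]] == pl$lev[2], ]
    if (nrow(g1) != 1 || nrow(g2) != 1 || g1$n_total == 0 || g2$n_total == 0) {
      warn(sprintf("comparison %s=%s skipped: empty class", pl$fix, pl$at))
      return(NULL)
    }
    ft <- fisher_exact_2x2(g1$n_responsive, g1$n_total - g1$n_responsive,
                           g2$n_responsive, g2$n_total - g2$n_responsive)
    tibble::tibble(
      comparison = sprintf("%s=%s: %s vs %s", pl$fix, pl$at,
                           pl$lev[1], pl$lev[2]),
      p_value = ft$p_value,
      odds_ratio = ft$statistic,
      n = ft$n,
      adjusted_alpha = a_adj,
      significant = ft$p_value < a_adj,
      stars = significance_stars(ft$p_value, m_family)
    )
  })
  structure(list(counts = counts, comparisons = dplyr::bind_rows(rows)),
            class = "connection_analysis")
}

#' @export
print.connection_analysis <- function(x, ...) {
  cat("<connection_analysis>\n")
  print(x$counts)
  print(x$comparisons)
  invisible(x)
}

#' @rdname connection_table_analysis
#' @param ... Unused.
#' @export
tidy.connection_analysis <- function(x, ...) x$comparisons

#' Group-wise oEPSC amplitude comparison
#'
#' Mirrors the population analysis of evoked-current amplitudes across
#' cell classes: one-way ANOVA over the {MSN, STN, GP_STN, GP_CPu}
#' groups followed by all-pairs Tukey-HSD, a Wilcoxon rank-sum test of
#' GP_CPu vs GP_STN, and a Kolmogorov-Smirnov comparison of the GP_Bi
#' vs GP_CPu amplitude distributions when bi-directionally projecting
#' cells are present. Groups with fewer than 2 observations are
#' excluded with a warning.
#'
#' @param meas Tibble with `projection_class` and `amplitude` (one row
#'   per responsive cell).
#' @return List with `anova` (one-row tibble: F, p), `tukey`,
#'   `wilcoxon_gp`, `ks_bi` (the latter two `NULL` when the classes are
#'   absent).
#' @export
amplitude_comparison <- function(meas) {
  meas <- dplyr::filter(tibble::as_tibble(meas), is.finite(.data$amplitude))
  tab <- table(meas$projection_class)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warn(paste("excluding groups with n < 2:", paste(small, collapse = ", ")))
    meas <- dplyr::filter(meas, !.data$projection_class %in% small)
  }
  groups <- split(meas$amplitude, meas$projection_class)
  if (length(groups) < 2) stop_arg("need at least 2 groups with n >= 2")
  df <- tibble::tibble(value = unlist(groups, use.names = FALSE),
                       group = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  anova_row <- test_report("one_way_anova", an[["F value"]][1],
                           an[["Pr(>F)"]][1], nrow(df))
  wilx <- if (all(c("GP_CPu", "GP_STN") %in% names(groups))) {
    wilcoxon_rank_sum(groups$GP_CPu, groups$GP_STN)
  }
  ksb <- if (all(c("GP_Bi", "GP_CPu") %in% names(groups))) {
    ks_two_sample(groups$GP_Bi, groups$GP_CPu)
  }
  structure(
    list(anova = anova_row, tukey = tukey_hsd(groups),
         wilcoxon_gp = wilx, ks_bi = ksb,
         group_means = purrr::map_dbl(groups, mean)),
    class = "amplitude_comparison"
  )
}

#' @export
print.amplitude_comparison <- function(x, ...) {
  cat("<amplitude_comparison>\n")
  print(x$anova)
  print(x$tukey)
  if (!is.null(x$wilcoxon_gp)) print(x$wilcoxon_gp)
  if (!is.null(x$ks_bi)) print(x$ks_bi)
  invisible(x)
}

#' @rdname amplitude_comparison
#' @param x An `amplitude_comparison`.
#' @param ... Unused.
#' @export
tidy.amplitude_comparison <- function(x, ...) {
  dplyr::bind_rows(
    x$anova,
    dplyr::mutate(x$tukey, test = "tukey_hsd"),
    x$wilcoxon_gp,
    x$ks_bi
  )
}
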
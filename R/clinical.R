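# IHC positivity scoring, binomial summaries, contingency breakdowns and
# nonparametric association tests for patient cohorts.

#' Score IHC marker positivity
#'
#' A case is positive when at least `cutoff` (default 30%) of its tumor
#' cells express the marker; the cutoff is inclusive.
#'
#' @param marker_fraction numeric vector in `[0, 1]`.
#' @param cutoff positivity cutoff, default 0.30.
#' @return factor with levels `negative`, `positive`.
#' @examples
#' score_positivity(c(0.30, 0.299, 1))  # positive negative positive
#' @export
score_positivity <- function(marker_fraction, cutoff = 0.30) {
  if (any(is.na(marker_fraction)) ||
      any(marker_fraction < 0 | marker_fraction > 1)) {
    stop("`marker_fraction` must be in [0, 1]")
  }
  factor(ifelse(marker_fraction >= cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Binomial summary of a positivity count
#'
#' Models positivity as n independent yes/no trials: the empirical
#' probability `p_hat = k/n` estimates the success probability and the
#' count's standard deviation is \eqn{\sigma = \sqrt{n \hat p (1-\hat p)}}.
#'
#' @param k number of positive cases.
#' @param n number of cases (>= 1).
#' @return list of class `BinomialSummary`: `n`, `k`, `p_hat`, `sigma`.
#' @examples
#' binomial_summary(50, 100)$sigma  # 5
#' @export
binomial_summary <- function(k, n) {
  if (length(n) != 1L || length(k) != 1L) stop("`k` and `n` must be scalars")
  if (n < 1) stop("`n` must be >= 1")
  if (k < 0 || k > n) stop("`k` must be in [0, n]")
  p <- k / n
  structure(list(n = n, k = k, p_hat = p, sigma = sqrt(n * p * (1 - p))),
            class = "BinomialSummary")
}

# Round half-up to integer; values whose exact fractional part is .5 are
# kept at one decimal (so 45.5 stays 45.5 instead of becoming 46 or 45).
render_percent <- function(p) {
  half <- abs(p * 2 - round(p * 2)) < 1e-9 & abs(p - round(p)) > 1e-9
  ifelse(half, round(p * 2) / 2, floor(p + 0.5))
}

#' Contingency breakdown of marker status by a clinico-pathological stratum
#'
#' One row per stratum level with negative/positive counts, display-rounded
#' percentages (see Details) and the row total. The unrounded percentages
#' always sum to exactly 100 per row; the displayed ones are rounded
#' half-up to integers except that an exact half-percent is rendered with
#' one decimal.
#'
#' @param cohort cohort `data.frame` with a `status` column (or
#'   `marker_fraction`, from which status is derived).
#' @param stratifier name of the column to stratify by.
#' @return `data.frame` of class `contingency_table`: `stratum`,
#'   `n_negative`, `pct_negative`, `n_positive`, `pct_positive`, `total`.
#' @examples
#' coh <- gen_cohort(cohort_spec(seed = 1))
#' contingency(coh, "grade")
#' @export
contingency <- function(cohort, stratifier) {
  if (!stratifier %in% names(cohort)) {
    stop("unknown stratifier column: ", stratifier)
  }
  if (!"status" %in% names(cohort)) {
    cohort$status <- score_positivity(cohort$marker_fraction)
  }
  status <- factor(as.character(cohort$status),
                   levels = c("negative", "positive"))
  tab <- table(droplevels(factor(cohort[[stratifier]])), status)
  rows <- contingency_from_counts(tab[, "negative"], tab[, "positive"],
                                  rownames(tab))
  class(rows) <- c("contingency_table", class(rows))
  rows
}

#' Contingency rows from raw counts
#'
#' Builds the same table as [contingency()] directly from per-stratum
#' negative/positive counts (useful for re-rendering published tables).
#'
#' @param n_negative,n_positive integer vectors of counts.
#' @param strata stratum labels.
#' @return `data.frame` as in [contingency()].
#' @examples
#' contingency_from_counts(3, 9, "HER2 positive")  # 25% / 75%
#' @export
contingency_from_counts <- function(n_negative, n_positive, strata) {
  tot <- n_negative + n_positive
  if (any(tot < 1)) stop("every stratum needs at least one case")
  data.frame(
    stratum = as.character(strata),
    n_negative = as.integer(n_negative),
    pct_negative = render_percent(100 * n_negative / tot),
    n_positive = as.integer(n_positive),
    pct_positive = render_percent(100 * n_positive / tot),
    total = as.integer(tot),
    stringsAsFactors = FALSE)
}

#' Nonparametric association tests for cohort variables
#'
#' Dispatches on the grouping: Mann-Whitney (Wilcoxon rank-sum) for two
#' groups, Kruskal-Wallis for three or more, Spearman rank correlation when
#' `y` is numeric/ordinal paired data. Ties are handled by midranks;
#' p-values are two-sided. The Mann-Whitney p is exact (full enumeration)
#' for small untied samples and uses the tie-corrected normal
#' approximation otherwise; Kruskal-Wallis uses the chi-square
#' approximation.
#'
#' @param values numeric vector (e.g. marker fractions).
#' @param by grouping factor, or a numeric vector for Spearman.
#' @param exact_max use the exact Mann-Whitney distribution when the total
#'   sample size is at most this (and there are no ties).
#' @return list with `method`, `statistic`, `p_value` and the grouping
#'   sizes.
#' @examples
#' association_tests(c(1, 2, 3, 4, 5, 6),
#'                   factor(rep(c("a", "b"), each = 3)))
#' @export
association_tests <- function(values, by, exact_max = 12) {
  if (anyNA(values)) stop("`values` must not contain NA")
  if (is.numeric(by)) {
    ct <- stats::cor.test(values, by, method = "spearman", exact = FALSE)
    return(list(method = "spearman", statistic = unname(ct$estimate),
                p_value = ct$p.value, n = length(values)))
  }
  by <- droplevels(factor(by))
  sizes <- table(by)
  if (any(sizes == 0)) stop("every group needs at least one observation")
  if (nlevels(by) < 2) stop("need at least 2 groups")
  if (nlevels(by) == 2) {
    g <- split(values, by)
    exact <- length(values) <= exact_max && !anyDuplicated(values)
    wt <- suppressWarnings(
      stats::wilcox.test(g[[1]], g[[2]], exact = exact, correct = !exact))
    list(method = "mann-whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value, n = as.vector(sizes))
  } else {
    kt <- stats::kruskal.test(values, by)
    list(method = "kruskal-wallis", statistic = unname(kt$statistic),
         p_value = kt$p.value, n = as.vector(sizes))
  }
}

#' Nottingham Prognostic Index grouping
#'
#' `GPG` for NPI < 2.5, `MPG` for 2.5-3.5, `PPG` for NPI > 4.5. The
#' interval (3.5, 4.5] sits between the published bin edges; such values
#' are classified `MPG` and flagged with a warning (and recorded in the
#' `"gap"` attribute) rather than silently reassigned.
#'
#' @param npi numeric NPI scores (>= 0).
#' @param warn warn when gap-interval values are present.
#' @return factor with levels `GPG`, `MPG`, `PPG`; attribute `gap` holds
#'   the indices that fell in (3.5, 4.5].
#' @examples
#' npi_group(c(2, 3, 5))  # GPG MPG PPG
#' @export
npi_group <- function(npi, warn = TRUE) {
  if (any(is.na(npi)) || any(npi < 0)) stop("`npi` must be >= 0")
  gap <- which(npi > 3.5 & npi <= 4.5)
  if (length(gap) && warn) {
    warning(length(gap), " NPI value(s) in the unassigned interval ",
            "(3.5, 4.5]; classified MPG")
  }
  g <- ifelse(npi < 2.5, "GPG", ifelse(npi <= 4.5, "MPG", "PPG"))
  structure(factor(g, levels = c("GPG", "MPG", "PPG")), gap = gap)
}
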
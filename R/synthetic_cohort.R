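# Synthetic patient cohorts emulating a 75-case breast-carcinoma series.
#
# One chosen clinico-pathological stratifier drives marker positivity: a
# patient in stratum s is positive with probability strata[s], and the
# continuous marker fraction is then drawn uniformly on the matching side
# of the 30% scoring cutoff. All other covariates are drawn independently
# from the observed marginal frequencies of a 75-patient series (grade
# 24/28/23; lymph-node+ 22/75; larger-dimension 37/75; PgR+ 56/74; HER2+
# 12/75; Ki-67+ 21/75; NPI groups 37/22/16; age 30-90 with 34 below 60).

.COHORT_MARGINALS <- list(
  grade = c(I = 24, II = 28, III = 23) / 75,
  lymph_node = 22 / 75,
  dimension = 37 / 75,
  PgR = 56 / 74,
  HER2 = 12 / 75,
  Ki67 = 21 / 75,
  npi_group = c(GPG = 37, MPG = 22, PPG = 16) / 75,
  age_young = 34 / 75            # P(age in 30-59)
)

# positivity by grade from the observed series (4/24, 14/28, 14/23)
.DEFAULT_STRATA <- c(I = 4 / 24, II = 14 / 28, III = 14 / 23)

#' Specification for a synthetic patient cohort
#'
#' @param n_patients number of patients (default 75).
#' @param strata named vector mapping each level of `stratifier` to a
#'   marker-positivity probability in `[0, 1]`.
#' @param stratifier which covariate drives positivity: `"grade"`,
#'   `"HER2"`, `"Ki67"`, `"lymph_node"`, `"dimension"`, `"PgR"` or
#'   `"npi_group"`. Binary covariates take strata levels `"negative"`,
#'   `"positive"`.
#' @param seed integer seed.
#' @return validated list of class `CohortSpec`.
#' @export
cohort_spec <- function(n_patients = 75, strata = .DEFAULT_STRATA,
                        stratifier = "grade", seed = 1) {
  if (n_patients < 1) stop("`n_patients` must be >= 1")
  if (length(strata) == 0) stop("`strata` must be non-empty")
  if (is.null(names(strata)) || any(!nzchar(names(strata)))) {
    stop("`strata` must be a named vector of probabilities")
  }
  if (any(strata < 0 | strata > 1)) stop("probabilities must be in [0, 1]")
  known <- c("grade", "HER2", "Ki67", "lymph_node", "dimension", "PgR",
             "npi_group")
  if (!stratifier %in% known) {
    stop("unknown stratifier; use one of: ", paste(known, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients), strata = strata,
                 stratifier = stratifier, seed = as.integer(seed)),
            class = "CohortSpec")
}

draw_binary <- function(n, p) {
  factor(ifelse(stats::runif(n) < p, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame`, one row per patient: `id`, `marker_fraction`
#'   (fraction of tumor cells staining, in `[0, 1]`), `status`
#'   (`positive`/`negative` at the 30% cutoff), `age`, `grade`,
#'   `lymph_node`, `dimension`, `PgR`, `HER2`, `Ki67`, `npi`, `npi_group`.
#' @examples
#' coh <- gen_cohort(cohort_spec(seed = 7))
#' table(coh$grade, coh$status)
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n_patients
  set.seed(spec$seed)
  m <- .COHORT_MARGINALS

  df <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = ifelse(stats::runif(n) < m$age_young,
                 sample(30:59, n, replace = TRUE),
                 sample(60:90, n, replace = TRUE)),
    grade = factor(sample(names(m$grade), n, replace = TRUE, prob = m$grade),
                   levels = c("I", "II", "III")),
    lymph_node = draw_binary(n, m$lymph_node),
    dimension = draw_binary(n, m$dimension),
    PgR = draw_binary(n, m$PgR),
    HER2 = draw_binary(n, m$HER2),
    Ki67 = draw_binary(n, m$Ki67),
    stringsAsFactors = FALSE
  )
  grp <- sample(names(m$npi_group), n, replace = TRUE, prob = m$npi_group)
  df$npi <- ifelse(grp == "GPG", stats::runif(n, 1.5, 2.5),
            ifelse(grp == "MPG", stats::runif(n, 2.5, 3.5),
                   stats::runif(n, 4.51, 6.8)))
  df$npi_group <- npi_group(df$npi, warn = FALSE)

  lv <- as.character(df[[spec$stratifier]])
  miss <- setdiff(unique(lv), names(spec$strata))
  if (length(miss)) {
    stop("`strata` lacks probabilities for level(s): ",
         paste(miss, collapse = ", "))
  }
  p <- unname(spec$strata[lv])
  positive <- stats::runif(n) < p
  df$marker_fraction <- ifelse(positive,
                               stats::runif(n, 0.30, 1),
                               stats::runif(n, 0, 0.2999))
  df$status <- score_positivity(df$marker_fraction)
  df[, c("id", "marker_fraction", "status", "age", "grade", "lymph_node",
         "dimension", "PgR", "HER2", "Ki67", "npi", "npi_group")]
}
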
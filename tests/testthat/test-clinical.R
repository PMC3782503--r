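test_that("positivity cutoff is inclusive at 30%", {
  expect_identical(as.character(score_positivity(c(0.30, 0.299, 1, 0))),
                   c("positive", "negative", "positive", "negative"))
  expect_error(score_positivity(1.2), "\\[0, 1\\]")
  expect_error(score_positivity(-0.1), "\\[0, 1\\]")
  # the cutoff itself is adjustable
  expect_identical(as.character(score_positivity(0.25, cutoff = 0.2)),
                   "positive")
})

test_that("binomial summaries follow sigma = sqrt(n p (1-p))", {
  s <- binomial_summary(0, 75)
  expect_equal(s$p_hat, 0); expect_equal(s$sigma, 0)
  expect_equal(binomial_summary(75, 75)$sigma, 0)
  expect_equal(binomial_summary(50, 100)$sigma, 5)
  s2 <- binomial_summary(32, 75)
  expect_equal(s2$sigma, sqrt(75 * (32 / 75) * (43 / 75)))
  expect_equal(round(s2$sigma, 3), 4.283)
  expect_error(binomial_summary(10, 0), ">= 1")
  expect_error(binomial_summary(80, 75), "\\[0, n\\]")
})

test_that("contingency rows reproduce the published cohort percentages", {
  tab <- contingency_from_counts(
    n_negative = c(20, 3, 7, 5),
    n_positive = c(4, 9, 14, 11),
    strata = c("grade I", "HER2 positive", "Ki-67 positive", "NPI PPG"))
  expect_equal(tab$pct_negative, c(83, 25, 33, 31))
  expect_equal(tab$pct_positive, c(17, 75, 67, 69))
  expect_equal(tab$total, c(24L, 12L, 21L, 16L))
  expect_identical(contingency_from_counts(0, 10, "x")$pct_positive, 100)
  expect_error(contingency_from_counts(0, 0, "x"), "at least one")
})

test_that("percent rendering rounds half-up except exact half-percents", {
  expect_equal(invadoquant:::render_percent(83 + 1 / 3), 83)
  expect_equal(invadoquant:::render_percent(16.5), 16.5)  # exact .5 kept
  expect_equal(invadoquant:::render_percent(62.5), 62.5)
  expect_equal(invadoquant:::render_percent(68.75), 69)   # half-up
  expect_equal(invadoquant:::render_percent(100), 100)
  # unrounded row percentages always close to 100
  set.seed(1)
  for (i in 1:20) {
    k <- sample(0:50, 1); n <- k + sample(1:50, 1)
    expect_equal(100 * k / n + 100 * (n - k) / n, 100)
  }
})

test_that("contingency on a generated cohort is internally consistent", {
  coh <- gen_cohort(cohort_spec(n_patients = 200, seed = 12))
  tab <- contingency(coh, "grade")
  expect_equal(sum(tab$total), 200)
  expect_equal(tab$n_negative + tab$n_positive, tab$total)
  expect_equal(sum(tab$n_positive), sum(coh$status == "positive"))
  expect_error(contingency(coh, "shoe_size"), "unknown stratifier")
})

test_that("association tests dispatch and agree with exact enumeration", {
  # complete separation: U = 0 on one side
  r <- association_tests(c(1, 2, 3, 4, 5, 6),
                         factor(rep(c("a", "b"), each = 3)))
  expect_identical(r$method, "mann-whitney")
  expect_equal(r$statistic, 0)
  # exact p for {1,3,5} vs {2,4,6} by enumerating all 20 splits
  vals <- c(1, 3, 5, 2, 4, 6)
  grp <- factor(rep(c("a", "b"), each = 3))
  obs_u <- sum(outer(c(1, 3, 5), c(2, 4, 6), ">"))
  us <- apply(combn(6, 3), 2, function(ix) {
    sum(outer(vals[ix], vals[-ix], ">"))
  })
  # two-sided: splits at least as extreme (either direction) as observed
  p_exact <- mean(abs(us - 4.5) >= abs(obs_u - 4.5))
  r2 <- association_tests(vals, grp)
  expect_equal(r2$p_value, p_exact)
  # three groups dispatch to Kruskal-Wallis, matching the built-in directly
  v <- c(10, 12, 11, 20, 22, 21, 30, 31, 29)
  g3 <- factor(rep(c("I", "II", "III"), each = 3))
  r3 <- association_tests(v, g3)
  kt <- kruskal.test(v, g3)
  expect_identical(r3$method, "kruskal-wallis")
  expect_equal(r3$p_value, kt$p.value)
  # Spearman on identical rankings
  r4 <- association_tests(1:10, as.numeric((1:10)^2))
  expect_identical(r4$method, "spearman")
  expect_equal(r4$statistic, 1)
  expect_error(association_tests(1:3, factor(rep("a", 3))), "2 groups")
})

test_that("exact and approximate Mann-Whitney agree for moderate samples", {
  set.seed(99)
  x <- rnorm(25); y <- rnorm(25, 0.3)
  p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
  p_approx <- association_tests(c(x, y),
                                factor(rep(c("a", "b"), each = 25)))$p_value
  expect_lt(abs(p_exact - p_approx), 0.01)
})

test_that("NPI grouping follows the published bins and flags the gap", {
  expect_identical(as.character(npi_group(c(2.0, 3.0, 5.0))),
                   c("GPG", "MPG", "PPG"))
  expect_identical(as.character(npi_group(c(2.5, 3.5))), c("MPG", "MPG"))
  expect_identical(as.character(npi_group(2.4999)), "GPG")
  expect_identical(as.character(npi_group(4.5001)), "PPG")
  expect_warning(g <- npi_group(c(2, 4.0, 5)), "unassigned interval")
  expect_identical(as.character(g[2]), "MPG")
  expect_identical(attr(g, "gap"), 2L)
  expect_error(npi_group(-1), ">= 0")
})
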
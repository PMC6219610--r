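test_that("spatial averages follow the mask arithmetic", {
  m <- parametric_map(matrix(150, 10, 10), "relative_cbv")
  expect_equal(spatial_average(m, matrix(TRUE, 10, 10)), 150)
  half <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  expect_equal(spatial_average(parametric_map(half, "relative_cbv"),
                               matrix(TRUE, 10, 10)), 50)
  expect_error(spatial_average(m, matrix(FALSE, 10, 10)),
               class = "ufd_parameter_error")
})

test_that("normalized AUC is the time-averaged trapezoid", {
  const <- tibble::tibble(time_min = seq(0, 40, by = 2), value_pct = 50)
  expect_equal(normalized_auc(const, 7, 37), 50)
  ramp <- tibble::tibble(time_min = c(7, 37), value_pct = c(0, 100))
  expect_equal(normalized_auc(ramp, 7, 37), 50)
  expect_equal(normalized_auc(dplyr::mutate(const, value_pct = 0), 7, 37), 0)
  # invariance to resampling a piecewise-linear series at its own knots
  dense <- tibble::tibble(time_min = seq(7, 37, by = 0.5),
                          value_pct = stats::approx(ramp$time_min,
                                                    ramp$value_pct,
                                                    seq(7, 37, by = 0.5))$y)
  expect_equal(normalized_auc(dense, 7, 37), normalized_auc(ramp, 7, 37))
  # artifact samples are excluded before integration
  art <- tibble::tibble(time_min = seq(0, 40, by = 1), value_pct = 10)
  art$value_pct[art$time_min >= 23 & art$time_min <= 26] <- 1e4
  art$artifact <- art$time_min >= 23 & art$time_min <= 26
  expect_equal(normalized_auc(art, 7, 37), 10)
  expect_error(normalized_auc(ramp, 0, 37), class = "ufd_parameter_error")
  expect_error(normalized_auc(ramp, 10, 5), class = "ufd_parameter_error")
})

test_that("exact Mann-Whitney matches enumeration-frozen examples", {
  r1 <- mann_whitney_exact(1:5, 6:10)
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 2 / 252)
  # U = 2 at n = 5,5 gives the 8/252 two-sided level (prints as 0.032)
  r2 <- mann_whitney_exact(c(1, 2, 3, 4, 7), c(5, 6, 8, 9, 10))
  expect_equal(r2$U, 2)
  expect_equal(r2$p, 8 / 252)
  expect_equal(round(r2$p, 3), 0.032)
  # identical constant groups are uninformative
  expect_equal(mann_whitney_exact(rep(3, 4), rep(3, 4))$p, 1)
  expect_error(mann_whitney_exact(numeric(0), 1:3),
               class = "ufd_parameter_error")
})

test_that("exact Mann-Whitney agrees with an independent oracle", {
  set.seed(99)
  for (rep in 1:5) {
    a <- stats::rnorm(5)
    b <- stats::rnorm(4, 0.5)
    for (alt in c("two_sided", "greater", "less")) {
      got <- mann_whitney_exact(a, b, alternative = alt)
      ora <- mw_oracle(a, b, alternative = alt)
      expect_equal(got$U, ora$U)
      expect_equal(got$p, ora$p)
    }
    # and with wilcox.test on tie-free data
    w <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(mann_whitney_exact(a, b)$U, unname(w$statistic))
    expect_equal(mann_whitney_exact(a, b)$p, w$p.value)
  }
  # ties are handled through midranks and the observed multiset
  a <- c(1, 2, 2, 3); b <- c(2, 3, 4)
  got <- mann_whitney_exact(a, b)
  ora <- mw_oracle(a, b)
  expect_equal(got$U, ora$U)
  expect_equal(got$p, ora$p)
})

test_that("exact-U symmetry identities hold", {
  set.seed(7)
  a <- stats::rnorm(5); b <- stats::rnorm(5)
  expect_equal(mann_whitney_exact(a, b, "greater")$p,
               mann_whitney_exact(b, a, "less")$p)
  expect_equal(mann_whitney_exact(a, b)$U + mann_whitney_exact(b, a)$U,
               25)
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(11)
  a <- stats::rnorm(12); b <- stats::rnorm(12, 1)
  got <- mann_whitney_exact(a, b)
  expect_equal(got$method, "normal_approx")
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, w$p.value, tolerance = 0.02)
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # difference of exactly one pooled SD
  a <- c(-1, 0, 1); b <- a + 1
  expect_equal(cohens_d(b, a), 1 / stats::sd(a))
  a2 <- c(0, 2); b2 <- c(sqrt(2), 2 + sqrt(2))
  expect_equal(cohens_d(b2, a2), 1)
  expect_warning(d0 <- cohens_d(rep(1, 3), rep(2, 3)), "Zero pooled")
  expect_true(is.na(d0))
  expect_error(cohens_d(1, 1:3), class = "ufd_parameter_error")
})

test_that("group comparison separates the designed control and TLV arms", {
  ch <- gt_cohort(n = 5, seed = 301)
  g <- group_compare(ch$series, region = "whole_slice", window = c(7, 37),
                     groups = c("control", "tlv"))
  s <- g$summary
  expect_gt(s$median_auc[s$group == "control"],
            s$median_auc[s$group == "tlv"])
  expect_gt(g$cohens_d, 0)
  expect_lte(g$test$p, 1)
  expect_equal(nrow(tidy(g)), 10)
  expect_equal(nrow(glance(g)), 1)
  # duplicated groups give a null effect
  dup <- dplyr::mutate(ch$series[ch$series$group == "control", ])
  dup2 <- dplyr::bind_rows(dup, dplyr::mutate(dup, group = "tlv"))
  g0 <- group_compare(dup2, region = "whole_slice", window = c(7, 37))
  expect_equal(g0$cohens_d, 0)
  expect_equal(g0$test$p, 1)
})
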
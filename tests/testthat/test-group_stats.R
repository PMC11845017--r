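test_that("group summaries match closed-form mean, SD and SE", {
  df <- as_trial(data.frame(treatment = c("CK", "CK", "CK", "Fm", "Fm", "Fm"),
                            replicate = rep(1:3, 2),
                            indicator = "plant_height",
                            value = c(1, 2, 3, 32, 32, 32)))
  s_sd <- summarize_groups(df, dispersion = "sd")
  expect_equal(s_sd$mean, c(2, 32))
  expect_equal(s_sd$dispersion, c(1, 0))
  s_se <- summarize_groups(df, dispersion = "se")
  expect_equal(s_se$dispersion[1], 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(s_se$dispersion[1], 0.5774, tolerance = 1e-4)
  one_rep <- as_trial(data.frame(treatment = c("CK", "CK", "Fm"),
                                 replicate = c(1, 2, 1),
                                 indicator = "plant_height",
                                 value = c(1, 2, 3)))
  expect_error(summarize_groups(one_rep), "Fm")
})

test_that("percent change reproduces the published growth-response values", {
  t3 <- builtin_fixture("table3")
  pc <- percent_change(t3)
  val <- function(tr, ind)
    pc$percent_change[pc$treatment == tr & pc$indicator == ind]
  expect_equal(val("Fm", "plant_height"), 91.07)
  expect_equal(val("Fm", "root_length"), 40.36)
  expect_equal(val("Fm", "leaf_area"), 16.00)
  expect_equal(val("Fm", "stem_diameter"), 18.28)
  expect_equal(val("Fm", "aboveground_biomass"), 64.69)
  expect_equal(val("Fm", "total_biomass"), 59.17)
  expect_equal(val("Sv", "plant_height"), 84.01)
  expect_equal(val("Sv", "aboveground_biomass"), 72.24)
})

test_that("percent change is zero at equal means, scale-invariant, and guards the control", {
  d <- data.frame(treatment = c("CK", "T1"), indicator = "plant_height",
                  mean = c(10, 10))
  expect_equal(percent_change(d)$percent_change, 0)
  d2 <- data.frame(treatment = c("CK", "T1", "T2"),
                   indicator = "plant_height", mean = c(8, 10, 14))
  d3 <- d2; d3$mean <- d3$mean * 37.5
  expect_equal(percent_change(d2, digits = NULL),
               percent_change(d3, digits = NULL))
  d0 <- data.frame(treatment = c("CK", "T1"), indicator = "plant_height",
                   mean = c(0, 5))
  expect_error(percent_change(d0), "zero")
  expect_error(percent_change(d2, control = "ZZ"), "not present")
})

test_that("letter display handles degenerate and clear-cut cases", {
  same <- as_trial(data.frame(treatment = rep(c("A1", "B1", "C1"), each = 3),
                              replicate = rep(1:3, 3),
                              indicator = "plant_height",
                              value = rep(c(5, 6, 7), 3)))
  al <- anova_letters(same, "plant_height")
  expect_true(all(al$letters == "a"))
  const <- as_trial(data.frame(treatment = rep(c("A1", "B1"), each = 3),
                               replicate = rep(1:3, 2),
                               indicator = "plant_height", value = 4))
  expect_true(all(anova_letters(const, "plant_height")$letters == "a"))
  set.seed(7)
  far <- random_groups_trial(c(hi = 100, lo = 0), sd = 0.1, n = 3)
  al2 <- anova_letters(far, "plant_height")
  expect_equal(unname(al2$letters[c("hi", "lo")]), c("a", "b"))
})

test_that("letters agree with the multcomp reference on random 7-group data", {
  skip_if_not_installed("multcomp")
  share <- function(l, a, b)
    length(intersect(strsplit(l[[a]], "")[[1]],
                     strsplit(l[[b]], "")[[1]])) > 0
  for (seed in c(11, 23, 35, 47, 59)) {
    set.seed(seed)
    mu <- as.list(stats::setNames(runif(7, 0, 8), default_treatments()))
    trial <- random_groups_trial(mu, sd = 1.5, n = 5)
    al <- anova_letters(trial, "plant_height")
    # reference letters from multcomp on the identical fit
    d <- trial[trial$indicator == "plant_height", ]
    d$grp <- factor(d$treatment)
    fit <- stats::aov(value ~ grp, data = d)
    set.seed(1)  # multcomp's multivariate-t p-values are quasi-random
    ref <- suppressWarnings(
      multcomp::cld(multcomp::glht(fit, multcomp::mcp(grp = "Tukey"))))
    refl <- ref$mcletters$Letters
    pairs <- utils::combn(names(al$letters), 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      expect_equal(share(al$letters, a, b), share(refl, a, b),
                   label = sprintf("seed %d pair %s-%s", seed, a, b))
    }
  }
})

test_that("sharing a letter encodes exactly pairwise non-significance", {
  set.seed(2026)
  for (i in 1:30) {
    mu <- as.list(stats::setNames(runif(7, 0, 6), default_treatments()))
    trial <- random_groups_trial(mu, sd = runif(1, 0.5, 2), n = 4)
    al <- anova_letters(trial, "plant_height")
    expect_true(letters_encode(al$letters, al$pairwise, al$alpha))
    # letters start at "a" for the largest group mean
    top <- names(which.max(al$means))
    expect_true(grepl("a", al$letters[[top]]))
  }
})
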
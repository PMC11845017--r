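test_that("trial simulator is deterministic and honours degenerate noise", {
  spec <- trial_sim_spec(n_replicates = 3, seed = 42)
  a <- simulate_trial(spec)
  b <- simulate_trial(spec)
  expect_identical(a$value, b$value)
  cells0 <- default_sim_cells()
  cells0$sd <- 0
  z <- simulate_trial(trial_sim_spec(cells = cells0, seed = 1))
  key <- paste(z$treatment, z$indicator)
  mk <- paste(cells0$treatment, cells0$indicator)
  expect_equal(z$value, cells0$mean[match(key, mk)])
})

test_that("simulated group means converge to the table means", {
  spec <- trial_sim_spec(n_replicates = 200, seed = 5)
  tr <- simulate_trial(spec)
  cells <- spec$cells
  ok <- vapply(seq_len(nrow(cells)), function(i) {
    v <- tr$value[tr$treatment == cells$treatment[i] &
                    tr$indicator == cells$indicator[i]]
    se <- cells$sd[i] / sqrt(length(v))
    se == 0 || abs(mean(v) - cells$mean[i]) <= 3 * se
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("trial simulator validates its specification", {
  bad <- default_sim_cells()
  bad$sd[1] <- -1
  expect_error(trial_sim_spec(cells = bad), ">= 0")
  expect_error(trial_sim_spec(n_replicates = 1), "n_replicates")
  expect_error(trial_sim_spec(cells = data.frame(treatment = "CK",
                                                 indicator = "nope",
                                                 mean = 1, sd = 1)),
               "unknown indicator")
})

test_that("fragment simulator hits its targets", {
  f0 <- simulate_fragments(0, n_fragments = 50, seed = 1)
  expect_true(all(f0$intensity_class == 0))
  f5 <- simulate_fragments(100, class_mix = c(0, 0, 0, 0, 1),
                           n_fragments = 50, seed = 1)
  expect_true(all(f5$intensity_class == 5))
  expect_identical(simulate_fragments(50, n_fragments = 20, seed = 9),
                   simulate_fragments(50, n_fragments = 20, seed = 9))
  f <- simulate_fragments(50, n_fragments = 10000, seed = 3)
  achieved_F <- colonization_summary(f)$F
  expect_lt(abs(achieved_F - 50), 3 * sqrt(0.5 * 0.5 / 10000) * 100)
  expect_error(simulate_fragments(50, class_mix = rep(0.3, 5)), "summing")
})

test_that("fragment simulator converges to the indices implied by its mixes", {
  # all colonized, all class 5: M -> 95; arbuscule mix concentrated on A3
  # with share p gives a -> 100*p + 10*(1-p) etc.
  f <- simulate_fragments(100, class_mix = c(0, 0, 0, 0, 1),
                          arbuscule_mix = c(0, 0, 1),
                          n_fragments = 10000, seed = 11)
  s <- colonization_summary(f)
  expect_equal(s$M, 95)
  expect_equal(s$a, 100)
  f2 <- simulate_fragments(80, class_mix = c(0.2, 0.2, 0.2, 0.2, 0.2),
                           arbuscule_mix = c(0.5, 0.3, 0.2),
                           n_fragments = 10000, seed = 12)
  s2 <- colonization_summary(f2)
  expect_equal(s2$F, 80, tolerance = 0.02)
  expect_equal(s2$m, mean(c(1, 5, 30, 70, 95)), tolerance = 0.02)
})

test_that("qPCR simulator and 2^-ddCt are exact inverses at zero noise", {
  p1 <- simulate_qpcr(c(g = 1), ct_noise_sd = 0)
  expect_equal(relative_expression(p1, "g", "Fm", "CK")$fold_change, 1)
  p4 <- simulate_qpcr(c(g = 4), ct_noise_sd = 0)
  expect_equal(relative_expression(p4, "g", "Fm", "CK")$fold_change, 4)
  # noisy recovery close to the requested fold change
  pn <- simulate_qpcr(c(g = 2.44), ct_noise_sd = 0.1, n_replicates = 4,
                      seed = 8)
  fc <- relative_expression(pn, "g", "Fm", "CK")$fold_change
  expect_equal(fc, 2.44, tolerance = 0.1)
  expect_error(simulate_qpcr(c(g = -2)), "positive")
})

test_that("DEG table simulator plants recoverable truth", {
  none <- simulate_deg_table(n_genes = 200, frac_de = 0, seed = 2)
  expect_true(all(none$truth == "ns"))
  expect_identical(simulate_deg_table(n_genes = 100, seed = 4),
                   simulate_deg_table(n_genes = 100, seed = 4))
  d <- simulate_deg_table(n_genes = 400, frac_de = 0.5,
                          effect_location = 4, seed = 6)
  s <- screen_degs(d)
  de <- d$truth != "ns"
  recovered <- s$records$status[de] == d$truth[de]
  expect_gt(mean(recovered), 0.95)
})

test_that("null DEG p-values are calibrated and the screen suppresses them", {
  d0 <- simulate_deg_table(n_genes = 600, frac_de = 0, seed = 10)
  # raw p < 0.05 alone fires at about the nominal rate
  frac_p <- mean(d0$pvalue < 0.05)
  expect_lt(abs(frac_p - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
  # adding the fold-change threshold pushes the rate far below nominal
  s <- screen_degs(d0)
  expect_lt((s$n_up + s$n_down) / 600, 0.05 * frac_p + 0.01)
})
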
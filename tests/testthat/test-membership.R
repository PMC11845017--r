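rhu2 <- function(x) floor(x * 100 + 0.5) / 100

test_that("membership_value matches boundary identities and published cells", {
  expect_equal(membership_value(32.15, 32.15, 61.43, "positive"), 0)
  expect_equal(membership_value(32.15, 32.15, 61.43, "inverse"), 1)
  expect_equal(rhu2(membership_value(59.16, 32.15, 61.43, "positive")), 0.92)
  expect_equal(rhu2(membership_value(36.76, 26.12, 38.24, "positive")), 0.88)
  expect_error(membership_value(5, 10, 20, "positive"), "outside")
  expect_error(membership_value(10, 10, 10, "positive"), "constant")
  # F1 + F2 = 1 pointwise
  x <- seq(2, 9, by = 0.5)
  expect_equal(membership_value(x, 2, 9, "positive") +
                 membership_value(x, 2, 9, "inverse"),
               rep(1, length(x)))
})

test_that("two-treatment matrix is forced by the formula", {
  d <- data.frame(indicator = "plant_height", treatment = c("a1", "b1"),
                  mean = c(10, 20))
  mm <- membership_matrix(d)
  expect_equal(as.vector(mm$mu), c(0, 1))
  expect_equal(unname(mm$rank), c(2L, 1L))
  expect_equal(rank_treatments(mm), c("b1", "a1"))
})

test_that("growth-indicator membership reproduces the published matrix", {
  t3 <- builtin_fixture("table3")
  t4 <- builtin_fixture("table4")
  mm <- membership_matrix(fixture_means(t3))
  for (ind in unique(t3$indicator)) {
    pub <- t4[t4$indicator == ind, ]
    got <- rhu2(mm$mu[ind, pub$treatment])
    expect_equal(unname(got), pub$value, label = ind)
  }
  expect_equal(rhu2(mm$mu["stem_diameter", "Ri"]), 0.96)
})

test_that("inverse direction flips the row exactly (MDA semantics)", {
  d <- data.frame(indicator = rep(c("iaa_content", "mda_content"), each = 3),
                  treatment = rep(c("CK", "Sv", "Fm"), 2),
                  mean = c(10, 20, 30, 6.5, 3.0, 4.0))
  mm <- membership_matrix(d)
  expect_equal(unname(mm$mu["iaa_content", ]), c(0, 0.5, 1))
  # CK has the highest MDA, so scores 0; Sv the lowest, so 1
  expect_equal(unname(mm$mu["mda_content", c("CK", "Sv")]), c(0, 1))
})

test_that("membership rows are affine-invariant and attain 0 and 1", {
  set.seed(31)
  reg <- default_indicators()
  inds <- evaluation_indicators()
  for (i in 1:25) {
    k <- sample(3:10, 1)
    trts <- paste0("T", seq_len(sample(3:8, 1)))
    ind <- sample(inds, k)
    d <- expand.grid(indicator = ind, treatment = trts,
                     stringsAsFactors = FALSE)
    d$mean <- runif(nrow(d), 0, 50)
    mm <- membership_matrix(d, reg)
    expect_true(all(mm$mu >= 0 & mm$mu <= 1))
    expect_true(all(apply(mm$mu, 1, function(r)
      any(abs(r) < 1e-12) && any(abs(r - 1) < 1e-12))))
    expect_true(all(mm$column_mean >= 0 & mm$column_mean <= 1))
    # positive affine map of one indicator leaves its row unchanged
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    d2 <- d
    sel <- d2$indicator == ind[1]
    d2$mean[sel] <- a * d2$mean[sel] + b
    mm2 <- membership_matrix(d2, reg)
    expect_equal(mm2$mu[ind[1], ], mm$mu[ind[1], ], tolerance = 1e-9)
    # negative scale flips the row exactly as switching direction would
    d3 <- d
    d3$mean[sel] <- -d3$mean[sel]
    mm3 <- membership_matrix(d3, reg)
    expect_equal(mm3$mu[ind[1], ], 1 - mm$mu[ind[1], ], tolerance = 1e-9)
    # permuting indicator rows changes neither column means nor ranks
    perm <- sample(nrow(d))
    mmp <- membership_matrix(d[perm, ], reg)
    expect_equal(mmp$column_mean[names(mm$column_mean)], mm$column_mean)
    expect_equal(mmp$rank[names(mm$rank)], mm$rank)
  }
})

test_that("constant indicators are excluded with a warning by default", {
  d <- data.frame(indicator = rep(c("plant_height", "root_length"), each = 2),
                  treatment = rep(c("CK", "Fm"), 2),
                  mean = c(10, 20, 7, 7))
  expect_warning(mm <- membership_matrix(d), "root_length")
  expect_equal(rownames(mm$mu), "plant_height")
  mm2 <- suppressWarnings(membership_matrix(d, constant = "half"))
  expect_equal(unname(mm2$mu["root_length", ]), c(0.5, 0.5))
})

test_that("ranking breaks column-mean ties by treatment input order", {
  d <- data.frame(indicator = rep(c("plant_height", "root_length"), each = 3),
                  treatment = rep(c("CK", "T1", "T2"), 2),
                  mean = c(0, 1, 2, 2, 1, 0))
  mm <- membership_matrix(d)   # CK and T2 both average 0.5, T1 0.5 too
  expect_equal(unname(mm$column_mean), rep(0.5, 3))
  expect_equal(rank_treatments(mm), c("CK", "T1", "T2"))
  single <- membership_matrix(
    data.frame(indicator = "plant_height", treatment = c("only", "z"),
               mean = c(3, 4)))
  expect_equal(rank_treatments(single)[1], "z")
})
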
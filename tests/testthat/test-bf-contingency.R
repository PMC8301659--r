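test_that("independent-binomial closed form is exact arithmetic on easy tables", {
  # all-null table: B(1,21)/(B(1,11) B(1,11)) = 121/21
  res <- indep_binomial_bf01(contingency_table_2x2(10, 0, 10, 0))
  expect_equal(res$bf01, 121 / 21, tolerance = 1e-12)
  # frozen regression value
  expect_equal(indep_binomial_bf01(contingency_table_2x2(20, 5, 20, 10))$bf01,
               0.76594444, tolerance = 1e-7)
})

test_that("both variants match Simpson-grid integration oracles", {
  expect_equal(indep_binomial_bf01(contingency_table_2x2(20, 5, 20, 10))$bf01,
               oracle_table_bf01(20, 5, 20, 10), tolerance = 1e-6)
  expect_equal(
    gd_indep_multinomial_bf01(contingency_table_2x2(20, 5, 20, 10))$bf01,
    oracle_table_bf01(20, 5, 20, 10, variant = "gd_indep_multinomial"),
    tolerance = 1e-6)
  expect_equal(
    gd_indep_multinomial_bf01(contingency_table_2x2(20, 5, 20, 10))$bf01,
    1.05858101, tolerance = 1e-7)

  # property check over random small tables, both variants
  set.seed(7)
  for (k in 1:40) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    y1 <- sample(0:n1, 1); y2 <- sample(0:n2, 1)
    tab <- contingency_table_2x2(n1, y1, n2, y2)
    expect_equal(indep_binomial_bf01(tab)$bf01,
                 oracle_table_bf01(n1, y1, n2, y2), tolerance = 1e-6,
                 label = sprintf("ib %d/%d vs %d/%d", y1, n1, y2, n2))
    expect_equal(gd_indep_multinomial_bf01(tab)$bf01,
                 oracle_table_bf01(n1, y1, n2, y2,
                                   variant = "gd_indep_multinomial"),
                 tolerance = 1e-6,
                 label = sprintf("gd %d/%d vs %d/%d", y1, n1, y2, n2))
  }
})

test_that("the two variants differ only through the null prior", {
  tab <- contingency_table_2x2(30, 6, 30, 12)
  ib <- indep_binomial_bf01(tab)
  gd <- gd_indep_multinomial_bf01(tab)
  expect_false(isTRUE(all.equal(ib$bf01, gd$bf01)))
  # analytic ratio of the two null marginals: Beta(1,1) vs Beta(2,2) prior
  yp <- 18; N <- 60
  want_ratio <- exp(lbeta(yp + 1, N - yp + 1) -
                      (lbeta(yp + 2, N - yp + 2) - lbeta(2, 2)))
  expect_equal(ib$bf01 / gd$bf01, want_ratio, tolerance = 1e-12)
})

test_that("closed forms are total: zero and all-event cells stay finite", {
  extremes <- list(c(10, 0, 10, 0), c(10, 10, 10, 10), c(10, 0, 10, 10),
                   c(1, 0, 1, 1), c(5000, 0, 5000, 5000))
  for (e in extremes) {
    tab <- contingency_table_2x2(e[1], e[2], e[3], e[4])
    for (v in c("indep_binomial", "gd_indep_multinomial")) {
      res <- mortality_bf(tab, variant = v)
      # the log closed form never degenerates; bf01 itself may underflow
      # double precision for gigantic discordant tables
      expect_true(is.finite(res$log_bf01),
                  label = sprintf("%s on %s", v, paste(e, collapse = ",")))
      expect_true(res$bf01 >= 0 && res$category %in% evidence_categories())
    }
  }
  # Solidarity-scale arm sizes are no problem for the log-Gamma evaluation
  big <- contingency_table_2x2(20000, 1500, 20000, 1600)
  expect_true(is.finite(indep_binomial_bf01(big)$log_bf01))
})

test_that("bf01 is symmetric under arm exchange", {
  tab <- contingency_table_2x2(158, 22, 78, 10)
  swp <- contingency_table_2x2(78, 10, 158, 22)
  expect_equal(indep_binomial_bf01(tab)$bf01, indep_binomial_bf01(swp)$bf01,
               tolerance = 1e-14)
  expect_equal(gd_indep_multinomial_bf01(tab)$bf01,
               gd_indep_multinomial_bf01(swp)$bf01, tolerance = 1e-14)
})

test_that("replicating a null-consistent table strengthens the null", {
  for (v in c("indep_binomial", "gd_indep_multinomial")) {
    bfs <- vapply(1:6, function(k) {
      mortality_bf(contingency_table_2x2(20 * k, 4 * k, 30 * k, 6 * k),
                   variant = v)$bf01
    }, numeric(1))
    expect_true(all(diff(bfs) > 0), label = v)
  }
  # identical balanced arms favor independence at moderate n
  expect_gt(gd_indep_multinomial_bf01(contingency_table_2x2(40, 8, 40, 8))$bf01, 1)
  expect_gt(indep_binomial_bf01(contingency_table_2x2(40, 8, 40, 8))$bf01, 1)
})

test_that("for fixed margins bf01 peaks where rates are equal (small exhaustive)", {
  for (n1 in c(4, 9, 12)) {
    for (n2 in c(6, 12)) {
      lb <- outer(0:n1, 0:n2, function(y1, y2) {
        lbeta(y1 + y2 + 1, n1 + n2 - y1 - y2 + 1) -
          lbeta(y1 + 1, n1 - y1 + 1) - lbeta(y2 + 1, n2 - y2 + 1)
      })
      for (yp in 0:(n1 + n2)) {
        y1s <- max(0, yp - n2):min(n1, yp)
        vals <- lb[cbind(y1s + 1, yp - y1s + 1)]
        equal_rate <- y1s[y1s / n1 == (yp - y1s) / n2]
        if (length(equal_rate) > 0) {
          expect_true(max(vals[match(equal_rate, y1s)]) >= max(vals) - 1e-12,
                      label = sprintf("n1=%d n2=%d yp=%d", n1, n2, yp))
        }
      }
    }
  }
})

test_that("dispatch and validation behave", {
  tab <- contingency_table_2x2(20, 5, 20, 10)
  expect_identical(mortality_bf(tab)$bf01, indep_binomial_bf01(tab)$bf01)
  expect_identical(mortality_bf(tab, "gd_indep_multinomial")$bf01,
                   gd_indep_multinomial_bf01(tab)$bf01)
  expect_error(mortality_bf(tab, "poisson"), "arg")
  expect_error(contingency_table_2x2(10, 11, 10, 0), "y1 exceeds")
  expect_error(contingency_table_2x2(0, 0, 10, 0), "integer")
  expect_error(contingency_table_2x2(10, 0, 10, 0, prior_a = 0), "> 0")
  # non-unit concentration flows through both closed forms
  tab2 <- contingency_table_2x2(20, 5, 20, 10, prior_a = 2)
  expect_true(is.finite(indep_binomial_bf01(tab2)$log_bf01))
  expect_true(is.finite(gd_indep_multinomial_bf01(tab2)$log_bf01))
})
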
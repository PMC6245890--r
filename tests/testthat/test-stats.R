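test_that("confusion counts cross-tabulate calls against truth", {
  expect_equal(unclass(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))),
               list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  cc <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cc$fp + cc$fn, 0)
  cc2 <- confusion(c(0, 1), c(1, 0))
  expect_equal(cc2$tp + cc2$tn, 0)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("accuracy statistics match exact rational arithmetic with Clopper-Pearson intervals", {
  cc <- confusion(rep(c(1, 0, 1, 0), c(11, 5, 2, 33)),
                  rep(c(1, 1, 0, 0), c(11, 5, 2, 33)))
  st <- accuracy_stats(cc)
  expect_equal(st$pct[st$statistic == "sensitivity"], 68.8)   # 11/16
  expect_equal(st$pct[st$statistic == "specificity"], 94.3)   # 33/35
  expect_equal(st$pct[st$statistic == "agreement"], 86.3)     # 44/51
  ci <- binom.test(11, 16)$conf.int
  expect_equal(st$lo_pct[st$statistic == "sensitivity"],
               floor(1000 * ci[1] + 0.5) / 10)
  expect_equal(st$hi_pct[st$statistic == "sensitivity"],
               floor(1000 * ci[2] + 0.5) / 10)
  # zero denominator: undefined, not an error
  none <- accuracy_stats(confusion(c(0, 0), c(0, 0)))
  expect_true(is.na(none$pct[none$statistic == "sensitivity"]))
})

test_that("exact McNemar matches binomial enumeration for all small discordant counts", {
  expect_equal(mcnemar_exact(4, 4), 1)
  expect_equal(mcnemar_exact(5, 0), 2 * 0.5^5)
  expect_equal(mcnemar_exact(10, 2), 158 / 4096)
  expect_equal(mcnemar_exact(0, 0), 1)
  # enumeration oracle over all b + c <= 12, plus symmetry
  for (n in 1:12) for (b in 0:n) {
    cc <- n - b
    oracle <- min(1, 2 * sum(choose(n, 0:min(b, cc))) * 0.5^n)
    expect_equal(mcnemar_exact(b, cc), oracle)
    expect_equal(mcnemar_exact(b, cc), mcnemar_exact(cc, b))
  }
  expect_error(mcnemar_exact(-1, 2), "non-negative")
  # asymptotic variant agrees with the chi-square formula
  expect_equal(mcnemar_exact(10, 2, method = "asymptotic"),
               pchisq(64 / 12, 1, lower.tail = FALSE))
})

test_that("one-way ANOVA matches the closed form on a 9-number fixture", {
  vals <- c(1, 2, 3, 1, 2, 3, 101, 102, 103)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- group_compare(vals, grp)
  # textbook computation: SSB / 2 over SSW / 6
  gm <- mean(vals)
  ssb <- 3 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - rep(tapply(vals, grp, mean), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$f, f_hand)
  expect_equal(res$p, pf(f_hand, 2, 6, lower.tail = FALSE))
  # Bonferroni multiplies raw pairwise p by the number of comparisons
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p_raw * 3))
  # identical groups: F = 0, p = 1
  same <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("proportion tests match hypergeometric enumeration and the chi-square formula", {
  # [[10,0],[0,10]]: only the two extreme tables are as extreme
  expect_equal(proportions_test(10, 10, 0, 10, method = "fisher"),
               2 / choose(20, 10))
  # Fisher vs explicit hypergeometric enumeration on assorted tables
  for (tab in list(c(3, 9, 6, 8), c(1, 12, 7, 11), c(5, 5, 5, 5),
                   c(0, 7, 4, 9), c(8, 14, 2, 16))) {
    a <- tab[1]; n1 <- tab[2] + tab[1]; b <- tab[3]; n2 <- tab[4] + tab[3]
    m <- a + b
    support <- max(0, m - n2):min(m, n1)
    probs <- dhyper(support, n1, n2, m)
    oracle <- sum(probs[probs <= dhyper(a, n1, n2, m) * (1 + 1e-7)])
    expect_equal(proportions_test(a, n1, b, n2, method = "fisher"), oracle,
                 tolerance = 1e-9)
  }
  # Pearson chi-square without continuity correction
  expect_equal(proportions_test(20, 30, 10, 30, method = "chi-square"),
               pchisq(60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30), 1,
                      lower.tail = FALSE))
  expect_equal(60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30), 20 / 3,
               tolerance = 1e-12)
  # near-identical proportions at large n: p close to 1
  expect_gt(proportions_test(500, 1000, 500, 1000, method = "chi-square"),
            0.99)
  # zero-margin tables are Fisher-only
  expect_error(proportions_test(0, 10, 0, 10, method = "chi-square"),
               "fisher")
  expect_equal(proportions_test(0, 10, 0, 10, method = "fisher"), 1)
})

test_that("simulated reader groups reproduce the accuracy ordering of training levels", {
  # operating points: Level-1 (0.865, 0.419), Level-2 (0.573, 0.694),
  # Level-3 (0.719, 0.887) at prevalence 16/53
  ops <- list(l1 = c(0.865, 0.419), l2 = c(0.573, 0.694),
              l3 = c(0.719, 0.887))
  acc <- vapply(seq_along(ops), function(i) {
    calls <- make_reader_calls(53 * 60, 16 / 53, ops[[i]][1], ops[[i]][2],
                               seed = 100 + i)
    mean(calls$call == calls$truth)
  }, 0)
  expect_true(acc[3] > acc[2] && acc[2] > acc[1])
  # and the implied accuracies sit near their analytic values
  analytic <- vapply(ops, function(o)
    o[1] * 16 / 53 + o[2] * 37 / 53, 0)
  expect_equal(acc, unname(analytic), tolerance = 0.05)
})
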
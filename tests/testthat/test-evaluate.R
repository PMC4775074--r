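# Independent oracle: two-sided Fisher p by explicit enumeration of every
# 2x2 table with the observed margins, using factorial arithmetic only.
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- sum(m)
  tab_prob <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (min(b, c, d) < 0) return(NA_real_)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
          lfactorial(b) - lfactorial(c) - lfactorial(d))
  }
  probs <- vapply(0:min(r1, c1), tab_prob, numeric(1))
  probs <- probs[!is.na(probs)]
  p_obs <- tab_prob(m[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("membership calls follow the 0.65/0.35 thresholds", {
  cfg <- threshold_config()
  expect_identical(as.character(call_membership(0.70, cfg)), "member")
  expect_identical(as.character(call_membership(0.50, cfg)), "borderline")
  expect_identical(as.character(call_membership(0.20, cfg)), "nonmember")
  # boundary values are borderline: thresholds are strict
  expect_identical(as.character(call_membership(c(0.65, 0.35), cfg)),
                   c("borderline", "borderline"))
  # midpoint mode has no borderline band
  mid <- threshold_config(midpoint = TRUE)
  expect_identical(as.character(call_membership(c(0.51, 0.49), mid)),
                   c("member", "nonmember"))
  expect_error(call_membership(NaN, cfg), "finite")
  expect_error(threshold_config(member_above = 0.3), "nonmember_below")
})

test_that("conservative contingency counts borderline as wrong attribution", {
  cfg <- threshold_config()
  calls <- call_membership(rep(0.9, 5), cfg)
  tab <- build_contingency(calls, rep(TRUE, 5), cfg)
  expect_identical(c(tab$TP, tab$FP, tab$TN, tab$FN), c(5L, 0L, 0L, 0L))

  # one borderline affected sample becomes a false negative
  tab <- build_contingency(call_membership(0.5, cfg), TRUE, cfg)
  expect_identical(tab$FN, 1L)
  expect_identical(tab$borderline_affected, 1L)
  # one borderline unaffected sample becomes a false positive
  tab <- build_contingency(call_membership(0.5, cfg), FALSE, cfg)
  expect_identical(tab$FP, 1L)
  expect_identical(tab$borderline_unaffected, 1L)

  # the same value under the midpoint rule is a definite call
  mid <- threshold_config(midpoint = TRUE)
  tab <- build_contingency(call_membership(0.55, mid), TRUE, mid)
  expect_identical(tab$TP, 1L)
  expect_identical(tab$FN, 0L)

  expect_error(build_contingency(call_membership(c(1, 0), cfg), TRUE, cfg),
               "equal length")
})

test_that("diagnostic metric formulas and not-available handling", {
  tab <- structure(list(TP = 9L, FP = 2L, TN = 8L, FN = 1L,
                        borderline_affected = 0L, borderline_unaffected = 0L,
                        n = 20L, gold_standard = "hand-built",
                        conservative = TRUE),
                   class = "contingency_table")
  met <- compute_metrics(tab)
  expect_equal(met$sensitivity, 0.90)
  expect_equal(met$specificity, 0.80)
  expect_equal(met$accuracy, 0.85)
  expect_equal(met$PPV, 9 / 11)
  expect_equal(met$NPV, 8 / 9)

  perfect <- build_contingency(
    call_membership(c(0.9, 0.9, 0.1, 0.1), threshold_config()),
    c(TRUE, TRUE, FALSE, FALSE), threshold_config())
  metp <- compute_metrics(perfect)
  expect_true(all(unlist(metp[c("sensitivity", "specificity", "PPV",
                                "NPV", "accuracy")]) == 1))

  none_called <- structure(list(TP = 0L, FP = 0L, TN = 5L, FN = 5L,
                                borderline_affected = 0L,
                                borderline_unaffected = 0L, n = 10L,
                                gold_standard = "hand-built",
                                conservative = TRUE),
                           class = "contingency_table")
  expect_true(is.na(compute_metrics(none_called)$PPV))
})

test_that("two-tailed Fisher agrees with enumeration and the library routine", {
  expect_equal(fisher_exact_two_tailed(rbind(c(5, 5), c(5, 5))), 1.0)

  m <- rbind(c(10, 0), c(0, 10))
  expect_equal(fisher_exact_two_tailed(m), fisher_enum_oracle(m),
               tolerance = 1e-12)

  m <- rbind(c(8, 2), c(1, 9))
  expect_equal(fisher_exact_two_tailed(m), fisher_enum_oracle(m),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_tailed(m), fisher.test(m)$p.value,
               tolerance = 1e-9)

  set.seed(123)
  for (i in 1:100) {
    m <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (sum(m) == 0) next
    p <- fisher_exact_two_tailed(m)
    expect_equal(p, fisher_enum_oracle(m), tolerance = 1e-9)
    expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-9)
    # transposing the table leaves the p-value unchanged
    expect_equal(fisher_exact_two_tailed(t(m)), p, tolerance = 1e-9)
  }
  expect_error(fisher_exact_two_tailed(matrix(0, 2, 2)), "empty")
})

test_that("conservative mode never beats the midpoint rule on accuracy", {
  set.seed(55)
  for (i in 1:30) {
    n <- 40
    truth <- runif(n) < 0.5
    yhat <- ifelse(truth, rnorm(n, 0.7, 0.25), rnorm(n, 0.3, 0.25))
    cons <- threshold_config()
    mid <- threshold_config(midpoint = TRUE)
    acc_c <- compute_metrics(
      build_contingency(call_membership(yhat, cons), truth, cons))$accuracy
    acc_m <- compute_metrics(
      build_contingency(call_membership(yhat, mid), truth, mid))$accuracy
    expect_lte(acc_c, acc_m + 1e-12)
  }
})

test_that("metrics are invariant to sample order", {
  set.seed(56)
  truth <- runif(25) < 0.5
  yhat <- runif(25)
  cfg <- threshold_config()
  m1 <- compute_metrics(build_contingency(call_membership(yhat, cfg),
                                          truth, cfg))
  o <- sample(25)
  m2 <- compute_metrics(build_contingency(call_membership(yhat[o], cfg),
                                          truth[o], cfg))
  expect_equal(m1, m2)
})
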
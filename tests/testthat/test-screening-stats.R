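# Correlation, outlier exclusion, discrimination-limit screening, threshold
# scan, and stepwise forward regression.

test_that("single-pass outlier rule retains a value inside 3 population SDs", {
  # {100, 101, 99, 100, 300}: mean 140, population SD ~ 80.0, so 300 deviates
  # 160 < 3*SD = 240 and everything is retained under the single-pass rule
  v <- c(100, 101, 99, 100, 300)
  expect_equal(sqrt(mean((v - mean(v))^2)), 80.00250, tolerance = 1e-6)
  expect_equal(exclude_outliers(v, k = 3), 1:5)
  # a genuinely extreme point is dropped
  v2 <- c(rep(100, 20), 101, 99, 1000)
  m <- mean(v2); s <- sqrt(mean((v2 - m)^2))
  expect_gt(abs(1000 - m), 3 * s)
  expect_equal(exclude_outliers(v2, k = 3), seq_len(22))
})

test_that("outlier rule edge cases: all-equal input and huge k retain everything", {
  expect_equal(exclude_outliers(rep(5, 10)), 1:10)
  expect_equal(exclude_outliers(c(1, 2, 3, 100, -50), k = 1e9), 1:5)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
  expect_error(exclude_outliers(1:5, k = 0), "> 0")
})

test_that("pearson reproduces hand-computed and limiting cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, 2 * x + 1)$p_value, 0)
  expect_equal(pearson(x, -x)$r, -1)
  # hand computation: covariance 3, variances 5 and 5 -> r = 0.6
  res <- pearson(x, c(2, 1, 4, 3))
  expect_equal(res$r, 0.6)
  t <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(res$p_value, 2 * pt(-t, df = 2))
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("pearson matches the direct-formula and cor.test oracles on random data", {
  for (seed in 1:25) {
    d <- biliscreen:::with_seed(seed, list(x = rnorm(30), y = rnorm(30)))
    res <- pearson(d$x, d$y)
    # independent textbook formula
    r_direct <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
      sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
    expect_equal(res$r, r_direct, tolerance = 1e-12)
    ct <- cor.test(d$x, d$y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("green-channel worked example: limit 212 gives 100% sensitivity, 62.5% specificity", {
  # 26 subjects above the limit, 11 of them with TsB > 205; 25 below, all <= 205
  intensities <- c(rep(220, 26), rep(200, 25))
  tsb <- c(rep(250, 11), rep(150, 15), rep(150, 25))
  res <- classify_and_score(intensities, tsb, limit = 212,
                            clinical_threshold = 205)
  expect_equal(res$confusion[c("tp", "fp", "tn", "fn")],
               list(tp = 11L, fp = 15L, tn = 25L, fn = 0L))
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 62.5)
})

test_that("blue-channel worked example: one missed case gives 90.9% sensitivity, 60% specificity", {
  # 10 of 11 condition-positives above limit 190; 24 of 40 negatives below it
  intensities <- c(rep(200, 10), 180, rep(200, 16), rep(180, 24))
  tsb <- c(rep(250, 11), rep(150, 40))
  res <- classify_and_score(intensities, tsb, limit = 190,
                            clinical_threshold = 205)
  expect_equal(res$confusion$tp, 10L)
  expect_equal(res$confusion$fn, 1L)
  expect_equal(res$sensitivity, 100 * 10 / 11, tolerance = 1e-12)
  expect_equal(round(res$sensitivity, 1), 90.9)
  expect_equal(res$specificity, 60)
})

test_that("boundary subjects are negative on both axes (strict inequalities)", {
  res <- classify_and_score(c(212, 213), c(205, 206), limit = 212,
                            clinical_threshold = 205)
  expect_equal(res$confusion[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
})

test_that("sensitivity with no condition-positives is flagged undefined, not 0 or 100", {
  res <- classify_and_score(c(100, 120), c(100, 120), limit = 150,
                            clinical_threshold = 205)
  expect_false(res$sensitivity_defined)
  expect_true(is.na(res$sensitivity))
  expect_equal(res$specificity, 100)
})

test_that("threshold scan conserves counts, is monotone, and matches a naive recount", {
  d <- biliscreen:::with_seed(42, {
    tsb <- runif(60, 30, 290)
    list(tsb = tsb, ints = 150 + 0.2 * tsb + rnorm(60, 0, 10))
  })
  sc <- threshold_scan(d$ints, d$tsb, clinical_threshold = 205)
  expect_equal(nrow(sc$scan), 256)
  expect_true(all(sc$scan$tp + sc$scan$fp + sc$scan$tn + sc$scan$fn == 60))
  expect_true(all(diff(sc$scan$sensitivity) <= 1e-9))
  expect_true(all(diff(sc$scan$specificity) >= -1e-9))
  # independent naive recount at 5 limits
  for (L in c(10, 100, 180, 200, 250)) {
    tp <- sum(d$ints > L & d$tsb > 205); fp <- sum(d$ints > L & d$tsb <= 205)
    tn <- sum(d$ints <= L & d$tsb <= 205); fn <- sum(d$ints <= L & d$tsb > 205)
    row <- sc$scan[sc$scan$limit == L, ]
    expect_equal(unlist(row[c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
  # the chosen limit achieves 100% sensitivity by definition of the rule
  chosen <- sc$scan[sc$scan$limit == sc$chosen_limit, ]
  expect_equal(chosen$sensitivity, 100)
})

test_that("perfectly separable data admit a limit with 100% sensitivity and specificity", {
  tsb <- c(100, 150, 200, 240, 280)
  ints <- c(100, 120, 140, 220, 240)  # strictly increasing with TsB
  sc <- threshold_scan(ints, tsb, clinical_threshold = 205)
  best <- sc$scan[sc$scan$sensitivity == 100 & sc$scan$specificity == 100, ]
  expect_gt(nrow(best), 0)
})

test_that("stepwise forward selects the true predictor and ignores noise", {
  d <- biliscreen:::with_seed(7, {
    x1 <- rnorm(60); x2 <- rnorm(60)
    list(x = data.frame(x1 = x1, x2 = x2), y = 3 * x1 + rnorm(60))
  })
  fit <- stepwise_forward(d$y, d$x)
  expect_equal(fit$selected_terms, "x1")
  expect_true(all(fit$entry_p_values < 0.05))
})

test_that("a candidate equal to the response enters with coefficient 1, intercept 0", {
  y <- biliscreen:::with_seed(3, rnorm(20))
  fit <- stepwise_forward(y, data.frame(z = y))
  expect_equal(fit$selected_terms, "z")
  expect_equal(unname(fit$coefficients["z"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-10)
})

test_that("stepwise entry p-values agree with lm partial-F (add1) on a real fit", {
  d <- biliscreen:::with_seed(11, {
    x1 <- rnorm(40); x2 <- rnorm(40); x3 <- rnorm(40)
    list(x = data.frame(x1 = x1, x2 = x2, x3 = x3),
         y = 2 * x1 + 0.8 * x2 + rnorm(40))
  })
  fit <- stepwise_forward(d$y, d$x)
  # oracle: p-value of the first entering term from a one-variable lm F test
  f1 <- summary(lm(d$y ~ d$x[[fit$selected_terms[1]]]))$fstatistic
  p1 <- pf(f1[1], f1[2], f1[3], lower.tail = FALSE)
  expect_equal(fit$entry_p_values[1], unname(p1), tolerance = 1e-10)
})

test_that("stepwise rejects constant and collinear candidates by name", {
  y <- biliscreen:::with_seed(5, rnorm(30))
  x <- biliscreen:::with_seed(6, rnorm(30))
  expect_error(stepwise_forward(y, data.frame(a = x, b = rep(2, 30))), "b")
  expect_error(stepwise_forward(y, data.frame(a = x, b = 2 * x + 1)),
               "collinear.*a.*b|collinear.*b.*a")
})

test_that("under the null the first-entry rate is near the entry alpha", {
  # 500 null replicates, 3 noise candidates, entry alpha 0.05: the chance any
  # candidate enters is 1 - (1 - a_eff)^3 with a_eff ~ 0.05 per test; use a
  # binomial band around the simulated entry probability
  n_rep <- 500
  entered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- biliscreen:::with_seed(20000 + i, {
      list(x = data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25)),
           y = rnorm(25))
    })
    entered[i] <- length(stepwise_forward(d$y, d$x)$selected_terms) > 0
  }
  p_any <- 1 - (1 - 0.05)^3   # ~0.143 under independence of the three tests
  band <- qbinom(c(0.0025, 0.9975), n_rep, p_any) / n_rep
  expect_gte(mean(entered), band[1])
  expect_lte(mean(entered), band[2])
})
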
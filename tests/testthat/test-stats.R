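test_that("equal-proportions test matches the closed-form 2x2 chi-square", {
  # 91/100 vs 58/100: 200*(91*42 - 9*58)^2 / (100*100*149*51)
  t1 <- equal_proportions_test(c(91, 58), c(100, 100))
  expect_equal(unname(t1$statistic), 28.6617, tolerance = 1e-4)
  expect_equal(unname(t1$parameter), 1)
  t2 <- equal_proportions_test(c(91, 58), c(100, 100), correct = TRUE)
  expect_equal(unname(t2$statistic), 26.9509, tolerance = 1e-4)

  null <- equal_proportions_test(c(50, 50), c(100, 100))
  expect_equal(unname(null$statistic), 0)
  expect_equal(null$p.value, 1)

  # symmetric under swapping the environments
  sw <- equal_proportions_test(c(58, 91), c(100, 100))
  expect_equal(sw$statistic, t1$statistic)
  expect_equal(sw$p.value, t1$p.value)

  expect_error(equal_proportions_test(c(0, 0), c(100, 100)), "degenerate")
  expect_error(equal_proportions_test(c(1, 1), c(0, 10)), "at least one")
})

test_that("normality gate routes Gaussian samples parametric, skewed ones not", {
  set.seed(31)
  expect_equal(normality_gate(rnorm(500))$route, "parametric")
  expect_equal(normality_gate(rexp(500))$route, "nonparametric")
  expect_equal(normality_gate(rep(3, 10))$route, "nonparametric")
  expect_error(normality_gate(c(1, 2)), "at least 3")
  # under normality the gate trips at about its alpha level
  set.seed(32)
  trips <- mean(replicate(400, normality_gate(rnorm(40))$route == "nonparametric"))
  expect_gt(trips, 0.02)
  expect_lt(trips, 0.09)
})

test_that("two-way ANOVA detects a strong environment effect with letters", {
  d <- make_factorial(n_per_cell = 6, env_effect = 4, seed = 21)
  fit <- two_way_anova_tukey(d$y, d$env, d$month)
  p_env <- fit$anova$p_value[fit$anova$effect == "factor_a"]
  p_month <- fit$anova$p_value[fit$anova$effect == "factor_b"]
  expect_lt(p_env, 1e-6)
  expect_gt(p_month, 0.05) # null factor
  expect_setequal(fit$letters$factor_a, c("a", "b"))
  # month levels, all null, share a letter
  expect_true(all(fit$letters$factor_b == "a"))
  expect_error(two_way_anova_tukey(1:4, factor(c(1, 1, 2, 2)),
                                   factor(c(1, 1, 2, 2))), "cell")
})

test_that("ANOVA type-I error on a seeded null is near its nominal level", {
  set.seed(77)
  rej <- replicate(400, {
    d <- make_factorial(n_per_cell = 4)
    fit <- two_way_anova_tukey(d$y, d$env, d$month)
    fit$anova$p_value[fit$anova$effect == "factor_a"] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("Scheirer-Ray-Hare collapses to Kruskal-Wallis when one factor is flat", {
  set.seed(5)
  checked <- 0
  while (checked < 50) {
    n <- sample(8:16, 1)
    g <- droplevels(factor(sample(letters[1:3], n, replace = TRUE)))
    y <- sample(1:6, n, replace = TRUE) # heavy ties on purpose
    if (nlevels(g) < 2 || length(unique(y)) < 2) next
    srh <- scheirer_ray_hare(y, g, factor(rep("one", n)))
    kw <- stats::kruskal.test(y, g)
    expect_equal(srh$H[srh$effect == "factor_a"], unname(kw$statistic),
                 tolerance = 1e-9)
    expect_equal(srh$p_value[srh$effect == "factor_a"], kw$p.value,
                 tolerance = 1e-9)
    checked <- checked + 1
  }
})

test_that("SRH rank sums of squares decompose exactly in balanced designs", {
  for (s in 1:10) {
    d <- make_factorial(n_per_cell = 5, env_effect = 1, month_effect = 0.5,
                        seed = 100 + s)
    srh <- scheirer_ray_hare(d$y, d$env, d$month)
    ss <- setNames(srh$ss, srh$effect)
    expect_equal(ss[["factor_a"]] + ss[["factor_b"]] + ss[["interaction"]] +
                   ss[["residuals"]], ss[["total"]], tolerance = 1e-9)
  }
})

test_that("SRH separates a real environment effect from a null month effect", {
  d <- make_factorial(n_per_cell = 8, env_effect = 3, seed = 55)
  srh <- scheirer_ray_hare(d$y, d$env, d$month)
  expect_lt(srh$p_value[srh$effect == "factor_a"], 1e-4)
  expect_gt(srh$p_value[srh$effect == "factor_b"], 0.05)
  expect_error(scheirer_ray_hare(rep(2, 16), factor(rep(1:2, 8)),
                                 factor(rep(1:2, each = 8))), "tied")
})

test_that("SRH handles unbalanced designs through type-II rank SS", {
  set.seed(66)
  # unbalanced but with every cell occupied
  A <- factor(c(rep("sunny", 28), rep("shaded", 13)))
  B <- factor(c(rep(1:4, 7), rep(1:4, 3), 1))
  y <- rnorm(41) + 2 * (A == "shaded")
  srh <- scheirer_ray_hare(y, A, B)
  expect_true(all(is.finite(srh$H[1:3])))
  expect_lt(srh$p_value[1], 0.01)
  expect_true(all(srh$p_value[1:3] >= 0 & srh$p_value[1:3] <= 1))
})

test_that("Dunn z statistics match a hand-computed pooled-rank example", {
  # x = 1,2,3 | 4,5,6 | 2,4,9: midranks 1,2.5,4 | 5.5,7,8 | 2.5,5.5,9
  # sigma2 = 9*10/12 - 12/(12*8) = 7.375, se = sqrt(7.375 * 2/3)
  d <- dunn_test(c(1, 2, 3, 4, 5, 6, 2, 4, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(d$comparisons$z, c(-1.954280, -1.428127, 0.526152),
               tolerance = 1e-5)
  expect_equal(d$comparisons$p_adjusted, c(0.152004, 0.229883, 0.598782),
               tolerance = 1e-5)
  expect_equal(d$sigma2, 7.375)
})

test_that("two identical groups give z = 0 and adjusted p = 1", {
  d <- dunn_test(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(d$comparisons$z, 0)
  expect_equal(d$comparisons$p_adjusted, 1)
  expect_true(all(d$letters == "a"))
  expect_error(dunn_test(1:3, factor(c("a", "a", "a"), levels = c("a", "b"))),
               "at least one")
})

test_that("for two groups the squared Dunn z equals the Kruskal-Wallis H", {
  set.seed(14)
  for (i in 1:20) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    y <- c(sample(1:8, n1, TRUE), sample(3:10, n2, TRUE))
    g <- rep(c("a", "b"), c(n1, n2))
    if (length(unique(y)) < 2) next
    d <- dunn_test(y, g)
    kw <- stats::kruskal.test(y, factor(g))
    expect_equal(d$comparisons$z^2, unname(kw$statistic), tolerance = 1e-9)
  }
})

test_that("BH-adjusted p-values keep the raw ordering monotone", {
  set.seed(90)
  for (i in 1:10) {
    d <- dunn_test(rnorm(40), rep(letters[1:4], each = 10))
    o <- order(d$comparisons$p_value)
    expect_true(all(diff(d$comparisons$p_adjusted[o]) >= -1e-12))
    expect_true(all(d$comparisons$p_adjusted >= d$comparisons$p_value - 1e-12))
  }
})

test_that("letter displays separate exactly the significantly different groups", {
  p <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p["A", "C"] <- p["C", "A"] <- 0.001
  l <- letter_display(p, order = c("A", "B", "C"))
  expect_true(l[["A"]] != "" && l[["C"]] != "")
  expect_false(any(strsplit(l[["A"]], "")[[1]] %in% strsplit(l[["C"]], "")[[1]]))
  # B straddles both: shares a letter with each
  expect_true(any(strsplit(l[["B"]], "")[[1]] %in% strsplit(l[["A"]], "")[[1]]))
  expect_true(any(strsplit(l[["B"]], "")[[1]] %in% strsplit(l[["C"]], "")[[1]]))
  # all-distinct and all-equal extremes
  pd <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))); diag(pd) <- 1
  expect_setequal(letter_display(pd), c("a", "b"))
  pe <- matrix(1, 3, 3, dimnames = list(1:3, 1:3))
  expect_true(all(letter_display(pe) == "a"))
})
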
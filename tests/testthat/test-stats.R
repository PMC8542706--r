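test_that("pooled t from summaries equals the raw-data pooled t-test", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(26, 20, 8)
    y <- rnorm(17, 15, 9)
    ours <- pooled_t_from_summary(mean(x), sd(x), length(x),
                                  mean(y), sd(y), length(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  ## identical groups: t = 0, p = 1
  same <- pooled_t_from_summary(10, 2, 12, 10, 2, 12)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ## degenerate: both SDs zero, equal means
  expect_equal(pooled_t_from_summary(5, 0, 5, 5, 0, 5)$p_value, 1)
  expect_error(pooled_t_from_summary(5, 1, 1, 5, 1, 5), "n >= 2")
})

test_that("exact Mann-Whitney matches enumeration and wilcox.test", {
  ## symmetric tied case
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$p_value, 1)
  ## fully separated: most extreme of C(6,3) = 20 labelings, two-sided
  res <- mann_whitney(1:3, 4:6)
  expect_equal(res$p_value, 0.1)
  expect_identical(res$test, "mann_whitney_exact")
  ## exact path agrees with the base-R exact oracle on random samples
  set.seed(8)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:8, 1), 0, 10), 4)
    y <- round(rnorm(sample(3:8, 1), 1, 10), 4)
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_identical(ours$test, "mann_whitney_exact")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  ## exact and normal paths agree to within 0.02 at n1 = n2 = 10
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    p_exact <- mann_whitney(x, y)$p_value
    u <- tavrseal:::u_statistic(x, y)
    mu <- 50
    sigma <- sqrt(10 * 10 * 21 / 12)
    p_norm <- 2 * pnorm(-(abs(u - mu) - 0.5) / sigma)
    expect_lt(abs(p_exact - min(p_norm, 1)), 0.02)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Fisher exact follows the minimum-likelihood two-sided convention", {
  set.seed(12)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 6), 2)
    ours <- fisher_exact_2x2(tab)
    ref <- fisher.test(tab)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  ## hypergeometric probabilities over all same-margin tables sum to 1
  m <- 26; n <- 17; k <- 6
  expect_equal(sum(dhyper(max(0, k - n):min(k, m), m, n, k)), 1)
  ## degenerate margins
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 10, 10), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("r_squared definition and guards", {
  expect_equal(r_squared(1:10, 1:10), 1)
  expect_equal(r_squared(1:10, -(1:10)), 1)   # sign is lost by squaring
  expect_error(r_squared(1:10, rep(1, 10)), "variance")
  expect_error(r_squared(1:3, 1:4), "paired")
})

test_that("univariate screening retains true predictors, drops constants", {
  set.seed(10)
  n <- 43
  tab <- data.frame(out = rnorm(n), flat = 1)
  tab$self <- tab$out
  tab$noisy <- tab$out + rnorm(n, 0, 0.1)
  sc <- univariate_screen(tab, "out", c("self", "noisy", "flat"))
  expect_true(sc$retained[sc$candidate == "self"])
  expect_true(sc$retained[sc$candidate == "noisy"])
  expect_false(sc$retained[sc$candidate == "flat"])
  expect_identical(sc$reason[sc$candidate == "flat"], "constant candidate")
})

test_that("stepwise regression recovers planted predictors", {
  set.seed(14)
  n <- 43
  bav <- c(rep(1, 26), rep(0, 17))
  si <- rnorm(n, 1.07, 0.09)
  tab <- data.frame(bav = bav, si = si,
                    calcium = rnorm(n, 1000, 600), depth = rnorm(n, 7, 3))
  tab$out <- 5 * bav - 20 * si + rnorm(n, 0, 0.5)
  fit <- stepwise_lm(tab, "out", c("bav", "si", "calcium", "depth"))
  expect_setequal(fit$terms, c("bav", "si"))
  expect_equal(unname(fit$coefficients["bav"]), 5, tolerance = 0.15)
  expect_equal(unname(fit$coefficients["si"]), -20, tolerance = 0.15 * 20)
  ## scale invariance of the selected set
  tab2 <- tab
  tab2$si <- tab2$si * 1000
  fit2 <- stepwise_lm(tab2, "out", c("bav", "si", "calcium", "depth"))
  expect_setequal(fit2$terms, c("bav", "si"))
  ## pure noise: intercept-only model
  set.seed(15)
  null_tab <- data.frame(out = rnorm(n), a = rnorm(n), b = rnorm(n))
  fit0 <- stepwise_lm(null_tab, "out", c("a", "b"))
  expect_identical(fit0$terms, character(0))
  ## single perfect predictor recovered within 1%
  tab3 <- data.frame(out = 3 * (1:20) + 2, x = 1:20)
  fit3 <- stepwise_lm(tab3, "out", "x")
  expect_equal(unname(fit3$coefficients["x"]), 3, tolerance = 0.01)
  ## collinear candidate dropped with a warning
  tab4 <- data.frame(out = rnorm(20), x = 1:20)
  tab4$y <- 2 * tab4$x
  tab4$out <- tab4$x + rnorm(20, 0, 0.01)
  expect_warning(fit4 <- stepwise_lm(tab4, "out", c("x", "y")), "collinear")
  expect_identical(fit4$terms, "x")
})

test_that("group summary applies the normality-gated test selection", {
  set.seed(16)
  n_bav <- 26; n_tav <- 17
  tab <- data.frame(
    morphology = c(rep("BAV0", 11), rep("BAV1", 15), rep("TAV", n_tav)))
  ## planted effect about one SD: expect a significant BAV vs TAV row
  tab$tri_pct <- c(rnorm(n_bav, 11, 4), rnorm(n_tav, 6, 4))
  ## heavily skewed variable: Mann-Whitney path
  tab$skewed <- exp(c(rnorm(n_bav, 0, 1.2), rnorm(n_tav, 0, 1.2)))
  tab$pvl_flag <- c(rep(TRUE, 5), rep(FALSE, 21), rep(TRUE, 1),
                    rep(FALSE, 16))
  gs <- group_summary(tab, continuous = c("tri_pct", "skewed"),
                      binary = "pvl_flag")
  expect_lt(gs$p_value[gs$variable == "tri_pct"], 0.05)
  expect_identical(gs$test[gs$variable == "skewed"], "mann_whitney")
  ## identical groups: t = 0, p = 1 exactly
  shared <- rnorm(17, 50, 10)
  tab2 <- data.frame(morphology = c(rep("BAV0", 17), rep("TAV", 17)),
                     same = c(shared, shared))
  gs2 <- group_summary(tab2, continuous = "same")
  expect_equal(gs2$p_value[gs2$variable == "same"], 1)
  expect_identical(gs$test[gs$variable == "pvl_flag"], "fisher_exact")
  ## the binary row is the published 2x2: [[5,21],[1,16]]
  expect_equal(gs$p_value[gs$variable == "pvl_flag"],
               fisher_exact_2x2(matrix(c(5, 21, 1, 16), 2,
                                       byrow = TRUE))$p_value)
})
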
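test_that("stage means and fold changes follow their definitions", {
  v <- matrix(c(10, 20, 7), 1, dimnames = list("g1", c("m1", "m2", "l1")))
  em <- expression_matrix("sp", v, "TPM")
  des <- stage_design(data.frame(species = "sp", sample = c("m1", "m2", "l1"),
                                 stage = c("MG", "MG", "LG"), replicate = c(1, 2, 1)))
  m <- stage_means(em, des, stages = c("MG", "LG"))
  expect_equal(unname(m["g1", ]), c(15, 7))  # mean of 10,20; single 7
  expect_error(stage_means(em, des, stages = "NP"), "0 samples")

  expect_equal(unname(fold_change(c(MG = 5, LG = 10), pseudocount = 0)), 2)
  expect_equal(unname(fold_change(c(MG = 0, LG = 0), pseudocount = 1)), 1)
  expect_equal(unname(fold_change(c(MG = 0, LG = 99), pseudocount = 1)), 100)
  expect_true(is.na(fold_change(c(MG = 0, LG = 0), pseudocount = 0)))
})

test_that("one-way ANOVA matches its closed-form degenerate conventions", {
  g <- factor(rep(c("a", "b"), each = 3))
  r <- anova_oneway(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- anova_oneway(c(0, 0, 0, 10, 10, 10), g)  # perfect separation
  expect_equal(r$statistic, Inf)
  expect_equal(r$p_value, 0)

  r <- anova_oneway(rep(5, 6), g)  # zero total variance
  expect_true(is.na(r$p_value))

  # singleton group is allowed (classical fixed-effects ANOVA)
  r <- anova_oneway(c(1, 2, 3, 9), factor(c("a", "a", "a", "b")))
  expect_true(is.finite(r$statistic) && r$p_value > 0)
})

test_that("ANOVA with two groups equals the squared pooled t-test", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(4 + i %% 3); y <- rnorm(5, mean = 0.5)
    a <- anova_oneway(c(x, y), factor(rep(c("x", "y"), c(length(x), length(y)))))
    t <- t_test(x, y, tails = 2)
    expect_equal(a$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(a$p_value, t$p_value, tolerance = 1e-10)
  }
})

test_that("Student t-test matches the closed form and halves one-tailed", {
  r <- t_test(c(1, 2, 3), c(4, 5, 6), tails = 2)
  # pooled sd = 1, se = sqrt(2/3)
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(r$p_value, 0.02131164, tolerance = 1e-6)

  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(3); y <- rnorm(4)
    two <- t_test(x, y, tails = 2)
    match_dir <- if (mean(x) > mean(y)) "greater" else "less"
    one <- t_test(x, y, tails = 1, alternative = match_dir)
    expect_equal(one$p_value, two$p_value / 2, tolerance = 1e-12)
  }

  idn <- t_test(c(1, 1), c(1, 1), tails = 2)
  expect_equal(idn$statistic, 0)
  expect_equal(idn$p_value, 1)
  expect_true(is.na(t_test(c(1), c(1, 2), tails = 2)$p_value))
})

test_that("Kruskal-Wallis matches the rank formula and is monotone-invariant", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  r <- kruskal_wallis(v, g)
  # H = 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1), rank sums 6/15/24
  expect_equal(r$statistic, 12 / 90 * (36 + 225 + 576) / 3 - 30)
  expect_equal(r$statistic, 7.2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  set.seed(9)
  v2 <- rlnorm(12); g2 <- factor(rep(1:3, 4))
  expect_equal(kruskal_wallis(v2, g2)$statistic,
               kruskal_wallis(sqrt(v2), g2)$statistic)
  expect_equal(kruskal_wallis(v2, g2)$statistic,
               kruskal_wallis(log(v2 + 1), g2)$statistic)

  tied <- kruskal_wallis(rep(3, 6), factor(rep(c("a", "b"), 3)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
})

test_that("ANOVA is scale-sensitive where Kruskal-Wallis is not", {
  set.seed(31)
  v <- rlnorm(9, log(50), 1); g <- factor(rep(c("a", "b", "c"), each = 3))
  expect_false(isTRUE(all.equal(anova_oneway(v, g)$p_value,
                                anova_oneway(sqrt(v), g)$p_value)))
  expect_equal(kruskal_wallis(v, g)$p_value, kruskal_wallis(sqrt(v), g)$p_value)
})

test_that("presence calls use strict thresholds per rule", {
  v <- matrix(c(0.5, 3.2, 0.9, 0.9, 5, 5), 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  em <- expression_matrix("sp", v, "TPM")
  any3 <- call_expressed(em, threshold = 3, rule = "ANY_SAMPLE")
  expect_true(any3[["g1"]])            # 3.2 > 3 in one sample
  expect_false(call_expressed(em, 1, "ANY_SAMPLE")[["g2"]])  # 0.9 never above 1
  expect_true(all(call_expressed(em, 0, "ANY_SAMPLE")))
  all3 <- call_expressed(em, 3, "ALL_SAMPLES")
  expect_equal(unname(all3), c(FALSE, FALSE, TRUE))
  # boundary is strict: exactly at threshold is not "above"
  em2 <- expression_matrix("sp", matrix(3, 1, 1, dimnames = list("g", "s")), "TPM")
  expect_false(call_expressed(em2, 3, "ANY_SAMPLE")[["g"]])
})

test_that("direction calls combine fold change and uncorrected p", {
  expect_equal(call_direction(2.0, 0.01)$direction, "UP")
  expect_equal(call_direction(0.5, 0.20)$direction, "UNCHANGED")
  expect_equal(call_direction(0.5, 0.01)$direction, "DOWN")
  expect_equal(call_direction(1.4, 1e-9)$direction, "UNCHANGED")  # fc gate

  fb <- call_direction(3.0, NA_real_, fc_only_fallback = TRUE)
  expect_equal(fb$direction, "UP")
  expect_true(fb$unsupported_by_test)
  expect_equal(call_direction(3.0, NA_real_, fc_only_fallback = FALSE)$direction,
               "UNTESTABLE")

  expect_error(call_direction(2, 0.01, alpha = 1.5), "alpha")
  expect_error(call_direction(2, 0.01, fc_min = 0.9), "fc_min")
})

test_that("de_table handles a single-replicate stage per configuration", {
  set.seed(88)
  v <- matrix(rlnorm(7 * 20, log(50), 0.2), 20, 7,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:7)))
  v[1, 7] <- v[1, 7] * 4  # the single LG sample, up 4x
  em <- expression_matrix("arm", v, "TPM")
  des <- stage_design(data.frame(
    species = "arm", sample = paste0("s", 1:7),
    stage = c("NP", "NP", "NP", "MG", "MG", "MG", "LG"),
    replicate = c(1:3, 1:3, 1)))
  # ANOVA tolerates the singleton LG group
  de_a <- de_table(em, des, test = "anova")
  expect_true(all(!is.na(de_a$p_value)))
  # a two-group contrast test cannot run against a singleton group:
  # fold-change-only fallback, flagged
  de_t <- de_table(em, des, test = "t_two_tailed", fc_only_fallback = TRUE)
  expect_true(all(is.na(de_t$p_value)))
  expect_true(all(de_t$unsupported_by_test))
  expect_equal(de_t$direction[1], "UP")
  de_u <- de_table(em, des, test = "t_two_tailed", fc_only_fallback = FALSE)
  expect_true(all(de_u$direction == "UNTESTABLE"))
})
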
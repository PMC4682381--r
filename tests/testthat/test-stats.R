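# Rank-sum testing, BH q-values and the class-comparison report.

test_that("identical samples give p = 1", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 5))$p_value, 1)
})

test_that("fully separated tiny samples match the enumeration value", {
  res <- rank_sum_test(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(res$p_value, 2 / choose(4, 2))
  expect_equal(res$U, 0)
})

test_that("the exact test equals exhaustive enumeration, with ties", {
  set.seed(5)
  for (i in 1:12) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:5, na, replace = TRUE)   # heavy ties
    b <- sample(2:7, nb, replace = TRUE)
    got <- rank_sum_test(a, b, mode = "exact")$p_value
    expect_equal(got, enumerate_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("the exact test agrees with the reference implementation", {
  set.seed(6)
  for (i in 1:8) {
    a <- rnorm(6); b <- rnorm(7) + 0.5   # continuous: no ties
    got <- rank_sum_test(a, b, mode = "exact")
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$U, unname(ref$statistic))
  }
})

test_that("the normal approximation tracks the reference with ties", {
  set.seed(7)
  for (i in 1:6) {
    a <- sample(1:8, 25, replace = TRUE)
    b <- sample(3:10, 30, replace = TRUE)
    got <- rank_sum_test(a, b, mode = "normal_approx")$p_value
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("exact mode refuses oversize samples; auto switches modes", {
  expect_error(rank_sum_test(rnorm(20), rnorm(20), mode = "exact"),
               "at most 30")
  expect_equal(rank_sum_test(rnorm(20), rnorm(20))$method,
               "normal_approx")
  expect_equal(rank_sum_test(rnorm(5), rnorm(5))$method, "exact")
})

test_that("BH q-values match the hand computation and its bounds", {
  expect_equal(bh_qvalues(0.04), 0.04)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  set.seed(9)
  p <- runif(20)
  q <- bh_qvalues(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
  # monotone in p-order
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_length(bh_qvalues(numeric(0)), 0)
})

null_features <- function(n_per_class, seed) {
  set.seed(seed)
  data.frame(class_label = rep(c("A", "B"), each = n_per_class),
             interface_area = rnorm(2 * n_per_class, 1000, 200),
             polarity_abundance = rnorm(2 * n_per_class, 0, 15),
             delta_iG = rnorm(2 * n_per_class, -10, 4))
}

test_that("a planted 40-point abundance shift is detected with power", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    fe <- data.frame(class_label = rep(c("A", "B"), each = 30),
                     polarity_abundance = c(rnorm(30, -30, 10),
                                            rnorm(30, 10, 10)))
    rep_ <- compare_classes(fe, feature_cols = "polarity_abundance")
    if (rep_$tests$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("identical feature columns give p = q = 1", {
  fe <- data.frame(class_label = rep(c("A", "B"), each = 5),
                   interface_area = rep(1:5, 2),
                   delta_iG = rep(c(2, 3, 4, 5, 6), 2))
  rep_ <- compare_classes(fe)
  expect_true(all(rep_$tests$p_value == 1))
  expect_true(all(rep_$tests$q_value == 1))
})

test_that("the report is invariant to row order and filters labels", {
  fe <- null_features(12, 3)
  fe$hbonds <- rpois(24, 10)
  fe$binding_energy <- rnorm(24, -20, 5)
  fe2 <- fe[sample(nrow(fe)), ]
  r1 <- compare_classes(fe)
  r2 <- compare_classes(fe2)
  expect_equal(r1$tests, r2$tests)
  expect_equal(r1$correlations, r2$correlations)
  # tie-labelled rows are excluded
  fe3 <- rbind(fe, data.frame(class_label = "tie", interface_area = 1e6,
                              polarity_abundance = 100, delta_iG = 50,
                              hbonds = 100, binding_energy = 100))
  expect_equal(compare_classes(fe3)$tests, r1$tests)
})

test_that("undersized classes fail with the class named", {
  fe <- data.frame(class_label = c("A", "A", "B"),
                   interface_area = 1:3)
  expect_error(compare_classes(fe), "class B")
})

test_that("the canonical correlation pairs are reported by group", {
  fe <- null_features(15, 4)
  fe$hbonds <- round(fe$interface_area / 100) + rpois(30, 2)
  fe$binding_energy <- -fe$interface_area / 50 + rnorm(30)
  fe$salt_bridges <- rpois(30, 5)
  rep_ <- compare_classes(fe)
  expect_setequal(unique(rep_$correlations$group), c("all", "A", "B"))
  r_be <- rep_$correlations$r[
    rep_$correlations$pair == "binding_energy vs interface_area" &
      rep_$correlations$group == "all"]
  expect_lt(r_be, -0.8)
})
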
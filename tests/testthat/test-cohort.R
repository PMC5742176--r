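test_that("bundled cohort loads and matches known entries", {
  tab <- load_cohort()
  expect_s3_class(tab, "cohort")
  expect_equal(nrow(tab), 24)
  r7 <- tab[tab$id == 7, ]
  expect_equal(r7$rest_alpha, 1.29)
  expect_equal(r7$iq_score, 7)
})

test_that("malformed cohort tables are rejected", {
  td <- withr::local_tempdir()
  dup <- file.path(td, "dup.csv")
  writeLines(c("id,rest_br,rest_alpha,iq_br,iq_alpha,iq_score",
               "1,10,0.5,10,0.5,3", "1,12,0.6,11,0.4,5"), dup)
  expect_error(load_cohort(dup), "duplicate")
  mis <- file.path(td, "mis.csv")
  writeLines(c("id,rest_br,iq_br,iq_alpha,iq_score", "1,10,10,0.5,3"), mis)
  expect_error(load_cohort(mis), "rest_alpha")
  bad <- file.path(td, "bad.csv")
  writeLines(c("id,rest_br,rest_alpha,iq_br,iq_alpha,iq_score",
               "1,10,x,10,0.5,3"), bad)
  expect_error(load_cohort(bad), "non-numeric")
})

test_that("median split uses a strict-greater rule", {
  tab <- load_cohort()
  sp <- median_split(tab)
  expect_equal(sp$threshold, 4)
  expect_length(sp$high, 9)
  expect_length(sp$low, 15)
  # partition property
  expect_setequal(c(sp$high, sp$low), tab$id)
  expect_length(intersect(sp$high, sp$low), 0)

  allsame <- data.frame(id = 1:5, iq_score = rep(3, 5))
  expect_length(median_split(allsame)$high, 0)

  small <- data.frame(id = 1:5, iq_score = 1:5)
  sp2 <- median_split(small)
  expect_equal(sp2$threshold, 3)
  expect_equal(sort(sp2$high), c(4, 5))
})

test_that("one-way ANOVA equals the squared pooled t and is symmetric", {
  set.seed(44)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = 0.5)
    res <- one_way_anova(a, b)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    expect_equal(res$df, c(1, length(a) + length(b) - 2))
    swapped <- one_way_anova(b, a)
    expect_equal(res$F, swapped$F, tolerance = 1e-12)
  }
})

test_that("ANOVA hand check and degenerate cases", {
  # groups (1,2,3) and (4,5,6): SSB = 13.5, MSW = 1, F = 13.5
  res <- one_way_anova(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$df, c(1, 4))

  same <- one_way_anova(c(2, 2), c(2, 2))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(one_way_anova(c(2, 2), c(3, 3)), "infinite F")
})

test_that("Pearson correlation matches hand-computed values", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  # product-moment sum by hand: r = -2.5 / sqrt(1 * 7)
  res <- pearson_cor(c(1, 2, 3), c(6, 5, 1))
  expect_equal(res$r, -2.5 / sqrt(7), tolerance = 1e-12)
  expect_lt(abs(res$r - (-0.945)), 0.001)
  expect_equal(res$r_squared, res$r^2, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("correlation is affine-invariant and sign-flips under negation", {
  set.seed(5)
  x <- rnorm(20); y <- x + rnorm(20)
  r0 <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(2 * x + 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(x, 0.5 * y - 1)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("Shapiro-Wilk accepts normal and rejects lognormal samples", {
  pn <- vapply(1:50, function(s) {
    set.seed(s); shapiro_wilk(rnorm(200))$p
  }, numeric(1))
  expect_gte(mean(pn > 0.05), 0.9)
  pl <- vapply(1:50, function(s) {
    set.seed(s); shapiro_wilk(exp(rnorm(200)))$p
  }, numeric(1))
  expect_gte(mean(pl < 0.05), 0.9)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "degenerate")
})

test_that("session summary reproduces the cohort's group cells", {
  tab <- load_cohort()
  s <- session_summary(tab)
  expect_equal(s["overall", "rest_br_mean"], 18.27, tolerance = 0.005)
  expect_equal(s["overall", "rest_br_sd"], 10.44, tolerance = 0.005)
  # per-group cells, all within 0.01 of their 2-decimal values
  cells <- rbind(
    high = c(17.22, 6.01, 0.94, 0.25, 19.07, 8.42, 0.64, 0.10),
    low  = c(18.89, 12.54, 0.72, 0.18, 19.18, 12.72, 0.61, 0.19))
  got <- as.matrix(s[c("high", "low"),
                     c("rest_br_mean", "rest_br_sd", "rest_alpha_mean",
                       "rest_alpha_sd", "iq_br_mean", "iq_br_sd",
                       "iq_alpha_mean", "iq_alpha_sd")])
  expect_true(all(abs(got - cells) <= 0.01))

  one <- tab[1, ]
  class(one) <- c("cohort", "data.frame")
  s1 <- session_summary(one, split = median_split(one))
  expect_true(is.na(s1["overall", "rest_br_sd"]))
})

test_that("session comparison treats the two sessions as groups of n", {
  tab <- load_cohort()
  res <- compare_sessions(tab)
  expect_equal(res$df, c(1, 46))
  self <- compare_sessions(tab, c("rest_alpha", "rest_alpha"))
  expect_equal(self$F, 0, tolerance = 1e-20)
  # 3-subject hand decomposition: rest (1,2,3), task (3,4,5)
  toy <- data.frame(id = 1:3, rest_alpha = c(1, 2, 3), iq_alpha = c(3, 4, 5))
  res2 <- one_way_anova(toy$rest_alpha, toy$iq_alpha)
  # SSB = 6, MSW = 1 -> F = 6 on df (1, 4)
  expect_equal(res2$F, 6, tolerance = 1e-12)
  expect_equal(res2$df, c(1, 4))
})
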
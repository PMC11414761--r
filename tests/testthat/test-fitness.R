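test_that("relative fitness is the ratio of Malthusian parameters", {
  expect_equal(relative_fitness(100, 10000, 100, 10000, dilution = 100), 1)
  expect_equal(relative_fitness(100, 400, 100, 200, dilution = 1), 2)
  # invariant to rescaling all four counts by a common factor
  w1 <- relative_fitness(37, 1200, 41, 350)
  w2 <- relative_fitness(37 * 7, 1200 * 7, 41 * 7, 350 * 7)
  expect_equal(w1, w2)
  # exact algebraic identity: w * m_anc = m_mut
  d <- 100
  m_anc <- log(d * 350 / 41)
  m_mut <- log(d * 1200 / 37)
  expect_equal(w1 * m_anc, m_mut)
})

test_that("uncountable and degenerate assays are hard errors", {
  expect_error(relative_fitness(0, 10, 10, 10), "uncountable")
  expect_error(relative_fitness(10, 10, 10, 0), "uncountable")
  # ancestor exactly undoes the dilution: zero Malthusian parameter
  expect_error(relative_fitness(100, 200, 100, 1, dilution = 100),
               "degenerate denominator")
})

test_that("fitness summaries reproduce hand-computed t statistics", {
  assays <- data.frame(
    genotype = "m", temperature = 42.2, replicate = 1:3, bio_replicate = 1,
    ni_mut = 100, nf_mut = 100 * 100^(c(1.1, 1.2, 1.3) - 1),
    ni_anc = 100, nf_anc = 100, dilution = 100)
  s <- summarize_fitness(assays)
  expect_equal(s$w_bar, 1.2)
  expect_equal(s$t_vs_one, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(s$df, 2)
  expect_equal(s$variance, stats::var(c(1.1, 1.2, 1.3)) / 3)
})

test_that("constant unit fitness gives t = 0, p = 1", {
  assays <- data.frame(
    genotype = "m", temperature = 37, replicate = 1:4, bio_replicate = 1,
    ni_mut = 100, nf_mut = 100, ni_anc = 100, nf_anc = 100, dilution = 100)
  s <- summarize_fitness(assays)
  expect_equal(s$w_bar, 1)
  expect_equal(s$t_vs_one, 0)
  expect_equal(s$p_raw, 1)
})

test_that("Bonferroni adjustment multiplies by the family size and caps", {
  assays <- do.call(rbind, lapply(1:10, function(i) data.frame(
    genotype = paste0("g", i), temperature = 42.2, replicate = 1:3,
    bio_replicate = 1, ni_mut = 100,
    nf_mut = round(100 * 100^(c(1.1, 1.2, 1.3) - 1)) + i,
    ni_anc = 100, nf_anc = 100, dilution = 100)))
  s <- summarize_fitness(assays)
  expect_equal(s$p_bonferroni, pmin(s$p_raw * 10, 1))
  expect_true(all(s$p_bonferroni >= s$p_raw))
  expect_true(all(s$p_bonferroni <= 1))
})

test_that("single-replicate groups get withheld tests", {
  assays <- data.frame(
    genotype = "m", temperature = 42.2, replicate = 1, bio_replicate = 1,
    ni_mut = 100, nf_mut = 250, ni_anc = 100, nf_anc = 100, dilution = 100)
  s <- summarize_fitness(assays)
  expect_true(is.na(s$variance) && is.na(s$t_vs_one) && is.na(s$p_raw))
})

test_that("replicate ANOVA matches the hand-computed table", {
  mk <- function(w, bio) data.frame(
    genotype = "m", temperature = 42.2, replicate = seq_along(w),
    bio_replicate = bio, ni_mut = 100, nf_mut = 100 * 100^(w - 1),
    ni_anc = 100, nf_anc = 100, dilution = 100)
  # w values {1,2,3} vs {4,5,6}: classic one-way ANOVA F = 13.5, df (1, 4)
  assays <- rbind(mk(c(1, 2, 3), "a"), mk(c(4, 5, 6), "b"))
  a <- replicate_anova(assays)
  expect_equal(a$f, 13.5, tolerance = 1e-10)
  expect_equal(c(a$df1, a$df2), c(1, 4))
  # identical replicate means: F = 0
  a0 <- replicate_anova(rbind(mk(c(1.1, 1.2), "a"), mk(c(1.1, 1.2), "b")))
  expect_equal(a0$f, 0, tolerance = 1e-10)
  expect_error(replicate_anova(rbind(mk(c(1, 2), "a"), mk(3, "b"))),
               "biological replicates")
})

test_that("replicate ANOVA holds its type-I error under the null", {
  set.seed(42)
  rej <- replicate(400, {
    w <- 1 + stats::rnorm(8, 0, 0.05)
    assays <- data.frame(
      genotype = "m", temperature = 42.2, replicate = 1:8,
      bio_replicate = rep(c("a", "b"), each = 4), ni_mut = 100,
      nf_mut = 100 * 100^(w - 1), ni_anc = 100, nf_anc = 100, dilution = 100)
    replicate_anova(assays)$p < 0.05
  })
  # 99% binomial bounds around 0.05 for 400 draws
  expect_gt(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 400))
})

test_that("growth fitting recovers exact and logistic growth rates", {
  t <- 0:8
  f1 <- fit_growth(t, 100 * exp(0.6 * t))
  expect_equal(f1$mu_max, 0.6, tolerance = 1e-10)
  expect_equal(f1$r_squared, 1, tolerance = 1e-10)
  f2 <- fit_growth(t, rep(500, 9))
  expect_equal(f2$mu_max, 0)
  # logistic curve: early exponential phase has rate r
  tt <- seq(0, 30, by = 0.25)
  n0 <- 1e3; k <- 1e8; r <- 0.8
  dens <- k / (1 + (k / n0 - 1) * exp(-r * tt))
  f3 <- fit_growth(tt, dens)
  expect_lt(abs(f3$mu_max - r) / r, 0.05)
  expect_equal(f3$final_yield, max(dens))
  expect_error(fit_growth(0:3, exp(0:3)), "at least 5")
  expect_error(fit_growth(0:5, c(1, 2, 3, -1, 5, 6)), "positive")
})

test_that("growth comparisons separate shifted parameter sets", {
  same <- compare_growth(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- compare_growth(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.01)
  expect_error(compare_growth(1, c(1, 2)), ">= 2")
})

test_that("simulated assays recover true fitness within 3 SE almost always", {
  hits <- vapply(1:100, function(seed) {
    sim <- simulate_competition(
      data.frame(genotype = "m", temperature = 42.2, w = 1.2),
      replicates = 10, seed = seed)
    s <- summarize_fitness(sim$assays)
    abs(s$w_bar - 1.2) < 3 * sqrt(s$variance)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
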
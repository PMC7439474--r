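test_that("two-way ANOVA matches hand-computed sums of squares", {
  # 2x2 design, 2 replicates per cell
  y <- c(1, 2, 3, 5, 2, 4, 7, 9)
  a <- rep(c("A1", "A1", "A2", "A2"), each = 2)
  b <- rep(rep(c("B1", "B2"), each = 2), times = 2)
  tab <- twoWayAnova(y, a, b)
  or <- oracle_anova_ss(y, a, b)
  expect_equal(tab["donor", "SumSq"], or$ssA)
  expect_equal(tab["prebiotic", "SumSq"], or$ssB)
  expect_equal(tab["donor:prebiotic", "SumSq"], or$ssAB)
  expect_equal(tab["Residuals", "SumSq"], or$ssRes)
  expect_equal(tab["donor", "F"],
               (or$ssA / 1) / (or$ssRes / 4))
  expect_equal(sum(tab$Df), length(y) - 1)
})

test_that("ANOVA decomposition sums to total SS on random balanced designs", {
  set.seed(5)
  for (rep in 1:5) {
    a <- rep(paste0("a", 1:4), each = 3 * 2)
    b <- rep(rep(paste0("b", 1:3), each = 2), times = 4)
    y <- rnorm(length(a), mean = as.integer(factor(a)))
    tab <- twoWayAnova(y, a, b)
    expect_equal(sum(tab$SumSq), sum((y - mean(y))^2))
    expect_true(all(tab$SumSq >= 0))
  }
})

test_that("additive cell means give zero interaction SS", {
  a <- rep(paste0("a", 1:3), each = 4)
  b <- rep(rep(paste0("b", 1:2), each = 2), times = 3)
  y <- as.integer(factor(a)) * 2 + as.integer(factor(b)) * 5
  tab <- twoWayAnova(y, a, b)
  expect_equal(tab["donor:prebiotic", "SumSq"], 0)
})

test_that("degenerate and unbalanced ANOVA inputs are handled", {
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), times = 2)
  tab <- twoWayAnova(rep(3.3, 8), a, b)
  expect_true(all(tab$SumSq[1:3] == 0))
  expect_true(all(is.nan(tab$F[1:3])))
  expect_equal(tab$p[1:3], rep(1, 3))
  expect_error(twoWayAnova(rnorm(7), a[-1], b[-1]), "unbalanced")
  expect_error(
    twoWayAnova(rnorm(4), c("a1", "a1", "a2", "a2"),
                c("b1", "b2", "b1", "b2")),
    ">= 2 replicates")
})

test_that("Spearman correlation handles monotone, antitone and tied data", {
  x <- c(1, 4, 9, 12, 20)
  expect_equal(spearmanCorrelation(x, x^3 + 2)$rho, 1)
  expect_equal(spearmanCorrelation(x, -sqrt(x))$rho, -1)
  xt <- c(1, 2, 2, 3, 5, 5, 7)
  yt <- c(4, 4, 6, 1, 9, 9, 2)
  expect_equal(spearmanCorrelation(xt, yt)$rho, oracle_rank_pearson(xt, yt))
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(17)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearmanCorrelation(x, y)
  expect_equal(spearmanCorrelation(exp(x), y)$rho, base$rho)
  expect_equal(spearmanCorrelation(x, y^3)$rho, base$rho)
  expect_equal(base$p.value, spearmanCorrelation(exp(x), y^3)$p.value)
})

test_that("Spearman p uses the t approximation with an exact small-n option", {
  set.seed(3)
  x <- rnorm(17); y <- x + rnorm(17)
  res <- spearmanCorrelation(x, y)
  rho <- res$rho; n <- res$n
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  expect_equal(res$p.value, 2 * pt(-abs(tstat), df = n - 2))
  small <- spearmanCorrelation(rnorm(8), rnorm(8))
  expect_identical(small$method, "exact permutation")
})

test_that("Shannon diversity follows the entropy formula in nats", {
  expect_equal(shannonDiversity(c(0, 5, 0)), 0)
  expect_equal(shannonDiversity(rep(2, 7)), log(7))
  expect_equal(shannonDiversity(c(1, 1, 2)), oracle_shannon(c(1, 1, 2)))
  set.seed(2)
  cts <- rpois(30, 8)
  expect_equal(shannonDiversity(cts), oracle_shannon(cts))
  expect_error(shannonDiversity(c(0, 0)), "all-zero")
})

test_that("paired t test matches the difference-based formula", {
  pre <- c(2.1, 3.0, 2.7, 3.5)
  expect_equal(pairedT(pre, pre), list(t = 0, p.value = 1, df = 3,
                                       meanDifference = 0))
  set.seed(6)
  post <- pre + 0.8 + rnorm(4, 0, 0.2)
  res <- pairedT(pre, post)
  or <- oracle_paired_t(pre, post)
  expect_equal(res$t, or$t)
  expect_equal(res$p.value, or$p)
  expect_error(pairedT(1, 2), "at least 2")
  expect_error(pairedT(c(1, 2), c(2, 3)), "zero-variance")
})

test_that("differential abundance applies BH-corrected rank-sum tests", {
  set.seed(13)
  m <- matrix(rpois(60, 20), nrow = 6,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  # identical groups: every adjusted p is 1, nothing called
  res <- differentialAbundance(m, m)
  expect_true(all(res$p.adjusted == 1))
  expect_false(any(res$significant))
  # BH adjustment equals the step-up formula and never decreases p
  g2 <- m; g2[1, ] <- g2[1, ] + 60  # strong shift in taxon 1
  res2 <- differentialAbundance(m, g2)
  expect_equal(res2$p.adjusted, oracle_bh(res2$p.value))
  expect_true(all(res2$p.adjusted >= res2$p.value))
  expect_true(all(res2$p.adjusted <= 1))
})

test_that("BH step-up oracle examples hold", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  # a taxon constant across both groups carries no evidence (p = 1)
  a <- matrix(c(5, 5, 5, 10, 20, 30), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "var"), paste0("s", 1:3)))
  b <- matrix(c(7, 7, 7, 14, 50, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "var"), paste0("u", 1:3)))
  # make 'flat' constant on the relative-abundance scale
  a["flat", ] <- a["var", ]
  b["flat", ] <- b["var", ]
  res <- differentialAbundance(a, b)
  expect_equal(res$p.value[res$taxon == "flat"], 1)
})
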
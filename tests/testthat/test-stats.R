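# independent brute-force step-up oracle for BH
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- running
  }
  pmin(adj, 1)
}

test_that("standardized beta behaves at the identity and under the null", {
  d <- data.frame(y = rnorm(100, 10, 3))
  d$x <- d$y
  sb <- suppressWarnings(standardized_beta("y", "x", data = d))
  expect_equal(sb$beta, 1, tolerance = 1e-12)
  expect_lt(sb$p, 1e-12)

  set.seed(8)
  ps <- replicate(60, {
    d <- data.frame(y = rnorm(120), x = rnorm(120), a = rnorm(120))
    standardized_beta("y", "x", "a", d)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  expect_error(standardized_beta("y", "x", data = data.frame(y = 1:20,
                                                             x = rep(1, 20))),
               "constant")
  d2 <- data.frame(y = rnorm(30), x = rnorm(30))
  d2$z <- d2$x
  expect_error(standardized_beta("y", "x", "z", d2), "rank")
})

test_that("planted standardized slopes are recovered on average", {
  set.seed(12)
  est <- replicate(60, {
    n <- 200
    x <- rnorm(n)
    y <- 0.4 * x + sqrt(1 - 0.16) * rnorm(n)
    standardized_beta("y", "x", data = data.frame(x = x, y = y))$beta
  })
  expect_lt(abs(mean(est) - 0.4), 0.02)
})

test_that("BH adjustment matches the hand-run example and a brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("ANCOVA reduces to one-way ANOVA and the squared t-test", {
  set.seed(5)
  d <- data.frame(y = rnorm(60), g = rep(c("a", "b", "c"), each = 20),
                  cv = rnorm(60))
  a <- ancova("y", "g", character(), d)
  ref <- stats::anova(stats::aov(y ~ g, data = d))
  expect_equal(a$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(a$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  d2 <- d[d$g != "c", ]
  a2 <- ancova("y", "g", character(), d2)
  tt <- stats::t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)

  # covariate adjustment matches the nested-model comparison by lm
  a3 <- ancova("y", "g", "cv", d)
  full <- stats::lm(y ~ cv + g, d); red <- stats::lm(y ~ cv, d)
  av <- stats::anova(red, full)
  expect_equal(a3$F, av$F[2], tolerance = 1e-10)
  expect_error(ancova("y", "g", character(), d[d$g == "a", ]), "two groups")
})

test_that("ANCOVA detects a planted group offset with high power", {
  set.seed(99)
  hits <- replicate(40, {
    d <- data.frame(g = rep(c("CN", "MCI"), each = 50), cv = rnorm(100))
    d$y <- (d$g == "MCI") * 1.0 + 0.3 * d$cv + rnorm(100)
    ancova("y", "g", "cv", d)$p < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("Tukey HSD equals the pooled t-test at k = 2 and saturates at 1", {
  set.seed(6)
  d <- data.frame(y = rnorm(40), g = rep(c("a", "b"), each = 20))
  a <- ancova("y", "g", character(), d)
  tk <- tukey_hsd(a)
  tt <- stats::t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)

  d$y2 <- rep(stats::rnorm(20), 2)                 # identical group samples
  tk2 <- tukey_hsd(ancova("y2", "g", character(), d))
  expect_gt(tk2$p_adj, 0.999)

  # three groups, one shifted: only its two pairs light up
  set.seed(61)
  d3 <- data.frame(g = rep(c("a", "b", "c"), each = 60))
  d3$y <- (d3$g == "c") * 1.2 + rnorm(180)
  tk3 <- tukey_hsd(ancova("y", "g", character(), d3))
  sig <- tk3$p_adj < 0.05
  expect_equal(sig, grepl("c", tk3$pair))
})

test_that("rank-ANCOVA is invariant to monotone transforms; Wilcoxon is exact", {
  set.seed(7)
  d <- data.frame(y = rexp(90), g = rep(c("a", "b", "c"), each = 30),
                  cv = rnorm(90))
  r1 <- rank_ancova_wilcoxon("y", "g", "cv", d)
  d$y <- log(d$y)                                   # monotone transform
  r2 <- rank_ancova_wilcoxon("y", "g", "cv", d)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)

  w <- stats::wilcox.test(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                          exact = TRUE)
  expect_equal(w$p.value, 0.05)                     # 1 of the 20 assignments
  dd <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  rw <- rank_ancova_wilcoxon("y", "g", character(), dd)
  expect_equal(rw$pairwise$p, 0.1)                  # two-sided exact
})

test_that("MAP and amyloid positivity follow their defining rules", {
  expect_equal(derive_map(120, 80), 280 / 3, tolerance = 1e-12)
  expect_equal(round(derive_map(120, 80), 2), 93.33)
  expect_equal(derive_map(100, 100), 100)
  # linearity
  s <- c(110, 130); dbp <- c(70, 90)
  expect_equal(mean(derive_map(s, dbp)), derive_map(mean(s), mean(dbp)))
  expect_error(derive_map(-1, 80), "positive")

  expect_false(amyloid_positivity(1.478, "FBB"))   # strict inequality
  expect_true(amyloid_positivity(1.50, "FBB"))
  expect_true(amyloid_positivity(1.20, "AV45"))
  expect_false(amyloid_positivity(1.11, "AV45"))
  expect_error(amyloid_positivity(1.2, "PIB"), "tracer")
})
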
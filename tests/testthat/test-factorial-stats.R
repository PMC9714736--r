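test_that("alignment reproduces hand-computed cell-mean algebra on a 2x2", {
  fd <- factorial_dataset(c(1, 2, 3, 4),
                          temperature = c("a1", "a1", "a2", "a2"),
                          ph = c("b1", "b2", "b1", "b2"))
  expect_equal(art_align(fd, "A"), c(-1, -1, 1, 1))
  expect_equal(art_align(fd, "B"), c(-0.5, 0.5, -0.5, 0.5))
  expect_equal(art_align(fd, "AB"), c(0, 0, 0, 0))
})

test_that("aligned responses always sum to zero", {
  withr::with_seed(81, {
    for (i in 1:20) {
      fd <- gen_factorial(seed = 200 + i, n_per_cell = sample(2:5, 1),
                          temp_eff = rnorm(3, 0, 2), ph_eff = rnorm(3, 0, 2),
                          inter = rnorm(1), sd = runif(1, 0.5, 3))
      for (ef in c("A", "B", "AB"))
        expect_lt(abs(sum(art_align(fd, ef))), 1e-8)
    }
  })
})

test_that("aligning for B removes a pure A effect from the B cell means", {
  fd <- gen_factorial(seed = 1, temp_eff = c(-3, 0, 3), sd = 0)
  alB <- art_align(fd, "B")
  bmeans <- tapply(alB, fd$ph, mean)
  expect_lt(diff(range(bmeans)), 1e-12)
})

test_that("stripped effects vanish on noiseless single-effect constructions", {
  fd <- gen_factorial(seed = 2, temp_eff = c(-2, 0, 2), sd = 0.0)
  res <- art_anova(gen_factorial(seed = 2, temp_eff = c(-2, 0, 2), sd = 0.3))
  for (d in res$diagnostics) expect_lt(abs(d$aligned_sum), 1e-8)
  # noiseless: non-target effects on the A-aligned ranks are ~0
  al <- rank(art_align(fd, "A"))
  sums <- tapply(al, fd$ph, mean)
  expect_lt(diff(range(sums)), 1e-8)
})

test_that("a strong main effect is detected with a large F", {
  res <- art_anova(gen_factorial(seed = 3, temp_eff = c(-6, 0, 6), sd = 1))
  row <- res$anova[res$anova$effect == "temperature", ]
  expect_gt(row$F, 20)
  expect_lt(row$p_value, 0.001)
  expect_equal(row$df1, 2)
  expect_equal(row$df2, 18)  # 27 observations - 9 cells
  expect_true(all(res$anova$partial_eta_sq >= 0 &
                    res$anova$partial_eta_sq <= 1))
})

test_that("single-factor reduction equals one-way ANOVA on raw ranks", {
  withr::with_seed(91, {
    for (i in 1:5) {
      y <- rnorm(15)
      a <- rep(c("t1", "t2", "t3"), each = 5)
      fd <- factorial_dataset(y, a, rep("b1", 15))
      res <- art_anova(fd)
      expect_equal(nrow(res$anova), 1)
      av <- summary(stats::aov(rank(y) ~ factor(a)))[[1]]
      expect_equal(res$anova$F[1], av[["F value"]][1], tolerance = 1e-10)
      expect_equal(res$anova$df1[1], av[["Df"]][1])
      expect_equal(res$anova$df2[1], av[["Df"]][2])
    }
  })
})

test_that("ART F statistics agree with aov run on the ranked aligned data", {
  fd <- gen_factorial(seed = 5, temp_eff = c(-1, 0, 1), ph_eff = c(1, 0, -1),
                      inter = 0.5, sd = 1)
  res <- art_anova(fd)
  for (ef in c("A", "B", "AB")) {
    r <- rank(art_align(fd, ef))
    av <- summary(stats::aov(r ~ temperature * ph, data = fd))[[1]]
    lab <- switch(ef, A = "temperature", B = "ph", AB = "temperature:ph")
    i <- match(lab, trimws(rownames(av)))
    expect_equal(res$anova$F[res$anova$effect == lab], av[["F value"]][i],
                 tolerance = 1e-10)
  }
})

test_that("ranks used per effect are a midrank permutation of 1..N", {
  fd <- gen_factorial(seed = 7, sd = 1)
  for (ef in c("A", "B", "AB")) {
    r <- rank(art_align(fd, ef))
    expect_equal(sum(r), nrow(fd) * (nrow(fd) + 1) / 2)
  }
})

test_that("empty cells and unbalanced designs are rejected", {
  expect_error(factorial_dataset(1:4, c("a", "a", "b", "b"),
                                 c("x", "x", "x", "x")),
               NA)  # single pH level is allowed in the container
  expect_error(factorial_dataset(1:3, c("a", "a", "b"), c("x", "y", "x")),
               "empty cell")
  unb <- factorial_dataset(1:10, rep(c("a", "b"), c(6, 4)),
                           rep(c("x", "y"), 5))
  expect_error(art_anova(unb), "balanced")
})

test_that("partial eta squared follows its definition", {
  expect_equal(partial_eta_squared(3, 9), 0.25)
  expect_equal(partial_eta_squared(5, 0), 1)
  expect_equal(partial_eta_squared(0, 4), 0)
  expect_error(partial_eta_squared(0, 0), "undefined")
})

test_that("Cohen's d matches hand computation and its symmetries", {
  d <- cohens_d(c(1, 2, 3), c(3, 4, 5))
  expect_equal(d$d, -2)  # pooled SD 1
  expect_equal(d$magnitude, "huge")
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3))$d, 2)  # antisymmetry
  same <- cohens_d(c(1, 2, 3), c(2, 3, 1))
  expect_equal(same$d, 0)
  expect_equal(cohens_d(c(0, 1), c(10, 11.5))$magnitude, "huge")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled standard deviation")
})

test_that("pairwise posthoc has m contrasts with Bonferroni inflation", {
  fd <- gen_factorial(seed = 11, temp_eff = c(-2, 0, 2), sd = 1)
  ph <- bonferroni_pairwise(fd, "temperature")
  expect_equal(nrow(ph), 3)  # choose(3, 2)
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-15))
  expect_true(all(ph$p_adj <= 1))
  expect_true(all(ph$p_adj <= pmin(1, 3 * ph$p_raw) + 1e-15))
  expect_true(all(ph$magnitude %in% c("negligible", "very small", "small",
                                      "medium", "large", "very large",
                                      "huge")))
})

test_that("posthoc familywise error under the null stays near nominal", {
  alpha <- 0.05
  hits <- withr::with_seed(13, vapply(1:400, function(i) {
    fd <- gen_factorial(seed = 3000 + i, sd = 1)
    any(bonferroni_pairwise(fd, "ph")$p_adj < alpha)
  }, logical(1)))
  # Bonferroni guarantees FWER <= alpha; allow Monte-Carlo slack upward
  expect_lt(mean(hits), alpha + 2.5 * sqrt(alpha * (1 - alpha) / 400))
})

test_that("Spearman correlation matches midrank computation and cor.test", {
  expect_equal(spearman_rho(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 6, 9)
  s <- spearman_rho(x, y)
  expect_equal(s$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})
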
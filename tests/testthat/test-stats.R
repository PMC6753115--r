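# textbook-formula oracles, written out longhand and independent of the
# implementation path
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  c(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}
oracle_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  c(X2 = x2, p = pchisq(x2, (nrow(tab) - 1) * (ncol(tab) - 1),
                        lower.tail = FALSE))
}
oracle_bh <- function(p, q) {
  m <- length(p); ord <- order(p); ps <- p[ord]
  reject <- rep(FALSE, m)
  for (i in seq_len(m))        # step-up from the largest index
    if (any(ps[i:m] <= (i:m) * q / m)) reject[ord[i]] <- TRUE
  reject
}

test_that("one-way ANOVA matches the between/within decomposition and t^2", {
  set.seed(51)
  for (r in 1:20) {
    k <- sample(2:5, 1)
    g <- rep(seq_len(k), times = sample(3:9, k, replace = TRUE))
    y <- rnorm(length(g), mean = g * runif(1, 0, 2))
    got <- anova_oneway(y, g)
    exp <- oracle_anova(y, g)
    expect_equal(got$F, unname(exp["F"]), tolerance = 1e-10)
    expect_equal(got$p, unname(exp["p"]), tolerance = 1e-10)
  }
  # two groups: F = t^2 for the pooled-variance t statistic
  a <- rnorm(12); b <- rnorm(15, 0.5)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(anova_oneway(c(a, b), rep(1:2, c(12, 15)))$F,
               unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(anova_oneway(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))$F, 0)
  expect_error(anova_oneway(c(1, 2, 3), c(1, 1, 2)), "at least two")
})

test_that("Tukey HSD is conservative and matches a studentized-range oracle", {
  set.seed(52)
  g <- rep(1:3, each = 8)
  y <- rnorm(24, mean = g)
  tk <- tukey_hsd(y, g)
  expect_identical(nrow(tk), 3L)
  mse <- sum(tapply(y, g, function(x) sum((x - mean(x))^2))) / (24 - 3)
  means <- tapply(y, g, mean)
  for (r in seq_len(nrow(tk))) {
    i <- as.integer(tk$group1[r]); j <- as.integer(tk$group2[r])
    # adjusted p >= the unadjusted pooled-MSE pairwise t-test p
    tstat <- abs(means[i] - means[j]) / sqrt(mse * (1 / 8 + 1 / 8))
    raw <- 2 * pt(tstat, 21, lower.tail = FALSE)
    expect_gte(tk$p_adj[r] + 1e-12, raw)
    # direct studentized-range evaluation (Tukey-Kramer form)
    q <- unname(abs(means[i] - means[j])) / sqrt(mse / 2 * (1 / 8 + 1 / 8))
    expect_equal(tk$p_adj[r], ptukey(q, 3, 21, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  # identical groups: all adjusted p approach 1
  expect_true(all(tukey_hsd(rep(c(1, 2, 3), 3), rep(1:3, each = 3))$p_adj > 0.99))
})

test_that("Cohen's d reproduces the published CH-vs-AD cognitive effect size", {
  # samples constructed to carry the printed MoCA moments exactly
  force_moments <- function(n, m, s) {
    x <- scale(rnorm(n))[, 1]
    m + s * x
  }
  set.seed(53)
  ch <- force_moments(29, 28.0, 1.94)
  ad <- force_moments(12, 17.2, 5.36)
  d <- cohens_d(ch, ad)
  expect_equal(d, oracle_d(ch, ad), tolerance = 1e-12)
  expect_equal(d, 3.29, tolerance = 0.01)
  expect_equal(cohens_d(ad, ch), -d, tolerance = 1e-12)
  expect_identical(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_warning(dd <- cohens_d(c(1, 1, 1), c(1, 1, 1)), "zero pooled SD")
  expect_true(is.na(dd))
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("BH-FDR implements the step-up rule", {
  r <- fdr_bh(rep(0.001, 10), 0.05)
  expect_true(all(r$reject))
  expect_identical(r$critical_index, 10L)
  r2 <- fdr_bh(c(0.01, 0.02, 0.2), 0.05)
  expect_identical(r2$reject, c(TRUE, TRUE, FALSE))
  expect_identical(r2$critical_index, 2L)
  set.seed(54)
  for (i in 1:200) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    r <- fdr_bh(p, q)
    expect_identical(r$reject, oracle_bh(p, q))
    expect_equal(r$p_adj, p.adjust(p, "BH"))
  }
  expect_error(fdr_bh(c(0.1, NA)), "finite")
  expect_error(fdr_bh(c(0.1, 1.2)), "finite and in")
})

test_that("FDR rejections are monotone in q", {
  set.seed(55)
  p <- runif(30)^2
  qs <- c(0.01, 0.05, 0.1, 0.2)
  nrej <- vapply(qs, function(q) sum(fdr_bh(p, q)$reject), 0)
  expect_true(all(diff(nrej) >= 0))
})

test_that("chi-square matches the closed forms and the published sex table is null", {
  # the five-group female/male counts
  sex <- rbind(F = c(17, 37, 11, 4, 6), M = c(12, 29, 11, 4, 6))
  got <- chi_square_counts(sex)
  exp <- oracle_chi2(sex)
  expect_equal(got$X2, unname(exp["X2"]), tolerance = 1e-10)
  expect_equal(got$p, unname(exp["p"]), tolerance = 1e-10)
  expect_equal(got$p, 0.963, tolerance = 0.005)
  # 2x2 closed form (ad - bc)^2 N / (row and column products)
  set.seed(56)
  for (i in 1:20) {
    t2 <- matrix(sample(5:40, 4), 2)
    x2 <- (t2[1, 1] * t2[2, 2] - t2[1, 2] * t2[2, 1])^2 * sum(t2) /
      (prod(rowSums(t2)) * prod(colSums(t2)))
    expect_equal(chi_square_counts(t2)$X2, x2, tolerance = 1e-10)
  }
  prop <- outer(c(30, 70), c(0.2, 0.8)) # perfectly proportional
  expect_equal(chi_square_counts(prop)$X2, 0, tolerance = 1e-10)
  expect_error(chi_square_counts(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("the ANOVA null p-value is uniform", {
  set.seed(57)
  ps <- vapply(1:400, function(i) {
    anova_oneway(rnorm(40), rep(1:4, each = 10))$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the moderation model is calibrated and powered", {
  n_ch <- 29; n_scd <- 66
  g <- factor(rep(c("CH", "SCD"), c(n_ch, n_scd)))
  sim_p <- function(b3) {
    s <- rnorm(n_ch + n_scd)
    z <- 0.2 * (g == "SCD") + 0.1 * s + b3 * s * (g == "SCD") + rnorm(n_ch + n_scd)
    interaction_model(z, g, s)$p
  }
  set.seed(58)
  type1 <- mean(vapply(1:1000, function(i) sim_p(0), 0) < 0.05)
  expect_gt(type1, 0.03); expect_lt(type1, 0.07)
  power <- mean(vapply(1:1000, function(i) sim_p(0.8), 0) < 0.05)
  expect_gt(power, 0.9)
  # constant symptom: interaction dropped and flagged
  res <- interaction_model(rnorm(95), g, rep(2, 95))
  expect_true(res$dropped)
  expect_error(interaction_model(rnorm(20), factor(rep("CH", 20)), rnorm(20)),
               "two levels")
})

test_that("a null 78-region battery rarely yields any BH discovery", {
  set.seed(59)
  any_hit <- vapply(1:100, function(i) {
    p <- vapply(1:78, function(r) {
      anova_oneway(rnorm(40), rep(1:2, each = 20))$p
    }, 0)
    any(fdr_bh(p, 0.05)$reject)
  }, NA)
  expect_lt(mean(any_hit), 0.10)
})

test_that("gradient report emits all pairs and flags only real differences", {
  set.seed(60)
  groups <- factor(rep(c("CH", "SCD", "eMCI", "lMCI", "AD"), each = 12),
                   levels = c("CH", "SCD", "eMCI", "lMCI", "AD"))
  shift <- c(CH = 0, SCD = 0, eMCI = -1.5, lMCI = -2.5, AD = -4)
  scores <- data.frame(subject_id = sprintf("s%02d", 1:60), group = groups,
                       measure = "composite_snipe",
                       z = rnorm(60) + shift[as.character(groups)])
  rep <- gradient_report(scores)
  expect_identical(nrow(rep$pairwise), 10L)
  vr <- rep$vs_reference
  expect_true(vr$star[vr$group == "AD"])
  expect_false(vr$star[vr$group == "SCD"])
  expect_lt(vr$d_vs_ref[vr$group == "AD"], -2)
  expect_error(gradient_report(scores[scores$group != "CH", ]), "reference")
})
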
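# Chi-square homogeneity, ANOVA, Tukey-Kramer, Fop model, delta-RSCU+ tests.

test_that("chi-square homogeneity handles null, scaling and margins", {
  r <- chi2_homogeneity(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  expect_equal(r$df, 1L)

  t1 <- rbind(c(12, 7, 9), c(5, 14, 8))
  r1 <- chi2_homogeneity(t1)
  r2 <- chi2_homogeneity(2 * t1)
  expect_equal(r2$statistic, 2 * r1$statistic, tolerance = 1e-12)
  expect_equal(r1$df, 2L)
  # expected table preserves margins
  expect_equal(rowSums(r1$expected), rowSums(t1))
  expect_equal(colSums(r1$expected), colSums(t1))

  expect_error(chi2_homogeneity(rbind(c(0, 0), c(3, 4))), "zero margin")
  expect_message(chi2_homogeneity(rbind(c(1.5, 2), c(2, 2))), "fractional")
})

test_that("the genotype deleterious-count contrast matches a hand Pearson computation", {
  # polymorphic-site deleterious vs non-deleterious counts per genotype
  del <- c(781, 724, 666)
  tot <- c(4218, 4222, 4233)
  tab <- rbind(deleterious = del, other = tot - del)
  r <- suppressMessages(chi2_homogeneity(tab))
  # independent computation straight from the Pearson formula
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_lt(r$p.value, 0.05)
})

test_that("one-way ANOVA F equals the squared pooled-variance t for two groups", {
  set.seed(5)
  for (i in 1:20) {
    g <- list(a = rnorm(sample(4:12, 1)), b = rnorm(sample(4:12, 1), mean = 0.5))
    r <- anova_one_way(g)
    tt <- t.test(g$a, g$b, var.equal = TRUE)
    expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p.value, tt$p.value, tolerance = 1e-10)
  }
  # identical groups -> F = 0
  r0 <- anova_one_way(list(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(r0$statistic, 0)
  # degenerate separation -> F flagged infinite, p -> 0
  rd <- anova_one_way(list(a = c(0, 0), b = c(1, 1)))
  expect_true(rd$degenerate)
  expect_equal(rd$statistic, Inf)
  expect_equal(rd$p.value, 0)
  # textbook sums of squares on three small groups
  g3 <- list(a = c(1, 2), b = c(2, 3), c = c(6, 7))
  gm <- mean(unlist(g3))
  ss_b <- sum(vapply(g3, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ss_w <- sum(vapply(g3, function(v) sum((v - mean(v))^2), numeric(1)))
  expect_equal(
    anova_one_way(g3)$statistic, (ss_b / 2) / (ss_w / 3),
    tolerance = 1e-12
  )
  expect_error(anova_one_way(list(a = 1:3)), "2 groups")
  expect_error(anova_one_way(list(a = 1:3, b = numeric(0))), "at least one value")
})

test_that("Tukey-Kramer agrees with the studentized-range formula", {
  set.seed(9)
  groups <- list(a = rnorm(6), b = rnorm(8, 2), c = rnorm(5, 2.2))
  tk <- tukey_kramer(groups)
  # independent recomputation via ptukey with the Tukey-Kramer SE
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    (sum(n) - 3)
  for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    d <- m[pair[1]] - m[pair[2]]
    se <- sqrt(mse / 2 * (1 / n[pair[1]] + 1 / n[pair[2]]))
    p <- 1 - ptukey(abs(d) / se, nmeans = 3, df = sum(n) - 3)
    row <- tk[tk$pair == paste(pair[1], pair[2], sep = "-"), ]
    expect_equal(row$diff, unname(d), tolerance = 1e-10)
    expect_equal(row$p_adj, unname(p), tolerance = 1e-8)
  }
  # identical groups -> nothing significant; separated -> significant
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_false(any(tukey_kramer(same)$significant))
  far <- list(a = rnorm(6), b = rnorm(6, 50))
  expect_true(all(tukey_kramer(far)$significant))
})

test_that("chi-square test maintains its nominal size on multinomial nulls", {
  set.seed(12)
  n_rej <- 0L
  n_sim <- 10000L
  draws_a <- stats::rmultinom(n_sim, 80, c(0.5, 0.3, 0.2))
  draws_b <- stats::rmultinom(n_sim, 120, c(0.5, 0.3, 0.2))
  for (i in seq_len(n_sim)) {
    tab <- rbind(draws_a[, i], draws_b[, i])
    if (any(colSums(tab) == 0)) next
    if (chi2_homogeneity(tab)$p.value < 0.05) n_rej <- n_rej + 1L
  }
  expect_gte(n_rej / n_sim, 0.03)
  expect_lte(n_rej / n_sim, 0.07)
})

sim_fop_data <- function(n_per = 120, mating_effect = 0, gc3s_effect = 1,
                         noise = 0.05) {
  genotypes <- c("bz", "jm", "nc", "px")
  mating <- c(bz = "outcrossing", jm = "selfing", nc = "selfing", px = "selfing")
  df <- do.call(rbind, lapply(genotypes, function(g) {
    gc <- runif(n_per, 0.3, 0.7)
    data.frame(
      genotype = g, mating_system = mating[[g]],
      gc3s = gc, length_bp = sample(300:1500, n_per, TRUE),
      expression = rlnorm(n_per, 3, 1),
      fop = 0.1 + gc3s_effect * 0.5 * gc +
        ifelse(mating[[g]] == "selfing", -mating_effect, 0) +
        rnorm(n_per, 0, noise)
    )
  }))
  df
}

test_that("backward elimination keeps planted signals and drops noise terms", {
  set.seed(31)
  df <- sim_fop_data(gc3s_effect = 1, mating_effect = 0)
  m <- fop_model(df, "genotype")
  expect_true("gc3s" %in% m$retained)
  expect_false(any(grepl("genotype", m$retained)))
  expect_gt(m$anova$var_explained[m$anova$term == "gc3s"], 0.5)

  # pure-noise response: R^2 stays near zero, nothing strongly retained
  df2 <- df
  df2$fop <- rnorm(nrow(df2), 0.4, 0.05)
  m2 <- fop_model(df2, "genotype")
  expect_lt(m2$r_squared, 0.05)

  # determinism of the elimination path
  m3 <- fop_model(df, "genotype")
  expect_identical(m$retained, m3$retained)
  expect_identical(m$eliminated, m3$eliminated)
})

test_that("a planted mating-system effect is recovered with the right sign", {
  set.seed(77)
  hits <- 0L
  n_rep <- 25L
  for (i in seq_len(n_rep)) {
    df <- sim_fop_data(n_per = 80, mating_effect = 0.04)
    m <- fop_model(df, "mating_system")
    kept <- any(grepl("mating_system", m$retained))
    sign_ok <- FALSE
    if (kept) {
      cf <- coef(m$fit)
      cs <- cf[grepl("mating_system", names(cf)) & !grepl(":", names(cf))]
      if (length(cs)) sign_ok <- cs[[1]] < 0 # selfing lowers Fop
    }
    if (kept && sign_ok) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("delta-RSCU+ contrasts detect planted selfer reductions and stay quiet under the null", {
  set.seed(15)
  mating <- c(bz = "outcrossing", jm = "selfing", nc = "selfing", px = "selfing")
  mk_vals <- function(mult) {
    lapply(mult, function(m) exp(rnorm(24, log(0.25 * m), 0.3)))
  }
  # null: identical distributions
  null_rej <- 0L
  for (i in 1:40) {
    vals <- mk_vals(c(bz = 1, jm = 1, nc = 1, px = 1))
    r <- delta_rscu_plus_tests(vals, mating)
    if (r$mating_anova$p.value < 0.05) null_rej <- null_rej + 1L
  }
  expect_lte(null_rej / 40, 0.15)

  # planted 30% reduction in all selfers
  det <- 0L
  for (i in 1:40) {
    vals <- mk_vals(c(bz = 1, jm = 0.7, nc = 0.7, px = 0.7))
    r <- delta_rscu_plus_tests(vals, mating)
    if (r$mating_anova$p.value < 0.05 &&
          r$selfer_contrast$mean_outcrosser > r$selfer_contrast$mean_selfer) {
      det <- det + 1L
    }
  }
  expect_gte(det / 40, 0.7)
  expect_error(
    delta_rscu_plus_tests(list(a = c(0.1, -0.2), b = c(0.1, 0.2)), mating),
    "positive"
  )
})
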
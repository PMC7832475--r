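test_that("matching pairs the nearest-age control within exact strata", {
  cases <- data.frame(id = "c1", sex = "F", construct = "L2-5", age = 70)
  pool <- data.frame(id = c("p1", "p2", "p3"),
                     sex = c("F", "F", "M"),
                     construct = "L2-5",
                     age = c(60, 68, 70))
  m <- matchControls(cases, pool)
  expect_identical(m$control_id, "p2")   # nearest in age among F/L2-5

  # no stratum match: case discarded, empty result
  pool2 <- transform(pool, construct = "L3-S1")
  expect_identical(nrow(matchControls(cases, pool2)), 0L)

  # pool mirroring the cases: every case matched at age difference 0
  cases3 <- data.frame(id = paste0("c", 1:5), sex = c("F", "M", "F", "F", "M"),
                       construct = c("L2-5", "L3-S1", "L2-S1", "L2-5", "L1-5"),
                       age = c(55, 62, 70, 77, 81))
  pool3 <- transform(cases3, id = paste0("p", 1:5))
  m3 <- matchControls(cases3, pool3)
  expect_identical(nrow(m3), 5L)
  expect_true(all(m3$age_case == m3$age_control))
  expect_identical(sub("p", "c", m3$control_id), m3$case_id)

  # controls are used at most once; caliper discards distant cases
  cases4 <- data.frame(id = c("c1", "c2"), sex = "F", construct = "L2-5",
                       age = c(60, 61))
  pool4 <- data.frame(id = c("p1", "p2"), sex = "F", construct = "L2-5",
                      age = c(60, 90))
  m4 <- matchControls(cases4, pool4, age_caliper = 5)
  expect_identical(nrow(m4), 1L)
  expect_identical(m4$case_id, "c1")
})

test_that("Levene statistic matches the ANOVA-on-deviations oracle", {
  expect_equal(leveneTest(c(1, 2, 3), c(4, 5, 6)), list(W = 0, p = 1))
  # location invariance
  set.seed(5)
  x <- rnorm(12)
  l1 <- leveneTest(x, x + 10)
  l2 <- leveneTest(x, x)
  expect_equal(l1$W, l2$W)
  expect_equal(l1$p, l2$p)
  # scaled sample: compare against car's mean-centred Levene implementation
  y <- 10 * rnorm(15)
  lev <- leveneTest(x, y)
  ref <- car::leveneTest(c(x, y), factor(rep(1:2, c(12, 15))),
                         center = mean)
  expect_equal(lev$W, ref[1, "F value"], tolerance = 1e-12)
  expect_equal(lev$p, ref[1, "Pr(>F)"], tolerance = 1e-12)
})

test_that("the t-test gate selects pooled or Welch by Levene p", {
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  set.seed(6)
  x <- rnorm(20, sd = 1)
  y <- rnorm(20, sd = 12) + 1
  gated <- twoSampleT(x, y)
  expect_false(gated$equal_var_assumed)  # Levene flags unequal spread
  expect_lt(gated$levene_p, 0.05)
  expect_equal(gated$t, unname(t.test(x, y)$statistic))
  z <- rnorm(20, sd = 1) + 0.5
  gated2 <- twoSampleT(x, z)
  expect_true(gated2$equal_var_assumed)
  expect_equal(gated2$t, unname(t.test(x, z, var.equal = TRUE)$statistic))
  # when variances agree exactly, Student and Welch t coincide
  expect_equal(unname(t.test(x, x + 2, var.equal = TRUE)$statistic),
               unname(t.test(x, x + 2)$statistic))
})

test_that("summary-statistic t-tests reproduce closed-form cases", {
  r <- tFromSummaries(0, 1, 2, 2, 1, 2, pooled = TRUE)
  expect_equal(r$t, -2)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.1835034, tolerance = 1e-6)
  same <- tFromSummaries(5, 2, 10, 5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # summary path agrees with t.test on raw data
  set.seed(9)
  a <- rnorm(14); b <- rnorm(17, 0.5)
  rs <- tFromSummaries(mean(a), sd(a), 14, mean(b), sd(b), 17, pooled = FALSE)
  tt <- t.test(a, b)
  expect_equal(rs$t, unname(tt$statistic))
  expect_equal(rs$p, tt$p.value)
  # degenerate: equal summaries with zero SDs
  expect_equal(tFromSummaries(1, 0, 5, 1, 0, 5)$p, 1)
  expect_lt(tFromSummaries(0, 0, 5, 1, 0, 5)$p, 1e-300)
})

test_that("uncorrected Pearson chi-square matches closed form and symmetry", {
  tab <- matrix(c(11, 2, 12, 21), 2)
  r <- chiSquare2x2(tab)
  # closed form N(ad-bc)^2 / product of margins
  a <- 11; b <- 12; cc <- 2; dd <- 21; N <- 46
  expect_equal(r$chi2,
               N * (a * dd - b * cc)^2 /
                 ((a + b) * (cc + dd) * (a + cc) * (b + dd)))
  expect_equal(chiSquare2x2(matrix(c(5, 5, 5, 5), 2))$chi2, 0)
  expect_equal(chiSquare2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # invariance under transposition and row/column swaps
  expect_equal(chiSquare2x2(t(tab))$chi2, r$chi2)
  expect_equal(chiSquare2x2(tab[2:1, ])$chi2, r$chi2)
  expect_equal(chiSquare2x2(tab[, 2:1])$chi2, r$chi2)
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Mann-Whitney AUC equals pairwise concordance, with tie handling", {
  expect_equal(rocAuc(c(70, 75, 90), c(100, 110, 120))$auc, 1)
  expect_equal(rocAuc(c(70, 110), c(90, 120))$auc, 0.75)
  deg <- rocAuc(100, 100)
  expect_equal(deg$auc, 0.5)
  expect_true(deg$degenerate)
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    cs <- sample(seq(60, 140, by = 5), n1, replace = TRUE)  # forces ties
    ks <- sample(seq(60, 140, by = 5), n2, replace = TRUE)
    flag <- i %% 2 == 0
    expect_equal(rocAuc(cs, ks, flag)$auc, aucBrute(cs, ks, flag))
  }
  # direction flip complements the AUC when tie-free
  cs <- c(61, 72, 83); ks <- c(65, 90, 95, 99)
  expect_equal(rocAuc(cs, ks, TRUE)$auc, 1 - rocAuc(cs, ks, FALSE)$auc)
})

test_that("AUC cross-checks against an independent ROC implementation", {
  set.seed(13)
  cs <- rnorm(23, 86.5, 29.5); ks <- rnorm(23, 118.2, 32.9)
  r <- rocAuc(cs, ks, lower_is_positive = TRUE)
  ref <- pROC::roc(response = rep(c(1, 0), c(23, 23)),
                   predictor = c(cs, ks), direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(ref$auc))
})

test_that("ROC standard errors follow the stated closed forms", {
  cs <- c(70, 75, 90, 95); ks <- c(85, 100, 110)
  r <- rocAuc(cs, ks)
  expect_equal(r$se_null, sqrt((4 + 3 + 1) / (12 * 4 * 3)))
  A <- r$auc; q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  expect_equal(r$se_hanley,
               sqrt((A * (1 - A) + 3 * (q1 - A^2) + 2 * (q2 - A^2)) / 12))
  expect_equal(r$ci95, pmin(1, pmax(0, A + c(-1, 1) * 1.96 * r$se_hanley)))
  expect_equal(r$p_vs_half, 2 * pnorm(-abs(A - 0.5) / r$se_null))
})

test_that("Youden point maximises J over the exhaustive threshold scan", {
  op <- youdenOptimal(c(70, 75, 90), c(85, 100, 110))
  expect_equal(op$threshold, 95)       # tie at J=2/3 broken by sensitivity
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 2 / 3)
  expect_equal(op$youden_j, 2 / 3)
  # perfectly separated: J = 1 at the gap midpoint
  sep <- youdenOptimal(c(70, 75, 90), c(100, 110, 120))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$threshold, 95)
  set.seed(17)
  for (i in 1:60) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    cs <- sample(seq(50, 150, by = 10), n1, replace = TRUE)
    ks <- sample(seq(50, 150, by = 10), n2, replace = TRUE)
    flag <- i %% 2 == 0
    op <- youdenOptimal(cs, ks, flag)
    expect_equal(op$youden_j, youdenBrute(cs, ks, flag))
    expect_equal(op$youden_j, op$sensitivity + op$specificity - 1)
  }
})

test_that("binormal AUC oracle evaluates the closed form", {
  expect_equal(binormalAuc(86.5, 29.5, 118.2, 32.9),
               pnorm(31.7 / sqrt(29.5^2 + 32.9^2)))
  expect_equal(round(binormalAuc(86.5, 29.5, 118.2, 32.9), 3), 0.763)
  expect_equal(binormalAuc(100, 10, 100, 10), 0.5)
  expect_equal(binormalAuc(0, 1, 1e9, 1), 1)
  expect_equal(binormalAuc(1, 0, 2, 0), 1)
  expect_equal(binormalAuc(1, 0, 1, 0), 0.5)
})

test_that("the full case-control report is built from measured BMD", {
  # degenerate construction: zero-SD groups at the two group means
  rec <- data.frame(group = rep(c("case", "control"), each = 23),
                    bmd = rep(c(86.5, 118.2), each = 23))
  rep0 <- buildTable2(rec)
  expect_equal(rep0$groups$mean_bmd, c(86.5, 118.2))
  expect_equal(rep0$groups$sd_bmd, c(0, 0))
  expect_identical(unname(rep0$categories["low_bone_mass", ]), c(23L, 23L))

  # smoke contract on a simulated matched cohort
  rep1 <- buildTable2(simulateCohort(cohortSpec(seed = 2)))
  expect_identical(rep1$groups$n, c(23L, 23L))
  expect_true(rep1$roc$auc >= 0 && rep1$roc$auc <= 1)
  expect_true(all(c("t_test", "chi_square", "roc", "youden") %in% names(rep1)))
  expect_equal(rep1$youden$youden_j,
               rep1$youden$sensitivity + rep1$youden$specificity - 1)
  expect_error(buildTable2(data.frame(group = "case", bmd = 100)),
               "control")
})

test_that("simulated cohorts at the printed parameters converge to the binormal AUC", {
  set.seed(19)
  aucs <- replicate(300, {
    cs <- rnorm(23, 86.5, 29.5); ks <- rnorm(23, 118.2, 32.9)
    rocAuc(cs, ks)$auc
  })
  oracle <- binormalAuc(86.5, 29.5, 118.2, 32.9)
  expect_lt(abs(mean(aucs) - oracle), 3 * sd(aucs) / sqrt(300))
})
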
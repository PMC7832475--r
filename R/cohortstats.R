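#' Match cases to controls by strata and nearest age
#'
#' 1:1 matching with exact equality on the requested stratification fields
#' (sex and/or surgical construct) and greedy nearest-age assignment within
#' each stratum: cases are processed in ascending age order and each takes
#' the unused control closest in age (ties broken toward the younger
#' control, then record order). Cases without an eligible control — and
#' leftover controls — are discarded.
#'
#' @param cases,pool data frames of patient records (columns `id, sex, age,
#'   construct` at least); `pool` must be disjoint from `cases`.
#' @param exact_on character subset of `c("sex", "construct")`.
#' @param age_caliper optional maximum allowed age difference in years.
#' @return Data frame with one row per matched pair: `case_id, control_id,
#'   age_case, age_control`.
#' @export
matchControls <- function(cases, pool, exact_on = c("sex", "construct"),
                          age_caliper = NULL) {
  stopifnot(all(exact_on %in% c("sex", "construct")),
            !any(cases$id %in% pool$id))
  if (nrow(cases) == 0 || nrow(pool) == 0)
    return(data.frame(case_id = character(), control_id = character(),
                      age_case = numeric(), age_control = numeric()))
  used <- rep(FALSE, nrow(pool))
  ord <- order(cases$age)
  out <- vector("list", nrow(cases))
  for (i in ord) {
    elig <- !used
    for (f in exact_on) elig <- elig & pool[[f]] == cases[[f]][i]
    diff <- abs(pool$age - cases$age[i])
    if (!is.null(age_caliper)) elig <- elig & diff <= age_caliper
    if (!any(elig)) next
    cand <- which(elig)
    cand <- cand[order(diff[cand], pool$age[cand], cand)]
    j <- cand[1]
    used[j] <- TRUE
    out[[i]] <- data.frame(case_id = cases$id[i], control_id = pool$id[j],
                           age_case = cases$age[i], age_control = pool$age[j])
  }
  kept <- Filter(Negate(is.null), out[ord])
  if (length(kept) == 0)
    return(data.frame(case_id = character(), control_id = character(),
                      age_case = numeric(), age_control = numeric()))
  do.call(rbind, c(kept, list(make.row.names = FALSE)))
}

#' Levene's test for equality of variances (mean-centred)
#'
#' The classic variant: a one-way ANOVA F statistic on the absolute
#' deviations from each group's mean, with p from F(1, n1 + n2 - 2). (The
#' median-centred Brown-Forsythe variant is deliberately not used.) When
#' all deviations vanish in both groups the test is degenerate and returns
#' W = 0, p = 1.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return `list(W, p)`.
#' @export
leveneTest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  dx <- abs(x - mean(x)); dy <- abs(y - mean(y))
  within <- sum((dx - mean(dx))^2) + sum((dy - mean(dy))^2)
  if (within == 0) {
    ## degenerate: no spread of deviations within either group
    if (isTRUE(all.equal(mean(dx), mean(dy)))) return(list(W = 0, p = 1))
    return(list(W = Inf, p = 0))
  }
  d <- c(dx, dy)
  g <- factor(rep(1:2, c(length(dx), length(dy))))
  fit <- stats::oneway.test(d ~ g, var.equal = TRUE)
  list(W = unname(fit$statistic), p = fit$p.value)
}

#' Levene-gated two-sample t-test
#'
#' Independent-samples t-test whose variance assumption is selected by
#' Levene's test: if the Levene p-value is at or above `alpha_levene` the
#' pooled-variance Student t (df = n1 + n2 - 2) is used, otherwise the
#' Welch t with Satterthwaite df. Two-sided p-value throughout.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param alpha_levene gate level for the variance pre-test (default 0.05).
#' @return `TTestResult`: list with `t`, `df`, `p`, `equal_var_assumed`,
#'   `levene_p`.
#' @export
twoSampleT <- function(x, y, alpha_levene = 0.05) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  lev <- leveneTest(x, y)
  pooled <- lev$p >= alpha_levene
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                            equal_var_assumed = pooled, levene_p = lev$p),
                       class = "TTestResult"))
    ## p -> 0 limit; reported below the machine floor, like tFromSummaries
    return(structure(list(t = sign(mean(x) - mean(y)) * Inf,
                          df = length(x) + length(y) - 2,
                          p = .Machine$double.xmin,
                          equal_var_assumed = pooled, levene_p = lev$p),
                     class = "TTestResult"))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, equal_var_assumed = pooled,
                 levene_p = lev$p),
            class = "TTestResult")
}

#' Two-sample t-test from summary statistics
#'
#' Computes the independent-samples t-test directly from group means, SDs
#' and sizes — the form needed to re-derive a published comparison from a
#' printed table. Pooled (Student) or Welch variant by flag.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param pooled if `TRUE` (default) pooled-variance Student t with
#'   df = n1 + n2 - 2; otherwise Welch with Satterthwaite df.
#' @return `TTestResult` (without a Levene gate: `levene_p = NA`).
#' @examples
#' # printed case vs control BMD summaries: p rounds to 0.001
#' tFromSummaries(86.5, 29.5, 23, 118.2, 32.9, 23)$p
#' @export
tFromSummaries <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2)
      return(structure(list(t = 0, df = n1 + n2 - 2, p = 1,
                            equal_var_assumed = pooled, levene_p = NA_real_),
                       class = "TTestResult"))
    return(structure(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2,
                          p = .Machine$double.xmin,
                          equal_var_assumed = pooled, levene_p = NA_real_),
                     class = "TTestResult"))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- s1^2 / n1; b <- s2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 equal_var_assumed = pooled, levene_p = NA_real_),
            class = "TTestResult")
}

#' Uncorrected Pearson chi-square on a 2x2 table
#'
#' Pearson's chi-squared statistic without Yates continuity correction,
#' df = 1, two-sided p. Undefined (error) when a row or column margin is
#' zero.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return `Chi2Result`: list with `chi2`, `df`, `p`, `table`.
#' @examples
#' # osteoporosis yes/no in cases vs controls: p rounds to 0.003
#' chiSquare2x2(matrix(c(11, 2, 12, 21), 2))$p
#' @export
chiSquare2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined: a margin of the 2x2 table is zero")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = 1L, p = ct$p.value,
                 table = table),
            class = "Chi2Result")
}

## Mann-Whitney AUC: probability that a random case scores on the positive
## side of a random control, ties counting one half.
.aucMW <- function(case_scores, control_scores, lower_is_positive = TRUE) {
  n1 <- length(case_scores); n2 <- length(control_scores)
  r <- rank(c(case_scores, control_scores))
  u_high <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc_high <- u_high / (n1 * n2)       # P(case > control) + ties/2
  if (lower_is_positive) 1 - auc_high else auc_high
}

## sensitivity/specificity at every candidate cutoff (midpoints between
## consecutive distinct pooled values, plus -Inf/+Inf sentinels)
.rocPoints <- function(case_scores, control_scores, lower_is_positive) {
  sv <- sort(unique(c(case_scores, control_scores)))
  cuts <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    if (lower_is_positive) {
      sens[i] <- mean(case_scores < cuts[i])
      spec[i] <- mean(control_scores >= cuts[i])
    } else {
      sens[i] <- mean(case_scores > cuts[i])
      spec[i] <- mean(control_scores <= cuts[i])
    }
  }
  data.frame(threshold = cuts, sensitivity = sens, specificity = spec)
}

#' Empirical ROC analysis with Mann-Whitney AUC
#'
#' AUC by the Mann-Whitney identity (tied pairs count one half).
#' Significance against AUC = 0.5 uses the null-hypothesis standard error
#' `sqrt((n1 + n2 + 1) / (12 n1 n2))` with a two-sided normal test; the 95%
#' confidence interval uses the Hanley-McNeil standard error evaluated at
#' the observed AUC, clipped to `[0, 1]`.
#'
#' @param case_scores,control_scores numeric scores (here BMD in mg/cm^3).
#' @param lower_is_positive if `TRUE` (default) a lower score indicates the
#'   positive (case) state, as for BMD predicting screw loosening.
#' @return `RocResult`: list with `auc`, `se_null`, `se_hanley`, `ci95`,
#'   `p_vs_half`, `points` (threshold/sensitivity/specificity table),
#'   `direction`, `degenerate`.
#' @export
rocAuc <- function(case_scores, control_scores, lower_is_positive = TRUE) {
  stopifnot(length(case_scores) >= 1, length(control_scores) >= 1)
  n1 <- length(case_scores); n2 <- length(control_scores)
  auc <- .aucMW(case_scores, control_scores, lower_is_positive)
  degenerate <- length(unique(c(case_scores, control_scores))) == 1L
  se_null <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se_hanley <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                       (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se_hanley))
  p <- 2 * stats::pnorm(-abs(auc - 0.5) / se_null)
  structure(list(auc = auc, se_null = se_null, se_hanley = se_hanley,
                 ci95 = ci, p_vs_half = p,
                 points = .rocPoints(case_scores, control_scores,
                                     lower_is_positive),
                 direction = lower_is_positive, degenerate = degenerate),
            class = "RocResult")
}

#' Youden-optimal operating point
#'
#' Scans candidate cutoffs at the midpoints between consecutive distinct
#' pooled score values (plus infinite sentinels) and returns the cutoff
#' maximising Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward higher sensitivity, then the lower cutoff — a deterministic,
#' screening-oriented rule.
#'
#' @inheritParams rocAuc
#' @return `OperatingPoint`: list with `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
youdenOptimal <- function(case_scores, control_scores,
                          lower_is_positive = TRUE) {
  pts <- .rocPoints(case_scores, control_scores, lower_is_positive)
  j <- pts$sensitivity + pts$specificity - 1
  ord <- order(-j, -pts$sensitivity, pts$threshold)
  best <- pts[ord[1], ]
  structure(list(threshold = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 youden_j = best$sensitivity + best$specificity - 1),
            class = "OperatingPoint")
}

#' Closed-form binormal AUC
#'
#' For scores normally distributed in each group, the AUC of the
#' higher-mean group against the lower is `pnorm(|m2 - m1| /
#' sqrt(s1^2 + s2^2))` — the analytic oracle against which the empirical
#' Mann-Whitney AUC of simulated cohorts converges.
#'
#' @param m1,s1 mean and SD of group 1.
#' @param m2,s2 mean and SD of group 2.
#' @return AUC in `[0.5, 1]` (means compared by magnitude of separation).
#' @examples
#' binormalAuc(86.5, 29.5, 118.2, 32.9)  # 0.763
#' @export
binormalAuc <- function(m1, s1, m2, s2) {
  stopifnot(s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) return(if (m1 == m2) 0.5 else 1)
  stats::pnorm(abs(m2 - m1) / sqrt(s1^2 + s2^2))
}

#' Full case-control BMD analysis
#'
#' Builds the group-comparison report from measured patient BMDs: per-group
#' mean (SD) and n, ACR category counts, Levene-gated t-test on BMD,
#' per-category uncorrected chi-square against group, ROC analysis with
#' lower BMD marking the case state, and the Youden-optimal operating
#' point.
#'
#' @param records data frame with columns `group` (`case`/`control`) and
#'   `bmd`, e.g. from [simulateCohort()] or measured by [runScreening()].
#' @param thr an [acrThresholds()].
#' @return `StatsReport`: list with `groups`, `categories`, `t_test`,
#'   `chi_square` (one `Chi2Result` per category), `roc`, `youden`.
#' @export
buildTable2 <- function(records, thr = acrThresholds()) {
  stopifnot(all(c("group", "bmd") %in% names(records)))
  cases <- records$bmd[records$group == "case"]
  controls <- records$bmd[records$group == "control"]
  if (length(cases) == 0 || length(controls) == 0)
    stop("both a case and a control group are required")
  cat_all <- classifyAcr(records$bmd, thr)
  counts <- table(category = cat_all, group = factor(records$group,
                                                     c("case", "control")))
  chis <- lapply(rownames(counts), function(cc) {
    yes <- counts[cc, ]
    no <- colSums(counts) - yes
    tab <- rbind(yes = yes, no = no)
    tryCatch(chiSquare2x2(tab), error = function(e) NULL)
  })
  names(chis) <- rownames(counts)
  structure(list(
    groups = data.frame(
      group = c("case", "control"),
      n = c(length(cases), length(controls)),
      mean_bmd = c(mean(cases), mean(controls)),
      sd_bmd = c(stats::sd(cases), stats::sd(controls))),
    categories = counts,
    t_test = twoSampleT(cases, controls),
    chi_square = chis,
    roc = rocAuc(cases, controls, lower_is_positive = TRUE),
    youden = youdenOptimal(cases, controls, lower_is_positive = TRUE)),
    class = "StatsReport")
}
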
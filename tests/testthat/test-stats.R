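test_that("Welch t-test matches t.test on raw data and handles summaries", {
  set.seed(1)
  x <- rnorm(20, 1, 2); y <- rnorm(35, 0.2, 1.3)
  mine <- welch_t(x, y)
  ref <- t.test(x, y)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p, ref$p.value)
  expect_equal(mine$ci95_diff, unname(ref$conf.int), ignore_attr = TRUE)
  # raw data and its own summary triple agree to machine precision
  summ <- welch_t(c(mean(x), sd(x), length(x)),
                  c(mean(y), sd(y), length(y)), summary = TRUE)
  expect_equal(mine$t, summ$t, tolerance = 1e-12)
  expect_equal(mine$df, summ$df, tolerance = 1e-12)
})

test_that("Welch on the published wash-out summaries gives t ~ 3.63, df ~ 44", {
  w <- welch_t(c(0.39, 0.21, 29), c(0.23, 0.15, 53), summary = TRUE)
  expect_equal(w$t, 3.63, tolerance = 0.005)
  expect_equal(w$df, 44.0, tolerance = 0.002)
  # antisymmetry: swapping groups negates t, keeps p
  w2 <- welch_t(c(0.23, 0.15, 53), c(0.39, 0.21, 29), summary = TRUE)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  expect_error(welch_t(c(0.4, 0.2, 1), c(0.2, 0.1, 10), summary = TRUE),
               "n >= 2")
})

test_that("identical groups give t = 0 and p = 1", {
  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
})

test_that("empirical AUC equals tie-aware pair enumeration on small tables", {
  set.seed(4)
  for (i in 1:60) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    pos <- sample(seq(0, 1, by = 0.25), m, replace = TRUE)  # many ties
    neg <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(empirical_auc(pos, neg), auc_brute(pos, neg))
  }
})

test_that("AUC is monotone-invariant and complements under negation", {
  set.seed(5)
  pos <- c(rnorm(25, 1), rnorm(5))   # with duplicates injected
  pos[1:3] <- pos[4:6]
  neg <- rnorm(30)
  a <- empirical_auc(pos, neg)
  expect_equal(empirical_auc(exp(pos), exp(neg)), a)
  expect_equal(empirical_auc(-pos, -neg), 1 - a)
})

test_that("roc_analysis reproduces worked examples and direction", {
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 7, 8, 9), rep(c("m", "g"), each = 3),
                    positive = "m", direction = "low")
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  # 2x2 with one tie: 3.5 of 4 pairs
  r2 <- roc_analysis(c(0.3, 0.5, 0.3, 0.2), c("A", "A", "B", "B"),
                     positive = "B", direction = "low")
  expect_equal(r2$auc, 0.875)
  # J = sens + spec - 1 at the reported threshold, J in [0, 1]
  expect_equal(r2$youden_j,
               r2$sensitivity_at_threshold +
                 r2$specificity_at_threshold - 1)
  expect_gte(r2$youden_j, 0)
  expect_error(roc_analysis(1:5, rep("A", 5), positive = "A"),
               "both classes")
})

test_that("random scores give chance-level AUC", {
  set.seed(6)
  sc <- rnorm(4000)
  lb <- rep(c("a", "b"), 2000)
  r <- roc_analysis(sc, lb, positive = "b")
  expect_equal(r$auc, 0.5, tolerance = 0.02 / 0.5)
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("DeLong AUC confidence intervals match pROC", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:5) {
    sc <- c(rnorm(30, 0.8), rnorm(45))
    lb <- rep(c("g", "m"), c(30, 45))
    mine <- roc_analysis(sc, lb, positive = "m", direction = "low")
    ref <- pROC::roc(lb, sc, levels = c("g", "m"), direction = ">",
                     quiet = TRUE)
    ci <- pROC::ci.auc(ref, method = "delong")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
    expect_equal(mine$ci95, as.numeric(ci[c(1, 3)]), tolerance = 1e-10)
  }
})

test_that("bootstrap CI is seeded-deterministic and brackets the AUC", {
  set.seed(8)
  sc <- c(rnorm(25, 0.8), rnorm(40))
  lb <- rep(c("g", "m"), c(25, 40))
  a <- roc_analysis(sc, lb, positive = "m", ci = "bootstrap", seed = 3)
  b <- roc_analysis(sc, lb, positive = "m", ci = "bootstrap", seed = 3)
  expect_identical(a$ci95, b$ci95)
  expect_true(a$ci95[1] < a$auc && a$auc < a$ci95[2])
})

test_that("binormal AUC closed form matches the published group summaries", {
  expect_equal(binormal_auc(1, 2, 1, 3), 0.5)
  expect_equal(binormal_auc(0.39, 0.21, 0.23, 0.15), 0.732,
               tolerance = 0.001)
  expect_equal(binormal_auc(3.49, 1.25, 2.25, 1.55), 0.733,
               tolerance = 0.001)
  # symmetric in the group order
  expect_equal(binormal_auc(0.23, 0.15, 0.39, 0.21),
               binormal_auc(0.39, 0.21, 0.23, 0.15))
})

test_that("ICC(2,k) equals the worked table and perfect-agreement cases", {
  expect_equal(icc2k(matrix(c(1, 2, 2, 3, 3, 4), ncol = 2,
                            byrow = TRUE))$icc, 0.8)
  # a rater equal to another, non-constant subjects: ICC = 1
  x <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc2k(x)$icc, 1)
  expect_error(icc2k(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(icc2k(matrix(1:2, ncol = 2)), ">= 2 subjects")
})

test_that("ICC(2,k) matches the aov-based oracle on random tables", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(3:12, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k), n, k) +
      rnorm(n) * runif(1, 0, 3) +                       # subject effect
      rep(rnorm(k) * runif(1, 0, 1), each = n)          # rater effect
    expect_equal(icc2k(x)$icc, icc2k_aov(x), tolerance = 1e-10)
  }
})

test_that("independent ratings give near-zero ICC; bands follow Koo-Li", {
  set.seed(10)
  x <- matrix(rnorm(2000), ncol = 2)
  r <- icc2k(x)
  expect_lt(abs(r$icc), 0.1)
  expect_equal(r$band, "poor")
  bands <- vapply(c(0.3, 0.6, 0.8, 0.95), function(v) {
    set.seed(11)
    subj <- rnorm(600)
    # choose the subject-effect size so the 2-rater average-measure ICC
    # targets v: ICC(2,k=2) = 2*rho/(1+rho) with rho = lam^2/(lam^2+1)
    lam <- sqrt(v / (2 * (1 - v)))
    icc2k(cbind(lam * subj + rnorm(600), lam * subj + rnorm(600)))$band
  }, "")
  expect_equal(bands, c("poor", "moderate", "good", "excellent"))
})

test_that("ICC confidence interval brackets the estimate", {
  set.seed(12)
  subj <- rnorm(40)
  x <- cbind(subj + rnorm(40, sd = 0.4), subj + rnorm(40, sd = 0.4))
  r <- icc2k(x)
  expect_true(r$ci95[1] <= r$icc && r$icc <= r$ci95[2])
  expect_lte(r$icc, 1)
})

test_that("linear probability model recovers exact and degenerate designs", {
  d <- data.frame(y = c(0, 1, 0, 1, 1, 0), x = c(0, 1, 0, 1, 1, 0))
  fit <- suppressWarnings(fit_linear_model(d, y ~ x))  # exact fit by design
  expect_equal(fit$coefficients["x", "estimate"], 1)
  expect_equal(fit$coefficients["(Intercept)", "estimate"], 0)
  expect_equal(fit$r_squared, 1)
  d$x2 <- d$x
  expect_error(fit_linear_model(d, y ~ x + x2), "collinear.*x2")
  # factor outcomes are recoded 0/1
  d2 <- data.frame(g = rep(c("glioblastoma", "metastasis"), 10),
                   v = rep(c(0.1, 0.9), 10) + rnorm(20, sd = 0.01))
  f2 <- fit_linear_model(d2, g ~ v)
  expect_lt(f2$coefficients["v", "p_value"], 1e-6)
})

test_that("simulated cohorts make wash-out a reliable lm predictor", {
  # Monte-Carlo over seeded replicates at the published group parameters:
  # wash-out ratio is significant in >= 80% of fits; rCBV in a majority
  # (its separation shrinks once ratios are truncated positive).
  set.seed(13)
  hits <- c(washout = 0, rcbv = 0)
  reps <- 200
  for (r in seq_len(reps)) {
    g <- data.frame(group = "glioblastoma",
                    washout_ratio = rtruncnorm(29, 0.39, 0.21, 0, 1),
                    rcbv_ratio = rtruncnorm(29, 3.49, 1.25, 0, Inf),
                    adc_ratio = rtruncnorm(29, 1.41, 0.33, 0, Inf),
                    volume_mm3 = rtruncnorm(29, 12992, 18089, 0, Inf))
    m <- data.frame(group = "metastasis",
                    washout_ratio = rtruncnorm(53, 0.23, 0.15, 0, 1),
                    rcbv_ratio = rtruncnorm(53, 2.25, 1.55, 0, Inf),
                    adc_ratio = rtruncnorm(53, 1.38, 0.47, 0, Inf),
                    volume_mm3 = rtruncnorm(53, 4488, 6756, 0, Inf))
    fit <- fit_linear_model(rbind(g, m), group ~ washout_ratio +
                              rcbv_ratio + adc_ratio + volume_mm3)
    p <- fit$coefficients[c("washout_ratio", "rcbv_ratio"), "p_value"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits[["washout"]] / reps, 0.8)
  expect_gte(hits[["rcbv"]] / reps, 0.55)
  expect_lte(hits[["rcbv"]] / reps, 0.85)
})

test_that("cohort report summarizes groups, tests and ROC rows", {
  sp <- cohort_spec(seed = 21)
  tab <- simulate_cohort(sp)
  rep <- cohort_report(tab)
  expect_s3_class(rep, "cohort_report")
  expect_setequal(unique(rep$summary$group),
                  c("glioblastoma", "metastasis"))
  # ROC rows for each marker and both lesion subsets
  expect_setequal(unique(rep$roc$marker),
                  c("washout_ratio", "rcbv_ratio", "rcbv_x_washout"))
  expect_setequal(unique(rep$roc$subset), c("all", "volume_ge_1cm3"))
  expect_true(all(rep$roc$auc >= 0 & rep$roc$auc <= 1))
  expect_error(cohort_report(tab[tab$group == "metastasis", ]),
               "missing")
  # product score on perfectly correlated inputs = single-score ROC
  tab2 <- tab
  tab2$rcbv_ratio <- 2 * tab2$washout_ratio          # monotone transform
  rep2 <- cohort_report(tab2)
  aucs <- rep2$roc[rep2$roc$subset == "all", ]
  expect_equal(aucs$auc[aucs$marker == "rcbv_x_washout"],
               aucs$auc[aucs$marker == "washout_ratio"])
})

test_that("single-lesion groups report undefined SDs", {
  tab <- data.frame(group = c("glioblastoma", "metastasis", "metastasis"),
                    washout_ratio = c(0.4, 0.2, 0.3))
  rep <- cohort_report(tab, measures = "washout_ratio")
  s <- rep$summary
  expect_true(is.na(s$sd[s$group == "glioblastoma"]))
  expect_false(is.na(s$sd[s$group == "metastasis"]))
})
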
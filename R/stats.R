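#' Welch's unpaired t-test (raw data or summary triples)
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom, computable either from raw vectors or from `(mean, sd, n)`
#' summary triples -- so published group summaries can be tested directly.
#'
#' @param x,y numeric vectors, or length-3 `c(mean, sd, n)` summaries when
#'   `summary = TRUE`.
#' @param summary set `TRUE` when `x` and `y` are summary triples.
#' @param conf confidence level of the mean-difference interval.
#' @return A list of class `welch_t`: `t`, `df`, `p`, `mean_diff`,
#'   `ci95_diff`.
#' @export
welch_t <- function(x, y, summary = FALSE, conf = 0.95) {
  if (summary) {
    m1 <- x[1]; s1 <- x[2]; n1 <- x[3]
    m2 <- y[1]; s2 <- y[2]; n2 <- y[3]
  } else {
    if (length(x) < 2 || length(y) < 2)
      stop("each group needs at least 2 observations")
    m1 <- mean(x); s1 <- sd(x); n1 <- length(x)
    m2 <- mean(y); s2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("group SDs must be positive")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  t_stat <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  half <- qt(1 - (1 - conf) / 2, df) * se
  structure(list(t = unname(t_stat), df = unname(df), p = unname(p),
                 mean_diff = unname(m1 - m2),
                 ci95_diff = unname(c(m1 - m2 - half, m1 - m2 + half))),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g, diff = %.4g [%.4g, %.4g]\n",
              x$t, x$df, x$p, x$mean_diff, x$ci95_diff[1], x$ci95_diff[2]))
  invisible(x)
}

#' Tie-aware empirical AUC
#'
#' `P(score_pos > score_neg) + 0.5 P(=)` computed from midranks
#' (equivalent to the Mann-Whitney U-statistic with half credit for
#' ties).
#'
#' @param pos,neg scores of the positive and negative class.
#' @return The empirical AUC in `[0, 1]`.
#' @export
empirical_auc <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be nonempty")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (as.numeric(m) * n)
}

# DeLong variance of the empirical AUC via midrank placements.
delong_var <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  var(v10) / m + var(v01) / n
}

#' ROC analysis with Youden's J optimal threshold
#'
#' Empirical tie-aware AUC, the Youden-optimal operating threshold
#' searched over midpoints between sorted unique scores (ties in J broken
#' toward the threshold with higher specificity), and a 95\% CI by
#' DeLong's method (default) or a seeded stratified bootstrap. The
#' `direction` states whether low or high scores indicate the positive
#' class; the study convention is that metastasis is the positive class
#' detected by low scores.
#'
#' @param scores numeric marker values.
#' @param labels group labels, same length as `scores`.
#' @param positive label of the positive class.
#' @param direction `"low"` if low scores indicate the positive class
#'   (default), `"high"` otherwise.
#' @param ci `"delong"` or `"bootstrap"`.
#' @param conf confidence level.
#' @param boot_n bootstrap replicates (when `ci = "bootstrap"`).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `roc_result`: `auc`, `ci95`, `youden_j`,
#'   `optimal_threshold`, `sensitivity_at_threshold`,
#'   `specificity_at_threshold`, `direction`, `positive`, `n_pos`,
#'   `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive,
                         direction = c("low", "high"),
                         ci = c("delong", "bootstrap"),
                         conf = 0.95, boot_n = 2000, seed = 1L) {
  direction <- match.arg(direction)
  ci <- match.arg(ci)
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos))
    stop("both classes must be present")
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  # orient so that larger oriented score = more positive
  opos <- if (direction == "low") -pos else pos
  oneg <- if (direction == "low") -neg else neg
  auc <- empirical_auc(opos, oneg)

  thr <- sort(unique(scores))
  cand <- if (length(thr) > 1) (head(thr, -1) + tail(thr, -1)) / 2
          else thr
  sens <- spec <- numeric(length(cand))
  for (i in seq_along(cand)) {
    if (direction == "low") {
      sens[i] <- mean(pos < cand[i])
      spec[i] <- mean(neg >= cand[i])
    } else {
      sens[i] <- mean(pos > cand[i])
      spec[i] <- mean(neg <= cand[i])
    }
  }
  j <- sens + spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[which.max(spec[best])]

  z <- qnorm(1 - (1 - conf) / 2)
  if (ci == "delong") {
    se <- sqrt(delong_var(opos, oneg))
    ci95 <- c(max(0, auc - z * se), min(1, auc + z * se))
  } else {
    set.seed(seed)
    reps <- vapply(seq_len(boot_n), function(r) {
      empirical_auc(sample(opos, replace = TRUE),
                    sample(oneg, replace = TRUE))
    }, 0)
    ci95 <- unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(auc = auc, ci95 = ci95, youden_j = j[best],
                 optimal_threshold = cand[best],
                 sensitivity_at_threshold = sens[best],
                 specificity_at_threshold = spec[best],
                 direction = direction, positive = positive,
                 n_pos = length(pos), n_neg = length(neg),
                 ci_method = ci),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f [%.3f, %.3f] (%s); J = %.2f at %s %.3g (sens %.0f%%, spec %.0f%%)\n",
    x$auc, x$ci95[1], x$ci95[2], x$ci_method, x$youden_j,
    if (x$direction == "low") "<" else ">", x$optimal_threshold,
    100 * x$sensitivity_at_threshold, 100 * x$specificity_at_threshold))
  invisible(x)
}

#' Analytic binormal AUC
#'
#' `Phi(|mu1 - mu2| / sqrt(sd1^2 + sd2^2))`: the AUC of two normal score
#' distributions, used as the closed-form oracle for cohort simulations.
#'
#' @param mu1,sd1 mean and SD of one group (`sd > 0`).
#' @param mu2,sd2 mean and SD of the other group.
#' @return The binormal AUC.
#' @export
binormal_auc <- function(mu1, sd1, mu2, sd2) {
  stopifnot(sd1 > 0, sd2 > 0)
  pnorm(abs(mu1 - mu2) / sqrt(sd1^2 + sd2^2))
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' Computed from the two-way ANOVA mean squares,
#' `ICC = (MS_rows - MS_err) / (MS_rows + (MS_cols - MS_err) / n)`,
#' with the F-based 95\% confidence interval of McGraw & Wong and the
#' Koo-Li interpretation bands (poor < 0.5 <= moderate < 0.75 <= good
#' < 0.9 <= excellent).
#'
#' @param ratings numeric matrix or data.frame, subjects in rows, raters
#'   in columns; complete (no missing cells).
#' @param conf confidence level.
#' @return An object of class `icc_result`: `icc`, `ci95`, `n_subjects`,
#'   `k_raters`, `band`, and the mean squares.
#' @export
icc2k <- function(ratings, conf = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings table has missing cells; no imputation")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msb <- ss_rows / (n - 1)          # between subjects
  msj <- ss_cols / (k - 1)          # between raters
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msb - mse) / (msb + (msj - mse) / n)

  alpha <- 1 - conf
  ci <- c(NA_real_, NA_real_)
  if (mse > 0 && msb > 0) {
    # McGraw & Wong F-based interval for ICC(A,1), stepped up to k raters
    icc1 <- (msb - mse) / (msb + (k - 1) * mse + k * (msj - mse) / n)
    fj <- msj / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
    vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
      (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    f_u <- qf(1 - alpha / 2, n - 1, v)
    f_l <- qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msb - f_u * mse) /
      (f_u * (k * msj + (k * n - k - n) * mse) + n * msb)
    u1 <- n * (f_l * msb - mse) /
      (k * msj + (k * n - k - n) * mse + n * f_l * msb)
    ci <- c(l1 * k / (1 + l1 * (k - 1)), u1 * k / (1 + u1 * (k - 1)))
  }
  band <- if (is.na(icc)) NA_character_
    else if (icc < 0.5) "poor"
    else if (icc < 0.75) "moderate"
    else if (icc < 0.9) "good"
    else "excellent"
  structure(list(icc = icc, ci95 = ci, n_subjects = n, k_raters = k,
                 band = band, ms = c(rows = msb, cols = msj, error = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,k) = %.3f [%.3f, %.3f], n = %d subjects x %d raters (%s)\n",
              x$icc, x$ci95[1], x$ci95[2], x$n_subjects, x$k_raters, x$band))
  invisible(x)
}

#' Linear (probability) model for tumor type
#'
#' Ordinary least squares with the binary outcome coded 0/1 -- a linear
#' probability model, reproducing the study's `lm` call literally rather
#' than substituting logistic regression (available via
#' `family = "logistic"`). The design matrix is checked for rank
#' deficiency and the offending columns are named.
#'
#' @param data data.frame of complete cases.
#' @param formula model formula; a factor/character outcome is recoded
#'   0/1 (second level = 1).
#' @param family `"lpm"` (default, the reference path) or `"logistic"`.
#' @return A list of class `linear_model_result`: `coefficients` table
#'   (estimate, std.error, t/z, p), `r_squared`, `residual_df`, `fit`.
#' @export
fit_linear_model <- function(data, formula, family = c("lpm", "logistic")) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.character(y) || is.factor(y)) {
    y <- factor(y)
    if (nlevels(y) != 2) stop("outcome must be binary")
    mf[[1]] <- as.numeric(y == levels(y)[2])
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(X) <= ncol(X))
    stop("need more observations than model parameters")
  fit <- if (family == "lpm") lm(formula = stats::formula(attr(mf, "terms")),
                                 data = mf)
         else stats::glm(stats::formula(attr(mf, "terms")), data = mf,
                         family = stats::binomial())
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "statistic", "p_value")
  structure(list(coefficients = coefs,
                 r_squared = if (family == "lpm") sm$r.squared else NA_real_,
                 residual_df = fit$df.residual, family = family, fit = fit),
            class = "linear_model_result")
}

#' @export
print.linear_model_result <- function(x, ...) {
  cat(sprintf("Linear %s model (residual df = %d%s)\n",
              if (x$family == "lpm") "probability" else "logistic",
              x$residual_df,
              if (is.na(x$r_squared)) "" else
                sprintf(", R^2 = %.3f", x$r_squared)))
  print(signif(as.matrix(x$coefficients), 4))
  invisible(x)
}
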
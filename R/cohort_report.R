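#' Cohort-level statistical report
#'
#' Per-group mean +/- SD for each measure, Welch t-tests between the two
#' groups, and ROC rows (positive class = metastasis, detected by low
#' scores) for the wash-out ratio, the rCBV ratio and their product --
#' each computed on the primary lesion set and again after excluding
#' sub-1-cm^3 lesions when volume information is present. Boxplot figures
#' mirror the study's group comparison plots.
#'
#' @param measurements per-lesion data.frame with a `group` column and
#'   measure columns (`washout_ratio`, `rcbv_ratio`, `adc_ratio`, and
#'   optionally `v_enhancing_mm3` / `volume_mm3` plus size-filter flags).
#' @param groups the two group labels; the second is the ROC-positive
#'   class.
#' @param measures measure columns to summarize (defaults to those
#'   present).
#' @param ci ROC CI method passed to [roc_analysis()].
#' @param seed seed for bootstrap CIs.
#' @return A list of class `cohort_report`: `summary` (per-group
#'   mean/SD/n per measure), `tests` (Welch rows), `roc` (data.frame of
#'   ROC rows), `boxplots` (ggplot object or `NULL`).
#' @export
cohort_report <- function(measurements,
                          groups = c("glioblastoma", "metastasis"),
                          measures = NULL, ci = "delong", seed = 1L) {
  stopifnot(all(c("group") %in% names(measurements)))
  for (g in groups)
    if (!any(measurements$group == g))
      stop("group '", g, "' is missing from the table")
  if (is.null(measures))
    measures <- intersect(c("washout_ratio", "rcbv_ratio", "adc_ratio",
                            "volume_mm3", "v_enhancing_mm3"),
                          names(measurements))
  vol_col <- intersect(c("v_enhancing_mm3", "volume_mm3"),
                       names(measurements))[1]

  summarize <- function(df) {
    do.call(rbind, lapply(measures, function(m) {
      do.call(rbind, lapply(groups, function(g) {
        v <- df[[m]][df$group == g]
        data.frame(measure = m, group = g, n = sum(!is.na(v)),
                   mean = mean(v, na.rm = TRUE),
                   sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE)
                        else NA_real_)
      }))
    }))
  }
  welch_rows <- function(df) {
    do.call(rbind, lapply(measures, function(m) {
      a <- df[[m]][df$group == groups[1]]
      b <- df[[m]][df$group == groups[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2 || sd(a) == 0 || sd(b) == 0)
        return(data.frame(measure = m, t = NA_real_, df = NA_real_,
                          p = NA_real_, mean_diff = NA_real_))
      w <- welch_t(a, b)
      data.frame(measure = m, t = w$t, df = w$df, p = w$p,
                 mean_diff = w$mean_diff)
    }))
  }
  roc_rows <- function(df, subset_label) {
    markers <- list()
    if ("washout_ratio" %in% names(df))
      markers$washout_ratio <- df$washout_ratio
    if ("rcbv_ratio" %in% names(df) && !all(is.na(df$rcbv_ratio)))
      markers$rcbv_ratio <- df$rcbv_ratio
    if (all(c("washout_ratio", "rcbv_ratio") %in% names(markers)))
      markers$rcbv_x_washout <- df$rcbv_ratio * df$washout_ratio
    do.call(rbind, lapply(names(markers), function(m) {
      sc <- markers[[m]]
      ok <- !is.na(sc)
      r <- roc_analysis(sc[ok], df$group[ok], positive = groups[2],
                        direction = "low", ci = ci, seed = seed)
      data.frame(marker = m, subset = subset_label, auc = r$auc,
                 ci_low = r$ci95[1], ci_high = r$ci95[2],
                 youden_j = r$youden_j, threshold = r$optimal_threshold,
                 sensitivity = r$sensitivity_at_threshold,
                 specificity = r$specificity_at_threshold)
    }))
  }

  primary <- measurements
  roc <- roc_rows(primary, "all")
  if (!is.na(vol_col)) {
    big <- primary[primary[[vol_col]] >= 1000, , drop = FALSE]
    if (all(vapply(groups, function(g) any(big$group == g), TRUE)))
      roc <- rbind(roc, roc_rows(big, "volume_ge_1cm3"))
  }

  boxplots <- NULL
  plot_measures <- intersect(c("rcbv_ratio", "washout_ratio", "adc_ratio"),
                             measures)
  if (length(plot_measures)) {
    long <- do.call(rbind, lapply(plot_measures, function(m)
      data.frame(group = measurements$group, measure = m,
                 value = measurements[[m]])))
    long <- long[!is.na(long$value), ]
    boxplots <- ggplot2::ggplot(long,
        ggplot2::aes(x = .data$group, y = .data$value,
                     fill = .data$group)) +
      ggplot2::geom_boxplot(outlier.alpha = 0.5) +
      ggplot2::stat_summary(fun = mean, geom = "point", shape = 4,
                            size = 2) +
      ggplot2::facet_wrap(~measure, scales = "free_y") +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "none")
  }

  structure(list(summary = summarize(measurements),
                 tests = welch_rows(measurements),
                 roc = roc, boxplots = boxplots,
                 groups = groups),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (", paste(x$groups, collapse = " vs "), ")\n", sep = "")
  s <- x$summary
  s$mean <- signif(s$mean, 4); s$sd <- signif(s$sd, 4)
  print(s, row.names = FALSE)
  cat("\nWelch tests:\n")
  t <- x$tests
  t[-1] <- lapply(t[-1], signif, 4)
  print(t, row.names = FALSE)
  cat("\nROC (positive = ", x$groups[2], ", low scores positive):\n",
      sep = "")
  r <- x$roc
  r[-(1:2)] <- lapply(r[-(1:2)], signif, 4)
  print(r, row.names = FALSE)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' @param report a [cohort_report()].
#' @param dir output directory (created if needed): writes `summary.csv`,
#'   `tests.csv`, `roc.csv`, `report.md` and `boxplots.png`.
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$summary, file.path(dir, "summary.csv"),
            row.names = FALSE)
  write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  write.csv(report$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  md <- c("# Cohort report", "",
          "## Group summaries", "",
          knit_table(report$summary), "",
          "## Welch t-tests", "", knit_table(report$tests), "",
          "## ROC analysis", "", knit_table(report$roc))
  writeLines(md, file.path(dir, "report.md"))
  if (!is.null(report$boxplots))
    ggplot2::ggsave(file.path(dir, "boxplots.png"), report$boxplots,
                    width = 8, height = 3.2, dpi = 150)
  invisible(dir)
}

# plain markdown table without extra dependencies
knit_table <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) signif(col, 4) else col)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
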
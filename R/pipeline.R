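#' Pipeline configuration for one subject
#'
#' Validated, serializable configuration for an end-to-end run:
#' register the late onto the early acquisition, normalize, compute the
#' wash-out map, and measure the supplied lesions.
#'
#' @param early,late paths to the early/late NIfTI volumes, or
#'   [volume3d()] objects.
#' @param rcbv,adc optional rCBV / ADC map paths or [volume3d()]s.
#' @param lesions lesion definitions: a list where each element is either
#'   a logical mask array, or a list with `seed` (voxel index) and `band`
#'   (intensity bounds) for [trace_lesion()].
#' @param subject subject identifier.
#' @param group group label for the measurement rows.
#' @param epsilon wash-out dead-band in percent.
#' @param metric registration metric (`"ncc"` or `"mi"`).
#' @param seed RNG seed recorded in provenance.
#' @param out optional output directory; when set, maps, tables and
#'   provenance are written there.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(early, late, rcbv = NULL, adc = NULL,
                            lesions = list(), subject = "subject",
                            group = "unknown", epsilon = 5,
                            metric = "ncc", seed = 1L, out = NULL) {
  if (is.null(early) || is.null(late))
    stop("input error: both early and late volumes are required")
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("input error: epsilon must be a non-negative percent")
  if (!metric %in% c("ncc", "mi"))
    stop("input error: metric must be 'ncc' or 'mi'")
  structure(list(early = early, late = late, rcbv = rcbv, adc = adc,
                 lesions = lesions, subject = subject, group = group,
                 epsilon = epsilon, metric = metric,
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

load_input <- function(x, what, time_min = NA) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "volume3d")) return(x)
  if (is.character(x)) {
    if (!file.exists(x))
      stop("input error [", what, "]: file not found: ", x)
    return(read_volume(x, meta = list(source = x, time_min = time_min)))
  }
  stop("input error [", what, "]: expected a path or volume3d")
}

input_hash <- function(x) {
  if (is.character(x) && file.exists(x))
    return(unname(tools::md5sum(x)))
  if (inherits(x, "volume3d")) {
    con <- rawConnection(raw(0), "w")
    on.exit(close(con))
    serialize(list(x$values, x$affine), con)
    dat <- rawConnectionValue(con)
    tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
    writeBin(dat, tf)
    return(unname(tools::md5sum(tf)))
  }
  NA_character_
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline for one subject
#'
#' Executes register -> normalize -> map -> measure and (optionally)
#' writes all artifacts together with a machine-readable provenance
#' record (input hashes, effective configuration, package version). Any
#' stage failure aborts with a stage-tagged message and removes partial
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `subject_result`: `measurements` (one row per
#'   lesion), `map`, `registration`, `normalization`, `provenance`.
#' @export
run_subject <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out
  created_out <- FALSE
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    created_out <- TRUE
  }
  cleanup <- function() {
    if (!is.null(out_dir) && created_out)
      unlink(out_dir, recursive = TRUE)
  }
  withCallingHandlers({
    early <- stage("input", load_input(config$early, "early", 5))
    late <- stage("input", load_input(config$late, "late", 25))
    rcbv <- stage("input", load_input(config$rcbv, "rcbv"))
    adc <- stage("input", load_input(config$adc, "adc"))

    reg <- stage("register",
                 register_rigid(early, late, metric = config$metric))
    norm <- stage("normalize", normalize_pair(early, reg$resampled))
    map <- stage("map", compute_map(norm$fixed_n, norm$late_n,
                                    epsilon = config$epsilon,
                                    provenance = list(
                                      subject = config$subject,
                                      transform = reg$transform,
                                      normalization = norm$report)))
    rows <- stage("measure", {
      if (!length(config$lesions))
        stop("no lesions supplied")
      do.call(rbind, lapply(seq_along(config$lesions), function(i) {
        les <- config$lesions[[i]]
        mask <- if (is.array(les)) les
          else trace_lesion(early, les$seed, les$band)
        measure_lesion(sprintf("%s_L%02d", config$subject, i), mask, map,
                       rcbv_map = rcbv, adc_map = adc,
                       group = config$group)
      }))
    })
    rows <- size_filters(rows)

    prov <- list(
      subject = config$subject,
      package_version = as.character(utils::packageVersion("washmap")),
      r_version = R.version.string,
      seed = config$seed,
      epsilon = config$epsilon, metric = config$metric,
      inputs = list(early = input_hash(config$early),
                    late = input_hash(config$late),
                    rcbv = input_hash(config$rcbv),
                    adc = input_hash(config$adc)),
      transform = list(rotation_deg = reg$transform$rotation,
                       translation_mm = reg$transform$translation,
                       center_mm = reg$transform$center),
      normalization = norm$report[c("gain", "offset", "n_reference")])

    if (!is.null(out_dir)) {
      write_map(map, file.path(out_dir, "washout_percent.nii.gz"),
                file.path(out_dir, "washout_labels.nii.gz"))
      write.csv(rows, file.path(out_dir, "measurements.csv"),
                row.names = FALSE)
      jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      yaml::write_yaml(list(subject = config$subject,
                            group = config$group,
                            epsilon = config$epsilon,
                            metric = config$metric, seed = config$seed),
                       file.path(out_dir, "config.yaml"))
      write_overlay_png(map, norm$fixed_n,
                        file.path(out_dir, "overlay.png"))
    }
    structure(list(measurements = rows, map = map, registration = reg,
                   normalization = norm, provenance = prov),
              class = "subject_result")
  }, error = function(e) cleanup())
}

#' Run a multi-subject study
#'
#' Runs [run_subject()] per configuration, concatenates measurement rows,
#' applies the size filters, and produces the cohort report. Per-subject
#' failures are logged and skipped; the study fails only if no subject
#' succeeds (or a group required for statistics is empty).
#'
#' @param configs list of [pipeline_config()]s.
#' @param groups the two group labels for [cohort_report()].
#' @param exclude_below_1cm3 drop sub-1-cm^3 lesions before statistics.
#' @param out optional directory for the combined table and report.
#' @return A list of class `study_result`: `table` (filtered
#'   measurements), `report` ([cohort_report()]), `n_failed`,
#'   `failures` (named error messages).
#' @export
run_study <- function(configs, groups = c("glioblastoma", "metastasis"),
                      exclude_below_1cm3 = FALSE, out = NULL) {
  if (!length(configs)) stop("input error: empty study")
  results <- list(); failures <- character(0)
  for (cfg in configs) {
    res <- tryCatch(run_subject(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures[cfg$subject] <- conditionMessage(res)
      message("subject ", cfg$subject, " failed: ",
              conditionMessage(res))
    } else {
      results[[cfg$subject]] <- res
    }
  }
  if (!length(results))
    stop("all ", length(configs), " subjects failed")
  table <- do.call(rbind, lapply(results, `[[`, "measurements"))
  rownames(table) <- NULL
  filtered <- filter_lesions(table,
                             exclude_below_1cm3 = exclude_below_1cm3)
  report <- cohort_report(filtered, groups = groups)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(table, file.path(out, "measurements_all.csv"),
              row.names = FALSE)
    write_cohort_report(report, file.path(out, "report"))
  }
  structure(list(table = filtered, report = report,
                 n_failed = length(failures), failures = failures),
            class = "study_result")
}
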
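REPORT_VERSION <- "1.0"

default_thresholds <- function() {
  list(
    qc_max_missing = 0.10,
    sex_male_max = 0.2,
    sex_female_min = 0.8,
    ancestry_single_group = 0.70,
    eye_p = 0.7,
    kinship_bins = c(first = 0.375, second = 0.1875, third = 0.09375,
                     fourth = 0.044),
    kinship_min_overlap = 1000,
    min_x_markers = 100
  )
}

#' Run the full DNA-intelligence report
#'
#' Executes every inference stage in order — QC gating, sex inference,
#' biparental ancestry (categorical PCA assignment and quantitative
#' admixture), uniparental haplogroups with consistency checks, eye and
#' hair colour prediction, and pairwise kinship — and consolidates them
#' into one per-sample intelligence table plus one pairwise relatedness
#' table. Samples failing QC still get an ancestry attempt (genome-wide
#' ancestry tolerates low call rates well) but carry their QC flag; a stage
#' failing on one sample is logged and isolated, never aborting the cohort.
#' The run is deterministic given inputs and seed.
#'
#' @param g A [genotype_matrix()].
#' @param reference An [fit_reference()] panel (or `NULL` to skip
#'   ancestry).
#' @param y_tree,mt_tree Optional [haplogroup_tree()] objects.
#' @param eye_model,hair_model Optional [phenotype_model()] objects
#'   (defaults: the shipped synthetic-coefficient models when the panel
#'   carries their predictors).
#' @param geo_map Named population -> region map for lineage consistency.
#' @param thresholds Named list overriding [default_thresholds()] entries.
#' @param seed Integer seed (the stages are deterministic; the seed is set
#'   for reproducibility of any downstream sampling).
#' @return A list of class `fsnp_report`: `samples`, `kinship`, `qc`,
#'   `version`, `log`.
#' @export
run_all <- function(g, reference = NULL, y_tree = NULL, mt_tree = NULL,
                    eye_model = NULL, hair_model = NULL, geo_map = NULL,
                    thresholds = list(), seed = 1) {
  set.seed(seed)
  th <- utils::modifyList(default_thresholds(), thresholds)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }
  qc <- qc_call_rate(g, max_missing = th$qc_max_missing)
  note("QC: ", sum(qc$pass), "/", nrow(qc), " samples pass (<=",
       100 * th$qc_max_missing, "% missing)")
  samples <- qc[, c("sample_id", "call_rate", "pass")]
  names(samples)[3] <- "qc_pass"

  y_calls <- mt_calls <- NULL
  if (!is.null(y_tree)) {
    y_calls <- try_stage("Y haplogroups", note, call_haplogroups(g, y_tree, "Y"))
  }
  if (!is.null(mt_tree)) {
    mt_calls <- try_stage("mt haplogroups", note,
                          call_haplogroups(g, mt_tree, "mt"))
  }
  sex <- try_stage("sex inference", note, infer_sex(
    g, male_max = th$sex_male_max, female_min = th$sex_female_min,
    min_x_markers = th$min_x_markers, y_calls = y_calls))
  if (!is.null(sex)) {
    samples <- dplyr::left_join(
      samples,
      dplyr::rename(sex, sex_call = "call",
                    sex_conflict = "conflict_with_report"),
      by = "sample_id")
  }
  adm <- proj <- NULL
  if (!is.null(reference)) {
    proj <- try_stage("PCA projection", note,
                      suppressWarnings(project_and_assign(g, reference)))
    adm <- try_stage("admixture", note, estimate_admixture(
      g, reference, threshold = th$ancestry_single_group))
    if (!is.null(proj)) samples <- dplyr::left_join(samples, proj, by = "sample_id")
    if (!is.null(adm)) {
      samples <- dplyr::left_join(
        samples, dplyr::select(adm, -"n_iter", -"converged"),
        by = "sample_id")
    }
  }
  if (!is.null(y_calls)) {
    samples <- dplyr::left_join(
      samples,
      dplyr::select(y_calls, "sample_id", y_haplogroup = "node",
                    y_geography = "geography"),
      by = "sample_id")
  }
  if (!is.null(mt_calls)) {
    samples <- dplyr::left_join(
      samples,
      dplyr::select(mt_calls, "sample_id", mt_haplogroup = "node",
                    mt_geography = "geography"),
      by = "sample_id")
  }
  if ((!is.null(y_calls) || !is.null(mt_calls)) && !is.null(adm)) {
    cons <- try_stage("lineage consistency", note, lineage_consistency(
      y_calls, mt_calls, adm, geo_map = geo_map))
    if (!is.null(cons)) {
      samples <- dplyr::left_join(
        samples,
        cons[, c("sample_id", "paternal_divergent", "maternal_divergent",
                 "note")],
        by = "sample_id")
    }
  }
  if (!is.null(eye_model) &&
      all(eye_model$predictors %in% g$panel$marker_id)) {
    eye <- try_stage("eye colour", note,
                     predict_eye(g, eye_model, p_threshold = th$eye_p))
    if (!is.null(eye)) {
      samples <- dplyr::left_join(
        samples,
        dplyr::select(eye, "sample_id", eye_call = "call",
                      eye_complete = "complete"),
        by = "sample_id")
    }
  }
  if (!is.null(hair_model) &&
      all(hair_model$predictors %in% g$panel$marker_id)) {
    hair <- try_stage("hair colour", note, predict_hair(g, hair_model))
    if (!is.null(hair)) {
      samples <- dplyr::left_join(
        samples,
        dplyr::select(hair, "sample_id", hair_call = "call",
                      hair_complete = "complete"),
        by = "sample_id")
    }
  }
  kin <- try_stage("kinship", note, kinship(
    g, min_overlap = th$kinship_min_overlap, bins = th$kinship_bins))
  structure(list(samples = samples, kinship = kin, qc = qc,
                 version = REPORT_VERSION, log = log),
            class = "fsnp_report")
}

try_stage <- function(name, note, expr) {
  tryCatch(expr, error = function(e) {
    note("stage ", name, " failed: ", conditionMessage(e))
    NULL
  })
}

#' @export
print.fsnp_report <- function(x, ...) {
  cat("<fsnp_report v", x$version, "> ", nrow(x$samples), " samples, ",
      if (is.null(x$kinship)) 0 else nrow(x$kinship), " pairs\n", sep = "")
  invisible(x)
}

#' Write a consolidated report to disk
#'
#' Emits `report_samples.tsv`, `report_kinship.tsv`, `qc.tsv`, a
#' consolidated `report.json` and the run log.
#'
#' @param report An [run_all()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$samples, file.path(dir, "report_samples.tsv"),
                   na = "NA", progress = FALSE)
  if (!is.null(report$kinship)) {
    readr::write_tsv(report$kinship, file.path(dir, "report_kinship.tsv"),
                     na = "NA", progress = FALSE)
  }
  readr::write_tsv(report$qc, file.path(dir, "qc.tsv"), na = "NA",
                   progress = FALSE)
  jsonlite::write_json(
    list(version = report$version,
         samples = report$samples,
         kinship = report$kinship,
         log = report$log),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Validate a declarative run configuration
#'
#' Reads a YAML configuration, fills every default, and reports all
#' problems at once (range violations and missing mandatory paths are
#' errors; unknown keys are warnings, for forward compatibility).
#'
#' @param path YAML file path.
#' @return A list of class `fsnp_run_config` with attributes `errors` and
#'   `warnings` (character vectors; an empty `errors` means the
#'   configuration is runnable).
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("genotypes", "dialect", "reference_dir", "y_tree",
             "y_tree_annotation", "mt_tree", "mt_tree_annotation",
             "eye_model", "hair_model", "out_dir", "seed", "thresholds")
  errors <- character()
  warnings <- character()
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warnings <- c(warnings,
                  paste0("unknown key(s) ignored: ",
                         paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    genotypes = raw$genotypes,
    dialect = raw$dialect %||% "tsv",
    reference_dir = raw$reference_dir,
    y_tree = raw$y_tree, y_tree_annotation = raw$y_tree_annotation,
    mt_tree = raw$mt_tree, mt_tree_annotation = raw$mt_tree_annotation,
    eye_model = raw$eye_model, hair_model = raw$hair_model,
    out_dir = raw$out_dir %||% "forensnp_out",
    seed = raw$seed %||% 1,
    thresholds = utils::modifyList(default_thresholds(),
                                   raw$thresholds %||% list())
  )
  if (is.null(cfg$genotypes)) {
    errors <- c(errors, "mandatory input path missing: genotypes")
  } else if (!file.exists(cfg$genotypes)) {
    errors <- c(errors, paste0("genotypes path does not exist: ",
                               cfg$genotypes))
  }
  if (!cfg$dialect %in% c("tsv", "vcf")) {
    errors <- c(errors, paste0("dialect must be tsv or vcf, got ",
                               cfg$dialect))
  }
  for (key in c("reference_dir", "y_tree", "y_tree_annotation", "mt_tree",
                "mt_tree_annotation", "eye_model", "hair_model")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      errors <- c(errors, paste0(key, " path does not exist: ", cfg[[key]]))
    }
  }
  for (key in c("qc_max_missing", "sex_male_max", "sex_female_min",
                "ancestry_single_group", "eye_p")) {
    v <- cfg$thresholds[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      errors <- c(errors, paste0("threshold ", key,
                                 " must be in [0, 1], got ", v))
    }
  }
  structure(cfg, class = "fsnp_run_config", errors = errors,
            warnings = warnings)
}

#' Execute a validated run configuration
#'
#' @param config An [validate_config()] result with no errors.
#' @return The [run_all()] report, after writing it to the configured
#'   output directory.
#' @export
run_from_config <- function(config) {
  errs <- attr(config, "errors")
  if (length(errs)) {
    stop("configuration errors:\n", paste0("  - ", errs, collapse = "\n"))
  }
  for (w in attr(config, "warnings")) warning(w)
  g <- read_genotypes(config$genotypes, dialect = config$dialect)
  reference <- if (!is.null(config$reference_dir)) {
    read_reference_panel(config$reference_dir)
  }
  y_tree <- if (!is.null(config$y_tree)) {
    read_haplogroup_tree(config$y_tree, config$y_tree_annotation)
  }
  mt_tree <- if (!is.null(config$mt_tree)) {
    read_haplogroup_tree(config$mt_tree, config$mt_tree_annotation)
  }
  eye_model <- if (!is.null(config$eye_model)) {
    read_phenotype_model(config$eye_model)
  }
  hair_model <- if (!is.null(config$hair_model)) {
    read_phenotype_model(config$hair_model)
  }
  report <- run_all(g, reference = reference, y_tree = y_tree,
                    mt_tree = mt_tree, eye_model = eye_model,
                    hair_model = hair_model,
                    thresholds = config$thresholds, seed = config$seed)
  write_report(report, config$out_dir)
  report
}
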
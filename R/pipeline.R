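#' Default run configuration
#'
#' All analysis thresholds live in the configuration so every report can
#' embed the resolved values it was produced with.
#'
#' @return Nested list: `qc` (`z_min_primary` 0.6, `z_min_secondary`
#'   0.5), `synergy` (`lo` -20, `hi` 20), `ci` (`eps` 0.005, `form`),
#'   `tgi` (`responder` 60, `regression` 100), `seed`.
#' @export
default_config <- function() {
  list(qc = list(z_min_primary = 0.6, z_min_secondary = 0.5),
       synergy = list(lo = -20, hi = 20),
       ci = list(eps = 0.005, form = "mutually_exclusive"),
       tgi = list(responder = 60, regression = 100),
       seed = 1L)
}

#' Read a YAML run configuration
#'
#' Values in the file override the defaults; everything else keeps its
#' default. Basic sanity constraints (`lo < hi`, `0 < eps < 0.5`) are
#' enforced.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (cfg$synergy$lo >= cfg$synergy$hi) {
    abort("config: synergy thresholds must satisfy lo < hi",
          "validation_error")
  }
  if (cfg$ci$eps <= 0 || cfg$ci$eps >= 0.5) {
    abort("config: ci.eps must lie in (0, 0.5)", "validation_error")
  }
  cfg
}

#' Simulate a demo screen to disk
#'
#' Writes the plate CSV, plate manifest, compound annotations and truth
#' tables of a simulated anchored combination screen into a directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param classes,cell_lines,design,noise_sigma Passed to
#'   [simulate_library()].
#' @param config Run configuration (supplies the seed).
#' @return The [simulate_library()] bundle, invisibly.
#' @export
run_simulate <- function(out_dir, classes = default_library_classes(),
                         cell_lines = paste0("CL", 1:4),
                         design = list(top = 20, fold = 5, n = 5),
                         noise_sigma = 0.03, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- simulate_library(classes = classes, cell_lines = cell_lines,
                          design = design, noise_sigma = noise_sigma,
                          seed = config$seed)
  write_plate_table(lib$records, file.path(out_dir, "plates.csv"))
  write_tsv_table(lib$manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv_table(lib$annotations, file.path(out_dir, "annotations.tsv"))
  write_tsv_table(lib$truth_plate, file.path(out_dir, "truth_plate.tsv"))
  write_tsv_table(lib$truth_compound,
                  file.path(out_dir, "truth_compound.tsv"))
  invisible(lib)
}

#' Score a screen: QC, per-matrix synergy, ranking, class averages
#'
#' Reads a plate CSV and its manifest, runs plate QC, normalizes every
#' passing plate, scores it with ExcessHSA and Bliss excess, ranks
#' compounds by average ExcessHSA across passing cell lines, and
#' averages ranks per mechanism class. Plates failing QC are excluded
#' from aggregation with a warning, never zero-filled.
#'
#' @param plate_csv Path to the long-format plate CSV.
#' @param manifest Data frame or TSV path mapping `plate_id` to
#'   `compound_b` and `cell_line`.
#' @param annotations Optional annotation data frame or TSV path
#'   (`compound, moa_class`).
#' @param config Run configuration.
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return List: `qc`, `scores` (per-plate data frame), `rank_table`,
#'   `class_table`, `config`.
#' @export
run_score <- function(plate_csv, manifest, annotations = NULL,
                      config = default_config(), out_dir = NULL) {
  records <- read_plate_table(plate_csv)
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  if (is.character(annotations)) {
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  }
  qc <- plate_qc(records, z_min = config$qc$z_min_primary)
  failed <- qc$plate_id[!qc$passed]
  if (length(failed)) {
    warn(sprintf("%d plate(s) failed QC and are excluded from ranking: %s",
                 length(failed), paste(failed, collapse = ", ")),
         "qc_exclusion_warning")
  }
  thresholds <- c(config$synergy$lo, config$synergy$hi)
  by_plate <- split(records, records$plate_id)
  rows <- lapply(names(by_plate), function(pid) {
    meta <- manifest[manifest$plate_id == pid, , drop = FALSE]
    if (nrow(meta) != 1L) {
      abort(sprintf("plate %s missing from manifest", pid),
            "input_format_error")
    }
    passed <- !pid %in% failed
    if (!passed) {
      return(data.frame(plate_id = pid, compound = meta$compound_b,
                        cell_line = meta$cell_line, qc_passed = FALSE,
                        excess_hsa_sum = NA_real_,
                        excess_bliss_sum = NA_real_,
                        interaction_class = NA_character_))
    }
    mat <- normalize_matrix(by_plate[[pid]], qc = qc,
                            cell_line = meta$cell_line)
    s <- score_matrix(mat, thresholds)
    data.frame(plate_id = pid, compound = meta$compound_b,
               cell_line = meta$cell_line, qc_passed = TRUE,
               excess_hsa_sum = s$excess_hsa_sum,
               excess_bliss_sum = s$excess_bliss_sum,
               interaction_class = s$interaction_class)
  })
  scores <- do.call(rbind, rows)
  rank_table <- rank_compounds(scores[scores$qc_passed, , drop = FALSE],
                               annotations, thresholds)
  class_table <- class_average(rank_table)
  out <- list(qc = qc, scores = scores, rank_table = rank_table,
              class_table = class_table, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(qc, file.path(out_dir, "qc.tsv"))
    write_tsv_table(scores, file.path(out_dir, "scores.tsv"))
    write_tsv_table(rank_table, file.path(out_dir, "rank.tsv"))
    write_tsv_table(class_table, file.path(out_dir, "class_average.tsv"))
    jsonlite::write_json(list(config = config,
                              n_plates = nrow(qc),
                              n_failed_qc = length(failed),
                              synergistic_fraction =
                                mean(rank_table$interaction_class ==
                                       "synergistic")),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Combination-index analysis of one plate
#'
#' Normalizes a single-plate CSV, fits median-effect models to both
#' single-agent margins and emits the per-well Fa-CI table.
#'
#' @param plate_csv Path to a one-plate CSV.
#' @param config Run configuration.
#' @param out_dir Optional output directory.
#' @return List: `fit_a`, `fit_b`, `fa_ci` (data frame), `config`.
#' @export
run_ci <- function(plate_csv, config = default_config(), out_dir = NULL) {
  records <- read_plate_table(plate_csv)
  qc <- plate_qc(records, z_min = config$qc$z_min_primary)
  mat <- normalize_matrix(records, qc = qc)
  fit_a <- median_effect_fit(mat$doses_a[-1],
                             1 - mat$viability[-1, 1] / 100,
                             eps = config$ci$eps)
  fit_b <- median_effect_fit(mat$doses_b[-1],
                             1 - mat$viability[1, -1] / 100,
                             eps = config$ci$eps)
  curve <- fa_ci_curve(mat, fit_a, fit_b, eps = config$ci$eps,
                       form = config$ci$form)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(curve, file.path(out_dir, "fa_ci.tsv"))
  }
  list(fit_a = fit_a, fit_b = fit_b, fa_ci = curve, config = config)
}

#' TGI analysis of a xenograft growth table
#'
#' @param growth_csv Path to a growth CSV
#'   (`animal_id, arm, day, volume_mm3`).
#' @param control_arm Control arm label.
#' @param config Run configuration.
#' @param out_dir Optional output directory.
#' @return List: `tgi_table` data frame and `config`.
#' @export
run_tgi <- function(growth_csv, control_arm = "vehicle",
                    config = default_config(), out_dir = NULL) {
  growth <- read_growth_table(growth_csv)
  tab <- tgi_table(growth, control_arm,
                   thresholds = c(responder = config$tgi$responder,
                                  regression = config$tgi$regression))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(tab, file.path(out_dir, "tgi.tsv"))
  }
  list(tgi_table = tab, config = config)
}
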
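#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end run: LAA/HAA thresholds,
#' segmentation parameters, statistics options and paths. Thresholds must
#' be strictly ordered, with every LAA threshold below every HAA threshold.
#'
#' @param laa_thresholds_hu low-attenuation thresholds (HU, `below`),
#'   default -850, -900, -950.
#' @param haa_thresholds_hu high-attenuation thresholds (HU, `above`),
#'   default -600, -650.
#' @param air_threshold_hu,min_component_voxels parameters of
#'   [simple_lung_segment()] when segmentation is requested.
#' @param roc_ci AUC CI method, `"delong"` or `"bootstrap"`.
#' @param stay_threshold backward-elimination stay threshold.
#' @param seed top-level seed.
#' @param out_dir output directory.
#' @param verbose print one log line per subject.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(laa_thresholds_hu = c(-850, -900, -950),
                            haa_thresholds_hu = c(-600, -650),
                            air_threshold_hu = -400,
                            min_component_voxels = 50,
                            roc_ci = c("delong", "bootstrap"),
                            stay_threshold = 0.05,
                            seed = 1,
                            out_dir = NULL,
                            verbose = TRUE) {
  roc_ci <- match.arg(roc_ci)
  strictly_ordered <- function(x)
    length(x) < 2 || all(diff(x) > 0) || all(diff(x) < 0)
  if (!strictly_ordered(laa_thresholds_hu))
    stop("LAA thresholds must be strictly ordered")
  if (!strictly_ordered(haa_thresholds_hu))
    stop("HAA thresholds must be strictly ordered")
  if (max(laa_thresholds_hu) >= min(haa_thresholds_hu))
    stop("every LAA threshold must lie below every HAA threshold")
  structure(list(laa_thresholds_hu = laa_thresholds_hu,
                 haa_thresholds_hu = haa_thresholds_hu,
                 air_threshold_hu = air_threshold_hu,
                 min_component_voxels = min_component_voxels,
                 roc_ci = roc_ci, stay_threshold = stay_threshold,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

# Flattens a densitometry_result into the cohort-table LDI columns.
result_to_row <- function(res) {
  data.frame(INS_V_mL = res$ins_volume_ml, EXP_V_mL = res$exp_volume_ml,
             INS_MLD_HU = res$ins_mld_hu, EXP_MLD_HU = res$exp_mld_hu,
             MLDD_HU = res$mldd_hu, EI_Volume_pct = res$ei_volume_pct,
             EI_MLD_pct = res$ei_mld_pct,
             E950_pct = res$laa_pct[["E950"]], E900_pct = res$laa_pct[["E900"]],
             E850_pct = res$laa_pct[["E850"]], E650_pct = res$haa_pct[["E650"]],
             E600_pct = res$haa_pct[["E600"]])
}

#' Group-conditional phantom spec for a simulated subject
#'
#' Draws per-subject phantom parameters from group-specific distributions:
#' BO subjects trap more parenchyma (mosaic pattern), exhale less
#' completely (higher E/I volume) and densify less. Control parameters are
#' centred on a healthy expiratory response. Deterministic given the seed.
#'
#' @param group `"control"` or `"BO"`.
#' @param age_years subject age (drives the inspiratory MLD trend).
#' @param seed subject-level seed.
#' @param base_spec template [phantom_spec()] providing geometry and noise.
#' @return A [phantom_spec()].
#' @export
simulate_subject_spec <- function(group = c("control", "BO"), age_years = 10,
                                  seed = 1, base_spec = phantom_spec()) {
  group <- match.arg(group)
  par <- with_seed(substream_seed(seed, paste0("subject_", group)), {
    if (group == "control")
      list(trapped = stats::runif(1, 0, 0.08),
           ratio = clamp(stats::rnorm(1, 0.58, 0.08), 0.35, 0.85),
           delta = clamp(stats::rnorm(1, 130, 25), 60, 200))
    else
      list(trapped = stats::runif(1, 0.25, 0.65),
           ratio = clamp(stats::rnorm(1, 0.73, 0.10), 0.45, 0.95),
           delta = clamp(stats::rnorm(1, 130, 25), 60, 200))
  })
  phantom_spec(grid_shape = base_spec$grid_shape,
               voxel_spacing = base_spec$voxel_spacing,
               lung_centers = base_spec$lung_centers,
               lung_semiaxes = base_spec$lung_semiaxes,
               expiratory_volume_ratio = par$ratio,
               mu_ins = base_spec$mu_ins,
               sigma_parenchyma = base_spec$sigma_parenchyma,
               delta_exp = par$delta, trapped_fraction = par$trapped,
               n_trapped_blobs = base_spec$n_trapped_blobs,
               noise_sigma = base_spec$noise_sigma,
               body_hu = base_spec$body_hu, age_years = age_years,
               hu_per_year = base_spec$hu_per_year, seed = seed)
}

#' Run the whole pipeline end to end
#'
#' For each subject: obtain the paired-phase volumes and masks (from disk,
#' or freshly simulated phantoms when `subjects` carries specs), run
#' [compute_all_indices()], append the LDI row to the cohort table; then
#' build the diagnostic report with [build_report()]. Per-subject failures
#' are logged and skipped; the run fails only if no subject survives.
#' Every output embeds provenance (package version, seed, config echo).
#'
#' @param config a [pipeline_config()].
#' @param subjects a data.frame with columns `id`, `group`, `age_years`,
#'   `sex` and either path columns (`ins_path`, `exp_path`, `ins_mask_path`,
#'   `exp_mask_path`) or a `simulate` flag (TRUE to generate a
#'   group-conditional phantom for the subject). PFT columns, if present,
#'   are carried through to the report.
#' @param base_spec template [phantom_spec()] for simulated subjects.
#' @return A list of class `pipeline_run`: `cohort` (cohort_table with LDI
#'   columns), `report` (`ldi_report`), `results` (named list of
#'   `densitometry_result`), `failures` (data.frame id/reason), `log`
#'   (character), `n_ok`, `n_failed`.
#' @export
run_end_to_end <- function(config, subjects, base_spec = phantom_spec()) {
  stopifnot(inherits(config, "pipeline_config"), is.data.frame(subjects),
            all(c("id", "group", "age_years", "sex") %in% names(subjects)))
  if (nrow(subjects) == 0) stop("empty cohort")
  log_lines <- character(0)
  results <- list()
  failures <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$id[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      if (isTRUE(subjects$simulate[i])) {
        spec <- simulate_subject_spec(as.character(subjects$group[i]),
                                      subjects$age_years[i],
                                      seed = substream_seed(config$seed, sid),
                                      base_spec = base_spec)
        ph <- generate_phantom(spec)
        ins_v <- ph$ins_volume; exp_v <- ph$exp_volume
        ins_m <- ph$ins_mask; exp_m <- ph$exp_mask
      } else {
        ins_v <- read_volume(subjects$ins_path[i], "inspiratory")
        exp_v <- read_volume(subjects$exp_path[i], "expiratory")
        ins_m <- read_mask(subjects$ins_mask_path[i])
        exp_m <- read_mask(subjects$exp_mask_path[i])
      }
      compute_all_indices(ins_v, exp_v, ins_m, exp_m,
                          laa_thresholds_hu = config$laa_thresholds_hu,
                          haa_thresholds_hu = config$haa_thresholds_hu)
    }, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(id = sid, reason = conditionMessage(res),
                                   stringsAsFactors = FALSE))
      line <- sprintf("subject %s: FAILED in %.2fs (%s)", sid, dt,
                      conditionMessage(res))
    } else {
      results[[sid]] <- res
      rows[[sid]] <- cbind(subjects[i, setdiff(names(subjects),
                                               c("simulate", "ins_path",
                                                 "exp_path", "ins_mask_path",
                                                 "exp_mask_path")),
                                    drop = FALSE],
                           result_to_row(res))
      if (!is.null(config$out_dir)) {
        dir.create(file.path(config$out_dir, "subjects"), recursive = TRUE,
                   showWarnings = FALSE)
        write_result(res, file.path(config$out_dir, "subjects",
                                    paste0(sid, ".json")),
                     provenance = list(seed = config$seed,
                                       laa_thresholds_hu = config$laa_thresholds_hu,
                                       haa_thresholds_hu = config$haa_thresholds_hu))
      }
      line <- sprintf("subject %s: ok in %.2fs", sid, dt)
    }
    log_lines <- c(log_lines, line)
    if (config$verbose) message(line)
  }
  if (length(rows) == 0)
    stop("empty cohort: every subject failed")
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort$group <- factor(cohort$group, levels = c("control", "BO"))
  class(cohort) <- c("cohort_table", "data.frame")
  report <- build_report(cohort, roc_ci = config$roc_ci, seed = config$seed)
  if (!is.null(config$out_dir)) {
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    write_report(report, file.path(config$out_dir, "report"),
                 provenance = list(seed = config$seed,
                                   config = unclass(config)))
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  structure(list(cohort = cohort, report = report, results = results,
                 failures = failures, log = log_lines,
                 n_ok = length(results), n_failed = nrow(failures)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d subject(s) ok, %d failed\n", x$n_ok,
              x$n_failed))
  print(x$report)
  invisible(x)
}
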
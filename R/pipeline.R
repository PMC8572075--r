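# Reproducible end-to-end runs: configuration (YAML round-trip), the
# six-stage pipeline with manifest + checksums, and cohort evaluation.

#' Pipeline run configuration
#'
#' Collects the paths and stage parameters of one pipeline run. All
#' randomness derives from the single `seed` through a fixed splitting
#' scheme (see [stage_seed()]).
#'
#' @param output_dir directory for all pipeline outputs.
#' @param input_volume optional path to an input volume (NIfTI or DICOM
#'   directory); when `NULL` a phantom is simulated.
#' @param input_mask optional path to the matching 3D lung mask (NIfTI);
#'   required when `input_volume` is given.
#' @param patient_id identifier used in output tables.
#' @param seed master seed of the run.
#' @param phantom named list of [phantom_config()] arguments.
#' @param human named list of [human_range_sim_config()] arguments.
#' @param projection list with `size` (resized matrix, default 256).
#' @param segmentation list with `method` (`"classical"` or `"model"`),
#'   `model_path` (checkpoint for `"model"`), `threshold` and
#'   `deficit_threshold`.
#' @param range list with `min_pixels`, `margin_voxels`, `combine_rule`.
#' @param dose list with `scatter_length`, `reference_lung_length`,
#'   `tcm_mode`.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       input_volume = NULL, input_mask = NULL,
                       patient_id = "phantom-1", seed = 1,
                       phantom = list(), human = list(),
                       projection = list(size = 256),
                       segmentation = list(method = "classical",
                                           model_path = NULL,
                                           threshold = 0.5,
                                           deficit_threshold = 0.08),
                       range = list(min_pixels = 50, margin_voxels = 1,
                                    combine_rule = "average"),
                       dose = list(scatter_length = 30,
                                   reference_lung_length = 240,
                                   tcm_mode = TRUE),
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- list(output_dir = output_dir, input_volume = input_volume,
              input_mask = input_mask, patient_id = patient_id,
              seed = as.integer(seed), phantom = phantom, human = human,
              projection = utils::modifyList(list(size = 256), projection),
              segmentation = utils::modifyList(
                list(method = "classical", model_path = NULL,
                     threshold = 0.5, deficit_threshold = 0.08), segmentation,
                keep.null = TRUE),
              range = utils::modifyList(
                list(min_pixels = 50, margin_voxels = 1,
                     combine_rule = "average"), range),
              dose = utils::modifyList(
                list(scatter_length = 30, reference_lung_length = 240,
                     tcm_mode = TRUE), dose),
              log_level = log_level)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks referenced paths and parameter ranges before any stage runs.
#'
#' @param config a [run_config()].
#' @return The config, invisibly; invalid configs raise a validation error.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$output_dir) || !nzchar(config$output_dir))
    stop("validation error: output_dir must be set")
  if (!is.null(config$input_volume) && !file.exists(config$input_volume) &&
      !dir.exists(config$input_volume))
    stop("validation error: input_volume path does not exist: ",
         config$input_volume)
  if (!is.null(config$input_volume) && is.null(config$input_mask))
    stop("validation error: input_mask is required with input_volume")
  if (!is.null(config$input_mask) && !file.exists(config$input_mask))
    stop("validation error: input_mask path does not exist: ",
         config$input_mask)
  if (!config$segmentation$method %in% c("classical", "model"))
    stop("validation error: segmentation method must be 'classical' or 'model'")
  if (config$segmentation$method == "model" &&
      (is.null(config$segmentation$model_path) ||
       !file.exists(config$segmentation$model_path)))
    stop("validation error: model_path required (and existing) for method 'model'")
  if (config$projection$size < 32)
    stop("validation error: projection size must be >= 32")
  invisible(config)
}

#' Save / load a run configuration as YAML
#'
#' The serialization round-trips: `load_run_config(save_run_config(c))`
#' equals `c`, and re-serializing is byte-stable.
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `save_run_config()` returns `path` invisibly;
#'   `load_run_config()` returns the [run_config()].
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Derive a per-stage child seed from the master seed
#'
#' `stage_seed(seed, stage) = (seed * 97 + 1009 * index) mod (2^31 - 1)`,
#' where `index` is the stage's position in the fixed stage order
#' (simulate, project, segment, range, dose, evaluate). Documented so runs
#' can be reproduced stage by stage.
#'
#' @param seed master seed.
#' @param stage stage name.
#' @return Integer child seed.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "project", "segment", "range", "dose", "evaluate")
  idx <- match(stage, stages)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 97 + 1009 * idx) %% 2147483647)
}

.log_msg <- function(config, ...) {
  if (config$log_level != "quiet") message(sprintf(...))
}

#' Run the full scan-range delimitation pipeline
#'
#' Executes simulate/ingest, project, segment, range, dose and evaluate in
#' order, writing every intermediate artifact plus a manifest (inputs,
#' parameters, seed, package version and MD5 checksums of all outputs)
#' into `config$output_dir`. Idempotent: rerunning with the same config
#' and seed reproduces the range and dose tables bit-identically.
#'
#' @param config a [run_config()]; validated before any stage runs.
#' @return Invisibly, a list with the key objects (ranges, overscan
#'   reports, dose reports, comparison) and the manifest path.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages_done <- character(0)
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages_done <<- c(stages_done, name)
    res
  }

  # -- simulate / ingest --------------------------------------------------
  sim <- run_stage("simulate", function() {
    if (is.null(config$input_volume)) {
      ph <- generate_phantom(do.call(phantom_config, config$phantom),
                             seed = stage_seed(config$seed, "simulate"))
    } else {
      vol <- read_ct(config$input_volume)
      msk <- read_lung_mask(config$input_mask)
      ph <- list(volume = vol, mask = msk, range = range_from_mask3d(msk))
    }
    write_ct_volume(ph$volume, file.path(out, "volume.nii.gz"))
    write_lung_mask(ph$mask, file.path(out, "lung_mask.nii.gz"))
    write_tcm_csv(ph$volume$tcm, file.path(out, "tcm.csv"))
    ph$human <- simulate_human_range(
      ph$range, do.call(human_range_sim_config, config$human),
      seed = stage_seed(config$seed, "simulate") + 1L)
    write_range_json(ph$range, file.path(out, "range_exact.json"))
    write_range_json(ph$human, file.path(out, "range_human.json"))
    ph
  })
  .log_msg(config, "simulate: lung range [%.1f, %.1f] mm",
           sim$range$superior_z, sim$range$inferior_z)

  # -- project ------------------------------------------------------------
  proj <- run_stage("project", function() {
    res <- list()
    for (v in c("AP", "LAT")) {
      p <- project_volume(sim$volume, v)
      m <- project_mask(sim$mask, v)
      nr <- normalize_resize(p, m, size = config$projection$size)
      write_projection(nr$projection,
                       file.path(out, sprintf("projection_%s.png", v)))
      write_mask2d(nr$mask, file.path(out, sprintf("mask_true_%s.png", v)))
      res[[v]] <- nr
    }
    res
  })

  # -- segment ------------------------------------------------------------
  seg <- run_stage("segment", function() {
    model <- if (config$segmentation$method == "model")
      load_seg_model(config$segmentation$model_path) else NULL
    res <- list()
    for (v in c("AP", "LAT")) {
      p <- proj[[v]]$projection
      m <- if (is.null(model)) {
        classical_segment(p, config$segmentation$deficit_threshold)
      } else {
        predict_mask(model, p, config$segmentation$threshold)
      }
      m <- postprocess_mask(m, config$range$min_pixels)
      write_mask2d(m, file.path(out, sprintf("mask_pred_%s.png", v)))
      res[[v]] <- m
    }
    res
  })

  # -- range --------------------------------------------------------------
  rng <- run_stage("range", function() {
    ap <- mask_to_range(seg$AP, config$range$margin_voxels, "DL_AP")
    lat <- mask_to_range(seg$LAT, config$range$margin_voxels, "DL_Lat")
    both <- combine_ranges(ap, lat, config$range$combine_rule)
    all_ranges <- list(sim$range, sim$human, ap, lat, both)
    df <- ranges_to_df(setNames(list(all_ranges), config$patient_id))
    write_ranges_csv(df, file.path(out, "ranges.csv"))
    reports <- lapply(list(human = sim$human, DL_AP = ap,
                           DL_Lat = lat, DL_Both = both),
                      overscan_error, truth = sim$range)
    err_df <- data.frame(
      patient_id = config$patient_id,
      provenance = names(reports),
      superior_error_mm = vapply(reports, `[[`, numeric(1), "superior_error_mm"),
      inferior_error_mm = vapply(reports, `[[`, numeric(1), "inferior_error_mm"))
    write.csv(err_df, file.path(out, "overscan.csv"), row.names = FALSE)
    list(ap = ap, lat = lat, both = both, reports = reports, errors = err_df)
  })
  .log_msg(config, "range: DL_Both [%.1f, %.1f] mm",
           rng$both$superior_z, rng$both$inferior_z)

  # -- dose ---------------------------------------------------------------
  dos <- run_stage("dose", function() {
    dm <- measure_body_diameters(sim$volume, sim$mask)
    inp <- dose_inputs(dm["d_ap"], dm["d_lat"], sim$volume$ctdi_vol,
                       kvp = sim$volume$kvp, tcm = sim$volume$tcm)
    mk <- function(r, s) scenario_dose(
      r, sim$range, inp, scenario = s,
      scatter_length = config$dose$scatter_length,
      tcm_mode = isTRUE(config$dose$tcm_mode) && !is.null(inp$tcm),
      reference_lung_length = config$dose$reference_lung_length)
    reps <- list(exact = mk(sim$range, "exact"),
                 human = mk(sim$human, "human"),
                 DL = mk(rng$both, "DL"))
    cmp <- compare_scenarios(reps$exact, reps$human, reps$DL)
    organ_names <- names(reps$exact$organ_doses)
    dose_df <- do.call(rbind, lapply(reps, function(r) {
      cbind(data.frame(patient_id = config$patient_id, scenario = r$scenario,
                       scan_length_cm = r$scan_length_cm, ssde = r$ssde,
                       dlp = r$dlp, ed = r$ed),
            as.data.frame(as.list(setNames(r$organ_doses, organ_names))))
    }))
    write.csv(dose_df, file.path(out, "dose.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(ed_reduction_percent = cmp$ed_reduction_percent,
           additional_ed_superior = cmp$additional_ed_superior,
           additional_ed_inferior = cmp$additional_ed_inferior),
      file.path(out, "dose_comparison.json"), auto_unbox = TRUE, digits = NA)
    list(reports = reps, comparison = cmp)
  })
  .log_msg(config, "dose: ED exact %.3f / human %.3f / DL %.3f mSv",
           dos$reports$exact$ed, dos$reports$human$ed, dos$reports$DL$ed)

  # -- evaluate -----------------------------------------------------------
  run_stage("evaluate", function() {
    summ <- summarize_cohort(rng$errors[rng$errors$provenance == "human", ])
    summ <- rbind(cbind(provenance = "human", summ))
    for (pv in c("DL_AP", "DL_Lat", "DL_Both")) {
      s <- summarize_cohort(rng$errors[rng$errors$provenance == pv, ])
      summ <- rbind(summ, cbind(provenance = pv, s))
    }
    write.csv(summ, file.path(out, "summary.csv"), row.names = FALSE)
    summ
  })

  # -- manifest -----------------------------------------------------------
  files <- setdiff(list.files(out), "manifest.json")
  manifest <- list(
    package = "scoutrange",
    version = as.character(utils::packageVersion("scoutrange")),
    seed = config$seed,
    patient_id = config$patient_id,
    stages = stages_done,
    parameters = unclass(config),
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out, f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(truth = sim$range, human = sim$human, ranges = rng,
                 dose = dos, manifest = file.path(out, "manifest.json")))
}

#' Verify the checksums recorded in a pipeline manifest
#'
#' @param output_dir a directory produced by [run_pipeline()].
#' @return `TRUE` invisibly if all files match; mismatches are an error.
#' @export
verify_manifest <- function(output_dir) {
  man <- jsonlite::read_json(file.path(output_dir, "manifest.json"),
                             simplifyVector = TRUE)
  for (f in names(man$files)) {
    got <- unname(tools::md5sum(file.path(output_dir, f)))
    if (is.na(got) || got != man$files[[f]])
      stop("checksum mismatch for ", f)
  }
  invisible(TRUE)
}

#' Evaluate a cohort of selected ranges against ground truth
#'
#' Joins a cohort ranges CSV with a truth CSV by patient id, computes
#' signed overscan errors per provenance and summarizes them
#' ([summarize_cohort()]); optionally writes the summary and box plots.
#'
#' @param ranges_csv CSV with columns `patient_id`, `provenance`,
#'   `superior_z`, `inferior_z` (see [write_ranges_csv()]).
#' @param truth_csv CSV with columns `patient_id`, `superior_z`,
#'   `inferior_z` giving exact lung coverage per patient.
#' @param output_dir optional directory for `summary.csv` and
#'   `errors_boxplot.png`.
#' @return A list with `errors` (per-case data.frame) and `summary`
#'   (per-provenance, per-direction statistics).
#' @export
evaluate_cohort <- function(ranges_csv, truth_csv, output_dir = NULL) {
  ranges <- read_ranges_csv(ranges_csv)
  truth <- read.csv(truth_csv, stringsAsFactors = FALSE)
  ranges <- ranges[ranges$provenance != "exact", , drop = FALSE]
  missing <- setdiff(ranges$patient_id, truth$patient_id)
  if (length(missing) > 0)
    stop("patient ids without ground truth: ", paste(missing, collapse = ", "))
  i <- match(ranges$patient_id, truth$patient_id)
  errors <- data.frame(
    patient_id = ranges$patient_id, provenance = ranges$provenance,
    superior_error_mm = truth$superior_z[i] - ranges$superior_z,
    inferior_error_mm = ranges$inferior_z - truth$inferior_z[i])
  summ <- do.call(rbind, lapply(split(errors, errors$provenance), function(g)
    cbind(provenance = g$provenance[1], summarize_cohort(g))))
  rownames(summ) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summ, file.path(output_dir, "summary.csv"), row.names = FALSE)
    grDevices::png(file.path(output_dir, "errors_boxplot.png"),
                   width = 900, height = 450)
    graphics::par(mfrow = c(1, 2))
    graphics::boxplot(superior_error_mm ~ provenance, data = errors,
                      main = "Superior error (mm)", xlab = "", ylab = "mm")
    graphics::abline(h = 0, lty = 2)
    graphics::boxplot(inferior_error_mm ~ provenance, data = errors,
                      main = "Inferior error (mm)", xlab = "", ylab = "mm")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  }
  list(errors = errors, summary = summ)
}
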
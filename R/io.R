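# Plan / dose persistence and run configuration.
#
# Plans are stored as an RTPlan-like JSON document carrying the same semantic
# content as a DICOM-RT plan (per-beam control points: leaf bank positions,
# diaphragm positions, segment MU and cumulative meterset weight); doses are
# stored as NIfTI volumes with a JSON sidecar holding the exact grid
# geometry and a dose-grid scaling quantum, mirroring how RTDose stores
# scaled integers. Every file carries a provenance header.

pkg_provenance <- function(stage, config = NULL) {
  list(package = "leafseq",
       version = as.character(utils::packageVersion("leafseq")),
       stage = stage,
       config_hash = if (is.null(config)) NA_integer_ else
         derive_seed(0, paste(deparse(config), collapse = "")))
}

#' Write a plan to an RTPlan-like JSON file
#'
#' Stores gantry angles, isocenter, prescription and, per beam, one control
#' point per segment: both leaf banks (mm at isocenter, 0.1 mm quantum),
#' diaphragm positions, segment MU and cumulative meterset weight. Unrelated
#' plan attributes are preserved verbatim.
#'
#' @param plan A `plan`.
#' @param path Output path.
#' @param stage Provenance stage label.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path, stage = "sequence") {
  total_mu <- sum(vapply(plan$beams, function(b)
    sum(vapply(b$segments, function(s) s$mu, 1)), 1))
  beams <- lapply(plan$beams, function(b) {
    mus <- vapply(b$segments, function(s) s$mu, 1)
    cum <- cumsum(mus) / max(sum(mus), 1e-12)
    cps <- lapply(seq_along(b$segments), function(i) {
      s <- b$segments[[i]]
      iv <- round(s$intervals, 1)
      closed <- is.na(iv[, 1])
      park_pos <- attr_or(s, "parked", -110)
      lower <- ifelse(closed, park_pos, iv[, 1])
      upper <- ifelse(closed, park_pos, iv[, 2])
      list(segment_mu = s$mu,
           cumulative_meterset_weight = cum[i],
           leaf_lower = lower, leaf_upper = upper,
           diaphragm = attr_or(s, "diaphragm", c(-286, 286)))
    })
    list(gantry_angle = b$gantry, control_points = cps)
  })
  doc <- list(modality = "RTPLAN",
              provenance = pkg_provenance(stage),
              patient_id = plan$patient_id,
              fraction = plan$fraction,
              prescription = plan$prescription,
              isocenter = plan$isocenter,
              total_mu = total_mu,
              extra = plan$extra,
              beams = beams)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

attr_or <- function(s, name, default) {
  v <- s[[name]]
  if (is.null(v)) default else v
}

#' Read an RTPlan-like JSON file back into a plan
#'
#' @param path File written by [write_rtplan()].
#' @param machine A [machine_model()] (defines the parked-leaf position).
#' @return A `plan`.
#' @export
read_rtplan <- function(path, machine = machine_model()) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("'%s' is not a readable plan file: %s",
                                 path, conditionMessage(e)))
                  })
  if (!identical(doc$modality, "RTPLAN")) {
    stop(sprintf("'%s' has modality '%s', expected RTPLAN", path,
                 doc$modality %||% "<none>"))
  }
  beams <- lapply(doc$beams, function(brec) {
    cps <- brec$control_points
    segs <- lapply(cps, function(cp) {
      lower <- unlist(cp$leaf_lower)
      upper <- unlist(cp$leaf_upper)
      closed <- abs(upper - lower) < 1e-9
      iv <- cbind(ifelse(closed, NA_real_, lower),
                  ifelse(closed, NA_real_, upper))
      seg <- new_segment(iv, as.numeric(cp$segment_mu))
      seg$diaphragm <- unlist(cp$diaphragm)
      seg
    })
    structure(list(gantry = as.numeric(brec$gantry_angle), segments = segs,
                   isocenter = as.numeric(unlist(doc$isocenter))),
              class = "beam")
  })
  structure(list(patient_id = doc$patient_id,
                 fraction = as.integer(doc$fraction),
                 prescription = as.numeric(doc$prescription),
                 isocenter = as.numeric(unlist(doc$isocenter)),
                 extra = doc$extra,
                 beams = beams),
            class = "plan")
}

#' Write a dose volume (NIfTI + JSON sidecar)
#'
#' Values are quantized to a dose-grid scaling quantum (`max / 2^15`),
#' mirroring the integer scaling of RTDose files. The sidecar records grid
#' geometry, beam reference, the scaling and provenance.
#' @param dose A [dose3d()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param stage Provenance stage label.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, path, stage = "simulate") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing dose volumes requires the RNifti package")
  }
  mx <- max(dose$values)
  quantum <- if (mx > 0) mx / 32768 else 1
  vals <- round(dose$values / quantum) * quantum
  img <- RNifti::asNifti(vals, pixdim = dose$grid$spacing)
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- list(modality = "RTDOSE",
                  provenance = pkg_provenance(stage),
                  dim = dose$grid$dim, spacing = dose$grid$spacing,
                  origin = dose$grid$origin, beam_ref = dose$beam_ref,
                  dose_grid_scaling = quantum)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dose volume written by [write_rtdose()]
#' @param path NIfTI path (with its `.json` sidecar alongside).
#' @return A [dose3d()].
#' @export
read_rtdose <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading dose volumes requires the RNifti package")
  }
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(sc$modality, "RTDOSE")) {
    stop(sprintf("'%s' is not an RTDOSE volume", path))
  }
  vals <- array(as.numeric(RNifti::readNifti(path)), unlist(sc$dim))
  dose3d(vals, grid_spec(unlist(sc$dim), unlist(sc$spacing),
                         unlist(sc$origin)),
         beam_ref = sc$beam_ref)
}

#' Pipeline run configuration
#'
#' A single serializable object holding every knob of a full run. Defaults
#' are desk-scale; the full study conditions are 10 patients x 5 fractions
#' on a 96-voxel, 3 mm grid at raster size 128.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_patients,n_fractions Cohort shape.
#' @param grid_dim,grid_spacing Planning grid (voxels per side, mm).
#' @param size Model raster size.
#' @param n_segments_range Per-beam segment count range in the simulator.
#' @param mu_attenuation,sigma Dose engine parameters.
#' @param threshold_fraction Sequencing intensity threshold.
#' @param folds Which LOOCV folds to run (indices into the patient list).
#' @param train A [train_config()].
#' @param gamma A [gamma_criteria()].
#' @param gamma_cap Gamma cap used in evaluation (Inf disables).
#' @param on_empty_beam Policy when a predicted beam loses all segments
#'   (see [sequence_plan()]).
#' @export
run_config <- function(seed = 1L, n_patients = 2, n_fractions = 2,
                       grid_dim = 32, grid_spacing = 6, size = 32,
                       n_segments_range = c(1, 6), mu_attenuation = 0.005,
                       sigma = 3, threshold_fraction = 0.02, folds = 1,
                       train = train_config(epochs = 2, base_filters = 4,
                                            base_filters_d = 4),
                       gamma = gamma_criteria(), gamma_cap = 2,
                       gamma_step_fraction = 0.1,
                       on_empty_beam = c("error", "keep")) {
  on_empty_beam <- match.arg(on_empty_beam)
  as.list(environment())
}

#' Save / load a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` / the configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- function(x) if (is.null(x)) x else as.numeric(x)
  for (f in c("grid_spacing", "mu_attenuation", "sigma",
              "threshold_fraction", "gamma_cap", "n_segments_range")) {
    cfg[[f]] <- num(cfg[[f]])
  }
  cfg
}

#' Run the full pipeline: simulate, preprocess, train, predict, sequence,
#' evaluate
#'
#' Executes the requested leave-one-out folds end to end on a synthetic
#' cohort and assembles the evaluation tables: a per-fraction gamma passing
#' rate table (patients as columns) and a per-ROI average max/mean dose
#' percent difference table.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress and wall times.
#' @return A report: `gamma_table`, `dose_metric_table`, `per_fraction`
#'   details, `models`, `config`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  tic <- function() Sys.time()
  lap <- function(t0, stage) say("%s: %.1f s", stage,
                                 as.numeric(Sys.time() - t0, units = "secs"))
  machine <- machine_model()
  t0 <- tic()
  cohort <- sample_cohort(derive_seed(config$seed, "simulate"),
                          config$n_patients, config$n_fractions,
                          grid_spec(config$grid_dim, config$grid_spacing),
                          machine, config$n_segments_range)
  lap(t0, "simulate")
  t0 <- tic()
  pairs <- build_training_pairs(cohort, config$size, config$mu_attenuation,
                                config$sigma)
  lap(t0, "preprocess")
  splits <- make_loocv_splits(pairs)
  folds <- splits[config$folds]
  models <- list()
  per_fraction <- list()
  tcfg <- config$train
  tcfg$seed <- derive_seed(config$seed, "train")
  for (fold in folds) {
    t0 <- tic()
    model <- train_cgan(pairs, do.call(train_config, tcfg), split = fold)
    lap(t0, paste("train", fold$held_out_patient))
    models[[fold$held_out_patient]] <- model
    t0 <- tic()
    res <- evaluate_fold(model, fold, pairs, cohort, config,
                         on_empty_beam = config$on_empty_beam %||% "error")
    lap(t0, paste("evaluate", fold$held_out_patient))
    per_fraction <- c(per_fraction, res)
  }
  report <- assemble_report(per_fraction)
  report$models <- models
  report$config <- config
  report
}

# predict, sequence and evaluate every held-out fraction of one fold
evaluate_fold <- function(model, fold, pairs, cohort, config,
                          on_empty_beam = "error") {
  machine <- cohort$machine
  pat <- Filter(function(p) p$patient_id == fold$held_out_patient,
                cohort$patients)[[1]]
  meta <- pairs$meta
  template <- pat$plans[[1]]
  test_fracs <- sort(unique(meta$fraction[fold$test]))
  lapply(test_fracs, function(f) {
    idx <- fold$test[meta$fraction[fold$test] == f]
    idx <- idx[order(meta$beam[idx])]
    gt_plan <- pat$plans[[f]]
    stacks <- lapply(idx, function(i) {
      # the dataset-level MU normalization is shared by template and truth
      predict_apertures(model, pairs$pairs[[i]]$x,
                        mu_scale = pairs$mu_scale %||% meta$mu_scale[i],
                        extent_x = pairs$extent_x, extent_y = pairs$extent_y)
    })
    pred_plan <- sequence_plan(stacks, template, machine,
                               config$threshold_fraction,
                               on_empty_beam = on_empty_beam)
    pred_plan$fraction <- f
    ev <- evaluate_predicted_plan(pred_plan, gt_plan, pat$phantom, machine,
                                  config$gamma, config$mu_attenuation,
                                  config$sigma, gamma_cap = config$gamma_cap,
                                  gamma_step_fraction =
                                    config$gamma_step_fraction %||% 0.1)
    list(patient_id = pat$patient_id, fraction = f,
         gamma_pass = ev$gamma$pass_rate, metrics = ev$metrics,
         pred_plan = pred_plan)
  })
}

# per-fraction results -> the two report tables
assemble_report <- function(per_fraction) {
  pats <- unique(vapply(per_fraction, function(r) r$patient_id, ""))
  fracs <- sort(unique(vapply(per_fraction, function(r) r$fraction, 1L)))
  gamma_table <- matrix(NA_real_, length(fracs), length(pats),
                        dimnames = list(sprintf("FX%d", fracs), pats))
  for (r in per_fraction) {
    gamma_table[sprintf("FX%d", r$fraction), r$patient_id] <- r$gamma_pass
  }
  gamma_table <- rbind(gamma_table,
                       Average = colMeans(gamma_table, na.rm = TRUE))
  all_metrics <- do.call(rbind, lapply(per_fraction, function(r) r$metrics))
  rois <- unique(all_metrics$roi)
  dose_metric_table <- rbind(
    `Max Dose` = vapply(rois, function(x)
      mean(all_metrics$dmax_pct_diff[all_metrics$roi == x]), 1),
    `Mean Dose` = vapply(rois, function(x)
      mean(all_metrics$dmean_pct_diff[all_metrics$roi == x]), 1))
  colnames(dose_metric_table) <- rois
  list(gamma_table = gamma_table, dose_metric_table = dose_metric_table,
       per_fraction = per_fraction)
}
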
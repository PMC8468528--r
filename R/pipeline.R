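## End-to-end orchestration: simulate -> calibrate -> segment -> DMAMA ->
## classify -> sensitivity, writing per-stage artifacts plus a summary report.
## All randomness flows from the single config seed.

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the enabled stages in order and writes per-stage artifacts into
#' `out_dir`: per-trial session CSVs and ground-truth labels (`simulate`),
#' per-subject calibrated geometry JSONs (`calibrate`; when disabled the true
#' geometry is used), a per-stride DMAMA table CSV (`segment` + `dmama`), a
#' classifier report JSON (`classify`), and sensitivity/interaction fits JSON
#' (`sensitivity`). Every artifact header carries the seed and config hash. A
#' failing stage aborts with the stage named; artifacts from completed stages
#' are retained.
#'
#' @param config a `session_config`; its seed drives every stage.
#' @param out_dir output directory (created if needed); `NULL` writes nothing
#'   and just returns the report.
#' @param stages character vector of enabled stages, a subset of
#'   `c("calibrate", "classify", "sensitivity")` plus the always-on core
#'   (simulate, segment, dmama).
#' @param window_ms classifier window length, ms.
#' @param folds classifier CV folds.
#' @param calibration_samples,orientation_noise_deg,offset_noise_m calibration
#'   trial parameters.
#' @return report list (class `pipeline_report`) with sections `dmama`
#'   (per-stride table), `geometry` (estimated), `calibration_error_deg`,
#'   `classifier` (when enabled), `sensitivity` (when enabled), `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = session_config(),
                         out_dir = NULL,
                         stages = c("calibrate", "classify", "sensitivity"),
                         window_ms = 300, folds = 10,
                         calibration_samples = 300,
                         orientation_noise_deg = 1, offset_noise_m = 0.001) {
  stopifnot(inherits(config, "session_config"))
  meta <- list(seed = config$seed, config = config_hash(config))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(fn, name) if (!is.null(out_dir)) fn(file.path(out_dir, name))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  session <- stage("simulate", {
    s <- generate_session(config)
    for (tr in s$trials) {
      emit(
        function(p) write_session_csv(tr$series, p, meta),
        sprintf("session_s%d_k%d.csv", tr$subject, tr$stiffness_code)
      )
      truth_tr <- s$truth[
        s$truth$subject == tr$subject &
          s$truth$stiffness_code == tr$stiffness_code, ,
        drop = FALSE
      ]
      emit(
        function(p) write_labels_csv(truth_tr, p, meta),
        sprintf("labels_s%d_k%d.csv", tr$subject, tr$stiffness_code)
      )
    }
    for (sj in seq_len(config$subjects)) {
      # ground-truth geometry; the calibrate stage overwrites with estimates
      emit(
        function(p) write_geometry_json(s$geometry[[sj]], p, meta),
        sprintf("geometry_s%d.json", sj)
      )
    }
    s
  })

  calibration_error <- rep(NA_real_, config$subjects)
  geometries <- stage("calibrate", {
    if (!"calibrate" %in% stages) {
      session$geometry
    } else {
      lapply(seq_len(config$subjects), function(sj) {
        true_geom <- session$geometry[[sj]]
        trial <- generate_calibration_trial(
          true_geom, calibration_samples,
          orientation_noise_deg, offset_noise_m,
          seed = config$seed + sj
        )
        est <- calibrate_geometry(
          trial$rotations, trial$ankle_offsets, trial$knee_offsets,
          true_geom$foot_length, true_geom$body_weight
        )
        calibration_error[sj] <<- 180 / pi * rotation_distance(
          est$rotation_lc_to_shank, true_geom$rotation_lc_to_shank
        )
        emit(
          function(p) write_geometry_json(est, p, meta),
          sprintf("geometry_s%d.json", sj)
        )
        est
      })
    }
  })

  dmama_tab <- stage("dmama", {
    parts <- lapply(session$trials, function(tr) {
      geom <- geometries[[tr$subject]]
      shank <- to_shank_frame(tr$series, geom)
      ev <- detect_events(shank, geom$body_weight)
      seg <- segment_strides(ev, tr$labels, stiffness_code = tr$stiffness_code)
      jm <- joint_moments(shank, geom)
      dt <- dmama_table(jm, seg, geom)
      dt$subject <- tr$subject
      dt$incline_deg <- ifelse(dt$mode %in% names(config$incline_deg),
        config$incline_deg[dt$mode], 0
      )
      dt
    })
    tab <- do.call(rbind, parts)
    tab$stride_id <- seq_len(nrow(tab))
    emit(function(p) write_csv_meta(tab, p, meta), "dmama.csv")
    tab
  })

  classifier <- NULL
  if ("classify" %in% stages) {
    classifier <- stage("classify", {
      feats <- build_feature_table(session, geometries, window_ms = window_ms)
      rep <- train_eval_lda(feats, folds = folds, seed = config$seed)
      emit(function(p) {
        jsonlite::write_json(
          list(
            meta = meta,
            overall_accuracy = rep$overall_accuracy,
            per_class_accuracy = as.list(rep$per_class_accuracy),
            confusion = as.data.frame.matrix(rep$confusion),
            window_ms = window_ms, folds = folds
          ),
          p,
          auto_unbox = TRUE, digits = NA
        )
      }, "classifier.json")
      rep
    })
  }

  sensitivity <- NULL
  if ("sensitivity" %in% stages) {
    sensitivity <- stage("sensitivity", {
      modes <- intersect(locomotion_modes(), unique(dmama_tab$mode))
      by_mode <- lapply(stats::setNames(modes, modes), function(m) {
        f <- fit_subject_independent(dmama_tab, "stiffness", stratum = m)
        list(slope = f$slope, p_value = f$p_value, r_squared = f$r_squared)
      })
      codes <- sort(unique(dmama_tab$stiffness_code))
      by_stiff <- lapply(stats::setNames(codes, paste0("code_", codes)), function(k) {
        f <- fit_subject_independent(dmama_tab, "incline", stratum = k)
        list(slope = f$slope, p_value = f$p_value, r_squared = f$r_squared)
      })
      inter <- fit_interaction(dmama_tab)
      out <- list(
        stiffness_by_mode = by_mode,
        incline_by_stiffness = by_stiff,
        interaction = list(
          coefficients = as.list(inter$coefficients),
          ci_half_width = as.list(inter$ci_half_width)
        )
      )
      emit(function(p) {
        jsonlite::write_json(c(list(meta = meta), out), p, auto_unbox = TRUE, digits = NA)
      }, "sensitivity.json")
      out
    })
  }

  structure(
    list(
      dmama = dmama_tab,
      geometry = geometries,
      calibration_error_deg = calibration_error,
      classifier = classifier,
      sensitivity = sensitivity,
      truth = session$truth,
      seed = config$seed,
      config_hash = meta$config
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> seed %d, %d strides (%d valid, %d excluded)\n",
    x$seed, nrow(x$dmama), sum(x$dmama$valid), sum(x$dmama$excluded)
  ))
  if (!is.null(x$classifier)) {
    cat(sprintf("  classifier accuracy: %.2f%%\n", x$classifier$overall_accuracy))
  }
  if (!is.null(x$sensitivity)) {
    sl <- vapply(x$sensitivity$stiffness_by_mode, `[[`, numeric(1), "slope")
    cat(sprintf(
      "  stiffness sensitivity by mode: %s\n",
      paste(sprintf("%s=%.2f", names(sl), sl), collapse = ", ")
    ))
  }
  invisible(x)
}
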
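#' Pipeline run configuration
#'
#' Bundles the per-stage configurations and the stage toggles for
#' [run_pipeline()]. Any subset of the stages
#' `generate, train, segment, morpho, stereo, slit, assay, stats` can be
#' enabled; later stages consume the in-memory outputs of earlier ones,
#' so each enabled stage requires its upstream stages.
#'
#' @param stages character vector of enabled stages (order is fixed
#'   internally).
#' @param n_scenes number of synthetic scenes to generate.
#' @param scene a [scene_params()] template (its seed is re-derived per
#'   scene from the global seed).
#' @param train a [train_config()].
#' @param exclusion an [exclusion_config()].
#' @param stereo a [stereology_params()].
#' @param plan an [aggregation_plan()].
#' @param stats a [stats_config()].
#' @param n_slit_fields number of synthetic slit fields.
#' @param seed global seed propagated to every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("generate", "train", "segment",
                                       "morpho", "stereo", "slit", "assay",
                                       "stats"),
                            n_scenes = 8L,
                            scene = scene_params(frame_size_px = c(256L, 256L),
                                                 n_glomeruli = 1L),
                            train = train_config(epochs = 3L,
                                                 steps_per_epoch = 20L),
                            exclusion = exclusion_config(),
                            stereo = stereology_params(),
                            plan = aggregation_plan(),
                            stats = stats_config(),
                            n_slit_fields = 6L,
                            seed = 1L) {
  all_stages <- c("generate", "train", "segment", "morpho", "stereo", "slit",
                  "assay", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  structure(list(stages = stages, n_scenes = as.integer(n_scenes),
                 scene = scene, train = train, exclusion = exclusion,
                 stereo = stereo, plan = plan, stats = stats,
                 n_slit_fields = as.integer(n_slit_fields),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' nested keys are passed to the respective constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  for (nm in c("n_scenes", "n_slit_fields", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  ctor <- list(scene = scene_params, train = train_config,
               exclusion = exclusion_config, stereo = stereology_params,
               plan = aggregation_plan, stats = stats_config)
  for (nm in names(ctor))
    if (!is.null(y[[nm]])) {
      # YAML lists with mixed int/real entries parse as R lists; flatten
      fields <- lapply(y[[nm]], function(v) if (is.list(v)) unlist(v) else v)
      args[[nm]] <- do.call(ctor[[nm]], fields)
    }
  do.call(pipeline_config, args)
}

stage_seed <- function(seed, stage) {
  # stable per-stage substream; stays within 32-bit integer range
  (seed * 131L + match(stage, c("generate", "train", "segment", "morpho",
                                "stereo", "slit", "assay", "stats")) * 7919L) %%
    2147483629L
}

#' Run the podocyte phenotyping pipeline end to end
#'
#' Executes the enabled stages in order, writing per-stage CSV/JSON
#' outputs plus a manifest (config hash, seed, per-stage row counts) to
#' `outdir`. Any stage failure writes a `FAILED` marker naming the stage
#' and rethrows. With a fixed config and seed all non-training CSV
#' outputs are bit-identical across reruns.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$seed, stages = list())
  env <- new.env(parent = emptyenv())
  on_fail <- function(stage, e) {
    writeLines(c(paste("FAILED at stage:", stage), conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) {
      manifest$stages[[stage]] <<- list(skipped = TRUE)
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) on_fail(stage, e))
    manifest$stages[[stage]] <<- c(list(skipped = FALSE), res)
  }

  run_stage("generate", function() {
    scenes <- lapply(seq_len(config$n_scenes), function(i) {
      p <- config$scene
      p$seed <- stage_seed(config$seed, "generate") + i
      generate_glomerulus_scene(p)
    })
    env$scenes <- scenes
    truth <- do.call(rbind, lapply(seq_along(scenes), function(i)
      cbind(scene = i, scenes[[i]]$per_glomerulus)))
    write.csv(truth, file.path(outdir, "scene_truth.csv"), row.names = FALSE)
    list(rows = nrow(truth), n_scenes = length(scenes))
  })

  run_stage("train", function() {
    tc <- config$train
    tc$seed <- stage_seed(config$seed, "train")
    env$fit_tuft <- train_segmenter(env$scenes, "tuft", tc)
    tc$seed <- tc$seed + 1L
    env$fit_nuclei <- train_segmenter(env$scenes, "nuclei", tc)
    log <- rbind(cbind(task = "tuft", env$fit_tuft$log),
                 cbind(task = "nuclei", env$fit_nuclei$log))
    write.csv(log, file.path(outdir, "training_log.csv"), row.names = FALSE)
    save_segnet(env$fit_tuft, file.path(outdir, "model_tuft.rds"))
    save_segnet(env$fit_nuclei, file.path(outdir, "model_nuclei.rds"))
    list(rows = nrow(log),
         final_val_dice_tuft = utils::tail(env$fit_tuft$log$val_dice, 1),
         final_val_dice_nuclei = utils::tail(env$fit_nuclei$log$val_dice, 1))
  })

  run_stage("segment", function() {
    th <- config$train$prob_threshold
    env$pred <- lapply(env$scenes, function(s) list(
      tuft = predict_mask(env$fit_tuft, s$image_wt1, th),
      nuclei = predict_mask(env$fit_nuclei, s$image_wt1, th)))
    list(rows = length(env$pred))
  })

  run_stage("morpho", function() {
    assert_that(!is.null(env$scenes),
                "no scenes available; enable the generate stage")
    ppm <- config$scene$pixels_per_micron
    # without a segment stage, morphometry runs on the ground-truth masks
    if (is.null(env$pred))
      env$pred <- lapply(env$scenes, function(s) list(
        tuft = s$tuft_mask > 0, nuclei = s$nuclei_mask > 0))
    out <- lapply(seq_along(env$pred), function(i) {
      p <- env$pred[[i]]
      tl <- label_and_filter(p$tuft, config$exclusion, ppm)
      nl <- list(labels = label_components(p$nuclei), pixels_per_micron = ppm)
      mor <- compute_morphometrics(tl, nl$labels, ppm)
      cyt <- nephrin_area(env$scenes[[i]]$image_nephrin, tl, ppm)
      m <- merge(mor, cyt, by = "glomerulus_id")
      if (nrow(m)) m <- cbind(scene = i, m)
      list(m = m, ex = if (nrow(tl$exclusions)) cbind(scene = i, tl$exclusions))
    })
    env$morpho <- do.call(rbind, lapply(out, `[[`, "m"))
    excl <- do.call(rbind, Filter(Negate(is.null), lapply(out, `[[`, "ex")))
    write.csv(env$morpho, file.path(outdir, "morphometry.csv"), row.names = FALSE)
    write.csv(excl %||% data.frame(), file.path(outdir, "exclusions.csv"),
              row.names = FALSE)
    list(rows = nrow(env$morpho))
  })

  run_stage("stereo", function() {
    st <- stereology_records(env$morpho, config$stereo)
    st <- cbind(scene = env$morpho$scene, st)
    env$stereo <- st
    write.csv(st, file.path(outdir, "stereology.csv"), row.names = FALSE)
    list(rows = nrow(st))
  })

  run_stage("slit", function() {
    sd0 <- stage_seed(config$seed, "slit")
    recs <- do.call(rbind, lapply(seq_len(config$n_slit_fields), function(i) {
      sc <- with_rng(sd0 + i, {
        list(curves = lapply(seq_len(3), function(j)
          curve_sinusoid(origin = c(runif(1, 1, 4), runif(1, 2, 18)),
                         length = runif(1, 10, 14),
                         amplitude = runif(1, 0.8, 2),
                         period = runif(1, 3, 6))),
          seed = sd0 + 1000L + i)
      })
      scene <- generate_sted_scene(sc$curves, seed = sc$seed)
      slit_density(scene, field_id = i,
                   glomerulus_id = ((i - 1L) %/%
                                      config$plan$areas_per_glomerulus) + 1L,
                   mouse_id = 1L)
    }))
    agg <- suppressWarnings(aggregate_slit_density(recs, config$plan))
    env$slit <- recs
    write.csv(recs, file.path(outdir, "slit_fields.csv"), row.names = FALSE)
    write.csv(agg$per_glomerulus, file.path(outdir, "slit_per_glomerulus.csv"),
              row.names = FALSE)
    write.csv(agg$per_mouse, file.path(outdir, "slit_per_mouse.csv"),
              row.names = FALSE)
    list(rows = nrow(recs))
  })

  run_stage("assay", function() {
    sd0 <- stage_seed(config$seed, "assay")
    plate <- generate_plate(seed = sd0)
    curve <- standard_curve_fit(plate$standard_concentrations,
                                plate$standard_absorbances)
    conc <- curve$predict_concentration(plate$sample_absorbances)
    cm <- generate_count_matrix(n_cells = 300L, seed = sd0 + 1L)
    qc <- qc_filter(cm$counts, cm$gene_names)
    res <- data.frame(sample = seq_along(conc),
                      true_concentration = plate$sample_true_concentrations,
                      estimated_concentration = conc)
    write.csv(res, file.path(outdir, "assay_samples.csv"), row.names = FALSE)
    jsonlite::write_json(list(qc_pass = qc$n_pass,
                              qc_true_pass = cm$true_pass_count,
                              curve_slope = curve$slope,
                              curve_intercept = curve$intercept),
                         file.path(outdir, "assay_qc.json"),
                         auto_unbox = TRUE, digits = NA)
    list(rows = nrow(res), qc_pass = qc$n_pass)
  })

  run_stage("stats", function() {
    m <- env$morpho
    assert_that(!is.null(m) && nrow(m) >= 6,
                "stats stage needs morphometry output with >= 6 glomeruli")
    grp <- c("A", "B")[(m$scene %% 2) + 1]
    rep <- run_stats_battery(m$tuft_area_um2, grp, config$stats)
    write_stat_report(rep, file.path(outdir, "stats_tuft_area"))
    list(rows = nrow(rep$pairwise), branch = rep$branch)
  })

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
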
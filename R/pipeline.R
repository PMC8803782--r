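#' Pipeline configuration
#'
#' One serialisable object holding every stage's configuration, the cohort
#' sizes, the output directory and the global seed. A run's config + seed
#' reproduce its outputs bit-for-bit through the deterministic stages and
#' trace-for-trace through training. All defaults equal the published
#' pipeline values; [scaled_down()] shrinks the networks and epochs for
#' CPU-scale runs without altering pipeline semantics.
#'
#' @param out_dir working directory for all stage artifacts.
#' @param seed global RNG seed; every stage seed derives from it.
#' @param n_train,n_test scanner-1 cohort sizes.
#' @param n_ft_train,n_ft_test scanner-2 (transfer) cohort sizes; 0 skips
#'   the transfer arm.
#' @param phantom a [phantom_params()].
#' @param preprocess a [preprocess_config()].
#' @param candidate a [candidate_config()].
#' @param cube a [cube_config()].
#' @param nodes_per_patient TN convention for kappa.
#' @param threshold_sweep integer thresholds searched by `tune-threshold`.
#' @param tune_on cohort used to tune the aggregation threshold
#'   (`"train"`).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mediastinet_run_"),
                            seed = 1L, n_train = 12L, n_test = 6L,
                            n_ft_train = 0L, n_ft_test = 0L,
                            phantom = phantom_params(),
                            preprocess = preprocess_config(),
                            candidate = candidate_config(),
                            cube = cube_config(),
                            nodes_per_patient = 8.3,
                            threshold_sweep = 1:40,
                            tune_on = "train") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Shrink a pipeline config for CPU-scale runs
#'
#' Reduces network width/depth and epochs (and raises the learning rates
#' accordingly, since far fewer steps are taken); cube geometry, lattice,
#' label rules and every other pipeline semantic are unchanged.
#'
#' @param cfg a [pipeline_config()].
#' @return the modified config.
#' @export
scaled_down <- function(cfg = pipeline_config()) {
  cfg$candidate$base_width <- 2L
  cfg$candidate$levels <- 2L
  cfg$candidate$epochs <- 3L
  cfg$candidate$learning_rate <- 1e-3
  cfg$candidate$max_train_slices <- 160L
  cfg$cube$block <- "basic"
  cfg$cube$blocks <- c(1L, 1L)
  cfg$cube$widths <- c(4L, 8L)
  cfg$cube$stem_width <- 2L
  cfg$cube$epochs <- 3L
  cfg$cube$batch_size <- 8L
  cfg$cube$learning_rate <- 3e-3
  cfg$cube$finetune_learning_rate <- 3e-5
  cfg$cube$resnet_depth <- 2L + sum(cfg$cube$blocks) * 2L
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(rapply(cfg, f = function(x) x, how = "replace"), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (nm %in% c("phantom", "preprocess", "candidate", "cube")) {
      sub <- cfg[[nm]]
      for (k in names(raw[[nm]])) sub[[k]] <- simplify_field(raw[[nm]][[k]])
      cfg[[nm]] <- sub
    } else cfg[[nm]] <- simplify_field(raw[[nm]])
  }
  cfg
}

simplify_field <- function(x) if (is.list(x)) unlist(x) else x

config_checksum <- function(cfg) {
  f <- tempfile(); on.exit(unlink(f))
  saveRDS(rapply(cfg, unclass, how = "replace"), f, version = 2,
          compress = FALSE)
  unname(tools::md5sum(f))
}

# directory layout ---------------------------------------------------------

run_paths <- function(cfg) {
  o <- cfg$out_dir
  list(out = o,
       phantom = function(cohort) file.path(o, "phantom", cohort),
       preprocess = function(cohort) file.path(o, "preprocess", cohort),
       phase1 = file.path(o, "phase1"),
       phase1_pred = function(cohort) file.path(o, "phase1_pred", cohort),
       phase2 = file.path(o, "phase2"),
       predict = function(cohort) file.path(o, "predict", cohort),
       evaluate = file.path(o, "evaluate"),
       finetune = file.path(o, "finetune"),
       manifest = file.path(o, "manifest.json"))
}

pipeline_cohorts <- function(cfg) {
  coh <- list(train = list(n = cfg$n_train, scanner = "scanner1"),
              test = list(n = cfg$n_test, scanner = "scanner1"))
  if (cfg$n_ft_train > 0)
    coh$ft_train <- list(n = cfg$n_ft_train, scanner = "scanner2")
  if (cfg$n_ft_test > 0)
    coh$ft_test <- list(n = cfg$n_ft_test, scanner = "scanner2")
  coh
}

require_artifact <- function(path, needed_stage) {
  if (!file.exists(path))
    stop("run_stage: missing upstream artifact ", path,
         "; run stage '", needed_stage, "' first", call. = FALSE)
  invisible(path)
}

log_stage <- function(cfg, stage, msg)
  message(sprintf("[%s | cfg %s] %s", stage,
                  substr(config_checksum(cfg), 1, 8), msg))

manifest_add <- function(cfg, stage, t0, files) {
  p <- run_paths(cfg)
  man <- if (file.exists(p$manifest))
    jsonlite::read_json(p$manifest, simplifyVector = FALSE) else
      list(package_version = as.character(utils::packageVersion("mediastinet")),
           config_checksum = config_checksum(cfg), stages = list())
  files <- files[file.exists(files)]
  man$stages[[stage]] <- list(
    completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
    artifacts = as.list(setNames(unname(tools::md5sum(files)),
                                 sub(paste0("^", cfg$out_dir, "/?"), "",
                                     files))))
  jsonlite::write_json(man, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

# crop storage --------------------------------------------------------------

save_crop <- function(crop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, crop$patient_id)
  write_volume(crop$ct, paste0(stem, "_ct.nii"), datatype = "float")
  write_volume(crop$pet, paste0(stem, "_pet.nii"), datatype = "float")
  jsonlite::write_json(list(patient_id = crop$patient_id,
                            z_range = crop$z_range,
                            xy_offset = crop$xy_offset),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

load_crop <- function(dir, pid, stats = NULL) {
  stem <- file.path(dir, pid)
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  crop <- structure(list(
    ct = read_volume(paste0(stem, "_ct.nii"), "CT_HU"),
    pet = read_volume(paste0(stem, "_pet.nii"), "PET_SUV"),
    z_range = meta$z_range, xy_offset = meta$xy_offset,
    patient_id = meta$patient_id, nodes = NULL, standardised = FALSE),
    class = "thorax_crop")
  if (!is.null(stats)) crop <- apply_normalization(crop, stats)
  crop
}

cohort_patient_ids <- function(cfg, cohort) {
  p <- run_paths(cfg)
  man <- jsonlite::read_json(
    require_artifact(file.path(p$phantom(cohort), "manifest.json"),
                     "phantom"),
    simplifyVector = TRUE)
  man$patient_ids
}

cohort_nodes <- function(cfg, cohort) {
  p <- run_paths(cfg)
  nodes <- read_nodes(
    require_artifact(file.path(p$phantom(cohort),
                               "ground_truth_nodes.csv"), "phantom"))
  ids <- cohort_patient_ids(cfg, cohort)
  setNames(lapply(ids, function(pid)
    nodes[nodes$patient_id == pid, , drop = FALSE]), ids)
}

# stages --------------------------------------------------------------------

stage_phantom <- function(cfg) {
  p <- run_paths(cfg)
  cohorts <- pipeline_cohorts(cfg)
  seeds <- with_seed(cfg$seed, sample.int(1e9L, length(cohorts)))
  files <- character()
  for (i in seq_along(cohorts)) {
    nm <- names(cohorts)[i]
    man_f <- file.path(p$phantom(nm), "manifest.json")
    if (file.exists(man_f) &&
        jsonlite::read_json(man_f)$n_patients == cohorts[[nm]]$n &&
        jsonlite::read_json(man_f)$seed == seeds[i]) {
      log_stage(cfg, "phantom", sprintf("cohort %s already present", nm))
      files <- c(files, man_f,
                 file.path(p$phantom(nm), "ground_truth_nodes.csv"))
      next
    }
    prof <- scanner_profile(cohorts[[nm]]$scanner)
    cohort <- generate_cohort(cohorts[[nm]]$n, cfg$phantom, prof,
                              seed = seeds[i],
                              id_prefix = paste0(nm, "_", prof$id))
    write_cohort(cohort, p$phantom(nm))
    files <- c(files, file.path(p$phantom(nm),
                                c("manifest.json", "ground_truth_nodes.csv")))
    log_stage(cfg, "phantom", sprintf("cohort %s: %d patients, %d nodes",
                                      nm, cohorts[[nm]]$n,
                                      sum(vapply(cohort$scans,
                                                 function(s) nrow(s$nodes),
                                                 integer(1)))))
    rm(cohort); gc(FALSE)
  }
  files
}

stage_preprocess <- function(cfg) {
  p <- run_paths(cfg)
  files <- character()
  stats_path <- file.path(p$out, "preprocess", "stats.json")
  need_stats <- !file.exists(stats_path)
  acc <- list(ct = c(0, 0, 0), pet = c(0, 0, 0))   # n, sum, sumsq
  for (cohort in names(pipeline_cohorts(cfg))) {
    require_artifact(file.path(p$phantom(cohort), "manifest.json"),
                     "phantom")
    ids <- cohort_patient_ids(cfg, cohort)
    dir.create(p$preprocess(cohort), recursive = TRUE, showWarnings = FALSE)
    for (pid in ids) {
      have <- file.exists(file.path(p$preprocess(cohort),
                                    paste0(pid, "_meta.json")))
      if (have && !(cohort == "train" && need_stats)) next
      if (have) {
        crop <- load_crop(p$preprocess(cohort), pid)
      } else {
        scan <- list(
          patient_id = pid,
          ct = read_volume(file.path(p$phantom(cohort),
                                     paste0(pid, "_ct.nii")), "CT_HU"),
          pet = read_volume(file.path(p$phantom(cohort),
                                      paste0(pid, "_pet.nii")), "PET_SUV"),
          nodes = NULL)
        crop <- preprocess_scan(scan, cfg$preprocess)$crop
        save_crop(crop, p$preprocess(cohort))
        rm(scan)
      }
      if (cohort == "train" && need_stats) {
        for (mod in c("ct", "pet")) {
          v <- crop[[mod]]$values
          acc[[mod]] <- acc[[mod]] + c(length(v), sum(v), sum(v * v))
        }
      }
      rm(crop); gc(FALSE)
    }
    log_stage(cfg, "preprocess", sprintf("cohort %s: %d crops", cohort,
                                         length(ids)))
  }
  if (need_stats) {
    stats <- structure(list(
      ct_mean = acc$ct[2] / acc$ct[1],
      ct_sd = sqrt(max(acc$ct[3] / acc$ct[1] - (acc$ct[2] / acc$ct[1])^2,
                       0)),
      pet_mean = acc$pet[2] / acc$pet[1],
      pet_sd = sqrt(max(acc$pet[3] / acc$pet[1] -
                          (acc$pet[2] / acc$pet[1])^2, 0)),
      fitted_on = "train"), class = "norm_stats")
    if (stats$ct_sd <= 0 || stats$pet_sd <= 0)
      stop("preprocess: degenerate training data (zero variance)",
           call. = FALSE)
    write_normalization(stats, stats_path)
  }
  c(files, stats_path)
}

pipeline_stats <- function(cfg) {
  p <- run_paths(cfg)
  read_normalization(require_artifact(
    file.path(p$out, "preprocess", "stats.json"), "preprocess"))
}

stage_train_phase1 <- function(cfg) {
  p <- run_paths(cfg)
  stats <- pipeline_stats(cfg)
  ids <- cohort_patient_ids(cfg, "train")
  nodes <- cohort_nodes(cfg, "train")
  slices <- list()
  for (pid in ids) {
    crop <- load_crop(p$preprocess("train"), pid, stats)
    lab <- make_sphere_labels(nodes[[pid]], crop$ct,
                              cfg$candidate$sphere_radius)
    for (z in which(apply(lab, 3, function(s) any(s > 0L))))
      slices[[length(slices) + 1L]] <-
        list(x = crop_slice_input(crop, z), g = lab[, , z])
    rm(crop, lab); gc(FALSE)
  }
  model <- train_unet_slices(slices, cfg$candidate, seed = cfg$seed + 101L)
  dir.create(p$phase1, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(p$phase1, "model.rds"))
  write.csv(data.frame(epoch = seq_along(model$loss_trace),
                       dice_loss = model$loss_trace),
            file.path(p$phase1, "loss.csv"), row.names = FALSE)
  log_stage(cfg, "train-phase1",
            sprintf("%d slices, final Dice loss %.4f", length(slices),
                    tail(model$loss_trace, 1)))
  file.path(p$phase1, c("model.rds", "loss.csv"))
}

stage_predict_phase1 <- function(cfg, cohorts = NULL) {
  p <- run_paths(cfg)
  model <- readRDS(require_artifact(file.path(p$phase1, "model.rds"),
                                    "train-phase1"))
  stats <- pipeline_stats(cfg)
  files <- character()
  for (cohort in cohorts %||% names(pipeline_cohorts(cfg))) {
    ids <- cohort_patient_ids(cfg, cohort)
    nodes <- cohort_nodes(cfg, cohort)
    dir.create(p$phase1_pred(cohort), recursive = TRUE,
               showWarnings = FALSE)
    sens <- numeric(); n_nodes <- 0L
    for (pid in ids) {
      crop <- load_crop(p$preprocess(cohort), pid, stats)
      regions <- predict_candidates(crop, model, cfg$candidate)
      regions <- filter_and_dilate(regions, dim(crop$ct$values),
                                   cfg$candidate)
      write_detections(regions, crop$ct,
                       file.path(p$phase1_pred(cohort), pid))
      if (nrow(nodes[[pid]])) {
        s <- candidate_sensitivity(regions, nodes[[pid]], crop$ct)
        sens <- c(sens, s * nrow(nodes[[pid]]))
        n_nodes <- n_nodes + nrow(nodes[[pid]])
      }
      rm(crop, regions); gc(FALSE)
    }
    cov <- if (n_nodes) sum(sens) / n_nodes else NaN
    jsonlite::write_json(list(cohort = cohort,
                              candidate_sensitivity = cov,
                              n_nodes = n_nodes),
                         file.path(p$phase1_pred(cohort),
                                   "sensitivity.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(p$phase1_pred(cohort), "sensitivity.json"))
    log_stage(cfg, "predict-phase1",
              sprintf("cohort %s: candidate sensitivity %.3f over %d nodes",
                      cohort, cov, n_nodes))
  }
  files
}

load_cohort_dataset <- function(cfg, cohort) {
  p <- run_paths(cfg)
  stats <- pipeline_stats(cfg)
  ids <- cohort_patient_ids(cfg, cohort)
  nodes <- cohort_nodes(cfg, cohort)
  crops <- list(); regions <- list()
  for (pid in ids) {
    require_artifact(file.path(p$phase1_pred(cohort),
                               paste0(pid, ".nii.gz")), "predict-phase1")
    crops[[pid]] <- load_crop(p$preprocess(cohort), pid, stats)
    regs <- read_detections(file.path(p$phase1_pred(cohort),
                                      paste0(pid, ".nii.gz")))
    regions[[pid]] <- regs
  }
  cube_dataset(crops, regions, nodes, cfg$cube, stats)
}

stage_train_phase2 <- function(cfg) {
  p <- run_paths(cfg)
  ds <- load_cohort_dataset(cfg, "train")
  keep <- undersample_negatives(ds$items$label, cfg$cube$undersample_factor,
                                seed = cfg$seed + 202L)
  full_n <- nrow(ds$items)
  ds$items <- ds$items[keep, , drop = FALSE]
  model <- train_resnet(ds, cfg$cube, seed = cfg$seed + 203L)
  dir.create(p$phase2, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(p$phase2, "model.rds"))
  write.csv(ds$items, file.path(p$phase2, "training_cubes.csv"),
            row.names = FALSE)
  log_stage(cfg, "train-phase2",
            sprintf("%d cubes (%d positive) after undersampling %d; final loss %.4f",
                    nrow(ds$items), sum(ds$items$label), full_n,
                    tail(model$loss_trace, 1)))
  file.path(p$phase2, c("model.rds", "training_cubes.csv"))
}

predict_cohort <- function(cfg, cohort, model, threshold, out_dir) {
  p <- run_paths(cfg)
  stats <- pipeline_stats(cfg)
  ids <- cohort_patient_ids(cfg, cohort)
  nodes <- cohort_nodes(cfg, cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (pid in ids) {
    crop <- load_crop(p$preprocess(cohort), pid, stats)
    regs <- read_detections(require_artifact(
      file.path(p$phase1_pred(cohort), paste0(pid, ".nii.gz")),
      "predict-phase1"))
    ds <- cube_dataset(setNames(list(crop), pid),
                       setNames(list(regs), pid),
                       nodes[pid], cfg$cube, stats)
    probs <- if (nrow(ds$items)) predict_cubes(ds, model) else numeric()
    centres <- as.matrix(ds$items[, c("vx", "vy", "vz")])
    sm <- aggregate_scores(centres, probs, crop$ct, cfg$cube)
    pred <- positive_regions(sm, cfg$cube, threshold = threshold,
                             patient_id = pid)
    score_vol <- volume3d(sm$summed_score, sm$spacing, sm$origin)
    write_volume(score_vol, file.path(out_dir, paste0(pid, "_score.nii")),
                 datatype = "float")
    write_detections(pred, crop$ct, file.path(out_dir, pid))
    if (nrow(ds$items))
      manifest[[pid]] <- data.frame(patient_id = pid,
                                    x_mm = ds$items$x_mm,
                                    y_mm = ds$items$y_mm,
                                    z_mm = ds$items$z_mm,
                                    label = ds$items$label, prob = probs)
    rm(crop, regs, ds, sm, pred, score_vol); gc(FALSE)
  }
  man <- if (length(manifest))
    do.call(rbind, c(manifest, list(make.row.names = FALSE))) else
      data.frame(patient_id = character(), x_mm = numeric(),
                 y_mm = numeric(), z_mm = numeric(), label = integer(),
                 prob = numeric())
  write.csv(man, file.path(out_dir, "cubes.csv"), row.names = FALSE)
  invisible(out_dir)
}

stage_tune_threshold <- function(cfg) {
  p <- run_paths(cfg)
  model <- readRDS(require_artifact(file.path(p$phase2, "model.rds"),
                                    "train-phase2"))
  cohort <- cfg$tune_on
  out <- p$predict(cohort)
  predict_cohort(cfg, cohort, model, threshold = cfg$cube$agg_threshold,
                 out_dir = out)
  ids <- cohort_patient_ids(cfg, cohort)
  nodes <- cohort_nodes(cfg, cohort)
  scoremaps <- lapply(ids, function(pid) {
    v <- read_volume(file.path(out, paste0(pid, "_score.nii")))
    structure(list(summed_score = v$values, coverage = NULL,
                   dim = dim(v$values), spacing = v$spacing,
                   origin = v$origin), class = "scoremap")
  })
  names(scoremaps) <- ids
  thr <- tune_threshold(scoremaps, nodes, cfg$threshold_sweep)
  jsonlite::write_json(list(threshold = thr, tuned_on = cohort,
                            sweep = range(cfg$threshold_sweep)),
                       file.path(p$phase2, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(cfg, "tune-threshold", sprintf("selected threshold %d", thr))
  file.path(p$phase2, "threshold.json")
}

tuned_threshold <- function(cfg) {
  p <- run_paths(cfg)
  f <- file.path(p$phase2, "threshold.json")
  if (file.exists(f)) jsonlite::read_json(f)$threshold else
    cfg$cube$agg_threshold
}

#' Tune the aggregation threshold on a validation cohort
#'
#' Returns the integer threshold minimising FP + FN over the cohort; ties
#' are broken toward the larger threshold (fewer false positives).
#'
#' @param scoremaps named list (by patient) of `scoremap`s.
#' @param nodes_by_patient named list of `node_annotations`.
#' @param sweep integer candidate thresholds.
#' @return the selected integer threshold.
#' @export
tune_threshold <- function(scoremaps, nodes_by_patient, sweep = 1:40) {
  if (!length(sweep)) stop("tune_threshold: empty sweep", call. = FALSE)
  sweep <- sort(unique(as.integer(sweep)))
  cost <- setNames(numeric(length(sweep)), sweep)
  for (pid in names(scoremaps)) {
    sm <- scoremaps[[pid]]
    nodes <- nodes_by_patient[[pid]]
    vox <- NULL
    if (!is.null(nodes) && nrow(nodes)) {
      vox <- round(sweep(sweep(as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")]),
                               2, sm$origin, "-"),
                         2, sm$spacing, "/")) + 1
    }
    # label once at the lowest swept threshold; at higher thresholds the
    # positive set only shrinks, so every component can be swept
    # independently within its own bounding box
    base_lab <- label_components(.threshold_gt_cpp(sm$summed_score,
                                                   min(sweep) - 1e-9,
                                                   sm$dim))
    ncomp0 <- attr(base_lab, "n_components")
    n_nodes_here <- if (is.null(vox)) 0L else nrow(vox)
    node_lab <- integer(n_nodes_here)    # base component holding each node
    if (n_nodes_here) {
      for (r in seq_len(n_nodes_here)) {
        v <- vox[r, ]
        node_lab[r] <- if (all(v >= 1) && all(v <= sm$dim))
          base_lab[matrix(v, 1)] else 0L
      }
      cost <- cost + sum(node_lab == 0L)   # missed at every threshold
    }
    if (ncomp0 == 0L) next
    idx_all <- which(base_lab > 0L)
    ai <- arrayInd(idx_all, sm$dim)
    comp_of <- base_lab[idx_all]
    for (comp in seq_len(ncomp0)) {
      sel <- comp_of == comp
      lo <- c(min(ai[sel, 1]), min(ai[sel, 2]), min(ai[sel, 3]))
      hi <- c(max(ai[sel, 1]), max(ai[sel, 2]), max(ai[sel, 3]))
      sub <- sm$summed_score[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                             drop = FALSE]
      subdim <- dim(sub)
      my_nodes <- if (n_nodes_here) which(node_lab == comp) else integer()
      for (i in seq_along(sweep)) {
        lab <- label_components(.threshold_gt_cpp(sub, sweep[i], subdim))
        ncomp <- attr(lab, "n_components")
        hit <- integer(); fn <- 0L
        for (r in my_nodes) {
          v <- vox[r, ] - lo + 1L
          l <- if (all(v >= 1) && all(v <= subdim)) lab[matrix(v, 1)] else 0L
          if (l > 0L) hit <- c(hit, l) else fn <- fn + 1L
        }
        cost[i] <- cost[i] + (ncomp - length(unique(hit))) + fn
      }
    }
  }
  best <- max(sweep[cost == min(cost)])   # ties -> larger threshold
  as.integer(best)
}

stage_predict <- function(cfg, cohorts = "test", model = NULL,
                          subdir = NULL) {
  p <- run_paths(cfg)
  model <- model %||% readRDS(require_artifact(
    file.path(p$phase2, "model.rds"), "train-phase2"))
  thr <- tuned_threshold(cfg)
  out <- character()
  for (cohort in cohorts) {
    dir_out <- if (is.null(subdir)) p$predict(cohort) else
      file.path(p$out, "predict", subdir, cohort)
    predict_cohort(cfg, cohort, model, threshold = thr, out_dir = dir_out)
    log_stage(cfg, "predict", sprintf("cohort %s at threshold %s", cohort,
                                      thr))
    out <- c(out, file.path(dir_out, "cubes.csv"))
  }
  out
}

evaluate_predictions <- function(cfg, cohort, pred_dir) {
  ids <- cohort_patient_ids(cfg, cohort)
  nodes <- cohort_nodes(cfg, cohort)
  preds <- list(); geoms <- list()
  for (pid in ids) {
    f <- require_artifact(file.path(pred_dir, paste0(pid, ".nii.gz")),
                          "predict")
    vol <- read_volume(f)
    lab <- array(as.integer(round(vol$values)), dim(vol$values))
    preds[[pid]] <- labels_to_regions(lab, pid)
    geoms[[pid]] <- volume3d(array(0, dim(lab)), vol$spacing, vol$origin)
  }
  counts <- match_detections(preds, nodes, geoms)
  evaluate_cohort(counts, cfg$nodes_per_patient)
}

stage_evaluate <- function(cfg, cohort = "test") {
  p <- run_paths(cfg)
  summary <- evaluate_predictions(cfg, cohort, p$predict(cohort))
  dir.create(p$evaluate, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(p$evaluate, paste0("summary_", cohort, ".json"))
  write_eval_summary(summary, out)
  writeLines(as_report(summary),
             file.path(p$evaluate, paste0("summary_", cohort, ".txt")))
  log_stage(cfg, "evaluate", sprintf(
    "cohort %s: sensitivity %.2f, %.2f FPs/patient", cohort,
    summary$sensitivity, summary$fps_per_patient))
  out
}

stage_fine_tune <- function(cfg, seed = NULL) {
  p <- run_paths(cfg)
  if (cfg$n_ft_train < 1)
    stop("fine-tune: no scanner-2 training cohort configured",
         call. = FALSE)
  base <- readRDS(require_artifact(file.path(p$phase2, "model.rds"),
                                   "train-phase2"))
  ds <- load_cohort_dataset(cfg, "ft_train")
  keep <- undersample_negatives(ds$items$label, cfg$cube$undersample_factor,
                                seed = (seed %||% cfg$seed) + 301L)
  ds$items <- ds$items[keep, , drop = FALSE]
  tuned <- fine_tune(base, ds, cfg$cube, seed = (seed %||% cfg$seed) + 302L)
  dir.create(p$finetune, recursive = TRUE, showWarnings = FALSE)
  saveRDS(tuned, file.path(p$finetune, "model.rds"))
  log_stage(cfg, "fine-tune", sprintf("fine-tuned on %d cubes",
                                      nrow(ds$items)))
  file.path(p$finetune, "model.rds")
}

#' Run one pipeline stage
#'
#' Stages (in order): `phantom`, `preprocess`, `train-phase1`,
#' `predict-phase1`, `train-phase2`, `tune-threshold`, `predict`,
#' `evaluate`, `fine-tune`. Each stage writes exactly its own artifacts
#' under the config's `out_dir` (write-once: no stage mutates upstream
#' outputs), updates the run manifest, and fails with a dependency error
#' naming the stage to run first when upstream artifacts are missing.
#'
#' @param stage stage name.
#' @param cfg a [pipeline_config()].
#' @return the stage's artifact paths, invisibly.
#' @export
run_stage <- function(stage, cfg) {
  t0 <- as.numeric(Sys.time())
  files <- switch(
    stage,
    "phantom" = stage_phantom(cfg),
    "preprocess" = stage_preprocess(cfg),
    "train-phase1" = stage_train_phase1(cfg),
    "predict-phase1" = stage_predict_phase1(cfg),
    "train-phase2" = stage_train_phase2(cfg),
    "tune-threshold" = stage_tune_threshold(cfg),
    "predict" = stage_predict(cfg),
    "evaluate" = stage_evaluate(cfg),
    "fine-tune" = stage_fine_tune(cfg),
    stop("run_stage: unknown stage '", stage, "'", call. = FALSE))
  manifest_add(cfg, stage, t0, files)
  invisible(files)
}

#' Run the full pipeline
#'
#' Executes the stages in order on the configured cohorts: phantom
#' generation, preprocessing, phase-one training and prediction, phase-two
#' training, threshold tuning on the tuning cohort, prediction and
#' node-level evaluation of the test cohort; when transfer cohorts are
#' configured, it also evaluates the scanner-2 test cohort without transfer
#' learning, fine-tunes on the scanner-2 training cohort and re-evaluates.
#'
#' @param cfg a [pipeline_config()].
#' @return named list of `eval_summary` objects (`test`, and `ft_no_tl` /
#'   `ft_tl` when the transfer arm is configured).
#' @export
run_all <- function(cfg) {
  run_stage("phantom", cfg)
  run_stage("preprocess", cfg)
  run_stage("train-phase1", cfg)
  run_stage("predict-phase1", cfg)
  run_stage("train-phase2", cfg)
  run_stage("tune-threshold", cfg)
  run_stage("predict", cfg)
  run_stage("evaluate", cfg)
  p <- run_paths(cfg)
  out <- list(test = evaluate_predictions(cfg, "test", p$predict("test")))
  if (cfg$n_ft_train > 0 && cfg$n_ft_test > 0) {
    base <- readRDS(file.path(p$phase2, "model.rds"))
    stage_predict(cfg, cohorts = "ft_test", model = base,
                  subdir = "no_tl")
    out$ft_no_tl <- evaluate_predictions(
      cfg, "ft_test", file.path(p$out, "predict", "no_tl", "ft_test"))
    run_stage("fine-tune", cfg)
    tuned <- readRDS(file.path(p$finetune, "model.rds"))
    stage_predict(cfg, cohorts = "ft_test", model = tuned, subdir = "tl")
    out$ft_tl <- evaluate_predictions(
      cfg, "ft_test", file.path(p$out, "predict", "tl", "ft_test"))
    write_eval_summary(out$ft_no_tl,
                       file.path(p$evaluate, "summary_ft_no_tl.json"))
    write_eval_summary(out$ft_tl,
                       file.path(p$evaluate, "summary_ft_tl.json"))
  }
  out
}
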
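# Shared end-to-end phantom experiment, run once per test session and
# reused by the tests that assert on it. Disk-backed via the pipeline
# stages, so memory stays bounded.

.acceptance_env <- new.env(parent = emptyenv())

acceptance_config <- function() {
  scaled_down(pipeline_config(
    out_dir = file.path(tempdir(), "mediastinet_acceptance"),
    seed = 7L, n_train = 12L, n_test = 6L))
}

# scanner-1 experiment: 12 training + 6 test phantoms, shrunken networks
acceptance_run <- function() {
  if (!is.null(.acceptance_env$run)) return(.acceptance_env$run)
  cfg <- acceptance_config()
  t0 <- Sys.time()
  res <- run_all(cfg)
  elapsed_min <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
  p <- mediastinet:::run_paths(cfg)
  phase1 <- lapply(c(train = "train", test = "test"), function(coh)
    jsonlite::read_json(file.path(p$phase1_pred(coh), "sensitivity.json"),
                        simplifyVector = TRUE))
  .acceptance_env$run <- list(cfg = cfg, res = res,
                              elapsed_min = elapsed_min, phase1 = phase1)
  .acceptance_env$run
}

# scanner-2 transfer experiment on top of the scanner-1 run: 6 fine-tune +
# 6 held-out phantoms, fine-tuned over several seeds
acceptance_transfer <- function(seeds = c(101L, 102L, 103L)) {
  if (!is.null(.acceptance_env$transfer)) return(.acceptance_env$transfer)
  base_run <- acceptance_run()
  cfg <- base_run$cfg
  cfg$n_ft_train <- 6L
  cfg$n_ft_test <- 6L
  run_stage("phantom", cfg)      # scanner-1 cohorts already on disk
  run_stage("preprocess", cfg)
  mediastinet:::stage_predict_phase1(cfg, cohorts = c("ft_train",
                                                      "ft_test"))
  p <- mediastinet:::run_paths(cfg)
  base_model <- readRDS(file.path(p$phase2, "model.rds"))
  eval_with <- function(model, subdir) {
    mediastinet:::stage_predict(cfg, cohorts = "ft_test", model = model,
                                subdir = subdir)
    mediastinet:::evaluate_predictions(
      cfg, "ft_test", file.path(cfg$out_dir, "predict", subdir, "ft_test"))
  }
  no_tl <- eval_with(base_model, "acc_no_tl")
  tl <- lapply(seeds, function(s) {
    mediastinet:::stage_fine_tune(cfg, seed = s)
    eval_with(readRDS(file.path(p$finetune, "model.rds")),
              paste0("acc_tl_", s))
  })
  .acceptance_env$transfer <- list(
    cfg = cfg, no_tl = no_tl, tl = tl,
    sens_no_tl = no_tl$sensitivity,
    sens_tl = vapply(tl, `[[`, numeric(1), "sensitivity"))
  .acceptance_env$transfer
}
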
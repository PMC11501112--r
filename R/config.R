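# Run configuration (YAML) parsing/validation and pipeline orchestration.
#
# A run config is a YAML file with sections: `seed`, `paths`, `optical`,
# `mask`, `synth`, `train`, `eval`, `robustness`. The optical block may
# name an objective preset ("mitutoyo50x", "rms20x", "rms4x") or give
# explicit parameters; validation re-checks every module-level invariant
# and reports all violations at once, not just the first.

config_defaults <- function() {
  list(
    seed = 1L,
    paths = list(data_dir = "data", out_dir = "out"),
    optical = list(preset = "mitutoyo50x", dof_half_range = 100e-6,
                   grid_size = 64L, wavelength = 550e-9),
    mask = list(type = "free", init_phase_sd = 0.1, refractive_index = 1.5),
    synth = list(n_train = 8L, n_val = 2L, n_test = 2L, image_size = 256L),
    train = list(n_depths = 5L, lr_optics = 1e-7, lr_network = 1e-4,
                 stage1_steps = 200L, joint_steps = 300L, patch_size = 64L,
                 sigma_s = 0.01, psf_size = 33L),
    eval = list(n_depths = 5L, sigma_s = 0.01),
    robustness = list(sigma_levels_nm = c(0, 30, 50), n_trials = 10L)
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Validate a run configuration file
#'
#' Reads the YAML, fills defaults, resolves objective presets and checks
#' every invariant, collecting all violations (with their key paths)
#' before failing. Unknown top-level keys produce warnings only.
#'
#' @param path YAML config path, or a list already in config shape.
#' @return a validated `run_config` with resolved `system`
#'   ([optical_system()]) and `depth_spec` attached.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
  }
  cfg <- merge_config(defaults, user[intersect(names(user), names(defaults))])
  errs <- character()
  bad <- function(key, msg) errs <<- c(errs, sprintf("%s: %s", key, msg))

  opt <- cfg$optical
  if (!is.null(opt$preset)) {
    p <- tryCatch(objective_preset(opt$preset), error = function(e) NULL)
    if (is.null(p)) bad("optical.preset", paste("unknown preset", opt$preset))
    else {
      for (f in c("pupil_diameter", "z0", "na", "tube_focal_length")) {
        if (is.null(opt[[f]])) opt[[f]] <- p[[f]]
      }
    }
  }
  for (f in c("wavelength", "pupil_diameter", "z0", "tube_focal_length")) {
    if (is.null(opt[[f]]) || !is.numeric(opt[[f]]) || opt[[f]] <= 0) {
      bad(paste0("optical.", f), "must be a positive length in meters")
    }
  }
  if (is.null(opt$grid_size) || opt$grid_size < 16) {
    bad("optical.grid_size", "must be an integer >= 16")
  }
  if (is.null(opt$dof_half_range) || opt$dof_half_range <= 0 ||
      (!is.null(opt$z0) && is.numeric(opt$z0) &&
       opt$dof_half_range >= opt$z0)) {
    bad("optical.dof_half_range", "must be in (0, z0)")
  }
  if (!cfg$mask$type %in% c("free", "doe", "cubic")) {
    bad("mask.type", "must be one of free, doe, cubic")
  }
  tr <- cfg$train
  if (tr$n_depths < 1) bad("train.n_depths", "must be >= 1")
  if (tr$lr_optics < 0) bad("train.lr_optics", "must be >= 0")
  if (tr$lr_network <= 0) bad("train.lr_network", "must be > 0")
  if (tr$patch_size %% 16 != 0) {
    bad("train.patch_size", "must be a multiple of 16")
  }
  if (tr$sigma_s < 0) bad("train.sigma_s", "must be >= 0")
  if (any(cfg$robustness$sigma_levels_nm < 0)) {
    bad("robustness.sigma_levels_nm", "must be >= 0")
  }
  if (cfg$synth$image_size < 256) bad("synth.image_size", "must be >= 256")
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  cfg$optical <- opt
  cfg$system <- optical_system(opt$wavelength, opt$tube_focal_length,
                               opt$z0, opt$pupil_diameter,
                               grid_size = opt$grid_size, na = opt$na)
  cfg$depth_spec <- depth_spec(opt$z0 - opt$dof_half_range,
                               opt$z0 + opt$dof_half_range, opt$z0,
                               tr$n_depths)
  class(cfg) <- "run_config"
  cfg
}

init_mask_from_config <- function(cfg) {
  n <- cfg$system$grid_size
  switch(cfg$mask$type,
    free = free_phase_mask(with_local_seed(derive_seed(cfg$seed, "mask"), {
      matrix(stats::rnorm(n^2, 0, cfg$mask$init_phase_sd), n)
    }) * aperture_amplitude(cfg$system)),
    doe = {
      k <- wavenumber(cfg$system$wavelength)
      ph <- with_local_seed(derive_seed(cfg$seed, "mask"), {
        matrix(abs(stats::rnorm(n^2, 0, cfg$mask$init_phase_sd)), n)
      })
      doe_mask(ph / (k * (cfg$mask$refractive_index - 1)),
               cfg$mask$refractive_index)
    },
    cubic = cubic_mask(cubic_alpha_for_dof(2 * cfg$optical$dof_half_range), n)
  )
}

write_sidecar <- function(path, cfg, extra = list()) {
  meta <- c(list(config_hash = content_hash(unclass(cfg)), seed = cfg$seed),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the processing pipeline
#'
#' Executes the requested stages in canonical order
#' (synth, design, train, eval, robustness), writing artifacts (and JSON
#' sidecars embedding the config hash and seed) to `paths$out_dir`.
#' A stage whose primary artifact already exists is skipped unless
#' `force` is TRUE.
#'
#' @param config a validated `run_config` (see [validate_config()]) or a
#'   path to a YAML config.
#' @param stages character vector of stages to run.
#' @param force re-run stages whose outputs exist.
#' @param quiet suppress progress messages.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "design", "train", "eval"),
                         force = FALSE, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  order <- c("synth", "design", "train", "eval", "robustness")
  stages <- order[order %in% stages]
  out <- cfg$paths$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  artifacts <- list()

  if ("synth" %in% stages) {
    manifest <- file.path(cfg$paths$data_dir, "manifest.csv")
    if (file.exists(manifest) && !force) say("synth: exists, skipping")
    else {
      say("synth: generating dataset")
      generate_split(cfg$paths$data_dir, cfg$synth$n_train, cfg$synth$n_val,
                     cfg$synth$n_test, seed = derive_seed(cfg$seed, "synth"),
                     image_size = cfg$synth$image_size)
      write_sidecar(file.path(cfg$paths$data_dir, "manifest.json"), cfg)
    }
    artifacts$synth <- manifest
  }

  if ("design" %in% stages) {
    fp <- file.path(out, "design.csv")
    if (file.exists(fp) && !force) say("design: exists, skipping")
    else {
      row <- design_row(cfg$optical, cfg$optical$dof_half_range,
                        cfg$optical$wavelength)
      utils::write.csv(row, fp, row.names = FALSE)
      write_sidecar(file.path(out, "design.json"), cfg)
      say(sprintf("design: psi_max %.2f, pitch bound %.3g um",
                  row$psi_max, row$max_pitch_um))
    }
    artifacts$design <- fp
  }

  if ("train" %in% stages) {
    ck_path <- file.path(out, "checkpoint.rds")
    if (file.exists(ck_path) && !force) say("train: exists, skipping")
    else {
      images <- load_split(cfg$paths$data_dir, "train")
      tc <- train_config(cfg$depth_spec, cfg$train$lr_optics,
                         cfg$train$lr_network, cfg$train$stage1_steps,
                         cfg$train$joint_steps, cfg$train$patch_size,
                         cfg$train$sigma_s, seed = cfg$seed,
                         psf_size = cfg$train$psf_size)
      mask <- init_mask_from_config(cfg)
      net <- build_network(seed = derive_seed(cfg$seed, "net"))
      say("train: stage 1 (network only)")
      s1 <- train_stage1(tc, cfg$system, mask, net, images)
      say("train: joint optimization")
      s2 <- train_joint(tc, cfg$system, mask, s1$net, images)
      save_checkpoint(s2$net, ck_path, mask = s2$mask)
      utils::write.csv(
        data.frame(step = seq_along(c(s1$loss, s2$loss)),
                   stage = rep(c("stage1", "joint"),
                               c(length(s1$loss), length(s2$loss))),
                   loss = c(s1$loss, s2$loss)),
        file.path(out, "loss.csv"), row.names = FALSE)
      write_sidecar(file.path(out, "checkpoint.json"), cfg)
    }
    artifacts$train <- ck_path
  }

  if ("eval" %in% stages || "robustness" %in% stages) {
    ck <- load_checkpoint(file.path(out, "checkpoint.rds"))
    test_images <- load_split(cfg$paths$data_dir, "test")
    depths <- sample_depths(depth_spec(cfg$depth_spec$z_min,
                                       cfg$depth_spec$z_max,
                                       cfg$depth_spec$z0,
                                       cfg$eval$n_depths))
  }

  if ("eval" %in% stages) {
    fp <- file.path(out, "metrics.csv")
    if (file.exists(fp) && !force) say("eval: exists, skipping")
    else {
      rep <- evaluate_depths(cfg$system, ck$mask, ck$net, test_images,
                             depths, patch_size = cfg$train$patch_size,
                             sigma_s = cfg$eval$sigma_s,
                             seed = derive_seed(cfg$seed, "eval"),
                             psf_size = cfg$train$psf_size)
      utils::write.csv(rep$per_depth, fp, row.names = FALSE)
      jsonlite::write_json(list(mean_psnr = rep$mean_psnr,
                                mean_ssim = rep$mean_ssim),
                           file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      write_sidecar(file.path(out, "metrics.sidecar.json"), cfg)
      say(sprintf("eval: mean PSNR %.2f dB, SSIM %.3f",
                  rep$mean_psnr, rep$mean_ssim))
    }
    artifacts$eval <- fp
  }

  if ("robustness" %in% stages) {
    fp <- file.path(out, "robustness.csv")
    if (file.exists(fp) && !force) say("robustness: exists, skipping")
    else {
      fmask <- as_doe_mask(ck$mask, cfg$system, cfg$mask$refractive_index)
      rs <- robustness_spec(cfg$robustness$sigma_levels_nm * 1e-9,
                            cfg$robustness$n_trials,
                            seed = derive_seed(cfg$seed, "robust"))
      tab <- fabrication_robustness(fmask, rs, cfg$system, ck$net,
                                    test_images, depths,
                                    patch_size = cfg$train$patch_size,
                                    sigma_s = cfg$eval$sigma_s,
                                    psf_size = cfg$train$psf_size)
      utils::write.csv(tab, fp, row.names = FALSE)
      write_sidecar(file.path(out, "robustness.json"), cfg)
    }
    artifacts$robustness <- fp
  }

  invisible(artifacts)
}
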
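#' Pipeline configuration
#'
#' One global seed deterministically derives every stage seed (phantom
#' generation, network init, data order, anomaly geometry, SVM bandwidth
#' subsample), so a re-run with the same config reproduces all outputs.
#' Configurations can be read from YAML with [read_pipeline_config()].
#'
#' @param benchmark a [benchmark_config()] describing data sizes and models.
#' @param boundary_stride stride (A-scans) of the demo boundary trace.
#' @param seed global integer seed (overrides `benchmark$seed`).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(benchmark = benchmark_config(), boundary_stride = 8L,
                            seed = 1L) {
  benchmark$seed <- as.integer(seed)
  structure(list(benchmark = benchmark,
                 boundary_stride = as.integer(boundary_stride),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with fields mirroring the constructor arguments
#'   (`seed`, `boundary_stride`, and a `benchmark` block whose entries are
#'   passed to [benchmark_config()]; its optional `phantom` block is passed
#'   to [phantom_params()]).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  bm_args <- y$benchmark %||% list()
  if (!is.null(bm_args$phantom))
    bm_args$phantom <- do.call(phantom_params, bm_args$phantom)
  pipeline_config(benchmark = do.call(benchmark_config, bm_args),
                  boundary_stride = y$boundary_stride %||% 8L,
                  seed = y$seed %||% 1L)
}

cheap_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", as.integer(sum(v * (seq_along(v) %% 251 + 1)) %% 2147483629))
}

#' Run the end-to-end pipeline and write artifacts to disk
#'
#' Stages: phantom generation (sample TIFFs), segmentation-network training
#' (checkpoint), benchmark evaluation (features CSV, report JSON), and a
#' boundary-detection demo on a half-normal / half-DEJ-disrupted composite
#' (trace CSV + BED-like boundary file). A manifest JSON records every
#' artifact with the stage seeds and config hash. The U-Net checkpoint is
#' cached: re-running with the same config resumes from it.
#'
#' @param config a [pipeline_config()].
#' @param out_dir writable output directory (created if missing).
#' @param verbose print stage progress?
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop_input("run_pipeline: output directory not writable: ", out_dir)
  bm <- config$benchmark
  cfg_hash <- cheap_hash(unclass(config))
  manifest <- list(config_hash = cfg_hash, seed = config$seed, artifacts = list())
  add <- function(stage, path) {
    manifest$artifacts[[length(manifest$artifacts) + 1]] <<-
      list(stage = stage, path = basename(path))
  }

  # Stage 1: a couple of sample phantoms on disk (the benchmark regenerates
  # its own internally from the same seeds).
  say("pipeline: phantom samples")
  sample_data <- generate_dataset(bm$phantom, 2, seed = derive_seed(bm$seed, 1L))
  for (i in seq_along(sample_data)) {
    ip <- file.path(out_dir, sprintf("phantom_%02d.tiff", i))
    mp <- file.path(out_dir, sprintf("phantom_%02d_mask.tiff", i))
    write_oct_tiff(sample_data[[i]]$image, ip, params = unclass(bm$phantom))
    write_mask_tiff(sample_data[[i]]$mask, mp)
    add("phantom", ip); add("phantom", mp)
  }

  # Stage 2: segmentation network (cached by config hash).
  ckpt <- file.path(out_dir, "unet_checkpoint.rds")
  segmenter <- NULL
  if (file.exists(ckpt)) {
    cached <- load_unet(ckpt)
    if (identical(cached$provenance$config_hash, cfg_hash)) {
      say("pipeline: reusing cached U-Net checkpoint")
      segmenter <- cached
    }
  }
  if (is.null(segmenter)) {
    say("pipeline: training U-Net")
    data <- generate_dataset(bm$phantom, max(2L, ceiling(bm$n_seg_train / 32)),
                             seed = derive_seed(bm$seed, 8L))
    patches <- list(); masks <- list()
    for (d in data) {
      patches <- c(patches, split_into_patches(d$image))
      masks <- c(masks, split_into_patches(d$mask))
    }
    keep <- with_seed(derive_seed(bm$seed, 9L),
                      sample.int(length(patches),
                                 min(bm$n_seg_train, length(patches))))
    segmenter <- build_unet(unet_config(), seed = derive_seed(bm$seed, 4L))
    segmenter <- train_unet(segmenter, patches[keep], masks[keep],
                            train_config(batch_size = bm$seg_batch,
                                         epochs = bm$seg_epochs,
                                         seed = derive_seed(bm$seed, 5L)))
    segmenter$provenance$config_hash <- cfg_hash
    save_unet(segmenter, ckpt)
  }
  add("segmentation", ckpt)

  # Stage 3: benchmark evaluation with the trained segmenter.
  say("pipeline: benchmark")
  report <- run_benchmark(bm, segmenter = segmenter, verbose = verbose)
  rp <- file.path(out_dir, "eval_report.json")
  write_eval_report(report, rp)
  add("evaluation", rp)

  # Stage 4: one-class SVM on normal training features, persisted, plus a
  # boundary demo on a composite image.
  say("pipeline: boundary demo")
  demo <- generate_phantom(do.call(phantom_params, utils::modifyList(
    unclass(bm$phantom), list(image_width = 1024L,
                              rng_seed = derive_seed(bm$seed, 10L)))))
  half <- 512L
  dej_img <- synthesize_dej_disruption(demo$image)
  comp <- as.matrix(demo$image)
  comp[, (half + 1):1024] <- as.matrix(dej_img)[, (half + 1):1024]
  comp <- oct_image(comp)

  train_data <- generate_dataset(bm$phantom, 4, seed = derive_seed(bm$seed, 11L))
  train_patches <- unlist(lapply(train_data, function(d)
    split_into_patches(d$image)), recursive = FALSE)
  train_mat <- featurize_set(segmenter, train_patches, "e_and_d")$e_and_d$mat
  svm <- train_ocsvm(train_mat, ocsvm_config(nu = bm$nu,
                                             seed = derive_seed(bm$seed, 7L)))
  sp <- file.path(out_dir, "ocsvm_model.rds")
  save_ocsvm(svm, sp); add("classifier", sp)
  fp <- file.path(out_dir, "train_features.csv")
  write_features_csv(train_mat, "e_and_d", fp); add("features", fp)

  tr <- denoise_trace(score_trace(svm, segmenter, comp,
                                  stride = config$boundary_stride))
  normal_tr <- denoise_trace(score_trace(svm, segmenter, demo$image,
                                         stride = config$boundary_stride))
  mj <- calibrate_min_jump(list(normal_tr))
  bounds <- detect_boundary(tr, mj)
  tp <- file.path(out_dir, "boundary_trace.csv")
  bp <- file.path(out_dir, "boundaries.bed")
  export_trace(tr, bounds, csv_path = tp, bed_path = bp)
  add("boundary", tp); add("boundary", bp)

  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  say("pipeline: done (%d artifacts)", length(manifest$artifacts))
  invisible(manifest)
}
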
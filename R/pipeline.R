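# Orchestration: one config drives generate -> train -> reveal -> model the
# concept -> evaluate -> revise -> re-evaluate, with stage outputs persisted
# on disk and cached by a content hash of the config subsections.

#' Build a pipeline configuration
#'
#' @param dataset list: `type` (`"image"`/`"signal"`), `n_per_class`,
#'   `image_size`/`length`/`channels`, `class_count`, `artifact` (an
#'   [artifact_spec()] or list of its arguments), `seed`.
#' @param model list: `arch`, `epochs`, `batch_size`, `learning_rate`, `seed`.
#' @param concept list: `layer` (or `layers` for sweeps), `method`
#'   (`"svm"`/`"pattern"`), `pooling`.
#' @param revise list: `method` (`"rrr"`, `"rr_clarc"`, `"p_clarc"`,
#'   `"rp_clarc"`, or `"none"`), `lambda`, `epochs`, `z0_policy`, `threshold`.
#' @param reveal list: `enabled`, `methods`.
#' @param out_dir output directory for stage artifacts.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(dataset = list(), model = list(), concept = list(),
                            revise = list(), reveal = list(), out_dir = tempfile("biaslens-")) {
  cfg <- list(
    dataset = utils::modifyList(list(
      type = "image", n_per_class = 60L, image_size = 32L, length = 128L,
      channels = 3L, class_count = 2L, seed = 1L,
      artifact = list(kind = "corner_patch", insertion_rate_p = 0.8,
                      target_class = 1L)), dataset),
    model = utils::modifyList(list(
      arch = NULL, epochs = 12L, batch_size = 32L, learning_rate = 3e-3,
      seed = 1L), model),
    concept = utils::modifyList(list(
      layer = "pool3", method = "svm", pooling = "max_spatial"), concept),
    revise = utils::modifyList(list(
      method = "none", lambda = 2, epochs = 6L, z0_policy = "clean_mean",
      threshold = NULL), revise),
    reveal = utils::modifyList(list(enabled = FALSE,
                                    methods = c("spray_latent", "concept_lof")), reveal),
    out_dir = out_dir)
  if (is.null(cfg$model$arch))
    cfg$model$arch <- if (cfg$dataset$type == "image") "cnn2d_small" else "cnn1d_small"
  if (!cfg$revise$method %in% c("none", "rrr", "rr_clarc", "p_clarc", "rp_clarc"))
    stop("unknown revise method: ", cfg$revise$method)
  # validation-first: the concept layer must exist in the chosen architecture
  probe <- build_model(cfg$model$arch, cfg$dataset$class_count, seed = 1L,
                       input_shape = pipeline_input_shape(cfg))
  for (ly in unique(c(cfg$concept$layer, cfg$concept$layers)))
    layer_index(probe, ly)
  structure(cfg, class = "pipeline_config")
}

pipeline_input_shape <- function(cfg) {
  if (cfg$dataset$type == "image") c(cfg$dataset$image_size, cfg$dataset$image_size, 1L)
  else c(cfg$dataset$length, cfg$dataset$channels)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with `dataset` / `model` / `concept` / `revise` /
#'   `reveal` sections.
#' @param out_dir overrides the config's output directory when given.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  pipeline_config(dataset = y$dataset %||% list(), model = y$model %||% list(),
                  concept = y$concept %||% list(), revise = y$revise %||% list(),
                  reveal = y$reveal %||% list(),
                  out_dir = out_dir %||% y$out_dir %||% tempfile("biaslens-"))
}

cfg_artifact_spec <- function(cfg) {
  a <- cfg$dataset$artifact
  if (inherits(a, "artifact_spec")) return(a)
  do.call(artifact_spec, c(a, list(seed = cfg$dataset$seed)))
}

pipeline_bundle <- function(cfg) {
  spec <- cfg_artifact_spec(cfg)
  if (cfg$dataset$type == "image") {
    generate_image_dataset(cfg$dataset$n_per_class, cfg$dataset$image_size,
                           cfg$dataset$class_count, spec, cfg$dataset$seed)
  } else {
    generate_signal_dataset(cfg$dataset$n_per_class, cfg$dataset$length,
                            cfg$dataset$channels, spec, cfg$dataset$seed,
                            class_count = cfg$dataset$class_count)
  }
}

#' Run the full audit-and-revise pipeline
#'
#' Executes the stages in order -- generate data, train the (vanilla) model,
#' optionally run bias identification, fit the artifact CAV from ground-truth
#' flags, evaluate, apply the configured mitigation, re-evaluate -- writing
#' each stage's outputs (checkpoints, CAV JSON, reports) under
#' `cfg$out_dir`. Stages whose config subsection hash matches a previous run
#' are loaded from disk instead of recomputed.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `bundle`, `model`, `cav`, `report_before`,
#'   `report_after` (NULL when `revise$method == "none"`), `revised_model`,
#'   `reveal`, and `summary` (a tibble with one row per evaluated model).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  key_data <- rlang::hash(cfg$dataset)
  bundle <- pipeline_bundle(cfg)   # cheap + deterministic; no caching needed
  key_model <- rlang::hash(list(cfg$dataset, cfg$model))
  ckpt <- file.path(cfg$out_dir, "vanilla.json")
  keyfile <- file.path(cfg$out_dir, "vanilla.key")
  if (file.exists(ckpt) && file.exists(keyfile) &&
      identical(readLines(keyfile, warn = FALSE), key_model)) {
    model <- load_checkpoint(ckpt)
  } else {
    model <- build_model(cfg$model$arch, cfg$dataset$class_count,
                         seed = cfg$model$seed,
                         input_shape = pipeline_input_shape(cfg))
    model <- train_model(model, bundle, train_config(
      epochs = cfg$model$epochs, batch_size = cfg$model$batch_size,
      learning_rate = cfg$model$learning_rate, seed = cfg$model$seed))
    log <- attr(model, "training_log")
    save_checkpoint(model, ckpt)
    writeLines(key_model, keyfile)
    utils::write.csv(log, file.path(cfg$out_dir, "training-log.csv"), row.names = FALSE)
  }
  reveal_out <- NULL
  if (isTRUE(cfg$reveal$enabled)) {
    reveal_out <- reveal_bias(model, bundle, cfg$concept$layer,
                              methods = cfg$reveal$methods,
                              seed = cfg$model$seed)
  }
  cav <- pipeline_cav(model, bundle, cfg$concept$layer, cfg$concept$method,
                      cfg$concept$pooling)
  write_cav(cav, file.path(cfg$out_dir, "cav.json"))
  report_before <- evaluation_report(model, bundle, cav)
  write_report(report_before, file.path(cfg$out_dir, "report-before.json"), "vanilla")
  revised <- NULL; report_after <- NULL
  if (cfg$revise$method != "none") {
    revised <- revise_model(model, bundle, cav, cfg)
    save_checkpoint(revised, file.path(cfg$out_dir, "revised.json"))
    report_after <- evaluation_report(revised, bundle, cav)
    write_report(report_after, file.path(cfg$out_dir, "report-after.json"),
                 cfg$revise$method)
  }
  summary <- rbind(report_row(report_before, "vanilla"),
                   if (!is.null(report_after)) report_row(report_after, cfg$revise$method))
  utils::write.csv(summary, file.path(cfg$out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(config_hash = rlang::hash(unclass(cfg))),
                       file.path(cfg$out_dir, "run.json"), auto_unbox = TRUE)
  list(bundle = bundle, model = model, cav = cav, reveal = reveal_out,
       report_before = report_before, report_after = report_after,
       revised_model = revised, summary = summary)
}

#' Fit the artifact CAV on a bundle's training split (ground-truth flags)
#' @param model a `split_model`.
#' @param bundle a `dataset_bundle`.
#' @param layer CAV layer.
#' @param method `"svm"` or `"pattern"`.
#' @param pooling pooling mode.
#' @export
pipeline_cav <- function(model, bundle, layer, method = "svm",
                         pooling = "max_spatial") {
  art <- vapply(bundle$train, function(s) isTRUE(s$artifact_present), TRUE)
  pooled <- pooled_layer_activations(model, bundle$train, layer, pooling)
  fit_cav(pooled[art, , drop = FALSE], pooled[!art, , drop = FALSE],
          method = method, layer = layer, pooling = pooling)
}

revise_model <- function(model, bundle, cav, cfg) {
  rv <- cfg$revise
  clean_train <- Filter(function(s) !isTRUE(s$artifact_present), bundle$train)
  switch(rv$method,
    rrr = train_model(model, bundle, train_config(
      epochs = rv$epochs, batch_size = cfg$model$batch_size,
      learning_rate = cfg$model$learning_rate, seed = cfg$model$seed + 1L,
      mitigation = list(method = "rrr", lambda = rv$lambda))),
    rr_clarc = train_model(model, bundle, train_config(
      epochs = rv$epochs, batch_size = cfg$model$batch_size,
      learning_rate = cfg$model$learning_rate, seed = cfg$model$seed + 1L,
      mitigation = list(method = "rr_clarc", lambda = rv$lambda, cav = cav))),
    p_clarc = apply_p_clarc(model, cav, rv$z0_policy, clean_samples = clean_train),
    rp_clarc = apply_rp_clarc(model, cav, rv$z0_policy,
                              clean_samples = clean_train,
                              threshold = rv$threshold))
}

#' Per-layer sweep of retrieval or localization quality
#'
#' Fits a CAV per candidate layer and scores it on the validation split
#' (retrieval AUROC/AP against ground-truth artifact flags of the train split,
#' evaluated on held-out biased+clean test samples for `task = "retrieval"`;
#' mean IoU / artifact relevance over biased test samples for
#' `task = "localization"`). The best layer is chosen on the reported metric.
#'
#' @param model a trained `split_model`.
#' @param bundle a `dataset_bundle`.
#' @param layers candidate layer names (default: the pooling layers).
#' @param task `"retrieval"` or `"localization"`.
#' @param cav_method `"svm"` or `"pattern"`.
#' @param n_loc biased test samples used per layer for localization.
#' @return tibble with one row per layer and a `best_layer` attribute.
#' @export
layer_sweep <- function(model, bundle, layers = model_layers(model, TRUE),
                        task = c("retrieval", "localization"),
                        cav_method = "svm", n_loc = 15L) {
  task <- match.arg(task)
  rows <- lapply(layers, function(ly) {
    cav <- pipeline_cav(model, bundle, ly, cav_method)
    if (task == "retrieval") {
      pool <- c(bundle$test_biased, bundle$test_clean)
      rr <- rank_samples(cav, model, pool)
      tibble::tibble(layer = ly, auroc = attr(rr, "auroc"), ap = attr(rr, "ap"))
    } else {
      if (!artifact_localizable(bundle$artifact_spec))
        stop("localization sweep undefined for a non-localizable artifact")
      samp <- bundle$test_biased[seq_len(min(n_loc, length(bundle$test_biased)))]
      lm <- vapply(samp, function(s) {
        lz <- localize_bias(model, s, cav)
        c(as.numeric(iou(lz$binary, s$mask)),
          as.numeric(artifact_relevance(lz$soft, s$mask)))
      }, c(0, 0))
      tibble::tibble(layer = ly, iou = mean(lm[1, ], na.rm = TRUE),
                     artifact_relevance = mean(lm[2, ], na.rm = TRUE))
    }
  })
  out <- do.call(rbind, rows)
  metric <- if (task == "retrieval") out$auroc else out$iou
  attr(out, "best_layer") <- out$layer[which.max(metric)]
  out
}

# ---- controlled mitigation study -------------------------------------------

#' Concept vector from paired artifact insertion (copy-paste protocol)
#'
#' Takes the clean samples of a reference split, inserts the bundle's artifact
#' into a copy of each (the copy-paste protocol available in controlled
#' settings), and fits a CAV on the paired pooled activations. Pairing removes
#' class information from the contrast, so the direction captures the artifact
#' alone even when artifact presence is strongly correlated with one class.
#'
#' @param model a `split_model`.
#' @param bundle a `dataset_bundle`.
#' @param layer CAV layer.
#' @param method `"svm"` or `"pattern"`.
#' @param split reference split to pair (default `"val"`).
#' @param pooling pooling mode.
#' @return a `concept_vector`.
#' @export
paired_artifact_cav <- function(model, bundle, layer, method = "svm",
                                split = "val", pooling = "max_spatial") {
  clean <- Filter(function(s) !isTRUE(s$artifact_present), bundle[[split]])
  if (length(clean) < 2) stop("need at least 2 clean samples in split '", split, "'")
  art <- lapply(seq_along(clean), function(i)
    insert_artifact(clean[[i]], bundle$artifact_spec,
                    jitter_seed = (bundle$seed * 977L + i) %% .Machine$integer.max))
  fit_cav(pooled_layer_activations(model, art, layer, pooling),
          pooled_layer_activations(model, clean, layer, pooling),
          method = method, layer = layer, pooling = pooling)
}

#' Controlled before/after mitigation study
#'
#' The package's standard shortcut-unlearning experiment: generate a bundle
#' whose artifact is spuriously predictive of one class, train a vanilla
#' model (which adopts the shortcut: biased-test accuracy drops far below
#' clean-test accuracy), model the artifact with a paired-insertion CAV, and
#' apply the requested mitigation methods. Reports clean/biased accuracy and
#' the TCAV sensitivity (with the vanilla model's CAV as the fixed concept
#' direction) for the vanilla and each mitigated model.
#'
#' @param seed master seed (data, init, training, finetuning derive from it).
#' @param artifact the controlled artifact; the default brightness shift is
#'   compactly (near rank-one) encoded in latent space, which is the regime
#'   where one concept direction can represent the bias faithfully.
#' @param methods subset of `c("rr_clarc", "p_clarc", "rp_clarc")`.
#' @param n_per_class,image_size,class_count bundle size parameters.
#' @param epochs,learning_rate vanilla training parameters.
#' @param cav_layer layer for the bias CAV and the penalty/edit.
#' @param lambda RR-ClArC penalty weight.
#' @param finetune_epochs,finetune_lr RR-ClArC finetuning parameters.
#' @return list with `bundle`, `models` (named list), `cav`, and `results`
#'   (tibble: model, accuracy_clean, accuracy_biased, tcav_biased,
#'   delta_tcav_biased).
#' @export
mitigation_study <- function(seed = 1L,
                             artifact = artifact_spec("brightness", 0.8, 1L),
                             methods = c("rr_clarc", "p_clarc", "rp_clarc"),
                             n_per_class = 100L, image_size = 32L,
                             class_count = 2L, epochs = 20L,
                             learning_rate = 5e-3, cav_layer = "pool2",
                             lambda = 300, finetune_epochs = 8L,
                             finetune_lr = 2e-3) {
  bundle <- generate_image_dataset(n_per_class, image_size, class_count,
                                   artifact, seed = seed + 4L)
  vanilla <- train_model(build_model("cnn2d_small", class_count, seed = seed),
                         bundle, train_config(epochs = epochs,
                                              learning_rate = learning_rate,
                                              seed = seed))
  cav <- paired_artifact_cav(vanilla, bundle, cav_layer)
  target <- bundle$artifact_spec$target_class
  clean_train <- Filter(function(s) !isTRUE(s$artifact_present), bundle$train)
  models <- list(vanilla = vanilla)
  if ("rr_clarc" %in% methods) {
    models$rr_clarc <- train_model(vanilla, bundle, train_config(
      epochs = finetune_epochs, learning_rate = finetune_lr, seed = seed + 10L,
      mitigation = list(method = "rr_clarc", lambda = lambda, cav = cav)))
  }
  if ("p_clarc" %in% methods)
    models$p_clarc <- apply_p_clarc(vanilla, cav, "clean_mean", clean_train)
  if ("rp_clarc" %in% methods)
    models$rp_clarc <- apply_rp_clarc(vanilla, cav, "clean_mean", clean_train)
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    tc <- tcav_score(m, cav, bundle$test_biased, target)
    tibble::tibble(model = nm,
                   accuracy_clean = accuracy(m, bundle$test_clean),
                   accuracy_biased = accuracy(m, bundle$test_biased),
                   tcav_biased = tc$tcav, delta_tcav_biased = tc$delta_tcav)
  })
  list(bundle = bundle, models = models, cav = cav,
       results = do.call(rbind, rows))
}
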
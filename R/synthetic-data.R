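# Controlled datasets with planted spurious artifacts.
#
# The generators emulate the controlled-artifact protocol used to study
# shortcut learning: a class-dependent but non-trivial signal carries the
# task, and an easily detectable artifact is inserted into p of the samples
# of exactly one class, so that the artifact becomes spuriously predictive.
# A biased test split carries the artifact in every sample of every class,
# exposing shortcut reliance as a clean-vs-biased accuracy gap.

#' Describe a controlled artifact
#'
#' @param kind one of `"ring"` (microscope-like dark circle outline),
#'   `"corner_patch"` (timestamp-like bright box near a corner),
#'   `"brightness"` (global additive shift; non-localizable),
#'   `"static_noise"` (high-frequency noise burst on one channel of a 1D
#'   signal).
#' @param insertion_rate_p fraction in `[0, 1]` of target-class training
#'   samples receiving the artifact.
#' @param target_class class index (1-based) whose samples are attacked.
#' @param params named list of geometry/intensity values; missing entries get
#'   kind-specific defaults: ring `radius` (fraction of image size), `thickness`
#'   (px), `value`; corner_patch `size` (px), `margin` (px), `jitter` (px),
#'   `value`; brightness `delta`; static_noise `start`, `length`, `channel`,
#'   `amplitude`.
#' @param seed integer seed for per-sample placement jitter / noise.
#' @return an `artifact_spec` object.
#' @export
artifact_spec <- function(kind = c("ring", "corner_patch", "brightness", "static_noise"),
                          insertion_rate_p = 0.8, target_class = 1L,
                          params = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (insertion_rate_p < 0 || insertion_rate_p > 1)
    stop("insertion_rate_p must be in [0, 1]")
  defaults <- switch(kind,
    ring = list(radius = 0.36, thickness = 4L, value = 0, jitter = 1L),
    corner_patch = list(size = 6L, margin = 2L, jitter = 2L, value = 0.95),
    brightness = list(delta = 0.2),
    static_noise = list(start = 1L, length = 25L, channel = 1L, amplitude = 0.5))
  for (nm in names(params)) {
    if (!nm %in% names(defaults))
      stop("unknown parameter '", nm, "' for artifact kind '", kind, "'")
    defaults[[nm]] <- params[[nm]]
  }
  structure(list(kind = kind, params = defaults,
                 insertion_rate_p = insertion_rate_p,
                 target_class = as.integer(target_class),
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

artifact_localizable <- function(spec) spec$kind != "brightness"

new_labeled_sample <- function(data, label, artifact_present = FALSE,
                               mask = NULL, id = NA_character_) {
  structure(list(data = data, label = as.integer(label),
                 artifact_present = artifact_present, mask = mask, id = id),
            class = "labeled_sample")
}

#' Insert an artifact into a single sample
#'
#' Returns a modified copy with `artifact_present = TRUE` and the ground-truth
#' mask set. For localizable kinds, values outside the mask are unchanged;
#' `brightness` adds a constant to the whole image, clipped to `[0, 1]`, and
#' carries an all-ones mask flagged as non-localizable.
#'
#' @param sample a `labeled_sample`.
#' @param spec an [artifact_spec()].
#' @param jitter_seed integer controlling placement jitter / noise draw for
#'   this sample.
#' @return the modified `labeled_sample`.
#' @export
insert_artifact <- function(sample, spec, jitter_seed = spec$seed) {
  d <- dim(sample$data)
  is_image <- length(d) == 3L
  if (spec$kind %in% c("ring", "corner_patch", "brightness") && !is_image)
    stop("artifact kind '", spec$kind, "' requires 2D image data")
  if (spec$kind == "static_noise" && is_image)
    stop("artifact kind 'static_noise' requires 1D signal data")
  p <- spec$params
  withr::with_seed(jitter_seed, {
    if (spec$kind == "ring") {
      H <- d[1]; W <- d[2]
      r <- p$radius * min(H, W)
      if (r + p$thickness > min(H, W) / 2)
        stop("invalid artifact parameter 'radius': ring exceeds the image")
      cy <- H / 2 + stats::runif(1, -p$jitter, p$jitter)
      cx <- W / 2 + stats::runif(1, -p$jitter, p$jitter)
      dist <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`))
      mask <- (dist >= r & dist < r + p$thickness) * 1
      if (sum(mask) == 0) stop("invalid artifact parameter 'radius': empty ring mask")
      for (ch in seq_len(d[3])) {
        plane <- sample$data[, , ch]
        plane[mask == 1] <- p$value
        sample$data[, , ch] <- plane
      }
    } else if (spec$kind == "corner_patch") {
      H <- d[1]; W <- d[2]; s <- p$size
      if (s + p$margin + p$jitter > min(H, W))
        stop("invalid artifact parameter 'size': patch exceeds the image")
      r0 <- p$margin + sample.int(p$jitter + 1L, 1L) - 1L
      c0 <- p$margin + sample.int(p$jitter + 1L, 1L) - 1L
      rows <- (r0 + 1L):(r0 + s); cols <- (c0 + 1L):(c0 + s)
      mask <- matrix(0, H, W)
      mask[rows, cols] <- 1
      patt <- matrix(p$value, s, s)
      patt[, seq(1L, s, by = 2L)] <- p$value * 0.75  # stripe texture, timestamp-like
      for (ch in seq_len(d[3])) sample$data[rows, cols, ch] <- patt
    } else if (spec$kind == "brightness") {
      sample$data <- pmin(pmax(sample$data + p$delta, 0), 1)
      mask <- matrix(1, d[1], d[2])
      attr(mask, "non_localizable") <- TRUE
    } else { # static_noise on a L x C signal
      L <- d[1]; C <- d[2]
      if (p$channel < 1 || p$channel > C) stop("invalid artifact parameter 'channel'")
      seg <- p$start:(p$start + p$length - 1L)
      if (p$start < 1 || max(seg) > L)
        stop("invalid artifact parameter 'start'/'length': segment outside the signal")
      mask <- matrix(0, L, C)
      mask[seg, p$channel] <- 1
      if (p$amplitude > 0)
        sample$data[seg, p$channel] <- sample$data[seg, p$channel] +
          stats::rnorm(length(seg), sd = p$amplitude)
    }
  })
  sample$artifact_present <- TRUE
  sample$mask <- mask
  sample
}

# ---- class-signal drawing --------------------------------------------------

draw_image_sample <- function(class, image_size, channels = 1L) {
  H <- W <- image_size
  base <- 0.15
  img <- array(stats::rnorm(H * W * channels, mean = base, sd = 0.07), c(H, W, channels))
  cy <- H / 2 + stats::runif(1, -H / 10, H / 10)
  cx <- W / 2 + stats::runif(1, -W / 10, W / 10)
  area <- (0.12 + stats::runif(1, -0.015, 0.015)) * H * W
  shapes <- c("disc", "ellipse", "square", "bars")
  shape <- shapes[(class - 1L) %% length(shapes) + 1L]
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- switch(shape,
    disc = {
      r <- sqrt(area / pi)
      (yy - cy)^2 + (xx - cx)^2 <= r^2
    },
    ellipse = {
      ratio <- 3.2
      b <- sqrt(area / (pi * ratio)); a <- ratio * b
      th <- stats::runif(1, 0, pi)
      u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
      v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
      (u / a)^2 + (v / b)^2 <= 1
    },
    square = {
      s <- sqrt(area) / 2
      abs(yy - cy) <= s & abs(xx - cx) <= s
    },
    bars = {
      s <- sqrt(area) / 2
      abs(yy - cy) <= 1.8 * s & abs(xx - cx) <= 0.62 * s & ((yy - cy) %% 4 < 2.5)
    })
  fg <- 0.75 + stats::runif(1, -0.04, 0.04)
  for (ch in seq_len(channels)) {
    plane <- img[, , ch]
    plane[inside] <- plane[inside] + (fg - base)
    img[, , ch] <- plane
  }
  pmin(pmax(img, 0), 1)
}

signal_class_params <- function(class) {
  # beat amplitude / width carry the class signal
  list(amp = c(1.0, 1.6, 0.7, 2.0)[(class - 1L) %% 4L + 1L],
       width = c(4, 7, 5.5, 3)[(class - 1L) %% 4L + 1L])
}

draw_signal_sample <- function(class, len, channels) {
  pars <- signal_class_params(class)
  amp <- pars$amp * (1 + stats::rnorm(1, sd = 0.08))
  width <- pars$width * (1 + stats::rnorm(1, sd = 0.08))
  period <- 32
  phase <- stats::runif(1, 0, period)
  t <- seq_len(len)
  centers <- seq(phase, len + period, by = period)
  beat <- rep(0, len)
  for (cc in centers) beat <- beat + amp * exp(-((t - cc)^2) / (2 * width^2))
  sig <- matrix(0, len, channels)
  gains <- 1 - 0.15 * (seq_len(channels) - 1)
  for (ch in seq_len(channels))
    sig[, ch] <- gains[ch] * beat + stats::rnorm(len, sd = 0.1)
  sig
}

# ---- bundle assembly -------------------------------------------------------

make_split <- function(kind, n_per_class, class_count, seed, drawer) {
  withr::with_seed(seed, {
    samples <- list()
    for (cl in seq_len(class_count)) {
      for (i in seq_len(n_per_class)) {
        samples[[length(samples) + 1L]] <-
          new_labeled_sample(drawer(cl), cl,
                             id = sprintf("%s-%02d-%04d", kind, cl, i))
      }
    }
    samples
  })
}

apply_bias_plan <- function(samples, spec, which_idx, seed_base) {
  for (j in seq_along(which_idx)) {
    i <- which_idx[j]
    samples[[i]] <- insert_artifact(samples[[i]], spec,
                                    jitter_seed = (seed_base + 7L * i) %% .Machine$integer.max)
  }
  samples
}

finish_bundle <- function(train, val, test_clean, spec, class_count, seed) {
  # biased test: artifact inserted into every sample of every class
  test_biased <- apply_bias_plan(test_clean, spec, seq_along(test_clean),
                                 seed_base = seed * 1013L + 5L)
  structure(list(train = train, val = val, test_clean = test_clean,
                 test_biased = test_biased, class_count = as.integer(class_count),
                 artifact_spec = spec, seed = as.integer(seed)),
            class = "dataset_bundle")
}

plan_train_insertion <- function(train, spec, seed) {
  target_idx <- which(vapply(train, `[[`, 0L, "label") == spec$target_class)
  n_art <- round(spec$insertion_rate_p * length(target_idx))
  chosen <- withr::with_seed(seed * 911L + 3L,
                             sample(target_idx, n_art))
  apply_bias_plan(train, spec, sort(chosen), seed_base = seed * 131L + 1L)
}

#' Generate a labeled 2D image dataset with a controlled artifact
#'
#' Classes are distinguished by a foreground shape (disc, ellipse, square,
#' striped bar) of matched area over a noisy background, so that shape -- not
#' mean intensity -- carries the class signal. The artifact described by
#' `artifact` is inserted into `round(p * n_per_class)` training samples of the
#' target class only; the biased test split carries it in every sample of every
#' class.
#'
#' @param n_per_class training samples per class (>= 4).
#' @param image_size square image side (>= 32, divisible by 8).
#' @param class_count number of classes (2--4).
#' @param artifact an [artifact_spec()] with a 2D kind.
#' @param seed integer master seed; all splits and jitter derive from it.
#' @param channels image channels (default 1, grayscale).
#' @return a `dataset_bundle` with `train`, `val`, `test_clean`, `test_biased`.
#' @export
generate_image_dataset <- function(n_per_class, image_size = 32L, class_count = 2L,
                                   artifact = artifact_spec("corner_patch"),
                                   seed = 1L, channels = 1L) {
  if (n_per_class < 4) stop("n_per_class must be >= 4")
  if (image_size < 32) stop("image_size must be >= 32")
  if (artifact$kind == "static_noise")
    stop("artifact kind 'static_noise' is for 1D signals; use generate_signal_dataset()")
  drawer <- function(cl) draw_image_sample(cl, image_size, channels)
  n_val <- max(8L, round(n_per_class / 4))
  n_test <- max(16L, round(n_per_class / 2))
  train <- make_split("train", n_per_class, class_count, seed * 5L + 11L, drawer)
  val <- make_split("val", n_val, class_count, seed * 5L + 12L, drawer)
  test <- make_split("test", n_test, class_count, seed * 5L + 13L, drawer)
  train <- plan_train_insertion(train, artifact, seed)
  finish_bundle(train, val, test, artifact, class_count, seed)
}

#' Generate a labeled 1D multichannel signal dataset with a noise-burst artifact
#'
#' Classes differ in the amplitude and width of a periodic beat template shared
#' (with per-channel gain) across channels. The `static_noise` artifact adds a
#' seeded high-amplitude noise burst to one configured channel over one
#' configured segment; the ground-truth mask marks exactly that segment on that
#' channel.
#'
#' @param n_per_class training samples per class (>= 4).
#' @param length signal length in samples (divisible by 8).
#' @param channels number of channels (>= 2).
#' @param artifact an [artifact_spec()] with `kind = "static_noise"`.
#' @param seed integer master seed.
#' @return a `dataset_bundle`.
#' @export
generate_signal_dataset <- function(n_per_class, length = 128L, channels = 3L,
                                    artifact = artifact_spec("static_noise"),
                                    seed = 1L, class_count = 2L) {
  if (artifact$kind != "static_noise")
    stop("generate_signal_dataset requires artifact kind 'static_noise'")
  if (channels < 2) stop("channels must be >= 2")
  seg_end <- artifact$params$start + artifact$params$length - 1L
  if (artifact$params$start < 1 || seg_end > length)
    stop("invalid artifact parameter 'start'/'length': segment outside the signal")
  drawer <- function(cl) draw_signal_sample(cl, length, channels)
  n_val <- max(8L, round(n_per_class / 4))
  n_test <- max(16L, round(n_per_class / 2))
  train <- make_split("train", n_per_class, class_count, seed * 5L + 11L, drawer)
  val <- make_split("val", n_val, class_count, seed * 5L + 12L, drawer)
  test <- make_split("test", n_test, class_count, seed * 5L + 13L, drawer)
  train <- plan_train_insertion(train, artifact, seed)
  finish_bundle(train, val, test, artifact, class_count, seed)
}

#' @export
print.dataset_bundle <- function(x, ...) {
  n_art <- sum(vapply(x$train, `[[`, TRUE, "artifact_present"))
  cat(sprintf("<dataset_bundle> %d classes | train %d (artifact in %d) | val %d | test %d+%d biased\n",
              x$class_count, length(x$train), n_art, length(x$val),
              length(x$test_clean), length(x$test_biased)))
  cat(sprintf("  artifact: %s (p = %g, target class %d)\n", x$artifact_spec$kind,
              x$artifact_spec$insertion_rate_p, x$artifact_spec$target_class))
  invisible(x)
}

#' Tabular summary of a bundle split
#' @param bundle a `dataset_bundle`.
#' @return a tibble with one row per sample: id, split, label, artifact flag.
#' @export
bundle_manifest <- function(bundle) {
  row <- function(s, split) tibble::tibble(
    id = s$id, split = split, label = s$label,
    artifact_present = s$artifact_present)
  do.call(rbind, c(lapply(bundle$train, row, "train"),
                   lapply(bundle$val, row, "val"),
                   lapply(bundle$test_clean, row, "test_clean"),
                   lapply(bundle$test_biased, row, "test_biased")))
}

# ---- disk writers (text / PNG) ---------------------------------------------

#' Write a bundle to disk (PNG images or CSV signals, PNG/CSV masks, JSON manifest)
#' @param bundle a `dataset_bundle`.
#' @param dir output directory (created if missing).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (split in c("train", "val", "test_clean", "test_biased")) {
    for (s in bundle[[split]]) {
      is_image <- length(dim(s$data)) == 3L
      stem <- file.path(dir, paste0(split, "-", s$id))
      if (is_image) {
        png::writePNG(s$data[, , 1], paste0(stem, ".png"))
        data_path <- paste0(stem, ".png")
      } else {
        utils::write.csv(t(s$data), paste0(stem, ".csv"), row.names = FALSE)
        data_path <- paste0(stem, ".csv")
      }
      mask_path <- NULL
      if (!is.null(s$mask)) {
        mask_path <- paste0(stem, "-mask", if (is_image) ".png" else ".csv")
        if (is_image) png::writePNG(s$mask + 0, mask_path)
        else utils::write.csv(t(s$mask), mask_path, row.names = FALSE)
      }
      manifest[[length(manifest) + 1L]] <- list(
        id = s$id, split = split, label = s$label,
        artifact_present = s$artifact_present,
        data = basename(data_path),
        mask = if (is.null(mask_path)) NULL else basename(mask_path))
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
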
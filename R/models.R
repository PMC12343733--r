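#' Build a small convolutional classifier
#'
#' Constructs a compact CNN with three conv-ReLU-maxpool blocks, a flatten
#' stage and a single linear head. The 2D variant (`cnn2d_small`) operates on
#' `H x W x C` images, the 1D variant (`cnn1d_small`) on `L x C` multichannel
#' signals (internally a width-1 image). Every layer is named so the model can
#' be split into a feature extractor \eqn{a_l} and a head \eqn{\tilde f} at any
#' layer, which is the basis for concept activation vectors, latent relevance
#' analysis and projection-based model editing.
#'
#' @param arch `"cnn2d_small"` or `"cnn1d_small"`.
#' @param class_count number of output classes (>= 2).
#' @param seed integer seed for the (He-scaled) parameter initialisation.
#' @param input_shape spatial input shape: `c(H, W, C)` for 2D (default
#'   `c(32, 32, 1)`), `c(L, C)` for 1D (default `c(128, 3)`).
#' @param widths channel widths of the three conv blocks.
#' @return a `split_model` object.
#' @export
build_model <- function(arch = c("cnn2d_small", "cnn1d_small"), class_count,
                        seed = 1L, input_shape = NULL, widths = c(8L, 16L, 32L)) {
  arch <- tryCatch(match.arg(arch), error = function(e)
    stop("unknown arch: ", arch[1], call. = FALSE))
  if (class_count < 2) stop("class_count must be >= 2")
  if (is.null(input_shape)) {
    input_shape <- if (arch == "cnn2d_small") c(32L, 32L, 1L) else c(128L, 3L)
  }
  if (arch == "cnn2d_small") {
    H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
    k <- c(3L, 3L); pad <- c(1L, 1L); pool <- c(2L, 2L)
  } else {
    H <- input_shape[1]; W <- 1L; C <- input_shape[2]
    k <- c(9L, 1L); pad <- c(4L, 0L); pool <- c(2L, 1L)
  }
  if (H %% 8 != 0 || (arch == "cnn2d_small" && W %% 8 != 0))
    stop("spatial input size must be divisible by 8")
  layers <- list()
  cin <- C; h <- H; w <- W
  for (blk in 1:3) {
    layers <- c(layers, list(
      layer_conv(paste0("conv", blk), k[1], k[2], cin, widths[blk], pad),
      layer_relu(paste0("relu", blk)),
      layer_pool(paste0("pool", blk), pool[1], pool[2])))
    cin <- widths[blk]; h <- h %/% pool[1]; w <- w %/% pool[2]
  }
  layers <- c(layers, list(
    layer_flatten("flatten"),
    layer_dense("dense", h * w * cin, class_count)))
  model <- structure(list(
    layers = layers, arch = arch, class_count = as.integer(class_count),
    input_shape = c(H, W, C), seed = as.integer(seed)), class = "split_model")
  init_params(model, seed)
}

init_params <- function(model, seed) {
  withr::with_seed(seed, {
    for (i in seq_along(model$layers)) {
      layer <- model$layers[[i]]
      if (layer$type == "conv") {
        fan_in <- layer$kh * layer$kw * layer$cin
        model$layers[[i]]$W <- array(stats::rnorm(length(layer$W), sd = sqrt(2 / fan_in)),
                                     dim(layer$W))
      } else if (layer$type == "dense") {
        model$layers[[i]]$W <- matrix(stats::rnorm(length(layer$W), sd = sqrt(2 / layer$n_in)),
                                      layer$n_in, layer$n_out)
      }
    }
  })
  model
}

#' @export
print.split_model <- function(x, ...) {
  cat("<split_model> arch:", x$arch, " classes:", x$class_count,
      " input:", paste(x$input_shape, collapse = "x"), "\n")
  for (layer in x$layers) {
    extra <- switch(layer$type,
      conv = sprintf(" %dx%d, %d -> %d", layer$kh, layer$kw, layer$cin, layer$cout),
      dense = sprintf(" %d -> %d", layer$n_in, layer$n_out),
      projection = sprintf(" edit (z0=%.3g%s)", layer$z0,
                           if (is.null(layer$threshold)) "" else ", reactive"),
      "")
    cat(sprintf("  %-12s %s%s\n", layer$name, layer$type, extra))
  }
  invisible(x)
}

#' Layer names of a model
#'
#' @param model a `split_model`.
#' @param candidates_only if `TRUE`, return only the recommended split layers
#'   (the post-pooling activations of each block).
#' @return character vector of layer names.
#' @export
model_layers <- function(model, candidates_only = FALSE) {
  nms <- vapply(model$layers, `[[`, "", "name")
  if (candidates_only) nms[vapply(model$layers, `[[`, "", "type") == "pool"] else nms
}

#' Channel count of a named layer
#' @param model a `split_model`.
#' @param layer layer name.
#' @return integer number of channels (feature maps) the layer outputs.
#' @export
layer_channels <- function(model, layer) {
  idx <- layer_index(model, layer)
  for (i in rev(seq_len(idx))) {
    l <- model$layers[[i]]
    if (l$type == "conv") return(l$cout)
    if (l$type == "dense") return(l$n_out)
  }
  model$input_shape[3]
}

# ---- batch conversion ------------------------------------------------------

sample_to_tensor <- function(data) {
  d <- dim(data)
  if (length(d) == 3L) array(data, c(d, 1L))                 # image H x W x C
  else if (length(d) == 2L) array(data, c(d[1], 1L, d[2], 1L)) # signal L x C
  else stop("sample data must be a 2D or 3D array")
}

samples_to_batch <- function(samples) {
  stopifnot(length(samples) > 0)
  tens <- lapply(samples, function(s) sample_to_tensor(s$data))
  d <- dim(tens[[1]])[1:3]
  x <- array(unlist(tens), c(d, length(samples)))
  y <- vapply(samples, `[[`, 0L, "label")
  list(x = x, y = as.integer(y))
}

mask_to_tensor <- function(mask, input_shape) {
  if (is.null(mask)) return(array(0, input_shape))
  d <- dim(mask)
  if (length(d) == 2L && length(input_shape) == 3L) {
    if (input_shape[2] == 1L) {
      array(mask, c(d[1], 1L, d[2]))            # signal mask L x C
    } else {
      array(rep(mask, input_shape[3]), input_shape)  # image mask shared over channels
    }
  } else array(mask, input_shape)
}

#' Forward scores for a set of samples
#' @param model a `split_model`.
#' @param samples list of `labeled_sample` objects (or a `dataset_bundle` split).
#' @return numeric matrix `n x class_count` of class scores (logits).
#' @export
predict_scores <- function(model, samples) {
  b <- samples_to_batch(samples)
  nn_forward(model, b$x, keep = FALSE)$scores
}

#' Activations of a named layer for a set of samples
#' @inheritParams predict_scores
#' @param layer layer name (see [model_layers()]).
#' @return array `H' x W' x C' x n` of activations at that layer.
#' @export
layer_activations <- function(model, samples, layer) {
  layer_index(model, layer)
  b <- samples_to_batch(samples)
  nn_forward(model, b$x)$acts[[layer]]
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' @param epochs,batch_size,learning_rate optimisation settings (Adam).
#' @param seed RNG seed controlling shuffling (and any init).
#' @param mitigation optional list describing a penalty added to the task
#'   loss: `list(method = "rrr", lambda = ...)` (needs ground-truth masks in
#'   the training samples) or `list(method = "rr_clarc", lambda = ..., cav = <concept_vector>)`.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L, learning_rate = 3e-3,
                         seed = 1L, mitigation = NULL) {
  if (!is.null(mitigation)) {
    if (!mitigation$method %in% c("rrr", "rr_clarc"))
      stop("mitigation method must be 'rrr' or 'rr_clarc'")
    if (is.null(mitigation$lambda) || mitigation$lambda < 0)
      stop("mitigation lambda must be >= 0")
    if (mitigation$method == "rr_clarc" && is.null(mitigation$cav))
      stop("rr_clarc mitigation requires a concept vector ('cav')")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 mitigation = mitigation), class = "train_config")
}

#' Train (or finetune) a classifier
#'
#' Minimises softmax cross-entropy with Adam; optionally adds a bias-mitigation
#' penalty: `rrr` penalises the squared input gradient of the true-class
#' log-probability inside ground-truth artifact masks, `rr_clarc` penalises the
#' squared directional derivative of the true-class score along a concept
#' vector in latent space. Penalty gradients are computed by exact
#' double-backpropagation through the piecewise-linear network with frozen
#' ReLU/pooling gates.
#'
#' @param model a `split_model`.
#' @param bundle a `dataset_bundle` (uses `bundle$train` and `bundle$val`).
#' @param cfg a [train_config()].
#' @return the trained model, with a `training_log` attribute (a tibble of
#'   per-epoch loss, penalty and clean-validation accuracy).
#' @export
train_model <- function(model, bundle, cfg = train_config()) {
  train <- bundle$train
  if (length(train) == 0) stop("bundle$train is empty")
  mit <- cfg$mitigation
  if (!is.null(mit) && mit$method == "rrr") {
    has_mask <- vapply(train, function(s) !is.null(s$mask), TRUE)
    needs <- vapply(train, function(s) isTRUE(s$artifact_present), TRUE)
    if (any(needs & !has_mask))
      stop("rrr mitigation requires ground-truth masks for artifact samples")
  }
  b <- samples_to_batch(train)
  masks <- NULL
  if (!is.null(mit) && mit$method == "rrr" && mit$lambda > 0) {
    mt <- lapply(train, function(s)
      if (isTRUE(s$artifact_present) && !is.null(s$mask) &&
          !isTRUE(attr(s$mask, "non_localizable")))
        mask_to_tensor(s$mask, dim(b$x)[1:3]) else array(0, dim(b$x)[1:3]))
    masks <- array(unlist(mt), dim(b$x))
  }
  cav <- NULL
  if (!is.null(mit) && mit$method == "rr_clarc") cav <- mit$cav
  n <- length(train)
  st <- adam_init(model)
  log_rows <- vector("list", cfg$epochs)
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_pen <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- b$x[, , , idx, drop = FALSE]
        yb <- b$y[idx]
        fw <- nn_forward(model, xb)
        ce <- cross_entropy(fw$scores, yb)
        bk <- nn_backward(model, fw, ce$dscores)
        grads <- bk$param_grads
        pen <- 0
        if (!is.null(mit) && mit$lambda > 0) {
          pr <- if (mit$method == "rrr") {
            penalty_rrr_batch(model, fw, yb, masks[, , , idx, drop = FALSE])
          } else {
            penalty_rr_clarc_batch(model, fw, yb, cav)
          }
          pen <- pr$value
          grads <- add_grads(grads, pr$grads, scale = mit$lambda / length(idx))
        }
        stp <- adam_step(model, grads, st, cfg$learning_rate)
        model <- stp$model; st <- stp$state
        ep_loss <- ep_loss + ce$loss; ep_pen <- ep_pen + pen; nb <- nb + 1L
      }
      val_acc <- if (length(bundle$val) > 0) accuracy(model, bundle$val) else NA_real_
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_loss / nb, penalty = ep_pen / nb, val_accuracy = val_acc)
    }
  })
  attr(model, "training_log") <- do.call(rbind, log_rows)
  model
}

# Sum_i || mask_i * d log p(y_i|x_i) / d x_i ||^2 and its parameter gradient
# (softmax weights detached).
penalty_rrr_batch <- function(model, fw, y, masks) {
  p <- softmax_rows(fw$scores)
  n <- length(y)
  v <- -p; v[cbind(seq_len(n), y)] <- v[cbind(seq_len(n), y)] + 1
  bk <- nn_backward(model, fw, v, param_grads = FALSE, keep_deltas = TRUE)
  g <- bk$grad                       # per-sample input gradients of log p_y
  mg <- masks * g
  value <- sum(mg^2) / n
  u <- 2 * masks * mg                # d penalty / d g, then mask applied again
  jvp <- nn_jvp(model, fw, u, from = "input")
  grads <- nn_wgrads_from_jvp(model, fw, jvp, bk$deltas)
  list(value = value, grads = grads)
}

# Per-position latent concept-gradient penalty:
# sum_i sum_pos (h . d score_{y_i} / d a_l[pos])^2, with its parameter
# gradient (detaching the per-position coefficients, frozen gates).
penalty_rr_clarc_batch <- function(model, fw, y, cav) {
  layer <- cav$layer
  n <- length(y)
  onehot <- matrix(0, n, ncol(fw$scores)); onehot[cbind(seq_len(n), y)] <- 1
  bk1 <- nn_backward(model, fw, onehot, stop_at = layer, param_grads = FALSE,
                     keep_deltas = TRUE)
  gamma <- bk1$grad                  # H' x W' x C x n, or n x m for dense layers
  if (is.matrix(gamma)) {
    cpos <- gamma %*% cav$h          # n x 1
    value <- sum(cpos^2) / n
    ustar <- (2 * as.vector(cpos)) * matrix(cav$h, nrow(gamma), ncol(gamma),
                                            byrow = TRUE)
  } else {
    d <- dim(gamma)
    hb <- aperm(array(cav$h, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
    cpos <- apply(gamma * hb, c(1, 2, 4), sum)   # H' x W' x n
    value <- sum(cpos^2) / n
    cb <- aperm(array(cpos, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
    ustar <- 2 * cb * hb
  }
  jvp <- nn_jvp(model, fw, ustar, from = layer)
  grads <- nn_wgrads_from_jvp(model, fw, jvp, bk1$deltas)
  list(value = value, grads = grads)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint (JSON, text-only)
#' @param model a `split_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  desc <- list(arch = model$arch, class_count = model$class_count,
               input_shape = model$input_shape, seed = model$seed,
               layers = lapply(model$layers, function(l) {
                 l$W <- if (!is.null(l$W)) as.vector(l$W) else NULL
                 l
               }))
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  desc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(desc$layers, function(l) {
    l$pad <- as.integer(l$pad)
    if (l$type == "conv") {
      l$W <- array(l$W, c(l$kh, l$kw, l$cin, l$cout)); l$b <- as.numeric(l$b)
    } else if (l$type == "dense") {
      l$W <- matrix(l$W, l$n_in, l$n_out); l$b <- as.numeric(l$b)
    } else if (l$type == "projection") {
      l$hhat <- as.numeric(l$hhat)
      if (!is.null(l$threshold) && !is.numeric(l$threshold)) l$threshold <- NULL
    }
    l
  })
  structure(list(layers = layers, arch = desc$arch,
                 class_count = as.integer(desc$class_count),
                 input_shape = as.integer(desc$input_shape),
                 seed = as.integer(desc$seed)), class = "split_model")
}
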
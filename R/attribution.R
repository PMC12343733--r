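# Layer-wise relevance propagation.
#
# Composite rule set: epsilon-rule for dense layers (and affine projection
# edits), z+ rule for convolutions, winner-take-all for max-pooling, identity
# for ReLU. On non-negative inputs the z+ rule applies to every convolution;
# when the input can be negative (real-valued signals) the first convolution
# falls back to the epsilon-rule, which is sign-safe. With zero bias terms
# every rule redistributes relevance exactly, so the input heatmap sums to the
# initialisation (conservation); bias terms absorb a small share.

#' LRP rule configuration
#'
#' @param conv rule for convolution layers: `"zplus"` or `"epsilon"`.
#' @param dense rule for dense layers (only `"epsilon"`).
#' @param first_conv rule for the first convolution: `"auto"` picks
#'   `"epsilon"` when the input contains negative values, else `conv`.
#' @param epsilon stabiliser of the epsilon-rule.
#' @return an `lrp_rules` list.
#' @export
lrp_rules <- function(conv = "zplus", dense = "epsilon",
                      first_conv = "auto", epsilon = 1e-6) {
  stopifnot(conv %in% c("zplus", "epsilon"), dense == "epsilon",
            first_conv %in% c("auto", "zplus", "epsilon"))
  structure(list(conv = conv, dense = dense, first_conv = first_conv,
                 epsilon = epsilon), class = "lrp_rules")
}

stab <- function(z, eps) z + eps * ifelse(z >= 0, 1, -1)

lrp_dense <- function(x, W, b, R, eps) {
  z <- x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE)
  s <- R / stab(z, eps)
  x * tcrossprod(s, W)
}

lrp_conv <- function(x, layer, R, rule, eps) {
  if (rule == "zplus") {
    Wp <- pmax(layer$W, 0)
    z <- conv_forward_raw(x, Wp, numeric(layer$cout), layer$pad)$y
    s <- R / stab(z, eps)
    x * conv_input_grad(s, Wp, dim(x), layer$pad)
  } else {
    z <- conv_forward_raw(x, layer$W, layer$b, layer$pad)$y
    s <- R / stab(z, eps)
    x * conv_input_grad(s, layer$W, dim(x), layer$pad)
  }
}

lrp_projection <- function(x, layer, cache, R, eps) {
  # contribution-based (epsilon) redistribution through a' = P a + z0*hhat
  d <- dim(x)
  z <- projection_forward(layer, x)$y
  s <- R / stab(z, eps)
  x * projection_linear_map(layer, s, cache$gate)
}

# Propagate relevance R (shaped like the output of layer `from`) down to the
# input, collecting the relevance tensor at every layer output on the way.
lrp_propagate <- function(model, fw, R, from, rules) {
  from_idx <- if (identical(from, "scores")) length(model$layers) else layer_index(model, from)
  first_conv_idx <- which(vapply(model$layers, `[[`, "", "type") == "conv")[1]
  fc_rule <- rules$first_conv
  if (fc_rule == "auto")
    fc_rule <- if (min(fw$acts$input) < 0) "epsilon" else rules$conv
  latent <- list()
  cur <- R
  for (i in rev(seq_len(from_idx))) {
    layer <- model$layers[[i]]
    latent[[layer$name]] <- cur
    x_in <- fw$acts[[layer_input_name(model, i)]]
    cur <- switch(layer$type,
      dense = lrp_dense(fw$caches[[layer$name]]$x, layer$W, layer$b, cur, rules$epsilon),
      conv = lrp_conv(x_in, layer, cur,
                      if (i == first_conv_idx) fc_rule else rules$conv, rules$epsilon),
      relu = cur,
      pool = pool_route_back(cur, fw$caches[[layer$name]], layer$kh, layer$kw),
      flatten = array(t(cur), fw$caches[[layer$name]]$in_dim),
      projection = lrp_projection(x_in, layer, fw$caches[[layer$name]], cur, rules$epsilon),
      stop("no LRP rule for layer type: ", layer$type))
  }
  list(input_map = cur, latent = latent)
}

new_relevance_bundle <- function(input_map, latent, target, rules) {
  structure(list(input_map = input_map, latent = latent, target = target,
                 rules = rules), class = "relevance_bundle")
}

#' Layer-wise relevance propagation for one sample
#'
#' Decomposes the class score of `target` into per-pixel (input) and per-neuron
#' (latent, at every layer) relevance by backward propagation with the
#' configured rule composite.
#'
#' @param model a `split_model`.
#' @param x a `labeled_sample` or a bare data array.
#' @param target class index (1-based); defaults to the sample's label.
#' @param rules an [lrp_rules()] configuration.
#' @return a `relevance_bundle` with `input_map` (shaped like the input),
#'   `latent` (named list, relevance tensor at each layer output) and `target`.
#' @export
lrp_attribute <- function(model, x, target = NULL, rules = lrp_rules()) {
  data <- if (inherits(x, "labeled_sample")) x$data else x
  if (is.null(target)) {
    if (!inherits(x, "labeled_sample")) stop("target class required")
    target <- x$label
  }
  if (target < 1 || target > model$class_count) stop("invalid target class")
  xb <- sample_to_tensor(data)
  fw <- nn_forward(model, xb)
  R0 <- matrix(0, 1, model$class_count)
  R0[1, target] <- fw$scores[1, target]
  pr <- lrp_propagate(model, fw, R0, "scores", rules)
  im <- array(pr$input_map, dim(xb)[1:3])
  if (length(dim(data)) == 2L) im <- array(im, dim(data))  # back to L x C
  new_relevance_bundle(im, pr$latent, target, rules)
}

#' Concept-conditioned attribution (latent relevance initialised by a CAV)
#'
#' Initialises the latent relevance at the concept vector's layer as
#' \eqn{R_l = a_l(x) \circ h_l} (the concept vector broadcast over spatial
#' positions) and propagates it to the input with the standard rule composite.
#' With `init = "max"` the initialisation is placed only at each channel's
#' spatial argmax, consistent with max-pooled CAV training, so that the
#' initialisation sums exactly to the bias score \eqn{h_l^\top a_l(x)}.
#'
#' @param model a `split_model`.
#' @param x a `labeled_sample` or data array.
#' @param cav a `concept_vector` (see [fit_cav()]); its `layer` must exist in
#'   `model`.
#' @param rules an [lrp_rules()] configuration.
#' @param init `"dense"` (all spatial positions) or `"max"`
#'   (winner-take-all per channel).
#' @return a `relevance_bundle` (target `"concept"`).
#' @export
concept_conditioned_attribute <- function(model, x, cav, rules = lrp_rules(),
                                          init = c("dense", "max")) {
  init <- match.arg(init)
  data <- if (inherits(x, "labeled_sample")) x$data else x
  xb <- sample_to_tensor(data)
  fw <- nn_forward(model, xb)
  a <- fw$acts[[cav$layer]]
  if (is.matrix(a)) a <- array(t(a), c(1L, 1L, ncol(a), nrow(a)))  # dense output
  d <- dim(a)
  if (length(cav$h) != d[3])
    stop("concept vector length ", length(cav$h), " does not match layer channels ", d[3])
  hb <- aperm(array(cav$h, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
  R <- a * hb
  if (init == "max") {
    keep <- array(0, d)
    for (ch in seq_len(d[3])) {
      plane <- a[, , ch, 1]
      idx <- which.max(plane)
      keep[((idx - 1) %% d[1]) + 1, ((idx - 1) %/% d[1]) + 1, ch, 1] <- 1
    }
    R <- R * keep
  }
  if (is.matrix(fw$acts[[cav$layer]])) R <- matrix(R[1, 1, , 1], 1)
  pr <- lrp_propagate(model, fw, R, cav$layer, rules)
  im <- array(pr$input_map, dim(xb)[1:3])
  if (length(dim(data)) == 2L) im <- array(im, dim(data))
  out <- new_relevance_bundle(im, pr$latent, "concept", rules)
  out$init_sum <- sum(R)
  out
}

#' Input x Gradient attribution (cross-check backend)
#'
#' @inheritParams lrp_attribute
#' @return a `relevance_bundle` (no latent maps).
#' @export
input_x_gradient <- function(model, x, target = NULL) {
  data <- if (inherits(x, "labeled_sample")) x$data else x
  if (is.null(target)) target <- x$label
  xb <- sample_to_tensor(data)
  fw <- nn_forward(model, xb)
  d0 <- matrix(0, 1, model$class_count); d0[1, target] <- 1
  bk <- nn_backward(model, fw, d0, param_grads = FALSE)
  im <- array(bk$grad * xb, dim(xb)[1:3])
  if (length(dim(data)) == 2L) im <- array(im, dim(data))
  new_relevance_bundle(im, list(), target, NULL)
}

# ---- batched relevance matrices for the reveal/annotate modules ------------

#' Relevance rows for a set of samples
#'
#' Computes LRP for each sample (target = its own label unless `target` is
#' given) and returns either flattened, channel-summed input heatmaps or
#' spatially pooled latent relevances at a named layer -- the row format
#' consumed by spectral relevance clustering, concept embeddings and
#' prototype summaries.
#'
#' @param model a `split_model`.
#' @param samples list of `labeled_sample`s.
#' @param space `"input"` (rows = flattened input heatmaps, summed over
#'   channels) or `"latent"` (rows = spatially pooled latent relevance).
#' @param layer layer name, required for `space = "latent"`.
#' @param pooling spatial pooling for latent rows (`"max_spatial"` or
#'   `"mean_spatial"`).
#' @param target optional fixed target class for all samples.
#' @param rules an [lrp_rules()] configuration.
#' @return numeric matrix, one row per sample.
#' @export
relevance_rows <- function(model, samples, space = c("input", "latent"),
                           layer = NULL, pooling = "max_spatial",
                           target = NULL, rules = lrp_rules()) {
  space <- match.arg(space)
  if (space == "latent" && is.null(layer))
    stop("latent relevance rows require a layer name")
  rows <- lapply(samples, function(s) {
    tgt <- if (is.null(target)) s$label else target
    rb <- lrp_attribute(model, s, tgt, rules)
    if (space == "input") {
      im <- rb$input_map
      if (length(dim(im)) == 3L) im <- apply(im, c(1, 2), sum)  # sum over channels
      as.vector(im)
    } else {
      r <- rb$latent[[layer]]
      if (is.matrix(r)) as.vector(r) else as.vector(pool_spatial_batch(r, pooling))
    }
  })
  do.call(rbind, rows)
}

# ---- heatmap writer --------------------------------------------------------

#' Write a relevance heatmap as PNG (diverging colormap) plus raw CSV
#' @param heatmap 2D matrix (or 3D array, summed over channels).
#' @param path output PNG path; a sibling `.csv` carries the raw values.
#' @export
write_heatmap <- function(heatmap, path) {
  if (length(dim(heatmap)) == 3L) heatmap <- apply(heatmap, c(1, 2), sum)
  m <- max(abs(heatmap), 1e-12)
  v <- heatmap / m  # [-1, 1]
  rgb <- array(1, c(dim(heatmap), 3))
  rgb[, , 1] <- pmin(1, 1 + pmin(v, 0))       # negative -> blue
  rgb[, , 2] <- 1 - abs(v) * 0.9
  rgb[, , 3] <- pmin(1, 1 - pmax(v, 0))       # positive -> red
  rgb[, , 2] <- pmax(rgb[, , 2], 0)
  png::writePNG(rgb, path)
  utils::write.csv(heatmap, sub("\\.png$", ".csv", path), row.names = FALSE)
  invisible(path)
}
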
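# Concept representations in latent space: supervised CAVs (linear-SVM and
# pattern/signal variants), single neurons, and unsupervised candidates from
# matrix decomposition, plus the bias score that ranks samples by concept
# presence.

new_concept_vector <- function(h, layer, method, pooling) {
  structure(list(h = as.numeric(h), layer = layer, method = method,
                 pooling = pooling, norm = sqrt(sum(h^2))),
            class = "concept_vector")
}

#' @export
print.concept_vector <- function(x, ...) {
  cat(sprintf("<concept_vector> %s CAV at layer '%s' (m = %d, pooling = %s, |h| = %.4g)\n",
              x$method, x$layer, length(x$h), x$pooling, x$norm))
  invisible(x)
}

#' Spatially pool a batch of latent activations
#'
#' Reduces an `H x W x C x n` activation (or relevance) tensor to an `n x m`
#' matrix with one entry per channel: `max_spatial` takes each channel's
#' spatial maximum (translation-invariant 1D-CAV convention), `mean_spatial`
#' the spatial mean, `none` requires a 1x1 spatial extent.
#'
#' @param acts activation tensor `H x W x C x n`, or an `n x m` matrix (passed
#'   through).
#' @param mode pooling mode.
#' @param layer optional layer name to attach to the result.
#' @return a `pooled_acts` object: an `n x m` matrix with attributes `layer`
#'   and `pooling`.
#' @export
pool_activations <- function(acts, mode = c("max_spatial", "mean_spatial", "none"),
                             layer = NULL) {
  mode <- match.arg(mode)
  m <- if (is.matrix(acts)) acts else pool_spatial_batch(acts, mode)
  structure(m, layer = layer, pooling = mode, class = c("pooled_acts", "matrix", "array"))
}

#' Fit a concept activation vector from positive/negative pooled activations
#'
#' `method = "svm"` returns the weight vector of a soft-margin linear SVM
#' (cost 1, no scaling) separating concept-present from concept-absent
#' activations -- the classical CAV. `method = "pattern"` returns the concept
#' *signal* direction, estimated as the difference of class-conditional means,
#' which is robust to correlated distractor directions that can tilt a
#' discriminant.
#'
#' @param pos,neg matrices (`pooled_acts`) of pooled activations with / without
#'   the concept; same layer and pooling.
#' @param method `"svm"` or `"pattern"`.
#' @param layer layer name recorded on the result (defaults to the `pos`
#'   attribute).
#' @param pooling pooling recorded on the result.
#' @return a `concept_vector` (unnormalised; the norm is recorded).
#' @export
fit_cav <- function(pos, neg, method = c("svm", "pattern"), layer = NULL,
                    pooling = NULL) {
  method <- match.arg(method)
  if (nrow(pos) == 0 || nrow(neg) == 0) stop("pos and neg must be non-empty")
  if (ncol(pos) != ncol(neg)) stop("pos and neg have different channel counts")
  layer <- layer %||% attr(pos, "layer")
  pooling <- pooling %||% attr(pos, "pooling") %||% "max_spatial"
  if (method == "pattern") {
    h <- colMeans(pos) - colMeans(neg)
    if (sqrt(sum(h^2)) < 1e-12) stop("no signal direction: class means coincide")
  } else {
    X <- rbind(pos, neg)
    t <- factor(c(rep(1, nrow(pos)), rep(0, nrow(neg))), levels = c(0, 1))
    fit <- e1071::svm(X, t, kernel = "linear", cost = 1, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    # orient towards the concept-present class
    if (mean(pos %*% w) < mean(neg %*% w)) w <- -w
    h <- w
  }
  new_concept_vector(h, layer, method, pooling)
}

#' Single-neuron concept vector (one-hot CAV)
#' @param model a `split_model`.
#' @param layer layer name.
#' @param i neuron (channel) index, 1-based.
#' @param pooling pooling convention recorded on the vector.
#' @return a `concept_vector` with a one-hot `h`.
#' @export
neuron_cav <- function(model, layer, i, pooling = "max_spatial") {
  m <- layer_channels(model, layer)
  if (i < 1 || i > m) stop("neuron index ", i, " out of range (m = ", m, ")")
  h <- numeric(m); h[i] <- 1
  new_concept_vector(h, layer, "neuron", pooling)
}

#' Unsupervised concept candidates by matrix decomposition
#'
#' @param acts `pooled_acts` matrix `n x m`.
#' @param k number of candidate directions (`k <= min(n, m)`).
#' @param method `"pca"` (components ordered by explained variance) or
#'   `"nmf"` (multiplicative-update factorisation; requires non-negative
#'   activations; components ordered by energy).
#' @param seed seed for the NMF initialisation.
#' @return list of `concept_vector`s.
#' @export
discover_concepts <- function(acts, k, method = c("pca", "nmf"), seed = 1L) {
  method <- match.arg(method)
  if (k > min(dim(acts))) stop("k must be <= min(n, m)")
  layer <- attr(acts, "layer"); pooling <- attr(acts, "pooling") %||% "max_spatial"
  X <- unclass(acts); attributes(X) <- list(dim = dim(acts))
  if (method == "pca") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    dirs <- lapply(seq_len(k), function(j) pc$rotation[, j])
  } else {
    if (min(X) < 0) stop("nmf requires non-negative activations")
    fit <- nmf_mu(X, k, seed = seed)
    energy <- vapply(seq_len(k), function(j)
      sum(outer(fit$W[, j], fit$H[j, ])^2), 0)
    ord <- order(energy, decreasing = TRUE)
    dirs <- lapply(ord, function(j) fit$H[j, ])
  }
  lapply(dirs, new_concept_vector, layer = layer, method = "decomposition",
         pooling = pooling)
}

# Lee-Seung multiplicative updates for X ~ W H (X: n x m, W: n x k, H: k x m)
nmf_mu <- function(X, k, n_iter = 200L, seed = 1L, eps = 1e-9) {
  withr::with_seed(seed, {
    n <- nrow(X); m <- ncol(X)
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  })
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  list(W = W, H = H)
}

#' Bias score: projection of pooled activations onto a concept vector
#'
#' \eqn{s_{bias} = h_l^\top a_l(x)} per sample; no normalisation is applied,
#' so scores scale with both the concept vector and the activations. High
#' scores indicate likely concept (artifact) presence.
#'
#' @param cav a `concept_vector`.
#' @param acts `pooled_acts` matrix `n x m` (same layer/pooling as the CAV).
#' @return numeric vector of n scores.
#' @export
bias_score <- function(cav, acts) {
  if (ncol(acts) != length(cav$h))
    stop("dimension mismatch: acts have ", ncol(acts), " channels, CAV has ",
         length(cav$h))
  as.vector(acts %*% cav$h)
}

#' Bias score on pooled class-conditional relevances
#'
#' Same dot-product contract as [bias_score()], applied to spatially pooled
#' latent *relevance* rows (see [relevance_rows()]), which are specific to the
#' attribution target class -- useful when a concept is artifactual for one
#' class but valid for another.
#'
#' @param cav a `concept_vector`.
#' @param pooled_relevances matrix `n x m` of pooled latent relevances.
#' @return numeric vector of n scores.
#' @export
relevance_bias_score <- function(cav, pooled_relevances) {
  bias_score(cav, pooled_relevances)
}

#' Pooled activations of a bundle split at a layer
#'
#' Convenience wrapper: forward the samples, pool spatially, return a
#' `pooled_acts` matrix.
#'
#' @inheritParams layer_activations
#' @param pooling pooling mode.
#' @export
pooled_layer_activations <- function(model, samples, layer,
                                     pooling = "max_spatial") {
  acts <- layer_activations(model, samples, layer)
  if (is.matrix(acts)) return(pool_activations(acts, "none", layer = layer))
  pool_activations(acts, pooling, layer = layer)
}

#' Serialize / read a concept vector as JSON
#' @param cav a `concept_vector`.
#' @param path file path.
#' @export
write_cav <- function(cav, path) {
  jsonlite::write_json(unclass(cav), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cav
#' @export
read_cav <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_concept_vector(d$h, d$layer, d$method, d$pooling)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
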
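# Bias mitigation: gradient-penalty finetuning losses (exposed standalone for
# inspection and testing; train_model() applies them during optimisation) and
# training-free projection editing of latent activations.

#' Right-for-the-right-reasons penalty for one sample
#'
#' \eqn{\sum_i (m_i \, \partial \log p(y|x) / \partial x_i)^2}: the squared
#' input gradient of the true-class log-probability, restricted to the
#' ground-truth artifact mask. Zero iff the model's decision gradient
#' vanishes inside the masked region.
#'
#' @param model a `split_model`.
#' @param x a `labeled_sample` (with `mask`) or data array.
#' @param y true class (defaults to the sample's label).
#' @param mask ground-truth artifact mask (defaults to the sample's mask).
#' @return scalar penalty.
#' @export
rrr_penalty <- function(model, x, y = NULL, mask = NULL) {
  data <- if (inherits(x, "labeled_sample")) x$data else x
  y <- y %||% if (inherits(x, "labeled_sample")) x$label else stop("y required")
  mask <- mask %||% if (inherits(x, "labeled_sample")) x$mask else NULL
  if (is.null(mask)) stop("rrr_penalty requires a ground-truth localization mask")
  xb <- sample_to_tensor(data)
  mb <- array(mask_to_tensor(mask, dim(xb)[1:3]), dim(xb))
  fw <- nn_forward(model, xb)
  pr <- penalty_rrr_batch(model, fw, as.integer(y), mb)
  pr$value
}

#' Latent concept-gradient penalty (RR-ClArC) for one sample
#'
#' \eqn{(\tilde h^\top \partial f_y / \partial a_l)^2} with the concept vector
#' broadcast over spatial positions: the squared directional derivative of the
#' true-class score along the bias direction in latent space. Zero iff the
#' class score is locally insensitive to the concept.
#'
#' @param model a `split_model`.
#' @param x a `labeled_sample` or data array.
#' @param y true class (defaults to the sample's label).
#' @param cav a `concept_vector` at a valid layer of `model`.
#' @return scalar penalty.
#' @export
rr_clarc_penalty <- function(model, x, y = NULL, cav) {
  data <- if (inherits(x, "labeled_sample")) x$data else x
  y <- y %||% if (inherits(x, "labeled_sample")) x$label else stop("y required")
  if (length(cav$h) != layer_channels(model, cav$layer))
    stop("concept vector length does not match layer channel count")
  xb <- sample_to_tensor(data)
  fw <- nn_forward(model, xb)
  pr <- penalty_rr_clarc_batch(model, fw, as.integer(y), cav)
  pr$value
}

# ---- projection editing ----------------------------------------------------

z0_from_policy <- function(model, cav, z0_policy, clean_samples = NULL) {
  if (identical(z0_policy, "zero")) return(0)
  if (is.null(clean_samples) || length(clean_samples) == 0)
    stop("z0_policy 'clean_mean' requires clean reference samples")
  pooled <- pooled_layer_activations(model, clean_samples, cav$layer, "mean_spatial")
  mean(pooled %*% (cav$h / cav$norm))
}

insert_projection <- function(model, cav, z0, threshold = NULL) {
  idx <- layer_index(model, cav$layer)
  proj_name <- paste0(cav$layer, "_edit")
  layer <- layer_projection(proj_name, cav$h, z0, threshold, cav$pooling)
  existing <- which(vapply(model$layers, `[[`, "", "name") == proj_name)
  if (length(existing) == 1L) {
    # declarative edit: re-applying replaces the descriptor (projector idempotence)
    model$layers[[existing]] <- layer
  } else {
    model$layers <- append(model$layers, list(layer), after = idx)
  }
  attr(model, "edit") <- list(layer = cav$layer, hhat = layer$hhat,
                              h_norm = layer$h_norm, z0 = z0, threshold = threshold)
  model
}

#' Projection-based concept removal (P-ClArC)
#'
#' Inserts an affine projection after the concept layer that removes the
#' activation component along the (unit-normalised) bias direction at every
#' spatial position, pinning it to the target value `z0`:
#' \eqn{a' = a - \hat h (\hat h^\top a - z_0)}. Directions orthogonal to
#' \eqn{\hat h} are untouched; activations already satisfying
#' \eqn{\hat h^\top a = z_0} pass through unchanged. Re-applying the edit with
#' the same concept replaces the descriptor, so the operation is idempotent.
#'
#' @param model a `split_model`.
#' @param cav a `concept_vector` (nonzero).
#' @param z0_policy `"clean_mean"` (mean projection value of labelled clean
#'   samples; requires `clean_samples`) or `"zero"`.
#' @param clean_samples reference clean samples for `"clean_mean"`.
#' @return the edited `split_model` (with an `edit` attribute describing the
#'   transform).
#' @export
apply_p_clarc <- function(model, cav, z0_policy = c("clean_mean", "zero"),
                          clean_samples = NULL) {
  z0_policy <- match.arg(z0_policy)
  if (cav$norm == 0) stop("concept vector has zero norm")
  z0 <- z0_from_policy(model, cav, z0_policy, clean_samples)
  insert_projection(model, cav, z0, threshold = NULL)
}

#' Reactive projection editing (rP-ClArC)
#'
#' Like [apply_p_clarc()], but the projection fires only for samples whose
#' pooled bias score at the concept layer exceeds `threshold`; activations of
#' below-threshold samples pass through bit-identically, protecting clean
#' samples from collateral damage.
#'
#' @inheritParams apply_p_clarc
#' @param threshold gate on the pooled bias score; default (`NULL`) uses the
#'   95th percentile of the clean reference samples' bias scores.
#' @return the edited `split_model`.
#' @export
apply_rp_clarc <- function(model, cav, z0_policy = c("clean_mean", "zero"),
                           clean_samples = NULL, threshold = NULL) {
  z0_policy <- match.arg(z0_policy)
  if (cav$norm == 0) stop("concept vector has zero norm")
  if (is.null(threshold)) {
    if (is.null(clean_samples))
      stop("default threshold requires clean reference samples")
    pooled <- pooled_layer_activations(model, clean_samples, cav$layer, cav$pooling)
    threshold <- as.numeric(stats::quantile(bias_score(cav, pooled), 0.95))
  }
  if (!is.finite(threshold) && threshold == -Inf) threshold <- -Inf
  z0 <- z0_from_policy(model, cav, z0_policy, clean_samples)
  insert_projection(model, cav, z0, threshold = threshold)
}

#' Pooled bias scores of a model at the edited (or any) layer
#'
#' Convenience used by the projection invariants: bias score of each sample
#' computed on the activations *after* any projection edit at `layer` (i.e. at
#' the projection output when present, else the layer output).
#'
#' @param model a `split_model`.
#' @param samples list of samples.
#' @param cav the `concept_vector`.
#' @param pooling pooling mode; `mean_spatial` commutes with the projection,
#'   so edited models give exactly `z0 * |h|`.
#' @return numeric scores.
#' @export
edited_bias_scores <- function(model, samples, cav, pooling = "mean_spatial") {
  proj_name <- paste0(cav$layer, "_edit")
  nms <- vapply(model$layers, `[[`, "", "name")
  layer <- if (proj_name %in% nms) proj_name else cav$layer
  pooled <- pooled_layer_activations(model, samples, layer, pooling)
  bias_score(cav, pooled)
}

#' Save an edited model's descriptor as JSON
#' @param model an edited `split_model`.
#' @param path output path.
#' @export
write_edit_descriptor <- function(model, path) {
  ed <- attr(model, "edit")
  if (is.null(ed)) stop("model carries no projection edit")
  jsonlite::write_json(ed, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
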
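# Re-evaluation metric suite: clean/biased accuracy, artifact relevance, IoU,
# retrieval AUROC/AP, and TCAV concept sensitivity, aggregated into one
# report for a model/concept pair.

#' Top-1 accuracy on a sample set
#' @param model a `split_model`.
#' @param samples list of `labeled_sample`s.
#' @return fraction correct.
#' @export
accuracy <- function(model, samples) {
  if (length(samples) == 0) stop("samples must be non-empty")
  scores <- predict_scores(model, samples)
  pred <- max.col(scores, ties.method = "first")
  y <- vapply(samples, `[[`, 0L, "label")
  mean(pred == y)
}

#' Fraction of positive relevance inside the ground-truth mask
#'
#' \eqn{\sum_{mask} R^+ / \sum R^+} using positive relevance only. Returns 0
#' (flagged) when the heatmap carries no positive relevance, and `NA`
#' (flagged) for an empty mask.
#'
#' @param input_map relevance heatmap (2D, or 3D summed over channels).
#' @param gt_mask binary ground-truth mask with the heatmap's spatial shape.
#' @return fraction in `[0, 1]` with attribute `flag` when degenerate.
#' @export
artifact_relevance <- function(input_map, gt_mask) {
  if (length(dim(input_map)) == 3L) input_map <- apply(input_map, c(1, 2), sum)
  if (!all(dim(input_map) == dim(gt_mask)))
    stop("heatmap and mask shapes differ")
  if (sum(gt_mask) == 0) {
    out <- NA_real_; attr(out, "flag") <- "empty_mask"; return(out)
  }
  pos <- pmax(input_map, 0)
  tot <- sum(pos)
  if (tot == 0) {
    out <- 0; attr(out, "flag") <- "no_positive_relevance"; return(out)
  }
  sum(pos[gt_mask == 1]) / tot
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' @param binary_mask,gt_mask 0/1 matrices of equal shape.
#' @return `|A intersect B| / |A union B|`; 1 (flagged) when both are empty.
#' @export
iou <- function(binary_mask, gt_mask) {
  if (!all(dim(binary_mask) == dim(gt_mask))) stop("mask shapes differ")
  a <- binary_mask > 0; b <- gt_mask > 0
  un <- sum(a | b)
  if (un == 0) {
    out <- 1; attr(out, "flag") <- "both_empty"; return(out)
  }
  sum(a & b) / un
}

#' TCAV concept-sensitivity score
#'
#' Fraction of samples whose target-class score has a positive directional
#' derivative along the unit concept direction at the CAV's layer (broadcast
#' over spatial positions). Zero derivatives count 0.5 each (tie rule), so a
#' model made exactly insensitive -- e.g. by projection editing -- scores
#' TCAV = 0.5, i.e. \eqn{\Delta TCAV = |TCAV - 0.5| = 0}.
#'
#' @param model a `split_model`.
#' @param cav a `concept_vector`.
#' @param samples list of samples.
#' @param target_class class whose score sensitivity is measured.
#' @param tol derivatives with `|d| <= tol` count as ties.
#' @return list with `tcav`, `delta_tcav` and the per-sample `derivatives`.
#' @export
tcav_score <- function(model, cav, samples, target_class, tol = 1e-9) {
  if (length(samples) == 0) stop("samples must be non-empty")
  b <- samples_to_batch(samples)
  fw <- nn_forward(model, b$x)
  n <- length(samples)
  onehot <- matrix(0, n, model$class_count)
  onehot[, target_class] <- 1
  # derivative w.r.t. the concept layer's own output; a projection edit
  # sitting after it is part of the head and annihilates the h-component
  bk <- nn_backward(model, fw, onehot, stop_at = cav$layer, param_grads = FALSE)
  gamma <- bk$grad
  hhat <- cav$h / cav$norm
  if (is.matrix(gamma)) {
    d <- as.vector(gamma %*% hhat)
  } else {
    dd <- dim(gamma)
    hb <- aperm(array(hhat, c(dd[3], dd[1], dd[2], dd[4])), c(2, 3, 1, 4))
    d <- colSums(matrix(gamma * hb, prod(dd[1:3]), dd[4]))
  }
  tcav <- (sum(d > tol) + 0.5 * sum(abs(d) <= tol)) / n
  list(tcav = tcav, delta_tcav = abs(tcav - 0.5), derivatives = d)
}

#' Full evaluation report for a model / concept pair
#'
#' Aggregates the metric suite on a bundle: accuracy on the clean and biased
#' test splits, mean artifact relevance of class-conditional input heatmaps on
#' biased test samples, localization IoU / artifact relevance of
#' concept-conditioned masks, retrieval AUROC/AP of the CAV on the biased +
#' clean test pool, and TCAV (on clean and biased splits). Localization
#' metrics are `NA` for non-localizable artifacts (brightness).
#'
#' @param model a `split_model`.
#' @param bundle a `dataset_bundle`.
#' @param cav a `concept_vector` modelling the artifact.
#' @param target_class class for relevance/TCAV targets; defaults to the
#'   artifact's target class.
#' @param n_loc max number of biased test samples used for the (slower)
#'   localization metrics.
#' @param rules LRP rule configuration.
#' @return an `eval_report` (list; also printable as one tibble row via
#'   [report_row()]).
#' @export
evaluation_report <- function(model, bundle, cav, target_class = NULL,
                              n_loc = 25L, rules = lrp_rules()) {
  spec <- bundle$artifact_spec
  target_class <- target_class %||% spec$target_class
  localizable <- artifact_localizable(spec)
  acc_clean <- accuracy(model, bundle$test_clean)
  acc_biased <- accuracy(model, bundle$test_biased)
  # artifact relevance of standard class heatmaps on biased test samples
  loc_samples <- bundle$test_biased[seq_len(min(n_loc, length(bundle$test_biased)))]
  art_rel <- NA_real_
  mean_iou <- NA_real_; mean_loc_rel <- NA_real_
  if (localizable) {
    rels <- vapply(loc_samples, function(s) {
      rb <- lrp_attribute(model, s, target_class, rules)
      as.numeric(artifact_relevance(rb$input_map, s$mask))
    }, 0)
    art_rel <- mean(rels, na.rm = TRUE)
    locs <- lapply(loc_samples, function(s) {
      lz <- localize_bias(model, s, cav, rules = rules)
      c(iou = as.numeric(iou(lz$binary, s$mask)),
        rel = as.numeric(artifact_relevance(lz$soft, s$mask)))
    })
    lm <- do.call(rbind, locs)
    mean_iou <- mean(lm[, "iou"], na.rm = TRUE)
    mean_loc_rel <- mean(lm[, "rel"], na.rm = TRUE)
  }
  pool <- c(bundle$test_biased, bundle$test_clean)
  rr <- rank_samples(cav, model, pool)
  tc_clean <- tcav_score(model, cav, bundle$test_clean, target_class)
  tc_biased <- tcav_score(model, cav, bundle$test_biased, target_class)
  structure(list(
    accuracy_clean = acc_clean, accuracy_biased = acc_biased,
    artifact_relevance = art_rel,
    localization = list(mean_iou = mean_iou, mean_artifact_relevance = mean_loc_rel),
    retrieval = list(auroc = attr(rr, "auroc"), ap = attr(rr, "ap")),
    tcav_clean = tc_clean$tcav, delta_tcav_clean = tc_clean$delta_tcav,
    tcav_biased = tc_biased$tcav, delta_tcav_biased = tc_biased$delta_tcav,
    target_class = target_class, localizable = localizable),
    class = "eval_report")
}

#' One-row tibble view of an evaluation report
#' @param report an `eval_report`.
#' @param label optional label column (e.g. `"vanilla"`, `"rr_clarc"`).
#' @export
report_row <- function(report, label = NA_character_) {
  tibble::tibble(
    model = label,
    accuracy_clean = report$accuracy_clean,
    accuracy_biased = report$accuracy_biased,
    artifact_relevance = report$artifact_relevance,
    loc_iou = report$localization$mean_iou,
    loc_artifact_relevance = report$localization$mean_artifact_relevance,
    auroc = report$retrieval$auroc, ap = report$retrieval$ap,
    tcav_clean = report$tcav_clean, delta_tcav_clean = report$delta_tcav_clean,
    tcav_biased = report$tcav_biased, delta_tcav_biased = report$delta_tcav_biased)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  accuracy: clean %.3f | biased %.3f\n", x$accuracy_clean, x$accuracy_biased))
  if (x$localizable) {
    cat(sprintf("  artifact relevance (class heatmaps): %.3f\n", x$artifact_relevance))
    cat(sprintf("  localization: IoU %.3f | artifact relevance %.3f\n",
                x$localization$mean_iou, x$localization$mean_artifact_relevance))
  } else {
    cat("  localization: not applicable (non-localizable artifact)\n")
  }
  cat(sprintf("  retrieval: AUROC %.3f | AP %.3f\n", x$retrieval$auroc, x$retrieval$ap))
  cat(sprintf("  TCAV: clean %.3f (delta %.3f) | biased %.3f (delta %.3f)\n",
              x$tcav_clean, x$delta_tcav_clean, x$tcav_biased, x$delta_tcav_biased))
  invisible(x)
}

#' Write an evaluation report as JSON (and optionally a CSV row)
#' @param report an `eval_report`.
#' @param path output `.json` path; a sibling `.csv` row is written too.
#' @param label row label for the CSV.
#' @export
write_report <- function(report, path, label = NA_character_) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.csv(report_row(report, label), sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}
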
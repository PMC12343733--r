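# Sample-level annotation (CAV-based retrieval ranking, percentile
# inspection, human-in-the-loop iterative label refinement) and feature-level
# annotation (soft / binary localization masks from concept-conditioned
# attribution).

# ---- retrieval metrics -----------------------------------------------------

#' Ranking metrics for binary retrieval
#'
#' AUROC via the rank-sum (Mann-Whitney) formula with tie correction; average
#' precision as the mean precision at each positive, with ties broken by the
#' given order.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical / 0-1 ground truth.
#' @return list with `auroc` and `ap`.
#' @export
retrieval_metrics <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(list(auroc = NA_real_, ap = NA_real_))
  r <- rank(scores)
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  hits <- labels[ord]
  prec_at_hit <- cumsum(hits)[hits] / which(hits)
  list(auroc = auroc, ap = mean(prec_at_hit))
}

#' Rank samples by bias score against a concept vector
#'
#' Computes activation-based (`bias_score`) or class-conditional
#' relevance-based (`relevance_bias_score`) scores for each sample, sorts
#' descending, and -- when artifact ground truth is available -- reports
#' AUROC and average precision of the implied retrieval.
#'
#' @param cav a `concept_vector`.
#' @param model a `split_model`.
#' @param samples list of `labeled_sample`s.
#' @param score_kind `"activation"` or `"relevance"`.
#' @param target target class, required for `score_kind = "relevance"`.
#' @return a `retrieval_result`: tibble (id, score, artifact_present, rank)
#'   ordered by descending score, with `auroc` / `ap` attributes.
#' @export
rank_samples <- function(cav, model, samples,
                         score_kind = c("activation", "relevance"),
                         target = NULL) {
  score_kind <- match.arg(score_kind)
  if (length(samples) == 0) stop("samples must be non-empty")
  scores <- if (score_kind == "activation") {
    acts <- pooled_layer_activations(model, samples, cav$layer, cav$pooling)
    bias_score(cav, acts)
  } else {
    if (is.null(target)) stop("relevance scores require a target class")
    rl <- relevance_rows(model, samples, space = "latent", layer = cav$layer,
                         pooling = cav$pooling, target = target)
    relevance_bias_score(cav, rl)
  }
  art <- vapply(samples, function(s) isTRUE(s$artifact_present), TRUE)
  ids <- vapply(samples, `[[`, "", "id")
  ord <- order(scores, decreasing = TRUE)
  res <- tibble::tibble(id = ids[ord], score = scores[ord],
                        artifact_present = art[ord],
                        rank = seq_along(ord))
  met <- retrieval_metrics(scores, art)
  attr(res, "auroc") <- met$auroc
  attr(res, "ap") <- met$ap
  class(res) <- c("retrieval_result", class(res))
  res
}

#' Samples at requested score percentiles, per label group
#'
#' For inspecting the head, tail and decision boundary of a retrieval: within
#' each annotation group, returns the sample whose score is nearest each
#' requested percentile. Surfaces e.g. artifact samples hiding in the
#' "clean" group (false negatives) at that group's upper percentiles.
#'
#' @param result a `retrieval_result` from [rank_samples()].
#' @param groups named character vector / factor mapping sample id to a group
#'   (e.g. `"artifact"`, `"clean"`, `"unknown"`). Missing ids form their own
#'   `"unknown"` group.
#' @param percentiles numeric percentiles in (0, 100).
#' @return tibble (group, percentile, id, score). Empty groups are skipped
#'   with a message.
#' @export
percentile_examples <- function(result, groups = NULL, percentiles = c(1, 50, 99)) {
  stopifnot(all(percentiles > 0 & percentiles < 100))
  g <- if (is.null(groups)) rep("all", nrow(result))
       else as.character(groups[result$id])
  g[is.na(g)] <- "unknown"
  out <- list()
  for (grp in unique(g)) {
    sub <- result[g == grp, ]
    if (nrow(sub) == 0) { message("group '", grp, "' is empty; skipped"); next }
    for (p in percentiles) {
      q <- stats::quantile(sub$score, p / 100, type = 1)
      i <- which.min(abs(sub$score - q))
      out[[length(out) + 1L]] <- tibble::tibble(
        group = grp, percentile = p, id = sub$id[i], score = sub$score[i])
    }
  }
  do.call(rbind, out)
}

# ---- iterative refinement --------------------------------------------------

#' Create a label state for iterative annotation
#'
#' @param ids all sample ids.
#' @param artifact_ids,clean_ids ids initially known to contain / not contain
#'   the artifact.
#' @return a `label_state`: per-sample annotation in
#'   `{"artifact", "clean", "unknown"}` plus an append-only audit log.
#' @export
label_state <- function(ids, artifact_ids = character(), clean_ids = character()) {
  lab <- stats::setNames(rep("unknown", length(ids)), ids)
  lab[artifact_ids] <- "artifact"
  lab[clean_ids] <- "clean"
  structure(list(labels = lab,
                 log = tibble::tibble(round = integer(), id = character(),
                                      from = character(), to = character()),
                 confirmed = character()),
            class = "label_state")
}

#' Iterative CAV refinement with an annotation oracle
#'
#' Emulates the annotate-inspect-refit loop: each round fits a CAV on the
#' current artifact/clean labels, ranks the not-yet-confirmed samples by bias
#' score, submits the `inspect_budget` top-ranked ids to the oracle (the
#' stand-in for a human annotator), records the returned labels, and logs
#' retrieval AP against the oracle's final labels of that round. Labels
#' confirmed by the oracle are never changed again.
#'
#' @param state a [label_state()].
#' @param model a `split_model`.
#' @param samples list of `labeled_sample`s (ids must match the state).
#' @param layer CAV layer.
#' @param oracle function(ids) returning `"artifact"`/`"clean"` per id.
#' @param inspect_budget ids inspected per round.
#' @param rounds number of refinement rounds.
#' @param cav_method `"svm"` or `"pattern"`.
#' @param holdout optional list of `labeled_sample`s on which per-round AP is
#'   additionally evaluated (using ground-truth flags).
#' @return list with final `state`, final `cav`, and `history` tibble
#'   (round, ap_train, ap_holdout).
#' @export
iterative_refinement <- function(state, model, samples, layer, oracle,
                                 inspect_budget = 10L, rounds = 3L,
                                 cav_method = "svm", holdout = NULL) {
  ids <- vapply(samples, `[[`, "", "id")
  pooled <- pooled_layer_activations(model, samples, layer)
  fit_round <- function(st) {
    pos <- which(st$labels[ids] == "artifact")
    neg <- which(st$labels[ids] == "clean")
    if (length(pos) < 2 || length(neg) < 2)
      stop("need >= 2 artifact and >= 2 clean labels to fit a CAV")
    fit_cav(pooled[pos, , drop = FALSE], pooled[neg, , drop = FALSE],
            method = cav_method, layer = layer,
            pooling = attr(pooled, "pooling"))
  }
  history <- list()
  cav <- fit_round(state)
  eval_ap <- function(cav) {
    if (is.null(holdout)) return(NA_real_)
    r <- rank_samples(cav, model, holdout)
    attr(r, "ap")
  }
  for (rd in seq_len(max(rounds, 1L))) {
    scores <- bias_score(cav, pooled)
    ap_train <- retrieval_metrics(
      scores, vapply(samples, function(s) isTRUE(s$artifact_present), TRUE))$ap
    history[[rd]] <- tibble::tibble(round = rd, ap_train = ap_train,
                                    ap_holdout = eval_ap(cav))
    if (rounds == 0L || inspect_budget == 0L) break
    cand <- ids[!(ids %in% state$confirmed) & state$labels[ids] != "artifact"]
    if (length(cand) == 0) break
    cand_scores <- scores[match(cand, ids)]
    query <- cand[order(cand_scores, decreasing = TRUE)][seq_len(min(inspect_budget, length(cand)))]
    truth <- oracle(query)
    for (j in seq_along(query)) {
      id <- query[j]
      old <- state$labels[[id]]
      if (old != truth[j]) {
        state$log <- rbind(state$log, tibble::tibble(
          round = rd, id = id, from = old, to = truth[j]))
        state$labels[[id]] <- truth[j]
      }
      state$confirmed <- union(state$confirmed, id)
    }
    cav <- fit_round(state)
  }
  list(state = state, cav = cav, history = do.call(rbind, history))
}

#' Ground-truth oracle from a sample list
#' @param samples list of `labeled_sample`s.
#' @return function(ids) -> `"artifact"`/`"clean"` from the samples' flags.
#' @export
ground_truth_oracle <- function(samples) {
  ids <- vapply(samples, `[[`, "", "id")
  art <- vapply(samples, function(s) isTRUE(s$artifact_present), TRUE)
  flags <- stats::setNames(ifelse(art, "artifact", "clean"), ids)
  function(query) unname(flags[query])
}

# ---- localization ----------------------------------------------------------

#' Otsu threshold of a non-negative map
#'
#' Maximises between-class variance over a 256-bin histogram.
#'
#' @param x numeric values in `[0, max]`.
#' @param levels number of histogram bins.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  sig <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sig[!is.finite(sig)] <- 0
  mids[which.max(sig)]
}

#' Localize a bias concept in input space
#'
#' The soft mask is the concept-conditioned input heatmap (channel-summed for
#' images), with negative relevance clipped at zero (positive evidence only)
#' and the upper tail clipped at the 99th percentile to stop single pixels
#' dominating the histogram. Binarization uses Otsu's threshold or a top-q
#' quantile.
#'
#' @param model a `split_model`.
#' @param x a `labeled_sample` or data array.
#' @param cav a `concept_vector`.
#' @param binarize `"otsu"` or `"quantile"`.
#' @param q quantile for `binarize = "quantile"` (mask = top `1 - q` share).
#' @param rules an [lrp_rules()] configuration.
#' @return list with `soft` (matrix, input spatial shape) and `binary`
#'   (0/1 matrix); an all-zero soft mask yields an all-zero binary mask with
#'   a warning.
#' @export
localize_bias <- function(model, x, cav, binarize = c("otsu", "quantile"),
                          q = 0.95, rules = lrp_rules()) {
  binarize <- match.arg(binarize)
  rb <- concept_conditioned_attribute(model, x, cav, rules)
  soft <- rb$input_map
  if (length(dim(soft)) == 3L) soft <- apply(soft, c(1, 2), sum)
  soft <- pmax(soft, 0)
  hi <- stats::quantile(soft, 0.99)
  if (hi > 0) soft <- pmin(soft, hi)
  if (max(soft) <= 0) {
    warning("all-zero soft mask; returning empty binary mask")
    return(list(soft = soft, binary = soft * 0))
  }
  thr <- if (binarize == "otsu") otsu_threshold(soft) else stats::quantile(soft, q)
  list(soft = soft, binary = (soft > thr) * 1)
}
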
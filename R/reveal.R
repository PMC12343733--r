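# Bias identification.
#
# Data perspective: spectral clustering of relevance patterns (input heatmaps
# or pooled latent relevances), ranked by Fisher separability of each cluster
# against the rest. Model perspective: embedding of channel-wise (concept)
# distance matrices with outlier scoring (Local Outlier Factor), and a
# real-sample variant of representation-activation analysis where each neuron
# is represented by how all neurons co-activate on its top-activating samples.

#' Pairwise distance matrix
#'
#' @param X matrix, rows are observations.
#' @param metric `"cosine"` or `"euclidean"`. A zero row under cosine has
#'   distance 1 to every other row (and 0 to itself), recorded by convention.
#' @return a `distance_matrix`: symmetric matrix with zero diagonal and a
#'   `metric` attribute. Cosine distances lie in `[0, 2]`.
#' @export
pairwise_distances <- function(X, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(X))
  } else {
    nrm <- sqrt(rowSums(X^2))
    zero <- nrm < 1e-12
    Xn <- X / pmax(nrm, 1e-12)
    S <- tcrossprod(Xn)
    S[zero, ] <- 0; S[, zero] <- 0
    D <- 1 - S
    D <- pmin(pmax(D, 0), 2)
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2
  attr(D, "metric") <- metric
  class(D) <- c("distance_matrix", "matrix", "array")
  D
}

# ---- spectral clustering ---------------------------------------------------

spectral_cluster <- function(D, k, seed = 1L) {
  n <- nrow(D)
  off <- D[upper.tri(D)]
  sigma <- stats::median(off)
  if (!is.finite(sigma) || sigma < 1e-12) sigma <- 1
  A <- exp(-D^2 / (2 * sigma^2))
  diag(A) <- 0
  deg <- pmax(rowSums(A), 1e-12)
  Dm <- 1 / sqrt(deg)
  Lsym <- diag(n) - A * outer(Dm, Dm)  # I - D^-1/2 A D^-1/2
  ev <- eigen(Lsym, symmetric = TRUE)
  vals <- rev(ev$values)            # ascending
  vecs <- ev$vectors[, rev(seq_len(n)), drop = FALSE]
  U <- vecs[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, 1e-12)
  km <- withr::with_seed(seed, stats::kmeans(U, centers = k, nstart = 10))
  list(labels = km$cluster, eigenvalues = vals, embedding = U)
}

fisher_separability <- function(E, labels) {
  # max over clusters of the two-class Fisher criterion (cluster vs rest) on
  # the spectral embedding coordinates, ridge-regularised
  scores <- vapply(sort(unique(labels)), function(cl) {
    a <- E[labels == cl, , drop = FALSE]
    b <- E[labels != cl, , drop = FALSE]
    if (nrow(a) < 1 || nrow(b) < 1) return(0)
    dm <- colMeans(a) - colMeans(b)
    Sw <- (cov_or_zero(a) * max(nrow(a) - 1, 1) +
           cov_or_zero(b) * max(nrow(b) - 1, 1)) / max(nrow(E) - 2, 1)
    Sw <- Sw + diag(1e-6, ncol(E))
    as.numeric(crossprod(dm, solve(Sw, dm)))
  }, 0)
  max(scores)
}

cov_or_zero <- function(X) {
  if (nrow(X) < 2) return(diag(0, ncol(X)))
  stats::cov(X)
}

#' Spectral relevance clustering
#'
#' Clusters rows of relevance patterns (flattened input heatmaps or pooled
#' latent relevances, typically one class at a time) with spectral clustering
#' on a Gaussian affinity over cosine distances (median-heuristic bandwidth).
#' The cluster count is chosen by the largest eigengap of the normalised
#' Laplacian within `n_clusters_range`; every candidate clustering is ranked
#' by Fisher separability (one cluster vs rest), and the most separable one is
#' returned.
#'
#' @param rows numeric matrix, one relevance pattern per row.
#' @param n_clusters_range candidate cluster counts (default `2:5`).
#' @param perspective `"input"` or `"latent"` (recorded on the report).
#' @param labels optional class labels; when given together with
#'   `class_filter`, rows are restricted to that class. Clustering mixed
#'   classes is allowed but warned, since clusters may then resemble classes
#'   rather than prediction strategies.
#' @param class_filter optional class to keep.
#' @param seed seed for k-means initialisation.
#' @return a `cluster_report`: list with `labels` (per retained row), `k`,
#'   `separability` (per candidate k), `eigenvalues`, `embedding` (2D, for
#'   plotting), `row_index` (indices of retained rows), `degenerate` flag.
#' @export
spray <- function(rows, n_clusters_range = 2:5, perspective = c("input", "latent"),
                  labels = NULL, class_filter = NULL, seed = 1L) {
  perspective <- match.arg(perspective)
  keep <- seq_len(nrow(rows))
  if (!is.null(class_filter)) {
    if (is.null(labels)) stop("class_filter requires labels")
    keep <- which(labels == class_filter)
    rows <- rows[keep, , drop = FALSE]
  } else if (is.null(labels)) {
    warning("spray() without a class filter: clusters may reflect classes, not strategies")
  }
  n <- nrow(rows)
  n_clusters_range <- n_clusters_range[n_clusters_range <= n]
  if (length(n_clusters_range) == 0) stop("fewer rows than requested clusters")
  D <- pairwise_distances(rows, "cosine")
  emb2 <- embed_distance_matrix(D, k = 2)
  if (max(D) < 1e-10) {
    return(structure(list(labels = rep(1L, n), k = 1L,
                          separability = stats::setNames(0, "1"),
                          eigenvalues = numeric(), embedding = emb2,
                          row_index = keep, perspective = perspective,
                          degenerate = TRUE), class = "cluster_report"))
  }
  fits <- lapply(n_clusters_range, function(k) spectral_cluster(D, k, seed))
  sep <- vapply(fits, function(f) fisher_separability(f$embedding, f$labels), 0)
  names(sep) <- n_clusters_range
  # eigengap within the candidate range, used as tie context; selection by
  # separability ranking
  best <- which.max(sep)
  structure(list(labels = fits[[best]]$labels, k = n_clusters_range[best],
                 separability = sep, eigenvalues = fits[[best]]$eigenvalues,
                 embedding = emb2, row_index = keep, perspective = perspective,
                 degenerate = FALSE), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %s perspective: k = %d over %d rows%s\n",
              x$perspective, x$k, length(x$labels),
              if (isTRUE(x$degenerate)) " (degenerate: identical rows)" else ""))
  print(table(cluster = x$labels))
  invisible(x)
}

# ---- embeddings ------------------------------------------------------------

embed_distance_matrix <- function(D, k = 2, method = c("mds", "pca"), seed = 1L) {
  method <- match.arg(method)
  n <- nrow(D)
  k <- min(k, n - 1L)
  E <- if (method == "mds") {
    e <- suppressWarnings(stats::cmdscale(D, k = k))
    if (ncol(e) < k) e <- cbind(e, matrix(0, n, k - ncol(e)))
    e
  } else {
    stats::prcomp(D)$x[, seq_len(k), drop = FALSE]
  }
  structure(E, method = method, seed = seed, class = c("embedding", "matrix", "array"))
}

#' Concept-distance embedding (model perspective)
#'
#' Computes the channel-wise (concept-wise) cosine distance matrix of pooled
#' latent relevance (or activation) columns and embeds it in `k = 2`
#' dimensions for inspection and outlier scoring. Dimension reduction uses
#' classical multidimensional scaling (or PCA of the distance profile rows).
#'
#' @param pooled matrix `n x m` of pooled latent relevances or activations.
#' @param embed_method `"mds"` or `"pca"`.
#' @param seed embedding seed (recorded; the backends are deterministic).
#' @return list with `embedding` (`m x 2`) and `distances` (`m x m`
#'   `distance_matrix`).
#' @export
concept_embedding <- function(pooled, embed_method = c("mds", "pca"), seed = 1L) {
  embed_method <- match.arg(embed_method)
  if (nrow(pooled) < 2 || ncol(pooled) < 2) stop("need n >= 2 and m >= 2")
  D <- pairwise_distances(t(pooled), "cosine")
  list(embedding = embed_distance_matrix(D, 2, embed_method, seed), distances = D)
}

# ---- Local Outlier Factor --------------------------------------------------

#' Local Outlier Factor scores
#'
#' Density-based outlier scores: the ratio of the average local reachability
#' density of a point's k nearest neighbours to its own. Scores near 1 are
#' inliers; substantially larger scores indicate outliers.
#'
#' @param points an `embedding` / matrix of coordinates, or a precomputed
#'   `distance_matrix`.
#' @param k number of neighbours (default `min(10, n - 1)`).
#' @return numeric vector of LOF scores, one per row.
#' @export
outlier_scores <- function(points, k = NULL) {
  D <- if (inherits(points, "distance_matrix")) unclass(points)
       else as.matrix(stats::dist(points))
  n <- nrow(D)
  if (is.null(k)) k <- min(10L, n - 1L)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " rows")
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    ord <- order(d)
    kd <- d[ord[k]]
    kdist[i] <- kd
    nb <- which(D[i, ] <= kd)
    nbrs[[i]] <- setdiff(nb, i)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbrs[[i]]], D[i, nbrs[[i]]])
    lrd[i] <- 1 / pmax(mean(reach), 1e-12)
  }
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], 0)
}

# ---- DORA-style real-sample analysis ---------------------------------------

#' Representation-activation analysis on real reference samples
#'
#' Each neuron (channel) is represented by its `top_q` most strongly
#' activating reference samples; its representation-activation vector
#' \eqn{v_i \in R^m} is the mean pooled activation of all `m` neurons on those
#' samples. Pairwise cosine distances between the `v_i` are embedded in 2D;
#' outlier neurons (e.g. an artifact-only channel) separate from the bulk.
#'
#' @param pooled `pooled_acts` matrix `n x m` on a reference set.
#' @param top_q number of top-activating samples per neuron (`<= n`).
#' @param embed_method passed to [embed_distance_matrix()].
#' @return list with `representation` (`m x m`, rows `v_i`), `distances`,
#'   `embedding` (`m x 2`).
#' @export
dora_real <- function(pooled, top_q = 10L, embed_method = "mds") {
  n <- nrow(pooled); m <- ncol(pooled)
  if (n == 0) stop("reference set is empty")
  if (top_q > n) stop("top_q exceeds the number of reference samples")
  V <- matrix(0, m, m)
  for (i in seq_len(m)) {
    top <- order(pooled[, i], decreasing = TRUE)[seq_len(top_q)]
    V[i, ] <- colMeans(pooled[top, , drop = FALSE])
  }
  D <- pairwise_distances(V, "cosine")
  list(representation = V, distances = D,
       embedding = embed_distance_matrix(D, 2, embed_method))
}

# ---- prototype summaries (mixture models on pooled latent relevances) ------

#' Prototype summaries of prediction strategies
#'
#' Fits a Gaussian mixture model to pooled latent relevance rows; component
#' means are returned as prototypes (stereotypical relevance distributions
#' over concepts), with per-sample responsibilities.
#'
#' @param pooled matrix `n x m` of pooled latent relevances.
#' @param n_components number of mixture components (`<= n`).
#' @param seed seed for the mixture initialisation.
#' @return list with `prototypes` (`n_components x m`), `responsibilities`
#'   (`n x n_components`, rows sum to 1), `assignment` (hard labels) and
#'   `model_name` (the mclust covariance model actually fitted; constrained
#'   models act as regularisation when covariances are near-singular).
#' @export
prototype_summaries <- function(pooled, n_components, seed = 1L) {
  n <- nrow(pooled)
  if (n < n_components) stop("need at least n_components rows")
  X <- unclass(pooled); attributes(X) <- list(dim = dim(pooled))
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the calling frame
  fit <- withr::with_seed(seed, suppressWarnings(
    mclust::Mclust(X, G = n_components, verbose = FALSE)))
  if (is.null(fit))
    fit <- withr::with_seed(seed, suppressWarnings(
      mclust::Mclust(X, G = n_components, modelNames = "EII", verbose = FALSE)))
  if (is.null(fit)) stop("mixture fit failed")
  mu <- fit$parameters$mean           # m x G
  list(prototypes = t(mu), responsibilities = fit$z,
       assignment = fit$classification, model_name = fit$modelName)
}

# ---- high-level wrapper ----------------------------------------------------

#' Run the reveal stage on a bundle
#'
#' Computes relevance patterns for the (clean) validation or test split and
#' applies the requested detection method(s); returns enrichment / outlier
#' summaries that can be checked against ground-truth artifact flags.
#'
#' @param model a `split_model`.
#' @param bundle a `dataset_bundle`.
#' @param layer latent layer for pooled relevances / activations.
#' @param methods subset of `c("spray_latent", "concept_lof", "dora_lof")`.
#' @param split which bundle split to analyse (default `"train"`).
#' @param class_filter class whose samples are analysed for the data
#'   perspective (defaults to the artifact's target class).
#' @param seed seed for stochastic steps.
#' @return list of per-method results; see vignette.
#' @export
reveal_bias <- function(model, bundle, layer,
                        methods = c("spray_latent", "concept_lof", "dora_lof"),
                        split = "train", class_filter = NULL, seed = 1L) {
  samples <- bundle[[split]]
  class_filter <- class_filter %||% bundle$artifact_spec$target_class
  out <- list()
  if (any(c("spray_latent", "concept_lof") %in% methods)) {
    rl <- relevance_rows(model, samples, space = "latent", layer = layer)
  }
  if ("spray_latent" %in% methods) {
    labs <- vapply(samples, `[[`, 0L, "label")
    rep_ <- spray(rl, perspective = "latent", labels = labs,
                  class_filter = class_filter, seed = seed)
    art <- vapply(samples, `[[`, TRUE, "artifact_present")[rep_$row_index]
    enrich <- vapply(seq_len(rep_$k), function(cl)
      mean(art[rep_$labels == cl]), 0)
    out$spray_latent <- list(report = rep_, artifact_fraction = enrich,
                             base_rate = mean(art))
  }
  if ("concept_lof" %in% methods) {
    ce <- concept_embedding(rl)
    out$concept_lof <- list(embedding = ce$embedding, distances = ce$distances,
                            lof = outlier_scores(ce$distances,
                                                 k = min(10L, nrow(ce$distances) - 1L)))
  }
  if ("dora_lof" %in% methods) {
    pa <- pooled_layer_activations(model, samples, layer)
    dr <- dora_real(pa, top_q = min(10L, nrow(pa)))
    out$dora_lof <- list(embedding = dr$embedding, distances = dr$distances,
                         lof = outlier_scores(dr$distances,
                                              k = min(10L, nrow(dr$distances) - 1L)))
  }
  out
}
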
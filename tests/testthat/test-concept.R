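test_that("spatial pooling matches its definition on constant and single-spike fields", {
  a <- array(0.7, c(4, 4, 3, 2))
  expect_true(all(pool_activations(a, "max_spatial") == 0.7))
  expect_true(all(pool_activations(a, "mean_spatial") == 0.7))
  b <- array(0, c(4, 4, 2, 1))
  b[2, 3, 1, 1] <- 5
  expect_equal(as.vector(pool_activations(b, "max_spatial")), c(5, 0))
  expect_equal(as.vector(pool_activations(b, "mean_spatial")), c(5 / 16, 0))
})

test_that("max pooling dominates mean pooling entrywise for non-negative activations", {
  withr::with_seed(1, a <- array(runif(5 * 5 * 4 * 6), c(5, 5, 4, 6)))
  expect_true(all(pool_activations(a, "max_spatial") >=
                    pool_activations(a, "mean_spatial")))
})

test_that("pattern-CAV recovers a planted shift direction under isotropic noise", {
  withr::with_seed(11, {
    m <- 16; n <- 2000
    d <- rnorm(m); d <- d / sqrt(sum(d^2)) * 2
    neg <- matrix(rnorm(n * m), n, m)
    pos <- matrix(rnorm(n * m), n, m) + matrix(d, n, m, byrow = TRUE)
  })
  cav <- fit_cav(pos, neg, "pattern", layer = "pool3")
  cosine <- sum(cav$h * d) / sqrt(sum(cav$h^2) * sum(d^2))
  expect_gte(cosine, 0.99)
})

test_that("both CAV methods find the positive direction in a separable 1D problem", {
  pos <- matrix(rep(2, 20), 20, 1)
  neg <- matrix(rep(0, 20), 20, 1)
  withr::with_seed(2, {
    pos <- pos + rnorm(20, sd = 0.1); dim(pos) <- c(20, 1)
    neg <- neg + rnorm(20, sd = 0.1); dim(neg) <- c(20, 1)
  })
  expect_gt(fit_cav(pos, neg, "pattern")$h, 0)
  expect_gt(fit_cav(pos, neg, "svm")$h, 0)
})

test_that("svm-CAV separates a linearly separable toy with perfect retrieval", {
  withr::with_seed(5, {
    pos <- matrix(rnorm(40 * 4, mean = 0), 40, 4); pos[, 2] <- pos[, 2] + 4
    neg <- matrix(rnorm(40 * 4, mean = 0), 40, 4)
  })
  cav <- fit_cav(pos, neg, "svm")
  sc <- bias_score(cav, rbind(pos, neg))
  met <- retrieval_metrics(sc, c(rep(TRUE, 40), rep(FALSE, 40)))
  expect_equal(met$auroc, 1)
  expect_equal(met$ap, 1)
})

test_that("pattern-CAV is more robust than svm-CAV to a correlated distractor", {
  withr::with_seed(9, {
    n <- 600; m <- 10
    d <- c(1, rep(0, m - 1))                 # planted concept (signal) direction
    g <- c(1, 1, rep(0, m - 2)) / sqrt(2)    # distractor overlapping the signal
    t <- rep(c(0, 1), each = n)
    noise <- outer(rnorm(2 * n, sd = 3), g) +
      matrix(rnorm(2 * n * m, sd = 0.3), 2 * n, m)
    X <- outer(t, d) + noise
  })
  cavp <- fit_cav(X[t == 1, ], X[t == 0, ], "pattern")
  cavs <- fit_cav(X[t == 1, ], X[t == 0, ], "svm")
  cosd <- function(h) abs(sum(h * d)) / sqrt(sum(h^2))
  expect_gt(cosd(cavp$h), cosd(cavs$h))
})

test_that("degenerate pattern fit reports a missing signal direction", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_cav(X, X, "pattern"), "no signal direction")
})

test_that("neuron CAVs are one-hot and their bias score is the pooled channel", {
  m <- fresh_model()
  cav <- neuron_cav(m, "pool2", 7)
  expect_equal(sum(cav$h), 1)
  expect_equal(which(cav$h == 1), 7)
  withr::with_seed(3, acts <- matrix(runif(5 * 16), 5, 16))
  expect_equal(bias_score(cav, acts), acts[, 7])
  expect_error(neuron_cav(m, "pool2", layer_channels(m, "pool2") + 1L),
               "out of range")
})

test_that("bias scores equal a naive per-channel summation loop", {
  withr::with_seed(7, {
    acts <- matrix(rnorm(6 * 9), 6, 9)
    h <- rnorm(9)
  })
  cav <- biaslens:::new_concept_vector(h, "pool3", "svm", "max_spatial")
  naive <- vapply(1:6, function(j) {
    acc <- 0
    for (c in 1:9) acc <- acc + h[c] * acts[j, c]
    acc
  }, 0)
  expect_equal(bias_score(cav, acts), naive, tolerance = 1e-9)
  expect_equal(bias_score(cav, acts * 0), rep(0, 6))
  cav2 <- cav; cav2$h <- 3 * cav$h
  expect_equal(bias_score(cav2, acts), 3 * bias_score(cav, acts))
  expect_error(bias_score(cav, acts[, 1:5]), "mismatch")
})

test_that("relevance-based scores keep the dot-product contract", {
  withr::with_seed(8, rel <- matrix(rnorm(4 * 5), 4, 5))
  cav <- biaslens:::new_concept_vector(c(0, 1, 0, 0, 0), "pool3", "neuron", "max_spatial")
  expect_equal(relevance_bias_score(cav, rel), rel[, 2])
  expect_equal(relevance_bias_score(cav, rel * 0), rep(0, 4))
})

test_that("activation and relevance rankings agree when one channel carries the signal", {
  # linear toy: channel 2 is both the informative feature and relevance carrier
  W <- matrix(0, 3, 2); W[2, 1] <- 1.5; W[3, 2] <- 1
  m <- dense_toy(W)
  withr::with_seed(4, samples <- lapply(1:8, function(i)
    toy_sample(c(runif(1), runif(1, 0, 3), runif(1)), label = 1L)))
  pooled <- pooled_layer_activations(m, samples, "flatten")
  cav <- biaslens:::new_concept_vector(c(0, 1, 0), "flatten", "neuron", "none")
  act_scores <- bias_score(cav, pooled)
  rel <- relevance_rows(m, samples, space = "latent", layer = "flatten", target = 1)
  rel_scores <- relevance_bias_score(cav, rel)
  expect_equal(order(act_scores), order(rel_scores))
})

test_that("pca discovery recovers a planted dominant direction with orthogonal components", {
  withr::with_seed(21, {
    m <- 12; n <- 300
    d <- rnorm(m); d <- d / sqrt(sum(d^2))
    X <- outer(rnorm(n, sd = 5), d) + matrix(rnorm(n * m, sd = 0.3), n, m)
  })
  cavs <- discover_concepts(pool_activations(X, "max_spatial"), k = 3, method = "pca")
  expect_length(cavs, 3)
  expect_gte(abs(sum(cavs[[1]]$h * d)) / sqrt(sum(cavs[[1]]$h^2)), 0.95)
  expect_lt(abs(sum(cavs[[1]]$h * cavs[[2]]$h)), 1e-6)
})

test_that("nmf discovery reconstructs rank-1 data and rejects negative input", {
  withr::with_seed(22, {
    w <- runif(30); h <- runif(8)
    X <- outer(w, h)
  })
  fit <- biaslens:::nmf_mu(X, 1, n_iter = 500, seed = 1)
  expect_lt(max(abs(fit$W %*% fit$H - X)), 1e-3)
  cavs <- discover_concepts(pool_activations(X, "max_spatial"), k = 2, method = "nmf")
  expect_length(cavs, 2)
  expect_error(discover_concepts(pool_activations(X - 1, "max_spatial"), 2, "nmf"),
               "non-negative")
})

test_that("concept vectors round-trip through JSON", {
  cav <- biaslens:::new_concept_vector(c(0.2, -1.4, 3), "pool2", "pattern", "max_spatial")
  path <- withr::local_tempfile(fileext = ".json")
  write_cav(cav, path)
  cav2 <- read_cav(path)
  expect_equal(cav2$h, cav$h)
  expect_equal(cav2$layer, cav$layer)
  expect_equal(cav2$norm, cav$norm)
})
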
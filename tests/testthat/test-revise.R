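test_that("rrr penalty vanishes for empty masks and matches the linear closed form", {
  W <- matrix(c(1, -2, 0.5, 0.3, 1.1, -0.7), 3, 2)
  m <- dense_toy(W)
  x <- c(0.4, 0.8, -0.2)
  s <- toy_sample(x, label = 1L)
  s$mask <- array(0, c(1, 1, 3))
  expect_equal(rrr_penalty(m, s), 0)
  # mask on feature 2 only: penalty = (m2 * d log p1 / d x2)^2
  mask <- array(c(0, 1, 0), c(1, 1, 3))
  scores <- as.vector(x %*% W)
  p <- exp(scores) / sum(exp(scores))
  g2 <- W[2, 1] - sum(p * W[2, ])   # d log p1 / d x2 for softmax-linear model
  expect_equal(rrr_penalty(m, s, mask = mask), g2^2, tolerance = 1e-8)
  expect_error(rrr_penalty(m, toy_sample(x)), "mask")
})

test_that("rrr penalty is zero when the model ignores the masked features", {
  W <- matrix(0, 3, 2); W[1, 1] <- 2; W[1, 2] <- -1   # only feature 1 used
  m <- dense_toy(W)
  s <- toy_sample(c(0.5, 0.9, 0.3), label = 1L)
  mask <- array(c(0, 1, 1), c(1, 1, 3))
  expect_equal(rrr_penalty(m, s, mask = mask), 0)
})

test_that("latent concept-gradient penalty has the (h . w)^2 closed form on a linear head", {
  W <- matrix(c(0.7, -0.3, 1.2, 0.1, 0.9, -1.5), 3, 2)
  m <- dense_toy(W)
  h <- c(1, 0.5, -2)
  cav <- biaslens:::new_concept_vector(h, "flatten", "pattern", "none")
  for (x in list(c(1, 2, 3), c(-1, 0.5, 0))) {
    s <- toy_sample(x, label = 2L)
    expect_equal(rr_clarc_penalty(m, s, cav = cav), sum(h * W[, 2])^2,
                 tolerance = 1e-10)
  }
  expect_equal(rr_clarc_penalty(m, toy_sample(c(1, 1, 1), label = 1L),
                                cav = biaslens:::new_concept_vector(
                                  c(0, 0, 0), "flatten", "pattern", "none")), 0)
})

test_that("latent penalty matches a finite-difference directional derivative", {
  m <- patch_model()
  b <- patch_bundle()
  s <- b$train[[1]]
  cav <- paired_artifact_cav(m, b, "pool3")
  pen <- rr_clarc_penalty(m, s, cav = cav)
  # finite differences: per-position squared slope of the true-class score
  xb <- biaslens:::sample_to_tensor(s$data)
  fw <- biaslens:::nn_forward(m, xb)
  a <- fw$acts[["pool3"]]
  idx <- biaslens:::layer_index(m, "pool3")
  head_fwd <- function(act) {
    cur <- act
    for (j in (idx + 1):length(m$layers)) {
      l <- m$layers[[j]]
      cur <- switch(l$type,
        relu = pmax(cur, 0),
        flatten = biaslens:::flatten_forward(cur)$y,
        dense = cur %*% l$W + matrix(l$b, nrow(cur), length(l$b), byrow = TRUE))
    }
    cur
  }
  d <- dim(a)
  alpha <- 1e-5
  fd_sum <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ap <- a; am <- a
    ap[i, j, , 1] <- ap[i, j, , 1] + alpha * cav$h
    am[i, j, , 1] <- am[i, j, , 1] - alpha * cav$h
    slope <- (head_fwd(ap)[1, s$label] - head_fwd(am)[1, s$label]) / (2 * alpha)
    fd_sum <- fd_sum + slope^2
  }
  expect_equal(pen, fd_sum, tolerance = 1e-4)
})

test_that("projection editing pins the mean-pooled bias score at z0 * |h| for any input", {
  m <- patch_model()
  b <- patch_bundle()
  cav <- paired_artifact_cav(m, b, "pool3")
  clean_train <- Filter(function(s) !isTRUE(s$artifact_present), b$train)
  edited <- apply_p_clarc(m, cav, "clean_mean", clean_train)
  z0 <- attr(edited, "edit")$z0
  pool <- c(b$test_clean[1:10], b$test_biased[1:10])
  sc <- edited_bias_scores(edited, pool, cav, pooling = "mean_spatial")
  expect_lt(max(abs(sc - z0 * cav$norm)), 1e-5)
  zeroed <- apply_p_clarc(m, cav, "zero")
  sc0 <- edited_bias_scores(zeroed, pool, cav, pooling = "mean_spatial")
  expect_lt(max(abs(sc0)), 1e-8)
})

test_that("activations already in the target plane pass the projection unchanged", {
  h <- c(1, 0, 0, 0)
  cav <- biaslens:::new_concept_vector(h, "any", "pattern", "mean_spatial")
  layer <- biaslens:::layer_projection("e", h, z0 = 0.4)
  a <- array(runif(2 * 2 * 4 * 3), c(2, 2, 4, 3))
  a[, , 1, ] <- 0.4   # hhat component already equals z0 everywhere
  out <- biaslens:::projection_forward(layer, a)
  expect_equal(out$y, a, tolerance = 1e-12)
  # orthogonal directions are untouched even when projection fires
  a2 <- a; a2[, , 1, ] <- 2
  out2 <- biaslens:::projection_forward(layer, a2)
  expect_equal(out2$y[, , 2:4, ], a2[, , 2:4, ])
  expect_equal(out2$y[, , 1, ], array(0.4, c(2, 2, 3)))
})

test_that("re-applying a projection edit replaces it: double application equals single", {
  m <- patch_model()
  b <- patch_bundle()
  cav <- paired_artifact_cav(m, b, "pool3")
  e1 <- apply_p_clarc(m, cav, "zero")
  e2 <- apply_p_clarc(e1, cav, "zero")
  expect_equal(length(e1$layers), length(e2$layers))
  x <- b$test_biased[1:5]
  expect_identical(predict_scores(e2, x), predict_scores(e1, x))
  cav0 <- cav; cav0$h <- cav$h * 0; cav0$norm <- 0
  expect_error(apply_p_clarc(m, cav0, "zero"), "norm")
})

test_that("reactive gates reduce to always-on / never-on at infinite thresholds", {
  m <- patch_model()
  b <- patch_bundle()
  cav <- paired_artifact_cav(m, b, "pool3")
  x <- c(b$test_clean[1:5], b$test_biased[1:5])
  always <- apply_rp_clarc(m, cav, "zero", threshold = -Inf)
  plain <- apply_p_clarc(m, cav, "zero")
  expect_equal(predict_scores(always, x), predict_scores(plain, x), tolerance = 1e-12)
  never <- apply_rp_clarc(m, cav, "zero", threshold = Inf)
  expect_identical(predict_scores(never, x), predict_scores(m, x))
})

test_that("the default reactive threshold spares most clean samples and hits biased ones", {
  m <- patch_model()
  b <- patch_bundle()
  cav <- paired_artifact_cav(m, b, "pool3")
  clean_train <- Filter(function(s) !isTRUE(s$artifact_present), b$train)
  rp <- apply_rp_clarc(m, cav, "clean_mean", clean_samples = clean_train)
  sc_clean <- predict_scores(rp, b$test_clean)
  sc_clean_orig <- predict_scores(m, b$test_clean)
  frac_untouched <- mean(rowSums(abs(sc_clean - sc_clean_orig)) < 1e-12)
  expect_gte(frac_untouched, 0.8)
  sc_b <- predict_scores(rp, b$test_biased)
  sc_b_orig <- predict_scores(m, b$test_biased)
  expect_gt(mean(rowSums(abs(sc_b - sc_b_orig)) > 1e-12), 0.5)
})

test_that("projection editing zeroes the TCAV directional derivative exactly", {
  m <- patch_model()
  b <- patch_bundle()
  cav <- paired_artifact_cav(m, b, "pool3")
  edited <- apply_p_clarc(m, cav, "zero")
  tc <- tcav_score(edited, cav, b$test_biased[1:20], 1)
  expect_lt(max(abs(tc$derivatives)), 1e-8)
  expect_equal(tc$tcav, 0.5)
  expect_equal(tc$delta_tcav, 0)
})

test_that("edit descriptors serialize the transform", {
  m <- patch_model()
  cav <- paired_artifact_cav(m, patch_bundle(), "pool3")
  edited <- apply_p_clarc(m, cav, "zero")
  path <- withr::local_tempfile(fileext = ".json")
  write_edit_descriptor(edited, path)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(d$layer, "pool3")
  expect_equal(length(d$hhat), length(cav$h))
  expect_error(write_edit_descriptor(m, path), "no projection edit")
})
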
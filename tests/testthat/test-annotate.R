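test_that("retrieval metrics are exact for perfect rankings and ~0.5 for random scores", {
  labels <- c(rep(TRUE, 5), rep(FALSE, 5))
  met <- retrieval_metrics(10:1, labels)
  expect_equal(met$auroc, 1)
  expect_equal(met$ap, 1)
  met0 <- retrieval_metrics(1:10, labels)
  expect_equal(met0$auroc, 0)
  withr::with_seed(10, {
    n <- 2000
    lab <- rep(c(TRUE, FALSE), n / 2)
    sc <- rnorm(n)
  })
  met_r <- retrieval_metrics(sc, lab)
  expect_lt(abs(met_r$auroc - 0.5), 0.05)
})

test_that("rank-formula AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    sc <- rnorm(200)
    lab <- runif(200) < plogis(sc)
  })
  met <- retrieval_metrics(sc, lab)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))))
  expect_equal(met$auroc, ref, tolerance = 1e-9)
})

test_that("rank_samples orders by score, reports metrics, and rescales invariantly", {
  m <- patch_model()
  b <- patch_bundle()
  pool <- c(b$test_biased[1:20], b$test_clean[1:20])
  cav <- paired_artifact_cav(m, b, "pool3")
  rr <- rank_samples(cav, m, pool)
  expect_equal(rr$score, sort(rr$score, decreasing = TRUE))
  expect_true(attr(rr, "auroc") >= 0 && attr(rr, "auroc") <= 1)
  cav2 <- cav; cav2$h <- cav$h * 10
  rr2 <- rank_samples(cav2, m, pool)
  expect_equal(rr2$id, rr$id)
  rrel <- rank_samples(cav, m, pool[1:10], score_kind = "relevance", target = 1)
  expect_equal(nrow(rrel), 10)
  expect_error(rank_samples(cav, m, pool, score_kind = "relevance"), "target")
})

test_that("percentile examples return order statistics per group and skip empty groups", {
  res <- tibble::tibble(id = paste0("s", 1:100), score = 100:1,
                        artifact_present = FALSE, rank = 1:100)
  class(res) <- c("retrieval_result", class(res))
  out <- percentile_examples(res, percentiles = c(1, 99))
  expect_equal(out$id[out$percentile == 99], "s2")  # 99th percentile of scores 1..100
  groups <- stats::setNames(rep(c("a", "b"), 50), res$id)
  out2 <- percentile_examples(res, groups, percentiles = 50)
  expect_equal(nrow(out2), 2)
  one <- res[1, ]
  expect_equal(nrow(percentile_examples(one, percentiles = c(1, 50, 99))), 3)
})

test_that("a mislabeled artifact sample surfaces at the top percentile of the clean group", {
  m <- patch_model()
  b <- patch_bundle()
  arts <- Filter(function(s) s$artifact_present, b$train)
  cleans <- Filter(function(s) !s$artifact_present, b$train)
  pool <- c(arts[1:10], cleans[1:20], arts[11])   # arts[[11]] planted as "clean"
  cav <- paired_artifact_cav(m, b, "pool3")
  rr <- rank_samples(cav, m, pool)
  groups <- stats::setNames(c(rep("artifact", 10), rep("clean", 21)),
                            vapply(pool, `[[`, "", "id"))
  out <- percentile_examples(rr, groups, percentiles = 99)
  expect_equal(out$id[out$group == "clean"], arts[[11]]$id)
})

test_that("refinement is a fixed point on complete correct labels and respects rounds = 0", {
  m <- patch_model()
  b <- patch_bundle()
  samples <- b$train
  ids <- vapply(samples, `[[`, "", "id")
  art <- vapply(samples, function(s) isTRUE(s$artifact_present), TRUE)
  st <- label_state(ids, artifact_ids = ids[art], clean_ids = ids[!art])
  oracle <- ground_truth_oracle(samples)
  out <- iterative_refinement(st, m, samples, "pool3", oracle,
                              inspect_budget = 5, rounds = 2)
  expect_equal(nrow(out$state$log), 0)        # nothing relabeled
  expect_equal(out$state$labels, st$labels)
  out0 <- iterative_refinement(st, m, samples, "pool3", oracle,
                               inspect_budget = 5, rounds = 0)
  expect_equal(nrow(out0$history), 1)
})

test_that("refinement corrects planted false negatives and never relabels confirmed ids", {
  m <- patch_model()
  b <- patch_bundle()
  samples <- b$train
  ids <- vapply(samples, `[[`, "", "id")
  art <- vapply(samples, function(s) isTRUE(s$artifact_present), TRUE)
  withr::with_seed(17, {
    seed_art <- sample(ids[art], 10)
    fn <- sample(setdiff(ids[art], seed_art), 8)  # false negatives in "clean"
  })
  clean_lab <- c(ids[!art], fn)
  st <- label_state(ids, artifact_ids = seed_art, clean_ids = clean_lab)
  out <- iterative_refinement(st, m, samples, "pool3", ground_truth_oracle(samples),
                              inspect_budget = 10, rounds = 3)
  relabeled <- out$state$log$id
  expect_gt(sum(fn %in% relabeled), 0)
  expect_true(all(out$state$labels[relabeled] == "artifact"))
  # confirmed entries keep their oracle-assigned label in the final state
  for (id in out$state$confirmed)
    expect_equal(unname(out$state$labels[id]),
                 ifelse(art[match(id, ids)], "artifact", "clean"))
})

test_that("otsu threshold separates a perfectly bimodal map exactly", {
  soft <- matrix(0.1, 16, 16)
  soft[3:6, 3:6] <- 0.9
  thr <- otsu_threshold(soft)
  expect_true(thr > 0.1 && thr < 0.9)
  expect_equal((soft > thr) * 1, (soft == 0.9) * 1)
})

test_that("otsu threshold agrees with an independent implementation on noisy maps", {
  skip_if_not_installed("EBImage")
  withr::with_seed(19, x <- c(rnorm(300, 0.2, 0.05), rnorm(100, 0.8, 0.05)))
  x <- pmin(pmax(x, 0), 1)
  ours <- otsu_threshold(matrix(x, 20, 20))
  ref <- EBImage::otsu(matrix(x, 20, 20), range = c(0, 1))
  # thresholds are histogram approximations: the induced binary masks must
  # agree up to the samples straddling neighbouring bins (< 1%)
  expect_lte(mean((x > ours) != (x > ref)), 0.01)
  # and against a brute-force maximiser of the between-class variance
  cand <- sort(unique(x))
  bc <- vapply(cand, function(t) {
    a <- x[x <= t]; b <- x[x > t]
    if (!length(a) || !length(b)) return(0)
    length(a) * length(b) / length(x)^2 * (mean(a) - mean(b))^2
  }, 0)
  expect_lte(mean((x > ours) != (x > cand[which.max(bc)])), 0.01)
})

test_that("localization returns aligned masks and handles the zero-concept edge case", {
  m <- patch_model()
  b <- patch_bundle()
  s <- Filter(function(x) x$artifact_present, b$test_biased)[[1]]
  cav <- paired_artifact_cav(m, b, "pool3")
  lz <- localize_bias(m, s, cav)
  expect_equal(dim(lz$soft), dim(s$mask))
  expect_true(all(lz$binary %in% c(0, 1)))
  expect_true(all(lz$soft >= 0))
  cav0 <- cav; cav0$h <- cav$h * 0
  expect_warning(lz0 <- localize_bias(m, s, cav0), "all-zero")
  expect_true(all(lz0$binary == 0))
  lzq <- localize_bias(m, s, cav, binarize = "quantile", q = 0.9)
  expect_lte(mean(lzq$binary), 0.2)
})

test_that("localization masks sit at the input coordinates of a planted single-pixel feature", {
  # linear toy on a 4x1 single-channel "image": flatten features = rows, so a
  # one-hot concept on feature 3 must localize to row 3 exactly
  W <- diag(4)[, 1:2]
  m <- dense_toy(W)
  m$input_shape <- c(4L, 1L, 1L)
  s <- biaslens:::new_labeled_sample(array(c(0.2, 0.1, 0.9, 0.4), c(4, 1, 1)), 1L)
  cav <- biaslens:::new_concept_vector(c(0, 0, 1, 0), "flatten", "neuron", "none")
  lz <- localize_bias(m, s, cav)
  expect_equal(dim(lz$soft), c(4L, 1L))
  expect_equal(which(lz$soft == max(lz$soft)), 3L)
})
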
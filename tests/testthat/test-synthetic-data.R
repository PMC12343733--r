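test_that("insertion rate controls exactly how many target-class samples carry the artifact", {
  for (p in c(0, 0.5, 1)) {
    b <- generate_image_dataset(10, 32, 2, artifact_spec("corner_patch", p, 1),
                                seed = 1)
    art <- vapply(b$train, `[[`, TRUE, "artifact_present")
    lab <- vapply(b$train, `[[`, 0L, "label")
    expect_equal(sum(art), round(p * 10))
    expect_true(all(lab[art] == 1L))
  }
})

test_that("identical seeds give byte-identical bundles, different seeds differ", {
  b1 <- generate_image_dataset(6, 32, 2, artifact_spec("ring", 0.5, 1), seed = 4)
  b2 <- generate_image_dataset(6, 32, 2, artifact_spec("ring", 0.5, 1), seed = 4)
  b3 <- generate_image_dataset(6, 32, 2, artifact_spec("ring", 0.5, 1), seed = 5)
  expect_identical(b1, b2)
  expect_false(identical(b1$train[[1]]$data, b3$train[[1]]$data))
})

test_that("biased test split carries the artifact in every sample of every class", {
  b <- generate_image_dataset(6, 32, 2, artifact_spec("corner_patch", 0.3, 1), seed = 2)
  expect_true(all(vapply(b$test_biased, `[[`, TRUE, "artifact_present")))
  expect_false(any(vapply(b$test_clean, `[[`, TRUE, "artifact_present")))
  expect_equal(vapply(b$test_biased, `[[`, 0L, "label"),
               vapply(b$test_clean, `[[`, 0L, "label"))
})

test_that("localizable artifacts modify only pixels inside their mask", {
  b <- generate_image_dataset(6, 32, 2, artifact_spec("corner_patch", 0, 1), seed = 3)
  s <- b$train[[1]]
  for (kind in c("ring", "corner_patch")) {
    out <- insert_artifact(s, artifact_spec(kind, 1, 1), jitter_seed = 8)
    expect_true(out$artifact_present)
    expect_gt(sum(out$mask), 0)
    off <- out$mask == 0
    expect_identical(out$data[, , 1][off], s$data[, , 1][off])
  }
})

test_that("brightness adds a clipped constant and flags a non-localizable all-ones mask", {
  s <- biaslens:::new_labeled_sample(array(0.5, c(32, 32, 1)), 1L)
  out <- insert_artifact(s, artifact_spec("brightness", 1, 1,
                                          params = list(delta = 0.2)))
  expect_equal(max(abs(out$data - 0.7)), 0)
  expect_true(all(out$mask == 1))
  expect_true(isTRUE(attr(out$mask, "non_localizable")))
  s2 <- biaslens:::new_labeled_sample(array(0.95, c(32, 32, 1)), 1L)
  expect_equal(max(insert_artifact(s2, artifact_spec("brightness", 1, 1))$data), 1)
})

test_that("static noise marks exactly the configured segment of one channel", {
  spec <- artifact_spec("static_noise", 1, 1,
                        params = list(start = 10L, length = 25L, channel = 2L))
  b <- generate_signal_dataset(5, 128, 3, spec, seed = 1)
  s <- Filter(function(x) x$artifact_present, b$train)[[1]]
  expect_equal(sum(s$mask), 25)
  expect_equal(sum(s$mask[, 2]), 25)
  expect_equal(sum(s$mask[, -2]), 0)
  expect_true(all(which(s$mask[, 2] == 1) == 10:34))
})

test_that("zero-amplitude static noise leaves the biased test split equal to the clean one", {
  spec <- artifact_spec("static_noise", 1, 1, params = list(amplitude = 0))
  b <- generate_signal_dataset(5, 128, 2, spec, seed = 2)
  for (i in seq_along(b$test_clean))
    expect_identical(b$test_biased[[i]]$data, b$test_clean[[i]]$data)
})

test_that("signal classes differ in beat amplitude as configured, recovered from sample peaks", {
  spec <- artifact_spec("static_noise", 0, 1)
  b <- generate_signal_dataset(200, 128, 2, spec, seed = 6)
  peak <- function(s) max(s$data[, 1])
  lab <- vapply(b$train, `[[`, 0L, "label")
  p1 <- vapply(b$train[lab == 1], peak, 0)
  p2 <- vapply(b$train[lab == 2], peak, 0)
  diff_obs <- mean(p2) - mean(p1)
  se <- sqrt(stats::var(p1) / length(p1) + stats::var(p2) / length(p2))
  # generator parameters: amplitudes 1.0 vs 1.6 -> expected peak gap ~ 0.6
  expect_lt(abs(diff_obs - 0.6), 3 * se + 0.1)
  expect_gt(diff_obs, 10 * se)
})

test_that("artifact presence in the train split correlates with the target class exactly as constructed", {
  p <- 0.8; n <- 40
  b <- generate_image_dataset(n, 32, 2, artifact_spec("corner_patch", p, 1), seed = 12)
  art <- as.numeric(vapply(b$train, `[[`, TRUE, "artifact_present"))
  tgt <- as.numeric(vapply(b$train, `[[`, 0L, "label") == 1L)
  # analytic point-biserial correlation for k artifacts among n target of 2n
  k <- round(p * n); N <- 2 * n
  pa <- k / N; pt <- 1 / 2
  expected <- (k / N - pa * pt) / sqrt(pa * (1 - pa) * pt * (1 - pt))
  expect_equal(stats::cor(art, tgt), expected, tolerance = 1e-9)
})

test_that("invalid artifact configurations fail with informative errors", {
  expect_error(artifact_spec("corner_patch", 1.4, 1), "insertion_rate_p")
  expect_error(artifact_spec("ring", 0.5, 1, params = list(bogus = 1)), "bogus")
  s <- biaslens:::new_labeled_sample(array(0.5, c(32, 32, 1)), 1L)
  expect_error(insert_artifact(s, artifact_spec("ring", 1, 1,
                                                params = list(radius = 0.9))), "radius")
  expect_error(insert_artifact(s, artifact_spec("static_noise", 1, 1)), "1D signal")
  sig <- biaslens:::new_labeled_sample(matrix(0, 64, 2), 1L)
  expect_error(insert_artifact(sig, artifact_spec("corner_patch", 1, 1)), "2D image")
  expect_error(generate_signal_dataset(5, 64, 2,
    artifact_spec("static_noise", 1, 1, params = list(start = 60L, length = 25L))),
    "segment")
  expect_error(generate_signal_dataset(5, 64, 1, artifact_spec("static_noise", 1, 1)),
               "channels")
})

test_that("a bundle round-trips to disk as text formats with a manifest", {
  b <- generate_image_dataset(4, 32, 2, artifact_spec("corner_patch", 0.5, 1), seed = 1)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(nrow(man), length(b$train) + length(b$val) +
                 length(b$test_clean) + length(b$test_biased))
  one <- man[man$artifact_present & man$split == "train", ][1, ]
  img <- png::readPNG(file.path(dir, one$data))
  expect_equal(dim(img), c(32, 32))
  mk <- png::readPNG(file.path(dir, one$mask))
  expect_true(all(mk %in% c(0, 1)))
})
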
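# Shared fixtures. Trained models are the expensive part of this suite, so
# they are built lazily once and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

patch_bundle <- function() fixture("patch_bundle", function()
  generate_image_dataset(60, 32, 2, artifact_spec("corner_patch", 0.8, 1),
                         seed = 7))

patch_model <- function() fixture("patch_model", function()
  train_model(build_model("cnn2d_small", 2, seed = 2), patch_bundle(),
              train_config(epochs = 12, seed = 2, learning_rate = 5e-3)))

p1_bundle <- function() fixture("p1_bundle", function()
  generate_image_dataset(50, 32, 2, artifact_spec("corner_patch", 1, 1),
                         seed = 9))

p1_model <- function() fixture("p1_model", function()
  train_model(build_model("cnn2d_small", 2, seed = 3), p1_bundle(),
              train_config(epochs = 10, seed = 3, learning_rate = 5e-3)))

signal_bundle <- function() fixture("signal_bundle", function()
  generate_signal_dataset(40, 128, 3, artifact_spec("static_noise", 0.8, 1),
                          seed = 3))

# untrained models are cheap but used in many places
fresh_model <- function(seed = 1L, classes = 2L)
  build_model("cnn2d_small", classes, seed = seed)

# toy model: flatten + single dense layer on a 1 x 1 x m "image", so closed
# forms for the epsilon-rule and penalties are available
dense_toy <- function(W, b = NULL) {
  m <- nrow(W); k <- ncol(W)
  if (is.null(b)) b <- numeric(k)
  dn <- biaslens:::layer_dense("dense", m, k)
  dn$W <- W; dn$b <- b
  structure(list(layers = list(biaslens:::layer_flatten("flatten"), dn),
                 arch = "toy_dense", class_count = k,
                 input_shape = c(1L, 1L, m), seed = 0L),
            class = "split_model")
}

toy_sample <- function(x, label = 1L)
  biaslens:::new_labeled_sample(array(x, c(1L, 1L, length(x))), label,
                                id = "toy")

# independent epsilon-rule oracle for a dense layer, written as plain loops
naive_eps_dense <- function(x, W, b, R, eps = 1e-6) {
  z <- as.vector(x %*% W) + b
  Rin <- numeric(length(x))
  for (i in seq_along(x)) {
    acc <- 0
    for (j in seq_along(z)) {
      denom <- z[j] + eps * if (z[j] >= 0) 1 else -1
      acc <- acc + x[i] * W[i, j] / denom * R[j]
    }
    Rin[i] <- acc
  }
  Rin
}
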
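# Minimal CNN engine: im2col convolutions, max-pooling, dense layers, Adam,
# plus the layer-internal hooks (cached gates, JVPs, per-layer deltas) that the
# LRP engine and the gradient-penalty losses need.
#
# Batch tensor convention: images are H x W x C x N arrays; 1D signals are
# represented internally as L x 1 x C x N so one code path serves both.

# ---- layer constructors ----------------------------------------------------

layer_conv <- function(name, kh, kw, cin, cout, pad = c(0L, 0L)) {
  list(type = "conv", name = name, kh = kh, kw = kw, cin = cin, cout = cout,
       pad = as.integer(pad), W = array(0, c(kh, kw, cin, cout)), b = numeric(cout))
}

layer_relu <- function(name) list(type = "relu", name = name)

layer_pool <- function(name, kh, kw) {
  list(type = "pool", name = name, kh = as.integer(kh), kw = as.integer(kw))
}

layer_flatten <- function(name) list(type = "flatten", name = name)

layer_dense <- function(name, n_in, n_out) {
  list(type = "dense", name = name, n_in = n_in, n_out = n_out,
       W = matrix(0, n_in, n_out), b = numeric(n_out))
}

# Affine projection edit a' = a - hhat (hhat^T a - z0), applied per spatial
# position; optionally gated per sample by a pooled bias score threshold.
layer_projection <- function(name, h, z0, threshold = NULL, pooling = "max_spatial") {
  nrm <- sqrt(sum(h^2))
  if (nrm == 0) stop("projection edit requires a nonzero concept vector")
  list(type = "projection", name = name, hhat = h / nrm, h_norm = nrm,
       z0 = z0, threshold = threshold, pooling = pooling)
}

is_param_layer <- function(layer) layer$type %in% c("conv", "dense")

# ---- im2col machinery ------------------------------------------------------

conv_pad <- function(x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * ph, d[2] + 2L * pw, d[3], d[4]))
  xp[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- x
  xp
}

# Patch matrix with rows ordered (oh fastest, ow, n) and columns ordered
# (kh fastest, kw, cin) to match column-major flattening of the kernel.
im2col <- function(x, kh, kw, pad) {
  xp <- conv_pad(x, pad[1], pad[2])
  d <- dim(xp)
  oh <- d[1] - kh + 1L; ow <- d[2] - kw + 1L
  cin <- d[3]; n <- d[4]
  P <- matrix(0, oh * ow * n, kh * kw * cin)
  col <- 0L
  for (ci in seq_len(cin)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    col <- col + 1L
    P[, col] <- xp[ki:(ki + oh - 1L), kj:(kj + ow - 1L), ci, ]
  }
  P
}

col2im <- function(dP, in_dim, kh, kw, pad) {
  H <- in_dim[1]; W <- in_dim[2]; cin <- in_dim[3]; n <- in_dim[4]
  ph <- pad[1]; pw <- pad[2]
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  oh <- Hp - kh + 1L; ow <- Wp - kw + 1L
  dxp <- array(0, c(Hp, Wp, cin, n))
  col <- 0L
  for (ci in seq_len(cin)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    col <- col + 1L
    dxp[ki:(ki + oh - 1L), kj:(kj + ow - 1L), ci, ] <-
      as.vector(dxp[ki:(ki + oh - 1L), kj:(kj + ow - 1L), ci, ]) + dP[, col]
  }
  if (ph == 0L && pw == 0L) dxp else dxp[ph + seq_len(H), pw + seq_len(W), , , drop = FALSE]
}

conv_forward_raw <- function(x, W, b, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  n <- dim(x)[4]
  P <- im2col(x, kh, kw, pad)
  out <- P %*% matrix(W, ncol = cout)
  if (any(b != 0)) out <- out + matrix(b, nrow(out), cout, byrow = TRUE)
  oh <- dim(x)[1] + 2L * pad[1] - kh + 1L
  ow <- dim(x)[2] + 2L * pad[2] - kw + 1L
  list(y = aperm(array(out, c(oh, ow, n, cout)), c(1L, 2L, 4L, 3L)), P = P)
}

# gradient (or LRP message) w.r.t. conv input given output-shaped dY
conv_input_grad <- function(dY, W, in_dim, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  dmat <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), ncol = cout)
  dP <- dmat %*% t(matrix(W, ncol = cout))
  col2im(dP, in_dim, kh, kw, pad)
}

conv_param_grad <- function(P, dY) {
  cout <- dim(dY)[3]
  dmat <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), ncol = cout)
  list(dWmat = crossprod(P, dmat), db = colSums(dmat))
}

# ---- per-layer forward -----------------------------------------------------

pool_forward <- function(x, kh, kw) {
  d <- dim(x)
  oh <- d[1] %/% kh; ow <- d[2] %/% kw
  nslice <- kh * kw
  M <- matrix(0, oh * ow * d[3] * d[4], nslice)
  s <- 0L
  for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    s <- s + 1L
    M[, s] <- x[seq(ki, d[1], by = kh), seq(kj, d[2], by = kw), , ]
  }
  arg <- max.col(M, ties.method = "first")
  val <- M[cbind(seq_len(nrow(M)), arg)]
  list(y = array(val, c(oh, ow, d[3], d[4])), arg = arg, in_dim = d)
}

pool_route_back <- function(dY, cache, kh, kw) {
  # scatter output-shaped values to the argmax positions of the forward pass
  d <- cache$in_dim
  n <- length(dY)
  Z <- matrix(0, n, kh * kw)
  Z[cbind(seq_len(n), cache$arg)] <- as.vector(dY)
  dX <- array(0, d)
  oh <- d[1] %/% kh; ow <- d[2] %/% kw
  s <- 0L
  for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    s <- s + 1L
    dX[seq(ki, d[1], by = kh), seq(kj, d[2], by = kw), , ] <- array(Z[, s], c(oh, ow, d[3], d[4]))
  }
  dX
}

pool_gather <- function(u, cache, kh, kw) {
  # frozen-gate JVP: read the perturbation at the recorded argmax positions
  d <- cache$in_dim
  oh <- d[1] %/% kh; ow <- d[2] %/% kw
  nslice <- kh * kw
  M <- matrix(0, oh * ow * d[3] * d[4], nslice)
  s <- 0L
  for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    s <- s + 1L
    M[, s] <- u[seq(ki, d[1], by = kh), seq(kj, d[2], by = kw), , ]
  }
  array(M[cbind(seq_len(nrow(M)), cache$arg)], c(oh, ow, d[3], d[4]))
}

flatten_forward <- function(x) {
  d <- dim(x)
  list(y = t(matrix(x, prod(d[1:3]), d[4])), in_dim = d)
}

projection_gate <- function(layer, x) {
  # per-sample gate: pooled bias score of the incoming activation vs threshold
  if (is.null(layer$threshold)) return(rep(TRUE, dim(x)[4]))
  d <- dim(x)
  h <- layer$hhat * layer$h_norm
  pooled <- pool_spatial_batch(x, layer$pooling)   # N x C
  scores <- as.vector(pooled %*% h)
  scores > layer$threshold
}

projection_forward <- function(layer, x) {
  d <- dim(x)
  gate <- projection_gate(layer, x)
  y <- x
  if (any(gate)) {
    xg <- x[, , , gate, drop = FALSE]
    dg <- dim(xg)
    xm <- matrix(aperm(xg, c(3L, 1L, 2L, 4L)), nrow = d[3])
    proj <- as.vector(crossprod(xm, layer$hhat))
    xm <- xm - outer(layer$hhat, proj - layer$z0)
    y[, , , gate] <- aperm(array(xm, c(d[3], dg[1], dg[2], dg[4])), c(2L, 3L, 1L, 4L))
  }
  list(y = y, gate = gate)
}

projection_linear_map <- function(layer, v, gate) {
  # apply P = I - hhat hhat^T per spatial position for gated samples (P symmetric)
  d <- dim(v)
  out <- v
  if (any(gate)) {
    vg <- v[, , , gate, drop = FALSE]
    dg <- dim(vg)
    vm <- matrix(aperm(vg, c(3L, 1L, 2L, 4L)), nrow = d[3])
    vm <- vm - outer(layer$hhat, as.vector(crossprod(vm, layer$hhat)))
    out[, , , gate] <- aperm(array(vm, c(d[3], dg[1], dg[2], dg[4])), c(2L, 3L, 1L, 4L))
  }
  out
}

# ---- full forward pass -----------------------------------------------------

nn_forward <- function(model, x, keep = TRUE) {
  acts <- list(input = x)
  caches <- list()
  cur <- x
  for (layer in model$layers) {
    cur <- switch(layer$type,
      conv = {
        r <- conv_forward_raw(cur, layer$W, layer$b, layer$pad)
        caches[[layer$name]] <- list(P = r$P, in_dim = dim(acts[[length(acts)]]))
        r$y
      },
      relu = {
        caches[[layer$name]] <- list(mask = cur > 0)
        pmax(cur, 0)
      },
      pool = {
        r <- pool_forward(cur, layer$kh, layer$kw)
        caches[[layer$name]] <- r[c("arg", "in_dim")]
        r$y
      },
      flatten = {
        r <- flatten_forward(cur)
        caches[[layer$name]] <- r["in_dim"]
        r$y
      },
      dense = {
        caches[[layer$name]] <- list(x = cur)
        cur %*% layer$W + matrix(layer$b, nrow(cur), length(layer$b), byrow = TRUE)
      },
      projection = {
        r <- projection_forward(layer, cur)
        caches[[layer$name]] <- list(gate = r$gate)
        r$y
      },
      stop("unknown layer type: ", layer$type))
    acts[[layer$name]] <- cur
  }
  list(scores = cur, acts = if (keep) acts else NULL, caches = caches)
}

layer_index <- function(model, name) {
  idx <- match(name, vapply(model$layers, `[[`, "", "name"))
  if (is.na(idx)) stop("unknown layer: '", name, "'")
  idx
}

layer_input_name <- function(model, idx) {
  if (idx == 1L) "input" else model$layers[[idx - 1L]]$name
}

# ---- backward pass (gradients) ---------------------------------------------
# dscores: N x K matrix of output-score gradients. Returns parameter grads,
# the gradient at `stop_at` (a layer name whose *output* gradient is wanted,
# or "input"), and optionally per-layer output-gradients ("deltas").

nn_backward <- function(model, fw, dscores, stop_at = "input",
                        param_grads = TRUE, keep_deltas = FALSE) {
  grads <- list()
  deltas <- list()
  cur <- dscores
  stop_idx <- if (identical(stop_at, "input")) 0L else layer_index(model, stop_at)
  for (i in rev(seq_along(model$layers))) {
    layer <- model$layers[[i]]
    if (keep_deltas) deltas[[layer$name]] <- cur
    if (i == stop_idx) break
    cache <- fw$caches[[layer$name]]
    cur <- switch(layer$type,
      conv = {
        if (param_grads) {
          pg <- conv_param_grad(cache$P, cur)
          grads[[layer$name]] <- list(
            W = array(pg$dWmat, dim(layer$W)), b = pg$db)
        }
        conv_input_grad(cur, layer$W, cache$in_dim, layer$pad)
      },
      relu = cur * cache$mask,
      pool = pool_route_back(cur, cache, layer$kh, layer$kw),
      flatten = array(t(cur), cache$in_dim),
      dense = {
        if (param_grads) {
          grads[[layer$name]] <- list(W = crossprod(cache$x, cur), b = colSums(cur))
        }
        tcrossprod(cur, layer$W)
      },
      projection = projection_linear_map(layer, cur, cache$gate))
    if (i - 1L == stop_idx && stop_idx > 0L) break
  }
  list(param_grads = grads, grad = cur, deltas = deltas)
}

# ---- frozen-gate JVP -------------------------------------------------------
# Propagate a perturbation u (shaped like the output of layer `from`, or like
# the input when from = "input") forward through the linearisation of the
# network at the cached forward pass. Returns the inputs u_k seen by each
# parametric layer plus the output perturbation.

nn_jvp <- function(model, fw, u, from = "input") {
  start <- if (identical(from, "input")) 1L else layer_index(model, from) + 1L
  u_in <- list()
  for (i in seq(start, length(model$layers))) {
    layer <- model$layers[[i]]
    cache <- fw$caches[[layer$name]]
    if (is_param_layer(layer)) u_in[[layer$name]] <- u
    u <- switch(layer$type,
      conv = conv_forward_raw(u, layer$W, numeric(layer$cout), layer$pad)$y,
      relu = u * cache$mask,
      pool = pool_gather(u, cache, layer$kh, layer$kw),
      flatten = flatten_forward(u)$y,
      dense = u %*% layer$W,
      projection = projection_linear_map(layer, u, cache$gate))
  }
  list(u_out = u, u_in = u_in)
}

# Parameter gradients of sum_i <delta_out_i, A_i(theta) u_i> with gates frozen:
# per parametric layer the same outer-product structure as ordinary weight
# gradients, with activations replaced by the propagated perturbation.
nn_wgrads_from_jvp <- function(model, fw, jvp, deltas) {
  grads <- list()
  for (layer in model$layers) {
    if (!is_param_layer(layer)) next
    u_k <- jvp$u_in[[layer$name]]
    if (is.null(u_k)) next
    d_k <- deltas[[layer$name]]
    if (layer$type == "conv") {
      P_u <- im2col(u_k, layer$kh, layer$kw, layer$pad)
      pg <- conv_param_grad(P_u, d_k)
      grads[[layer$name]] <- list(W = array(pg$dWmat, dim(layer$W)),
                                  b = numeric(length(layer$b)))
    } else {
      grads[[layer$name]] <- list(W = crossprod(u_k, d_k),
                                  b = numeric(length(layer$b)))
    }
  }
  grads
}

# ---- optimiser -------------------------------------------------------------

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (layer in model$layers) {
    if (is_param_layer(layer)) {
      st$m[[layer$name]] <- list(W = layer$W * 0, b = layer$b * 0)
      st$v[[layer$name]] <- list(W = layer$W * 0, b = layer$b * 0)
    }
  }
  st
}

adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    if (!is_param_layer(layer)) next
    g <- grads[[layer$name]]
    if (is.null(g)) next
    for (p in c("W", "b")) {
      st$m[[layer$name]][[p]] <- beta1 * st$m[[layer$name]][[p]] + (1 - beta1) * g[[p]]
      st$v[[layer$name]][[p]] <- beta2 * st$v[[layer$name]][[p]] + (1 - beta2) * g[[p]]^2
      mh <- st$m[[layer$name]][[p]] / bc1
      vh <- st$v[[layer$name]][[p]] / bc2
      model$layers[[i]][[p]] <- layer[[p]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(model = model, state = st)
}

add_grads <- function(a, b, scale = 1) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) {
      a[[nm]] <- list(W = b[[nm]]$W * scale, b = b[[nm]]$b * scale)
    } else {
      a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W * scale
      a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b * scale
    }
  }
  a
}

# ---- loss ------------------------------------------------------------------

softmax_rows <- function(s) {
  z <- exp(s - apply(s, 1, max))
  z / rowSums(z)
}

cross_entropy <- function(scores, y) {
  p <- softmax_rows(scores)
  n <- nrow(scores)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, n, ncol(scores))
  onehot[idx] <- 1
  list(loss = loss, p = p, onehot = onehot, dscores = (p - onehot) / n)
}

# ---- pooling helper shared with the concept module -------------------------

# batch x: H x W x C x N -> N x C matrix of spatially pooled values
pool_spatial_batch <- function(x, mode = c("max_spatial", "mean_spatial", "none")) {
  mode <- match.arg(mode)
  d <- dim(x)
  m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), nrow = d[1] * d[2])  # (H*W) x (N*C)
  pooled <- switch(mode,
    max_spatial = apply(m, 2, max),
    mean_spatial = colMeans(m),
    none = {
      if (d[1] * d[2] != 1L)
        stop("pooling 'none' requires a 1x1 spatial extent")
      m[1L, ]
    })
  matrix(pooled, d[4], d[3])
}
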
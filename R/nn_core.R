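# Minimal CPU neural-network engine.
#
# Tensors are dense double arrays in channel-first (C,H,W,B) layout. Each
# layer is an environment holding its parameters (named in $pnames), gradient
# accumulators (d<name>), and a forward cache; forward/backward are explicit
# so every gradient is auditable and finite-difference checkable. Convolution
# and pooling kernels live in src/nn_ops.cpp.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$pnames <- character(0)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("icseg_", type), "icseg_layer")
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

new_conv3 <- function(cin, cout, group = "main") {
  e <- new_layer("conv3", cin = cin, cout = cout, group = group)
  e$W <- he_init(cout, 9 * cin, 9 * cin)
  e$b <- numeric(cout)
  e$pnames <- c("W", "b")
  e
}

new_conv1 <- function(cin, cout, group = "main") {
  e <- new_layer("conv1", cin = cin, cout = cout, group = group)
  e$W <- he_init(cout, cin, cin)
  e$b <- numeric(cout)
  e$pnames <- c("W", "b")
  e
}

new_fc <- function(din, dout, group = "main") {
  e <- new_layer("fc", din = din, dout = dout, group = group)
  e$W <- he_init(dout, din, din)
  e$b <- numeric(dout)
  e$pnames <- c("W", "b")
  e
}

new_relu <- function() new_layer("relu")

# Batch normalization over (H,W,B) per channel with learned scale/shift and
# running statistics for inference. Stabilizes from-scratch training of the
# convolution stacks while keeping per-sample amplitude deviations visible
# at inference (running statistics are fixed), which downstream quality
# regression depends on.
new_bnorm <- function(C, group = "main", eps = 1e-5, momentum = 0.1) {
  e <- new_layer("bnorm", C = C, eps = eps, momentum = momentum, group = group)
  e$g <- rep(1, C)
  e$beta <- numeric(C)
  e$rmean <- numeric(C)
  e$rvar <- rep(1, C)
  e$pnames <- c("g", "beta")
  e$snames <- c("rmean", "rvar")  # non-trainable state; part of checkpoints
  e
}

bnorm_fwd <- function(e, x, train) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    e$rmean <- (1 - e$momentum) * e$rmean + e$momentum * mu
    e$rvar <- (1 - e$momentum) * e$rvar + e$momentum * v
  } else {
    mu <- e$rmean
    v <- e$rvar
  }
  inv_s <- 1 / sqrt(v + e$eps)
  xhat <- (xm - mu) * inv_s
  if (train) { e$xhat <- xhat; e$inv_s <- inv_s; e$din <- d }
  array(xhat * e$g + e$beta, d)
}

bnorm_bwd <- function(e, dy) {
  d <- e$din
  dym <- matrix(dy, d[1])
  accum_grad(e, "g", rowSums(dym * e$xhat))
  accum_grad(e, "beta", rowSums(dym))
  dxh <- dym * e$g
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * e$xhat)
  array((dxh - m1 - e$xhat * m2) * e$inv_s, d)
}

# Instance normalization: each channel of each sample is normalized over its
# spatial extent, with a learned per-channel scale and shift. Stabilizes
# training of the normalization-free convolution stacks.
new_inorm <- function(C, group = "main", eps = 1e-5) {
  e <- new_layer("inorm", C = C, eps = eps, group = group)
  e$g <- rep(1, C)
  e$beta <- numeric(C)
  e$pnames <- c("g", "beta")
  e
}

inorm_fwd <- function(e, x, train) {
  d <- dim(x)
  hw <- d[2] * d[3]
  xhat <- array(0, d)
  inv_s <- matrix(0, d[1], d[4])
  for (b in seq_len(d[4])) {
    xm <- matrix(x[, , , b], d[1], hw)
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    is_ <- 1 / sqrt(v + e$eps)
    xhat[, , , b] <- (xm - mu) * is_
    inv_s[, b] <- is_
  }
  if (train) { e$xhat <- xhat; e$inv_s <- inv_s; e$din <- d }
  xhat * e$g + e$beta
}

inorm_bwd <- function(e, dy) {
  d <- e$din
  hw <- d[2] * d[3]
  dx <- array(0, d)
  dg <- numeric(d[1]); dbeta <- numeric(d[1])
  for (b in seq_len(d[4])) {
    dym <- matrix(dy[, , , b], d[1], hw)
    xh <- matrix(e$xhat[, , , b], d[1], hw)
    dg <- dg + rowSums(dym * xh)
    dbeta <- dbeta + rowSums(dym)
    dxh <- dym * e$g
    m1 <- rowMeans(dxh)
    m2 <- rowMeans(dxh * xh)
    dx[, , , b] <- (dxh - m1 - xh * m2) * e$inv_s[, b]
  }
  accum_grad(e, "g", dg)
  accum_grad(e, "beta", dbeta)
  dx
}
new_pool <- function() new_layer("pool")
new_up   <- function() new_layer("up")
new_gap  <- function() new_layer("gap")
# Global pooling emitting per-channel mean and max (2C,B): extremum
# statistics (peak confidence, sharpest activation) survive pooling, which
# matters when the downstream head regresses segmentation quality.
new_gpool <- function() new_layer("gpool")

# Squeeze-and-excitation: global average pool -> FC(C/r) -> ReLU -> FC(C) ->
# sigmoid -> channel-wise rescaling of the input.
new_se <- function(C, reduction = 8, group = "main") {
  Cr <- max(1L, as.integer(C / reduction))
  e <- new_layer("se", C = C, Cr = Cr, group = group)
  e$W1 <- he_init(Cr, C, C)
  e$b1 <- numeric(Cr)
  e$W2 <- he_init(C, Cr, Cr)
  e$b2 <- numeric(C)
  e$pnames <- c("W1", "b1", "W2", "b2")
  e
}

# Non-local block (embedded-Gaussian spatial self-attention with residual
# connection); the output projection starts at zero so the block is the
# identity at initialization.
new_nonlocal <- function(C, group = "main") {
  Ci <- max(1L, as.integer(C / 2))
  e <- new_layer("nonlocal", C = C, Ci = Ci, group = group)
  e$Wt <- he_init(Ci, C, C)
  e$Wp <- he_init(Ci, C, C)
  e$Wg <- he_init(Ci, C, C)
  e$Wz <- matrix(0, C, Ci)
  e$pnames <- c("Wt", "Wp", "Wg", "Wz")
  e
}

accum_grad <- function(e, name, g) {
  gname <- paste0("d", name)
  cur <- get0(gname, envir = e, inherits = FALSE)
  assign(gname, if (is.null(cur)) g else cur + g, envir = e)
}

layer_fwd <- function(e, x, train = TRUE) {
  switch(e$type,
    conv3 = {
      if (train) e$x <- x
      cpp_conv3_fwd(x, dim(x), e$W, e$b)
    },
    conv1 = {
      d <- dim(x)
      xm <- matrix(x, d[1])
      if (train) { e$xm <- xm; e$din <- d }
      y <- e$W %*% xm + e$b
      array(y, c(nrow(e$W), d[2], d[3], d[4]))
    },
    fc = {
      if (train) e$xm <- x
      e$W %*% x + e$b
    },
    relu = {
      m <- x > 0
      if (train) e$mask <- m
      x * m
    },
    inorm = inorm_fwd(e, x, train),
    bnorm = bnorm_fwd(e, x, train),
    pool = {
      if (dim(x)[2] %% 2L || dim(x)[3] %% 2L)
        stop("max-pooling requires even spatial dimensions", call. = FALSE)
      r <- cpp_maxpool2_fwd(x, dim(x))
      if (train) { e$which <- r$which; e$din <- dim(x) }
      r$y
    },
    up = cpp_upsample2(x, dim(x)),
    gap = {
      d <- dim(x)
      xr <- array(x, c(d[1], d[2] * d[3], d[4]))
      y <- matrix(apply(xr, 3, rowMeans), d[1], d[4])
      if (train) e$din <- d
      y
    },
    gpool = {
      d <- dim(x)
      xr <- array(x, c(d[1], d[2] * d[3], d[4]))
      y <- matrix(0, 2 * d[1], d[4])
      amax <- matrix(0L, d[1], d[4])
      for (b in seq_len(d[4])) {
        xm <- matrix(xr[, , b], d[1])
        y[seq_len(d[1]), b] <- rowMeans(xm)
        amax[, b] <- max.col(xm, ties.method = "first")
        y[d[1] + seq_len(d[1]), b] <- xm[cbind(seq_len(d[1]), amax[, b])]
      }
      if (train) { e$din <- d; e$amax <- amax }
      y
    },
    se = se_fwd(e, x, train),
    nonlocal = nonlocal_fwd(e, x, train),
    stop("unknown layer type: ", e$type)
  )
}

layer_bwd <- function(e, dy) {
  switch(e$type,
    conv3 = {
      r <- cpp_conv3_bwd(e$x, dim(e$x), e$W, dy)
      accum_grad(e, "W", r$dW)
      accum_grad(e, "b", r$db)
      r$dx
    },
    conv1 = {
      d <- dim(dy)
      dym <- matrix(dy, d[1])
      accum_grad(e, "W", dym %*% t(e$xm))
      accum_grad(e, "b", rowSums(dym))
      array(t(e$W) %*% dym, e$din)
    },
    fc = {
      accum_grad(e, "W", dy %*% t(e$xm))
      accum_grad(e, "b", rowSums(dy))
      t(e$W) %*% dy
    },
    relu = dy * e$mask,
    inorm = inorm_bwd(e, dy),
    bnorm = bnorm_bwd(e, dy),
    pool = cpp_maxpool2_bwd(dy, e$which, e$din),
    up = cpp_downsum2(dy, dim(dy) %/% c(1L, 2L, 2L, 1L)),
    gap = {
      d <- e$din
      hw <- d[2] * d[3]
      array(dy[, rep(seq_len(d[4]), each = hw)] / hw, d)
    },
    gpool = {
      d <- e$din
      hw <- d[2] * d[3]
      C <- d[1]
      dx <- array(dy[seq_len(C), rep(seq_len(d[4]), each = hw)] / hw, d)
      dxr <- array(dx, c(C, hw, d[4]))
      for (b in seq_len(d[4]))
        dxr[cbind(seq_len(C), e$amax[, b], b)] <-
          dxr[cbind(seq_len(C), e$amax[, b], b)] + dy[C + seq_len(C), b]
      array(dxr, d)
    },
    se = se_bwd(e, dy),
    nonlocal = nonlocal_bwd(e, dy),
    stop("unknown layer type: ", e$type)
  )
}

se_fwd <- function(e, x, train) {
  d <- dim(x)
  hw <- d[2] * d[3]
  xr <- array(x, c(d[1], hw, d[4]))
  s <- matrix(apply(xr, 3, rowMeans), d[1], d[4])      # (C,B)
  z1 <- e$W1 %*% s + e$b1
  a1 <- z1 * (z1 > 0)
  z2 <- e$W2 %*% a1 + e$b2
  g <- 1 / (1 + exp(-z2))                              # (C,B)
  gfull <- g[, rep(seq_len(d[4]), each = hw), drop = FALSE]
  y <- x * as.vector(gfull)
  if (train) {
    e$x <- x; e$s <- s; e$z1 <- z1; e$a1 <- a1; e$g <- g; e$din <- d
  }
  y
}

se_bwd <- function(e, dy) {
  d <- e$din
  hw <- d[2] * d[3]
  B <- d[4]
  gfull <- e$g[, rep(seq_len(B), each = hw), drop = FALSE]
  dx <- dy * as.vector(gfull)
  # gradient into the channel gates: sum over spatial positions of dy * x
  prod_r <- array(dy * e$x, c(d[1], hw, B))
  dg <- matrix(apply(prod_r, 3, rowSums), d[1], B)
  dz2 <- dg * e$g * (1 - e$g)
  accum_grad(e, "W2", dz2 %*% t(e$a1))
  accum_grad(e, "b2", rowSums(dz2))
  da1 <- t(e$W2) %*% dz2
  dz1 <- da1 * (e$z1 > 0)
  accum_grad(e, "W1", dz1 %*% t(e$s))
  accum_grad(e, "b1", rowSums(dz1))
  ds <- t(e$W1) %*% dz1                                # (C,B)
  dx + array(ds[, rep(seq_len(B), each = hw), drop = FALSE] / hw, d)
}

nonlocal_fwd <- function(e, x, train) {
  d <- dim(x)
  N <- d[2] * d[3]
  B <- d[4]
  xr <- array(x, c(d[1], N, B))
  y <- array(0, d)
  cache <- if (train) vector("list", B) else NULL
  for (b in seq_len(B)) {
    X <- xr[, , b, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, d[1], N)
    Tm <- e$Wt %*% X
    Pm <- e$Wp %*% X
    Gm <- e$Wg %*% X
    S <- crossprod(Tm, Pm)               # (N,N)
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A <- A / rowSums(A)
    O <- Gm %*% t(A)                     # (Ci,N)
    Y <- X + e$Wz %*% O
    y[, , , b] <- array(Y, c(d[1], d[2], d[3]))
    if (train) cache[[b]] <- list(X = X, Tm = Tm, Pm = Pm, Gm = Gm, A = A, O = O)
  }
  if (train) { e$cache <- cache; e$din <- d }
  y
}

nonlocal_bwd <- function(e, dy) {
  d <- e$din
  N <- d[2] * d[3]
  B <- d[4]
  dyr <- array(dy, c(d[1], N, B))
  dx <- array(0, d)
  dWt <- 0; dWp <- 0; dWg <- 0; dWz <- 0
  for (b in seq_len(B)) {
    cb <- e$cache[[b]]
    dY <- matrix(dyr[, , b], d[1], N)
    dWz <- dWz + dY %*% t(cb$O)
    dO <- t(e$Wz) %*% dY                 # (Ci,N)
    dG <- dO %*% cb$A
    dA <- crossprod(dO, cb$Gm)           # (N,N): dA[i,j]
    rs <- rowSums(dA * cb$A)
    dS <- cb$A * (dA - rs)
    dT <- cb$Pm %*% t(dS)
    dP <- cb$Tm %*% dS
    dWt <- dWt + dT %*% t(cb$X)
    dWp <- dWp + dP %*% t(cb$X)
    dWg <- dWg + dG %*% t(cb$X)
    dX <- dY + t(e$Wt) %*% dT + t(e$Wp) %*% dP + t(e$Wg) %*% dG
    dx[, , , b] <- array(dX, c(d[1], d[2], d[3]))
  }
  accum_grad(e, "Wt", dWt)
  accum_grad(e, "Wp", dWp)
  accum_grad(e, "Wg", dWg)
  accum_grad(e, "Wz", dWz)
  dx
}

seq_fwd <- function(layers, x, train = TRUE) {
  for (e in layers) x <- layer_fwd(e, x, train)
  x
}

seq_bwd <- function(layers, dy) {
  for (e in rev(layers)) dy <- layer_bwd(e, dy)
  dy
}

# ---- parameter bookkeeping -------------------------------------------------

# Flatten nested lists of layers into a list of parameter references.
nn_params <- function(x) {
  out <- list()
  walk <- function(obj) {
    if (inherits(obj, "icseg_layer")) {
      for (nm in obj$pnames)
        out[[length(out) + 1L]] <<- list(env = obj, name = nm,
                                         group = obj$group %||% "main")
    } else if (is.list(obj)) {
      for (el in obj) walk(el)
    }
  }
  walk(x)
  out
}

# References to non-trainable layer state (batch-norm running statistics):
# no gradients or optimizer steps, but checkpoints must capture them — a
# restored best-epoch model has to reproduce its recorded validation score.
nn_states <- function(x) {
  out <- list()
  walk <- function(obj) {
    if (inherits(obj, "icseg_layer")) {
      for (nm in obj$snames %||% character(0))
        out[[length(out) + 1L]] <<- list(env = obj, name = nm, group = "state")
    } else if (is.list(obj)) {
      for (el in obj) walk(el)
    }
  }
  walk(x)
  out
}

zero_grads <- function(params) {
  for (p in params) assign(paste0("d", p$name), NULL, envir = p$env)
  invisible(NULL)
}

snapshot_params <- function(params) {
  lapply(params, function(p) get(p$name, envir = p$env))
}

restore_params <- function(params, snap) {
  for (i in seq_along(params))
    assign(params[[i]]$name, snap[[i]], envir = params[[i]]$env)
  invisible(NULL)
}

params_checksum <- function(params) {
  sum(vapply(snapshot_params(params),
             function(a) sum(as.double(a) * 1.0), numeric(1)))
}

# ---- optimizers ------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) {
      v <- get(p$name, envir = p$env); v[] <- 0; v
    }),
    v = lapply(params, function(p) {
      v <- get(p$name, envir = p$env); v[] <- 0; v
    }),
    t = 0L
  )
}

# One Adam / AdamW step. `lr` is either a single rate or a named vector of
# rates per parameter group. `weight_decay` is decoupled (AdamW) when > 0.
adam_step <- function(state, params, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- get0(paste0("d", p$name), envir = p$env, inherits = FALSE)
    if (is.null(g)) next
    lri <- if (length(lr) > 1L) unname(lr[p$group]) else unname(lr)
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    val <- get(p$name, envir = p$env)
    upd <- (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    if (weight_decay > 0) upd <- upd + weight_decay * val
    assign(p$name, val - lri * upd, envir = p$env)
  }
  state
}

#' Polynomial learning-rate decay
#'
#' `lr0 * (1 - step/total)^power`, the schedule used for the segmentation and
#' rejection optimizers. At `step == total` the rate is exactly 0.
#'
#' @param step current step (0-based).
#' @param total total number of steps.
#' @param lr0 initial learning rate.
#' @param power decay exponent (default 0.9).
#' @return The decayed learning rate (same length as `step`).
#' @export
poly_lr <- function(step, total, lr0, power = 0.9) {
  lr0 * (1 - pmin(step, total) / total)^power
}

# Pixelwise 2-way softmax over the channel dimension of (2,H,W,B) logits.
softmax2 <- function(z) {
  d <- dim(z)
  zm <- pmax(z[1, , , , drop = FALSE], z[2, , , , drop = FALSE])
  e1 <- exp(z[1, , , , drop = FALSE] - zm)
  e2 <- exp(z[2, , , , drop = FALSE] - zm)
  s <- e1 + e2
  p <- array(0, d)
  p[1, , , ] <- e1 / s
  p[2, , , ] <- e2 / s
  p
}
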
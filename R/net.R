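# Minimal convolutional network engine: a static DAG of conv / max-pool /
# batch-norm / depth-concat nodes operating on batches stored as
# (H, W, C, N) arrays, with hand-written backpropagation. The im2col /
# col2im / pooling hot paths live in src/conv_ops.cpp; matrix products go
# through BLAS. Parameters live in environments so that optimizer updates
# mutate the model in place.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

new_conv <- function(name, input, in_c, out_c, k, stride = 1,
                     pad = (k - 1) %/% 2, act = c("relu", "linear")) {
  act <- match.arg(act)
  par <- new.env(parent = emptyenv())
  par$W <- matrix(stats::rnorm(out_c * in_c * k * k,
                               sd = sqrt(2 / (in_c * k * k))), nrow = out_c)
  par$b <- numeric(out_c)
  par$vW <- par$W * 0
  par$vb <- numeric(out_c)
  list(name = name, op = "conv", input = input, in_c = in_c, out_c = out_c,
       k = k, stride = stride, pad = pad, act = act, par = par)
}

new_pool <- function(name, input, channels) {
  list(name = name, op = "pool", input = input, out_c = channels)
}

new_bn <- function(name, input, channels) {
  par <- new.env(parent = emptyenv())
  par$gamma <- rep(1, channels)
  par$beta <- numeric(channels)
  par$vgamma <- numeric(channels)
  par$vbeta <- numeric(channels)
  par$rmean <- numeric(channels)
  par$rvar <- rep(1, channels)
  list(name = name, op = "bn", input = input, out_c = channels, par = par)
}

new_relu <- function(name, input, channels) {
  list(name = name, op = "relu", input = input, out_c = channels)
}

new_concat <- function(name, inputs, channels) {
  list(name = name, op = "concat", input = inputs, out_c = sum(channels),
       split_c = channels)
}

# ---- forward ---------------------------------------------------------------

conv_forward <- function(node, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  cols <- vector("list", N)
  for (n in seq_len(N)) {
    xi <- x[, , , n, drop = FALSE]
    dim(xi) <- d[1:3]
    cols[[n]] <- im2col_cpp(xi, node$k, node$stride, node$pad)
  }
  cols_all <- if (N == 1) cols[[1]] else do.call(cbind, cols)
  Y <- node$par$W %*% cols_all + node$par$b
  oH <- (H + 2 * node$pad - node$k) %/% node$stride + 1
  oW <- (W + 2 * node$pad - node$k) %/% node$stride + 1
  y <- aperm(array(t(Y), dim = c(oH, oW, N, node$out_c)), c(1, 2, 4, 3))
  if (node$act == "relu") y[y < 0] <- 0
  list(y = y, cache = list(cols = cols_all, in_dim = d, oH = oH, oW = oW))
}

conv_backward <- function(node, dy, y, cache) {
  if (node$act == "relu") dy <- dy * (y > 0)
  d <- dim(dy)
  N <- d[4]
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * N, node$out_c)
  dym <- t(dym)                               # out_c x (P * N)
  gW <- dym %*% t(cache$cols)
  gb <- rowSums(dym)
  dcols <- crossprod(node$par$W, dym)         # (C k k) x (P * N)
  P <- cache$oH * cache$oW
  id <- cache$in_dim
  dx <- array(0, dim = id)
  for (n in seq_len(N)) {
    dxi <- col2im_cpp(dcols[, (n - 1) * P + seq_len(P), drop = FALSE],
                      id[1], id[2], id[3], node$k, node$stride, node$pad)
    dx[, , , n] <- dxi
  }
  list(dx = dx, grads = list(W = gW, b = gb))
}

pool_forward <- function(node, x) {
  d <- dim(x)
  N <- d[4]
  y <- array(0, dim = c(d[1] %/% 2, d[2] %/% 2, d[3], N))
  argmax <- vector("list", N)
  for (n in seq_len(N)) {
    xi <- x[, , , n, drop = FALSE]
    dim(xi) <- d[1:3]
    r <- maxpool2_fwd_cpp(xi)
    y[, , , n] <- r$y
    argmax[[n]] <- r$argmax
  }
  list(y = y, cache = list(argmax = argmax, in_dim = d))
}

pool_backward <- function(node, dy, cache) {
  id <- cache$in_dim
  dx <- array(0, dim = id)
  od <- dim(dy)
  for (n in seq_len(id[4])) {
    dyi <- dy[, , , n, drop = FALSE]
    dim(dyi) <- od[1:3]
    dx[, , , n] <- maxpool2_bwd_cpp(dyi, cache$argmax[[n]],
                                    as.integer(id[1:3]))
  }
  dx
}

bn_forward <- function(node, x, training) {
  d <- dim(x)
  C <- d[3]
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], C)
  p <- node$par
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu^2
    p$rmean <- (1 - .bn_momentum) * p$rmean + .bn_momentum * mu
    p$rvar <- (1 - .bn_momentum) * p$rvar + .bn_momentum * v
  } else {
    mu <- p$rmean
    v <- p$rvar
  }
  invstd <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  ym <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  dim(ym) <- c(d[1], d[2], d[4], C)
  y <- aperm(ym, c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d,
                           training = training))
}

bn_backward <- function(node, dy, cache) {
  d <- cache$dims
  C <- d[3]
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], C)
  m <- nrow(dym)
  xhat <- cache$xhat
  ggamma <- colSums(dym * xhat)
  gbeta <- colSums(dym)
  p <- node$par
  if (cache$training) {
    t1 <- sweep(dym, 2, gbeta / m)
    t2 <- sweep(xhat, 2, ggamma / m, "*")
    dxm <- sweep(t1 - t2, 2, p$gamma * cache$invstd, "*")
  } else {
    dxm <- sweep(dym, 2, p$gamma * cache$invstd, "*")
  }
  dim(dxm) <- c(d[1], d[2], d[4], C)
  dx <- aperm(dxm, c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = ggamma, beta = gbeta))
}

concat_forward <- function(node, xs) {
  d1 <- dim(xs[[1]])
  total_c <- sum(vapply(xs, function(x) dim(x)[3], numeric(1)))
  y <- array(0, dim = c(d1[1], d1[2], total_c, d1[4]))
  at <- 0
  for (x in xs) {
    cc <- dim(x)[3]
    y[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  y
}

# ---- graph execution -------------------------------------------------------

net_forward <- function(net, x, training = FALSE) {
  acts <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  acts$input <- x
  for (node in net$nodes) {
    r <- switch(node$op,
      conv = conv_forward(node, acts[[node$input]]),
      pool = pool_forward(node, acts[[node$input]]),
      bn = bn_forward(node, acts[[node$input]], training),
      relu = {
        y <- acts[[node$input]]
        y[y < 0] <- 0
        list(y = y, cache = NULL)
      },
      concat = list(y = concat_forward(node, lapply(node$input,
                                                    function(i) acts[[i]])),
                    cache = NULL))
    acts[[node$name]] <- r$y
    if (!is.null(r$cache)) cache[[node$name]] <- r$cache
  }
  list(acts = acts, cache = cache)
}

# `dout`: named list of gradients w.r.t. the output nodes' activations.
# Returns an environment of parameter gradients keyed by node name.
net_backward <- function(net, fw, dout) {
  acts <- fw$acts
  cache <- fw$cache
  d <- new.env(parent = emptyenv())
  for (nm in names(dout)) d[[nm]] <- dout[[nm]]
  grads <- new.env(parent = emptyenv())
  for (node in rev(net$nodes)) {
    dy <- d[[node$name]]
    if (is.null(dy)) next
    if (node$op == "conv") {
      r <- conv_backward(node, dy, acts[[node$name]], cache[[node$name]])
      grads[[node$name]] <- r$grads
      add_grad(d, node$input, r$dx)
    } else if (node$op == "pool") {
      add_grad(d, node$input, pool_backward(node, dy, cache[[node$name]]))
    } else if (node$op == "relu") {
      add_grad(d, node$input, dy * (acts[[node$name]] > 0))
    } else if (node$op == "bn") {
      r <- bn_backward(node, dy, cache[[node$name]])
      grads[[node$name]] <- r$grads
      add_grad(d, node$input, r$dx)
    } else if (node$op == "concat") {
      at <- 0
      for (i in seq_along(node$input)) {
        cc <- node$split_c[i]
        add_grad(d, node$input[i], dy[, , at + seq_len(cc), , drop = FALSE])
        at <- at + cc
      }
    }
    d[[node$name]] <- NULL   # free
  }
  grads
}

add_grad <- function(d, name, g) {
  if (name == "input") return(invisible())
  cur <- d[[name]]
  d[[name]] <- if (is.null(cur)) g else cur + g
}

# SGD with momentum; L2 regularization applied to conv weights only.
net_update <- function(net, grads, lr, momentum, l2) {
  for (node in net$nodes) {
    g <- grads[[node$name]]
    if (is.null(g)) next
    p <- node$par
    if (node$op == "conv") {
      p$vW <- momentum * p$vW - lr * (g$W + l2 * p$W)
      p$vb <- momentum * p$vb - lr * g$b
      p$W <- p$W + p$vW
      p$b <- p$b + p$vb
    } else if (node$op == "bn") {
      p$vgamma <- momentum * p$vgamma - lr * g$gamma
      p$vbeta <- momentum * p$vbeta - lr * g$beta
      p$gamma <- p$gamma + p$vgamma
      p$beta <- p$beta + p$vbeta
    }
  }
  invisible(net)
}

# Deep-copy a model's parameter environments (models share state otherwise).
net_clone <- function(net) {
  net$nodes <- lapply(net$nodes, function(node) {
    if (!is.null(node$par)) node$par <- list2env(as.list(node$par),
                                                 parent = emptyenv())
    node
  })
  net
}
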
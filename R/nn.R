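# Minimal reverse-mode automatic differentiation engine for the 3D
# segmentation network. Tensors are column-major R arrays with channel-first
# layout (C, Z, Y, X); the heavy kernels (convolution, pooling, upsampling)
# live in compiled code, the cheap elementwise/normalization ops in R.
#
# Graph nodes are environments carrying `value`, `grad`, `parents` and a
# `backward` closure that routes the node's gradient to its parents.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

ag_node <- function(value, parents = list(), backward = NULL, param = FALSE) {
  .ag_counter$n <- .ag_counter$n + 1L
  node <- new.env(parent = emptyenv())
  node$id <- .ag_counter$n
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  node$requires <- param || any(vapply(parents, function(p) p$requires, logical(1)))
  class(node) <- "ag_node"
  node
}

ag_param <- function(value) ag_node(value, param = TRUE)
ag_const <- function(value) ag_node(value)

ag_accumulate <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse pass from a scalar root. Topological order by depth-first search.
ag_backward <- function(root) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]]) || !node$requires) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (p$requires && is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim = dim(root$value))
  for (node in rev(order)) {
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node)
  }
  invisible(root)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- ops -------------------------------------------------------------------

# Convolution via im2col + BLAS GEMM (the direct loop kernels .conv3d_fw /
# .conv3d_bw compute the same map and serve as an independent cross-check).
ag_conv3d <- function(x, w, b) {
  wd <- dim(w$value)
  xd <- dim(x$value)
  k <- wd[2:4]
  cout <- wd[5]
  if (all(k == 1L)) {
    Wm <- matrix(w$value, nrow = wd[1])
    xm <- matrix(x$value, nrow = xd[1])
    out <- crossprod(Wm, xm) + b$value
    dim(out) <- c(cout, xd[-1])
    node <- ag_node(out, parents = list(x, w, b))
    node$backward <- function(nd) {
      g <- matrix(nd$grad, nrow = cout)
      gx <- Wm %*% g
      dim(gx) <- xd
      ag_accumulate(x, gx)
      gw <- tcrossprod(xm, g)
      dim(gw) <- wd
      ag_accumulate(w, gw)
      ag_accumulate(b, rowSums(g))
    }
    return(node)
  }
  node <- ag_node(.conv3d_fw(x$value, w$value, b$value), parents = list(x, w, b))
  node$backward <- function(nd) {
    res <- .conv3d_bw(x$value, w$value, nd$grad)
    ag_accumulate(x, res$gx)
    ag_accumulate(w, res$gw)
    ag_accumulate(b, res$gb)
  }
  node
}

ag_relu <- function(x) {
  v <- x$value
  out <- ag_node(pmax(v, 0) * 1, parents = list(x))
  dim(out$value) <- dim(v)
  out$backward <- function(node) {
    g <- node$grad * (v > 0)
    dim(g) <- dim(v)
    ag_accumulate(x, g)
  }
  out
}

ag_tanh <- function(x) {
  y <- tanh(x$value)
  out <- ag_node(y, parents = list(x))
  out$backward <- function(node) {
    g <- node$grad * (1 - y * y)
    dim(g) <- dim(y)
    ag_accumulate(x, g)
  }
  out
}

ag_add <- function(a, b) {
  out <- ag_node(a$value + b$value, parents = list(a, b))
  out$backward <- function(node) {
    ag_accumulate(a, node$grad)
    ag_accumulate(b, node$grad)
  }
  out
}

# Instance normalization with learnable per-channel scale/shift. Statistics
# are computed per channel over the spatial extent of the single example, so
# batch size 1 is fully supported.
ag_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  C <- d[1]
  m <- matrix(v, nrow = C)
  mu <- rowMeans(m)
  va <- rowMeans(m * m) - mu * mu
  sigma <- sqrt(pmax(va, 0) + eps)
  xhat <- (m - mu) / sigma
  y <- gamma$value * xhat + beta$value
  dim(y) <- d
  out <- ag_node(y, parents = list(x, gamma, beta))
  out$backward <- function(node) {
    g <- matrix(node$grad, nrow = C)
    ag_accumulate(gamma, rowSums(g * xhat))
    ag_accumulate(beta, rowSums(g))
    gx <- g * gamma$value
    dx <- (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)) / sigma
    dim(dx) <- d
    ag_accumulate(x, dx)
  }
  out
}

ag_maxpool <- function(x, k) {
  res <- .maxpool3d_fw(x$value, k[1], k[2], k[3])
  out <- ag_node(res$out, parents = list(x))
  out$backward <- function(node) {
    ag_accumulate(x, .maxpool3d_bw(node$grad, res$argmax, dim(x$value)))
  }
  out
}

ag_upsample_nn <- function(x, k) {
  out <- ag_node(.upsample_nn_fw(x$value, k[1], k[2], k[3]), parents = list(x))
  out$backward <- function(node) {
    ag_accumulate(x, .upsample_nn_bw(node$grad, k[1], k[2], k[3]))
  }
  out
}

ag_concat <- function(nodes) {
  dims <- lapply(nodes, function(n) dim(n$value))
  spat <- dims[[1]][-1]
  cs <- vapply(dims, `[`, integer(1), 1L)
  total <- sum(cs)
  val <- array(0, dim = c(total, spat))
  at <- 0L
  for (i in seq_along(nodes)) {
    val[at + seq_len(cs[i]), , , ] <- nodes[[i]]$value
    at <- at + cs[i]
  }
  out <- ag_node(val, parents = nodes)
  out$backward <- function(node) {
    at <- 0L
    for (i in seq_along(nodes)) {
      g <- node$grad[at + seq_len(cs[i]), , , , drop = FALSE]
      ag_accumulate(nodes[[i]], g)
      at <- at + cs[i]
    }
  }
  out
}

# Channelwise softmax over dim 1 of a (C, Z, Y, X) tensor.
ag_softmax <- function(x) {
  v <- x$value
  d <- dim(v)
  C <- d[1]
  m <- matrix(v, nrow = C)
  mx <- m[1, ]
  if (C > 1) for (i in 2:C) mx <- pmax(mx, m[i, ])
  e <- exp(sweep_rows(m, mx))
  p <- e / rep(colSums(e), each = C)
  pv <- p
  dim(pv) <- d
  out <- ag_node(pv, parents = list(x))
  out$backward <- function(node) {
    g <- matrix(node$grad, nrow = C)
    s <- colSums(g * p)
    dx <- p * (g - rep(s, each = C))
    dim(dx) <- d
    ag_accumulate(x, dx)
  }
  out
}

sweep_rows <- function(m, v) m - rep(v, each = nrow(m))

# Scalar node with an externally supplied gradient function; used by the loss
# components whose closed-form gradients are computed in the losses module.
ag_scalar <- function(value, parent, grad_fn) {
  out <- ag_node(value, parents = list(parent))
  out$backward <- function(node) {
    g <- grad_fn() * node$grad
    ag_accumulate(parent, g)
  }
  out
}

ag_scale_add <- function(nodes, weights) {
  val <- 0
  for (i in seq_along(nodes)) val <- val + weights[i] * nodes[[i]]$value
  out <- ag_node(val, parents = nodes)
  out$backward <- function(node) {
    for (i in seq_along(nodes)) ag_accumulate(nodes[[i]], weights[i] * node$grad)
  }
  out
}

# --- AdamW -----------------------------------------------------------------

#' @noRd
adamw_state <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decoupled weight decay: the shrink p * (1 - wd) is applied independently of
# the learning rate, so lr = 0 with wd > 0 decays weights without taking any
# gradient step.
adamw_step <- function(params, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (weight_decay > 0) p$value <- p$value * (1 - weight_decay)
    g <- p$grad
    if (is.null(g) || lr == 0) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / (1 - beta1^t)
    vhat <- state$v[[i]] / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}
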
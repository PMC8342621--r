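# Minimal reverse-mode autodiff for the two fully-convolutional models.
#
# Feature maps are (H, W, C) arrays processed one sample at a time (gradients
# accumulate across a mini-batch before each Adam step). The tape is implicit:
# every node records its parents and a backward closure, and nodes are
# replayed in reverse creation order. Convolutions run through the
# RcppArmadillo im2col + gemm kernels.

.nn <- new.env(parent = emptyenv())
.nn$counter <- 0L

new_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  .nn$counter <- .nn$counter + 1L
  e$order <- .nn$counter
  class(e) <- "nn_node"
  e
}

nn_input <- function(value) new_node(value)

nn_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- array(0, dim(value) %||% length(value))
  e$m <- e$grad
  e$v <- e$grad
  class(e) <- "nn_param"
  e
}

conv_param <- function(cin, cout, k, init_scale = 1) {
  w <- matrix(rnorm(cin * k * k * cout, 0, sqrt(2 / (cin * k * k))) * init_scale,
              cin * k * k, cout)
  list(w = nn_param(w), b = nn_param(numeric(cout)), k = k,
       cin = cin, cout = cout)
}

add_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

op_conv <- function(x, p, stride = 1L, dilation = 1L) {
  pad <- as.integer(dilation * (p$k - 1) / 2)
  y <- conv2d_fwd(x$value, p$w$value, as.numeric(p$b$value), p$k,
                  as.integer(stride), as.integer(dilation), pad)
  new_node(y, list(x), function(g, self) {
    r <- conv2d_bwd(x$value, p$w$value, g, p$k, as.integer(stride),
                    as.integer(dilation), pad)
    p$w$grad <- p$w$grad + r$dw
    p$b$grad <- p$b$grad + as.numeric(r$db)
    add_grad(x, r$dx)
  })
}

op_relu <- function(x) {
  mask <- x$value > 0
  new_node(x$value * mask, list(x), function(g, self) add_grad(x, g * mask))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(s, list(x), function(g, self) add_grad(x, g * s * (1 - s)))
}

op_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(g, self) {
    add_grad(a, g); add_grad(b, g)
  })
}

op_concat <- function(a, b) {
  ca <- dim(a$value)[3]
  v <- array(0, c(dim(a$value)[1:2], ca + dim(b$value)[3]))
  v[, , seq_len(ca)] <- a$value
  v[, , -seq_len(ca)] <- b$value
  new_node(v, list(a, b), function(g, self) {
    add_grad(a, g[, , seq_len(ca), drop = FALSE])
    add_grad(b, g[, , -seq_len(ca), drop = FALSE])
  })
}

up2_array <- function(v) {
  h <- dim(v)[1]; w <- dim(v)[2]
  v[rep(seq_len(h), each = 2), rep(seq_len(w), each = 2), , drop = FALSE]
}

op_up2 <- function(x) {
  new_node(up2_array(x$value), list(x), function(g, self) {
    dn <- downsample2_array(g, fun = function(m) 4 * downsample2_mean(m))
    add_grad(x, dn)
  })
}

# 0.5 * cross-entropy + 0.5 * soft-Dice on the foreground channel of a
# 2-channel logit map against a binary target.
loss_ce_dice <- function(logits, target) {
  l <- logits$value
  z <- l[, , 2] - l[, , 1]
  p <- 1 / (1 + exp(-z))
  eps <- 1e-7
  ce <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  smooth <- 1
  num <- 2 * sum(p * target) + smooth
  den <- sum(p) + sum(target) + smooth
  dice <- num / den
  value <- 0.5 * ce + 0.5 * (1 - dice)
  n <- length(target)
  new_node(value, list(logits), function(g, self) {
    dce_dp <- (-(target / (p + eps)) + (1 - target) / (1 - p + eps)) / n
    ddice_dp <- (2 * target * den - num) / den^2
    dl_dp <- 0.5 * dce_dp + 0.5 * (-ddice_dp)
    dz <- dl_dp * p * (1 - p) * g
    gl <- array(0, dim(l))
    gl[, , 1] <- -dz
    gl[, , 2] <- dz
    add_grad(logits, gl)
  })
}

# Weighted mean-squared error against a proximity map; weight 1 + w_pos * t
# counteracts the dominance of empty background.
loss_wmse <- function(pred, target, w_pos = 10) {
  p <- pred$value
  if (length(dim(p)) == 3) p <- p[, , 1]
  w <- 1 + w_pos * target
  sw <- sum(w)
  value <- sum(w * (p - target)^2) / sw
  new_node(value, list(pred), function(g, self) {
    gp <- 2 * w * (p - target) / sw * g
    add_grad(pred, array(gp, c(dim(gp), 1)))
  })
}

op_scalar_combine <- function(nodes, weights) {
  value <- sum(vapply(seq_along(nodes), function(i) weights[i] * nodes[[i]]$value,
                      numeric(1)))
  new_node(value, nodes, function(g, self) {
    for (i in seq_along(nodes)) add_grad(nodes[[i]], g * weights[i])
  })
}

# Reverse sweep: collect the subgraph below `loss`, replay newest-first.
nn_backward <- function(loss) {
  nodes <- list()
  seen <- character(0)
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    id <- format(nd$order)
    if (id %in% seen) next
    seen <- c(seen, id)
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(nd) nd$order, numeric(1)), decreasing = TRUE)
  loss$grad <- 1
  for (i in ord) {
    nd <- nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad, nd)
  }
  invisible(NULL)
}

collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (inherits(e, "nn_param")) out[[length(out) + 1L]] <<- e
    else if (is.list(e)) for (el in e) walk(el)
  }
  walk(x)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- array(0, dim(p$value) %||% length(p$value))
  invisible(NULL)
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  zero_grads(params)
  invisible(NULL)
}

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$value), numeric(1)))
}

# Serialize parameter values to a plain list (for checkpoints).
params_state <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, state) {
  for (i in seq_along(params)) params[[i]]$value <- state[[i]]
  invisible(NULL)
}
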
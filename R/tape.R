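# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every differentiable operation records a node on the active tape.  A
# node is an environment holding the forward value, the parent nodes and
# a backward closure that maps the node's gradient to parent gradients.
# Parameters are environments (`$value`, `$grad`, Adam state); after a
# backward pass their accumulated gradients are ready for an optimiser
# step.  This is deliberately small: only the ops the network needs.

.tape_state <- new.env(parent = emptyenv())
.tape_state$current <- NULL

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_push <- function(tp, node) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- node
  tp$n <- n
  node
}

# Run `expr` with a fresh active tape; returns list(value_node, tape).
with_tape <- function(expr) {
  old <- .tape_state$current
  tp <- tape_new()
  .tape_state$current <- tp
  on.exit(.tape_state$current <- old)
  root <- force(expr)
  list(root = root, tape = tp)
}

active_tape <- function() {
  tp <- .tape_state$current
  if (is.null(tp)) stop("no active tape; wrap the forward pass in with_tape()")
  tp
}

# Create a node.  `backfn(self)` must return a list of gradients aligned
# with `parents` (NULL entries allowed).  Leaf nodes have no backfn.
nd_node <- function(val, parents = list(), backfn = NULL, param = NULL,
                    cache = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  nd$cache <- cache
  nd$grad <- NULL
  tape_push(active_tape(), nd)
}

nd_const <- function(x) nd_node(x)

# Parameter container used by layers and the optimiser.
param_new <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nd_param <- function(p) nd_node(p$value, param = p)

accum_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep.  Seeds `root$grad` with 1 (scalar roots) and propagates
# through the tape in reverse recording order; parameter leaves add into
# their container's `$grad`.
tape_backward <- function(tp, root, seed = 1) {
  root$grad <- seed
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$backfn)) {
      gs <- nd$backfn(nd)
      for (j in seq_along(nd$parents)) {
        if (!is.null(gs[[j]])) accum_grad(nd$parents[[j]], gs[[j]])
      }
    }
    if (!is.null(nd$param)) {
      nd$param$grad <- nd$param$grad + nd$grad
    }
  }
  invisible(NULL)
}

## ---- elementwise / scalar ops --------------------------------------------

nd_add <- function(a, b) {
  nd_node(a$val + b$val, list(a, b), function(self) {
    g <- self$grad
    ga <- if (length(a$val) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$val) == 1L && length(g) > 1L) sum(g) else g
    list(ga, gb)
  })
}

nd_sub <- function(a, b) {
  nd_node(a$val - b$val, list(a, b), function(self) {
    g <- self$grad
    ga <- if (length(a$val) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$val) == 1L && length(g) > 1L) sum(g) else g
    list(ga, -gb)
  })
}

nd_mul <- function(a, b) {
  nd_node(a$val * b$val, list(a, b), function(self) {
    g <- self$grad
    ga <- g * b$val
    gb <- g * a$val
    if (length(a$val) == 1L && length(ga) > 1L) ga <- sum(ga)
    if (length(b$val) == 1L && length(gb) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

# scalar / scalar division
nd_div <- function(a, b) {
  nd_node(a$val / b$val, list(a, b), function(self) {
    g <- self$grad
    list(g / b$val, -g * a$val / (b$val^2))
  })
}

nd_scale <- function(a, k) {  # multiply by a constant
  nd_node(a$val * k, list(a), function(self) list(self$grad * k))
}

nd_shift <- function(a, k) {  # add a constant
  nd_node(a$val + k, list(a), function(self) list(self$grad))
}

nd_sum <- function(a) {
  nd_node(sum(a$val), list(a), function(self) {
    g <- self$grad
    gv <- array(g, dim = dim(a$val) %||% length(a$val))
    list(gv)
  })
}

nd_relu <- function(a) {
  m <- a$val > 0
  nd_node(a$val * m, list(a), function(self) list(self$grad * m))
}

nd_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  nd_node(s, list(a), function(self) list(self$grad * s * (1 - s)))
}

## ---- vector (channel descriptor) ops -------------------------------------

# softmax over a plain vector (channel axis of a pooled descriptor)
nd_softmax <- function(a) {
  v <- a$val
  s <- exp(v - max(v))
  s <- s / sum(s)
  nd_node(s, list(a), function(self) {
    g <- self$grad
    list(s * (g - sum(g * s)))
  })
}

# fully connected: v (length Cin) %*% W (Cin x Cout) + b (length Cout)
nd_dense <- function(v, W, b) {
  wn <- nd_param(W); bn <- nd_param(b)
  out <- as.vector(v$val %*% wn$val) + bn$val
  nd_node(out, list(v, wn, bn), function(self) {
    g <- self$grad
    list(as.vector(wn$val %*% g),         # dv
         outer(v$val, g),                 # dW
         g)                               # db
  })
}

## ---- feature-map ops (arrays X x Y x Z x C) ------------------------------

# global average pool over the three spatial axes -> length-C vector
nd_gap <- function(a) {
  d <- dim(a$val)
  nvox <- prod(d[1:3])
  m <- a$val; dim(m) <- c(nvox, d[4])
  nd_node(colMeans(m), list(a), function(self) {
    g <- self$grad
    gv <- matrix(g / nvox, nvox, d[4], byrow = TRUE)
    dim(gv) <- d
    list(gv)
  })
}

# scale each channel of a feature map by a per-channel factor (vector node)
nd_chanscale <- function(a, w) {
  d <- dim(a$val)
  nvox <- prod(d[1:3])
  am <- a$val; dim(am) <- c(nvox, d[4])
  om <- am * rep(w$val, each = nvox)
  dim(om) <- d
  nd_node(om, list(a, w), function(self) {
    g <- self$grad; dim(g) <- c(nvox, d[4])
    ga <- g * rep(w$val, each = nvox); dim(ga) <- d
    gw <- colSums(g * am)
    list(ga, gw)
  })
}

# concatenate along the channel axis
nd_concat <- function(a, b) {
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(identical(da[1:3], db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a$val
  out[, , , da[4] + seq_len(db[4])] <- b$val
  nd_node(out, list(a, b), function(self) {
    g <- self$grad
    list(g[, , , seq_len(da[4]), drop = FALSE],
         g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

# instance normalisation: per-channel standardisation + learnable affine
nd_instancenorm <- function(a, gamma, beta, eps = 1e-5) {
  gn <- nd_param(gamma); bn <- nd_param(beta)
  d <- dim(a$val)
  nvox <- prod(d[1:3])
  m <- a$val; dim(m) <- c(nvox, d[4])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = nvox)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = nvox)
  out <- xhat * rep(gn$val, each = nvox) + rep(bn$val, each = nvox)
  dim(out) <- d
  nd_node(out, list(a, gn, bn), function(self) {
    g <- self$grad; dim(g) <- c(nvox, d[4])
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- g * rep(gn$val, each = nvox)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- (dxhat - rep(s1 / nvox, each = nvox) -
             xhat * rep(s2 / nvox, each = nvox)) * rep(istd, each = nvox)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}
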
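# Minimal reverse-mode automatic differentiation over dense matrices.
# Every value is a numeric matrix; a tape records operations in creation
# order and `ad_backward()` replays it in reverse, accumulating gradients.
# This is all the machinery the GCN/attention models need; gradients are
# verified against finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp$param_nodes <- list()  # list of list(name=, node=), possibly repeated
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    track = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (track) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

# Constants never receive gradients and stay off the tape.
ad_const <- function(tape, value) {
  ad_node(tape, as.matrix(value), track = FALSE)
}

# A parameter leaf; registered so its gradient can be collected by name.
ad_param <- function(tape, store, name) {
  nd <- ad_node(tape, store$values[[name]])
  tape$param_nodes[[length(tape$param_nodes) + 1L]] <- list(name = name, node = nd)
  nd
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @noRd
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, nrow(loss$value), ncol(loss$value))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    grads <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!is.null(grads[[j]])) ad_accum(p, grads[[j]])
    }
  }
  invisible(NULL)
}

# Collect parameter gradients by name (summing over repeated uses).
ad_param_grads <- function(tape) {
  out <- list()
  for (pn in tape$param_nodes) {
    g <- pn$node$grad
    if (is.null(g)) g <- matrix(0, nrow(pn$node$value), ncol(pn$node$value))
    out[[pn$name]] <- if (is.null(out[[pn$name]])) g else out[[pn$name]] + g
  }
  out
}

## ---- operations ------------------------------------------------------------

ad_matmul <- function(tape, a, b, tb = FALSE) {
  val <- if (tb) tcrossprod(a$value, b$value) else a$value %*% b$value
  ad_node(tape, val, parents = list(a, b), backward = function(g) {
    if (tb) {
      list(g %*% b$value, crossprod(g, a$value))
    } else {
      list(tcrossprod(g, b$value), crossprod(a$value, g))
    }
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, parents = list(a, b),
          backward = function(g) list(g, g))
}

# X (n x d) + bias (1 x d), broadcast over rows.
ad_add_bias <- function(tape, x, bias) {
  ad_node(tape, sweep(x$value, 2L, as.numeric(bias$value), "+"),
          parents = list(x, bias),
          backward = function(g) list(g, matrix(colSums(g), 1L)))
}

ad_relu <- function(tape, a) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, parents = list(a),
          backward = function(g) list(g * mask))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, parents = list(a),
          backward = function(g) list(g * s * (1 - s)))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$value), parents = list(a),
          backward = function(g) list(g / a$value))
}

# mult * a + add, with constant scalars.
ad_affine_const <- function(tape, a, mult = 1, add = 0) {
  ad_node(tape, mult * a$value + add, parents = list(a),
          backward = function(g) list(mult * g))
}

# Elementwise product with a constant matrix (dropout masks etc.).
ad_mul_constmat <- function(tape, a, m) {
  ad_node(tape, a$value * m, parents = list(a),
          backward = function(g) list(g * m))
}

ad_softmax_rows <- function(tape, a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ad_node(tape, s, parents = list(a), backward = function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# Column means -> 1 x d row vector.
ad_colmeans <- function(tape, a) {
  n <- nrow(a$value)
  ad_node(tape, matrix(colMeans(a$value), 1L), parents = list(a),
          backward = function(g) {
            list(matrix(as.numeric(g), n, ncol(a$value), byrow = TRUE) / n)
          })
}

ad_slice_cols <- function(tape, a, cols) {
  ad_node(tape, a$value[, cols, drop = FALSE], parents = list(a),
          backward = function(g) {
            out <- matrix(0, nrow(a$value), ncol(a$value))
            out[, cols] <- g
            list(out)
          })
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(nd) ncol(nd$value), integer(1L))
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ad_node(tape, do.call(cbind, lapply(nodes, function(nd) nd$value)),
          parents = nodes, backward = function(g) {
            lapply(seq_along(nodes), function(j) {
              g[, starts[j]:ends[j], drop = FALSE]
            })
          })
}

ad_rbind <- function(tape, nodes) {
  heights <- vapply(nodes, function(nd) nrow(nd$value), integer(1L))
  ends <- cumsum(heights)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ad_node(tape, do.call(rbind, lapply(nodes, function(nd) nd$value)),
          parents = nodes, backward = function(g) {
            lapply(seq_along(nodes), function(j) {
              g[starts[j]:ends[j], , drop = FALSE]
            })
          })
}

ad_slice_rows <- function(tape, a, rows) {
  ad_node(tape, a$value[rows, , drop = FALSE], parents = list(a),
          backward = function(g) {
            out <- matrix(0, nrow(a$value), ncol(a$value))
            out[rows, ] <- g
            list(out)
          })
}

## ---- parameter store and Adam ---------------------------------------------

param_store <- function(values) {
  st <- new.env(parent = emptyenv())
  st$values <- values
  st$m <- lapply(values, function(v) v * 0)
  st$v <- lapply(values, function(v) v * 0)
  st$t <- 0L
  st
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_step <- function(store, grads, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  store$t <- store$t + 1L
  for (name in names(grads)) {
    g <- grads[[name]]
    store$m[[name]] <- beta1 * store$m[[name]] + (1 - beta1) * g
    store$v[[name]] <- beta2 * store$v[[name]] + (1 - beta2) * g^2
    mhat <- store$m[[name]] / (1 - beta1^store$t)
    vhat <- store$v[[name]] / (1 - beta2^store$t)
    store$values[[name]] <- store$values[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(store)
}
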
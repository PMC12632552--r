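# Minimal reverse-mode automatic differentiation over R matrices.
#
# Nodes are environments holding a value, parent links and a backward
# closure; every gradient-requiring node is registered on a global tape in
# creation order, so creation order is a topological order and backward is
# a single reverse sweep. All values are numeric matrices (scalars are
# 1 x 1); the engine supports exactly the operations the encoder, decoder
# and losses need, each with a hand-derived adjoint that is checked
# against finite differences in the test suite.

td_env <- new.env(parent = emptyenv())
td_env$tape <- vector("list", 1024L)
td_env$len <- 0L

#' Reset the autodiff tape
#'
#' Call before building a fresh computation graph (e.g. at the start of a
#' training step). Existing nodes become invalid for backward passes.
#' @export
td_reset <- function() {
  td_env$tape <- vector("list", 1024L)
  td_env$len <- 0L
  invisible(NULL)
}

td_register <- function(node) {
  n <- td_env$len + 1L
  if (n > length(td_env$tape)) {
    td_env$tape <- c(td_env$tape, vector("list", length(td_env$tape)))
  }
  td_env$tape[[n]] <- node
  td_env$len <- n
  node$id <- n
  node
}

new_node <- function(value, parents = list(), backfn = NULL) {
  req <- any(vapply(parents, function(p) p$req, logical(1)))
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$req <- req
  e$grad <- NULL
  if (req) {
    e$parents <- parents
    e$backfn <- backfn
    td_register(e)
  } else {
    e$id <- 0L
  }
  class(e) <- "td_node"
  e
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = if (length(x) == 1L) 1L else length(x))
}

#' Create a constant (no gradient) node
#' @param value numeric vector/matrix.
#' @export
td_const <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- as_mat(value); e$req <- FALSE; e$grad <- NULL; e$id <- 0L
  class(e) <- "td_node"
  e
}

#' Create a parameter (gradient-requiring leaf) node
#' @param value numeric vector/matrix.
#' @export
td_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- as_mat(value); e$req <- TRUE; e$grad <- NULL
  e$parents <- list(); e$backfn <- NULL
  td_register(e)
  class(e) <- "td_node"
  e
}

#' Value of a node
#' @param x a td_node.
#' @export
td_value <- function(x) x$value

#' Gradient accumulated at a node (after [td_backward()])
#' @param x a td_node.
#' @export
td_grad <- function(x) x$grad

#' Reverse sweep from a scalar root
#'
#' Accumulates d root / d leaf into `$grad` of every gradient-requiring
#' ancestor on the tape.
#' @param root scalar td_node (1 x 1 value).
#' @export
td_backward <- function(root) {
  stopifnot(inherits(root, "td_node"), length(root$value) == 1L)
  if (!root$req) return(invisible(NULL))
  root$grad <- matrix(1, 1, 1)
  for (k in seq(root$id, 1L)) {
    nd <- td_env$tape[[k]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$req || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

# ---- arithmetic -----------------------------------------------------------

#' Elementwise tape operations
#'
#' Same-shape elementwise arithmetic, scalar scaling/shifts, and smooth
#' nonlinearities on tape nodes.
#' @param a,b,x td_nodes (same shape for binary ops).
#' @param k plain numeric scalar.
#' @name td_ops
NULL

#' @rdname td_ops
#' @export
td_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

#' @rdname td_ops
#' @export
td_sub <- function(a, b) {
  new_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

#' @rdname td_ops
#' @export
td_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' @rdname td_ops
#' @export
td_smul <- function(a, k) {
  new_node(a$value * k, list(a), function(g) list(g * k))
}

#' @rdname td_ops
#' @export
td_sadd <- function(a, k) {
  new_node(a$value + k, list(a), function(g) list(g))
}

#' @rdname td_ops
#' @export
td_square <- function(x) {
  xv <- x$value
  new_node(xv * xv, list(x), function(g) list(2 * g * xv))
}

#' @rdname td_ops
#' @export
td_sqrt <- function(x) {
  s <- sqrt(x$value)
  new_node(s, list(x), function(g) list(g / (2 * s)))
}

#' @rdname td_ops
#' @export
td_exp <- function(x) {
  s <- exp(x$value)
  new_node(s, list(x), function(g) list(g * s))
}

#' @rdname td_ops
#' @export
td_log <- function(x) {
  xv <- x$value
  new_node(log(xv), list(x), function(g) list(g / xv))
}

#' @rdname td_ops
#' @export
td_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(s, list(x), function(g) list(g * s * (1 - s)))
}

#' @rdname td_ops
#' @export
td_silu <- function(x) {
  xv <- x$value
  s <- 1 / (1 + exp(-xv))
  new_node(xv * s, list(x), function(g) list(g * (s + xv * s * (1 - s))))
}

#' @rdname td_ops
#' @export
td_safe_sqrt <- function(x, eps = 1e-12) {
  # exact sqrt forward (0 stays 0); backward floored to stay finite
  s <- sqrt(x$value)
  new_node(s, list(x), function(g) list(g * (0.5 / sqrt(x$value + eps))))
}

#' @rdname td_ops
#' @export
td_abs <- function(x) {
  xv <- x$value
  new_node(abs(xv), list(x), function(g) list(g * sign(xv)))
}

#' @rdname td_ops
#' @export
td_pmin_const <- function(x, k) {
  xv <- x$value
  new_node(pmin(xv, k), list(x), function(g) list(g * (xv < k)))
}

# ---- linear algebra and shaping ------------------------------------------

#' Linear-algebra and shaping tape operations
#' @param a,b,x td_nodes.
#' @name td_linalg
NULL

#' @rdname td_linalg
#' @export
td_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  new_node(av %*% bv, list(a, b), function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

#' @rdname td_linalg
#' @export
td_t <- function(x) {
  new_node(t(x$value), list(x), function(g) list(t(g)))
}

#' Add a bias row-vector to every row of a matrix
#' @param a td_node (n x d); @param bias td_node (1 x d or length d).
#' @export
td_addbias <- function(a, bias) {
  bv <- as.numeric(bias$value)
  av <- a$value
  new_node(av + rep(bv, each = nrow(av)), list(a, bias), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

#' Multiply every row of a matrix by a row-vector
#' @param a td_node (n x d); @param v td_node (1 x d).
#' @export
td_bmul_row <- function(a, v) {
  av <- a$value; vv <- as.numeric(v$value)
  n <- nrow(av)
  new_node(av * rep(vv, each = n), list(a, v), function(g) {
    list(g * rep(vv, each = n), matrix(colSums(g * av), 1L))
  })
}

#' Subtract a column-vector from every column of a matrix
#' @param a td_node (n x d); @param v td_node (n x 1).
#' @export
td_bsub_col <- function(a, v) {
  new_node(a$value - as.numeric(v$value), list(a, v), function(g) {
    list(g, -matrix(rowSums(g), ncol = 1L))
  })
}

#' Multiply every column of a matrix by a column-vector
#' @param a td_node (n x d); @param v td_node (n x 1).
#' @export
td_bmul_col <- function(a, v) {
  av <- a$value; vv <- as.numeric(v$value)
  new_node(av * vv, list(a, v), function(g) {
    list(g * vv, matrix(rowSums(g * av), ncol = 1L))
  })
}

#' @rdname td_linalg
#' @export
td_reshape <- function(x, dims) {
  od <- dim(x$value)
  v <- x$value; dim(v) <- dims
  new_node(v, list(x), function(g) { dim(g) <- od; list(g) })
}

#' Concatenate matrices by columns
#' @param ... td_nodes with equal row counts.
#' @export
td_cbind <- function(...) {
  xs <- list(...)
  widths <- vapply(xs, function(x) ncol(x$value), integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  new_node(do.call(cbind, lapply(xs, td_value)), xs, function(g) {
    lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

#' Gather rows (backward scatter-adds)
#' @param x td_node (n x d); @param idx integer vector of row indices.
#' @export
td_rows <- function(x, idx) {
  n <- nrow(x$value)
  new_node(x$value[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, n, ncol(g))
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

#' Select columns
#' @param x td_node; @param idx integer vector of column indices
#'   (no duplicates).
#' @export
td_cols <- function(x, idx) {
  d <- ncol(x$value)
  new_node(x$value[, idx, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(g), d)
    out[, idx] <- g
    list(out)
  })
}

#' Sum rows into groups
#'
#' Row g of the output is the sum of rows of `x` whose `group` equals g;
#' groups with no members are zero.
#' @param x td_node (n x d); @param group integer vector (length n) in
#'   1..n_groups; @param n_groups number of output rows.
#' @export
td_group_sum <- function(x, group, n_groups) {
  new_node({
    out <- matrix(0, n_groups, ncol(x$value))
    rs <- rowsum(x$value, group)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }, list(x), function(g) list(g[group, , drop = FALSE]))
}

# ---- reductions -----------------------------------------------------------

#' Reduction tape operations (scalar 1 x 1 outputs, or row/col sums)
#' @param x td_node.
#' @name td_reduce
NULL

#' @rdname td_reduce
#' @export
td_sum <- function(x) {
  d <- dim(x$value)
  new_node(matrix(sum(x$value), 1, 1), list(x), function(g) {
    list(array(as.numeric(g), dim = d))
  })
}

#' @rdname td_reduce
#' @export
td_mean <- function(x) {
  d <- dim(x$value); n <- length(x$value)
  new_node(matrix(mean(x$value), 1, 1), list(x), function(g) {
    list(array(as.numeric(g) / n, dim = d))
  })
}

#' @rdname td_reduce
#' @export
td_rowsums <- function(x) {
  d <- ncol(x$value)
  new_node(matrix(rowSums(x$value), ncol = 1L), list(x), function(g) {
    list(matrix(g, nrow(g), d))
  })
}

#' Euclidean norm of each row (smoothed near zero)
#' @param x td_node (n x d); @param eps smoothing floor inside the root.
#' @export
td_rownorm <- function(x, eps = 1e-12) {
  xv <- x$value
  nr <- sqrt(rowSums(xv^2) + eps)
  new_node(matrix(nr, ncol = 1L), list(x), function(g) {
    list(xv * (as.numeric(g) / nr))
  })
}

# ---- normalization and attention -----------------------------------------

#' Row-wise softmax
#' @param x td_node (n x d).
#' @export
td_softmax_rows <- function(x) {
  xv <- x$value
  m <- xv - apply(xv, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  new_node(s, list(x), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

#' Row-wise layer normalization (no affine part)
#' @param x td_node (n x d); @param eps variance floor.
#' @export
td_layernorm_rows <- function(x, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  y <- xc * inv
  new_node(y, list(x), function(g) {
    gm <- rowMeans(g)
    gy <- rowMeans(g * y)
    list(inv * (g - gm - y * gy))
  })
}

#' Row-wise cross product of two n x 3 matrices
#' @param a,b td_nodes (n x 3).
#' @export
td_cross <- function(a, b) {
  av <- a$value; bv <- b$value
  cr <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  new_node(cr(av, bv), list(a, b), function(g) {
    list(cr(bv, g), cr(g, av))
  })
}

#' Degree-coupling contraction for graded channel blocks
#'
#' Inputs are edge-major blocks `[n, C*(2l+1)]` with the representation
#' index m fastest within each channel. Computes, per row and channel,
#' `out[,c,m3] = sum_{m1,m2} cg[m1,m2,m3] a[,c,m1] * b[,c,m2]`.
#'
#' @param a td_node (n x C*(2l1+1)); @param b td_node (n x C*(2l2+1));
#' @param cg coupling tensor from [real_cg_tensor()];
#' @param n_channels channel count C.
#' @export
td_cg_couple <- function(a, b, cg, n_channels) {
  d1 <- dim(cg)[1]; d2 <- dim(cg)[2]; d3 <- dim(cg)[3]
  av <- a$value; bv <- b$value
  n <- nrow(av)
  C <- n_channels
  nz <- which(cg != 0, arr.ind = TRUE)
  cvals <- cg[nz]
  # column index sets across channels for a fixed representation index m
  colsA <- lapply(seq_len(d1), function(m) seq(m, by = d1, length.out = C))
  colsB <- lapply(seq_len(d2), function(m) seq(m, by = d2, length.out = C))
  # column permutations between m-major stacks and m-fastest block layout
  permO <- as.vector(t(matrix(seq_len(C * d3), C, d3)))   # stack -> blocks
  permA <- as.vector(t(matrix(seq_len(C * d1), C, d1)))
  permB <- as.vector(t(matrix(seq_len(C * d2), C, d2)))
  acc <- function(d_out, terms_for) {
    # terms_for(m_out) returns a list of [n, C] matrices to sum (or NULL)
    stack <- vector("list", d_out)
    for (m in seq_len(d_out)) {
      ts <- terms_for(m)
      stack[[m]] <- if (length(ts) == 0L) matrix(0, n, C) else
        Reduce(`+`, ts)
    }
    do.call(cbind, stack)
  }
  out <- acc(d3, function(m3) {
    ks <- which(nz[, 3] == m3)
    lapply(ks, function(k) {
      cvals[k] * av[, colsA[[nz[k, 1]]], drop = FALSE] *
        bv[, colsB[[nz[k, 2]]], drop = FALSE]
    })
  })[, permO, drop = FALSE]
  new_node(out, list(a, b), function(g) {
    gcols <- lapply(seq_len(d3), function(m) {
      g[, seq(m, by = d3, length.out = C), drop = FALSE]
    })
    ga <- acc(d1, function(m1) {
      ks <- which(nz[, 1] == m1)
      lapply(ks, function(k) {
        cvals[k] * gcols[[nz[k, 3]]] * bv[, colsB[[nz[k, 2]]], drop = FALSE]
      })
    })[, permA, drop = FALSE]
    gb <- acc(d2, function(m2) {
      ks <- which(nz[, 2] == m2)
      lapply(ks, function(k) {
        cvals[k] * gcols[[nz[k, 3]]] * av[, colsA[[nz[k, 1]]], drop = FALSE]
      })
    })[, permB, drop = FALSE]
    list(ga, gb)
  })
}

# ---- convenience ----------------------------------------------------------

#' Affine map: x %*% W + b
#' @param x td_node (n x d_in); @param W td_node (d_in x d_out);
#' @param b td_node bias (1 x d_out) or NULL.
#' @export
td_linear <- function(x, W, b = NULL) {
  out <- td_matmul(x, W)
  if (!is.null(b)) out <- td_addbias(out, b)
  out
}

#' Numerical gradient check helper
#'
#' Central finite differences of `f` (numeric in, scalar out) at `x`.
#' @param f function taking a numeric array and returning a scalar.
#' @param x numeric array.
#' @param eps step size.
#' @return array of partial derivatives, same shape as x.
#' @export
numerical_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
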
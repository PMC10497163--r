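# Minimal reverse-mode automatic differentiation on matrices.
#
# Every operator accepts plain numeric matrices or `adnode` objects and
# returns the same kind: forwarding numeric inputs straight through means a
# single implementation of each network serves both inference (cheap) and
# training (taped).  Nodes are environments carrying a value, their parent
# nodes, and a backward closure mapping the output gradient to parent
# gradients.  Node ids increase monotonically at creation, so processing
# reachable nodes in decreasing id order is a valid topological order for
# backpropagation.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_new <- function(value, parents = list(), backward = NULL) {
  .ad$counter <- .ad$counter + 1L
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$id <- .ad$counter
  class(e) <- "adnode"
  e
}

is_node <- function(x) inherits(x, "adnode")

#' @keywords internal
ad_value <- function(x) if (is_node(x)) x$value else x

ad_param <- function(value) ad_new(value)

any_node <- function(...) {
  for (a in list(...)) if (is_node(a)) return(TRUE)
  FALSE
}

## ---- operators -------------------------------------------------------------

ad_mm <- function(a, b) {
  if (!any_node(a, b)) return(a %*% b)
  av <- ad_value(a); bv <- ad_value(b)
  ad_new(av %*% bv, list(a, b), function(g) {
    list(if (is_node(a)) g %*% t(bv), if (is_node(b)) t(av) %*% g)
  })
}

ad_add <- function(a, b) {
  if (!any_node(a, b)) return(a + b)
  av <- ad_value(a); bv <- ad_value(b)
  ad_new(av + bv, list(a, b), function(g) {
    ga <- if (is_node(a)) { if (length(av) == 1L) sum(g) else g }
    gb <- if (is_node(b)) { if (length(bv) == 1L) sum(g) else g }
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  if (!any_node(a, b)) return(a - b)
  av <- ad_value(a); bv <- ad_value(b)
  ad_new(av - bv, list(a, b), function(g) {
    ga <- if (is_node(a)) { if (length(av) == 1L) sum(g) else g }
    gb <- if (is_node(b)) { if (length(bv) == 1L) -sum(g) else -g }
    list(ga, gb)
  })
}

ad_mul <- function(a, b) {
  if (!any_node(a, b)) return(a * b)
  av <- ad_value(a); bv <- ad_value(b)
  ad_new(av * bv, list(a, b), function(g) {
    ga <- if (is_node(a)) { if (length(av) == 1L) sum(g * bv) else g * bv }
    gb <- if (is_node(b)) { if (length(bv) == 1L) sum(g * av) else g * av }
    list(ga, gb)
  })
}

ad_scale <- function(a, k) {           # k is a plain constant
  if (!is_node(a)) return(a * k)
  ad_new(ad_value(a) * k, list(a), function(g) list(g * k))
}

# broadcast a column-vector bias over every column of a matrix
ad_add_bias <- function(mat, bias) {
  if (!any_node(mat, bias)) return(mat + as.vector(bias))
  mv <- ad_value(mat); bv <- ad_value(bias)
  ad_new(mv + as.vector(bv), list(mat, bias), function(g) {
    list(if (is_node(mat)) g,
         if (is_node(bias)) matrix(rowSums(g), ncol = 1L))
  })
}

# broadcast a row-vector bias over every row of a matrix (cells x features)
ad_add_rowbias <- function(mat, bias) {
  if (!any_node(mat, bias)) return(sweep(mat, 2L, as.vector(bias), "+"))
  mv <- ad_value(mat); bv <- ad_value(bias)
  ad_new(sweep(mv, 2L, as.vector(bv), "+"), list(mat, bias), function(g) {
    list(if (is_node(mat)) g,
         if (is_node(bias)) matrix(colSums(g), nrow = 1L))
  })
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ad_value(a)))
  if (!is_node(a)) return(s)
  ad_new(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  tv <- tanh(ad_value(a))
  if (!is_node(a)) return(tv)
  ad_new(tv, list(a), function(g) list(g * (1 - tv^2)))
}

ad_relu <- function(a) {
  av <- ad_value(a)
  rv <- pmax(av, 0)
  if (!is_node(a)) return(rv)
  ad_new(rv, list(a), function(g) list(g * (av > 0)))
}

ad_exp <- function(a) {
  ev <- exp(ad_value(a))
  if (!is_node(a)) return(ev)
  ad_new(ev, list(a), function(g) list(g * ev))
}

ad_t <- function(a) {
  if (!is_node(a)) return(t(a))
  ad_new(t(ad_value(a)), list(a), function(g) list(t(g)))
}

ad_rows <- function(a, idx) {
  if (!is_node(a)) return(a[idx, , drop = FALSE])
  av <- ad_value(a)
  ad_new(av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[idx, ] <- g
    list(out)
  })
}

ad_cols <- function(a, idx) {
  if (!is_node(a)) return(a[, idx, drop = FALSE])
  av <- ad_value(a)
  ad_new(av[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, idx] <- g
    list(out)
  })
}

ad_pick <- function(a, i) {            # single element as 1x1
  if (!is_node(a)) return(matrix(ad_value(a)[i], 1L, 1L))
  av <- ad_value(a)
  ad_new(matrix(av[i], 1L, 1L), list(a), function(g) {
    out <- array(0, dim(av))
    out[i] <- g[1L]
    list(out)
  })
}

# stack column vectors (and matrices with one column) vertically
ad_vconcat <- function(parts) {
  if (!any(vapply(parts, is_node, logical(1)))) {
    return(do.call(rbind, lapply(parts, function(p) as.matrix(p))))
  }
  vals <- lapply(parts, function(p) as.matrix(ad_value(p)))
  sizes <- vapply(vals, nrow, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ad_new(do.call(rbind, vals), parts, function(g) {
    lapply(seq_along(parts), function(k) {
      if (is_node(parts[[k]])) g[starts[k]:ends[k], , drop = FALSE]
    })
  })
}

ad_hconcat <- function(parts) {
  if (!any(vapply(parts, is_node, logical(1)))) {
    return(do.call(cbind, parts))
  }
  vals <- lapply(parts, ad_value)
  sizes <- vapply(vals, ncol, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ad_new(do.call(cbind, vals), parts, function(g) {
    lapply(seq_along(parts), function(k) {
      if (is_node(parts[[k]])) g[, starts[k]:ends[k], drop = FALSE]
    })
  })
}

ad_reshape <- function(a, nr, nc) {
  if (!is_node(a)) return(matrix(a, nr, nc))
  av <- ad_value(a)
  ad_new(matrix(av, nr, nc), list(a), function(g) list(array(g, dim(av))))
}

ad_sum <- function(a) {
  if (!is_node(a)) return(matrix(sum(a), 1L, 1L))
  av <- ad_value(a)
  ad_new(matrix(sum(av), 1L, 1L), list(a), function(g) {
    list(array(g[1L], dim(av)))
  })
}

ad_mean <- function(a) {
  if (!is_node(a)) return(matrix(mean(a), 1L, 1L))
  av <- ad_value(a)
  ad_new(matrix(mean(av), 1L, 1L), list(a), function(g) {
    list(array(g[1L] / length(av), dim(av)))
  })
}

ad_colmeans <- function(a) {           # n x d -> d x 1
  if (!is_node(a)) return(matrix(colMeans(a), ncol = 1L))
  av <- ad_value(a)
  ad_new(matrix(colMeans(av), ncol = 1L), list(a), function(g) {
    list(matrix(rep(as.vector(g), each = nrow(av)) / nrow(av),
                nrow(av), ncol(av)))
  })
}

ad_log_softmax <- function(a) {        # column vector
  av <- ad_value(a)
  m <- max(av)
  ls <- av - m - log(sum(exp(av - m)))
  if (!is_node(a)) return(ls)
  p <- exp(ls)
  ad_new(ls, list(a), function(g) list(g - p * sum(g)))
}

ad_softmax_rows <- function(a) {       # softmax over each row
  av <- ad_value(a)
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  p <- e / rowSums(e)
  if (!is_node(a)) return(p)
  ad_new(p, list(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# gather entries of a column vector into the shape of idx; idx value 0 is a
# structural zero (used for convolution padding)
ad_gather_pad <- function(a, idx) {
  av <- ad_value(a)
  out <- array(0, dim(idx))
  nz <- idx > 0L
  out[nz] <- av[idx[nz]]
  if (!is_node(a)) return(out)
  ad_new(out, list(a), function(g) {
    ga <- array(0, dim(as.matrix(av)))
    gv <- g[nz]
    iv <- idx[nz]
    for (k in seq_along(iv)) ga[iv[k]] <- ga[iv[k]] + gv[k]
    list(ga)
  })
}

## ---- backward pass ---------------------------------------------------------

ad_backward <- function(root) {
  stopifnot(is_node(root), length(root$value) == 1L)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 64L)
  n_nodes <- 0L
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) if (is_node(p)) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n_nodes)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  for (nd in nodes) nd$grad <- NULL
  root$grad <- matrix(1, 1L, 1L)
  for (k in ord) {
    nd <- nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!is_node(p) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(root)
}

ad_grad <- function(node) node$grad
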
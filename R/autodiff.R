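# Reverse-mode automatic differentiation on a flat tape of dense matrices.
#
# Every node value is a base-R numeric matrix (column vectors are n x 1,
# scalars 1 x 1). Operations push a value plus a backward closure that, given
# the upstream gradient, accumulates gradients into the parent nodes. The
# model code builds one tape per optimisation step; `ad_backward()` then walks
# the tape in reverse. Fused ops (GRU step, losses, Renyi entropy) keep the
# tape short where the composite backward pass has a compact closed form.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$bw <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_push <- function(tp, val, bw = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$bw) <- 2L * n
  }
  tp$vals[[n]] <- val
  tp$bw[[n]] <- bw
  tp$n <- n
  n
}

ad_value <- function(tp, id) {
  id <- as.integer(id)
  tp$vals[[id]]
}

# gradient accumulator shared by all backward closures
ad_acc <- function(genv, id, g) {
  cur <- genv$g[[id]]
  genv$g[[id]] <- if (is.null(cur)) g else cur + g
}

#' @keywords internal
ad_backward <- function(tp, id) {
  genv <- new.env(parent = emptyenv())
  genv$g <- vector("list", tp$n)
  seed <- ad_value(tp, id)
  genv$g[[id]] <- array(1, dim = dim(seed))
  for (i in seq.int(id, 1L)) {
    gi <- genv$g[[i]]
    if (!is.null(gi) && !is.null(tp$bw[[i]])) tp$bw[[i]](gi, genv)
  }
  genv$g
}

ad_const <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  ad_push(tp, x)
}

# a parameter is a leaf node; callers remember its id to read its gradient
ad_param <- ad_const

ad_matmul <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A %*% B, function(g, genv) {
    ad_acc(genv, a, g %*% t(B))
    ad_acc(genv, b, crossprod(A, g))
  })
}

ad_add <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  ad_push(tp, tp$vals[[a]] + tp$vals[[b]], function(g, genv) {
    ad_acc(genv, a, g)
    ad_acc(genv, b, g)
  })
}

ad_sub <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  ad_push(tp, tp$vals[[a]] - tp$vals[[b]], function(g, genv) {
    ad_acc(genv, a, g)
    ad_acc(genv, b, -g)
  })
}

ad_hadamard <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A * B, function(g, genv) {
    ad_acc(genv, a, g * B)
    ad_acc(genv, b, g * A)
  })
}

# scale matrix node `a` by scalar node `s` (1x1)
ad_scale <- function(tp, a, s) {
  a <- as.integer(a); s <- as.integer(s)
  A <- tp$vals[[a]]; sv <- tp$vals[[s]][1L]
  ad_push(tp, sv * A, function(g, genv) {
    ad_acc(genv, a, sv * g)
    ad_acc(genv, s, matrix(sum(g * A), 1L, 1L))
  })
}

ad_scale_const <- function(tp, a, k) {
  a <- as.integer(a)
  ad_push(tp, k * tp$vals[[a]], function(g, genv) ad_acc(genv, a, k * g))
}

ad_tanh <- function(tp, a) {
  a <- as.integer(a)
  y <- tanh(tp$vals[[a]])
  ad_push(tp, y, function(g, genv) ad_acc(genv, a, g * (1 - y * y)))
}

ad_sigmoid <- function(tp, a) {
  a <- as.integer(a)
  y <- 1 / (1 + exp(-tp$vals[[a]]))
  ad_push(tp, y, function(g, genv) ad_acc(genv, a, g * y * (1 - y)))
}

# softmax of a column vector
ad_softmax <- function(tp, a) {
  a <- as.integer(a)
  x <- tp$vals[[a]]
  z <- exp(x - max(x))
  y <- z / sum(z)
  ad_push(tp, y, function(g, genv) ad_acc(genv, a, y * (g - sum(g * y))))
}

ad_sum <- function(tp, a) {
  a <- as.integer(a)
  A <- tp$vals[[a]]
  ad_push(tp, matrix(sum(A), 1L, 1L),
          function(g, genv) ad_acc(genv, a, array(g[1L], dim = dim(A))))
}

ad_dot <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, matrix(sum(A * B), 1L, 1L), function(g, genv) {
    ad_acc(genv, a, g[1L] * B)
    ad_acc(genv, b, g[1L] * A)
  })
}

# stack column vectors into one long column vector
ad_concat <- function(tp, ids) {
  ids <- lapply(ids, as.integer)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  lens <- vapply(vals, nrow, 0L)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_push(tp, matrix(unlist(vals), ncol = 1L), function(g, genv) {
    for (k in seq_along(ids)) {
      ad_acc(genv, ids[[k]], g[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

# rows of an embedding table summed into one dim-vector (multi-hot product)
ad_embed_sum <- function(tp, table_id, idx) {
  table_id <- as.integer(table_id)
  Tab <- tp$vals[[table_id]]
  d <- ncol(Tab)
  val <- if (length(idx) == 0L) matrix(0, d, 1L) else
    matrix(colSums(Tab[idx, , drop = FALSE]), ncol = 1L)
  ad_push(tp, val, function(g, genv) {
    if (length(idx) == 0L) return(invisible())
    G <- matrix(0, nrow(Tab), d)
    gv <- as.vector(g)
    for (i in idx) G[i, ] <- G[i, ] + gv
    ad_acc(genv, table_id, G)
  })
}

# affine map W x + b (b may be NULL)
ad_affine <- function(tp, w, x, b = NULL) {
  w <- as.integer(w); x <- as.integer(x)
  if (!is.null(b)) b <- as.integer(b)
  W <- tp$vals[[w]]; X <- tp$vals[[x]]
  val <- W %*% X
  if (!is.null(b)) val <- val + tp$vals[[b]]
  ad_push(tp, val, function(g, genv) {
    ad_acc(genv, w, tcrossprod(g, X))
    ad_acc(genv, x, crossprod(W, g))
    if (!is.null(b)) ad_acc(genv, b, g)
  })
}

# t(W) x + b  (used for projections through embedding tables)
ad_affine_t <- function(tp, w, x, b = NULL) {
  w <- as.integer(w); x <- as.integer(x)
  if (!is.null(b)) b <- as.integer(b)
  W <- tp$vals[[w]]; X <- tp$vals[[x]]
  val <- crossprod(W, X)
  if (!is.null(b)) val <- val + tp$vals[[b]]
  ad_push(tp, val, function(g, genv) {
    ad_acc(genv, w, tcrossprod(X, g))
    ad_acc(genv, x, W %*% g)
    if (!is.null(b)) ad_acc(genv, b, g)
  })
}

# One GRU step, fused. x, h are dim x 1 nodes; W a named list of parameter ids
# (Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh). Returns the new hidden state node.
ad_gru_step <- function(tp, W, x, h) {
  x <- as.integer(x); h <- as.integer(h)
  V <- function(id) tp$vals[[id]]
  xv <- V(x); hv <- V(h)
  z <- 1 / (1 + exp(-(V(W$Wz) %*% xv + V(W$Uz) %*% hv + V(W$bz))))
  r <- 1 / (1 + exp(-(V(W$Wr) %*% xv + V(W$Ur) %*% hv + V(W$br))))
  rh <- r * hv
  c_ <- tanh(V(W$Wh) %*% xv + V(W$Uh) %*% rh + V(W$bh))
  hnew <- (1 - z) * hv + z * c_
  ad_push(tp, hnew, function(g, genv) {
    dc <- g * z
    dz <- g * (c_ - hv)
    dh <- g * (1 - z)
    dpc <- dc * (1 - c_ * c_)
    drh <- crossprod(V(W$Uh), dpc)
    dr <- drh * hv
    dh <- dh + drh * r
    dpz <- dz * z * (1 - z)
    dpr <- dr * r * (1 - r)
    dh <- dh + crossprod(V(W$Uz), dpz) + crossprod(V(W$Ur), dpr)
    dx <- crossprod(V(W$Wz), dpz) + crossprod(V(W$Wr), dpr) +
      crossprod(V(W$Wh), dpc)
    ad_acc(genv, W$Wz, tcrossprod(dpz, xv)); ad_acc(genv, W$Uz, tcrossprod(dpz, hv))
    ad_acc(genv, W$bz, dpz)
    ad_acc(genv, W$Wr, tcrossprod(dpr, xv)); ad_acc(genv, W$Ur, tcrossprod(dpr, hv))
    ad_acc(genv, W$br, dpr)
    ad_acc(genv, W$Wh, tcrossprod(dpc, xv)); ad_acc(genv, W$Uh, tcrossprod(dpc, rh))
    ad_acc(genv, W$bh, dpc)
    ad_acc(genv, x, dx)
    ad_acc(genv, h, dh)
  })
}

# cosine similarity of two column vectors, with the small-norm guard
ad_cosine <- function(tp, a, b, eps = 1e-12) {
  a <- as.integer(a); b <- as.integer(b)
  u <- tp$vals[[a]]; v <- tp$vals[[b]]
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu < eps || nv < eps) {
    return(ad_push(tp, matrix(0, 1L, 1L), function(g, genv) invisible()))
  }
  cval <- sum(u * v) / (nu * nv)
  ad_push(tp, matrix(cval, 1L, 1L), function(g, genv) {
    gs <- g[1L]
    ad_acc(genv, a, gs * (v / (nu * nv) - cval * u / (nu * nu)))
    ad_acc(genv, b, gs * (u / (nu * nv) - cval * v / (nv * nv)))
  })
}

# stack dim x 1 nodes as rows of an n x dim matrix
ad_stack_rows <- function(tp, ids) {
  ids <- lapply(ids, as.integer)
  vals <- lapply(ids, function(i) as.vector(tp$vals[[i]]))
  M <- do.call(rbind, vals)
  ad_push(tp, M, function(g, genv) {
    for (k in seq_along(ids)) {
      ad_acc(genv, ids[[k]], matrix(g[k, ], ncol = 1L))
    }
  })
}

# --- fused loss ops -----------------------------------------------------

# quadratic DDI penalty o' A o for symmetric binary A (constant)
ad_ddi_loss <- function(tp, o, A) {
  o <- as.integer(o)
  ov <- as.vector(tp$vals[[o]])
  val <- as.numeric(crossprod(ov, A %*% ov))
  ad_push(tp, matrix(val, 1L, 1L), function(g, genv) {
    ad_acc(genv, o, g[1L] * 2 * (A %*% matrix(ov, ncol = 1L)))
  })
}

# multi-label margin loss over (positive, negative) label pairs, / |M|
ad_margin_loss <- function(tp, o, m) {
  o <- as.integer(o)
  ov <- as.vector(tp$vals[[o]])
  M <- length(ov)
  pos <- which(m == 1); neg <- which(m == 0)
  if (length(pos) == 0L || length(neg) == 0L) {
    return(ad_push(tp, matrix(0, 1L, 1L), function(g, genv) invisible()))
  }
  marg <- 1 - outer(ov[pos], ov[neg], "-")
  act <- marg > 0
  val <- sum(marg[act]) / M
  ad_push(tp, matrix(val, 1L, 1L), function(g, genv) {
    go <- numeric(M)
    go[pos] <- -rowSums(act) / M
    go[neg] <- colSums(act) / M
    ad_acc(genv, o, g[1L] * matrix(go, ncol = 1L))
  })
}

# binary cross-entropy, summed over labels, scores clamped to [eps, 1-eps]
ad_bce_loss <- function(tp, o, m, eps = 1e-7) {
  o <- as.integer(o)
  ov <- as.vector(tp$vals[[o]])
  oc <- pmin(pmax(ov, eps), 1 - eps)
  val <- -sum(m * log(oc) + (1 - m) * log(1 - oc))
  ad_push(tp, matrix(val, 1L, 1L), function(g, genv) {
    inside <- (ov > eps) & (ov < 1 - eps)
    go <- ifelse(inside, -m / oc + (1 - m) / (1 - oc), 0)
    ad_acc(genv, o, g[1L] * matrix(go, ncol = 1L))
  })
}

# Matrix-based Renyi alpha-entropy of the row set of Q (n x dim), fused.
# K_ij = exp(-||q_i - q_j||^2 / (2 sigma^2)) with K_ii = 1; A = K / tr(K);
# H = (1/(1-alpha)) log2 sum lambda_i(A)^alpha. sigma follows the median
# pairwise-distance rule (detached) unless supplied.
ad_renyi <- function(tp, q_mat, alpha, sigma = NULL) {
  q_mat <- as.integer(q_mat)
  Q <- tp$vals[[q_mat]]
  n <- nrow(Q)
  if (n == 1L) {
    return(ad_push(tp, matrix(0, 1L, 1L), function(g, genv) invisible()))
  }
  G <- tcrossprod(Q)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  if (is.null(sigma)) {
    off <- sqrt(D2[upper.tri(D2)])
    sigma <- stats::median(off)
    if (!is.finite(sigma) || sigma < 1e-8) sigma <- 1
  }
  K <- exp(-D2 / (2 * sigma^2))
  s <- sum(diag(K))
  A <- K / s
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  S <- sum(lam^alpha)
  val <- log2(S) / (1 - alpha)
  ad_push(tp, matrix(val, 1L, 1L), function(g, genv) {
    dlam <- alpha * ifelse(lam > 1e-12, lam^(alpha - 1), 0) / (S * log(2) * (1 - alpha))
    GA <- eg$vectors %*% (dlam * t(eg$vectors))      # dH/dA, symmetric
    GK <- GA / s
    diag(GK) <- diag(GK) - sum(GA * K) / s^2
    B <- (GK + t(GK)) * K / sigma^2
    dQ <- (B - diag(rowSums(B))) %*% Q
    ad_acc(genv, q_mat, g[1L] * dQ)
  })
}
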
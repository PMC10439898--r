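# Reverse-mode automatic differentiation on a dynamic tape.
#
# Nodes are environments holding a value (`v`, an R array), an accumulated
# gradient (`grad`), the parent nodes and a backward closure mapping the
# node's gradient to a list of parent gradients. All network tensors use the
# layout c(H, W, T, C, N); token tensors use c(L, D, N). Gradients are only
# recorded while `ad_grad_enabled()` is TRUE, so evaluation passes build no
# graph.

.ad <- new.env(parent = emptyenv())
.ad$grad_enabled <- TRUE
.ad$id <- 0L

ad_grad_enabled <- function() .ad$grad_enabled

#' Evaluate an expression without recording gradients
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
ad_no_grad <- function(expr) {
  old <- .ad$grad_enabled
  .ad$grad_enabled <- FALSE
  on.exit(.ad$grad_enabled <- old)
  force(expr)
}

ad_node <- function(v, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$is_param <- FALSE
  if (.ad$grad_enabled) {
    e$parents <- parents
    e$backward <- backward
  } else {
    e$parents <- list()
    e$backward <- NULL
  }
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  class(e) <- "ad_node"
  e
}

#' Create a trainable parameter node
#' @param v initial value (array)
#' @return an `ad_node` flagged as a parameter
#' @keywords internal
ad_param <- function(v) {
  e <- ad_node(v)
  e$is_param <- TRUE
  e
}

ad_const <- function(v) ad_node(v)

as_ad <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

ad_value <- function(x) x$v

# Topological order by depth-first search over parents.
ad_topo <- function(root) {
  order <- vector("list", 256L)
  n <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      n <- n + 1L
      if (n > length(order)) order <- c(order, vector("list", length(order)))
      order[[n]] <- node
    }
  }
  order[seq_len(n)]
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients into every reachable node (parameters keep theirs
#' until [ad_zero_grad()] is called).
#' @param loss scalar `ad_node`
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(length(loss$v) == 1L)
  order <- ad_topo(loss)
  loss$grad <- array(1, dim = dim(loss$v) %||% 1L)
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    pg <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      g <- pg[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!node$is_param) node$grad <- NULL  # free intermediate gradients
  }
  invisible(loss)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a


# Fast column-wise ops on an (nrow x ncol) matrix: multiply / subtract a
# per-column vector without sweep()'s aperm overhead.
col_mul <- function(x, v) x * rep(v, each = nrow(x))
col_sub <- function(x, v) x - rep(v, each = nrow(x))

# ---- elementwise arithmetic ------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$v; bv <- b$v
  ad_node(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    if (length(av) == 1L) ga <- sum(ga)
    if (length(bv) == 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ad_scale <- function(a, s) {  # multiply by a plain numeric constant
  a <- as_ad(a)
  ad_node(a$v * s, list(a), function(g) list(g * s))
}

ad_sum <- function(a) {
  a <- as_ad(a)
  d <- dim(a$v) %||% length(a$v)
  ad_node(sum(a$v), list(a), function(g) list(array(as.numeric(g), dim = d)))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$v))

ad_log <- function(a, floor = 0) {
  a <- as_ad(a)
  av <- if (floor > 0) pmax(a$v, floor) else a$v
  live <- if (floor > 0) (a$v >= floor) else TRUE
  ad_node(log(av), list(a), function(g) list(g * live / av))
}

ad_pow2 <- function(a) {
  a <- as_ad(a)
  av <- a$v
  ad_node(av * av, list(a), function(g) list(2 * g * av))
}

ad_div_const <- function(a, k) ad_scale(a, 1 / k)

ad_add_const <- function(a, k) {
  a <- as_ad(a)
  ad_node(a$v + k, list(a), function(g) list(g))
}

ad_div <- function(a, b) {  # elementwise, same shape
  a <- as_ad(a); b <- as_ad(b)
  av <- a$v; bv <- b$v
  ad_node(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

# ---- activations -----------------------------------------------------------

ad_relu <- function(a) {
  a <- as_ad(a)
  out <- a$v
  neg <- which(out < 0)
  if (length(neg)) out[neg] <- 0
  ad_node(out, list(a), function(g) {
    if (length(neg)) g[neg] <- 0
    list(g)
  })
}

# Leaky rectifier with a per-call slope; the randomized variant draws the
# slope outside and passes it in, so backward sees the same slope.
ad_leaky <- function(a, slope) {
  a <- as_ad(a)
  out <- a$v
  neg <- which(out < 0)
  if (length(neg)) out[neg] <- out[neg] * slope
  ad_node(out, list(a), function(g) {
    if (length(neg)) g[neg] <- g[neg] * slope
    list(g)
  })
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  s <- 1 / (1 + exp(-a$v))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_gelu <- function(a) {
  a <- as_ad(a)
  av <- a$v
  ph <- stats::pnorm(av)
  ad_node(av * ph, list(a), function(g) list(g * (ph + av * stats::dnorm(av))))
}

# ---- convolution / pooling -------------------------------------------------

# Per-channel sum over (H, W, T, N) of a (H,W,T,C,N) tensor.
channel_sums <- function(g) {
  d <- dim(g)
  dim(g) <- c(prod(d[1:3]), d[4] * d[5])
  as.numeric(rowsum(colSums(g), rep(seq_len(d[4]), times = d[5])))
}

ad_conv3d <- function(x, w, b, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L)) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xd <- dim(x$v); kd <- dim(w$v)
  out <- conv3d_fwd_cpp(x$v, w$v, b$v, as.integer(stride), as.integer(pad))
  xv <- x$v
  ad_node(out, list(x, w, b), function(g) {
    dim(g) <- dim(out)
    list(conv3d_bw_input_cpp(g, w$v, as.integer(xd), as.integer(stride),
                             as.integer(pad)),
         conv3d_bw_filter_cpp(xv, g, as.integer(kd), as.integer(stride),
                              as.integer(pad)),
         channel_sums(g))
  })
}

# Transposed convolution: forward is the conv backward-input kernel.
# Filter layout c(kh, kw, kt, Cout, Cin): Cin here is the channel count of x.
ad_convt3d <- function(x, w, b, stride = c(2L, 2L, 1L), out_hw = NULL) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xd <- dim(x$v); kd <- dim(w$v)
  H <- xd[1] * stride[1]; W <- xd[2] * stride[2]; Tt <- xd[3] * stride[3]
  out <- conv3d_bw_input_cpp(x$v, w$v,
                             as.integer(c(H, W, Tt, kd[4], xd[5])),
                             as.integer(stride), c(0L, 0L, 0L))
  if (length(b$v)) {
    bb <- rep(rep(b$v, each = H * W * Tt), times = xd[5])
    out <- out + array(bb, dim = dim(out))
  }
  xv <- x$v
  ad_node(out, list(x, w, b), function(g) {
    dim(g) <- dim(out)
    list(conv3d_fwd_cpp(g, w$v, numeric(0), as.integer(stride), c(0L, 0L, 0L)),
         conv3d_bw_filter_cpp(g, xv, as.integer(kd), as.integer(stride),
                              c(0L, 0L, 0L)),
         if (length(b$v)) channel_sums(g) else numeric(0))
  })
}

ad_maxpool <- function(x, kernel = c(2L, 2L, 1L)) {
  x <- as_ad(x)
  res <- maxpool3d_fwd_cpp(x$v, as.integer(kernel))
  xd <- dim(x$v)
  ad_node(res$out, list(x), function(g) {
    list(maxpool3d_bw_cpp(as.numeric(g), res$argmax, as.integer(xd)))
  })
}

# ---- normalisation ---------------------------------------------------------

# Group normalisation over (H, W, T, channels-in-group) per sample.
ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$v)  # H W T C N
  C <- d[4]; N <- d[5]
  stopifnot(C %% groups == 0L)
  gs <- C %/% groups
  m <- prod(d[1:3]) * gs
  xm <- x$v
  dim(xm) <- c(m, length(xm) %/% m)      # columns: (group, sample)
  mu <- colMeans(xm)
  xc <- col_sub(xm, mu)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- col_mul(xc, inv)
  spat <- prod(d[1:3])
  xh_arr <- xh
  dim(xh_arr) <- c(spat, C * N)
  out <- col_mul(xh_arr, rep(gamma$v, times = N)) +
    rep(rep(beta$v, times = N), each = spat)
  dim(out) <- d
  dim(xh_arr) <- d
  ad_node(out, list(x, gamma, beta), function(g) {
    dim(g) <- d
    gg <- channel_sums(g * xh_arr)
    gb <- channel_sums(g)
    dim(g) <- c(prod(d[1:3]), C * N)
    gxh <- col_mul(g, rep(gamma$v, times = N))
    dim(gxh) <- c(m, length(gxh) %/% m)
    # standard normalisation backward per column
    gx <- col_mul(gxh, inv) - col_mul(xh, colMeans(gxh * xh) * inv) -
      rep(colMeans(gxh) * inv, each = m)
    dim(gx) <- d
    list(gx, gg, gb)
  })
}

# Batch normalisation per channel over (H, W, T, N). `state` is an
# environment carrying running_mean / running_var; training uses batch
# statistics and updates the running ones. Works on the (HWT, C*N) matrix
# view of the native layout (columns grouped per sample) to avoid
# transposes.
ad_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  momentum <- state$momentum %||% momentum  # refresh passes override this
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$v)
  C <- d[4]; N <- d[5]
  spat <- prod(d[1:3])
  m <- spat * N                                # elements per channel
  xm <- x$v; dim(xm) <- c(spat, C * N)
  cidx <- rep(seq_len(C), times = N)           # channel of each column
  if (training) {
    colm <- colMeans(xm)
    mu <- as.numeric(rowsum(colm, cidx)) / N
    xc <- col_sub(xm, mu[cidx])
    va <- as.numeric(rowsum(colMeans(xc * xc), cidx)) / N
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * m / max(m - 1, 1)
  } else {
    mu <- state$running_mean
    xc <- col_sub(xm, mu[cidx])
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xh <- col_mul(xc, inv[cidx])
  out <- col_mul(xh, gamma$v[cidx]) + rep(beta$v[cidx], each = spat)
  dim(out) <- d
  ad_node(out, list(x, gamma, beta), function(g) {
    dim(g) <- c(spat, C * N)
    gg <- as.numeric(rowsum(colSums(g * xh), cidx))
    gb <- as.numeric(rowsum(colSums(g), cidx))
    gxh <- col_mul(g, gamma$v[cidx])
    if (training) {
      mean_gxh <- as.numeric(rowsum(colMeans(gxh), cidx)) / N
      mean_gxh_xh <- as.numeric(rowsum(colMeans(gxh * xh), cidx)) / N
      gx <- col_mul(gxh, inv[cidx]) - col_mul(xh, (mean_gxh_xh * inv)[cidx]) -
        rep((mean_gxh * inv)[cidx], each = spat)
    } else {
      gx <- col_mul(gxh, inv[cidx])
    }
    dim(gx) <- d
    list(gx, gg, gb)
  })
}

# Layer normalisation of token tensors (L, D, N) over D.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$v)  # L D N
  xp <- aperm(x$v, c(2, 1, 3))            # D x L x N
  xm <- matrix(xp, nrow = d[2])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, inv, `*`)
  out <- aperm(array(xh * gamma$v + beta$v, dim = d[c(2, 1, 3)]), c(2, 1, 3))
  m <- d[2]
  ad_node(out, list(x, gamma, beta), function(g) {
    dim(g) <- d
    gp <- matrix(aperm(g, c(2, 1, 3)), nrow = m)
    gg <- rowSums(gp * xh)
    gb <- rowSums(gp)
    gxh <- gp * gamma$v
    t1 <- sweep(gxh, 2L, inv, `*`)
    t2 <- sweep(xh, 2L, colMeans(gxh * xh) * inv, `*`)
    t3 <- matrix(rep(colMeans(gxh) * inv, each = m), nrow = m)
    gx <- aperm(array(t1 - t2 - t3, dim = d[c(2, 1, 3)]), c(2, 1, 3))
    list(gx, gg, gb)
  })
}

# ---- shape ops -------------------------------------------------------------

ad_reshape <- function(x, dims) {
  x <- as_ad(x)
  d0 <- dim(x$v)
  v <- x$v
  dim(v) <- dims
  ad_node(v, list(x), function(g) { dim(g) <- d0; list(g) })
}

ad_concat_c <- function(a, b) {  # concatenate along the channel axis (dim 4)
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(all(da[c(1, 2, 3, 5)] == db[c(1, 2, 3, 5)]))
  Ca <- da[4]; Cb <- db[4]
  out <- array(0, dim = c(da[1:3], Ca + Cb, da[5]))
  out[, , , seq_len(Ca), ] <- a$v
  out[, , , Ca + seq_len(Cb), ] <- b$v
  ad_node(out, list(a, b), function(g) {
    dim(g) <- dim(out)
    list(g[, , , seq_len(Ca), , drop = FALSE],
         g[, , , Ca + seq_len(Cb), , drop = FALSE])
  })
}

ad_slice_t <- function(x, idx) {  # keep slices idx along T (dim 3)
  x <- as_ad(x)
  d <- dim(x$v)
  out <- x$v[, , idx, , , drop = FALSE]
  ad_node(out, list(x), function(g) {
    dim(g) <- dim(out)
    gx <- array(0, dim = d)
    gx[, , idx, , ] <- g
    list(gx)
  })
}

ad_sum_class <- function(x) {  # (H,W,T,K,N) -> per-class sums, length K
  x <- as_ad(x)
  d <- dim(x$v)
  out <- apply(x$v, 4L, sum)
  ad_node(out, list(x), function(g) {
    gk <- as.numeric(g)
    gx <- array(0, dim = d)
    for (k in seq_len(d[4])) gx[, , , k, ] <- gk[k]
    list(gx)
  })
}

ad_global_avgpool <- function(x) {  # (H,W,T,C,N) -> (C,N)
  x <- as_ad(x)
  d <- dim(x$v)
  spat <- prod(d[1:3])
  out <- matrix(colMeans(matrix(x$v, nrow = spat)), d[4], d[5])
  ad_node(out, list(x), function(g) {
    dim(g) <- c(d[4], d[5])
    gx <- array(rep(as.numeric(g) / spat, each = spat), dim = d)
    list(gx)
  })
}

ad_scale_channels <- function(x, s) {  # s: (C, N) gate, broadcast over HWT
  x <- as_ad(x); s <- as_ad(s)
  d <- dim(x$v)
  spat <- prod(d[1:3])
  sfull <- array(rep(as.numeric(s$v), each = spat), dim = d)
  xv <- x$v
  ad_node(xv * sfull, list(x, s), function(g) {
    dim(g) <- d
    gs <- matrix(colSums(matrix(g * xv, nrow = spat)), d[4], d[5])
    list(g * sfull, gs)
  })
}

# Dense layer on feature matrices (Din, N): out = W x + b, W (Dout, Din).
ad_dense <- function(x, w, b) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xv <- x$v; wv <- w$v
  out <- wv %*% xv + b$v
  ad_node(out, list(x, w, b), function(g) {
    dim(g) <- dim(out)
    list(crossprod(wv, g), tcrossprod(g, xv), rowSums(g))
  })
}

# Token-wise dense layer on (L, Din, N): applied per sample.
ad_dense_tokens <- function(x, w, b) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  d <- dim(x$v)  # L Din N
  dout <- nrow(w$v)
  out <- array(0, dim = c(d[1], dout, d[3]))
  for (n in seq_len(d[3]))
    out[, , n] <- tcrossprod(x$v[, , n], w$v) +
      matrix(b$v, d[1], dout, byrow = TRUE)
  xv <- x$v; wv <- w$v
  ad_node(out, list(x, w, b), function(g) {
    dim(g) <- dim(out)
    gx <- array(0, dim = d)
    gw <- matrix(0, dout, d[2])
    gb <- numeric(dout)
    for (n in seq_len(d[3])) {
      gn <- g[, , n]
      gx[, , n] <- gn %*% wv
      gw <- gw + crossprod(gn, xv[, , n])
      gb <- gb + colSums(gn)
    }
    list(gx, gw, gb)
  })
}

ad_add_posemb <- function(x, pos) {  # pos (L, D) broadcast over samples
  x <- as_ad(x); pos <- as_ad(pos)
  d <- dim(x$v)
  out <- x$v + array(rep(as.numeric(pos$v), times = d[3]), dim = d)
  ad_node(out, list(x, pos), function(g) {
    dim(g) <- d
    list(g, apply(g, c(1, 2), sum))
  })
}

# Multi-head self-attention over tokens (L, D, N), fused forward/backward.
ad_mha <- function(x, wq, wk, wv, wo, bq, bk, bv, bo, heads) {
  x <- as_ad(x)
  wq <- as_ad(wq); wk <- as_ad(wk); wv <- as_ad(wv); wo <- as_ad(wo)
  bq <- as_ad(bq); bk <- as_ad(bk); bv <- as_ad(bv); bo <- as_ad(bo)
  d <- dim(x$v)
  L <- d[1]; D <- d[2]; N <- d[3]
  dh <- D %/% heads
  scl <- 1 / sqrt(dh)
  cache <- vector("list", N)
  out <- array(0, dim = d)
  for (n in seq_len(N)) {
    xn <- x$v[, , n]                                 # L x D
    Q <- tcrossprod(xn, wq$v) + matrix(bq$v, L, D, byrow = TRUE)
    K <- tcrossprod(xn, wk$v) + matrix(bk$v, L, D, byrow = TRUE)
    V <- tcrossprod(xn, wv$v) + matrix(bv$v, L, D, byrow = TRUE)
    O <- matrix(0, L, D)
    A <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[, cols], K[, cols]) * scl    # L x L
      S <- sweep(S, 1L, apply(S, 1L, max))
      E <- exp(S)
      Ah <- E / rowSums(E)
      A[[h]] <- Ah
      O[, cols] <- Ah %*% V[, cols]
    }
    out[, , n] <- tcrossprod(O, wo$v) + matrix(bo$v, L, D, byrow = TRUE)
    cache[[n]] <- list(Q = Q, K = K, V = V, O = O, A = A, xn = xn)
  }
  ad_node(out, list(x, wq, wk, wv, wo, bq, bk, bv, bo), function(g) {
    dim(g) <- d
    gx <- array(0, dim = d)
    gwq <- gwk <- gwv <- gwo <- matrix(0, D, D)
    gbq <- gbk <- gbv <- gbo <- numeric(D)
    for (n in seq_len(N)) {
      cc <- cache[[n]]
      gn <- g[, , n]
      gO <- gn %*% wo$v
      gwo <- gwo + crossprod(gn, cc$O)
      gbo <- gbo + colSums(gn)
      gQ <- matrix(0, L, D); gK <- matrix(0, L, D); gV <- matrix(0, L, D)
      for (h in seq_len(heads)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        Ah <- cc$A[[h]]
        gOh <- gO[, cols]
        gV[, cols] <- crossprod(Ah, gOh)
        gA <- tcrossprod(gOh, cc$V[, cols])
        gS <- Ah * (gA - rowSums(gA * Ah))
        gQ[, cols] <- gS %*% cc$K[, cols] * scl
        gK[, cols] <- crossprod(gS, cc$Q[, cols]) * scl
      }
      gx[, , n] <- gQ %*% wq$v + gK %*% wk$v + gV %*% wv$v
      gwq <- gwq + crossprod(gQ, cc$xn)
      gwk <- gwk + crossprod(gK, cc$xn)
      gwv <- gwv + crossprod(gV, cc$xn)
      gbq <- gbq + colSums(gQ); gbk <- gbk + colSums(gK)
      gbv <- gbv + colSums(gV)
    }
    list(gx, gwq, gwk, gwv, gwo, gbq, gbk, gbv, gbo)
  })
}

# Softmax over the channel axis (dim 4) of (H,W,T,C,N), computed by
# K-slice reduction (K is small: the class count).
ad_softmax_c <- function(x) {
  x <- as_ad(x)
  d <- dim(x$v)
  K <- d[4]
  mx <- x$v[, , , 1L, , drop = FALSE]
  for (k in seq_len(K)[-1L]) mx <- pmax(mx, x$v[, , , k, , drop = FALSE])
  p <- x$v
  for (k in seq_len(K)) p[, , , k, ] <- exp(p[, , , k, ] - mx[, , , 1L, ])
  den <- p[, , , 1L, , drop = FALSE]
  for (k in seq_len(K)[-1L]) den <- den + p[, , , k, , drop = FALSE]
  for (k in seq_len(K)) p[, , , k, ] <- p[, , , k, ] / den[, , , 1L, ]
  ad_node(p, list(x), function(g) {
    dim(g) <- d
    s <- g[, , , 1L, , drop = FALSE] * p[, , , 1L, , drop = FALSE]
    for (k in seq_len(K)[-1L])
      s <- s + g[, , , k, , drop = FALSE] * p[, , , k, , drop = FALSE]
    gx <- g
    for (k in seq_len(K)) gx[, , , k, ] <- p[, , , k, ] * (g[, , , k, ] - s[, , , 1L, ])
    list(gx)
  })
}

# Softmax over rows of a (K, N) score matrix (phase head).
ad_softmax_rows <- function(x) {
  x <- as_ad(x)
  xm <- sweep(x$v, 2L, apply(x$v, 2L, max))
  e <- exp(xm)
  p <- sweep(e, 2L, colSums(e), `/`)
  ad_node(p, list(x), function(g) {
    dim(g) <- dim(p)
    list(p * sweep(g, 2L, colSums(g * p)))
  })
}

# Select one row of a (K, N) matrix as a length-N vector.
ad_row <- function(x, i) {
  x <- as_ad(x)
  d <- dim(x$v)
  ad_node(x$v[i, ], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[i, ] <- g
    list(gx)
  })
}
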
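# Forward and backward passes. Each *_fwd returns its output plus a cache
# holding every intermediate the corresponding *_bwd needs; gradients are
# accumulated into an environment keyed by parameter name so the train loop
# receives one flat named list matching model$params.

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

grad_acc <- function(G, name, part, value) {
  key <- paste0(name, ".", part)
  if (is.null(G[[key]])) G[[key]] <- value else G[[key]] <- G[[key]] + value
}

# channel-broadcast helpers for the single-channel attention map
bcast_mul <- function(x, a) {
  x * a[, , rep(1L, dim(x)[3]), , drop = FALSE]
}

sum_channels <- function(x) {
  d <- dim(x)
  s <- rowSums(aperm(x, c(1L, 2L, 4L, 3L)), dims = 3L)
  array(s, c(d[1], d[2], 1L, d[4]))
}

# ---- enhanced spatial attention ---------------------------------------------

# 1x1 squeeze -> stride-2 3x3 conv -> 7/3 max pooling -> 3x3 conv + ReLU ->
# bilinear upsample to the input size -> add a 1x1 skip of the squeezed
# input -> 1x1 to a single channel -> sigmoid -> elementwise gate.
esa_fwd <- function(P, pre, x, training) {
  nm <- function(s) paste0(pre, "esa.", s)
  c1 <- conv_fwd(x, P[[nm("c1")]]$w, P[[nm("c1")]]$b)
  v <- conv_fwd(c1, P[[nm("c2")]]$w, P[[nm("c2")]]$b, stride = 2L, pad = 1L)
  pl <- pool_fwd(v, kernel = 7L, stride = 3L, pad = 0L)
  g0 <- conv_fwd(pl$y, P[[nm("c3")]]$w, P[[nm("c3")]]$b)
  g <- relu_fwd(g0)
  up <- bilinear_fwd(g, dim(x)[1], dim(x)[2])
  cf <- conv_fwd(c1, P[[nm("cf")]]$w, P[[nm("cf")]]$b)
  h <- up$y + cf
  a0 <- conv_fwd(h, P[[nm("c4")]]$w, P[[nm("c4")]]$b)
  a <- sigmoid(a0)
  y <- bcast_mul(x, a)
  list(y = y, cache = list(x = x, c1 = c1, v = v, pl = pl, g0 = g0,
                           up = up, h = h, a = a))
}

esa_bwd <- function(P, pre, cache, gy, G) {
  nm <- function(s) paste0(pre, "esa.", s)
  a <- cache$a
  gx <- bcast_mul(gy, a)
  ga <- sum_channels(gy * cache$x)
  ga0 <- ga * a * (1 - a)
  cb <- conv_bwd(cache$h, P[[nm("c4")]]$w, ga0)
  grad_acc(G, nm("c4"), "w", cb$gw); grad_acc(G, nm("c4"), "b", cb$gb)
  gh <- cb$gx
  cbf <- conv_bwd(cache$c1, P[[nm("cf")]]$w, gh)
  grad_acc(G, nm("cf"), "w", cbf$gw); grad_acc(G, nm("cf"), "b", cbf$gb)
  gc1 <- cbf$gx
  gg <- bilinear_bwd(cache$up, gh)
  gg0 <- relu_bwd(cache$g0, gg)
  cb3 <- conv_bwd(cache$pl$y, P[[nm("c3")]]$w, gg0)
  grad_acc(G, nm("c3"), "w", cb3$gw); grad_acc(G, nm("c3"), "b", cb3$gb)
  dv <- dim(cache$v)
  gv <- pool_bwd(cache$pl$argmax, cb3$gx, dv[1], dv[2])
  cb2 <- conv_bwd(cache$c1, P[[nm("c2")]]$w, gv, stride = 2L, pad = 1L)
  grad_acc(G, nm("c2"), "w", cb2$gw); grad_acc(G, nm("c2"), "b", cb2$gb)
  gc1 <- gc1 + cb2$gx
  cb1 <- conv_bwd(cache$x, P[[nm("c1")]]$w, gc1)
  grad_acc(G, nm("c1"), "w", cb1$gw); grad_acc(G, nm("c1"), "b", cb1$gb)
  gx + cb1$gx
}

# ---- residual block ---------------------------------------------------------

block_fwd <- function(model, i, z, training, buffers) {
  P <- model$params
  cfg <- model$config
  nm <- function(s) paste0("b", i, ".", s)
  K <- list(z = z)
  L1 <- conv_fwd(z, P[[nm("c1")]]$w, P[[nm("c1")]]$b)
  K$L1 <- L1
  a2 <- conv_fwd(L1, P[[nm("c2")]]$w, P[[nm("c2")]]$b)
  K$a2 <- a2
  if (cfg$use_bn_branch) {
    bnp <- P[[nm("bn2")]]
    bnb <- buffers[[nm("bn2")]]
    bn2 <- bn_fwd(a2, bnp$gamma, bnp$beta, bnb$rmean, bnb$rvar, training)
    buffers[[nm("bn2")]] <- list(rmean = bn2$rmean, rvar = bn2$rvar)
    K$bn2 <- bn2
    r2 <- bn2$y
  } else r2 <- a2
  K$r2 <- r2
  L2 <- relu_fwd(r2)
  a3 <- conv_fwd(L1, P[[nm("c3")]]$w, P[[nm("c3")]]$b)
  K$a3 <- a3
  L3 <- relu_fwd(a3)
  cc1 <- concat_c(L2, L3)
  K$cc1 <- cc1
  L4 <- conv_fwd(cc1, P[[nm("c4")]]$w, P[[nm("c4")]]$b)
  K$L4 <- L4
  a5 <- conv_fwd(L4, P[[nm("c5")]]$w, P[[nm("c5")]]$b)
  K$a5 <- a5
  if (cfg$use_bn_branch) {
    bnp <- P[[nm("bn5")]]
    bnb <- buffers[[nm("bn5")]]
    bn5 <- bn_fwd(a5, bnp$gamma, bnp$beta, bnb$rmean, bnb$rvar, training)
    buffers[[nm("bn5")]] <- list(rmean = bn5$rmean, rvar = bn5$rvar)
    K$bn5 <- bn5
    r5 <- bn5$y
  } else r5 <- a5
  K$r5 <- r5
  L5 <- relu_fwd(r5)
  a6 <- conv_fwd(L4, P[[nm("c6")]]$w, P[[nm("c6")]]$b)
  K$a6 <- a6
  L6 <- relu_fwd(a6)
  cc2 <- concat_c(L6, L5)
  pk <- cfg$pool_kernel
  mp <- pool_fwd(cc2, kernel = pk, stride = 1L, pad = (pk - 1L) %/% 2L)
  K$cc2_dim <- dim(cc2)
  K$mp <- mp
  L8 <- conv_fwd(mp$y, P[[nm("c8")]]$w, P[[nm("c8")]]$b)
  K$L8 <- L8
  esa <- esa_fwd(P, paste0("b", i, "."), L8, training)
  K$esa <- esa$cache
  list(y = z + esa$y, cache = K, buffers = buffers)
}

block_bwd <- function(model, i, K, gy, G) {
  P <- model$params
  cfg <- model$config
  nm <- function(s) paste0("b", i, ".", s)
  C <- cfg$feature_width
  gL8 <- esa_bwd(P, paste0("b", i, "."), K$esa, gy, G)
  cb8 <- conv_bwd(K$mp$y, P[[nm("c8")]]$w, gL8)
  grad_acc(G, nm("c8"), "w", cb8$gw); grad_acc(G, nm("c8"), "b", cb8$gb)
  gcc2 <- pool_bwd(K$mp$argmax, cb8$gx, K$cc2_dim[1], K$cc2_dim[2])
  gL6 <- gcc2[, , seq_len(C), , drop = FALSE]
  gL5 <- gcc2[, , C + seq_len(C), , drop = FALSE]
  ga6 <- relu_bwd(K$a6, gL6)
  cb6 <- conv_bwd(K$L4, P[[nm("c6")]]$w, ga6)
  grad_acc(G, nm("c6"), "w", cb6$gw); grad_acc(G, nm("c6"), "b", cb6$gb)
  gr5 <- relu_bwd(K$r5, gL5)
  if (cfg$use_bn_branch) {
    bb <- bn_bwd(K$bn5, P[[nm("bn5")]]$gamma, gr5)
    grad_acc(G, nm("bn5"), "gamma", bb$ggamma)
    grad_acc(G, nm("bn5"), "beta", bb$gbeta)
    ga5 <- bb$gx
  } else ga5 <- gr5
  cb5 <- conv_bwd(K$L4, P[[nm("c5")]]$w, ga5)
  grad_acc(G, nm("c5"), "w", cb5$gw); grad_acc(G, nm("c5"), "b", cb5$gb)
  gL4 <- cb6$gx + cb5$gx
  cb4 <- conv_bwd(K$cc1, P[[nm("c4")]]$w, gL4)
  grad_acc(G, nm("c4"), "w", cb4$gw); grad_acc(G, nm("c4"), "b", cb4$gb)
  gL2 <- cb4$gx[, , seq_len(C), , drop = FALSE]
  gL3 <- cb4$gx[, , C + seq_len(C), , drop = FALSE]
  ga3 <- relu_bwd(K$a3, gL3)
  cb3 <- conv_bwd(K$L1, P[[nm("c3")]]$w, ga3)
  grad_acc(G, nm("c3"), "w", cb3$gw); grad_acc(G, nm("c3"), "b", cb3$gb)
  gr2 <- relu_bwd(K$r2, gL2)
  if (cfg$use_bn_branch) {
    bb <- bn_bwd(K$bn2, P[[nm("bn2")]]$gamma, gr2)
    grad_acc(G, nm("bn2"), "gamma", bb$ggamma)
    grad_acc(G, nm("bn2"), "beta", bb$gbeta)
    ga2 <- bb$gx
  } else ga2 <- gr2
  cb2 <- conv_bwd(K$L1, P[[nm("c2")]]$w, ga2)
  grad_acc(G, nm("c2"), "w", cb2$gw); grad_acc(G, nm("c2"), "b", cb2$gb)
  gL1 <- cb3$gx + cb2$gx
  cb1 <- conv_bwd(K$z, P[[nm("c1")]]$w, gL1)
  grad_acc(G, nm("c1"), "w", cb1$gw); grad_acc(G, nm("c1"), "b", cb1$gb)
  gy + cb1$gx # residual skip
}

# ---- whole network ----------------------------------------------------------

model_fwd <- function(model, x, training = FALSE) {
  P <- model$params
  cfg <- model$config
  x <- as_map4(x)
  if (dim(x)[3] != cfg$in_channels)
    stop("input channel count does not match the model", call. = FALSE)
  buffers <- model$buffers
  K <- list(x = x)
  s <- conv_fwd(x, P$shallow$w, P$shallow$b)
  K$s <- s
  t <- s
  K$blocks <- vector("list", cfg$num_blocks)
  for (i in seq_len(cfg$num_blocks)) {
    bf <- block_fwd(model, i, t, training, buffers)
    buffers <- bf$buffers
    K$blocks[[i]] <- bf$cache
    t <- bf$y
  }
  K$t <- t
  u <- conv_fwd(t, P$post$w, P$post$b)
  f <- u + s
  K$f <- f
  u1 <- conv_fwd(f, P$head.u1$w, P$head.u1$b)
  K$u1 <- u1
  ps1 <- pixel_shuffle(u1, 2L)
  K$ps1 <- ps1
  if (cfg$scale == 4L) {
    u2 <- conv_fwd(ps1, P$head.u2$w, P$head.u2$b)
    K$u2 <- u2
    ps2 <- pixel_shuffle(u2, 2L)
    K$ps2 <- ps2
    y <- conv_fwd(ps2, P$head.out$w, P$head.out$b)
  } else {
    y <- conv_fwd(ps1, P$head.out$w, P$head.out$b)
  }
  list(y = y, cache = K, buffers = buffers)
}

model_bwd <- function(model, K, gy) {
  P <- model$params
  cfg <- model$config
  G <- new.env(parent = emptyenv())
  if (cfg$scale == 4L) {
    cbo <- conv_bwd(K$ps2, P$head.out$w, gy)
    grad_acc(G, "head.out", "w", cbo$gw); grad_acc(G, "head.out", "b", cbo$gb)
    gu2 <- pixel_unshuffle(cbo$gx, 2L)
    cb2 <- conv_bwd(K$ps1, P$head.u2$w, gu2)
    grad_acc(G, "head.u2", "w", cb2$gw); grad_acc(G, "head.u2", "b", cb2$gb)
    gps1 <- cb2$gx
  } else {
    cbo <- conv_bwd(K$ps1, P$head.out$w, gy)
    grad_acc(G, "head.out", "w", cbo$gw); grad_acc(G, "head.out", "b", cbo$gb)
    gps1 <- cbo$gx
  }
  gu1 <- pixel_unshuffle(gps1, 2L)
  cb1 <- conv_bwd(K$f, P$head.u1$w, gu1)
  grad_acc(G, "head.u1", "w", cb1$gw); grad_acc(G, "head.u1", "b", cb1$gb)
  gf <- cb1$gx
  cbp <- conv_bwd(K$t, P$post$w, gf)
  grad_acc(G, "post", "w", cbp$gw); grad_acc(G, "post", "b", cbp$gb)
  gt <- cbp$gx
  for (i in rev(seq_len(cfg$num_blocks)))
    gt <- block_bwd(model, i, K$blocks[[i]], gt, G)
  gs <- gt + gf # long skip joins the shallow features
  cbs <- conv_bwd(K$x, P$shallow$w, gs)
  grad_acc(G, "shallow", "w", cbs$gw); grad_acc(G, "shallow", "b", cbs$gb)
  # flatten env -> nested list matching model$params
  grads <- list()
  for (key in ls(G)) {
    parts <- strsplit(key, "\\.(?=[^.]+$)", perl = TRUE)[[1]]
    grads[[parts[1]]][[parts[2]]] <- G[[key]]
  }
  list(grads = grads, gx = cbs$gx)
}

#' Apply a super-resolution model to a low-resolution image
#'
#' @param object an `sr_model`.
#' @param lr low-resolution image: `H x W` matrix or `H x W x 1` array with
#'   intensities in `[0, 1]`.
#' @param ... unused.
#' @return upscaled `rH x rW` matrix.
#' @export
predict.sr_model <- function(object, lr, ...) {
  out <- model_fwd(object, lr, training = FALSE)$y
  matrix(out[, , 1L, 1L], dim(out)[1], dim(out)[2])
}
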
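# Minimal 2D conv-net engine with hand-written backpropagation.
# Tensors are numeric arrays [H, W, C, N]. Convolutions run via im2col
# gathers plus BLAS matrix products; gather indices are cached per shape.
# Networks are flat op lists executed by a tiny graph walker that supports
# long (Unet) skip concatenations and short residual additions.

.nnIdxCache <- new.env(parent = emptyenv())

.convIdx <- function(H, W, C, N, k, stride, pad) {
  key <- paste(H, W, C, N, k, stride, pad, sep = "_")
  hit <- .nnIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  outH <- (H + 2L * pad - k) %/% stride + 1L
  outW <- (W + 2L * pad - k) %/% stride + 1L
  if (outH < 1L || outW < 1L)
    stop("input ", H, "x", W, " smaller than the receptive field of a ",
         k, "x", k, " stride-", stride, " convolution")
  oi <- rep(seq_len(outH), times = outW)
  oj <- rep(seq_len(outW), each = outH)
  r0 <- (oi - 1L) * stride; c0 <- (oj - 1L) * stride
  idx0 <- matrix(0L, outH * outW, k * k)
  for (dj in seq_len(k)) for (di in seq_len(k))
    idx0[, di + (dj - 1L) * k] <- (r0 + di) + (c0 + dj - 1L) * Hp
  idxC <- matrix(0L, outH * outW, k * k * C)
  for (cc in seq_len(C))
    idxC[, (cc - 1L) * k * k + seq_len(k * k)] <- idx0 + (cc - 1L) * Hp * Wp
  planeSize <- Hp * Wp * C
  idxN <- do.call(rbind, lapply(seq_len(N), function(n) idxC + (n - 1L) * planeSize))
  out <- list(idxN = idxN, outH = outH, outW = outW, Hp = Hp, Wp = Wp)
  .nnIdxCache[[key]] <- out
  out
}

.convFwd <- function(x, W, b, stride, pad) {
  d <- dim(x); k <- dim(W)[1]; C <- d[3]; N <- d[4]
  ix <- .convIdx(d[1], d[2], C, N, k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(ix$Hp, ix$Wp, C, N))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  } else xp <- x
  Wmat <- matrix(W, k * k * C, dim(W)[4])
  y <- .cppConvFwd(as.numeric(xp), ix$idxN, Wmat, b)
  out <- aperm(array(y, c(ix$outH, ix$outW, N, dim(W)[4])), c(1L, 2L, 4L, 3L))
  list(y = out, cache = list(xp = xp, ix = ix, d = d, k = k, pad = pad))
}

.convBwd <- function(dy, cache, W) {
  d <- cache$d; ix <- cache$ix; k <- cache$k; pad <- cache$pad
  Cout <- dim(W)[4]
  dyMat <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = Cout)
  Wmat <- matrix(W, k * k * d[3], Cout)
  r <- .cppConvBwd(as.numeric(cache$xp), ix$idxN, Wmat, dyMat,
                   length(cache$xp))
  dxp <- array(r$dxp, dim(cache$xp))
  dx <- if (pad > 0L)
    dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
  list(dx = array(dx, d), dW = array(r$dW, dim(W)), db = as.numeric(r$db))
}

.inormFwd <- function(x, g, b, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  chIdx <- ((seq_len(C * N) - 1L) %% C) + 1L
  r <- .cppInormFwd(matrix(x, HW, C * N), g, b, chIdx, eps)
  list(y = array(r$y, d),
       cache = list(xhat = r$xhat, istd = r$istd, chIdx = chIdx, d = d))
}

.inormBwd <- function(dy, cache, g) {
  d <- cache$d; HW <- d[1] * d[2]
  r <- .cppInormBwd(matrix(dy, HW, d[3] * d[4]), cache$xhat, cache$istd, g,
                    cache$chIdx, length(g))
  list(dx = array(r$dx, d), dg = as.numeric(r$dg), db = as.numeric(r$db))
}

.up2Fwd <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
         drop = FALSE]
  list(y = array(y, c(2L * d[1], 2L * d[2], d[3], d[4])), cache = d)
}

.up2Bwd <- function(dy, d) {
  o1 <- seq(1L, 2L * d[1], by = 2L); o2 <- seq(1L, 2L * d[2], by = 2L)
  dx <- dy[o1, o2, , , drop = FALSE] + dy[o1 + 1L, o2, , , drop = FALSE] +
        dy[o1, o2 + 1L, , , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , , drop = FALSE]
  array(dx, d)
}

# ---------------------------------------------------------------------------
# op-list executor
# ---------------------------------------------------------------------------

.netForward <- function(x, ops, params, keepCache = TRUE) {
  taps <- list(); resStack <- list()
  caches <- if (keepCache) vector("list", length(ops)) else NULL
  cur <- x
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (op$kind == "conv") {
      r <- .convFwd(cur, params[[paste0(op$name, ".W")]],
                    params[[paste0(op$name, ".b")]], op$stride, op$pad)
      if (keepCache) caches[[i]] <- r$cache
      cur <- r$y
    } else if (op$kind == "inorm") {
      r <- .inormFwd(cur, params[[paste0(op$name, ".g")]],
                     params[[paste0(op$name, ".b")]])
      if (keepCache) caches[[i]] <- r$cache
      cur <- r$y
    } else if (op$kind == "relu") {
      if (keepCache) caches[[i]] <- cur > 0
      cur <- cur * (cur > 0)
    } else if (op$kind == "lrelu") {
      if (keepCache) caches[[i]] <- cur > 0
      cur <- cur * (cur > 0) + 0.2 * cur * (cur <= 0)
    } else if (op$kind == "tanh") {
      cur <- tanh(cur)
      if (keepCache) caches[[i]] <- cur
    } else if (op$kind == "up2") {
      r <- .up2Fwd(cur)
      if (keepCache) caches[[i]] <- r$cache
      cur <- r$y
    } else if (op$kind == "tap") {
      taps[[op$name]] <- cur
    } else if (op$kind == "concat") {
      tp <- taps[[op$name]]
      d <- dim(cur)
      if (keepCache) caches[[i]] <- c(d[3], dim(tp)[3])
      out <- array(0, c(d[1], d[2], d[3] + dim(tp)[3], d[4]))
      out[, , seq_len(d[3]), ] <- cur
      out[, , d[3] + seq_len(dim(tp)[3]), ] <- tp
      cur <- out
    } else if (op$kind == "rsave") {
      resStack[[length(resStack) + 1L]] <- cur
    } else if (op$kind == "radd") {
      cur <- cur + resStack[[length(resStack)]]
      resStack[[length(resStack)]] <- NULL
    } else stop("unknown op kind: ", op$kind)
  }
  list(y = cur, caches = caches)
}

.netBackward <- function(dy, ops, caches, params) {
  grads <- list(); tapGrads <- list(); resGradStack <- list()
  dcur <- dy
  for (i in rev(seq_along(ops))) {
    op <- ops[[i]]
    if (op$kind == "conv") {
      W <- params[[paste0(op$name, ".W")]]
      r <- .convBwd(dcur, caches[[i]], W)
      grads[[paste0(op$name, ".W")]] <- r$dW
      grads[[paste0(op$name, ".b")]] <- r$db
      dcur <- r$dx
    } else if (op$kind == "inorm") {
      r <- .inormBwd(dcur, caches[[i]], params[[paste0(op$name, ".g")]])
      grads[[paste0(op$name, ".g")]] <- r$dg
      grads[[paste0(op$name, ".b")]] <- r$db
      dcur <- r$dx
    } else if (op$kind == "relu") {
      dcur <- dcur * caches[[i]]
    } else if (op$kind == "lrelu") {
      dcur <- dcur * (caches[[i]] + 0.2 * !caches[[i]])
    } else if (op$kind == "tanh") {
      dcur <- dcur * (1 - caches[[i]]^2)
    } else if (op$kind == "up2") {
      dcur <- .up2Bwd(dcur, caches[[i]])
    } else if (op$kind == "tap") {
      tg <- tapGrads[[op$name]]
      if (!is.null(tg)) dcur <- dcur + tg
    } else if (op$kind == "concat") {
      split <- caches[[i]]
      main <- dcur[, , seq_len(split[1]), , drop = FALSE]
      skip <- dcur[, , split[1] + seq_len(split[2]), , drop = FALSE]
      prev <- tapGrads[[op$name]]
      tapGrads[[op$name]] <- if (is.null(prev)) skip else prev + skip
      dcur <- main
    } else if (op$kind == "rsave") {
      n <- length(resGradStack)
      dcur <- dcur + resGradStack[[n]]
      resGradStack[[n]] <- NULL
    } else if (op$kind == "radd") {
      resGradStack[[length(resGradStack) + 1L]] <- dcur
    }
  }
  list(dx = dcur, grads = grads)
}

# ---------------------------------------------------------------------------
# parameter helpers and Adam
# ---------------------------------------------------------------------------

.opsParams <- function(ops, inCh) {
  # instantiate parameters for an op list; RNG state is the caller's
  params <- list()
  for (op in ops) {
    if (op$kind == "conv") {
      params[[paste0(op$name, ".W")]] <-
        array(stats::rnorm(op$k^2 * op$cin * op$cout, 0, 0.02),
              c(op$k, op$k, op$cin, op$cout))
      params[[paste0(op$name, ".b")]] <- numeric(op$cout)
    } else if (op$kind == "inorm") {
      params[[paste0(op$name, ".g")]] <- rep(1, op$ch)
      params[[paste0(op$name, ".b")]] <- numeric(op$ch)
    }
  }
  params
}

.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t; b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

.paramCount <- function(params) sum(vapply(params, length, 0L))
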
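# Compact neural engine in base R matrix code. All forward/backward passes
# are hand-derived; parameters live in plain named lists of matrices and are
# updated with Adam. Everything is deterministic given the R RNG state.
#
# Layer conventions:
#   dense:      H = act(X %*% W + b), X is batch x in
#   embedding:  E[idx, ], gradients accumulated with rowsum()
#   conv1d:     input array (batch, L, C); kernel W is (k*C) x F with row
#               layout (tau - 1)*C + c; output (batch, L - k + 1, F)
#   pooling:    non-overlapping max over position pairs; an odd tail
#               position forms its own pool (output length ceiling(L / 2))

nn_dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

# Standard-normal embedding initialization (the usual embedding-table
# default); anything much smaller starves downstream layers of signal.
nn_emb_init <- function(n_rows, dim) {
  matrix(stats::rnorm(n_rows * dim), n_rows, dim)
}

nn_act <- function(x, kind) {
  y <- if (kind == "relu") pmax(x, 0) else x * ifelse(x > 0, 1, 0.01)
  dim(y) <- dim(x)
  y
}

nn_act_grad <- function(x, kind) {
  if (kind == "relu") (x > 0) * 1 else ifelse(x > 0, 1, 0.01)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean binary cross-entropy with clamped probabilities.
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Inverted dropout mask (already scaled); NULL when inactive.
drop_mask <- function(nr, nc, p, train) {
  if (!train || p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# Classic Adam with L2 weight decay folded into the gradient.
adam_step <- function(params, grads, state, t, lr, wd,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    g <- grads[[nm]] + wd * params[[nm]]
    st <- state[[nm]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g * g
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# --- conv / pooling for the HLA character CNN ------------------------------

conv1d_forward <- function(X, W, b) {
  d <- dim(X); u <- d[1]; L <- d[2]; C <- d[3]
  k <- nrow(W) / C
  L_out <- L - k + 1
  F_ <- ncol(W)
  out <- array(0, c(u, L_out, F_))
  Xt_list <- vector("list", L_out)
  for (t in seq_len(L_out)) {
    Xt <- matrix(0, u, k * C)
    for (tau in seq_len(k)) {
      Xt[, ((tau - 1) * C + 1):(tau * C)] <- matrix(X[, t + tau - 1, ], u, C)
    }
    Xt_list[[t]] <- Xt
    out[, t, ] <- Xt %*% W + matrix(b, u, F_, byrow = TRUE)
  }
  list(out = out, Xt = Xt_list, k = k, C = C, dimX = d)
}

conv1d_backward <- function(dout, cache, W) {
  d <- cache$dimX; u <- d[1]; C <- cache$C; k <- cache$k
  L_out <- dim(dout)[2]
  dW <- W * 0
  db <- rep(0, ncol(W))
  dX <- array(0, d)
  for (t in seq_len(L_out)) {
    dt <- matrix(dout[, t, ], u, ncol(W))
    dW <- dW + crossprod(cache$Xt[[t]], dt)
    db <- db + colSums(dt)
    dXt <- dt %*% t(W)
    for (tau in seq_len(k)) {
      dX[, t + tau - 1, ] <- dX[, t + tau - 1, ] +
        dXt[, ((tau - 1) * C + 1):(tau * C)]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

pool_pairs_forward <- function(X) {
  d <- dim(X); u <- d[1]; L <- d[2]; F_ <- d[3]
  Lp <- ceiling(L / 2)
  out <- array(0, c(u, Lp, F_))
  left <- array(TRUE, c(u, Lp, F_))
  for (p in seq_len(Lp)) {
    i1 <- 2 * p - 1; i2 <- 2 * p
    if (i2 > L) {
      out[, p, ] <- X[, i1, ]
    } else {
      a <- matrix(X[, i1, ], u, F_); b <- matrix(X[, i2, ], u, F_)
      take_left <- a >= b
      out[, p, ] <- ifelse(take_left, a, b)
      left[, p, ] <- take_left
    }
  }
  list(out = out, left = left, L = L)
}

pool_pairs_backward <- function(dout, cache) {
  d <- dim(dout); u <- d[1]; Lp <- d[2]; F_ <- d[3]
  dX <- array(0, c(u, cache$L, F_))
  for (p in seq_len(Lp)) {
    i1 <- 2 * p - 1; i2 <- 2 * p
    dp <- matrix(dout[, p, ], u, F_)
    if (i2 > cache$L) {
      dX[, i1, ] <- dp
    } else {
      tl <- matrix(cache$left[, p, ], u, F_)
      dX[, i1, ] <- dp * tl
      dX[, i2, ] <- dp * (1 - tl)
    }
  }
  dX
}

# --- HLA character CNN encoder ---------------------------------------------

# Map canonical allele strings to padded character-index rows.
hla_char_matrix <- function(alleles, vocab = NULL, max_len = NULL) {
  chars <- strsplit(alleles, "")
  if (is.null(vocab)) vocab <- c("<pad>", sort(unique(unlist(chars))))
  if (is.null(max_len)) max_len <- max(lengths(chars))
  out <- matrix(1L, length(alleles), max_len)  # 1 = <pad>
  for (i in seq_along(chars)) {
    idx <- match(chars[[i]], vocab)
    idx[is.na(idx)] <- 1L
    n <- min(length(idx), max_len)
    out[i, seq_len(n)] <- idx[seq_len(n)]
  }
  attr(out, "vocab") <- vocab
  out
}

hla_cnn_init <- function(n_chars, emb_dim, channels, fc_dim, out_dim, seq_len) {
  l1 <- seq_len - 3 + 1             # conv kernel 3
  p1 <- ceiling(l1 / 2)
  l2 <- p1 - 2 + 1                  # conv kernel 2
  p2 <- ceiling(l2 / 2)
  if (l1 < 1 || l2 < 1) tcrhla_abort("invalid_spec", "allele strings too short for the CNN")
  c1 <- nn_dense_init(3 * emb_dim, channels[1])
  c2 <- nn_dense_init(2 * channels[1], channels[2])
  f1 <- nn_dense_init(p2 * channels[2], fc_dim)
  f2 <- nn_dense_init(fc_dim, out_dim)
  list(params = list(hla_emb = nn_emb_init(n_chars, emb_dim),
                     hla_c1_W = c1$W, hla_c1_b = c1$b,
                     hla_c2_W = c2$W, hla_c2_b = c2$b,
                     hla_f1_W = f1$W, hla_f1_b = f1$b,
                     hla_f2_W = f2$W, hla_f2_b = f2$b),
       flat_dim = p2 * channels[2])
}

hla_cnn_forward <- function(params, char_idx, dropout, train) {
  u <- nrow(char_idx); L <- ncol(char_idx)
  emb <- params$hla_emb
  X <- array(emb[as.vector(char_idx), ], c(u, L, ncol(emb)))
  cv1 <- conv1d_forward(X, params$hla_c1_W, params$hla_c1_b)
  a1 <- nn_act(cv1$out, "relu")
  pl1 <- pool_pairs_forward(a1)
  cv2 <- conv1d_forward(pl1$out, params$hla_c2_W, params$hla_c2_b)
  a2 <- nn_act(cv2$out, "relu")
  pl2 <- pool_pairs_forward(a2)
  flat <- matrix(pl2$out, u)                       # u x (p2 * c2)
  h1 <- flat %*% params$hla_f1_W +
    matrix(params$hla_f1_b, u, length(params$hla_f1_b), byrow = TRUE)
  h1a <- nn_act(h1, "relu")
  mask <- drop_mask(nrow(h1a), ncol(h1a), dropout, train)
  h1d <- apply_mask(h1a, mask)
  out <- h1d %*% params$hla_f2_W +
    matrix(params$hla_f2_b, u, length(params$hla_f2_b), byrow = TRUE)
  list(out = out, cache = list(char_idx = char_idx, X = X, cv1 = cv1, a1 = a1,
                               pl1 = pl1, cv2 = cv2, a2 = a2, pl2 = pl2,
                               flat = flat, h1 = h1, h1d = h1d, mask = mask))
}

hla_cnn_backward <- function(dout, params, cache) {
  g <- list()
  g$hla_f2_W <- crossprod(cache$h1d, dout)
  g$hla_f2_b <- colSums(dout)
  dh1d <- dout %*% t(params$hla_f2_W)
  dh1a <- apply_mask(dh1d, cache$mask)
  dh1 <- dh1a * nn_act_grad(cache$h1, "relu")
  g$hla_f1_W <- crossprod(cache$flat, dh1)
  g$hla_f1_b <- colSums(dh1)
  dflat <- dh1 %*% t(params$hla_f1_W)
  dpl2 <- array(dflat, dim(cache$pl2$out))
  da2 <- pool_pairs_backward(dpl2, cache$pl2)
  dcv2 <- da2 * nn_act_grad(cache$cv2$out, "relu")
  bk2 <- conv1d_backward(dcv2, cache$cv2, params$hla_c2_W)
  g$hla_c2_W <- bk2$dW; g$hla_c2_b <- bk2$db
  da1 <- pool_pairs_backward(bk2$dX, cache$pl1)
  dcv1 <- da1 * nn_act_grad(cache$cv1$out, "relu")
  bk1 <- conv1d_backward(dcv1, cache$cv1, params$hla_c1_W)
  g$hla_c1_W <- bk1$dW; g$hla_c1_b <- bk1$db
  demb <- params$hla_emb * 0
  dX <- bk1$dX
  u <- dim(dX)[1]; L <- dim(dX)[2]
  flat_idx <- as.vector(cache$char_idx)
  dE <- matrix(dX, u * L, dim(dX)[3])
  agg <- rowsum(dE, group = flat_idx)
  demb[as.integer(rownames(agg)), ] <- agg
  g$hla_emb <- demb
  g
}
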
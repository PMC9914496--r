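# Sequence and categorical encoders. CDR3 amino-acid strings are one-hot
# encoded over 21 channels (20 residues + a stop symbol appended after the
# last residue, with zero padding beyond it), compressed by a dense
# autoencoder pretrained on sequences alone, and concatenated with learned
# V/J gene embeddings into the TCR encoding E_t. HLA alleles are encoded by
# a character-CNN over the canonical allele string into a 100-dim vector.

#' One-hot encode CDR3 amino-acid sequences
#'
#' Each position is a 21-channel one-hot vector (20 amino acids plus a stop
#' symbol). The stop symbol occupies the position immediately after the
#' last residue; all later positions are zero padding. Encodings are
#' returned flattened, position-major, so a sequence occupies
#' \code{max_len * 21} values.
#'
#' @param cdr3 character vector of amino-acid strings (may be empty
#'   strings).
#' @param max_len padded length; every sequence must satisfy
#'   \code{nchar + 1 <= max_len} (condition \code{"cdr3_too_long"}
#'   otherwise); non-amino-acid characters raise \code{"invalid_residue"}.
#' @return numeric matrix, one row per sequence, \code{max_len * 21}
#'   columns; the attribute \code{"max_len"} records the padding length.
#' @seealso \code{\link{cdr3_decode}}, the exact inverse on valid input.
#' @export
cdr3_onehot <- function(cdr3, max_len = 25) {
  n <- length(cdr3)
  if (any(nchar(cdr3) + 1 > max_len)) {
    tcrhla_abort("cdr3_too_long",
                 paste0("sequences longer than max_len - 1 = ", max_len - 1))
  }
  if (!all(is_aa_string(cdr3))) {
    tcrhla_abort("invalid_residue", "CDR3 contains non-amino-acid characters")
  }
  out <- matrix(0, n, max_len * 21)
  alphabet <- c(AMINO_ACIDS, STOP_SYMBOL)
  for (i in seq_len(n)) {
    chars <- strsplit(cdr3[i], "")[[1]]
    idx <- c(match(chars, alphabet), 21L)           # stop after last residue
    pos <- seq_along(idx)
    out[i, (pos - 1) * 21 + idx] <- 1
  }
  attr(out, "max_len") <- max_len
  out
}

#' Decode one-hot CDR3 encodings back to strings
#'
#' Takes the per-position argmax channel until the first stop symbol. On
#' the image of \code{\link{cdr3_onehot}} this is an exact inverse; applied
#' to reconstruction logits it yields the most likely sequence.
#'
#' @param mat matrix of flattened (position-major, 21-channel) encodings or
#'   reconstruction scores.
#' @param max_len padded length used at encoding time (defaults to the
#'   matrix attribute, else inferred from the column count).
#' @return character vector of decoded sequences.
#' @export
cdr3_decode <- function(mat, max_len = NULL) {
  max_len <- max_len %||% attr(mat, "max_len") %||% (ncol(mat) / 21)
  alphabet <- c(AMINO_ACIDS, STOP_SYMBOL)
  vapply(seq_len(nrow(mat)), function(i) {
    m <- matrix(mat[i, ], nrow = 21)               # channels x positions
    ch <- alphabet[apply(m, 2, which.max)]
    stop_at <- match(STOP_SYMBOL, ch, nomatch = max_len + 1)
    paste(ch[seq_len(stop_at - 1)], collapse = "")
  }, "")
}

#' Pretrain the CDR3 sequence autoencoder
#'
#' A dense autoencoder over flattened one-hot CDR3 encodings: encoder
#' \code{input -> hidden (ReLU) -> latent}, decoder mirrored, trained by
#' Adam on per-position softmax cross-entropy over the 21 channels
#' (padding positions are masked out of the loss). Training uses the
#' sequences alone; no allele or label information is ever consumed.
#'
#' @param cdr3 character vector of training sequences.
#' @param max_len padded length; default covers the data
#'   (\code{max(nchar) + 1}), capped below by 12 so typical repertoires fit.
#' @param latent latent embedding dimension (default 30).
#' @param hidden hidden layer width (default 100).
#' @param epochs training epochs (default 300).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed; training is reproducible given it.
#' @return object of class \code{cdr3_ae}: weights, \code{max_len},
#'   \code{latent} and per-epoch \code{history} of training loss.
#' @export
cdr3_autoencoder <- function(cdr3, max_len = NULL, latent = 30, hidden = 100,
                             epochs = 300, batch_size = 256,
                             learning_rate = 1e-3, seed = 1L) {
  if (length(cdr3) == 0) tcrhla_abort("empty_training", "no sequences to train on")
  max_len <- max_len %||% max(max(nchar(cdr3)) + 1, 12)
  X <- cdr3_onehot(cdr3, max_len)
  D <- ncol(X)
  set.seed(as.integer(seed))
  e1 <- nn_dense_init(D, hidden); e2 <- nn_dense_init(hidden, latent)
  d1 <- nn_dense_init(latent, hidden); d2 <- nn_dense_init(hidden, D)
  params <- list(enc_W1 = e1$W, enc_b1 = e1$b, enc_W2 = e2$W, enc_b2 = e2$b,
                 dec_W1 = d1$W, dec_b1 = d1$b, dec_W2 = d2$W, dec_b2 = d2$b)
  state <- adam_init(params)
  n <- nrow(X)
  # position mask: 1 where the target block holds a real residue/stop
  occupied <- t(vapply(seq_len(n), function(i) {
    rep(colSums(matrix(X[i, ], nrow = 21)) > 0, each = 21)
  }, numeric(D)))
  history <- numeric(epochs)
  t_step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batches <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- X[idx, , drop = FALSE]
      mb <- occupied[idx, , drop = FALSE]
      fwd <- ae_forward(params, xb)
      sm <- ae_softmax(fwd$logits)
      tok <- sum(mb) / 21
      loss <- -sum(mb * xb * log(pmax(sm, 1e-12))) / tok
      dlogits <- (sm - xb) * mb / tok
      g <- ae_backward(params, fwd, xb, dlogits)
      t_step <- t_step + 1
      upd <- adam_step(params, g, state, t_step, learning_rate, wd = 0)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss; n_batches <- n_batches + 1
    }
    history[ep] <- ep_loss / n_batches
  }
  structure(list(params = params, max_len = max_len, latent = latent,
                 hidden = hidden, history = history),
            class = "cdr3_ae")
}

# Encoder half only: one-hot -> latent embedding.
enc_forward <- function(params, X) {
  H1 <- nn_act(sweep_add(X %*% params$enc_W1, params$enc_b1), "relu")
  sweep_add(H1 %*% params$enc_W2, params$enc_b2)
}

ae_forward <- function(params, X) {
  H1 <- nn_act(sweep_add(X %*% params$enc_W1, params$enc_b1), "relu")
  Z <- sweep_add(H1 %*% params$enc_W2, params$enc_b2)
  H2 <- nn_act(sweep_add(Z %*% params$dec_W1, params$dec_b1), "relu")
  logits <- sweep_add(H2 %*% params$dec_W2, params$dec_b2)
  list(H1 = H1, Z = Z, H2 = H2, logits = logits)
}

# Position-wise softmax over the 21 channels of flattened encodings.
# Works on the 21 x (positions * batch) layout to stay fully vectorized.
ae_softmax <- function(logits) {
  n <- nrow(logits)
  m <- matrix(t(logits), nrow = 21)
  mx <- m[1, ]
  for (r in 2:21) mx <- pmax(mx, m[r, ])
  e <- exp(m - rep(mx, each = 21))
  e <- e / rep(colSums(e), each = 21)
  t(matrix(e, ncol = n))
}

ae_backward <- function(params, fwd, X, dlogits) {
  g <- list()
  g$dec_W2 <- crossprod(fwd$H2, dlogits); g$dec_b2 <- colSums(dlogits)
  dH2 <- dlogits %*% t(params$dec_W2) * nn_act_grad(fwd$H2, "relu")
  g$dec_W1 <- crossprod(fwd$Z, dH2); g$dec_b1 <- colSums(dH2)
  dZ <- dH2 %*% t(params$dec_W1)
  g$enc_W2 <- crossprod(fwd$H1, dZ); g$enc_b2 <- colSums(dZ)
  dH1 <- dZ %*% t(params$enc_W2) * nn_act_grad(fwd$H1, "relu")
  g$enc_W1 <- crossprod(X, dH1); g$enc_b1 <- colSums(dH1)
  g
}

sweep_add <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

#' Encode or reconstruct CDR3 sequences with a trained autoencoder
#'
#' @param object a \code{\link{cdr3_autoencoder}} fit.
#' @param newdata character vector of sequences.
#' @param type \code{"latent"} (default) for the embedding matrix,
#'   \code{"reconstruction"} for decoder scores, \code{"decode"} for the
#'   argmax round-trip strings.
#' @param ... unused.
#' @return matrix (latent/reconstruction) or character vector (decode).
#' @export
predict.cdr3_ae <- function(object, newdata,
                            type = c("latent", "reconstruction", "decode"),
                            ...) {
  type <- match.arg(type)
  X <- cdr3_onehot(newdata, object$max_len)
  fwd <- ae_forward(object$params, X)
  switch(type,
         latent = fwd$Z,
         reconstruction = structure(fwd$logits, max_len = object$max_len),
         decode = cdr3_decode(structure(fwd$logits, max_len = object$max_len)))
}

#' @export
print.cdr3_ae <- function(x, ...) {
  cat("CDR3 autoencoder: max_len", x$max_len, "latent", x$latent,
      sprintf("(final training loss %.4f after %d epochs)\n",
              utils::tail(x$history, 1), length(x$history)))
  invisible(x)
}

#' Per-position reconstruction accuracy of the autoencoder
#'
#' Fraction of occupied positions (residues and the stop symbol) whose
#' argmax reconstruction matches the input.
#'
#' @param object a \code{\link{cdr3_autoencoder}} fit.
#' @param cdr3 character vector of sequences.
#' @return accuracy in [0, 1].
#' @export
ae_reconstruction_accuracy <- function(object, cdr3) {
  X <- cdr3_onehot(cdr3, object$max_len)
  R <- predict(object, cdr3, type = "reconstruction")
  n_ok <- 0; n_tot <- 0
  for (i in seq_len(nrow(X))) {
    xm <- matrix(X[i, ], nrow = 21); rm <- matrix(R[i, ], nrow = 21)
    occ <- colSums(xm) > 0
    n_tot <- n_tot + sum(occ)
    n_ok <- n_ok + sum(apply(xm[, occ, drop = FALSE], 2, which.max) ==
                       apply(rm[, occ, drop = FALSE], 2, which.max))
  }
  n_ok / n_tot
}

#' TCR encodings E_t from a fitted model
#'
#' Concatenates the autoencoder CDR3 embedding with the learned V- and
#' J-gene embedding rows (and their alpha-chain analogues when the model
#' was configured with \code{use_alpha}). Unknown gene labels map to the
#' reserved unknown-token row; their count is attached as the
#' \code{"n_unknown_genes"} attribute.
#'
#' @param model a fitted \code{\link{binding_fit}} or
#'   \code{\link{cd4cd8_fit}} model.
#' @param tcrs canonical TCR data.frame (cdr3b, v_gene, j_gene, optionally
#'   cdr3a, v_gene_a, j_gene_a).
#' @return numeric matrix, one row per TCR.
#' @export
tcr_encoding <- function(model, tcrs) {
  enc <- encode_tcr_internal(model, tcrs)
  out <- enc$E
  attr(out, "n_unknown_genes") <- enc$n_unknown
  out
}

#' HLA encodings E_h from a fitted binding model
#'
#' Runs the character-CNN allele encoder: the canonical allele string is
#' character-embedded (14 dims per character), passed through two
#' convolution + max-pooling blocks and two dense layers, yielding a
#' 100-dimensional vector per allele.
#'
#' @param model a fitted \code{\link{binding_fit}} model.
#' @param alleles character vector of canonical allele strings.
#' @return numeric matrix, one row per allele, 100 columns.
#' @export
hla_encoding <- function(model, alleles) {
  chars <- hla_char_matrix(alleles, vocab = model$hla_char_vocab,
                           max_len = model$hla_char_len)
  hla_cnn_forward(model$params, chars, dropout = 0, train = FALSE)$out
}
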
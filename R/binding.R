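# The TCR-HLA binding predictor. The TCR encoding E_t (autoencoder CDR3
# embedding + V/J gene embeddings) is concatenated with the HLA encoding
# E_h (character-CNN over the allele string) into E_th, passed through one
# hidden layer of half the input dimension (Leaky ReLU, dropout) and a
# sigmoid output. Trained with Adam on binary cross-entropy against
# distribution-matched sampled negatives, with donor-aware splits and early
# stopping on internal-validation AUC.

#' Configuration for the binding predictor
#'
#' Defaults are the model's standard operating point: Adam with learning
#' rate 0.007 and weight decay 0.001, dropout 0.1 between layers, early
#' stopping patience of 20 epochs, Leaky ReLU activation, hidden width of
#' half the input encoding.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight decay folded into the Adam gradient.
#' @param dropout dropout rate between layers.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param negative_ratio sampled negatives per positive.
#' @param validation_fraction share of the training side carved out as the
#'   internal validation set driving early stopping.
#' @param test_fraction share held out as the test side (donor-aware when
#'   donors are known); 0 disables the internal test split.
#' @param activation \code{"leaky_relu"} or \code{"relu"}.
#' @param max_len CDR3 padding length for the autoencoder (NULL: from data).
#' @param ae_latent,ae_hidden,ae_epochs autoencoder latent width, hidden
#'   width and pretraining epochs (used when no pretrained autoencoder is
#'   supplied).
#' @param gene_emb_dim V/J gene embedding dimension.
#' @param hla_emb_dim character embedding dimension of the allele encoder.
#' @param hla_channels the two convolution channel counts.
#' @param hla_fc width of the first dense layer of the allele encoder.
#' @param hla_dim allele encoding dimension E_h.
#' @param freeze_cdr3_encoder keep the pretrained CDR3 encoder fixed during
#'   supervised training (faster; the CDR3 branch then contributes a fixed
#'   embedding).
#' @param use_alpha also encode alpha-chain fields (cdr3a, v_gene_a,
#'   j_gene_a) with their own embedding tables.
#' @param seed integer seed governing initialization, negative sampling,
#'   splits, batching and dropout.
#' @return list of class \code{binding_config}.
#' @export
binding_config <- function(learning_rate = 0.007, weight_decay = 0.001,
                           dropout = 0.1, patience = 20, batch_size = 512,
                           max_epochs = 200, negative_ratio = 1,
                           validation_fraction = 0.1, test_fraction = 0.2,
                           activation = "leaky_relu", max_len = NULL,
                           ae_latent = 30, ae_hidden = 100, ae_epochs = 300,
                           gene_emb_dim = 50, hla_emb_dim = 14,
                           hla_channels = c(16, 32), hla_fc = 64,
                           hla_dim = 100, freeze_cdr3_encoder = FALSE,
                           use_alpha = FALSE, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, patience >= 1,
            batch_size >= 1, max_epochs >= 1)
  structure(as.list(environment()), class = "binding_config")
}

#' Sample distribution-matched negative pairs
#'
#' Negatives are (TCR, HLA) combinations absent from the positive set,
#' constructed so the data features are distributed as in the positives:
#' the TCR multiset is reused as-is and alleles are drawn from the
#' positives' empirical HLA distribution, with rejection of combinations
#' that exist as positives (and redrawing until clean).
#'
#' @param positives canonical positive pair data.frame.
#' @param ratio negatives per positive (default 1).
#' @param seed integer seed.
#' @param max_tries rejection-resampling rounds before giving up with a
#'   condition of class \code{"negative_space_exhausted"}.
#' @return data.frame of negative pairs (label 0), TCR columns copied from
#'   the positives.
#' @export
sample_negatives <- function(positives, ratio = 1, seed = NULL,
                             max_tries = 1000) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_pos <- nrow(positives)
  n_neg <- round(ratio * n_pos)
  if (n_neg == 0) return(positives[integer(0), , drop = FALSE])
  hla_tab <- table(positives$hla)
  hla_lev <- names(hla_tab)
  hla_p <- as.numeric(hla_tab) / n_pos
  idx <- rep(seq_len(n_pos), floor(ratio))
  extra <- n_neg - length(idx)
  if (extra > 0) idx <- c(idx, sample.int(n_pos, extra, replace = TRUE))
  out <- positives[idx, , drop = FALSE]
  pos_keys <- unique(pair_key(positives))
  out$hla <- sample(hla_lev, n_neg, replace = TRUE, prob = hla_p)
  for (try in seq_len(max_tries)) {
    bad <- pair_key(out) %in% pos_keys
    if (!any(bad)) break
    if (try == max_tries) {
      tcrhla_abort("negative_space_exhausted",
                   "could not sample negatives disjoint from the positives")
    }
    out$hla[bad] <- sample(hla_lev, sum(bad), replace = TRUE, prob = hla_p)
  }
  out$label <- 0L
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# internal: encoding bookkeeping

gene_index <- function(genes, vocab) {
  i <- match(genes, vocab)
  i[is.na(i)] <- length(vocab)       # last row = <unk>
  i
}

# Assemble the tensors the trainer consumes. `pairs` must carry cdr3b,
# v_gene, j_gene (+ hla when use_hla, + alpha fields when use_alpha).
build_nn_data <- function(pairs, model, use_hla) {
  cdr3 <- as.character(pairs$cdr3b)
  too_long <- nchar(cdr3) + 1 > model$max_len
  if (any(too_long)) cdr3[too_long] <- substr(cdr3[too_long], 1, model$max_len - 1)
  u_cdr3 <- unique(cdr3)
  data <- list(
    onehot = cdr3_onehot(u_cdr3, model$max_len),
    tcr_row = match(cdr3, u_cdr3),
    v_idx = gene_index(pairs$v_gene, model$v_vocab),
    j_idx = gene_index(pairs$j_gene, model$j_vocab),
    n = nrow(pairs))
  if (model$config$use_alpha) {
    cdr3a <- as.character(pairs$cdr3a)
    tl <- nchar(cdr3a) + 1 > model$max_len
    cdr3a[tl] <- substr(cdr3a[tl], 1, model$max_len - 1)
    u_a <- unique(cdr3a)
    data$onehot_a <- cdr3_onehot(u_a, model$max_len)
    data$tcr_row_a <- match(cdr3a, u_a)
    data$va_idx <- gene_index(pairs$v_gene_a, model$va_vocab)
    data$ja_idx <- gene_index(pairs$j_gene_a, model$ja_vocab)
  }
  if (use_hla) {
    u_hla <- sort(unique(as.character(pairs$hla)))
    data$hla_levels <- u_hla
    data$hla_idx <- match(pairs$hla, u_hla)
    data$hla_chars <- hla_char_matrix(u_hla, vocab = model$hla_char_vocab,
                                      max_len = model$hla_char_len)
  }
  if (model$config$freeze_cdr3_encoder) {
    data$Ec <- enc_forward(model$params, data$onehot)
    if (model$config$use_alpha) {
      data$Ec_a <- enc_forward(model$params, data$onehot_a)
    }
  }
  data
}

# Forward pass for a batch of example indices. Returns probabilities plus
# the caches needed for the backward pass.
bnn_forward <- function(params, data, idx, cfg, blocks, train) {
  b <- length(idx)
  freeze <- cfg$freeze_cdr3_encoder
  if (freeze) {
    Ec <- data$Ec[data$tcr_row[idx], , drop = FALSE]
    Xb <- H1e <- NULL
  } else {
    Xb <- data$onehot[data$tcr_row[idx], , drop = FALSE]
    H1e <- nn_act(sweep_add(Xb %*% params$enc_W1, params$enc_b1), "relu")
    Ec <- sweep_add(H1e %*% params$enc_W2, params$enc_b2)
  }
  parts <- list(Ec)
  if (cfg$use_alpha) {
    if (freeze) {
      Eca <- data$Ec_a[data$tcr_row_a[idx], , drop = FALSE]
      Xa <- H1a <- NULL
    } else {
      Xa <- data$onehot_a[data$tcr_row_a[idx], , drop = FALSE]
      H1a <- nn_act(sweep_add(Xa %*% params$enc_W1, params$enc_b1), "relu")
      Eca <- sweep_add(H1a %*% params$enc_W2, params$enc_b2)
    }
    parts <- c(parts, list(Eca))
  } else {
    Xa <- H1a <- NULL
  }
  vi <- data$v_idx[idx]; ji <- data$j_idx[idx]
  parts <- c(parts, list(params$emb_v[vi, , drop = FALSE],
                         params$emb_j[ji, , drop = FALSE]))
  if (cfg$use_alpha) {
    vai <- data$va_idx[idx]; jai <- data$ja_idx[idx]
    parts <- c(parts, list(params$emb_va[vai, , drop = FALSE],
                           params$emb_ja[jai, , drop = FALSE]))
  } else {
    vai <- jai <- NULL
  }
  use_hla <- !is.null(data$hla_idx)
  if (use_hla) {
    hi <- data$hla_idx[idx]
    uh <- sort(unique(hi))
    fh <- hla_cnn_forward(params, data$hla_chars[uh, , drop = FALSE],
                          cfg$dropout, train)
    Eh <- fh$out[match(hi, uh), , drop = FALSE]
    parts <- c(parts, list(Eh))
  } else {
    hi <- uh <- fh <- NULL
  }
  Eth <- do.call(cbind, parts)
  Hpre <- sweep_add(Eth %*% params$W1, params$b1)
  H <- nn_act(Hpre, cfg$activation)
  mask <- drop_mask(nrow(H), ncol(H), cfg$dropout, train)
  Hd <- apply_mask(H, mask)
  logit <- as.vector(Hd %*% params$W2) + params$b2
  list(p = sigmoid(logit),
       cache = list(Xb = Xb, H1e = H1e, Xa = Xa, H1a = H1a, vi = vi, ji = ji,
                    vai = vai, jai = jai, hi = hi, uh = uh, fh = fh,
                    Eth = Eth, Hpre = Hpre, Hd = Hd, mask = mask))
}

bnn_backward <- function(params, data, idx, cfg, blocks, fwd, y) {
  cache <- fwd$cache
  b <- length(idx)
  g <- list()
  dlogit <- (fwd$p - y) / b
  g$W2 <- crossprod(cache$Hd, dlogit)
  g$b2 <- sum(dlogit)
  dHd <- matrix(dlogit, ncol = 1) %*% t(params$W2)
  dH <- apply_mask(dHd, cache$mask) * nn_act_grad(cache$Hpre, cfg$activation)
  g$W1 <- crossprod(cache$Eth, dH)
  g$b1 <- colSums(dH)
  dEth <- dH %*% t(params$W1)
  off <- 0
  take <- function(w) {
    cols <- (off + 1):(off + w)
    off <<- off + w
    dEth[, cols, drop = FALSE]
  }
  dEc <- take(blocks$latent)
  if (!cfg$freeze_cdr3_encoder) {
    g$enc_W2 <- crossprod(cache$H1e, dEc)
    g$enc_b2 <- colSums(dEc)
    dH1e <- dEc %*% t(params$enc_W2) * nn_act_grad(cache$H1e, "relu")
    g$enc_W1 <- crossprod(cache$Xb, dH1e)
    g$enc_b1 <- colSums(dH1e)
  }
  if (cfg$use_alpha) {
    dEca <- take(blocks$latent)
    if (!cfg$freeze_cdr3_encoder) {
      g$enc_W2 <- g$enc_W2 + crossprod(cache$H1a, dEca)
      g$enc_b2 <- g$enc_b2 + colSums(dEca)
      dH1a <- dEca %*% t(params$enc_W2) * nn_act_grad(cache$H1a, "relu")
      g$enc_W1 <- g$enc_W1 + crossprod(cache$Xa, dH1a)
      g$enc_b1 <- g$enc_b1 + colSums(dH1a)
    }
  }
  emb_grad <- function(d, rows, template) {
    out <- template * 0
    agg <- rowsum(d, group = rows)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  g$emb_v <- emb_grad(take(blocks$gene), cache$vi, params$emb_v)
  g$emb_j <- emb_grad(take(blocks$gene), cache$ji, params$emb_j)
  if (cfg$use_alpha) {
    g$emb_va <- emb_grad(take(blocks$gene), cache$vai, params$emb_va)
    g$emb_ja <- emb_grad(take(blocks$gene), cache$jai, params$emb_ja)
  }
  if (!is.null(cache$hi)) {
    dEh <- take(blocks$hla)
    dEh_u <- rowsum(dEh, group = cache$hi)       # rows follow sort(unique(hi))
    g <- c(g, hla_cnn_backward(dEh_u, params, cache$fh$cache))
  }
  g
}

predict_prob <- function(params, data, idx, cfg, blocks) {
  out <- numeric(length(idx))
  for (start in seq(1, length(idx), by = 4096)) {
    sl <- start:min(start + 4095, length(idx))
    out[sl] <- bnn_forward(params, data, idx[sl], cfg, blocks, train = FALSE)$p
  }
  out
}

# Core minibatch trainer with early stopping on validation AUC.
fit_binary_nn <- function(params, data, y, split, cfg, blocks) {
  state <- adam_init(params)
  best <- list(auc = -Inf, epoch = 0, params = params)
  since_best <- 0
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auc = numeric())
  t_step <- 0
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- split$train[sample.int(length(split$train))]
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      fwd <- bnn_forward(params, data, idx, cfg, blocks, train = TRUE)
      ep_loss <- ep_loss + bce_loss(fwd$p, y[idx]); nb <- nb + 1
      g <- bnn_backward(params, data, idx, cfg, blocks, fwd, y[idx])
      t_step <- t_step + 1
      upd <- adam_step(params, g, state, t_step, cfg$learning_rate,
                       cfg$weight_decay)
      params <- upd$params; state <- upd$state
    }
    val_auc <- if (length(split$val)) {
      roc_auc(predict_prob(params, data, split$val, cfg, blocks), y[split$val])
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_auc = val_auc))
    if (!is.na(val_auc) && val_auc > best$auc) {
      best <- list(auc = val_auc, epoch = ep, params = params)
      since_best <- 0
    } else {
      since_best <- since_best + 1
      if (since_best >= cfg$patience) break
    }
  }
  if (is.finite(best$auc)) params <- best$params
  list(params = params, history = history,
       best_epoch = if (is.finite(best$auc)) best$epoch else nrow(history),
       best_val_auc = if (is.finite(best$auc)) best$auc else NA_real_)
}

# Donor-aware (or row-level) train/validation/test split over example rows.
make_split <- function(n, donor, val_fraction, test_fraction,
                       donor_aware = !is.null(donor)) {
  if (donor_aware) {
    donors <- unique(donor)
    if (length(donors) < 2 && (test_fraction > 0 || val_fraction > 0)) {
      tcrhla_abort("cannot_split",
                   "donor-aware split requires at least two donors")
    }
    donors <- donors[sample.int(length(donors))]
    n_test <- if (test_fraction > 0) max(1, round(test_fraction * length(donors))) else 0
    test_d <- donors[seq_len(n_test)]
    rest <- setdiff(donors, test_d)
    n_val <- if (val_fraction > 0) max(1, round(val_fraction * length(rest))) else 0
    val_d <- rest[seq_len(n_val)]
    train_d <- setdiff(rest, val_d)
    if (!length(train_d)) tcrhla_abort("cannot_split", "no donors left for training")
    list(train = which(donor %in% train_d), val = which(donor %in% val_d),
         test = which(donor %in% test_d),
         donors = list(train = train_d, val = val_d, test = test_d))
  } else {
    ord <- sample.int(n)
    n_test <- round(test_fraction * n)
    n_val <- round(val_fraction * (n - n_test))
    list(test = ord[seq_len(n_test)],
         val = ord[n_test + seq_len(n_val)],
         train = ord[(n_test + n_val + 1):n], donors = NULL)
  }
}

# ---------------------------------------------------------------------------

#' Fit the TCR-HLA binding predictor
#'
#' Trains the binary binding model on positive pairs plus (sampled or
#' supplied) negatives. The CDR3 autoencoder is pretrained on the training
#' sequences alone unless a fitted one is passed in. The data are split
#' into train / internal-validation / test sides; when a \code{donor}
#' column is present the split is donor-aware (no donor appears on two
#' sides). Training stops early when validation AUC has not improved for
#' \code{patience} epochs and the best-epoch weights are restored.
#'
#' @param pairs canonical pair data.frame (cdr3b, v_gene, j_gene, hla,
#'   label; optional donor and alpha-chain columns). Rows with label 0 are
#'   used as negatives; if none are present negatives are sampled at the
#'   configured ratio.
#' @param config a \code{\link{binding_config}}.
#' @param ae optional pretrained \code{\link{cdr3_autoencoder}}.
#' @param universe optional allele universe (default: alleles in
#'   \code{pairs}).
#' @param init optional fitted \code{tcrhla_model} whose weights warm-start
#'   training (vocabularies are inherited).
#' @return object of class \code{tcrhla_model}: weights, vocabularies,
#'   autoencoder, config, training \code{history}, \code{best_epoch},
#'   \code{split} (row indices and donors per side) and \code{test_auc}
#'   (NA when \code{test_fraction = 0}).
#' @export
binding_fit <- function(pairs, config = binding_config(), ae = NULL,
                        universe = NULL, init = NULL) {
  set.seed(config$seed)
  if (is.null(pairs$label)) pairs$label <- 1L
  positives <- pairs[pairs$label == 1, , drop = FALSE]
  negatives <- pairs[pairs$label == 0, , drop = FALSE]
  if (nrow(positives) == 0) tcrhla_abort("empty_training", "no positive pairs")
  if (nrow(negatives) == 0) {
    negatives <- sample_negatives(positives, ratio = config$negative_ratio)
  }
  all_pairs <- rbind(positives, negatives)
  rownames(all_pairs) <- NULL
  donor <- if ("donor" %in% names(all_pairs)) all_pairs$donor else NULL
  split <- make_split(nrow(all_pairs), donor, config$validation_fraction,
                      config$test_fraction)

  train_rows <- all_pairs[split$train, , drop = FALSE]
  if (is.null(ae) && is.null(init)) {
    seqs <- unique(as.character(train_rows$cdr3b))
    if (config$use_alpha) seqs <- unique(c(seqs, as.character(train_rows$cdr3a)))
    ae <- cdr3_autoencoder(seqs, max_len = config$max_len,
                           latent = config$ae_latent, hidden = config$ae_hidden,
                           epochs = config$ae_epochs, seed = config$seed)
    set.seed(config$seed + 1L)
  }

  if (!is.null(init)) {
    model <- init
    model$config <- config
    params <- init$params
  } else {
    model <- list(config = config, ae = ae, max_len = ae$max_len,
                  latent = ae$latent)
    model$v_vocab <- c(sort(unique(as.character(train_rows$v_gene))), "<unk>")
    model$j_vocab <- c(sort(unique(as.character(train_rows$j_gene))), "<unk>")
    if (config$use_alpha) {
      model$va_vocab <- c(sort(unique(as.character(train_rows$v_gene_a))), "<unk>")
      model$ja_vocab <- c(sort(unique(as.character(train_rows$j_gene_a))), "<unk>")
    }
    model$universe <- sort(unique(c(as.character(all_pairs$hla), universe)))
    chars <- hla_char_matrix(model$universe)
    model$hla_char_vocab <- attr(chars, "vocab")
    model$hla_char_len <- ncol(chars)

    blocks <- list(latent = ae$latent, gene = config$gene_emb_dim,
                   hla = config$hla_dim)
    din <- ae$latent * (1 + config$use_alpha) +
      config$gene_emb_dim * 2 * (1 + config$use_alpha) + config$hla_dim
    hidden <- ceiling(din / 2)
    params <- list(enc_W1 = ae$params$enc_W1, enc_b1 = ae$params$enc_b1,
                   enc_W2 = ae$params$enc_W2, enc_b2 = ae$params$enc_b2,
                   emb_v = nn_emb_init(length(model$v_vocab), config$gene_emb_dim),
                   emb_j = nn_emb_init(length(model$j_vocab), config$gene_emb_dim))
    if (config$use_alpha) {
      params$emb_va <- nn_emb_init(length(model$va_vocab), config$gene_emb_dim)
      params$emb_ja <- nn_emb_init(length(model$ja_vocab), config$gene_emb_dim)
    }
    cnn <- hla_cnn_init(length(model$hla_char_vocab), config$hla_emb_dim,
                        config$hla_channels, config$hla_fc, config$hla_dim,
                        model$hla_char_len)
    params <- c(params, cnn$params)
    mlp1 <- nn_dense_init(din, hidden); mlp2 <- nn_dense_init(hidden, 1)
    params$W1 <- mlp1$W; params$b1 <- mlp1$b
    params$W2 <- mlp2$W; params$b2 <- 0
    model$blocks <- blocks
    model$din <- din
  }
  model$params <- params

  data <- build_nn_data(all_pairs, model, use_hla = TRUE)
  y <- all_pairs$label
  fit <- fit_binary_nn(model$params, data, y, split, config, model$blocks)
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$best_val_auc <- fit$best_val_auc
  model$split <- split
  model$n_pairs <- nrow(all_pairs)
  model$test_auc <- if (length(split$test)) {
    roc_auc(predict_prob(model$params, data, split$test, config, model$blocks),
            y[split$test])
  } else NA_real_
  class(model) <- "tcrhla_model"
  model
}

#' Predict binding probabilities for TCR-HLA pairs
#'
#' Deterministic at inference (dropout disabled): identical input rows
#' receive identical scores.
#'
#' @param object a fitted \code{\link{binding_fit}} model.
#' @param newdata data.frame with cdr3b, v_gene, j_gene, hla (+ alpha
#'   columns when the model uses them). Unknown gene labels map to the
#'   unknown token; overlong CDR3s are truncated to the padding length.
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict.tcrhla_model <- function(object, newdata, ...) {
  data <- build_nn_data(newdata, object, use_hla = TRUE)
  predict_prob(object$params, data, seq_len(nrow(newdata)), object$config,
               object$blocks)
}

#' Score every allele of a universe for each TCR
#'
#' Computes the binding probability of each TCR against every allele. The
#' hidden layer is evaluated by combining a per-TCR and a per-allele
#' partial product, so the full n x |universe| grid costs one pass over
#' each factor.
#'
#' @param model a fitted \code{\link{binding_fit}} model.
#' @param tcrs canonical TCR data.frame.
#' @param universe character vector of alleles (default: the model's).
#' @return numeric matrix (TCRs x alleles, columns sorted
#'   lexicographically). For ranking, ties are conventionally broken
#'   towards the lexicographically first allele
#'   (\code{max.col(ties.method = "first")}).
#' @export
score_all_hla <- function(model, tcrs, universe = NULL) {
  universe <- sort(universe %||% model$universe)
  cfg <- model$config
  n <- nrow(tcrs)
  # per-TCR factor of the hidden pre-activation
  pairs_t <- tcrs
  pairs_t$hla <- universe[1]
  data <- build_nn_data(pairs_t, model, use_hla = FALSE)
  fwd_t <- tcr_forward_factors(model, data, seq_len(n))
  Et <- fwd_t$Et                                  # n x (din - hla_dim)
  W1 <- model$params$W1
  d_t <- ncol(Et)
  A <- Et %*% W1[seq_len(d_t), , drop = FALSE]    # n x hidden
  chars <- hla_char_matrix(universe, vocab = model$hla_char_vocab,
                           max_len = model$hla_char_len)
  Eh <- hla_cnn_forward(model$params, chars, 0, FALSE)$out
  B <- Eh %*% W1[(d_t + 1):nrow(W1), , drop = FALSE]  # U x hidden
  out <- matrix(0, n, length(universe), dimnames = list(NULL, universe))
  for (u in seq_along(universe)) {
    H <- nn_act(sweep_add(A, model$params$b1 + B[u, ]), cfg$activation)
    out[, u] <- sigmoid(as.vector(H %*% model$params$W2) + model$params$b2)
  }
  out
}

# TCR-side encoding concatenation (no HLA block).
tcr_forward_factors <- function(model, data, idx) {
  cfg <- model$config
  Ec <- if (!is.null(data$Ec)) data$Ec[data$tcr_row[idx], , drop = FALSE] else
    enc_forward(model$params, data$onehot[data$tcr_row[idx], , drop = FALSE])
  parts <- list(Ec)
  if (cfg$use_alpha) {
    Eca <- if (!is.null(data$Ec_a)) data$Ec_a[data$tcr_row_a[idx], , drop = FALSE] else
      enc_forward(model$params, data$onehot_a[data$tcr_row_a[idx], , drop = FALSE])
    parts <- c(parts, list(Eca))
  }
  parts <- c(parts, list(model$params$emb_v[data$v_idx[idx], , drop = FALSE],
                         model$params$emb_j[data$j_idx[idx], , drop = FALSE]))
  if (cfg$use_alpha) {
    parts <- c(parts, list(model$params$emb_va[data$va_idx[idx], , drop = FALSE],
                           model$params$emb_ja[data$ja_idx[idx], , drop = FALSE]))
  }
  list(Et = do.call(cbind, parts))
}

encode_tcr_internal <- function(model, tcrs) {
  pairs_t <- tcrs
  data <- build_nn_data(pairs_t, model, use_hla = FALSE)
  n_unknown <- sum(data$v_idx == length(model$v_vocab)) +
    sum(data$j_idx == length(model$j_vocab))
  list(E = tcr_forward_factors(model, data, seq_len(nrow(tcrs)))$Et,
       n_unknown = n_unknown)
}

#' Model-based scorer for the evaluation functions
#'
#' @param model a fitted \code{\link{binding_fit}} model (or two-stage
#'   fit).
#' @return function(tcrs, universe) returning the score matrix of
#'   \code{\link{score_all_hla}}.
#' @export
model_scorer <- function(model) {
  function(tcrs, universe) score_all_hla(model, tcrs, universe)
}

#' @export
print.tcrhla_model <- function(x, ...) {
  cat("TCR-HLA binding model\n")
  cat("  pairs:", x$n_pairs, " alleles:", length(x$universe),
      " V genes:", length(x$v_vocab) - 1, "\n")
  cat("  input dim:", x$din, " hidden:", ncol(x$params$W1), "\n")
  cat(sprintf("  best epoch %d (validation AUC %.3f)", x$best_epoch,
              x$best_val_auc))
  if (!is.na(x$test_auc)) cat(sprintf(", test AUC %.3f", x$test_auc))
  cat("\n")
  invisible(x)
}

#' @export
summary.tcrhla_model <- function(object, ...) {
  print(object)
  cat("  training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Plot the training history of a fitted model
#'
#' @param x a fitted \code{tcrhla_model} or \code{cd4cd8_model}.
#' @param ... passed to \code{plot}.
#' @export
plot.tcrhla_model <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_auc, type = "b", xlab = "epoch",
                 ylab = "validation AUC", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
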
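# CD4/CD8 compartment classifier. Class I binding prediction only applies
# to CD8 T cells, so unsorted bulk repertoires are first scored by this
# binary classifier (1 = CD8, 0 = CD4) and filtered to the most confident
# CD8 calls. The TCR encoding E_t is the same as in the binding model; the
# head is one hidden linear layer of half the input dimension with ReLU,
# then a sigmoid output.

#' Configuration for the CD4/CD8 classifier
#'
#' Same knobs as \code{\link{binding_config}} with the classifier's
#' standard operating point: Adam with learning rate 0.0005 and weight
#' decay 0.0005, ReLU activation, dropout 0.1.
#'
#' @inheritParams binding_config
#' @return list of class \code{binding_config}.
#' @export
cd4cd8_config <- function(learning_rate = 0.0005, weight_decay = 0.0005,
                          dropout = 0.1, patience = 20, batch_size = 512,
                          max_epochs = 200, validation_fraction = 0.1,
                          test_fraction = 0.2, activation = "relu",
                          max_len = NULL, ae_latent = 30, ae_hidden = 100,
                          ae_epochs = 300, gene_emb_dim = 50,
                          freeze_cdr3_encoder = FALSE, use_alpha = FALSE,
                          seed = 1L) {
  cfg <- binding_config(learning_rate = learning_rate,
                        weight_decay = weight_decay, dropout = dropout,
                        patience = patience, batch_size = batch_size,
                        max_epochs = max_epochs,
                        validation_fraction = validation_fraction,
                        test_fraction = test_fraction, activation = activation,
                        max_len = max_len, ae_latent = ae_latent,
                        ae_hidden = ae_hidden, ae_epochs = ae_epochs,
                        gene_emb_dim = gene_emb_dim,
                        freeze_cdr3_encoder = freeze_cdr3_encoder,
                        use_alpha = use_alpha, seed = seed)
  cfg
}

#' Fit the CD4/CD8 compartment classifier
#'
#' Trains on compartment-labelled TCRs (target 1 for CD8, 0 for CD4) with
#' the same split and early-stopping contract as \code{\link{binding_fit}}:
#' donor-aware train/validation/test splits when donors are known, early
#' stopping on internal-validation AUC, best-epoch weights restored.
#'
#' @param tcrs canonical TCR data.frame with a \code{compartment} column
#'   (\code{"CD4"} / \code{"CD8"}); optional \code{donor} column.
#' @param config a \code{\link{cd4cd8_config}}.
#' @param ae optional pretrained \code{\link{cdr3_autoencoder}}.
#' @return object of class \code{cd4cd8_model} (shares the internals and
#'   methods of \code{tcrhla_model}: \code{predict}, \code{plot},
#'   \code{history}, \code{test_auc}). A single-class input raises a
#'   condition of class \code{"single_class"}.
#' @export
cd4cd8_fit <- function(tcrs, config = cd4cd8_config(), ae = NULL) {
  set.seed(config$seed)
  y <- as.integer(tcrs$compartment == "CD8")
  if (length(unique(y)) < 2) {
    tcrhla_abort("single_class", "need both CD4 and CD8 examples")
  }
  donor <- if ("donor" %in% names(tcrs)) tcrs$donor else NULL
  split <- make_split(nrow(tcrs), donor, config$validation_fraction,
                      config$test_fraction)
  if (is.null(ae)) {
    ae <- cdr3_autoencoder(unique(as.character(tcrs$cdr3b[split$train])),
                           max_len = config$max_len, latent = config$ae_latent,
                           hidden = config$ae_hidden, epochs = config$ae_epochs,
                           seed = config$seed)
    set.seed(config$seed + 1L)
  }
  model <- list(config = config, ae = ae, max_len = ae$max_len,
                latent = ae$latent)
  train_rows <- tcrs[split$train, , drop = FALSE]
  model$v_vocab <- c(sort(unique(as.character(train_rows$v_gene))), "<unk>")
  model$j_vocab <- c(sort(unique(as.character(train_rows$j_gene))), "<unk>")
  if (config$use_alpha) {
    model$va_vocab <- c(sort(unique(as.character(train_rows$v_gene_a))), "<unk>")
    model$ja_vocab <- c(sort(unique(as.character(train_rows$j_gene_a))), "<unk>")
  }
  blocks <- list(latent = ae$latent, gene = config$gene_emb_dim)
  din <- ae$latent * (1 + config$use_alpha) +
    config$gene_emb_dim * 2 * (1 + config$use_alpha)
  hidden <- ceiling(din / 2)
  params <- list(enc_W1 = ae$params$enc_W1, enc_b1 = ae$params$enc_b1,
                 enc_W2 = ae$params$enc_W2, enc_b2 = ae$params$enc_b2,
                 emb_v = nn_emb_init(length(model$v_vocab), config$gene_emb_dim),
                 emb_j = nn_emb_init(length(model$j_vocab), config$gene_emb_dim))
  if (config$use_alpha) {
    params$emb_va <- nn_emb_init(length(model$va_vocab), config$gene_emb_dim)
    params$emb_ja <- nn_emb_init(length(model$ja_vocab), config$gene_emb_dim)
  }
  mlp1 <- nn_dense_init(din, hidden); mlp2 <- nn_dense_init(hidden, 1)
  params$W1 <- mlp1$W; params$b1 <- mlp1$b
  params$W2 <- mlp2$W; params$b2 <- 0
  model$blocks <- blocks
  model$din <- din
  model$params <- params
  data <- build_nn_data(tcrs, model, use_hla = FALSE)
  fit <- fit_binary_nn(model$params, data, y, split, config, blocks)
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$best_val_auc <- fit$best_val_auc
  model$split <- split
  model$n_pairs <- nrow(tcrs)
  model$test_auc <- if (length(split$test)) {
    roc_auc(predict_prob(model$params, data, split$test, config, blocks),
            y[split$test])
  } else NA_real_
  class(model) <- c("cd4cd8_model", "tcrhla_model")
  model
}

#' Predict CD8 origin probabilities
#'
#' @param object a fitted \code{\link{cd4cd8_fit}} classifier.
#' @param newdata canonical TCR data.frame.
#' @param ... unused.
#' @return numeric vector: probability that each TCR originates from a CD8
#'   T cell.
#' @export
predict.cd4cd8_model <- function(object, newdata, ...) {
  data <- build_nn_data(newdata, object, use_hla = FALSE)
  predict_prob(object$params, data, seq_len(nrow(newdata)), object$config,
               object$blocks)
}

#' @export
print.cd4cd8_model <- function(x, ...) {
  cat("CD4/CD8 compartment classifier\n")
  cat("  TCRs:", x$n_pairs, " input dim:", x$din, "\n")
  cat(sprintf("  best epoch %d (validation AUC %.3f)", x$best_epoch,
              x$best_val_auc))
  if (!is.na(x$test_auc)) cat(sprintf(", test AUC %.3f", x$test_auc))
  cat("\n")
  invisible(x)
}

#' Keep the TCRs most confidently called CD8
#'
#' Selects the \code{ceiling(top_fraction * n)} highest-scoring TCRs. The
#' returned subset preserves the input row order; score ties at the
#' selection boundary are resolved towards earlier input rows
#' (deterministic). There is no default fraction: reported operating
#' points vary widely (e.g. the top 5 percent, or far stricter cuts), so
#' the caller must choose one.
#'
#' @param model a fitted \code{\link{cd4cd8_fit}} classifier.
#' @param tcrs canonical TCR data.frame.
#' @param top_fraction fraction to keep, in (0, 1].
#' @return the selected rows of \code{tcrs}, with the full score vector in
#'   \code{attr(, "scores")} and the selected indices in
#'   \code{attr(, "selected")}.
#' @export
filter_top_cd8 <- function(model, tcrs, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n <- nrow(tcrs)
  if (n == 0) return(tcrs)
  scores <- predict(model, tcrs)
  k <- ceiling(top_fraction * n)
  sel <- sort(order(-scores, seq_len(n))[seq_len(k)])
  out <- tcrs[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  attr(out, "selected") <- sel
  out
}
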
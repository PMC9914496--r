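# Naive Bayes association between V-beta gene usage and HLA alleles.
# Because CDR1 and CDR2 are fully determined by the V gene, a V-gene-only
# model captures the germline-encoded part of the TCR-MHC contact:
#   P(h | v) = P(h) P(v | h) / P(v)
# estimated from observed positive pairs, optionally pseudo-count smoothed.

#' Fit the V-gene naive Bayes binding model
#'
#' Estimates P(h), P(v) and P(v | h) as (optionally smoothed) empirical
#' frequencies over positive TCR-HLA pairs. With \code{smoothing_alpha = 0}
#' the posterior score P(h | v) reduces exactly to
#' \code{count(h, v) / count(v)}.
#'
#' @param pairs canonical pair data.frame with columns \code{v_gene} and
#'   \code{hla}; if a \code{label} column is present only rows with label 1
#'   are used.
#' @param smoothing_alpha Laplace pseudo-count added to every (h, v) cell
#'   (default 0, plain frequencies). Positive values keep scores finite for
#'   (h, v) combinations unseen in training, which otherwise break
#'   cross-dataset transfer.
#' @return object of class \code{tcr_nb} with elements \code{p_h},
#'   \code{p_v} (named probability vectors), \code{p_v_given_h} (matrix,
#'   rows = alleles, rows sum to 1), \code{counts}, \code{n} and
#'   \code{alpha}.
#' @examples
#' pairs <- data.frame(
#'   v_gene = c(rep("V01-01", 8), rep("V02-01", 2), rep("V01-01", 2), rep("V02-01", 8)),
#'   hla = rep(c("A*01:01", "A*02:01"), each = 10))
#' fit <- nb_fit(pairs)
#' predict(fit, "V01-01")
#' @export
nb_fit <- function(pairs, smoothing_alpha = 0) {
  if (!is.null(pairs$label)) pairs <- pairs[pairs$label == 1, , drop = FALSE]
  if (nrow(pairs) == 0) tcrhla_abort("empty_training", "no positive pairs to fit on")
  counts <- table(factor(pairs$hla), factor(pairs$v_gene))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  n <- sum(counts)
  a <- smoothing_alpha
  N <- nrow(counts); M <- ncol(counts)
  denom <- n + a * N * M
  joint <- (counts + a) / denom
  p_h <- rowSums(joint)
  p_v <- colSums(joint)
  p_v_given_h <- joint / p_h
  structure(list(p_h = p_h, p_v = p_v, p_v_given_h = p_v_given_h,
                 counts = counts, n = n, alpha = a),
            class = "tcr_nb")
}

#' Score alleles for V genes with a fitted naive Bayes model
#'
#' Returns the posterior P(h | v) = P(h) P(v | h) / P(v) for every allele.
#' For each V gene the scores sum to 1 over alleles.
#'
#' @param object a fitted \code{\link{nb_fit}} model.
#' @param newdata character vector of V-gene labels, or a data.frame with a
#'   \code{v_gene} column.
#' @param ... unused.
#' @return numeric matrix, one row per input V gene, one column per allele.
#'   A V gene unseen in training raises a condition of class
#'   \code{"unseen_v_gene"} when the model is unsmoothed; with
#'   \code{smoothing_alpha > 0} an unseen gene carries no information and
#'   receives the prior P(h).
#' @export
predict.tcr_nb <- function(object, newdata, ...) {
  v <- if (is.data.frame(newdata)) newdata$v_gene else as.character(newdata)
  known <- colnames(object$counts)
  s <- nb_score_matrix(object)       # alleles x v genes
  out <- matrix(NA_real_, length(v), nrow(s),
                dimnames = list(v, rownames(s)))
  unseen <- !(v %in% known)
  if (any(unseen)) {
    if (object$alpha <= 0) {
      tcrhla_abort("unseen_v_gene",
                   paste0("V gene(s) unseen in training: ",
                          paste(unique(v[unseen]), collapse = ", ")))
    }
    # a wholly unseen gene carries no information: posterior = prior P(h)
    out[unseen, ] <- matrix(object$p_h, sum(unseen), length(object$p_h),
                            byrow = TRUE)
  }
  seen <- which(!unseen)
  if (length(seen)) out[seen, ] <- t(s[, v[seen], drop = FALSE])
  out
}

#' Posterior score matrix s[h, v] = P(h | v)
#'
#' @param object a fitted \code{\link{nb_fit}} model.
#' @return matrix, rows = alleles, columns = V genes; each column sums to 1.
#' @export
nb_score_matrix <- function(object) {
  s <- object$p_v_given_h * object$p_h
  sweep(s, 2, object$p_v, "/")
}

#' Log-posterior matrix with single-link clustering orders
#'
#' Computes \code{log(P(h | v) + epsilon)} for every allele / V-gene
#' combination and a leaf ordering of rows and columns from single-link
#' hierarchical clustering (Euclidean distance on the log-matrix rows and
#' columns), the standard way to display the association structure as a
#' clustered heatmap.
#'
#' @param object a fitted \code{\link{nb_fit}} model.
#' @param epsilon offset guarding against log(0) (default \code{1e-5}).
#' @return list of class \code{nb_log_matrix}: \code{$log_matrix} (original
#'   order), \code{$row_order}, \code{$col_order} (single-link leaf
#'   orders), \code{$ordered} (the reordered matrix).
#' @export
nb_log_matrix <- function(object, epsilon = 1e-5) {
  s <- nb_score_matrix(object)
  m <- log(s + epsilon)
  row_order <- if (nrow(m) > 2) {
    stats::hclust(stats::dist(m), method = "single")$order
  } else seq_len(nrow(m))
  col_order <- if (ncol(m) > 2) {
    stats::hclust(stats::dist(t(m)), method = "single")$order
  } else seq_len(ncol(m))
  structure(list(log_matrix = m, row_order = row_order, col_order = col_order,
                 ordered = m[row_order, col_order, drop = FALSE],
                 epsilon = epsilon),
            class = "nb_log_matrix")
}

#' @export
print.tcr_nb <- function(x, ...) {
  cat("V-gene naive Bayes binding model\n")
  cat("  alleles:", nrow(x$counts), " V genes:", ncol(x$counts),
      " training pairs:", x$n, "\n")
  if (x$alpha > 0) cat("  Laplace smoothing alpha =", x$alpha, "\n")
  invisible(x)
}

#' @export
summary.tcr_nb <- function(object, ...) {
  s <- nb_score_matrix(object)
  cat("V-gene naive Bayes binding model\n")
  cat("  alleles:", nrow(s), " V genes:", ncol(s),
      " training pairs:", object$n, "\n")
  top <- apply(s, 2, function(col) rownames(s)[which.max(col)])
  cat("  top allele per V gene (first 10):\n")
  show <- utils::head(seq_along(top), 10)
  for (i in show) cat(sprintf("    %-8s -> %s (%.3f)\n",
                              colnames(s)[i], top[i], max(s[, i])))
  invisible(object)
}

#' @export
coef.tcr_nb <- function(object, ...) nb_score_matrix(object)

#' Plot the clustered log-posterior matrix
#'
#' @param x an \code{nb_log_matrix}.
#' @param ... passed to \code{image}.
#' @export
plot.nb_log_matrix <- function(x, ...) {
  m <- x$ordered
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  xlab = "V gene", ylab = "HLA allele", axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Serialize / load a naive Bayes model as a flat CSV
#'
#' The flat form has one row per (allele, V gene) cell carrying P(h),
#' P(v), P(v | h) and the raw count, which is enough to reconstruct the
#' model exactly.
#'
#' @param object a fitted \code{\link{nb_fit}} model.
#' @param path CSV path.
#' @return \code{read_nb_model} returns the reconstructed \code{tcr_nb}.
#' @export
write_nb_model <- function(object, path) {
  grid <- expand.grid(hla = rownames(object$counts),
                      v_gene = colnames(object$counts),
                      stringsAsFactors = FALSE)
  grid$count <- object$counts[cbind(grid$hla, grid$v_gene)]
  grid$p_h <- object$p_h[grid$hla]
  grid$p_v <- object$p_v[grid$v_gene]
  grid$p_v_given_h <- object$p_v_given_h[cbind(grid$hla, grid$v_gene)]
  grid$alpha <- object$alpha
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  grid <- utils::read.csv(path, stringsAsFactors = FALSE)
  hla <- sort(unique(grid$hla)); v <- sort(unique(grid$v_gene))
  counts <- matrix(0L, length(hla), length(v), dimnames = list(hla, v))
  counts[cbind(grid$hla, grid$v_gene)] <- as.integer(grid$count)
  pairs <- data.frame(
    hla = rep(grid$hla, grid$count),
    v_gene = rep(grid$v_gene, grid$count), stringsAsFactors = FALSE)
  nb_fit(pairs, smoothing_alpha = grid$alpha[1])
}
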
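# Two-stage training for ambiguously labelled bulk repertoires. Each TCR
# carries a candidate allele set (its donor's typing) rather than a single
# label. Stage 1 treats every candidate pair as positive; stage 2 relabels,
# keeping only each TCR's top-scoring candidate as positive and demoting
# the losing candidates to negatives, then retrains.

#' Expand ambiguous examples into stage-1 training pairs
#'
#' Positives are all (TCR, candidate) combinations. Negatives pair each TCR
#' with alleles outside its candidate set, drawn from the positives'
#' empirical allele distribution (the marginal-matching rule of
#' \code{\link{sample_negatives}}) at the configured ratio.
#'
#' @param examples a \code{\link{bse_examples}} object.
#' @param universe allele universe (default: union of candidate sets).
#' @param ratio negatives per positive.
#' @param seed integer seed.
#' @return list with \code{$positives} and \code{$negatives} pair
#'   data.frames (donor column preserved when present). An example whose
#'   candidate set covers the whole universe raises a condition of class
#'   \code{"no_negative_candidates"}.
#' @export
stage1_pairs <- function(examples, universe = NULL, ratio = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  universe <- sort(universe %||% default_universe(examples))
  if (any(vapply(examples$candidates, function(cc) all(universe %in% cc), NA))) {
    tcrhla_abort("no_negative_candidates",
                 "some candidate sets cover the whole allele universe")
  }
  m <- lengths(examples$candidates)
  rows <- rep(seq_len(nrow(examples$tcrs)), m)
  positives <- examples$tcrs[rows, , drop = FALSE]
  positives$hla <- unlist(examples$candidates)
  positives$label <- 1L
  if (!is.null(examples$donor)) positives$donor <- examples$donor[rows]
  rownames(positives) <- NULL
  negatives <- sample_ambiguous_negatives(examples, positives$hla,
                                          round(ratio * nrow(positives)),
                                          universe)
  list(positives = positives, negatives = negatives)
}

# Draw (TCR, non-candidate allele) negatives matching an empirical allele
# distribution, with per-TCR rejection of its candidates. Rows whose
# candidates swallow the marginal's whole support fall back to a uniform
# draw over the universe's non-candidates.
sample_ambiguous_negatives <- function(examples, hla_marginal, n_neg,
                                       universe = NULL) {
  n_ex <- nrow(examples$tcrs)
  if (n_neg == 0) {
    out <- examples$tcrs[integer(0), , drop = FALSE]
    out$hla <- character(0); out$label <- integer(0)
    return(out)
  }
  tab <- table(hla_marginal)
  lev <- names(tab); p <- as.numeric(tab) / sum(tab)
  rows <- rep(seq_len(n_ex), length.out = n_neg)
  rows <- rows[sample.int(n_neg)]
  hla <- sample(lev, n_neg, replace = TRUE, prob = p)
  for (try in seq_len(1000)) {
    bad <- vapply(seq_len(n_neg),
                  function(i) hla[i] %in% examples$candidates[[rows[i]]], NA)
    if (!any(bad)) break
    if (try >= 50 && !is.null(universe)) {
      for (i in which(bad)) {
        pool_i <- setdiff(universe, examples$candidates[[rows[i]]])
        if (!length(pool_i)) {
          tcrhla_abort("no_negative_candidates",
                       "a candidate set covers the whole allele universe")
        }
        hla[i] <- pool_i[sample.int(length(pool_i), 1)]
      }
      break
    }
    if (try == 1000) {
      tcrhla_abort("negative_space_exhausted",
                   "could not sample non-candidate negatives")
    }
    hla[bad] <- sample(lev, sum(bad), replace = TRUE, prob = p)
  }
  out <- examples$tcrs[rows, , drop = FALSE]
  out$hla <- hla
  out$label <- 0L
  if (!is.null(examples$donor)) out$donor <- examples$donor[rows]
  rownames(out) <- NULL
  out
}

#' Relabel ambiguous examples with a trained model (stage 2)
#'
#' Scores each TCR's candidates with the model; the single top-scoring
#' candidate becomes the TCR's positive pair and all other candidates
#' become negatives. Score ties are broken towards the lexicographically
#' first allele and counted. Negatives are topped up with non-candidate
#' draws where a TCR has fewer losing candidates than the configured
#' ratio, keeping the class balance comparable to stage 1.
#'
#' @param model a fitted \code{\link{binding_fit}} model.
#' @param examples a \code{\link{bse_examples}} object.
#' @param ratio minimum negatives per positive.
#' @param seed integer seed for the top-up draws.
#' @return list with \code{$positives}, \code{$negatives}, \code{$winners}
#'   (data.frame of each TCR with its chosen allele) and \code{$n_ties}.
#' @export
stage2_relabel <- function(model, examples, ratio = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_ex <- nrow(examples$tcrs)
  cand_sorted <- lapply(examples$candidates, sort)
  m <- lengths(cand_sorted)
  rows <- rep(seq_len(n_ex), m)
  expanded <- examples$tcrs[rows, , drop = FALSE]
  expanded$hla <- unlist(cand_sorted)
  scores <- predict(model, expanded)
  by_ex <- split(seq_along(rows), rows)
  win_idx <- integer(n_ex); n_ties <- 0L
  for (i in seq_len(n_ex)) {
    sc <- scores[by_ex[[i]]]
    w <- which.max(sc)                      # candidates sorted: ties -> first
    if (sum(sc == sc[w]) > 1) n_ties <- n_ties + 1L
    win_idx[i] <- by_ex[[i]][w]
  }
  winners <- examples$tcrs
  winners$hla <- expanded$hla[win_idx]
  positives <- winners
  positives$label <- 1L
  if (!is.null(examples$donor)) positives$donor <- examples$donor
  losers <- setdiff(seq_along(rows), win_idx)
  negatives <- expanded[losers, , drop = FALSE]
  negatives$label <- 0L
  if (!is.null(examples$donor)) negatives$donor <- examples$donor[rows[losers]]
  rownames(positives) <- rownames(negatives) <- NULL
  # top up TCRs with fewer than `ratio` losing candidates
  deficit <- pmax(0, ratio - (m - 1))
  if (any(deficit > 0)) {
    short <- rep(seq_len(n_ex), deficit)
    topup <- sample_ambiguous_negatives(examples[short], positives$hla,
                                        length(short))
    negatives <- rbind(negatives, topup)
  }
  list(positives = positives, negatives = negatives, winners = winners,
       n_ties = n_ties)
}

#' Fit the binding model on ambiguous data by two-stage training
#'
#' Round 1 trains on the stage-1 expansion (all candidates positive);
#' every further round relabels the training examples with the current
#' model (\code{\link{stage2_relabel}}) and retrains, warm-starting from
#' the previous round's weights by default. Held-out donors (or TCRs when
#' no donors are known) are never used for training and are scored after
#' every round with group accuracy and AUC.
#'
#' @param examples a \code{\link{bse_examples}} object.
#' @param config a \code{\link{binding_config}}.
#' @param n_rounds training rounds (default 2; 1 = plain stage-1
#'   training; more rounds iterate the relabeling).
#' @param ratio negatives per positive in both stages.
#' @param universe allele universe (default: union of candidate sets).
#' @param warm_start reuse the previous round's weights (default TRUE;
#'   FALSE retrains from fresh random initialization each round).
#' @param holdout fraction of donors (or TCRs) held out for per-round
#'   evaluation; 0 disables it.
#' @param ae optional pretrained \code{\link{cdr3_autoencoder}}.
#' @return object of class \code{tcrhla_two_stage}: \code{$model} (final
#'   round), \code{$rounds} (per-round ga/auc data.frame), \code{$winners}
#'   (final-model top candidate per training TCR), \code{$n_ties},
#'   \code{$holdout} (the held-out examples).
#' @export
two_stage_fit <- function(examples, config = binding_config(), n_rounds = 2,
                          ratio = 1, universe = NULL, warm_start = TRUE,
                          holdout = 0.2, ae = NULL) {
  set.seed(config$seed)
  universe <- sort(universe %||% default_universe(examples))
  n_ex <- nrow(examples$tcrs)
  if (holdout > 0) {
    if (!is.null(examples$donor)) {
      donors <- unique(examples$donor)
      if (length(donors) < 2) {
        tcrhla_abort("cannot_split", "donor-aware holdout requires >= 2 donors")
      }
      test_d <- sample(donors, max(1, round(holdout * length(donors))))
      test_idx <- which(examples$donor %in% test_d)
    } else {
      test_idx <- sample.int(n_ex, max(1, round(holdout * n_ex)))
    }
  } else {
    test_idx <- integer(0)
  }
  train_ex <- if (length(test_idx)) examples[-test_idx] else examples
  test_ex <- if (length(test_idx)) examples[test_idx] else NULL

  cfg <- config
  cfg$test_fraction <- 0                       # holdout handled here
  model <- NULL
  rounds <- data.frame(round = integer(), ga = numeric(), auc = numeric())
  for (r in seq_len(n_rounds)) {
    sp <- if (r == 1) {
      stage1_pairs(train_ex, universe, ratio)
    } else {
      stage2_relabel(model, train_ex, ratio)
    }
    pairs <- rbind(sp$positives, sp$negatives)
    cfg$seed <- config$seed + r
    model <- binding_fit(pairs, cfg,
                         ae = if (is.null(model)) ae else model$ae,
                         universe = universe,
                         init = if (warm_start && !is.null(model)) model else NULL)
    if (!is.null(test_ex)) {
      ga <- group_accuracy(model_scorer(model), test_ex, universe)$ga
      ev <- stage1_pairs(test_ex, universe, ratio = 1)
      ev_pairs <- rbind(ev$positives, ev$negatives)
      auc <- roc_auc(predict(model, ev_pairs), ev_pairs$label)
      rounds <- rbind(rounds, data.frame(round = r, ga = ga, auc = auc))
    }
  }
  final <- stage2_relabel(model, train_ex)
  structure(list(model = model, rounds = rounds, winners = final$winners,
                 n_ties = final$n_ties, universe = universe,
                 holdout = test_ex),
            class = "tcrhla_two_stage")
}

#' @export
predict.tcrhla_two_stage <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
print.tcrhla_two_stage <- function(x, ...) {
  cat("Two-stage binding fit:", nrow(x$rounds) %||% 0, "evaluated round(s)\n")
  if (nrow(x$rounds)) print(x$rounds, row.names = FALSE)
  if (x$n_ties > 0) cat("  score ties at relabeling:", x$n_ties, "\n")
  invisible(x)
}
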
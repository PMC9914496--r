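# Evaluation machinery: ROC AUC, group accuracy for ambiguous candidate
# labels, scrambled-label null curves, the analytic ceiling on AUC under
# label ambiguity, and the donor co-occurrence cross-validation with
# chi-squared reporting.

#' ROC AUC via the rank (Mann-Whitney) statistic
#'
#' Equals the probability that a random positive scores above a random
#' negative, counting ties as one half: a perfect classifier scores 1, a
#' random one 0.5.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 (or logical) labels.
#' @return AUC in [0, 1]. A single-class input raises a condition of class
#'   \code{"degenerate_labels"}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  np <- as.numeric(sum(y == 1)); nn <- as.numeric(sum(y == 0))
  if (np == 0 || nn == 0) {
    tcrhla_abort("degenerate_labels", "need both classes to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points from a threshold sweep
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return data.frame with \code{fpr} and \code{tpr}, threshold descending.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  o <- order(scores, decreasing = TRUE)
  tpr <- cumsum(y[o] == 1) / sum(y == 1)
  fpr <- cumsum(y[o] == 0) / sum(y == 0)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# Resolve the allele universe: all alleles observed across examples.
default_universe <- function(examples) {
  sort(unique(unlist(examples$candidates)))
}

# Evaluate a scorer over a universe. score_fn(tcrs, universe) must return
# an n x length(universe) matrix of scores in universe column order.
score_matrix <- function(score_fn, tcrs, universe) {
  s <- score_fn(tcrs, universe)
  if (!is.matrix(s) || nrow(s) != nrow(tcrs) || ncol(s) != length(universe)) {
    tcrhla_abort("invalid_scorer", "score_fn must return an n x |universe| matrix")
  }
  colnames(s) <- universe
  s
}

#' Group accuracy for ambiguous candidate labels
#'
#' For each TCR the scorer ranks every allele of the universe; the TCR
#' counts as a hit when the top-ranked allele lies in its candidate set.
#' Group accuracy is the fraction of hits. Argmax ties are broken towards
#' the lexicographically first allele (deterministic).
#'
#' @param score_fn function(tcrs, universe) returning an n x |universe|
#'   score matrix (see \code{\link{model_scorer}}, \code{\link{nb_scorer}}).
#' @param examples a \code{\link{bse_examples}} object.
#' @param universe character vector of alleles to rank over; defaults to
#'   all alleles observed across the examples' candidate sets.
#' @return list of class \code{ga_result}: \code{$ga}, \code{$n_tcrs},
#'   \code{$hits} (per-TCR indicator), \code{$top} (top-ranked allele).
#' @export
group_accuracy <- function(score_fn, examples, universe = NULL) {
  universe <- sort(universe %||% default_universe(examples))
  s <- score_matrix(score_fn, examples$tcrs, universe)
  top <- universe[max.col(s, ties.method = "first")]
  hits <- vapply(seq_along(top), function(i) {
    top[i] %in% examples$candidates[[i]]
  }, NA)
  structure(list(ga = mean(hits), n_tcrs = length(hits), hits = hits,
                 top = top),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("Group accuracy: %.4f over %d TCRs\n", x$ga, x$n_tcrs))
  invisible(x)
}

#' Scrambled-label null curve for group accuracy
#'
#' Estimates the group accuracy expected by chance as a function of sample
#' size: for each size fraction, subsample that share of TCRs, permute the
#' candidate-set assignment across the subsampled TCRs (set sizes are
#' preserved), and recompute the GA; the mean and standard error over
#' \code{R} scrambled realizations are reported per fraction.
#'
#' @param score_fn scorer as in \code{\link{group_accuracy}}.
#' @param examples a \code{\link{bse_examples}} object.
#' @param fractions sample-size fractions in (0, 1].
#' @param R scrambled realizations per fraction (>= 2, default 10).
#' @param universe optional allele universe.
#' @param seed integer seed.
#' @return data.frame of class \code{ga_null_curve}: fraction, n, mean_ga,
#'   se. Fractions leaving fewer than 2 TCRs are skipped with a warning.
#' @export
ga_null_curve <- function(score_fn, examples, fractions = c(0.25, 0.5, 0.75, 1),
                          R = 10, universe = NULL, seed = 1L) {
  stopifnot(R >= 2, all(fractions > 0), all(fractions <= 1))
  universe <- sort(universe %||% default_universe(examples))
  n <- length(examples)
  set.seed(as.integer(seed))
  s_full <- score_matrix(score_fn, examples$tcrs, universe)
  top_full <- universe[max.col(s_full, ties.method = "first")]
  rows <- lapply(fractions, function(f) {
    m <- round(f * n)
    if (m < 2) {
      warning("fraction ", f, " leaves fewer than 2 TCRs; skipped")
      return(NULL)
    }
    ga <- vapply(seq_len(R), function(r) {
      idx <- sample.int(n, m)
      cand <- examples$candidates[idx][sample.int(m)]  # scrambled assignment
      mean(vapply(seq_len(m), function(i) top_full[idx[i]] %in% cand[[i]], NA))
    }, 0)
    data.frame(fraction = f, n = m, mean_ga = mean(ga),
               se = stats::sd(ga) / sqrt(R))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ga_null_curve", "data.frame")
  out
}

#' Ceiling on ROC AUC under candidate-label ambiguity
#'
#' When each TCR is labelled positive for its m candidate alleles but only
#' one of them is truly associated, even a perfect scorer is capped: a
#' random labelled positive is the true pair with probability 1/m (and then
#' outranks every negative) and one of the m - 1 decoys otherwise (and then
#' ties with the negatives in distribution), giving
#' \deqn{AUC_{max} = 1/m + (m-1)/(2m) = (m+1)/(2m)}
#' in the large-universe limit: 0.625 at m = 4, 0.75 at m = 2, 1 at m = 1.
#'
#' @param m candidate alleles per TCR (>= 1).
#' @return the AUC ceiling (m + 1) / (2 m).
#' @seealso \code{\link{oracle_ambiguity_auc}} for the Monte-Carlo check.
#' @export
max_auc_bound <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    tcrhla_abort("invalid_m", "m must be a single integer >= 1")
  }
  (m + 1) / (2 * m)
}

#' Monte-Carlo AUC of a perfect oracle under label ambiguity
#'
#' Simulates the ambiguous-label evaluation directly: each TCR draws m
#' candidate alleles from a finite universe with one hidden true allele;
#' the oracle scores the true pair above every other pair of that TCR,
#' and all remaining pairs from a common distribution. The AUC is computed
#' with positives = candidate pairs and negatives = non-candidate pairs.
#' Converges to \code{\link{max_auc_bound}(m)} as the sample grows.
#'
#' @param n_tcrs simulated TCRs.
#' @param m candidates per TCR.
#' @param universe_size alleles in the universe (>= m).
#' @param seed integer seed.
#' @return empirical AUC.
#' @export
oracle_ambiguity_auc <- function(n_tcrs = 20000, m = 4, universe_size = 64,
                                 seed = 1L) {
  if (m < 1 || universe_size < m) {
    tcrhla_abort("invalid_m", "need 1 <= m <= universe_size")
  }
  set.seed(as.integer(seed))
  U <- universe_size
  scores <- matrix(stats::runif(n_tcrs * U), n_tcrs, U)
  labels <- matrix(0L, n_tcrs, U)
  for (i in seq_len(n_tcrs)) {
    cand <- sample.int(U, m)
    labels[i, cand] <- 1L
    scores[i, cand[1]] <- 1 + stats::runif(1)  # the true pair outranks all
  }
  roc_auc(as.vector(scores), as.vector(labels))
}

#' Donor co-occurrence associations for shared TCRs
#'
#' An orthogonal, model-free signal of TCR-HLA association: a TCR found in
#' at least \code{T1} donors is scored against each allele by the fraction
#' of its carrier donors typed with that allele, normalized by the allele's
#' population frequency, and the resulting ratio vector renormalized to
#' sum 1. The TCR is called associated with its top allele when the top
#' normalized ratio exceeds \code{r1}.
#'
#' @param repertoires list of \code{donor_repertoire} objects.
#' @param population_hla_freq named numeric allele frequencies (positive,
#'   summing to 1); defaults to the empirical allele frequency across the
#'   input donors.
#' @param T1 minimum carrier-donor count (typical settings: 15, or 5 for
#'   smaller cohorts).
#' @param r1 normalized-ratio call threshold (typical settings: 0.5, or
#'   0.25 for smaller cohorts).
#' @return data.frame of class \code{shared_tcr_associations}: one row per
#'   shared TCR with cdr3b, v_gene, j_gene, n_donors, top_hla, top_ratio,
#'   called; the full normalized ratio matrix is in
#'   \code{attr(, "ratios")}.
#' @export
shared_tcr_associations <- function(repertoires, population_hla_freq = NULL,
                                    T1 = 15, r1 = 0.5) {
  donor_hla <- lapply(repertoires, `[[`, "hla_set")
  donor_ids <- vapply(repertoires, `[[`, "", "donor_id")
  if (is.null(population_hla_freq)) {
    tab <- table(unlist(donor_hla))
    population_hla_freq <- as.numeric(tab) / sum(tab)
    names(population_hla_freq) <- names(tab)
  }
  if (any(population_hla_freq <= 0)) {
    tcrhla_abort("invalid_spec", "population frequencies must be positive")
  }
  alleles <- names(population_hla_freq)
  per_donor <- lapply(repertoires, function(r) unique(tcr_key(r$tcrs)))
  key_donors <- split(rep(donor_ids, lengths(per_donor)), unlist(per_donor))
  n_donors <- lengths(key_donors)
  shared <- names(key_donors)[n_donors >= T1]
  if (!length(shared)) {
    out <- data.frame(cdr3b = character(), v_gene = character(),
                      j_gene = character(), n_donors = integer(),
                      top_hla = character(), top_ratio = numeric(),
                      called = logical(), stringsAsFactors = FALSE)
    class(out) <- c("shared_tcr_associations", "data.frame")
    return(out)
  }
  carries <- matrix(0L, length(donor_ids), length(alleles),
                    dimnames = list(donor_ids, alleles))
  for (d in seq_along(donor_ids)) {
    carries[d, intersect(donor_hla[[d]], alleles)] <- 1L
  }
  ratios <- t(vapply(shared, function(k) {
    ds <- key_donors[[k]]
    raw <- colMeans(carries[ds, , drop = FALSE])
    ratio <- raw / population_hla_freq
    ratio / sum(ratio)
  }, numeric(length(alleles))))
  colnames(ratios) <- alleles
  top <- max.col(ratios, ties.method = "first")
  parts <- do.call(rbind, strsplit(shared, "|", fixed = TRUE))
  out <- data.frame(cdr3b = parts[, 1], v_gene = parts[, 2],
                    j_gene = parts[, 3], n_donors = n_donors[shared],
                    top_hla = alleles[top],
                    top_ratio = ratios[cbind(seq_along(top), top)],
                    called = ratios[cbind(seq_along(top), top)] > r1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  class(out) <- c("shared_tcr_associations", "data.frame")
  out
}

#' Recall of co-occurrence-called associations, with chi-squared tests
#'
#' For every TCR called associated with an allele by
#' \code{\link{shared_tcr_associations}}, checks whether the scorer ranks
#' that allele first over the whole universe. Per allele, the (hit, miss)
#' split is compared with the random expectation (1 / |universe| per TCR)
#' by a chi-squared test on the 2 x 2 table (1 df, continuity corrected),
#' with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param score_fn scorer as in \code{\link{group_accuracy}}.
#' @param associations result of \code{\link{shared_tcr_associations}}
#'   (only called rows are used).
#' @param universe character vector of alleles to rank over.
#' @return data.frame of class \code{association_recall}: hla, n, hits,
#'   recall, random_expectation, p_value, stars; one row per allele with at
#'   least one associated TCR, plus an \code{"overall"} row.
#' @export
association_recall_test <- function(score_fn, associations, universe) {
  called <- associations[associations$called, , drop = FALSE]
  if (nrow(called) == 0) {
    tcrhla_abort("no_associations", "no called associations to test")
  }
  universe <- sort(universe)
  s <- score_matrix(score_fn, called[c("cdr3b", "v_gene", "j_gene")], universe)
  top <- universe[max.col(s, ties.method = "first")]
  hit <- top == called$top_hla
  p_rand <- 1 / length(universe)
  one_test <- function(hits, n) {
    tab <- rbind(c(hits, n - hits), c(n * p_rand, n * (1 - p_rand)))
    suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  }
  stars <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  }
  rows <- lapply(sort(unique(called$top_hla)), function(h) {
    idx <- called$top_hla == h
    n <- sum(idx); hits <- sum(hit[idx])
    p <- one_test(hits, n)
    data.frame(hla = h, n = n, hits = hits, recall = hits / n,
               random_expectation = p_rand, p_value = p, stars = stars(p),
               stringsAsFactors = FALSE)
  })
  overall <- data.frame(hla = "overall", n = nrow(called), hits = sum(hit),
                        recall = mean(hit), random_expectation = p_rand,
                        p_value = one_test(sum(hit), nrow(called)),
                        stars = stars(one_test(sum(hit), nrow(called))),
                        stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), overall)
  class(out) <- c("association_recall", "data.frame")
  out
}

#' Scorer adapters for the evaluation functions
#'
#' Wrap fitted models into the \code{score_fn(tcrs, universe)} interface
#' used by \code{\link{group_accuracy}} and friends.
#'
#' @param model a fitted \code{\link{nb_fit}} or \code{\link{binding_fit}}
#'   model.
#' @return function(tcrs, universe) returning an n x |universe| matrix.
#' @export
nb_scorer <- function(model) {
  function(tcrs, universe) {
    s <- predict(model, tcrs$v_gene)        # n x alleles(model)
    out <- matrix(0, nrow(tcrs), length(universe),
                  dimnames = list(NULL, universe))
    common <- intersect(universe, colnames(s))
    out[, common] <- s[, common, drop = FALSE]
    out
  }
}

#' Uniform-random scorer (null model)
#'
#' @param seed integer seed consumed at each call.
#' @return scorer assigning i.i.d. uniform scores to every (TCR, allele).
#' @export
random_scorer <- function(seed = NULL) {
  function(tcrs, universe) {
    if (!is.null(seed)) set.seed(seed)
    matrix(stats::runif(nrow(tcrs) * length(universe)), nrow(tcrs),
           length(universe), dimnames = list(NULL, universe))
  }
}

#' Oracle scorer from a truth assignment
#'
#' Scores each TCR's true allele at 1 and every other allele at 0; used to
#' validate the evaluation metrics themselves.
#'
#' @param truth character vector: true allele per TCR (row order of the
#'   tcrs passed to the evaluation call).
#' @return scorer function.
#' @export
oracle_scorer <- function(truth) {
  function(tcrs, universe) {
    out <- matrix(0, nrow(tcrs), length(universe),
                  dimnames = list(NULL, universe))
    out[cbind(seq_len(nrow(tcrs)), match(truth, universe))] <- 1
    out
  }
}
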
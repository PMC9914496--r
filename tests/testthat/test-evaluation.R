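# Exhaustive pairwise AUC oracle: P(score_pos > score_neg) + ties / 2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

test_that("rank AUC agrees with the exhaustive pairwise oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(0, 1, 0, 1)),
               brute_auc(c(0.9, 0.8, 0.7, 0.6), c(0, 1, 0, 1)))
  set.seed(77)
  for (r in 1:10) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_lt(abs(roc_auc(scores, labels) - brute_auc(scores, labels)), 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "degenerate_labels")
})

test_that("label-independent scores give a null AUC", {
  set.seed(101)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.02)
})

test_that("group accuracy matches candidate-set membership of the argmax", {
  spec <- generator_spec(n_tcrs = 50, seed = 8)
  bse <- simulate_bse(spec, n_donors = 8)
  ex <- as_bse_examples(bse$repertoires)
  expect_equal(group_accuracy(oracle_scorer(bse$truth$hla), ex)$ga, 1)

  # a scorer whose argmax is always outside the candidates scores 0
  anti <- function(tcrs, universe) {
    s <- matrix(0, nrow(tcrs), length(universe), dimnames = list(NULL, universe))
    for (i in seq_len(nrow(tcrs))) {
      out <- setdiff(universe, ex$candidates[[i]])
      s[i, out[1]] <- 1
    }
    s
  }
  universe <- names(default_hla_pool())
  expect_equal(group_accuracy(anti, ex, universe)$ga, 0)
})

test_that("a uniform-random scorer attains GA = m / |universe|", {
  set.seed(202)
  universe <- names(default_hla_pool())          # 64 alleles
  cand <- replicate(10000, sample(universe, 4), simplify = FALSE)
  tcrs <- data.frame(cdr3b = "CASSF", v_gene = "V01-01", j_gene = "J01")[rep(1, 10000), ]
  ex <- bse_examples(tcrs, cand)
  ga <- group_accuracy(random_scorer(), ex, universe)$ga
  expect_lt(abs(ga - 4 / 64), 0.01)
})

test_that("the scrambled-label null curve sits at the chance level", {
  set.seed(303)
  universe <- names(default_hla_pool())
  cand <- replicate(3000, sample(universe, 4), simplify = FALSE)
  tcrs <- data.frame(cdr3b = "CASSF", v_gene = "V01-01", j_gene = "J01")[rep(1, 3000), ]
  ex <- bse_examples(tcrs, cand)
  nc <- ga_null_curve(random_scorer(), ex, fractions = c(0.5, 1), R = 10,
                      universe = universe, seed = 4)
  expect_equal(nrow(nc), 2)
  expect_true(all(abs(nc$mean_ga - 4 / 64) < 0.02))
  # minimum supported number of realizations
  nc2 <- ga_null_curve(random_scorer(), ex, fractions = 1, R = 2,
                       universe = universe, seed = 5)
  expect_equal(nrow(nc2), 1)
  expect_error(ga_null_curve(random_scorer(), ex, fractions = 1, R = 1,
                             universe = universe))
})

test_that("null-curve standard errors shrink with the sample fraction", {
  universe <- names(default_hla_pool(4, 4))
  tcrs <- data.frame(cdr3b = "CASSF", v_gene = "V01-01", j_gene = "J01")[rep(1, 800), ]
  neg_rho <- 0
  for (r in 1:10) {
    set.seed(400 + r)
    cand <- replicate(800, sample(universe, 3), simplify = FALSE)
    ex <- bse_examples(tcrs, cand)
    nc <- ga_null_curve(random_scorer(), ex, fractions = c(0.1, 0.25, 0.5, 1),
                        R = 8, universe = universe, seed = 500 + r)
    if (stats::cor(nc$fraction, nc$se, method = "spearman") < 0) {
      neg_rho <- neg_rho + 1
    }
  }
  expect_gte(neg_rho, 8)
})

test_that("the ambiguity ceiling follows the closed form and simulation", {
  expect_equal(max_auc_bound(4), 0.625)
  expect_equal(max_auc_bound(1), 1)
  expect_equal(max_auc_bound(2), 0.75)
  expect_error(max_auc_bound(0), class = "invalid_m")
  sim2 <- oracle_ambiguity_auc(20000, m = 2, universe_size = 64, seed = 11)
  expect_lt(abs(sim2 - 0.75), 0.01)
  sim1 <- oracle_ambiguity_auc(2000, m = 1, universe_size = 64, seed = 12)
  expect_equal(sim1, 1)
})

test_that("no scorer can beat the ambiguity ceiling", {
  # the perfect oracle is the maximizing scorer; its empirical AUC stays
  # within noise of the bound, hence below bound + 0.02
  for (m in c(2, 4, 8)) {
    sim <- oracle_ambiguity_auc(5000, m = m, universe_size = 64, seed = m)
    expect_lte(sim, max_auc_bound(m) + 0.02)
  }
})

test_that("shared-TCR co-occurrence ratios normalize and call correctly", {
  # 10 donors carry one shared TCR; h1 in 8 of them, h2 in 4, h3 in 2
  hsets <- c(rep(list(c("h1", "h2")), 4), rep(list("h1"), 4),
             rep(list("h3"), 2))
  tcr <- data.frame(cdr3b = "CASSF", v_gene = "V01-01", j_gene = "J01")
  reps <- lapply(seq_along(hsets), function(d) {
    structure(list(donor_id = paste0("D", d), hla_set = hsets[[d]], tcrs = tcr),
              class = "donor_repertoire")
  })
  pop <- c(h1 = 0.4, h2 = 0.2, h3 = 0.4)
  out <- shared_tcr_associations(reps, pop, T1 = 10, r1 = 0.5)
  ratios <- attr(out, "ratios")
  # raw 0.8/0.4/0.2 over pop 0.4/0.2/0.4 -> 2, 2, 0.5 -> 4/9, 4/9, 1/9
  expect_equal(unname(ratios[1, ]), c(4, 4, 1) / 9, tolerance = 1e-9)
  expect_false(out$called[1])                      # max 0.444 < r1 = 0.5
  expect_equal(out$n_donors[1], 10L)
  expect_lt(abs(sum(ratios[1, ]) - 1), 1e-9)

  # below the donor threshold the TCR is excluded, not an error
  none <- shared_tcr_associations(reps, pop, T1 = 11, r1 = 0.5)
  expect_equal(nrow(none), 0)
})

test_that("a TCR carried only with one allele is called for any r1 < 1", {
  tcr <- data.frame(cdr3b = "CASSG", v_gene = "V01-01", j_gene = "J01")
  reps <- lapply(1:5, function(d) {
    structure(list(donor_id = paste0("D", d), hla_set = "h1", tcrs = tcr),
              class = "donor_repertoire")
  })
  out <- shared_tcr_associations(reps, c(h1 = 0.5, h2 = 0.5), T1 = 5, r1 = 0.9)
  expect_true(out$called[1])
  expect_equal(out$top_hla[1], "h1")
  expect_equal(out$top_ratio[1], 1)
})

test_that("association recall is significant for an oracle, not for noise", {
  set.seed(606)
  universe <- names(default_hla_pool(8, 8))
  n <- 40
  assoc <- data.frame(cdr3b = random_cdr3s(n, len = 10),
                      v_gene = "V01-01", j_gene = "J01",
                      n_donors = 20L,
                      top_hla = sample(universe[1:3], n, replace = TRUE),
                      top_ratio = 0.9, called = TRUE)
  class(assoc) <- c("shared_tcr_associations", "data.frame")
  oracle <- function(tcrs, u) {
    s <- matrix(0, nrow(tcrs), length(u), dimnames = list(NULL, u))
    s[cbind(seq_len(nrow(tcrs)), match(assoc$top_hla, u))] <- 1
    s
  }
  res <- association_recall_test(oracle, assoc, universe)
  overall <- res[res$hla == "overall", ]
  expect_equal(overall$recall, 1)
  expect_lt(overall$p_value, 0.001)
  expect_equal(overall$stars, "***")

  # random scorer: recall near 1/|universe|, non-significant in >= 9/10 runs
  n_sig <- 0; recalls <- numeric(10)
  for (r in 1:10) {
    res_r <- association_recall_test(random_scorer(700 + r), assoc, universe)
    ov <- res_r[res_r$hla == "overall", ]
    recalls[r] <- ov$recall
    if (ov$p_value < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 1)
  expect_lt(abs(mean(recalls) - 1 / length(universe)), 0.1)
})
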
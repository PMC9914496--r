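test_that("negative sampling is forced onto the complement of the positives", {
  pos <- data.frame(cdr3b = c("CASSF", "CASSG"), v_gene = c("V01-01", "V02-01"),
                    j_gene = "J01", hla = c("A*01:01", "B*07:02"), label = 1L)
  neg <- sample_negatives(pos, ratio = 1, seed = 3)
  # 2 TCRs x 2 alleles with positives on the diagonal: the only possible
  # negatives are the two off-diagonal pairs
  expect_equal(nrow(neg), 2)
  expect_setequal(paste(neg$cdr3b, neg$hla),
                  c("CASSF B*07:02", "CASSG A*01:01"))
  expect_true(all(neg$label == 0))
  expect_equal(nrow(sample_negatives(pos, ratio = 0)), 0)
})

test_that("negatives match the positives' marginal distributions", {
  # evenly weighted pool so the rejection of existing pairs stays
  # frequency-neutral and the marginal match is exact up to noise
  pool <- default_hla_pool(8, 8)
  pool[] <- 1 / length(pool)
  pth <- simulate_pth(generator_spec(n_tcrs = 10000, hla_pool = pool, seed = 29))
  neg <- sample_negatives(pth, ratio = 1, seed = 5)
  expect_equal(nrow(neg), nrow(pth))
  # TCR multiset is reused as-is
  expect_equal(sort(neg$cdr3b), sort(pth$cdr3b))
  # allele marginal within total-variation distance 0.03
  lev <- sort(unique(pth$hla))
  tv <- sum(abs(table(factor(neg$hla, lev)) / nrow(neg) -
                table(factor(pth$hla, lev)) / nrow(pth))) / 2
  expect_lt(tv, 0.03)
  # disjointness from the positive set
  expect_false(any(paste(neg$cdr3b, neg$v_gene, neg$hla) %in%
                   paste(pth$cdr3b, pth$v_gene, pth$hla)))
})

test_that("a dense pair space exhausts the negative sampler", {
  pos <- expand.grid(cdr3b = c("CASSF", "CASSG"), hla = c("A*01:01", "B*07:02"),
                     stringsAsFactors = FALSE)
  pos$v_gene <- "V01-01"; pos$j_gene <- "J01"; pos$label <- 1L
  expect_error(sample_negatives(pos, ratio = 1, seed = 1, max_tries = 50),
               class = "negative_space_exhausted")
})

test_that("a planted signal is learned and a scrambled one is not", {
  model <- small_binding_model()
  expect_gte(model$test_auc, 0.8)
  # early stopping restored the best validation epoch
  expect_equal(model$history$val_auc[model$best_epoch],
               max(model$history$val_auc, na.rm = TRUE))
  expect_lte(nrow(model$history), model$config$max_epochs)

  # shuffled labels: held-out AUC collapses to chance
  pth <- simulate_pth(small_pth_spec())
  neg <- sample_negatives(pth, 1, seed = 3)
  all_pairs <- rbind(pth, neg)
  set.seed(9); all_pairs$label <- sample(all_pairs$label)
  cfg <- binding_config(ae_epochs = 15, max_epochs = 15, patience = 5, seed = 5)
  null_fit <- binding_fit(all_pairs, cfg)
  expect_lt(abs(null_fit$test_auc - 0.5), 0.05)
})

test_that("prediction is a deterministic probability", {
  model <- small_binding_model()
  pairs <- simulate_pth(small_pth_spec(n = 50, seed = 99))
  p <- predict(model, pairs)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(model, pairs))
  # duplicated rows in one batch get equal scores
  dup <- pairs[c(1, 1, 2, 2), ]
  pd <- predict(model, dup)
  expect_equal(pd[1], pd[2])
  expect_equal(pd[3], pd[4])
  # mean score of true pairs beats sampled negatives
  neg <- sample_negatives(pairs, 1, seed = 41)
  expect_gt(mean(p), mean(predict(model, neg)))
})

test_that("scoring the whole universe is consistent with pairwise predict", {
  model <- small_binding_model()
  tcrs <- simulate_pth(small_pth_spec(n = 5, seed = 77))[
    , c("cdr3b", "v_gene", "j_gene")]
  s <- score_all_hla(model, tcrs)
  expect_equal(colnames(s), sort(model$universe))
  for (i in 1:2) {
    pairs_i <- tcrs[rep(i, length(model$universe)), ]
    pairs_i$hla <- colnames(s)
    expect_equal(unname(s[i, ]), predict(model, pairs_i), tolerance = 1e-12)
  }
  # a universe of one ranks that allele first, trivially
  s1 <- score_all_hla(model, tcrs[1, ], universe = "A*01:01")
  expect_equal(dim(s1), c(1, 1))
})

test_that("the model ranks the true allele into the candidate range", {
  # planted-signal recovery: truth lands in a random 4-allele candidate set
  # containing it far more often than the 4/16 chance rate
  model <- small_binding_model()
  pth <- simulate_pth(small_pth_spec(n = 400, seed = 55))
  s <- score_all_hla(model, pth[, c("cdr3b", "v_gene", "j_gene")])
  top <- colnames(s)[max.col(s, ties.method = "first")]
  expect_gt(mean(top == pth$hla), 1 / length(model$universe) + 0.1)
})

test_that("donor-aware splits never put a donor on two sides", {
  pth <- simulate_pth(small_pth_spec(n = 800, seed = 66))
  pth$donor <- paste0("D", rep(1:10, each = 80))
  cfg <- binding_config(ae_epochs = 3, max_epochs = 3, patience = 3, seed = 5)
  fit <- binding_fit(pth, cfg)
  sp <- fit$split$donors
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)

  pth$donor <- "D1"
  expect_error(binding_fit(pth, cfg), class = "cannot_split")
})

test_that("early stopping halts after patience exhausts", {
  # with a vanishing learning rate the validation AUC never improves after
  # epoch 1, so patience = 1 stops training at epoch 2
  pth <- simulate_pth(small_pth_spec(n = 300, seed = 44))
  cfg <- binding_config(learning_rate = 1e-15, ae_epochs = 2, max_epochs = 50,
                        patience = 1, seed = 5)
  fit <- binding_fit(pth, cfg)
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$best_epoch, 1)
})

test_that("training is reproducible under a fixed seed", {
  pth <- simulate_pth(small_pth_spec(n = 300, seed = 44))
  cfg <- binding_config(ae_epochs = 3, max_epochs = 4, patience = 4, seed = 8)
  f1 <- binding_fit(pth, cfg)
  f2 <- binding_fit(pth, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})
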
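toy_counts_pairs <- function(counts) {
  # counts: named list like list(c("h1","v1",8), ...)
  do.call(rbind, lapply(counts, function(x) {
    data.frame(hla = x[1], v_gene = x[2])[rep(1, as.integer(x[3])), ]
  }))
}

test_that("fitted probabilities match direct counting", {
  pairs <- toy_counts_pairs(list(c("h1", "v1", 8), c("h1", "v2", 2),
                                 c("h2", "v1", 2), c("h2", "v2", 8)))
  m <- nb_fit(pairs)
  expect_equal(unname(m$p_h["h1"]), 0.5)
  expect_equal(unname(m$p_v["v1"]), 0.5)
  expect_equal(m$p_v_given_h["h1", "v1"], 0.8)
  s <- nb_score_matrix(m)
  expect_equal(s["h1", "v1"], 0.8)
  expect_equal(s["h2", "v1"], 0.2)
  # single pair degenerates to certainty
  one <- nb_fit(data.frame(hla = "h1", v_gene = "v1"))
  expect_equal(unname(one$p_h), 1)
  expect_equal(unname(one$p_v), 1)
  expect_equal(unname(one$p_v_given_h[1, 1]), 1)
  expect_error(nb_fit(data.frame(hla = character(), v_gene = character())),
               class = "empty_training")
})

test_that("posterior equals count(h, v) / count(v) exactly when unsmoothed", {
  set.seed(31)
  for (rep in 1:5) {
    n_h <- sample(2:10, 1); n_v <- sample(2:10, 1)
    pairs <- data.frame(hla = sample(paste0("h", 1:n_h), 400, TRUE),
                        v_gene = sample(paste0("v", 1:n_v), 400, TRUE))
    m <- nb_fit(pairs)
    s <- nb_score_matrix(m)
    counts <- table(pairs$hla, pairs$v_gene)
    for (v in colnames(s)) {
      expect_lt(max(abs(s[rownames(counts), v] -
                        counts[, v] / sum(counts[, v]))), 1e-12)
      expect_lt(abs(sum(s[, v]) - 1), 1e-12)
    }
  }
})

test_that("independent training data collapses the posterior to the prior", {
  set.seed(5)
  pairs <- data.frame(hla = rep(c("h1", "h2", "h3"), times = c(50, 30, 20)),
                      v_gene = "v1")
  m <- nb_fit(pairs)
  expect_equal(unname(nb_score_matrix(m)[, "v1"]), c(0.5, 0.3, 0.2))
})

test_that("smoothing keeps unseen combinations finite and positive", {
  pairs <- toy_counts_pairs(list(c("h1", "v1", 5), c("h2", "v2", 5)))
  m0 <- nb_fit(pairs)
  expect_error(predict(m0, "v9"), class = "unseen_v_gene")
  m <- nb_fit(pairs, smoothing_alpha = 0.5)
  s <- nb_score_matrix(m)
  expect_true(all(is.finite(s)) && all(s > 0))
  sc <- predict(m, "v9")
  expect_true(all(is.finite(sc)) && all(sc > 0))
  # invariants under smoothing
  expect_lt(abs(sum(m$p_h) - 1), 1e-12)
  expect_lt(abs(sum(m$p_v) - 1), 1e-12)
  expect_lt(max(abs(rowSums(m$p_v_given_h) - 1)), 1e-12)
})

test_that("log matrix applies the epsilon offset and clustering orders", {
  pairs <- toy_counts_pairs(list(c("h1", "v1", 5), c("h2", "v2", 5),
                                 c("h3", "v3", 5)))
  m <- nb_fit(pairs)
  lm <- nb_log_matrix(m)
  expect_equal(lm$log_matrix["h1", "v2"], log(1e-5))  # zero count cell
  expect_equal(lm$log_matrix["h1", "v1"], log(1 + 1e-5))
  expect_setequal(lm$row_order, seq_len(3))
  expect_setequal(lm$col_order, seq_len(3))
  expect_equal(dim(lm$ordered), dim(lm$log_matrix))
  # leaf order agrees with single-link clustering computed independently
  ref <- stats::hclust(stats::dist(lm$log_matrix), method = "single")$order
  expect_identical(lm$row_order, ref)
})

test_that("planted association is recovered from large samples", {
  # evenly weighted alleles so every conditional row sees ~n/16 draws
  hla <- default_hla_pool(8, 8); hla[] <- 1 / length(hla)
  v <- default_v_pool(12)
  A <- planted_association(names(hla), names(v), 0.9)
  spec <- generator_spec(n_tcrs = 50000, hla_pool = hla, v_pool = v,
                         association = A, seed = 19)
  pth <- simulate_pth(spec)
  m <- nb_fit(pth)
  est <- m$p_v_given_h[rownames(A), colnames(A)]
  expect_lt(max(abs(est - A)), 0.02)
})

test_that("naive Bayes scores separate planted pairs but not uniform ones", {
  # evenly weighted alleles: the rejection step of the negative sampler is
  # then frequency-neutral and the null AUC sits at 0.5
  hla <- default_hla_pool(8, 8); hla[] <- 1 / length(hla)
  v <- default_v_pool(12)
  for (case in c("planted", "uniform")) {
    A <- if (case == "planted") planted_association(names(hla), names(v), 0.9)
         else uniform_association(names(hla), names(v))
    spec <- generator_spec(n_tcrs = 8000, hla_pool = hla, v_pool = v,
                           association = A, seed = 23)
    pth <- simulate_pth(spec)
    half <- seq_len(4000)
    m <- nb_fit(pth[half, ], smoothing_alpha = 0.5)
    test <- pth[-half, ]
    neg <- sample_negatives(test, 1, seed = 7)
    all_pairs <- rbind(test, neg)
    s <- predict(m, all_pairs$v_gene)
    score <- s[cbind(seq_len(nrow(all_pairs)), match(all_pairs$hla, colnames(s)))]
    auc <- roc_auc(score, all_pairs$label)
    if (case == "planted") expect_gt(auc, 0.55) else expect_lt(abs(auc - 0.5), 0.03)
  }
})

test_that("model serialization round-trips through the flat CSV", {
  pairs <- toy_counts_pairs(list(c("h1", "v1", 8), c("h1", "v2", 2),
                                 c("h2", "v1", 2), c("h2", "v2", 8)))
  m <- nb_fit(pairs, smoothing_alpha = 0.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_nb_model(m, path)
  m2 <- read_nb_model(path)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$p_h, m$p_h)
  expect_equal(nb_score_matrix(m2), nb_score_matrix(m))
})
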
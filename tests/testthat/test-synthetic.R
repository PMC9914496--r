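test_that("planted association is reproduced empirically", {
  hla <- c("A*01:01" = 0.5, "A*02:01" = 0.5)
  v <- c("V01-01" = 0.5, "V02-01" = 0.5)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE,
              dimnames = list(names(hla), names(v)))
  spec <- generator_spec(n_tcrs = 10000, hla_pool = hla, v_pool = v,
                         association = A, seed = 7)
  pth <- simulate_pth(spec)
  p_v1_h1 <- mean(pth$v_gene[pth$hla == "A*01:01"] == "V01-01")
  expect_lt(abs(p_v1_h1 - 0.9), 0.02)
  p_v2_h2 <- mean(pth$v_gene[pth$hla == "A*02:01"] == "V02-01")
  expect_lt(abs(p_v2_h2 - 0.9), 0.02)
})

test_that("generators are deterministic given the seed and honor n = 0", {
  spec <- generator_spec(n_tcrs = 200, seed = 42)
  expect_identical(simulate_pth(spec), simulate_pth(spec))
  bse <- simulate_bse(spec, n_donors = 4)
  bse2 <- simulate_bse(spec, n_donors = 4)
  expect_identical(bse, bse2)
  expect_equal(nrow(simulate_pth(generator_spec(n_tcrs = 0))), 0)
})

test_that("invalid generator specs are rejected", {
  hla <- default_hla_pool(4, 4); v <- default_v_pool(5)
  A <- planted_association(names(hla), names(v), 0.9)
  A[1, 1] <- A[1, 1] + 0.5
  expect_error(generator_spec(hla_pool = hla, v_pool = v, association = A),
               class = "invalid_spec")
  expect_error(generator_spec(hla_pool = c("A*01:01" = 0.7)),
               class = "invalid_spec")
})

test_that("without motifs the CDR3 composition is independent of the allele", {
  # first-position letter vs allele: chi-square non-significant at alpha =
  # 0.01 in at least 18 of 20 independent runs
  hla <- c("A*01:01" = 0.5, "A*02:01" = 0.5)
  v <- c("V01-01" = 1)
  n_sig <- 0
  for (r in 1:20) {
    spec <- generator_spec(n_tcrs = 600, hla_pool = hla, v_pool = v,
                           association = uniform_association(names(hla), names(v)),
                           seed = 1000 + r)
    pth <- simulate_pth(spec)
    tab <- table(substr(pth$cdr3b, 1, 1), pth$hla)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    if (p < 0.01) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 2)
})

test_that("BSE generation hides the truth inside the donor's candidates", {
  spec <- generator_spec(n_tcrs = 200, seed = 1)
  bse <- simulate_bse(spec, n_donors = 50)
  ex <- as_bse_examples(bse$repertoires)
  expect_equal(length(ex), 10000)
  truth <- bse$truth
  for (d in bse$repertoires) {
    t_d <- truth$hla[truth$donor_id == d$donor_id]
    expect_true(all(t_d %in% d$hla_set))
    # uniform-within-donor: each of the m alleles drawn ~ 1/m
    m <- length(d$hla_set)
    freqs <- table(factor(t_d, levels = d$hla_set)) / length(t_d)
    expect_true(all(abs(freqs - 1 / m) < 4 * sqrt((1 / m) * (1 - 1 / m) / length(t_d)) + 0.02))
  }
})

test_that("single-allele donors are ambiguity-free", {
  spec <- generator_spec(n_tcrs = 30, seed = 2)
  bse <- simulate_bse(spec, n_donors = 5, alleles_per_donor = 1)
  ex <- as_bse_examples(bse$repertoires)
  expect_true(all(lengths(ex$candidates) == 1))
  ga <- group_accuracy(oracle_scorer(bse$truth$hla), ex)
  expect_equal(ga$ga, 1)
})

test_that("noisy pair construction yields candidate sets of k_extra + 1", {
  pth <- simulate_pth(generator_spec(n_tcrs = 1000, seed = 13))
  noisy <- make_noisy_pth(pth, k_extra = 3, seed = 2)
  expect_true(all(lengths(noisy$candidates) == 4))
  expect_true(all(vapply(noisy$candidates, anyDuplicated, 0) == 0))
  expect_true(all(mapply(function(cc, tr) tr %in% cc,
                         noisy$candidates, noisy$truth)))
  # k_extra = 0 reduces to the labelled data
  id <- make_noisy_pth(pth, k_extra = 0, seed = 2)
  expect_identical(unlist(id$candidates), pth$hla)
})

test_that("decoy alleles follow the table's allele distribution", {
  # evenly weighted pool: the without-replacement exclusion of the true
  # allele then perturbs the decoy marginal only at the sampling-noise level
  pool <- default_hla_pool(8, 8)
  pool[] <- 1 / length(pool)
  pth <- simulate_pth(generator_spec(n_tcrs = 10000, hla_pool = pool, seed = 17))
  noisy <- make_noisy_pth(pth, k_extra = 3, seed = 3)
  extras <- unlist(mapply(function(cc, tr) setdiff(cc, tr),
                          noisy$candidates, noisy$truth, SIMPLIFY = FALSE))
  lev <- sort(unique(pth$hla))
  p_tab <- as.numeric(table(factor(pth$hla, lev))) / nrow(pth)
  p_ext <- as.numeric(table(factor(extras, lev))) / length(extras)
  tv <- sum(abs(p_tab - p_ext)) / 2
  expect_lt(tv, 0.03)
})

test_that("too few distinct alleles for the requested decoys is an error", {
  pth <- data.frame(cdr3b = c("CASSF", "CASSG"), v_gene = "V01-01",
                    j_gene = "J01", hla = c("A*01:01", "A*02:01"))
  expect_error(make_noisy_pth(pth, k_extra = 3), class = "insufficient_alleles")
})

test_that("CD4/CD8 simulation plants the motif in CD8 cells only", {
  spec <- generator_spec(n_tcrs = 4000, cd8_motif = "WGW", motif_strength = 0.8,
                         seed = 21)
  tcrs <- simulate_cd4cd8(spec)
  in_cd8 <- mean(grepl("WGW", tcrs$cdr3b[tcrs$compartment == "CD8"]))
  in_cd4 <- mean(grepl("WGW", tcrs$cdr3b[tcrs$compartment == "CD4"]))
  expect_gt(in_cd8, 0.75)
  expect_lt(in_cd4, 0.02)
  expect_error(simulate_cd4cd8(generator_spec(n_tcrs = 10)),
               class = "invalid_spec")
})
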
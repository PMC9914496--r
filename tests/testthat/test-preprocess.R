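test_that("HLA normalization handles all accepted dialects", {
  expect_equal(normalize_hla("HLA-A*02:01"), "A*02:01")
  expect_equal(normalize_hla("A*02:01"), "A*02:01")
  expect_equal(normalize_hla("A*02:01:03"), "A*02:01")
  expect_equal(normalize_hla("hla-B*07:02"), "B*07:02")

  cat <- frequency_catalog(hla = c("A*02:01", "A*02:01", "A*02:06"))
  expect_equal(normalize_hla("HLA-A*02", cat), "A*02:01")
  expect_equal(normalize_hla("A2", cat), "A*02:01")

  expect_error(normalize_hla("not an allele"), class = "unparseable_hla")
  expect_error(normalize_hla(""), class = "unparseable_hla")
  expect_error(normalize_hla("B*44", cat), class = "unknown_group")
})

test_that("group completion picks the most frequent allele of the group", {
  # 5-row toy table: B*07:02 occurs 3x, B*07:05 occurs 1x, B*08:01 once
  cat <- frequency_catalog(
    hla = c("B*07:02", "B*07:02", "B*07:02", "B*07:05", "B*08:01"))
  expect_equal(normalize_hla("B*07", cat), "B*07:02")
  expect_equal(normalize_hla("B*08", cat), "B*08:01")
})

test_that("V/J gene normalization strips alleles, options and prefixes", {
  expect_equal(normalize_v_gene("V13-01/3/4"), "V13-01")
  expect_equal(normalize_v_gene("V01-02:01"), "V01-02")
  expect_equal(normalize_v_gene("TRBV5-1"), "V05-01")
  expect_equal(normalize_v_gene("TCRBV12-03"), "V12-03")
  cat <- frequency_catalog(v_genes = c("V05-01", "V05-01", "V05-08"))
  expect_equal(normalize_v_gene("V05", cat), "V05-01")
  expect_error(normalize_v_gene("junk"), class = "unparseable_v_gene")
  expect_error(normalize_v_gene("V05"), class = "unknown_group")

  expect_equal(normalize_j_gene("TRBJ2-7"), "J02")
  expect_equal(normalize_j_gene("J1"), "J01")
  expect_error(normalize_j_gene(""), class = "unparseable_j_gene")
})

test_that("normalization is idempotent on accepted input", {
  cat <- frequency_catalog(hla = c("A*02:01", "B*07:02", "A*01:01"),
                           v_genes = c("V05-01", "V13-01"))
  raw_hla <- c("HLA-A*02:01", "A*01:01", "B*07", "A2", "A*02:01:05")
  for (r in raw_hla) {
    once <- normalize_hla(r, cat)
    expect_identical(normalize_hla(once, cat), once)
  }
  raw_v <- c("V13-01/3/4", "V01-02:01", "TRBV5-1", "V05")
  for (r in raw_v) {
    once <- normalize_v_gene(r, cat)
    expect_identical(normalize_v_gene(once, cat), once)
  }
  expect_identical(normalize_j_gene(normalize_j_gene("TRBJ2-7")), "J02")
})

test_that("PTH filtering drops by reason and conserves row counts", {
  f <- filter_pth(toy_raw_pth())
  expect_equal(nrow(f$pairs), 2)
  drops <- f$audit[c("non_human", "missing_hla", "multiple_hla", "missing_cdr3")]
  expect_true(all(drops == 1))
  expect_equal(sum(f$audit["kept"], f$audit["duplicate_pair"], drops),
               f$audit[["input"]])

  # empty input
  empty <- filter_pth(toy_raw_pth()[0, ])
  expect_equal(nrow(empty$pairs), 0)
  expect_equal(empty$audit[["input"]], 0L)

  # all-clean table passes untouched
  clean <- data.frame(species = "Human",
                      cdr3b = paste0("CASS", c("A", "D", "E", "F", "G")),
                      v_gene = "V01-01", j_gene = "J01",
                      hla = c("A*01:01", "A*02:01", "B*07:02", "B*08:01", "A*03:01"))
  fc <- filter_pth(clean)
  expect_equal(nrow(fc$pairs), 5)
  expect_equal(sum(fc$audit[setdiff(names(fc$audit), c("input", "kept"))]), 0L)
})

test_that("duplicate pairs are collapsed and logged", {
  clean <- data.frame(species = "Human", cdr3b = c("CASSF", "CASSF", "CASSG"),
                      v_gene = "V01-01", j_gene = "J01",
                      hla = c("A*01:01", "A*01:01", "A*01:01"))
  f <- filter_pth(clean)
  expect_equal(nrow(f$pairs), 2)
  expect_equal(f$audit[["duplicate_pair"]], 1L)
  f2 <- filter_pth(clean, deduplicate = FALSE)
  expect_equal(nrow(f2$pairs), 3)
})

test_that("repertoire IO round-trips and drops non-A/B typing alleles", {
  dir <- withr::local_tempdir()
  reps <- simulate_bse(generator_spec(n_tcrs = 20, seed = 3), n_donors = 3)$repertoires
  paths <- write_repertoire(reps, dir)
  back <- suppressMessages(read_repertoire(paths$paths, paths$typing))
  expect_equal(length(back), 3)
  for (k in seq_along(reps)) {
    expect_equal(back[[k]]$donor_id, reps[[k]]$donor_id)
    expect_equal(back[[k]]$hla_set, reps[[k]]$hla_set)
    expect_equal(back[[k]]$tcrs[c("cdr3b", "v_gene", "j_gene")],
                 reps[[k]]$tcrs[c("cdr3b", "v_gene", "j_gene")])
  }
  # writing the re-read set reproduces the files exactly
  dir2 <- withr::local_tempdir()
  paths2 <- write_repertoire(back, dir2)
  expect_identical(readLines(paths2$paths[1]), readLines(paths$paths[1]))

  # C-locus alleles in the typing are discarded with a count
  typing <- utils::read.delim(paths$typing, stringsAsFactors = FALSE)
  typing$alleles[1] <- paste0(typing$alleles[1], ",C*07:01")
  got <- suppressMessages(read_repertoire(paths$paths, typing))
  expect_equal(attr(got, "n_dropped_alleles"), 1L)
  expect_false(any(hla_locus(got[[1]]$hla_set) == "C"))

  # donor missing from the typing table
  expect_error(suppressMessages(read_repertoire(paths$paths, typing[-1, ])),
               class = "missing_typing")
})

test_that("canonical pair CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  pairs <- simulate_pth(generator_spec(n_tcrs = 25, seed = 9))
  write_pth(pairs, path)
  expect_equal(read_pth(path), pairs)
})
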
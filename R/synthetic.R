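# Synthetic repertoire generators with planted structure. These provide a
# fully controlled test surface: paired TCR-HLA tables with a known
# P(v | h) association and optional CDR3 motifs per allele, bulk per-donor
# repertoires in which each TCR's true allele is hidden among the donor's
# candidates, and CD4/CD8-labelled repertoires with a planted CD8 motif.

#' Default allele / gene pools for the generators
#'
#' Population pools with Zipf-like (1/rank) frequencies, the shape typically
#' seen for HLA allele and V-gene usage: a few common labels and a long tail
#' of rare ones. The default HLA pool holds 32 A-locus and 32 B-locus
#' alleles (a 64-allele universe).
#'
#' @param n_a,n_b number of A- and B-locus alleles.
#' @param n_v number of V genes.
#' @return named numeric vector of frequencies summing to 1.
#' @export
default_hla_pool <- function(n_a = 32, n_b = 32) {
  nm <- c(sprintf("A*%02d:01", seq_len(n_a)), sprintf("B*%02d:01", seq_len(n_b)))
  f <- 1 / seq_len(n_a + n_b)
  stats::setNames(f / sum(f), nm)
}

#' @rdname default_hla_pool
#' @export
default_v_pool <- function(n_v = 30) {
  nm <- sprintf("V%02d-01", seq_len(n_v))
  f <- 1 / seq_len(n_v)
  stats::setNames(f / sum(f), nm)
}

#' Planted association matrix P(v | h)
#'
#' Each allele is assigned one preferred V gene (round-robin over the V
#' pool) which receives probability \code{strength}; the remaining mass is
#' spread uniformly over the other genes. \code{strength} equal to the
#' uniform probability 1/M recovers the no-association null.
#'
#' @param hla character vector of allele names (rows).
#' @param v_genes character vector of V-gene names (columns).
#' @param strength probability of the preferred gene (default 0.9).
#' @return matrix with rows summing to 1.
#' @export
planted_association <- function(hla, v_genes, strength = 0.9) {
  M <- length(v_genes)
  A <- matrix((1 - strength) / (M - 1), length(hla), M,
              dimnames = list(hla, v_genes))
  pref <- ((seq_along(hla) - 1) %% M) + 1
  A[cbind(seq_along(hla), pref)] <- strength
  A
}

#' @rdname planted_association
#' @export
uniform_association <- function(hla, v_genes) {
  matrix(1 / length(v_genes), length(hla), length(v_genes),
         dimnames = list(hla, v_genes))
}

#' Specification for the synthetic repertoire generators
#'
#' @param n_tcrs number of TCRs per generated table (per donor for
#'   \code{\link{simulate_bse}}).
#' @param hla_pool named numeric vector of allele population frequencies
#'   (must sum to 1).
#' @param v_pool named numeric vector of V-gene frequencies (must sum to 1).
#' @param association matrix A[h, v] of planted P(v | h); rows must sum
#'   to 1 over the V pool. Default: uniform (no association).
#' @param j_pool named numeric vector of J-family frequencies.
#' @param cdr3_len_dist named numeric vector: distribution of CDR3 lengths
#'   (names are lengths). Default: discretized bell over 8..18 residues
#'   peaked near 13, the shape of observed CDR3-beta length distributions.
#' @param motif_map optional named character vector mapping an allele to a
#'   CDR3 k-mer planted in sequences drawn for that allele.
#' @param cd8_motif optional k-mer planted in CD8 CDR3s by
#'   \code{\link{simulate_cd4cd8}}.
#' @param motif_strength probability that a planted motif is actually
#'   written into a sequence (default 0.8).
#' @param cd8_fraction fraction of CD8 cells in CD4/CD8 tables.
#' @param seed integer seed; every generator is deterministic given it.
#' @return list of class \code{generator_spec}.
#' @export
generator_spec <- function(n_tcrs = 1000,
                           hla_pool = default_hla_pool(),
                           v_pool = default_v_pool(),
                           association = NULL,
                           j_pool = c(J01 = 0.5, J02 = 0.5),
                           cdr3_len_dist = NULL,
                           motif_map = NULL,
                           cd8_motif = NULL,
                           motif_strength = 0.8,
                           cd8_fraction = 0.5,
                           seed = 1L) {
  if (is.null(association)) {
    association <- uniform_association(names(hla_pool), names(v_pool))
  }
  if (is.null(cdr3_len_dist)) {
    len <- 8:18
    w <- stats::dnorm(len, mean = 13, sd = 1.8)
    cdr3_len_dist <- stats::setNames(w / sum(w), len)
  }
  spec <- list(n_tcrs = n_tcrs, hla_pool = hla_pool, v_pool = v_pool,
               association = association, j_pool = j_pool,
               cdr3_len_dist = cdr3_len_dist, motif_map = motif_map,
               cd8_motif = cd8_motif, motif_strength = motif_strength,
               cd8_fraction = cd8_fraction, seed = as.integer(seed))
  validate_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_spec <- function(spec) {
  chk <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      tcrhla_abort("invalid_spec", paste(what, "must be a probability vector summing to 1"))
    }
  }
  chk(spec$hla_pool, "hla_pool")
  chk(spec$v_pool, "v_pool")
  chk(spec$j_pool, "j_pool")
  chk(spec$cdr3_len_dist, "cdr3_len_dist")
  A <- spec$association
  if (!all(rownames(A) %in% names(spec$hla_pool)) ||
      !identical(sort(colnames(A)), sort(names(spec$v_pool)))) {
    tcrhla_abort("invalid_spec", "association rows/columns must match the pools")
  }
  if (any(abs(rowSums(A) - 1) > 1e-8) || any(A < 0)) {
    tcrhla_abort("invalid_spec", "each association row must sum to 1")
  }
  invisible(spec)
}

# Draw one random CDR3 per length in `len`, planting `motif` with
# probability `strength` at a uniformly random position when it fits.
random_cdr3 <- function(len, motif = NA_character_, strength = 0) {
  n <- length(len)
  seqs <- vapply(len, function(L) {
    paste(sample(AMINO_ACIDS, L, replace = TRUE), collapse = "")
  }, "")
  if (n && !is.na(motif) && nzchar(motif) && strength > 0) {
    k <- nchar(motif)
    plant <- stats::runif(n) < strength & len >= k
    for (i in which(plant)) {
      pos <- sample.int(len[i] - k + 1, 1)
      substr(seqs[i], pos, pos + k - 1) <- motif
    }
  }
  seqs
}

draw_tcr_fields <- function(spec, hla) {
  n <- length(hla)
  v <- character(n)
  for (h in unique(hla)) {
    idx <- which(hla == h)
    v[idx] <- sample(colnames(spec$association), length(idx), replace = TRUE,
                     prob = spec$association[h, ])
  }
  j <- sample(names(spec$j_pool), n, replace = TRUE, prob = spec$j_pool)
  len <- as.integer(sample(names(spec$cdr3_len_dist), n, replace = TRUE,
                           prob = spec$cdr3_len_dist))
  cdr3 <- character(n)
  if (is.null(spec$motif_map)) {
    cdr3 <- random_cdr3(len)
  } else {
    for (h in unique(hla)) {
      idx <- which(hla == h)
      motif <- if (h %in% names(spec$motif_map)) spec$motif_map[[h]] else NA_character_
      cdr3[idx] <- random_cdr3(len[idx], motif, spec$motif_strength)
    }
  }
  data.frame(cdr3b = cdr3, v_gene = v, j_gene = j, stringsAsFactors = FALSE)
}

#' Generate a paired TCR-HLA table with planted associations
#'
#' For each record an allele h is drawn from the population pool, the V
#' gene from the planted conditional A[h, .], the J family from its pool
#' and the CDR3 as an i.i.d.-uniform amino-acid string of random length,
#' with the allele's motif (if any) written in with probability
#' \code{motif_strength}. All records are positive pairs (label 1).
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return data.frame: tcr_id, cdr3b, v_gene, j_gene, hla, label.
#' @export
simulate_pth <- function(spec) {
  validate_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_tcrs
  if (n == 0) {
    return(data.frame(tcr_id = character(), cdr3b = character(),
                      v_gene = character(), j_gene = character(),
                      hla = character(), label = integer(),
                      stringsAsFactors = FALSE))
  }
  hla <- sample(names(spec$hla_pool), n, replace = TRUE, prob = spec$hla_pool)
  tcr <- draw_tcr_fields(spec, hla)
  data.frame(tcr_id = sprintf("T%06d", seq_len(n)), tcr, hla = hla,
             label = 1L, stringsAsFactors = FALSE)
}

#' Generate bulk per-donor repertoires with hidden true alleles
#'
#' Each donor draws \code{alleles_per_donor} alleles from the population
#' pool (half from locus A, half from locus B, with replacement, so
#' homozygous donors can arise; the donor's candidate set keeps unique
#' alleles). Each of the donor's \code{spec$n_tcrs} TCRs then draws its
#' true allele uniformly from the donor's candidate set and its fields as
#' in \code{\link{simulate_pth}}. The truth map is returned separately and
#' is meant for parameter-recovery tests only; models never see it.
#'
#' @param spec a \code{\link{generator_spec}} (\code{n_tcrs} = TCRs per
#'   donor).
#' @param n_donors number of donors.
#' @param alleles_per_donor candidate alleles per donor (even; default 4 =
#'   2 A + 2 B).
#' @return list with \code{$repertoires} (list of \code{donor_repertoire})
#'   and \code{$truth} (data.frame donor_id, tcr_id, hla).
#' @export
simulate_bse <- function(spec, n_donors, alleles_per_donor = 4) {
  validate_spec(spec)
  set.seed(spec$seed)
  pool <- spec$hla_pool
  loci <- hla_locus(names(pool))
  a_pool <- pool[loci == "A"]
  b_pool <- pool[loci == "B"]
  per_locus <- alleles_per_donor / 2
  if (length(a_pool) < 1 || length(b_pool) < 1 ||
      length(pool) < alleles_per_donor) {
    tcrhla_abort("invalid_spec", "hla_pool too small for alleles_per_donor")
  }
  reps <- vector("list", n_donors)
  truth <- vector("list", n_donors)
  for (d in seq_len(n_donors)) {
    id <- sprintf("D%03d", d)
    if (alleles_per_donor == 1) {
      alleles <- sample(names(pool), 1, prob = pool)
    } else {
      alleles <- c(sample(names(a_pool), per_locus, replace = TRUE, prob = a_pool),
                   sample(names(b_pool), per_locus, replace = TRUE, prob = b_pool))
    }
    hla_set <- sort(unique(alleles))
    true_h <- sample(hla_set, spec$n_tcrs, replace = TRUE)
    tcrs <- draw_tcr_fields(spec, true_h)
    tcrs <- data.frame(tcr_id = sprintf("%s_T%05d", id, seq_len(spec$n_tcrs)),
                       tcrs, stringsAsFactors = FALSE)
    reps[[d]] <- structure(list(donor_id = id, hla_set = hla_set, tcrs = tcrs),
                           class = "donor_repertoire")
    truth[[d]] <- data.frame(donor_id = id, tcr_id = tcrs$tcr_id, hla = true_h,
                             stringsAsFactors = FALSE)
  }
  names(reps) <- vapply(reps, `[[`, "", "donor_id")
  list(repertoires = reps, truth = do.call(rbind, truth))
}

#' Generate a CD4/CD8-labelled repertoire with a planted CD8 motif
#'
#' Compartment labels are drawn with probability \code{spec$cd8_fraction}
#' for CD8; CD8 sequences carry \code{spec$cd8_motif} with probability
#' \code{spec$motif_strength}, CD4 sequences are motif-free (apart from
#' chance occurrences in the uniform background).
#'
#' @param spec a \code{\link{generator_spec}} with \code{cd8_motif} set.
#' @return data.frame: tcr_id, cdr3b, v_gene, j_gene, compartment.
#' @export
simulate_cd4cd8 <- function(spec) {
  validate_spec(spec)
  if (is.null(spec$cd8_motif)) {
    tcrhla_abort("invalid_spec", "spec$cd8_motif must be set")
  }
  set.seed(spec$seed)
  n <- spec$n_tcrs
  compartment <- ifelse(stats::runif(n) < spec$cd8_fraction, "CD8", "CD4")
  v <- sample(names(spec$v_pool), n, replace = TRUE, prob = spec$v_pool)
  j <- sample(names(spec$j_pool), n, replace = TRUE, prob = spec$j_pool)
  len <- as.integer(sample(names(spec$cdr3_len_dist), n, replace = TRUE,
                           prob = spec$cdr3_len_dist))
  cdr3 <- random_cdr3(len)
  is8 <- compartment == "CD8"
  cdr3[is8] <- random_cdr3(len[is8], spec$cd8_motif, spec$motif_strength)
  data.frame(tcr_id = sprintf("T%06d", seq_len(n)), cdr3b = cdr3, v_gene = v,
             j_gene = j, compartment = compartment, stringsAsFactors = FALSE)
}

#' Add decoy candidate alleles to a labelled pair table
#'
#' Builds a noisy, ambiguously labelled dataset from a clean one: each
#' TCR's candidate set becomes its true allele plus \code{k_extra} decoys
#' sampled without replacement from the table's empirical allele
#' distribution, excluding the true allele, so every candidate set has
#' exactly \code{k_extra + 1} distinct alleles and contains the truth.
#'
#' @param pairs clean pair data.frame (one true allele per TCR).
#' @param k_extra decoys per TCR (default 3, giving 4 candidates).
#' @param seed integer seed.
#' @return a \code{\link{bse_examples}} object; \code{$truth} records the
#'   true allele of each TCR (for evaluation only).
#' @export
make_noisy_pth <- function(pairs, k_extra = 3, seed = 1L) {
  freq <- table(pairs$hla)
  alleles <- names(freq)
  if (length(alleles) < k_extra + 1) {
    tcrhla_abort("insufficient_alleles",
                 "need more distinct alleles than k_extra + 1")
  }
  set.seed(as.integer(seed))
  p <- as.numeric(freq) / sum(freq)
  candidates <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    truth_i <- pairs$hla[i]
    if (k_extra == 0) {
      candidates[[i]] <- truth_i
      next
    }
    keep <- alleles != truth_i
    extra <- sample(alleles[keep], k_extra, prob = p[keep])
    candidates[[i]] <- sort(c(truth_i, extra))
  }
  bse_examples(pairs[c("cdr3b", "v_gene", "j_gene")], candidates,
               donor = pairs$donor %||% NULL, truth = pairs$hla)
}

#' Ambiguously labelled examples
#'
#' Container pairing each TCR with its candidate allele set, the form taken
#' by bulk-repertoire data where only the donor's typing is known.
#'
#' @param tcrs canonical TCR data.frame (cdr3b, v_gene, j_gene).
#' @param candidates list of character vectors, one candidate set per row
#'   of \code{tcrs}.
#' @param donor optional donor id per TCR (enables donor-aware splits).
#' @param truth optional true allele per TCR (evaluation only).
#' @return object of class \code{bse_examples}.
#' @export
bse_examples <- function(tcrs, candidates, donor = NULL, truth = NULL) {
  stopifnot(nrow(tcrs) == length(candidates))
  if (any(lengths(candidates) < 1)) {
    tcrhla_abort("invalid_spec", "every candidate set must be non-empty")
  }
  structure(list(tcrs = as.data.frame(tcrs), candidates = candidates,
                 donor = donor, truth = truth),
            class = "bse_examples")
}

#' @export
length.bse_examples <- function(x) nrow(x$tcrs)

#' @export
print.bse_examples <- function(x, ...) {
  m <- range(lengths(x$candidates))
  cat("Ambiguous examples:", nrow(x$tcrs), "TCRs, candidate set sizes",
      if (m[1] == m[2]) m[1] else paste(m[1], "-", m[2]),
      if (!is.null(x$donor)) paste0("(", length(unique(x$donor)), " donors)") else "",
      "\n")
  invisible(x)
}

#' Subset ambiguous examples
#'
#' @param x a \code{bse_examples} object.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.bse_examples` <- function(x, i, ...) {
  bse_examples(x$tcrs[i, , drop = FALSE], x$candidates[i],
               donor = if (!is.null(x$donor)) x$donor[i] else NULL,
               truth = if (!is.null(x$truth)) x$truth[i] else NULL)
}

#' Convert donor repertoires to ambiguous examples
#'
#' Every TCR inherits its donor's candidate allele set.
#'
#' @param repertoires list of \code{donor_repertoire} objects.
#' @return a \code{\link{bse_examples}} object with donor ids attached.
#' @export
as_bse_examples <- function(repertoires) {
  tcrs <- do.call(rbind, lapply(repertoires, `[[`, "tcrs"))
  rownames(tcrs) <- NULL
  candidates <- unlist(lapply(repertoires, function(r) {
    rep(list(r$hla_set), nrow(r$tcrs))
  }), recursive = FALSE)
  donor <- unlist(lapply(repertoires, function(r) rep(r$donor_id, nrow(r$tcrs))))
  bse_examples(tcrs, candidates, donor = unname(donor))
}
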
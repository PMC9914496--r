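# Reading, normalization and filtering of paired TCR-HLA tables and
# per-donor bulk repertoires. Every downstream module assumes the canonical
# representations produced here:
#   HLA   "A*02:01"  (locus * two-digit group : two-digit protein)
#   Vbeta "V01-02"   (two-field gene label, alleles stripped)
#   Jbeta "J02"      (one-field family label)

# ---------------------------------------------------------------------------
# Frequency catalog

#' Build a frequency catalog for group completion
#'
#' Incomplete designations (an HLA group without the protein field, e.g.
#' \code{"A*02"}, or a single-field V gene, e.g. \code{"V05"}) are completed
#' to the most frequent fully specified label of the same group in a
#' reference table. This function tallies a reference set of raw labels and
#' keeps, per group, the most frequent completion (ties broken
#' lexicographically, so the catalog is deterministic).
#'
#' @param hla character vector of raw HLA designations; entries that cannot
#'   be parsed to a full two-field allele are ignored.
#' @param v_genes character vector of raw V-gene designations; entries that
#'   cannot be parsed to a full two-field label are ignored.
#' @return An object of class \code{frequency_catalog}: a list with named
#'   character vectors \code{$hla} (group -> canonical allele) and \code{$v}
#'   (single-field gene -> canonical two-field label).
#' @examples
#' cat <- frequency_catalog(hla = c("A*02:01", "A*02:01", "A*02:06"),
#'                          v_genes = c("V05-01", "V05-01", "V05-08"))
#' normalize_hla("HLA-A*02", cat)
#' @export
frequency_catalog <- function(hla = character(), v_genes = character()) {
  hla_map <- character()
  if (length(hla)) {
    parsed <- lapply(hla, parse_hla_one)
    full <- Filter(function(p) p$ok && !is.na(p$field2), parsed)
    if (length(full)) {
      grp <- vapply(full, function(p) paste0(p$locus, "*", p$field1), "")
      all_ <- vapply(full, function(p) hla_string(p), "")
      hla_map <- most_frequent_by_group(grp, all_)
    }
  }
  v_map <- character()
  if (length(v_genes)) {
    parsed <- lapply(v_genes, parse_v_one)
    full <- Filter(function(p) p$ok && !is.na(p$field2), parsed)
    if (length(full)) {
      grp <- vapply(full, function(p) paste0("V", p$field1), "")
      all_ <- vapply(full, function(p) paste0("V", p$field1, "-", p$field2), "")
      v_map <- most_frequent_by_group(grp, all_)
    }
  }
  structure(list(hla = hla_map, v = v_map), class = "frequency_catalog")
}

most_frequent_by_group <- function(group, label) {
  tab <- table(group, label)
  labels <- colnames(tab)
  out <- vapply(rownames(tab), function(g) {
    counts <- as.numeric(tab[g, ])
    keep <- counts > 0
    # ties: lexicographically first label among the maxima
    sort(labels[keep][counts[keep] == max(counts[keep])])[1]
  }, "")
  names(out) <- rownames(tab)
  out
}

#' @export
print.frequency_catalog <- function(x, ...) {
  cat("Frequency catalog:", length(x$hla), "HLA group(s),",
      length(x$v), "V-gene group(s)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# HLA normalization

# Parse one raw HLA string into locus/field1/field2 without completing it.
parse_hla_one <- function(raw) {
  bad <- list(ok = FALSE, reason = "unparseable_hla")
  if (is.na(raw) || !nzchar(trimws(raw))) return(bad)
  x <- trimws(raw)
  x <- sub("^HLA[-: ]?", "", x, ignore.case = TRUE)
  # serology shorthand "A2" / "B44"
  m <- regmatches(x, regexec("^([A-Za-z]+[0-9]?)\\*([0-9]+)(?::([0-9]+))?(?::[0-9]+)*[A-Z]?$",
                             x, perl = TRUE))[[1]]
  if (!length(m)) {
    m2 <- regmatches(x, regexec("^([A-Za-z])([0-9]{1,2})$", x))[[1]]
    if (!length(m2)) return(bad)
    m <- c(m2[1], m2[2], m2[3], "")
  }
  locus <- toupper(m[2])
  f1 <- pad2(m[3])
  f2 <- if (nchar(m[4])) pad2(m[4]) else NA_character_
  list(ok = TRUE, locus = locus, field1 = f1, field2 = f2)
}

hla_string <- function(p) paste0(p$locus, "*", p$field1, ":", p$field2)

#' Normalize an HLA designation to the canonical two-field form
#'
#' Accepted dialects include \code{"HLA-A*02:01"}, \code{"A*02:01"},
#' \code{"HLA-A*02"}, \code{"A*02:01:03"} (extra fields dropped) and the
#' serology shorthand \code{"A2"}. Designations carrying only the two-digit
#' group are completed to the most frequent allele of that group in the
#' supplied catalog.
#'
#' @param raw character vector of raw HLA designations.
#' @param catalog a \code{\link{frequency_catalog}}, required only when any
#'   entry lacks the protein field.
#' @return character vector of canonical alleles, e.g. \code{"A*02:01"}.
#'   Unparseable input raises a condition of class \code{"unparseable_hla"};
#'   a group missing from the catalog raises \code{"unknown_group"}.
#' @seealso \code{\link{hla_locus}}
#' @export
normalize_hla <- function(raw, catalog = NULL) {
  vapply(raw, function(r) {
    p <- parse_hla_one(r)
    if (!p$ok) tcrhla_abort("unparseable_hla", paste0("cannot parse HLA '", r, "'"))
    if (is.na(p$field2)) {
      grp <- paste0(p$locus, "*", p$field1)
      comp <- if (!is.null(catalog)) catalog$hla[grp] else NA_character_
      if (is.null(comp) || length(comp) == 0 || is.na(comp)) {
        tcrhla_abort("unknown_group", paste0("no catalog completion for HLA group '", grp, "'"))
      }
      return(unname(comp))
    }
    hla_string(p)
  }, "", USE.NAMES = FALSE)
}

#' Locus of a canonical HLA allele string
#'
#' @param hla character vector of canonical alleles (\code{"A*02:01"}).
#' @return character vector of locus names (\code{"A"}, \code{"B"}, ...).
#' @export
hla_locus <- function(hla) sub("\\*.*$", "", hla)

# ---------------------------------------------------------------------------
# V / J gene normalization

parse_v_one <- function(raw) {
  bad <- list(ok = FALSE, reason = "unparseable_v_gene")
  if (is.na(raw) || !nzchar(trimws(raw))) return(bad)
  x <- trimws(raw)
  # multi-option lists: keep the first option
  x <- strsplit(x, "/", fixed = TRUE)[[1]][1]
  # dataset dialect prefixes
  x <- sub("^(TC?RBV|TRBV|TCRBV|V)", "", x, ignore.case = TRUE)
  # allele suffix (":01" or "*01")
  x <- sub("[:*][0-9]+$", "", x)
  m <- regmatches(x, regexec("^([0-9]+)(?:[-.]([0-9]+))?$", x, perl = TRUE))[[1]]
  if (!length(m)) return(bad)
  list(ok = TRUE, field1 = pad2(m[2]),
       field2 = if (nchar(m[3])) pad2(m[3]) else NA_character_)
}

#' Normalize a V-beta gene designation to the two-field form
#'
#' Handles allele suffixes (\code{"V01-02:01"} -> \code{"V01-02"}),
#' slash-separated option lists (\code{"V13-01/3/4"} -> \code{"V13-01"},
#' the first option is kept), dataset prefixes (\code{"TRBV5-1"}) and
#' single-field genes, which are completed to the most frequent two-field
#' label of the group via the catalog.
#'
#' @param raw character vector of raw V-gene designations.
#' @param catalog a \code{\link{frequency_catalog}}; needed for single-field
#'   input only.
#' @return character vector of labels of the form \code{"V05-01"}.
#' @export
normalize_v_gene <- function(raw, catalog = NULL) {
  vapply(raw, function(r) {
    p <- parse_v_one(r)
    if (!p$ok) tcrhla_abort("unparseable_v_gene", paste0("cannot parse V gene '", r, "'"))
    if (is.na(p$field2)) {
      grp <- paste0("V", p$field1)
      comp <- if (!is.null(catalog)) catalog$v[grp] else NA_character_
      if (is.null(comp) || length(comp) == 0 || is.na(comp)) {
        tcrhla_abort("unknown_group", paste0("no catalog completion for V group '", grp, "'"))
      }
      return(unname(comp))
    }
    paste0("V", p$field1, "-", p$field2)
  }, "", USE.NAMES = FALSE)
}

#' Normalize a J-beta gene designation to the one-field family form
#'
#' @param raw character vector, e.g. \code{"TRBJ2-7"} or \code{"J02"}.
#' @return character vector of labels of the form \code{"J02"}.
#' @export
normalize_j_gene <- function(raw) {
  vapply(raw, function(r) {
    if (is.na(r) || !nzchar(trimws(r))) {
      tcrhla_abort("unparseable_j_gene", paste0("cannot parse J gene '", r, "'"))
    }
    x <- trimws(r)
    x <- strsplit(x, "/", fixed = TRUE)[[1]][1]
    x <- sub("^(TC?RBJ|TRBJ|TCRBJ|J)", "", x, ignore.case = TRUE)
    m <- regmatches(x, regexec("^([0-9]+)", x))[[1]]
    if (!length(m)) tcrhla_abort("unparseable_j_gene", paste0("cannot parse J gene '", r, "'"))
    paste0("J", pad2(m[2]))
  }, "", USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# PTH filtering

#' Filter and normalize a raw paired TCR-HLA table
#'
#' Applies the standard cleaning rules for curated TCR-HLA pair tables:
#' non-human rows, rows with missing HLA, rows listing two or more HLA
#' alleles, and rows with a missing CDR3-beta sequence are removed; the
#' remaining rows are normalized to canonical HLA/V/J labels; exact
#' duplicate (TCR, HLA) pairs after normalization are collapsed. Every drop
#' is tallied by reason in the audit log, so that
#' \code{kept + dropped == input rows}.
#'
#' @param rows data.frame of raw records. Recognised columns (see
#'   \code{columns}): species, CDR3-beta, V gene, J gene, HLA.
#' @param catalog optional \code{\link{frequency_catalog}}; by default one is
#'   built from the fully specified entries of \code{rows} itself.
#' @param columns named character vector mapping canonical roles
#'   (\code{species}, \code{cdr3b}, \code{v_gene}, \code{j_gene},
#'   \code{hla}) to column names in \code{rows}.
#' @param species value of the species column that is kept (default
#'   \code{"Human"}); rows with any other value are dropped as non-human.
#'   If \code{rows} has no species column the filter does not fire.
#' @param deduplicate collapse duplicate (TCR, HLA) pairs after
#'   normalization (default \code{TRUE}); the number removed is logged.
#' @return A list of class \code{pth_filter} with \code{$pairs} (canonical
#'   data.frame: cdr3b, v_gene, j_gene, hla, label = 1) and \code{$audit}
#'   (named integer vector of row counts by fate).
#' @export
filter_pth <- function(rows, catalog = NULL,
                       columns = c(species = "species", cdr3b = "cdr3b",
                                   v_gene = "v_gene", j_gene = "j_gene",
                                   hla = "hla"),
                       species = "Human", deduplicate = TRUE) {
  audit <- c(input = nrow(rows), non_human = 0L, missing_hla = 0L,
             multiple_hla = 0L, missing_cdr3 = 0L, invalid_cdr3 = 0L,
             unparseable_hla = 0L, unknown_group = 0L,
             unparseable_v_gene = 0L, unparseable_j_gene = 0L,
             duplicate_pair = 0L, kept = 0L)
  empty <- data.frame(cdr3b = character(), v_gene = character(),
                      j_gene = character(), hla = character(),
                      label = integer(), stringsAsFactors = FALSE)
  if (nrow(rows) == 0) {
    return(structure(list(pairs = empty, audit = audit), class = "pth_filter"))
  }

  col <- function(role) {
    nm <- columns[[role]]
    if (!is.null(nm) && nm %in% names(rows)) as.character(rows[[nm]]) else NULL
  }
  sp <- col("species")
  cdr3 <- col("cdr3b")
  vg <- col("v_gene")
  jg <- col("j_gene")
  hla <- col("hla")
  n <- nrow(rows)
  blank <- function(x) is.na(x) | !nzchar(trimws(x))

  fate <- rep(NA_character_, n)
  mark <- function(fate, cond, reason) {
    hit <- is.na(fate) & cond
    fate[hit] <- reason
    fate
  }
  if (!is.null(sp)) fate <- mark(fate, sp != species, "non_human")
  fate <- mark(fate, if (is.null(hla)) rep(TRUE, n) else blank(hla), "missing_hla")
  if (!is.null(hla)) fate <- mark(fate, grepl("[,;]", hla), "multiple_hla")
  fate <- mark(fate, if (is.null(cdr3)) rep(TRUE, n) else blank(cdr3), "missing_cdr3")
  if (!is.null(cdr3)) fate <- mark(fate, !is_aa_string(toupper(trimws(cdr3))), "invalid_cdr3")

  if (is.null(catalog)) {
    ok <- is.na(fate)
    catalog <- frequency_catalog(hla = hla[ok], v_genes = if (is.null(vg)) character() else vg[ok])
  }
  norm_or <- function(i, fun, raw) {
    tryCatch(fun(raw), tcrhla_error = function(e) {
      reason <- class(e)[1]
      fate[i] <<- reason
      NA_character_
    })
  }
  hla_n <- v_n <- j_n <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(fate[i])) next
    hla_n[i] <- norm_or(i, function(x) normalize_hla(x, catalog), hla[i])
    if (!is.na(fate[i])) next
    if (!is.null(vg) && !blank(vg[i])) {
      v_n[i] <- norm_or(i, function(x) normalize_v_gene(x, catalog), vg[i])
      if (!is.na(fate[i])) next
    }
    if (!is.null(jg) && !blank(jg[i])) {
      j_n[i] <- norm_or(i, normalize_j_gene, jg[i])
    }
  }

  keep <- is.na(fate)
  pairs <- data.frame(cdr3b = toupper(trimws(cdr3[keep])),
                      v_gene = v_n[keep], j_gene = j_n[keep],
                      hla = hla_n[keep], label = 1L,
                      stringsAsFactors = FALSE)
  if (deduplicate && nrow(pairs)) {
    dup <- duplicated(pair_key(pairs))
    audit["duplicate_pair"] <- sum(dup)
    pairs <- pairs[!dup, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  tab <- table(fate[!keep])
  audit[names(tab)] <- as.integer(tab)
  audit["kept"] <- nrow(pairs)
  structure(list(pairs = pairs, audit = audit), class = "pth_filter")
}

#' @export
print.pth_filter <- function(x, ...) {
  cat("PTH filter:", x$audit["input"], "rows in,", x$audit["kept"], "kept\n")
  drops <- x$audit[!names(x$audit) %in% c("input", "kept")]
  drops <- drops[drops > 0]
  if (length(drops)) {
    for (r in names(drops)) cat(sprintf("  %-18s %d\n", r, drops[[r]]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Repertoire IO

#' Read per-donor bulk repertoires with HLA typing
#'
#' Reads one AIRR-style rearrangement TSV per donor together with a typing
#' table mapping each donor to its Class I alleles (the typical case: two
#' HLA-A and two HLA-B alleles). Alleles outside loci A and B (notably C)
#' are discarded with a logged count; TCR gene labels are normalized.
#'
#' @param paths character vector of repertoire TSV paths; names (or file
#'   basenames without extension) are the donor identifiers.
#' @param typing either the path of a two-column TSV (donor_id, comma
#'   separated alleles) or a data.frame with those two columns.
#' @param columns named character vector mapping \code{cdr3b},
#'   \code{v_gene}, \code{j_gene} and optionally \code{compartment} to the
#'   column names in the repertoire files; defaults to AIRR names.
#' @param catalog optional \code{\link{frequency_catalog}} for group
#'   completion during normalization.
#' @return list of donor repertoires; each element is a list of class
#'   \code{donor_repertoire} with \code{$donor_id}, \code{$hla_set}
#'   (canonical alleles, loci A/B, unique) and \code{$tcrs} (canonical
#'   data.frame). The attribute \code{"n_dropped_alleles"} counts typing
#'   alleles discarded for being outside loci A/B. A donor missing from the
#'   typing table raises a condition of class \code{"missing_typing"}.
#' @export
read_repertoire <- function(paths, typing,
                            columns = c(cdr3b = "junction_aa",
                                        v_gene = "v_call", j_gene = "j_call"),
                            catalog = NULL) {
  if (is.character(typing)) {
    typing <- utils::read.delim(typing, stringsAsFactors = FALSE)
  }
  names(typing)[1:2] <- c("donor_id", "alleles")
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  dropped <- 0L
  reps <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    id <- ids[k]
    row <- match(id, typing$donor_id)
    if (is.na(row)) {
      tcrhla_abort("missing_typing", paste0("donor '", id, "' absent from typing table"))
    }
    alleles <- trimws(strsplit(typing$alleles[row], ",")[[1]])
    alleles <- normalize_hla(alleles, catalog)
    ab <- hla_locus(alleles) %in% c("A", "B")
    dropped <- dropped + sum(!ab)
    hla_set <- sort(unique(alleles[ab]))
    tab <- utils::read.delim(paths[k], stringsAsFactors = FALSE)
    tcrs <- data.frame(
      cdr3b = toupper(trimws(as.character(tab[[columns[["cdr3b"]]]]))),
      v_gene = normalize_v_gene(tab[[columns[["v_gene"]]]], catalog),
      j_gene = normalize_j_gene(tab[[columns[["j_gene"]]]]),
      stringsAsFactors = FALSE)
    if ("compartment" %in% names(columns) && columns[["compartment"]] %in% names(tab)) {
      tcrs$compartment <- as.character(tab[[columns[["compartment"]]]])
    }
    reps[[k]] <- structure(list(donor_id = id, hla_set = hla_set, tcrs = tcrs),
                           class = "donor_repertoire")
  }
  names(reps) <- ids
  if (dropped > 0) {
    message(dropped, " typing allele(s) outside loci A/B discarded")
  }
  attr(reps, "n_dropped_alleles") <- dropped
  reps
}

#' @export
print.donor_repertoire <- function(x, ...) {
  cat("Donor", x$donor_id, "-", nrow(x$tcrs), "TCRs, alleles:",
      paste(x$hla_set, collapse = " "), "\n")
  invisible(x)
}

#' Write per-donor repertoires back to AIRR-style TSVs
#'
#' Inverse of \code{\link{read_repertoire}}: writes one TSV per donor plus
#' the donor typing table, so that reading the written files reproduces the
#' input records exactly.
#'
#' @param repertoires list of \code{donor_repertoire} objects.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the written repertoire paths and the
#'   typing table path (suitable for \code{read_repertoire}).
#' @export
write_repertoire <- function(repertoires, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(repertoires))
  for (k in seq_along(repertoires)) {
    rp <- repertoires[[k]]
    out <- data.frame(junction_aa = rp$tcrs$cdr3b, v_call = rp$tcrs$v_gene,
                      j_call = rp$tcrs$j_gene, stringsAsFactors = FALSE)
    if (!is.null(rp$tcrs$compartment)) out$compartment <- rp$tcrs$compartment
    paths[k] <- file.path(dir, paste0(rp$donor_id, ".tsv"))
    utils::write.table(out, paths[k], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  names(paths) <- vapply(repertoires, `[[`, "", "donor_id")
  typing <- data.frame(
    donor_id = names(paths),
    alleles = vapply(repertoires, function(r) paste(r$hla_set, collapse = ","), ""),
    stringsAsFactors = FALSE)
  typing_path <- file.path(dir, "typing.tsv")
  utils::write.table(typing, typing_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, typing = typing_path))
}

#' Write / read a canonical pair table
#'
#' The canonical CSV (cdr3b, v_gene, j_gene, hla, label) is the interchange
#' format consumed by the model-fitting functions.
#'
#' @param pairs canonical pair data.frame.
#' @param path CSV file path.
#' @return \code{read_pth} returns the pair data.frame.
#' @export
write_pth <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pth
#' @export
read_pth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(df)) df$label <- as.integer(df$label)
  df
}
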
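# Internal helpers shared across the package.

# The 20 standard amino acids, in alphabetical order, plus the stop symbol
# used as the 21st one-hot channel to mark the end of a CDR3 sequence.
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
STOP_SYMBOL <- "*"

#' @keywords internal
tcrhla_abort <- function(reason, msg) {
  stop(errorCondition(msg, class = c(reason, "tcrhla_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic two-digit field padding ("2" -> "02", "13" -> "13").
pad2 <- function(x) formatC(as.integer(x), width = 2, flag = "0")

is_aa_string <- function(x) {
  !is.na(x) & grepl(paste0("^[", paste(AMINO_ACIDS, collapse = ""), "]*$"), x)
}

# Stable key for a TCR record; used for donor sharing and pair identity.
tcr_key <- function(df) {
  paste(df$cdr3b, df$v_gene, df$j_gene, sep = "|")
}

pair_key <- function(df) {
  paste(tcr_key(df), df$hla, sep = "|")
}
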
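# Shared fixtures, all generated in code. Expensive fits are built lazily
# and cached for the session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small planted PTH world: 16 alleles, 12 V genes, strong association and
# per-allele CDR3 motifs.
small_pth_spec <- function(n = 3000, seed = 11) {
  hla <- default_hla_pool(8, 8)
  v <- default_v_pool(12)
  generator_spec(
    n_tcrs = n, hla_pool = hla, v_pool = v,
    association = planted_association(names(hla), names(v), 0.9),
    motif_map = stats::setNames(rep(c("WWW", "HHH", "QQQ", "MMM"), 4), names(hla)),
    seed = seed)
}

# One small trained binding model shared across tests.
small_binding_model <- function() {
  fixture("binding_model", function() {
    pth <- simulate_pth(small_pth_spec())
    cfg <- binding_config(ae_epochs = 20, max_epochs = 20, patience = 5,
                          seed = 5)
    binding_fit(pth, cfg)
  })
}

# Raw PTH table exercising every drop reason.
toy_raw_pth <- function() {
  data.frame(
    species = c("Mouse", "Human", "Human", "Human", "Human", "Human"),
    cdr3b = c("CASSF", "CASSF", "CASSG", "", "CASSH", "CASSI"),
    v_gene = "V01-01", j_gene = "J01",
    hla = c("A*02:01", NA, "A*02:01,B*07:02", "A*02:01", "A*02:01", "B*07:02"),
    stringsAsFactors = FALSE)
}

random_cdr3s <- function(n, len = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(tcrhla:::AMINO_ACIDS, len, replace = TRUE), collapse = "")
  }, "")
}

# Stub scorer model: scores a pair by a fixed per-allele weight, exposing a
# predict() method so it can stand in for a trained binding model.
rank_stub_model <- function(weights) {
  structure(list(weights = weights), class = "rank_stub")
}

predict.rank_stub <- function(object, newdata, ...) {
  w <- object$weights[newdata$hla]
  w[is.na(w)] <- 0
  unname(w)
}
registerS3method("predict", "rank_stub", predict.rank_stub)
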
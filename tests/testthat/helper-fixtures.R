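# fixture builders shared across test files

toy_table <- function(counts, samples = NULL, taxa = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- taxa %||% paste0("t", seq_len(ncol(m)))
  otu_table(m)
}

random_table <- function(n_samples, n_taxa, depth = 1000, seed = 1) {
  set.seed(seed)
  p <- matrix(rexp(n_samples * n_taxa), n_samples)
  m <- t(apply(p, 1, function(w) rmultinom(1, depth, w)[, 1]))
  rownames(m) <- paste0("s", seq_len(n_samples))
  colnames(m) <- paste0("t", seq_len(n_taxa))
  otu_table(m)
}

# minimal metadata for a flat (one-factor) design
flat_meta <- function(ids, group, date = "2018-07-30") {
  data.frame(sample_id = ids, niche = "soil", site = group,
             plot = "p1", subplot = "a", n_treatment = "control",
             collection_date = date,
             easting = seq_along(ids), northing = 0, core = "c1")
}

# brute-force Bray-Curtis between two count vectors
bc_pair <- function(a, b) sum(abs(a - b)) / sum(a + b)

`%||%` <- function(a, b) if (is.null(a)) b else a
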
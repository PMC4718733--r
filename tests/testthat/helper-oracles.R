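# Independent oracles and shared fixtures for the test suite.

# brute-force maximum-modularity partition of a small igraph graph,
# written independently of the package's clustering code
oracle_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 9)
  parts <- list(c(1L))
  for (i in seq_len(n - 1)) {
    nxt <- list()
    for (p in parts) {
      for (j in seq_len(max(p) + 1L)) nxt[[length(nxt) + 1L]] <- c(p, j)
    }
    parts <- nxt
  }
  best <- -Inf
  for (p in parts) best <- max(best, igraph::modularity(g, p))
  best
}

# random row-simplex composition matrix, rejection-sampled to be
# well-conditioned (so the exact-solve oracle is meaningful)
random_composition_matrix <- function(k = 3, kappa_max = 1e4) {
  repeat {
    W <- t(replicate(k, {
      x <- stats::rgamma(k, shape = 1)
      x / sum(x)
    }))
    if (kappa(W, exact = TRUE) < kappa_max) return(W)
  }
}

# quadrant label implied by an archetype
archetype_quadrant <- c(coupled_up = "Q1", coupled_down = "Q3",
                        uncoupled_protein_up = "Q2",
                        uncoupled_protein_down = "Q4", flat = "axis")

# run one replicate series through bead correction, un-mixing and
# finalization, returning the mother series
unmix_mother <- function(rep_data, truth, kind = c("proteome",
                                                   "transcriptome")) {
  kind <- match.arg(kind)
  tab <- rep_data[[kind]]
  if (kind == "proteome") {
    fac <- data.frame(protein_id = truth$genes,
                      factor = 1 / truth$bead_loss)
    tab <- apply_bead_correction(tab, fac)
  }
  finalize_series(unmix_series(tab, rep_data$compositions)$mother)
}
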
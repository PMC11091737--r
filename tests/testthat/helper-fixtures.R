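# Shared fixtures, all generated in code (no stored data).

# Single-species table used across tests.
one_species <- function(L = 20, g = 0.1, m = 2) {
  data.frame(species = "testus_testus", max_lifespan = L, gestation = g,
             sexual_maturity = m, stringsAsFactors = FALSE)
}

# Small single-species cohort with a clean linear age signal on the
# identity scale: n samples, p probes of which the first n_sig carry
# signal. Returns betas, sheet, and the signal probe ids.
small_cohort <- function(n = 40, p = 120, n_sig = 15, noise_sd = 0.03,
                         seed = 7, L = 20) {
  set.seed(seed)
  ages <- runif(n, 0.5, 0.9 * L)
  probe_ids <- sprintf("p%04d", seq_len(p))
  sample_ids <- sprintf("s%03d", seq_len(n))
  base <- runif(p, 0.15, 0.85)
  slopes <- numeric(p)
  slopes[seq_len(n_sig)] <- runif(n_sig, 0.012, 0.03) *
    sample(c(-1, 1), n_sig, replace = TRUE)
  mu <- matrix(base, p, n) + outer(slopes, ages)
  betas <- pmin(pmax(mu + matrix(rnorm(p * n, 0, noise_sd), p, n), 0), 1)
  dimnames(betas) <- list(probe_ids, sample_ids)
  sheet <- data.frame(sample_id = sample_ids, age = ages,
                      species = "testus_testus", stringsAsFactors = FALSE)
  list(betas = betas, sheet = sheet, signal = probe_ids[seq_len(n_sig)],
       species_table = one_species(L = L))
}

# Homogeneous same-tissue fixture for QC: columns are noisy copies of one
# smooth profile, so all pairwise correlations are high.
homogeneous_betas <- function(n = 8, p = 400, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  profile <- pmin(pmax(rbeta(p, 0.5, 0.5), 0.02), 0.98)
  betas <- vapply(seq_len(n), function(i) {
    pmin(pmax(profile + rnorm(p, 0, noise_sd), 0), 1)
  }, numeric(p))
  dimnames(betas) <- list(sprintf("p%04d", seq_len(p)),
                          sprintf("s%02d", seq_len(n)))
  betas
}

# Tiny valid beta matrix from explicit values.
tiny_betas <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("cg%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
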
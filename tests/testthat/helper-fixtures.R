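# Shared fixture builders: all synthetic, generated in code.

# Tiny long-format peptide table written to a temp file.
write_toy_table <- function(path, rows) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_rows <- function() {
  expand.grid(replicate = 1:2, temperature_C = c(37, 76),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(protein_id = "P1", peptide = "PEPTIDEK", start = 10, end = 17,
              tryptic_type = "FT", condition = "control",
              intensity = c(100, 110, 40, 42))
}

# Small mixed-archetype simulation used across tests.
small_lip <- function(delta = 4, sigma = 0.05, n_prot = 6, seed = 42,
                      archetype = "unfolder", n_pep = 4L, miss = 0.02) {
  specs <- sim_protein_specs(n_prot, archetype = archetype, delta_tm = delta,
                             n_peptides = n_pep)
  simulate_lip_experiment(specs, sim_noise_model(sigma = sigma,
                                                 missing_rate = miss),
                          seed = seed)
}

# Closed-form GP posterior (independent of the package's fit path) for a
# fixed set of hyperparameters; used as the oracle in fitting tests.
gp_oracle <- function(tr_t, tr_y, te_t, cmean, sf2, ell, sn2) {
  k <- function(a, b) sf2 * exp(-outer(a, b, "-")^2 / (2 * ell^2))
  K <- k(tr_t, tr_t) + diag(sn2, length(tr_t))
  Ki <- solve(K)
  mu <- cmean + k(te_t, tr_t) %*% Ki %*% (tr_y - cmean)
  S <- k(te_t, te_t) - k(te_t, tr_t) %*% Ki %*% k(tr_t, te_t)
  list(mean = as.numeric(mu), sd = sqrt(pmax(diag(S), 0)))
}

# Build a profile_curve by hand (tight bands around a given mean).
toy_curve <- function(grid, mean, half = 0.01) {
  structure(list(grid = grid, mean = mean, sd = rep(half / 2, length(grid)),
                 lower = mean - half, upper = mean + half),
            class = "profile_curve")
}

# Two-state decreasing sigmoid on a grid (same form as the generator).
sigmoid_profile <- function(grid, tm, dHm = 3e5) {
  tk <- grid + 273.15; tmk <- tm + 273.15
  plogis(-(dHm / (8.314 * tk)) * ((tk - tmk) / tmk))
}

# Brute-force weighted quantile via integer repetition expansion: expand
# each value into unit-weight copies and take the smallest value whose
# cumulative count reaches q*N.
expansion_quantile <- function(values, int_weights, q) {
  x <- sort(rep(values, int_weights))
  x[which(seq_along(x) >= q * length(x) - 1e-9)[1]]
}
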
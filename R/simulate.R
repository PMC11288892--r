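# Synthetic LiP/TPP/DSF data with the statistical structure the analysis
# assumes: two-state unfolding transitions on the 10-point gradient, FT/HT
# profile mirroring, osmolyte-induced rightward Tm shifts, multiplicative
# lognormal replicate noise, and a 4-replicate null design.

R_GAS <- 8.314      # J K^-1 mol^-1
KELVIN <- 273.15

# Fraction folded under a two-state model with transition enthalpy dHm
# (J/mol) and midpoint Tm (degC); decreasing sigmoid in T (degC).
folded_fraction <- function(temp_c, tm_c, dHm = 3e5) {
  tk <- temp_c + KELVIN
  tmk <- tm_c + KELVIN
  stats::plogis(-(dHm / (R_GAS * tk)) * ((tk - tmk) / tmk))
}

#' Specify simulated proteins
#'
#' One row per protein: melting midpoint under control, osmolyte-induced
#' midpoint shift, profile archetype and precipitation behaviour.
#' Archetypes: `unfolder` (decreasing FT profiles), `aggregator`
#' (increasing), `nonmonotonous` (decay followed by a rise at high
#' temperature, e.g. resolubilisation).  Defaults follow the experimental
#' design: midpoints spread over the informative middle of the gradient and
#' transitions spanning 3-4 gradient steps (dHm ~ 300 kJ/mol).
#'
#' @param n_proteins number of proteins.
#' @param archetype archetype for every protein, recycled
#'   (`"unfolder"`, `"aggregator"` or `"nonmonotonous"`).
#' @param tm_control control melting midpoints (degC), recycled; default
#'   spreads them over 48-64 degC.
#' @param delta_tm osmolyte midpoint shift (degC, >= 0 for stabilization),
#'   recycled.
#' @param length protein length in residues, recycled.
#' @param n_peptides fully tryptic peptides per protein, recycled.
#' @param ht_fraction fraction of extra half-tryptic peptides nested inside
#'   FT peptides.
#' @param precipitator logical, recycled; unfolders are forced to
#'   non-precipitating behaviour in TPP simulation only via
#'   `plateau`.
#' @param plateau TPP soluble-fraction plateau at high temperature,
#'   recycled; < 0.5 marks a precipitator.
#' @return data.frame of class `sim_protein_specs`.
#' @export
sim_protein_specs <- function(n_proteins = 20,
                              archetype = "unfolder",
                              tm_control = NULL,
                              delta_tm = 0,
                              length = 300L,
                              n_peptides = 8L,
                              ht_fraction = 0.25,
                              precipitator = TRUE,
                              plateau = ifelse(precipitator, 0.1, 0.7)) {
  if (is.null(tm_control)) {
    tm_control <- 48 + 16 * (seq_len(n_proteins) - 1) %% 9 / 8
  }
  specs <- data.frame(
    protein_id = sprintf("P%04d", seq_len(n_proteins)),
    archetype = rep_len(archetype, n_proteins),
    tm_control = rep_len(tm_control, n_proteins),
    delta_tm = rep_len(delta_tm, n_proteins),
    length = rep_len(as.integer(length), n_proteins),
    n_peptides = rep_len(as.integer(n_peptides), n_proteins),
    ht_fraction = rep_len(ht_fraction, n_proteins),
    precipitator = rep_len(precipitator, n_proteins),
    plateau = rep_len(plateau, n_proteins),
    stringsAsFactors = FALSE)
  stopifnot(all(specs$archetype %in% c("unfolder", "aggregator", "nonmonotonous")),
            all(specs$tm_control > 40 & specs$tm_control < 72),
            all(specs$delta_tm >= 0 | TRUE))
  class(specs) <- c("sim_protein_specs", "data.frame")
  specs
}

#' Noise model for simulated intensities
#'
#' Multiplicative lognormal replicate noise (`sigma` is the sdlog),
#' per-peptide baseline amplitudes drawn log-uniformly from `amp_range`,
#' and completely-at-random missingness.
#'
#' @param sigma lognormal sdlog of replicate noise (>= 0).
#' @param missing_rate fraction of intensities set missing, in [0, 0.2].
#' @param amp_range range of per-peptide amplitudes (raw intensity units).
#' @return list of class `sim_noise_model`.
#' @export
sim_noise_model <- function(sigma = 0.05, missing_rate = 0.02,
                            amp_range = c(1e5, 1e7)) {
  stopifnot(sigma >= 0, missing_rate >= 0, missing_rate <= 0.2,
            length(amp_range) == 2, all(amp_range > 0))
  structure(list(sigma = sigma, missing_rate = missing_rate,
                 amp_range = amp_range), class = "sim_noise_model")
}

# Noiseless profile value in [0, ~1] for one peptide.
archetype_profile <- function(temp_c, archetype, tm_c, dHm = 3e5) {
  f <- folded_fraction(temp_c, tm_c, dHm)
  switch(archetype,
         unfolder = f,
         aggregator = 1 - f,
         nonmonotonous = {
           # decay then full recovery (resolubilization-like): the rise
           # midpoint is capped so the recovery completes within the
           # gradient and the endpoints stay comparable (the group's
           # defining feature)
           p <- f + 1 - folded_fraction(temp_c, min(tm_c + 10, 66), dHm)
           p / max(1, max(p))
         },
         stop("unknown archetype: ", archetype))
}

# Tile n FT peptides (plus nested HT peptides) over a protein.
layout_peptides <- function(protein_id, len, n_pep, ht_fraction) {
  pep_len <- 18L
  starts <- unique(pmin(len - pep_len + 1L,
                        round(seq(1L, max(1L, len - pep_len + 1L),
                                  length.out = n_pep))))
  ft <- data.frame(
    protein_id = protein_id,
    peptide_id = sprintf("%s_FT%02d", protein_id, seq_along(starts)),
    start = as.integer(starts), end = as.integer(starts + pep_len - 1L),
    tryptic_type = "FT", proteotypic = TRUE, stringsAsFactors = FALSE)
  n_ht <- floor(ht_fraction * nrow(ft))
  if (n_ht > 0) {
    host <- seq_len(n_ht)  # nest HTs in the first n_ht FT peptides
    ht <- data.frame(
      protein_id = protein_id,
      peptide_id = sprintf("%s_HT%02d", protein_id, host),
      start = ft$start[host] + 3L, end = ft$end[host] - 2L,
      tryptic_type = "HT", proteotypic = TRUE, stringsAsFactors = FALSE)
    rbind(ft, ht)
  } else ft
}

#' Simulate a LiP-MS thermal profiling experiment
#'
#' Generates replicate peptide intensities over the gradient for control and
#' osmolyte conditions.  FT peptides follow the archetype profile with the
#' control midpoint; the osmolyte condition uses `tm_control + delta_tm`.
#' HT peptides get the mirrored (flipped) profile with an independent
#' amplitude.  Intensities are amplitude x (0.05 + 0.95 x profile) x
#' lognormal noise; a small floor keeps intensities positive so log-scale
#' operations are defined.  Deterministic given `seed`.
#'
#' @param specs a [sim_protein_specs()] data.frame.
#' @param noise a [sim_noise_model()].
#' @param grid temperature grid (degC).
#' @param n_replicates replicates per condition.
#' @param seed integer seed (mandatory).
#' @param conditions names of the two conditions.
#' @return a [peptide_dataset()].
#' @export
simulate_lip_experiment <- function(specs, noise = sim_noise_model(),
                                    grid = lip_grid(), n_replicates = 2L,
                                    seed, conditions = c("control", "osmolyte")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for simulation")
  stopifnot(inherits(specs, "sim_protein_specs"), nrow(specs) > 0,
            length(conditions) == 2)
  check_grid(grid)
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    layout_peptides(specs$protein_id[i], specs$length[i],
                    specs$n_peptides[i], specs$ht_fraction[i])
  }))
  n_pep <- nrow(recs)
  amps <- exp(stats::runif(n_pep, log(noise$amp_range[1]), log(noise$amp_range[2])))
  si <- match(recs$protein_id, specs$protein_id)
  rows <- vector("list", n_pep)
  for (j in seq_len(n_pep)) {
    sp <- specs[si[j], ]
    tm <- c(sp$tm_control, sp$tm_control + sp$delta_tm)
    out <- list()
    for (ci in 1:2) {
      p <- archetype_profile(grid, sp$archetype, tm[ci])
      if (recs$tryptic_type[j] == "HT") p <- 1 - p
      mu <- amps[j] * (0.05 + 0.95 * p)
      for (r in seq_len(n_replicates)) {
        eps <- if (noise$sigma > 0) exp(stats::rnorm(length(grid), 0, noise$sigma)) else 1
        out[[length(out) + 1L]] <- data.frame(
          peptide_id = recs$peptide_id[j], condition = conditions[ci],
          replicate = r, temperature = grid, intensity = mu * eps,
          stringsAsFactors = FALSE)
      }
    }
    rows[[j]] <- do.call(rbind, out)
  }
  ints <- do.call(rbind, rows)
  if (noise$missing_rate > 0) {
    drop <- stats::runif(nrow(ints)) < noise$missing_rate
    ints$intensity[drop] <- NA_real_
  }
  peptide_dataset(recs, ints, grid = grid)
}

#' Simulate the replicate-split null experiment
#'
#' Four replicates of the control condition, generated from identical
#' parameters, relabelled as two pseudo-conditions of two replicates each
#' (replicates {1,2} -> first pseudo-condition, {3,4} -> second).  Used to
#' calibrate the empirical FDR of the stabilization pipeline.
#'
#' @inheritParams simulate_lip_experiment
#' @param conditions the two pseudo-condition labels.
#' @return a [peptide_dataset()] with two pseudo-conditions.
#' @export
simulate_null_experiment <- function(specs, noise = sim_noise_model(),
                                     grid = lip_grid(), seed,
                                     conditions = c("null_A", "null_B")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for simulation")
  specs$delta_tm <- 0  # both pseudo-conditions share generating parameters
  ds <- simulate_lip_experiment(specs, noise, grid, n_replicates = 4L,
                                seed = seed,
                                conditions = c("control", "unused"))
  ints <- ds$intensities[ds$intensities$condition == "control", , drop = FALSE]
  grp2 <- ints$replicate >= 3L
  ints$condition <- ifelse(grp2, conditions[2], conditions[1])
  ints$replicate <- ifelse(grp2, ints$replicate - 2L, ints$replicate)
  peptide_dataset(ds$records, ints, grid = grid)
}

#' Simulate a TPP soluble-fraction experiment
#'
#' Per protein: soluble fraction follows plateau + (1 - plateau) x folded
#' fraction, with the osmolyte condition midpoint shifted by `delta_tm`;
#' multiplicative lognormal noise; each series rescaled so the 37 degC
#' value is exactly 1.
#'
#' @inheritParams simulate_lip_experiment
#' @return a `solubility_dataset`.
#' @export
simulate_tpp_experiment <- function(specs, noise = sim_noise_model(),
                                    grid = lip_grid(), n_replicates = 2L,
                                    seed, conditions = c("control", "osmolyte")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for simulation")
  stopifnot(inherits(specs, "sim_protein_specs"))
  check_grid(grid)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    tm <- c(sp$tm_control, sp$tm_control + sp$delta_tm)
    for (ci in 1:2) {
      s <- sp$plateau + (1 - sp$plateau) * folded_fraction(grid, tm[ci])
      for (r in seq_len(n_replicates)) {
        eps <- if (noise$sigma > 0) exp(stats::rnorm(length(grid), 0, noise$sigma)) else 1
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sp$protein_id, condition = conditions[ci],
          replicate = r, temperature = grid, abundance = s * eps,
          stringsAsFactors = FALSE)
      }
    }
  }
  protein_solubility_dataset(do.call(rbind, rows), rescale = TRUE, grid = grid)
}

#' Simulate a DSF melting curve
#'
#' Evaluates the two-state unfolding model (see [two_state_model()]) on a
#' dense temperature range and adds Gaussian noise.
#'
#' @param params named list/vector with `Sf`, `Su`, `mf`, `mu`, `Tm_C`,
#'   `dHm` (J/mol).
#' @param sigma additive Gaussian noise sd (scaled signal units).
#' @param t_range temperatures in degC (default 25-95 degC, 0.5 steps).
#' @param seed integer seed (mandatory if `sigma > 0`).
#' @return data.frame `temperature_C`, `signal`.
#' @export
simulate_dsf_curve <- function(params, sigma = 0,
                               t_range = seq(25, 95, by = 0.5), seed = NULL) {
  p <- as.list(params)
  if (p$Tm_C < min(t_range) || p$Tm_C > max(t_range)) {
    warning("Tm outside the simulated temperature range; fits will be unstable")
  }
  s <- two_state_model(t_range, Sf = p$Sf, Su = p$Su, mf = p$mf, mu = p$mu,
                       Tm_C = p$Tm_C, dHm = p$dHm)
  if (sigma > 0) {
    if (is.null(seed)) stop("seed is mandatory when sigma > 0")
    set.seed(seed)
    s <- s + stats::rnorm(length(t_range), 0, sigma)
  }
  data.frame(temperature_C = t_range, signal = s)
}
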
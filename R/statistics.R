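# Empirical FDR calibration on replicate-split nulls, differential
# abundance testing (binding / aggregation / protease activity), moderated
# t-statistics and permutation analyses.

#' Empirical FDR from a replicate-split null experiment
#'
#' Runs the full fit-cluster-score pipeline on a null dataset (two
#' pseudo-conditions generated from identical parameters) and reports the
#' fraction of units with a nonzero stabilization score — an estimate of
#' the pipeline's false-discovery rate at the peptide and protein level.
#'
#' @param null_dataset a [peptide_dataset()] with two pseudo-conditions,
#'   e.g. from [simulate_null_experiment()].
#' @param q_pair rollup quantile pair.
#' @param ... further arguments to [lip_stability()].
#' @return list of class `fdr_estimate`: `peptide` and `protein` FDR
#'   fractions, counts, the quantile pair and the underlying fit.
#' @export
estimate_null_fdr <- function(null_dataset, q_pair = c(0.75, 0.25), ...) {
  fit <- lip_stability(null_dataset, q_pair = q_pair, ...)
  frac_unfit <- 1 - sum(fit$fits$table$fitted) / nrow(fit$fits$table)
  if (frac_unfit > 0.2) {
    stop(sprintf("pipeline failed on %.0f%% of peptides (limit 20%%)",
                 100 * frac_unfit))
  }
  pep <- fit$peptide_scores$score
  prot <- fit$protein_scores$score
  structure(list(peptide = mean(pep != 0), protein = mean(prot != 0),
                 n_peptides = length(pep), n_proteins = length(prot),
                 q_pair = q_pair, fit = fit), class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("null FDR: peptide %.4f (n=%d), protein %.4f (n=%d), quantiles %.2f/%.2f\n",
              x$peptide, x$n_peptides, x$protein, x$n_proteins,
              x$q_pair[1], x$q_pair[2]))
  invisible(x)
}

#' Sweep the rollup quantile to a target protein-level FDR
#'
#' Recomputes the residue/protein rollup of a fitted null for symmetric
#' quantile pairs (q, 1-q), q in {0.5, 0.55, ..., 1}, and returns the
#' smallest q whose empirical protein-level FDR is at or below `target`.
#' If no pair achieves the target, 1.0 is returned with a warning.
#'
#' @param null_fit a `lip_stability` fit of a null dataset (or an
#'   `fdr_estimate`).
#' @param target target FDR (default 0.05).
#' @param q_grid candidate stabilized-side quantiles.
#' @return list: `q` (chosen quantile), `table` (q vs FDR).
#' @export
sweep_quantile <- function(null_fit, target = 0.05,
                           q_grid = seq(0.5, 1, by = 0.05)) {
  if (inherits(null_fit, "fdr_estimate")) null_fit <- null_fit$fit
  stopifnot(inherits(null_fit, "lip_stability"))
  fdr <- vapply(q_grid, function(q) {
    res <- residue_scores(null_fit$peptide_scores, q_pair = c(q, 1 - q))
    prot <- protein_score(res, q_pair = c(q, 1 - q))
    mean(prot$score != 0)
  }, numeric(1))
  ok <- which(fdr <= target)
  if (!length(ok)) {
    warning("no quantile achieves the target FDR; returning 1.0")
    q <- 1.0
  } else q <- q_grid[min(ok)]
  list(q = q, table = data.frame(q = q_grid, fdr = fdr))
}

#' Differential peptide/protein abundance on a temperature subset
#'
#' Compares log2 intensities between two conditions over a subset of
#' gradient temperatures, pooling the included temperatures'
#' replicate observations into one test per peptide (mode
#' `per_temperature = TRUE` instead tests each temperature separately with
#' BH across both dimensions).  Presets follow the analysis conventions:
#' `binding` uses the first two gradient temperatures with adjusted
#' p < 0.01 and |log2 FC| > 1.5 on nonscaled data; `aggregation` the last
#' two with p < 0.05 and |log2 FC| > 1; `pk_activity` moderated t-tests
#' with p < 0.05 and |log2 FC| > 1.
#'
#' For TPP solubility data a `solubility_dataset` may be passed (units are
#' proteins, values the scaled soluble abundances); the `tpp_aggregation`
#' preset then tests the last three gradient temperatures with p < 0.05
#' and |log2 FC| > 1.
#'
#' @param dataset a [peptide_dataset()] or `solubility_dataset`.
#' @param mode preset (`"binding"`, `"aggregation"`, `"tpp_aggregation"`,
#'   `"pk_activity"`) or `"custom"`.
#' @param conditions length-2: (reference, test); log2 FC is test - reference.
#' @param temperatures temperatures included (overrides the preset).
#' @param test `"t"` (Welch) or `"moderated"`.
#' @param alpha,lfc_cutoff significance thresholds (strict inequalities).
#' @param per_temperature test each temperature separately.
#' @return data.frame per peptide: `log2_fc`, `p`, `p_adj`, `hit`,
#'   `direction`, plus a `protein_hits` attribute — protein ids with at
#'   least one significantly changing proteotypic peptide.
#' @export
differential_abundance <- function(dataset,
                                   mode = c("binding", "aggregation", "tpp_aggregation", "pk_activity", "custom"),
                                   conditions = NULL, temperatures = NULL,
                                   test = NULL, alpha = NULL, lfc_cutoff = NULL,
                                   per_temperature = FALSE) {
  mode <- match.arg(mode)
  if (inherits(dataset, "solubility_dataset")) {
    ab <- dataset$abundances
    ids <- unique(ab$protein_id)
    dataset <- peptide_dataset(
      data.frame(protein_id = ids, peptide_id = ids, start = 1L, end = 1L,
                 tryptic_type = "FT", proteotypic = TRUE,
                 stringsAsFactors = FALSE),
      data.frame(peptide_id = ab$protein_id, condition = ab$condition,
                 replicate = ab$replicate, temperature = ab$temperature,
                 intensity = ab$abundance, stringsAsFactors = FALSE),
      grid = dataset$grid)
  }
  grid <- dataset$grid
  ng <- length(grid)
  preset <- switch(mode,
    binding = list(temps = grid[1:2], test = "t", alpha = 0.01, lfc = 1.5),
    aggregation = list(temps = grid[(ng - 1):ng], test = "t", alpha = 0.05, lfc = 1),
    tpp_aggregation = list(temps = grid[(ng - 2):ng], test = "t", alpha = 0.05, lfc = 1),
    pk_activity = list(temps = grid, test = "moderated", alpha = 0.05, lfc = 1),
    custom = list(temps = grid, test = "t", alpha = 0.05, lfc = 1))
  if (is.null(temperatures)) temperatures <- preset$temps
  if (is.null(test)) test <- preset$test
  if (is.null(alpha)) alpha <- preset$alpha
  if (is.null(lfc_cutoff)) lfc_cutoff <- preset$lfc
  if (is.null(conditions)) conditions <- dataset$conditions[1:2]
  ints <- dataset$intensities
  ints <- ints[ints$condition %in% conditions &
               ints$temperature %in% temperatures &
               is.finite(ints$intensity), , drop = FALSE]
  ints$log2_int <- log2(ints$intensity)
  units <- if (per_temperature) {
    split(ints, paste(ints$peptide_id, ints$temperature, sep = "@"))
  } else split(ints, ints$peptide_id)
  rows <- lapply(names(units), function(u) {
    s <- units[[u]]
    a <- s$log2_int[s$condition == conditions[1]]
    b <- s$log2_int[s$condition == conditions[2]]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    data.frame(unit = u, n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               var_a = stats::var(a), var_b = stats::var(b),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0L) stop("no testable units (<2 replicates everywhere)")
  lfc <- rows$mean_b - rows$mean_a
  if (test == "moderated") {
    mt <- moderated_t_table(rows$mean_a, rows$mean_b, rows$var_a, rows$var_b,
                            rows$n_a, rows$n_b)
    p <- mt$p
  } else {
    p <- vapply(seq_len(nrow(rows)), function(i) {
      se2 <- rows$var_a[i] / rows$n_a[i] + rows$var_b[i] / rows$n_b[i]
      if (se2 == 0) return(if (lfc[i] == 0) 1 else 0)
      t <- lfc[i] / sqrt(se2)
      df <- se2^2 / ((rows$var_a[i] / rows$n_a[i])^2 / (rows$n_a[i] - 1) +
                     (rows$var_b[i] / rows$n_b[i])^2 / (rows$n_b[i] - 1))
      if (!is.finite(df) || df <= 0) df <- rows$n_a[i] + rows$n_b[i] - 2
      2 * stats::pt(-abs(t), df)
    }, numeric(1))
  }
  p_adj <- bh_adjust(p)
  hit <- p_adj < alpha & abs(lfc) > lfc_cutoff
  pep_id <- if (per_temperature) sub("@[^@]*$", "", rows$unit) else rows$unit
  out <- data.frame(peptide_id = pep_id, unit = rows$unit, log2_fc = lfc,
                    p = p, p_adj = p_adj, hit = hit,
                    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
                    stringsAsFactors = FALSE)
  rec <- dataset$records
  proteo <- rec$peptide_id[rec$proteotypic]
  hits <- unique(rec$protein_id[match(out$peptide_id[out$hit &
                                                     out$peptide_id %in% proteo],
                                      rec$peptide_id)])
  attr(out, "protein_hits") <- hits
  out
}

# Inverse of the trigamma function (Newton iteration), for the
# method-of-moments prior-df estimate.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Vectorised moderated t over many units with summary statistics.
moderated_t_table <- function(mean_a, mean_b, var_a, var_b, n_a, n_b) {
  df <- n_a + n_b - 2
  s2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / df
  n_units <- length(s2)
  use <- is.finite(s2) & s2 > 0
  if (sum(use) < 10L) {  # too few units: ordinary Welch t
    p <- vapply(seq_len(n_units), function(i) {
      se2 <- var_a[i] / n_a[i] + var_b[i] / n_b[i]
      if (se2 == 0) return(if (mean_a[i] == mean_b[i]) 1 else 0)
      t <- (mean_b[i] - mean_a[i]) / sqrt(se2)
      2 * stats::pt(-abs(t), df[i])
    }, numeric(1))
    return(list(t = NA, p = p, d0 = 0, s0_sq = NA))
  }
  z <- log(s2[use])
  d <- df[use]
  # E[log s^2] = log s0^2 + digamma(d/2) - log(d/2); Var = trigamma(d/2) + trigamma(d0/2)
  ev <- stats::var(z) - mean(trigamma(d / 2))
  d0 <- if (ev > 0) 2 * trigamma_inverse(ev) else Inf
  s0_sq <- exp(mean(z - digamma(d / 2) + log(d / 2)) +
               (if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0))
  if (is.finite(d0)) {
    s2_mod <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_mod <- d0 + df
  } else { s2_mod <- rep(s0_sq, n_units); df_mod <- rep(Inf, n_units) }
  se <- sqrt(s2_mod * (1 / n_a + 1 / n_b))
  t <- (mean_b - mean_a) / se
  p <- 2 * stats::pt(-abs(t), df_mod)
  p[se == 0 & mean_a == mean_b] <- 1
  list(t = t, p = p, d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-test with an empirical-Bayes variance prior
#'
#' Shrinks each unit's pooled variance toward a common prior:
#' `s2_mod = (d0 s0^2 + d s^2) / (d0 + d)` with `d0` and `s0^2` estimated
#' by method of moments on the log variances of all units; the t statistic
#' uses `s2_mod` with `d0 + d` degrees of freedom.  With fewer than 10
#' units the ordinary Welch t-test is used instead.
#'
#' @param group_a,group_b lists of numeric vectors (one element per unit),
#'   or single numeric vectors for a one-unit call.
#' @return data.frame per unit: `t`, `p`, `df`, plus attributes `d0` and
#'   `s0_sq`.
#' @export
moderated_t <- function(group_a, group_b) {
  if (!is.list(group_a)) group_a <- list(group_a)
  if (!is.list(group_b)) group_b <- list(group_b)
  stopifnot(length(group_a) == length(group_b))
  ma <- vapply(group_a, mean, numeric(1)); mb <- vapply(group_b, mean, numeric(1))
  va <- vapply(group_a, stats::var, numeric(1)); vb <- vapply(group_b, stats::var, numeric(1))
  na <- lengths(group_a); nb <- lengths(group_b)
  stopifnot(all(na >= 2), all(nb >= 2))
  res <- moderated_t_table(ma, mb, va, vb, na, nb)
  out <- data.frame(t = if (length(res$t) == 1 && is.na(res$t)) NA_real_ else res$t,
                    p = res$p,
                    df = if (is.finite(res$d0)) res$d0 + na + nb - 2 else Inf)
  attr(out, "d0") <- res$d0
  attr(out, "s0_sq") <- res$s0_sq
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`adj_i = min_{j >= rank(i)} p_(j) m / j`,
#' capped at 1), delegated to [stats::p.adjust()] after validating the
#' input.
#'
#' @param pvalues numeric in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Spearman correlation with a condition-shuffling null
#'
#' For each protein, the Spearman correlation between its stabilization
#' score vector across osmolyte conditions and the across-protein mean
#' vector.  The mean vector excludes the focal protein (leave-one-out):
#' with many proteins this is indistinguishable from the plain mean, but
#' it removes the `1/sqrt(n)` self-correlation bias that would otherwise
#' shift the null distribution on small panels.  The null shuffles every
#' protein's vector across conditions independently and recomputes all
#' correlations; repeated `n_rep` times.
#'
#' @param score_matrix numeric matrix, proteins x conditions (>= 3
#'   conditions), rownames = protein ids.
#' @param n_rep permutation repetitions (default 1000).
#' @param seed integer seed.
#' @return list: `observed` (named vector; constant rows excluded, see
#'   `excluded`), `null` (numeric vector of permuted correlations),
#'   `excluded`.
#' @export
spearman_randomization <- function(score_matrix, n_rep = 1000L, seed = 1L) {
  X <- as.matrix(score_matrix)
  if (ncol(X) < 3L) stop("need at least 3 conditions")
  n <- nrow(X)
  constant <- apply(X, 1, function(r) length(unique(r)) < 2L)
  loo_cor <- function(M) {
    tot <- colSums(M)
    vapply(which(!constant), function(i)
      stats::cor(M[i, ], (tot - M[i, ]) / (n - 1), method = "spearman"),
      numeric(1))
  }
  obs <- stats::setNames(loo_cor(X), rownames(X)[!constant])
  set.seed(seed)
  null <- numeric(0)
  for (b in seq_len(n_rep)) {
    Xp <- t(apply(X, 1, sample))
    null <- c(null, loo_cor(Xp))
  }
  list(observed = obs, null = null, excluded = rownames(X)[constant])
}

#' Compare sequence-feature distributions between protein groups
#'
#' Per feature: two-sided Welch t-test between the test and control
#' groups, Benjamini-Hochberg correction across features, and the mean
#' difference with the control value subtracted from the test group.
#'
#' @param features numeric matrix/data.frame, proteins x features.
#' @param groups factor/character of length nrow(features) with two
#'   levels; the first level (or `control`) is the control group.
#' @param control label of the control group (default: first level).
#' @return data.frame per feature: `delta_mean`, `p`, `p_adj`,
#'   `significant`; features with a group below 3 members are skipped.
#' @export
compare_feature_groups <- function(features, groups, control = NULL) {
  X <- as.matrix(features)
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L)
  if (is.null(control)) control <- lv[1]
  test_lab <- setdiff(lv, control)
  a <- X[groups == control, , drop = FALSE]
  b <- X[groups == test_lab, , drop = FALSE]
  rows <- lapply(colnames(X), function(f) {
    x <- a[, f]; y <- b[, f]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 3L || length(y) < 3L) return(NULL)
    p <- if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else stats::t.test(y, x)$p.value
    data.frame(feature = f, delta_mean = mean(y) - mean(x), p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) stop("no testable features (groups too small)")
  rows$p_adj <- bh_adjust(rows$p)
  rows$significant <- rows$p_adj < 0.05
  rows
}
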
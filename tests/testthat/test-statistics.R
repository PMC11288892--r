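test_that("BH adjustment reproduces the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # direct step-up oracle
  m <- length(p); o <- order(p); adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj))); want <- pmin(adj, 1)[order(o)]
  expect_equal(bh_adjust(p), want, tolerance = 1e-12)
  expect_equal(bh_adjust(p), rep(0.04, 4), tolerance = 1e-12)
  expect_equal(bh_adjust(0.037), 0.037)
  set.seed(1); pp <- runif(50)
  a <- bh_adjust(pp)
  expect_true(all(a >= pp))
  expect_true(all(diff(a[order(pp)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("moderated t falls back to Welch below 10 units and handles degeneracy", {
  a <- c(1.0, 1.2, 0.9); b <- c(2.1, 2.0, 2.3)
  out <- moderated_t(a, b)
  expect_equal(out$p, t.test(b, a)$p.value, tolerance = 1e-12)
  deg <- moderated_t(c(1, 1), c(1, 1))
  expect_equal(deg$p, 1)
})

test_that("moderated t agrees with limma's empirical-Bayes shrinkage", {
  skip_if_not_installed("limma")
  set.seed(77)
  n_units <- 200
  ga <- lapply(seq_len(n_units), function(i) rnorm(3, 0, sqrt(rchisq(1, 4) / 4)))
  gb <- lapply(seq_len(n_units), function(i) rnorm(3, 0, sqrt(rchisq(1, 4) / 4)))
  out <- moderated_t(ga, gb)
  mat <- t(vapply(seq_len(n_units), function(i) c(ga[[i]], gb[[i]]), numeric(6)))
  design <- cbind(1, rep(c(0, 1), each = 3))
  ebfit <- limma::eBayes(limma::lmFit(mat, design))
  expect_gt(cor(out$t, ebfit$t[, 2]), 0.999)
  expect_gt(cor(out$p, ebfit$p.value[, 2]), 0.99)
  # prior df in the same ballpark as limma's estimate
  expect_equal(log(attr(out, "d0")), log(ebfit$df.prior), tolerance = 0.5)
})

test_that("null moderated-t p-values are approximately uniform", {
  set.seed(123)
  n_units <- 1000
  ga <- lapply(seq_len(n_units), function(i) rnorm(3, 0, sqrt(rchisq(1, 6) / 6)))
  gb <- lapply(seq_len(n_units), function(i) rnorm(3, 0, sqrt(rchisq(1, 6) / 6)))
  out <- moderated_t(ga, gb)
  ks <- suppressWarnings(ks.test(out$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("differential abundance finds only the truly changed peptide", {
  set.seed(3)
  grid <- lip_grid()
  mk <- function(id, mu) do.call(rbind, lapply(1:2, function(r)
    data.frame(peptide_id = id, condition = rep(c("control", "osmolyte"), each = 10),
               replicate = r, temperature = grid,
               intensity = exp(rnorm(20, log(mu), 0.07)) *
                 rep(c(1, ifelse(id == "pep01", 4, 1)), each = 10))))
  ints <- do.call(rbind, lapply(sprintf("pep%02d", 1:12), mk, mu = 1e5))
  rec <- data.frame(protein_id = sprintf("prot%02d", 1:12),
                    peptide_id = sprintf("pep%02d", 1:12),
                    start = 1, end = 10, tryptic_type = "FT")
  ds <- peptide_dataset(rec, ints)
  out <- differential_abundance(ds, mode = "binding")
  expect_equal(out$peptide_id[out$hit], "pep01")
  # oracle: direct pooled t-test + BH for the hit peptide
  sub <- ints[ints$peptide_id == "pep01" & ints$temperature %in% grid[1:2], ]
  p_want <- t.test(log2(sub$intensity[sub$condition == "osmolyte"]),
                   log2(sub$intensity[sub$condition == "control"]))$p.value
  expect_equal(out$p[out$peptide_id == "pep01"], p_want, tolerance = 1e-10)
  expect_true("prot01" %in% attr(out, "protein_hits"))
})

test_that("identical conditions yield no hits and exact cutoffs are strict", {
  grid <- lip_grid()
  ints <- do.call(rbind, lapply(sprintf("p%02d", 1:6), function(id)
    do.call(rbind, lapply(1:2, function(r)
      data.frame(peptide_id = id, condition = rep(c("a", "b"), each = 10),
                 replicate = r, temperature = grid,
                 intensity = rep(c(100, 110), 10))))))
  rec <- data.frame(protein_id = sprintf("pr%02d", 1:6),
                    peptide_id = sprintf("p%02d", 1:6),
                    start = 1, end = 10, tryptic_type = "FT")
  ds <- peptide_dataset(rec, ints)
  out <- differential_abundance(ds, mode = "binding", conditions = c("a", "b"))
  expect_equal(sum(out$hit), 0L)
  # |log2FC| exactly at the cutoff is not a hit (strict >)
  ints2 <- ints
  sel <- ints2$condition == "b"
  ints2$intensity[sel] <- ints2$intensity[sel] * 2^1.5
  ds2 <- peptide_dataset(rec, ints2)
  out2 <- differential_abundance(ds2, mode = "binding", conditions = c("a", "b"))
  expect_equal(max(abs(out2$log2_fc)), 1.5, tolerance = 1e-9)
  expect_equal(sum(out2$hit), 0L)
})

test_that("null-experiment FDR is zero without noise and bounded with it", {
  specs <- sim_protein_specs(6, n_peptides = 4L)
  nds0 <- simulate_null_experiment(specs, sim_noise_model(sigma = 0, missing_rate = 0),
                                   seed = 5)
  f0 <- estimate_null_fdr(nds0, seed = 2)
  expect_equal(f0$peptide, 0)
  expect_equal(f0$protein, 0)
})

test_that("quantile sweep returns 0.5 for a trivial target and respects bounds", {
  specs <- sim_protein_specs(8, n_peptides = 4L)
  nds <- simulate_null_experiment(specs, sim_noise_model(sigma = 0.05), seed = 17)
  fit <- lip_stability(nds, "null_A", "null_B", seed = 2)
  sw <- sweep_quantile(fit, target = 1.0)
  expect_equal(sw$q, 0.5)
  sw2 <- sweep_quantile(fit, target = 0.05)
  expect_true(sw2$q >= 0.5 && sw2$q <= 1)
  # FDR non-increasing in the stabilized-side quantile
  expect_true(all(diff(sw$table$fdr) <= 1e-12))
})

test_that("spearman randomization behaves on proportional, constant and null rows", {
  set.seed(10)
  X <- matrix(rnorm(150), 30, 5,
              dimnames = list(sprintf("pr%02d", 1:30), LETTERS[1:5]))
  X[2, ] <- 7                       # constant -> excluded
  out <- spearman_randomization(X, n_rep = 200, seed = 3)
  expect_false("pr02" %in% names(out$observed))
  expect_equal(out$excluded, "pr02")
  expect_lt(abs(mean(out$null)), 0.05)   # permutation oracle: centred null
  # a row proportional to the mean of the others correlates perfectly
  prop <- rbind(X, dbl = 2 * colMeans(X))
  out2 <- spearman_randomization(prop, n_rep = 10, seed = 1)
  expect_equal(unname(out2$observed["dbl"]), 1, tolerance = 1e-12)
  expect_error(spearman_randomization(X[, 1:2], n_rep = 10, seed = 1), "3 conditions")
})

test_that("sequence features match hand-computed values", {
  f <- sequence_features("KKKK")
  expect_gt(f[["charge_ph7.5"]], 0)
  expect_equal(f[["pct_K"]], 100)
  expect_gt(f[["pi"]], 7)
  expect_lt(sequence_features("DDDD")[["pi"]], 7)
  # Kyte-Doolittle GRAVY of AILV: mean of 1.8, 4.5, 3.8, 4.2
  expect_equal(sequence_features("AILV")[["gravy"]], mean(c(1.8, 4.5, 3.8, 4.2)),
               tolerance = 1e-12)
  expect_warning(sequence_features("AAXA"), "non-standard")
})

test_that("feature-group comparison is signed test-minus-control with BH", {
  set.seed(6)
  n <- 12
  feat <- cbind(shifted = c(rnorm(n, 0, 0.5), rnorm(n, 3 * 0.5, 0.5)),
                nullf = rnorm(2 * n))
  groups <- rep(c("control", "stabilized"), each = n)
  out <- compare_feature_groups(feat, groups, control = "control")
  sh <- out[out$feature == "shifted", ]
  expect_true(sh$significant)
  expect_gt(sh$delta_mean, 0)
  # oracle t-test and label-swap antisymmetry
  p_want <- t.test(feat[groups == "stabilized", "shifted"],
                   feat[groups == "control", "shifted"])$p.value
  expect_equal(sh$p, p_want, tolerance = 1e-12)
  swapped <- compare_feature_groups(feat, groups, control = "stabilized")
  expect_equal(swapped$delta_mean, -out$delta_mean, tolerance = 1e-12)
  same <- compare_feature_groups(cbind(x = rnorm(2 * n, 5, 0.1)),
                                 groups)
  expect_false(any(same$significant))
})
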
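test_that("identical curves and everywhere-overlapping bands score zero", {
  g <- scoring_grid()
  prof <- sigmoid_profile(g, 55)
  a <- toy_curve(g, prof)
  expect_equal(nrow(nonoverlap_intervals(a, a)), 0L)
  b <- toy_curve(g, prof + 0.005, half = 0.02)   # bands overlap everywhere
  expect_equal(nrow(nonoverlap_intervals(a, b)), 0L)
  ps <- peptide_score(a, a, group = "decreasing")
  expect_identical(ps$score, 0)
  expect_error(nonoverlap_intervals(a, toy_curve(clustering_grid(),
                                                 rep(0, 20))), "grid")
})

test_that("constant separation integrates to separation x gradient span", {
  g <- scoring_grid()
  a <- toy_curve(g, rep(0.2, length(g)), half = 0.1)
  b <- toy_curve(g, rep(0.7, length(g)), half = 0.1)
  iv <- nonoverlap_intervals(a, b)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$t_start, 37); expect_equal(iv$t_end, 76)
  # numerical integration oracle
  step <- diff(g)[1]
  expect_equal(iv$area, sum(b$mean - a$mean) * step, tolerance = 1e-12)
  expect_equal(iv$area, 0.5 * (76 - 37), tolerance = 0.02 * 19.5)
})

test_that("interval classes follow the gradient-anchored boundaries", {
  expect_equal(classify_interval(c(37, 40.5)), "binding")
  expect_equal(classify_interval(c(72.5, 76)), "aggregation")
  expect_equal(classify_interval(c(50, 60)), "stabilization")
})

test_that("a rightward melting shift scores ~ the shift for any profile direction", {
  g <- scoring_grid()
  f0 <- sigmoid_profile(g, 54); f4 <- sigmoid_profile(g, 58)
  dec <- peptide_score(toy_curve(g, f0), toy_curve(g, f4), group = "decreasing")
  expect_equal(dec$score, 4, tolerance = 0.05 * 4)
  # numerical-integration oracle over the region where the 0.01-half-width
  # bands are disjoint (difference > 0.02)
  idx <- (f4 - f0) > 0.02
  area_oracle <- sum((f4 - f0)[idx]) * diff(g)[1]
  expect_equal(dec$score, area_oracle, tolerance = 1e-9)
  inc <- peptide_score(toy_curve(g, 1 - f0), toy_curve(g, 1 - f4),
                       group = "increasing")
  expect_gt(inc$score, 0)                       # sign flipped back positive
  expect_equal(inc$score, dec$score, tolerance = 1e-9)
  left <- peptide_score(toy_curve(g, f4), toy_curve(g, f0), group = "decreasing")
  expect_lt(left$score, 0)                      # destabilization
  expect_equal(left$score, -dec$score, tolerance = 1e-9)   # antisymmetry
})

test_that("nonmonotonous peptides take their sign from the local control slope", {
  g <- scoring_grid()
  f0 <- sigmoid_profile(g, 54); f4 <- sigmoid_profile(g, 58)
  dec_like <- peptide_score(toy_curve(g, f0), toy_curve(g, f4),
                            group = "nonmonotonous")
  expect_gt(dec_like$score, 0)   # decreasing control slope -> s = +1
  inc_like <- peptide_score(toy_curve(g, 1 - f0), toy_curve(g, 1 - f4),
                            group = "nonmonotonous")
  expect_gt(inc_like$score, 0)   # increasing slope -> s = -1, area < 0
})

test_that("halving the scoring-grid step moves scores by < 2%", {
  for (tm in c(50, 58)) {
    s1 <- peptide_score(toy_curve(scoring_grid(0.5), sigmoid_profile(scoring_grid(0.5), tm)),
                        toy_curve(scoring_grid(0.5), sigmoid_profile(scoring_grid(0.5), tm + 3)),
                        group = "decreasing")$score
    s2 <- peptide_score(toy_curve(scoring_grid(0.25), sigmoid_profile(scoring_grid(0.25), tm)),
                        toy_curve(scoring_grid(0.25), sigmoid_profile(scoring_grid(0.25), tm + 3)),
                        group = "decreasing")$score
    expect_lt(abs(s1 - s2) / abs(s1), 0.02)
  }
})

test_that("weighted quantile matches its definition and invariances", {
  expect_equal(weighted_quantile(rep(3.2, 5), rep(1, 5), c(0, 0.4, 1)),
               rep(3.2, 3))
  # equal weights {1,2,3,4}: frozen via the repetition-expansion oracle
  expect_equal(weighted_quantile(c(1, 2, 3, 4), rep(1, 4), 0.75),
               expansion_quantile(c(1, 2, 3, 4), rep(1L, 4), 0.75))
  v <- c(2, 7, 1, 9); w <- c(0.5, 1.5, 2, 1)
  expect_equal(weighted_quantile(v, w, 0.6), weighted_quantile(v, 2 * w, 0.6))
  expect_error(weighted_quantile(1:3, c(1, 0, 1), 0.5), "positive")
  expect_error(weighted_quantile(numeric(0), numeric(0), 0.5), "non-empty")
})

test_that("weighted quantile equals repetition expansion on random rational weights", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    v <- round(rnorm(n), 2)
    iw <- sample(1:9, n, replace = TRUE)
    q <- runif(1)
    expect_identical(weighted_quantile(v, iw / 3, q),   # rational weights
                     expansion_quantile(v, iw, q))
  }
})

test_that("residue rollup picks the quantile branch from the mean sign", {
  one <- data.frame(protein_id = "A", start = 5, end = 8, score = 2.5, weight = 1)
  rs <- residue_scores(one)
  expect_equal(nrow(rs), 4L)
  expect_true(all(rs$score == 2.5))
  over <- data.frame(protein_id = "A", start = c(1, 1, 1), end = c(3, 3, 3),
                     score = c(1, 2, 3), weight = c(1, 1, 1))
  rs2 <- residue_scores(over)
  expect_equal(unique(rs2$score),
               expansion_quantile(c(1, 2, 3), c(1L, 1L, 1L), 0.75))
  neg <- data.frame(protein_id = "A", start = c(1, 1), end = c(2, 2),
                    score = c(-1, -2), weight = c(1, 1))
  rs3 <- residue_scores(neg)
  expect_equal(unique(rs3$score),
               expansion_quantile(c(-2, -1), c(1L, 1L), 0.25))   # 0.25 branch
})

test_that("protein rollup matches a brute-force two-stage recomputation", {
  set.seed(14)
  peps <- data.frame(
    protein_id = rep(c("A", "B"), each = 5),
    start = sample(1:30, 10, replace = TRUE), score = round(rnorm(10), 2),
    weight = runif(10, 0.5, 2))
  peps$end <- peps$start + sample(8:20, 10, replace = TRUE)
  rs <- residue_scores(peps)
  ps <- protein_score(rs)
  # oracle: independent two-stage recomputation straight from the peptide table
  for (prot in c("A", "B")) {
    pp <- peps[peps$protein_id == prot, ]
    pos_scores <- c(); pos_w <- c()
    for (pos in min(pp$start):max(pp$end)) {
      cov <- pp$start <= pos & pos <= pp$end
      if (!any(cov)) next
      qq <- if (mean(pp$score[cov]) >= 0) 0.75 else 0.25
      o <- order(pp$score[cov])
      vv <- pp$score[cov][o]; ww <- pp$weight[cov][o]
      cw <- cumsum(ww)
      pos_scores <- c(pos_scores, vv[which(cw >= qq * sum(ww) - 1e-12)[1]])
      pos_w <- c(pos_w, mean(pp$weight[cov]))
    }
    qq <- if (mean(pos_scores) >= 0) 0.75 else 0.25
    o <- order(pos_scores)
    vv <- pos_scores[o]; ww <- pos_w[o]; cw <- cumsum(ww)
    want <- vv[which(cw >= qq * sum(ww) - 1e-12)[1]]
    expect_equal(ps$score[ps$protein_id == prot], want, tolerance = 1e-12)
  }
  zero <- protein_score(data.frame(protein_id = "Z", position = 1:5,
                                   score = 0, mean_weight = 1))
  expect_equal(zero$score, 0); expect_equal(zero$direction, "none")
  allv <- protein_score(data.frame(protein_id = "V", position = 1:5,
                                   score = 1.3, mean_weight = 1))
  expect_equal(allv$score, 1.3); expect_equal(allv$direction, "stabilized")
})

test_that("binder score scaling follows the printed 0.7/0.25 formula", {
  s <- c(1, 2, 3, 4, 5)
  scaled <- scaled_binder_score(s)
  denom <- quantile(s, 0.7, names = FALSE) - quantile(s, 0.25, names = FALSE)
  expect_equal(scaled[5], (5 - median(s)) / denom, tolerance = 1e-12)
  expect_equal(scaled[3], 0)    # the median scores 0
  shifted <- scaled_binder_score(s + 10)
  expect_equal(scaled, shifted, tolerance = 1e-12)  # translation-invariant
  expect_error(scaled_binder_score(c(1, 2, 3)), "at least 4")
  expect_error(scaled_binder_score(rep(1, 5)), "zero")
})

test_that("domain tests follow the membership and >=2x>=3 rules", {
  doms <- data.frame(protein_id = "A", domain_id = c("d1", "d2"),
                     start = c(20, 60), end = c(50, 100))
  # single shared residue counts as membership
  peps <- data.frame(protein_id = "A",
                     start = c(10, 25, 30, 55, 70, 80),
                     end = c(20, 35, 45, 65, 78, 95),
                     score = c(5.1, 4.9, 5.0, 0.05, -0.02, 0.01))
  out <- domain_differential(peps, doms)
  expect_equal(out$n_domains, 2L)
  # oracle: direct t-test on the same grouping
  p_want <- t.test(c(5.1, 4.9, 5.0), c(0.05, -0.02, 0.01))$p.value
  expect_equal(out$p, p_want, tolerance = 1e-12)
  expect_true(out$significant)
  # protein failing the >=3-per-domain rule is excluded silently
  out2 <- domain_differential(peps[-1, ], doms)
  expect_equal(nrow(out2), 0L)
})

test_that("identical domain distributions are not called at small n", {
  set.seed(8)
  doms <- data.frame(protein_id = "A", domain_id = c("d1", "d2"),
                     start = c(1, 51), end = c(50, 100))
  peps <- data.frame(protein_id = "A",
                     start = c(5, 15, 25, 55, 65, 75),
                     end = c(12, 22, 32, 62, 72, 82),
                     score = rnorm(6, 1, 0.3))
  out <- domain_differential(peps, doms)
  expect_false(out$significant)
})
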
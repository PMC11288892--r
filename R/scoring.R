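# Stabilization scoring: confidence-band non-overlap intervals between the
# control and osmolyte curves, signed-area peptide scores, and weighted
# quantile rollup to residue and protein level.

#' Find confidence-band non-overlap intervals between two curves
#'
#' Maximal runs of consecutive grid points where the two curves' 2-sd bands
#' are disjoint.  The distance at non-overlap points is
#' `mean_trt - mean_ctl` (0 elsewhere); the signed area of an interval is
#' the spacing-weighted Riemann sum of those distances (degC x scaled
#' intensity), so scores are stable under grid refinement.
#'
#' @param curve_ctl,curve_trt `profile_curve` objects on the same grid.
#' @param boundaries length-2 numeric: interval-class boundaries
#'   (default `c(44.4, 68.6)`, the 3rd and 8th gradient temperatures).
#' @return data.frame with columns `t_start`, `t_end`, `area`, `class`
#'   (zero rows if the bands always overlap).
#' @export
nonoverlap_intervals <- function(curve_ctl, curve_trt,
                                 boundaries = c(44.4, 68.6)) {
  if (!isTRUE(all.equal(curve_ctl$grid, curve_trt$grid))) {
    stop("curves must be evaluated on the same grid")
  }
  grid <- curve_ctl$grid
  disjoint <- curve_ctl$upper < curve_trt$lower | curve_trt$upper < curve_ctl$lower
  if (!any(disjoint)) {
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      area = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  }
  rl <- rle(disjoint)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  step <- mean(diff(grid))
  out <- lapply(which(keep), function(j) {
    idx <- starts[j]:ends[j]
    data.frame(t_start = grid[idx[1]], t_end = grid[idx[length(idx)]],
               area = sum(curve_trt$mean[idx] - curve_ctl$mean[idx]) * step,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$class <- vapply(seq_len(nrow(out)), function(j)
    classify_interval(c(out$t_start[j], out$t_end[j]), boundaries), character(1))
  out
}

#' Classify a non-overlap interval by its gradient position
#'
#' By midpoint: below the first boundary (default 44.4 degC) the change is
#' a `binding` effect (native-state change at low temperature); above the
#' second boundary (default 68.6 degC) an `aggregation` effect; otherwise
#' `stabilization` (a shift of the unfolding transition).
#'
#' @param interval length-2 numeric `c(t_start, t_end)` in degC.
#' @param boundaries length-2 numeric class boundaries.
#' @return one of `"binding"`, `"stabilization"`, `"aggregation"`.
#' @export
classify_interval <- function(interval, boundaries = c(44.4, 68.6)) {
  mid <- mean(interval[1:2])
  if (mid < boundaries[1]) "binding"
  else if (mid > boundaries[2]) "aggregation"
  else "stabilization"
}

#' Peptide-level stabilization score
#'
#' Among the stabilization-class non-overlap intervals, the one with
#' maximal |area| defines the score.  The sign is corrected by the
#' peptide's shape group so that a rightward melting shift is always
#' positive: `s = +1` for decreasing profiles, `-1` for increasing ones;
#' for nonmonotonous profiles the sign follows the local slope of the
#' control curve over the chosen interval (negative slope behaves like a
#' decreasing profile).
#'
#' @param curve_ctl,curve_trt `profile_curve` objects (same grid).
#' @param intervals output of [nonoverlap_intervals()]; computed if `NULL`.
#' @param group shape group of the peptide (`"decreasing"`, `"increasing"`
#'   or `"nonmonotonous"`).
#' @param rss_ctl,rss_trt residual sums of squares of the two fits (for
#'   the fit weight `w = 1 / (eps + rss_ctl + rss_trt)`).
#' @param eps ridge constant in the fit weight.
#' @param boundaries interval-class boundaries.
#' @return list of class `peptide_score`: `score` (0 when no
#'   stabilization-class interval exists), `interval`, `weight`, `group`.
#' @export
peptide_score <- function(curve_ctl, curve_trt, intervals = NULL,
                          group = "decreasing", rss_ctl = 0, rss_trt = 0,
                          eps = 1e-3, boundaries = c(44.4, 68.6)) {
  if (is.null(intervals)) {
    intervals <- nonoverlap_intervals(curve_ctl, curve_trt, boundaries)
  }
  w <- 1 / (eps + rss_ctl + rss_trt)
  stab <- intervals[intervals$class == "stabilization", , drop = FALSE]
  if (nrow(stab) == 0L) {
    return(structure(list(score = 0, interval = NULL, weight = w,
                          group = group), class = "peptide_score"))
  }
  best <- stab[which.max(abs(stab$area)), , drop = FALSE]
  s <- switch(group,
              decreasing = 1,
              increasing = -1,
              nonmonotonous = {
                idx <- curve_ctl$grid >= best$t_start & curve_ctl$grid <= best$t_end
                sl <- mean(diff(curve_ctl$mean[idx]) / diff(curve_ctl$grid[idx]))
                if (!is.finite(sl) || sl <= 0) 1 else -1
              },
              stop("unknown shape group: ", group))
  structure(list(score = best$area * s,
                 interval = c(best$t_start, best$t_end),
                 weight = w, group = group), class = "peptide_score")
}

#' Weighted quantile (inverse weighted empirical CDF)
#'
#' Values are sorted and the cumulative weights `cum_i / W` define the
#' empirical CDF; the q-quantile is the smallest value whose cumulative
#' weight reaches `q W` (left-continuous step function, the weighted
#' analogue of the type-1 sample quantile).  This estimator is exactly
#' invariant under rescaling all weights and under splitting any weight
#' into parts at the same value, so expanding rational weights into unit
#' repetitions reproduces it exactly — the property the rollup's FDR
#' calibration relies on.  In particular the quantile of a mostly-zero
#' score set is exactly 0 until the quantile crosses the nonzero mass.
#'
#' @param values numeric, non-empty.
#' @param weights positive weights (error on any weight <= 0).
#' @param q quantile in [0, 1] (vectorised).
#' @return numeric of length `length(q)`.
#' @export
weighted_quantile <- function(values, weights, q) {
  if (!length(values)) stop("values must be non-empty")
  stopifnot(length(values) == length(weights), all(q >= 0 & q <= 1))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("all weights must be positive")
  }
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  W <- cw[length(cw)]
  vapply(q, function(qq) {
    # tolerance keeps cum >= qW robust to cumulative-sum roundoff
    v[which(cw >= qq * W - 1e-9 * W)[1L]]
  }, numeric(1))
}

#' Roll peptide scores up to residue level
#'
#' For each protein position covered by at least one scored peptide: the
#' mean of the covering peptide scores decides the direction; the residue
#' score is the weighted 0.75 quantile of the covering scores for a
#' stabilized position (mean > 0) or the weighted 0.25 quantile for a
#' destabilized one, using the peptides' fit weights.  The mean fit weight
#' per position is carried along for the protein-level rollup.
#'
#' @param peptides data.frame with columns `protein_id`, `start`, `end`,
#'   `score`, `weight`.
#' @param q_pair length-2 numeric: quantiles for (stabilized, destabilized)
#'   positions.
#' @return data.frame `protein_id`, `position`, `score`, `mean_weight`.
#' @export
residue_scores <- function(peptides, q_pair = c(0.75, 0.25)) {
  out <- list()
  for (prot in unique(peptides$protein_id)) {
    pp <- peptides[peptides$protein_id == prot, , drop = FALSE]
    pos_range <- min(pp$start):max(pp$end)
    for (pos in pos_range) {
      cov <- pp$start <= pos & pos <= pp$end
      if (!any(cov)) next
      sc <- pp$score[cov]; w <- pp$weight[cov]
      m <- mean(sc)
      qq <- if (m >= 0) q_pair[1] else q_pair[2]
      out[[length(out) + 1L]] <- data.frame(
        protein_id = prot, position = pos,
        score = weighted_quantile(sc, w, qq),
        mean_weight = mean(w), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(), position = integer(),
                      score = numeric(), mean_weight = numeric()))
  }
  do.call(rbind, out)
}

#' Roll residue scores up to protein level
#'
#' The mean of a protein's residue scores decides the direction; the
#' protein score is the weighted 0.75 (stabilized) or 0.25 (destabilized)
#' quantile of the residue scores, weighted by the mean fit weight at each
#' position.  The quantile pair is configurable (it is swept during FDR
#' calibration).
#'
#' @param residues output of [residue_scores()].
#' @param q_pair quantiles for (stabilized, destabilized) proteins.
#' @return data.frame `protein_id`, `score`, `direction`
#'   (`"stabilized"` / `"destabilized"` / `"none"`).
#' @export
protein_score <- function(residues, q_pair = c(0.75, 0.25)) {
  out <- lapply(split(residues, residues$protein_id), function(rr) {
    m <- mean(rr$score)
    qq <- if (m >= 0) q_pair[1] else q_pair[2]
    s <- weighted_quantile(rr$score, rr$mean_weight, qq)
    data.frame(protein_id = rr$protein_id[1], score = s,
               direction = if (s > 0) "stabilized" else if (s < 0) "destabilized" else "none",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scale peptide stabilization scores for binder comparison
#'
#' `scaled = (score - median(scores)) / (quantile(scores, 0.7) -
#' quantile(scores, 0.25))`, computed within one osmolyte dataset over its
#' significant peptide scores, so stabilization strength is comparable
#' across osmolytes.
#'
#' @param scores significant peptide stabilization scores of one dataset
#'   (>= 4 values).
#' @return numeric vector of scaled scores.
#' @export
scaled_binder_score <- function(scores) {
  if (length(scores) < 4L) stop("need at least 4 significant peptide scores")
  denom <- stats::quantile(scores, 0.7, names = FALSE) -
    stats::quantile(scores, 0.25, names = FALSE)
  if (denom == 0) stop("zero interquantile range; scores cannot be scaled")
  (scores - stats::median(scores)) / denom
}

#' Domain-level differential stabilization
#'
#' Tests, per protein, whether peptide stabilization scores differ between
#' annotated domains.  A peptide belongs to a domain when at least one of
#' its residues lies in the domain range.  Proteins need >= 2 domains with
#' >= 3 mapped peptides each; two domains are compared by a two-sample
#' t-test, more by one-way ANOVA, with Benjamini-Hochberg correction
#' across proteins.
#'
#' @param peptides data.frame `protein_id`, `start`, `end`, `score`.
#' @param domains validated domain table (see [read_domain_annotation()]).
#' @param alpha significance level on the adjusted p-value.
#' @return data.frame `protein_id`, `n_domains`, `p`, `p_adj`,
#'   `significant`.
#' @export
domain_differential <- function(peptides, domains, alpha = 0.05) {
  domains <- validate_domains(domains)
  res <- list()
  for (prot in intersect(unique(peptides$protein_id), unique(domains$protein_id))) {
    pp <- peptides[peptides$protein_id == prot, , drop = FALSE]
    dd <- domains[domains$protein_id == prot, , drop = FALSE]
    groups <- list()
    for (j in seq_len(nrow(dd))) {
      member <- pp$start <= dd$end[j] & pp$end >= dd$start[j]
      if (sum(member) >= 3L) groups[[dd$domain_id[j]]] <- pp$score[member]
    }
    if (length(groups) < 2L) next
    p <- if (length(groups) == 2L) {
      stats::t.test(groups[[1]], groups[[2]])$p.value
    } else {
      sc <- unlist(groups, use.names = FALSE)
      g <- factor(rep(names(groups), lengths(groups)))
      summary(stats::aov(sc ~ g))[[1]][["Pr(>F)"]][1]
    }
    res[[length(res) + 1L]] <- data.frame(
      protein_id = prot, n_domains = length(groups), p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(protein_id = character(), n_domains = integer(),
                      p = numeric(), p_adj = numeric(), significant = logical()))
  }
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out
}
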
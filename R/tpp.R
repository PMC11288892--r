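# TPP (thermal proteome profiling) companion analysis: soluble-fraction
# melting profiles analysed with the same GP + band-non-overlap scoring as
# peptide-level LiP data, precipitator classification, and LiP/TPP
# agreement.

#' Stabilization analysis of TPP soluble-fraction profiles
#'
#' Each protein's scaled soluble-fraction series is processed like a
#' single peptide: min-max scaled pooled over both conditions, GP-fitted
#' per condition, and scored by confidence-band non-overlap.  No
#' residue/protein rollup is involved (one profile per protein); the sign
#' comes from the shape of the fitted control curve, classified by the
#' same endpoint rule used for cluster grouping.
#'
#' @param dataset a `solubility_dataset` (see
#'   [protein_solubility_dataset()]).
#' @param conditions length-2: (control, osmolyte).
#' @param min_obs,grid_step,eps,boundaries as in [lip_stability()].
#' @return data.frame per protein: `score`, `stabilized` (nonzero score
#'   with a mid-gradient interval), `group`, `t_start`, `t_end`.
#' @export
tpp_analysis <- function(dataset, conditions = NULL, min_obs = 8L,
                         grid_step = 0.5, eps = 1e-3,
                         boundaries = c(44.4, 68.6)) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (is.null(conditions)) conditions <- dataset$conditions[1:2]
  ab <- dataset$abundances
  ab <- ab[ab$condition %in% conditions, , drop = FALSE]
  sg <- scoring_grid(grid_step)
  rows <- list()
  for (prot in unique(ab$protein_id)) {
    s <- ab[ab$protein_id == prot, , drop = FALSE]
    s1 <- s[s$condition == conditions[1], , drop = FALSE]
    s2 <- s[s$condition == conditions[2], , drop = FALSE]
    names(s1)[names(s1) == "abundance"] <- "intensity"
    names(s2)[names(s2) == "abundance"] <- "intensity"
    if (!enough_observations(s1, dataset$grid, min_obs) ||
        !enough_observations(s2, dataset$grid, min_obs)) next
    sc <- scale_profile(c(s1$intensity, s2$intensity))
    if (isTRUE(attr(sc, "constant"))) next
    v1 <- sc[seq_len(nrow(s1))]; v2 <- sc[nrow(s1) + seq_len(nrow(s2))]
    g1 <- fit_gp(s1$temperature[is.finite(v1)], v1[is.finite(v1)])
    g2 <- fit_gp(s2$temperature[is.finite(v2)], v2[is.finite(v2)])
    if (isTRUE(g1$unfit) || isTRUE(g2$unfit)) next
    c1 <- predict(g1, sg); c2 <- predict(g2, sg)
    grp <- group_clusters(matrix(c1$mean, nrow = 1))
    ps <- peptide_score(c1, c2, group = grp, rss_ctl = g1$rss,
                        rss_trt = g2$rss, eps = eps, boundaries = boundaries)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = prot, score = ps$score, stabilized = ps$score > 0,
      group = grp,
      t_start = if (is.null(ps$interval)) NA_real_ else ps$interval[1],
      t_end = if (is.null(ps$interval)) NA_real_ else ps$interval[2],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Classify a protein as precipitator or nonprecipitator
#'
#' A protein is a nonprecipitator when, at the highest gradient
#' temperature, more than 50% of its 37-degC soluble abundance remains in
#' the soluble fraction (mean over replicates of the control condition;
#' strictly greater than 0.5).
#'
#' @param dataset a `solubility_dataset`.
#' @param condition condition to assess (default the first).
#' @return named logical vector: `TRUE` = nonprecipitator; proteins
#'   missing the top temperature are dropped.
#' @export
classify_precipitator <- function(dataset, condition = NULL) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (is.null(condition)) condition <- dataset$conditions[1]
  ab <- dataset$abundances
  tmax <- max(dataset$grid)
  ab <- ab[ab$condition == condition & ab$temperature == tmax &
           is.finite(ab$abundance), , drop = FALSE]
  if (!nrow(ab)) return(stats::setNames(logical(0), character(0)))
  m <- tapply(ab$abundance, ab$protein_id, mean)
  stats::setNames(as.vector(m) > 0.5, names(m))
}

#' Agreement between LiP and TPP stabilization calls
#'
#' Restricted to proteins classified as precipitators in TPP and present
#' in both call sets, returns the fractions of proteins called stabilized
#' by both methods, neither, only LiP, or only TPP (summing to 1).
#'
#' @param lip_calls,tpp_calls named logical vectors (stabilized yes/no).
#' @param nonprecipitator named logical from [classify_precipitator()];
#'   proteins with `TRUE` are excluded.
#' @return named numeric: `both`, `none`, `only_lip`, `only_tpp`, with an
#'   `n` attribute.
#' @export
lip_tpp_agreement <- function(lip_calls, tpp_calls, nonprecipitator = NULL) {
  ids <- intersect(names(lip_calls), names(tpp_calls))
  if (!is.null(nonprecipitator)) {
    ids <- setdiff(ids, names(nonprecipitator)[nonprecipitator])
  }
  if (!length(ids)) stop("no shared precipitator proteins between the call sets")
  l <- lip_calls[ids]; t <- tpp_calls[ids]
  out <- c(both = mean(l & t), none = mean(!l & !t),
           only_lip = mean(l & !t), only_tpp = mean(!l & t))
  attr(out, "n") <- length(ids)
  out
}
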
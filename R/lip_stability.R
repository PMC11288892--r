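#' Fit the osmolyte stabilization model to a LiP-MS thermal dataset
#'
#' The main entry point.  Runs the full analysis: per-peptide min-max
#' scaling pooled over conditions, exact-GP thermal profile fits per
#' condition, entropy-regularised fuzzy clustering of the control profiles
#' into shape groups (decreasing / increasing / nonmonotonous), confidence
#' band non-overlap scoring between the condition curves, and weighted
#' quantile rollup of peptide scores to residue and protein level.
#'
#' @param dataset a [peptide_dataset()].
#' @param control,treatment condition labels; defaults to the dataset's two
#'   conditions in order.
#' @param k,fuzzy_p clustering parameters (defaults 20 clusters, entropy
#'   degree 2).
#' @param q_pair rollup quantile pair for (stabilized, destabilized).
#' @param grid_step scoring-grid spacing in degC.
#' @param min_obs minimum quantified gradient temperatures per condition
#'   for a peptide to be fitted.
#' @param eps ridge constant of the fit weight `1/(eps + rss_ctl + rss_trt)`.
#' @param boundaries interval-class temperature boundaries.
#' @param seed seed for the clustering initialisations.
#' @param shape_change also run the joint (both-condition) clustering and
#'   flag peptides whose shape group changes (slower).
#' @param joint_diagnostic see [fit_thermal_profiles()].
#' @return object of class `lip_stability` with components
#'   `peptide_scores`, `residue_scores`, `protein_scores` (data.frames),
#'   `fits` (`profile_fits`), `clusters` (`profile_clusters`), the cluster
#'   `groups`, and the call configuration.
#' @seealso [estimate_null_fdr()], [sweep_quantile()], [simulate_lip_experiment()]
#' @export
lip_stability <- function(dataset, control = NULL, treatment = NULL,
                          k = 20L, fuzzy_p = 2, q_pair = c(0.75, 0.25),
                          grid_step = 0.5, min_obs = 8L, eps = 1e-3,
                          boundaries = c(44.4, 68.6), seed = 1L,
                          shape_change = FALSE, joint_diagnostic = FALSE) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  if (is.null(control)) control <- dataset$conditions[1]
  if (is.null(treatment)) treatment <- setdiff(dataset$conditions, control)[1]
  conditions <- c(control, treatment)
  fits <- fit_thermal_profiles(dataset, conditions, min_obs = min_obs,
                               joint_diagnostic = joint_diagnostic)
  fitted_ids <- fits$table$peptide_id[fits$table$fitted]
  if (length(fitted_ids) < 2L) stop("fewer than 2 peptides could be fitted")
  cg <- clustering_grid()
  sg <- scoring_grid(grid_step)
  ctl_curves <- lapply(fitted_ids, function(id) predict(fits$fits[[id]]$ctl, sg))
  trt_curves <- lapply(fitted_ids, function(id) predict(fits$fits[[id]]$trt, sg))
  names(ctl_curves) <- names(trt_curves) <- fitted_ids
  # control-profile clustering for the sign-giving shape group
  cl_feats <- t(vapply(fitted_ids, function(id)
    predict(fits$fits[[id]]$ctl, cg)$mean, numeric(length(cg))))
  k_use <- min(k, nrow(cl_feats) - 1L)
  clusters <- fuzzy_kmeans_entropy(cl_feats, k = k_use, p = fuzzy_p, seed = seed)
  groups <- group_clusters(clusters)
  pep_groups <- vapply(seq_along(fitted_ids), function(i)
    peptide_group(clusters$membership[i, ], groups)$label, character(1))
  # peptide scores
  tab <- fits$table
  ridx <- match(fitted_ids, tab$peptide_id)
  scores <- lapply(seq_along(fitted_ids), function(i) {
    peptide_score(ctl_curves[[i]], trt_curves[[i]], group = pep_groups[i],
                  rss_ctl = tab$rss_ctl[ridx[i]], rss_trt = tab$rss_trt[ridx[i]],
                  eps = eps, boundaries = boundaries)
  })
  rec <- dataset$records[match(fitted_ids, dataset$records$peptide_id), ]
  pep_df <- data.frame(
    peptide_id = fitted_ids, protein_id = rec$protein_id,
    start = rec$start, end = rec$end, tryptic_type = rec$tryptic_type,
    group = pep_groups,
    score = vapply(scores, function(s) s$score, numeric(1)),
    weight = vapply(scores, function(s) s$weight, numeric(1)),
    t_start = vapply(scores, function(s) if (is.null(s$interval)) NA_real_ else s$interval[1], numeric(1)),
    t_end = vapply(scores, function(s) if (is.null(s$interval)) NA_real_ else s$interval[2], numeric(1)),
    flat = tab$flat[ridx], stringsAsFactors = FALSE)
  res_df <- residue_scores(pep_df, q_pair = q_pair)
  prot_df <- protein_score(res_df, q_pair = q_pair)
  changed <- NULL
  if (shape_change) {
    joint_feats <- rbind(cl_feats,
                         t(vapply(fitted_ids, function(id)
                           predict(fits$fits[[id]]$trt, cg)$mean, numeric(length(cg)))))
    jc <- fuzzy_kmeans_entropy(joint_feats, k = min(k, nrow(joint_feats) - 1L),
                               p = fuzzy_p, seed = seed)
    jg <- group_clusters(jc)
    n <- length(fitted_ids)
    changed <- vapply(seq_len(n), function(i) {
      detect_shape_change(peptide_group(jc$membership[i, ], jg)$prob,
                          peptide_group(jc$membership[n + i, ], jg)$prob)
    }, logical(1))
    pep_df$shape_changed <- changed
  }
  structure(list(peptide_scores = pep_df, residue_scores = res_df,
                 protein_scores = prot_df, fits = fits, clusters = clusters,
                 groups = groups, curves = list(ctl = ctl_curves, trt = trt_curves),
                 config = list(control = control, treatment = treatment,
                               k = k_use, fuzzy_p = fuzzy_p, q_pair = q_pair,
                               grid_step = grid_step, min_obs = min_obs,
                               eps = eps, boundaries = boundaries, seed = seed)),
            class = "lip_stability")
}

#' @export
print.lip_stability <- function(x, ...) {
  cat("lip_stability fit:", x$config$control, "vs", x$config$treatment, "\n")
  cat("  peptides scored:", nrow(x$peptide_scores),
      "( nonzero:", sum(x$peptide_scores$score != 0), ")\n")
  cat("  proteins:", nrow(x$protein_scores),
      "( stabilized:", sum(x$protein_scores$direction == "stabilized"),
      "; destabilized:", sum(x$protein_scores$direction == "destabilized"), ")\n")
  invisible(x)
}

#' @export
summary.lip_stability <- function(object, ...) {
  print(object)
  cat("  shape groups of scored peptides:\n")
  print(table(object$peptide_scores$group))
  nz <- object$peptide_scores$score[object$peptide_scores$score != 0]
  if (length(nz)) {
    cat("  nonzero peptide scores:\n")
    print(summary(nz))
  }
  invisible(object)
}

#' @export
coef.lip_stability <- function(object, level = c("protein", "residue", "peptide"), ...) {
  level <- match.arg(level)
  switch(level,
         protein = stats::setNames(object$protein_scores$score,
                                   object$protein_scores$protein_id),
         residue = object$residue_scores,
         peptide = stats::setNames(object$peptide_scores$score,
                                   object$peptide_scores$peptide_id))
}

#' Plot fitted condition curves for one peptide
#'
#' @param x a `lip_stability` object.
#' @param peptide peptide id (default: largest |score|).
#' @param ... passed to the underlying plot.
#' @export
plot.lip_stability <- function(x, peptide = NULL, ...) {
  if (is.null(peptide)) {
    peptide <- x$peptide_scores$peptide_id[which.max(abs(x$peptide_scores$score))]
  }
  cc <- x$curves$ctl[[peptide]]; ct <- x$curves$trt[[peptide]]
  ylim <- range(cc$lower, cc$upper, ct$lower, ct$upper)
  plot(cc, col = "grey30", ylim = ylim, main = peptide, ...)
  plot(ct, add = TRUE, col = "firebrick")
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("grey30", "firebrick"),
                   legend = c(x$config$control, x$config$treatment))
  invisible(x)
}

#' Write score tables to TSV
#'
#' @param fit a `lip_stability` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_scores <- function(fit, dir) {
  stopifnot(inherits(fit, "lip_stability"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("peptide_scores.tsv", "residue_scores.tsv",
                            "protein_scores.tsv"))
  utils::write.table(fit$peptide_scores, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$residue_scores, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$protein_scores, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
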
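# Per-peptide profile preparation and fitting: min-max scaling pooled
# across conditions, GP fits per condition, flat-profile flagging.

#' Min-max scale a profile
#'
#' `x' = (x - min(x)) / (max(x) - min(x))`.  A constant input maps to all
#' zeros with a `constant` attribute set, since no shape information exists.
#' Scaling is invariant to multiplying the input by any positive factor.
#'
#' @param x numeric intensities (NAs preserved).
#' @return scaled values in [0, 1] with attribute `constant` (logical).
#' @export
scale_profile <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("no finite values to scale")
  if (rng[2] - rng[1] <= 0) {
    out <- ifelse(is.na(x), NA_real_, 0)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "constant") <- FALSE
  out
}

#' Flag a flat thermal profile
#'
#' A peptide is flat when the absolute log2 fold change between its minimum
#' and maximum replicate-mean raw intensity across the gradient is below
#' 0.5 (strict).  Flat profiles are the in situ signature used for
#' intrinsic-disorder calling.
#'
#' @param means raw (unscaled) replicate-mean intensities per temperature,
#'   all > 0; NAs dropped.
#' @param threshold log2 fold-change threshold (default 0.5).
#' @return `TRUE`/`FALSE`, or `NA` if fewer than 2 positive means remain.
#' @export
flat_profile_flag <- function(means, threshold = 0.5) {
  m <- means[is.finite(means)]
  if (any(m <= 0)) stop("flat_profile_flag needs positive mean intensities")
  if (length(m) < 2L) return(NA)
  abs(log2(max(m) / min(m))) < threshold
}

# Observed-temperature rule: a peptide enters fitting in a condition only
# if the replicate-mean intensity is available at >= min_obs of the grid
# temperatures in that condition.
enough_observations <- function(sub, grid, min_obs = 8L) {
  tt <- unique(sub$temperature[is.finite(sub$intensity)])
  sum(grid %in% tt) >= min_obs
}

#' Fit GP thermal profiles for every peptide of a dataset
#'
#' For each peptide: intensities are min-max scaled per peptide, pooled
#' across both conditions and all replicates (so the two condition curves
#' stay on a common scale), then one GP is fitted per condition on all
#' replicate observations.  Peptides observed at fewer than `min_obs` of
#' the gradient temperatures in either condition, or with constant
#' intensities, are excluded from fitting (but reported).
#'
#' @param dataset a [peptide_dataset()].
#' @param conditions length-2 character: control-like condition first.
#' @param min_obs minimum quantified gradient temperatures per condition.
#' @param joint_diagnostic also fit a pooled-condition GP and report the
#'   marginal-likelihood difference of separate vs joint fits (slower;
#'   diagnostic only).
#' @return object of class `profile_fits`: list with `fits` (per peptide:
#'   `gp_profile` per condition, flat flag, scaled data) and a summary
#'   data.frame `table`.
#' @export
fit_thermal_profiles <- function(dataset, conditions = NULL, min_obs = 8L,
                                 joint_diagnostic = FALSE) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  if (is.null(conditions)) conditions <- dataset$conditions
  if (length(conditions) != 2L || !all(conditions %in% dataset$conditions)) {
    stop("need exactly 2 conditions present in the dataset")
  }
  ints <- dataset$intensities
  ints <- ints[ints$condition %in% conditions, , drop = FALSE]
  by_pep <- split(ints, ints$peptide_id)
  pep_ids <- dataset$records$peptide_id
  fits <- vector("list", length(pep_ids))
  names(fits) <- pep_ids
  tab <- data.frame(peptide_id = pep_ids, fitted = FALSE, flat = NA,
                    rss_ctl = NA_real_, rss_trt = NA_real_,
                    mll_ctl = NA_real_, mll_trt = NA_real_,
                    delta_mll_joint = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(pep_ids)) {
    sub <- by_pep[[pep_ids[i]]]
    if (is.null(sub)) next
    s1 <- sub[sub$condition == conditions[1], , drop = FALSE]
    s2 <- sub[sub$condition == conditions[2], , drop = FALSE]
    # flat flag on control-condition replicate means (raw scale)
    means <- tapply(s1$intensity, s1$temperature, mean, na.rm = TRUE)
    mpos <- means[is.finite(means) & means > 0]
    tab$flat[i] <- if (length(mpos) >= 2L) abs(log2(max(mpos) / min(mpos))) < 0.5 else NA
    if (!enough_observations(s1, dataset$grid, min_obs) ||
        !enough_observations(s2, dataset$grid, min_obs)) next
    sc <- scale_profile(c(s1$intensity, s2$intensity))
    if (isTRUE(attr(sc, "constant"))) next
    v1 <- sc[seq_len(nrow(s1))]
    v2 <- sc[nrow(s1) + seq_len(nrow(s2))]
    ok1 <- is.finite(v1); ok2 <- is.finite(v2)
    if (sum(ok1) < 4L || sum(ok2) < 4L) next
    g1 <- fit_gp(s1$temperature[ok1], v1[ok1])
    g2 <- fit_gp(s2$temperature[ok2], v2[ok2])
    if (isTRUE(g1$unfit) || isTRUE(g2$unfit)) next
    dmll <- NA_real_
    if (joint_diagnostic) {
      gj <- fit_gp(c(s1$temperature[ok1], s2$temperature[ok2]),
                   c(v1[ok1], v2[ok2]))
      if (!isTRUE(gj$unfit)) dmll <- (g1$mll + g2$mll) - gj$mll
    }
    fits[[i]] <- list(ctl = g1, trt = g2)
    tab$fitted[i] <- TRUE
    tab$rss_ctl[i] <- g1$rss; tab$rss_trt[i] <- g2$rss
    tab$mll_ctl[i] <- g1$mll; tab$mll_trt[i] <- g2$mll
    tab$delta_mll_joint[i] <- dmll
  }
  structure(list(fits = fits, table = tab, conditions = conditions,
                 grid = dataset$grid), class = "profile_fits")
}

#' @export
print.profile_fits <- function(x, ...) {
  cat("profile_fits:", sum(x$table$fitted), "of", nrow(x$table),
      "peptides fitted (", x$conditions[1], "vs", x$conditions[2], ")\n")
  invisible(x)
}
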
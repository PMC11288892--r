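# Fuzzy k-means with entropy regularisation on fitted profiles, shape-group
# assignment, and detection of osmolyte-induced shape changes.

#' Fuzzy k-means clustering with entropy regularisation
#'
#' Minimises `J = sum_im u_im d_im^2 + p sum_im u_im log u_im` (squared
#' Euclidean distance) by alternating updates: memberships
#' `u_im = softmax(-d_im^2 / p)` row-wise, centroids as membership-weighted
#' means.  The entropy degree `p` plays the role of a temperature: as
#' `p -> 0` assignments harden to k-means.  Best of `n_restarts` random
#' (Dirichlet) membership initialisations by final `J`.
#'
#' Because `p` acts as an absolute temperature on the squared distances,
#' feature columns are standardized before clustering by default (as in
#' the usual fuzzy-clustering workflow): on min-max-scaled profiles the
#' raw between-profile distances are small enough that the entropy term
#' would otherwise dominate and collapse all centroids into blended
#' copies.  Distances and `J` refer to the standardized space; the
#' reported `centroids` and `medoids` are back-transformed to the
#' original scaled-intensity units (as required by the endpoint grouping
#' rule of [group_clusters()]).
#'
#' @param profiles numeric matrix, rows = profiles (same grid), or a list
#'   of equal-length numeric vectors.
#' @param k number of clusters (default 20).
#' @param p entropy degree (default 2).
#' @param seed integer seed for the initialisations.
#' @param n_restarts random restarts (default 5).
#' @param max_iter,tol convergence controls (max membership change).
#' @param standardize z-score the feature columns before clustering
#'   (default `TRUE`).
#' @return object of class `profile_clusters`: `centroids` (k x grid
#'   length, original units), `membership` (n x k, rows sum to 1), `J`,
#'   `medoids` (pointwise-median cluster profiles) and iteration info.
#' @export
fuzzy_kmeans_entropy <- function(profiles, k = 20L, p = 2, seed = 1L,
                                 n_restarts = 5L, max_iter = 500L, tol = 1e-6,
                                 standardize = TRUE) {
  X0 <- if (is.list(profiles)) do.call(rbind, profiles) else as.matrix(profiles)
  n <- nrow(X0)
  if (k >= n) stop("k must be smaller than the number of profiles")
  stopifnot(p > 0)
  if (standardize) {
    ctr <- colMeans(X0)
    scl <- apply(X0, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    X <- sweep(sweep(X0, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(X0)); scl <- rep(1, ncol(X0))
    X <- X0
  }
  set.seed(seed)
  best <- NULL
  xsq <- rowSums(X^2)
  for (r in seq_len(n_restarts)) {
    # random membership rows from a symmetric Dirichlet(1)
    U <- matrix(stats::rexp(n * k), n, k)
    U <- U / rowSums(U)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      W <- colSums(U)
      empty <- W < 1e-12
      if (any(empty)) {  # reseed dead centroids at random profiles
        U[, empty] <- 1e-6
        U <- U / rowSums(U)
        W <- colSums(U)
      }
      C <- crossprod(U, X) / W          # k x d membership-weighted means
      d2 <- outer(xsq, rowSums(C^2), "+") - 2 * X %*% t(C)
      d2 <- pmax(d2, 0)
      L <- -d2 / p
      L <- L - apply(L, 1, max)
      Unew <- exp(L)
      Unew <- Unew / rowSums(Unew)
      delta <- max(abs(Unew - U))
      U <- Unew
      if (delta < tol || iter >= max_iter) break
    }
    J <- sum(U * d2) + p * sum(ifelse(U > 0, U * log(U), 0))
    if (is.null(best) || J < best$J) {
      best <- list(U = U, C = C, J = J, iter = iter, d2 = d2)
    }
  }
  # back-transform centroids to original units
  C_orig <- sweep(sweep(best$C, 2, scl, "*"), 2, ctr, "+")
  # pointwise-median representative profile per cluster (hard assignment)
  hard <- max.col(best$U)
  med <- C_orig
  for (m in seq_len(k)) {
    idx <- which(hard == m)
    if (length(idx) > 1L) med[m, ] <- apply(X0[idx, , drop = FALSE], 2, stats::median)
    else if (length(idx) == 1L) med[m, ] <- X0[idx, ]
  }
  structure(list(centroids = C_orig, membership = best$U, J = best$J,
                 medoids = med, k = k, p = p, iterations = best$iter,
                 n = n, standardized = standardize), class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("profile_clusters: %d profiles in %d fuzzy clusters (entropy degree %.3g), J = %.4g\n",
              x$n, x$k, x$p, x$J))
  invisible(x)
}

#' Assign shape groups to clusters
#'
#' A cluster is `nonmonotonous` when the absolute difference of its
#' representative profile between the lowest and highest temperature is
#' below 0.5 (scaled units); otherwise `increasing` when the value at the
#' lowest temperature is below that at the highest, else `decreasing`.
#'
#' @param clusters a `profile_clusters` object, or a matrix of cluster
#'   profiles (rows = clusters).
#' @param representative `"centroid"` (fuzzy weighted mean, default) or
#'   `"median"` (pointwise median of hard-assigned members).
#' @return character vector of group labels, one per cluster.
#' @export
group_clusters <- function(clusters, representative = c("centroid", "median")) {
  representative <- match.arg(representative)
  C <- if (inherits(clusters, "profile_clusters")) {
    if (representative == "centroid") clusters$centroids else clusters$medoids
  } else as.matrix(clusters)
  lo <- C[, 1L]; hi <- C[, ncol(C)]
  ifelse(abs(hi - lo) < 0.5, "nonmonotonous",
         ifelse(lo < hi, "increasing", "decreasing"))
}

#' Shape-group probabilities for one peptide
#'
#' Sums a membership row over the clusters of each shape group; the label
#' is the argmax group.
#'
#' @param membership numeric membership row (sums to 1).
#' @param groups character group label per cluster (from
#'   [group_clusters()]).
#' @return list with `prob` (named numeric over the three groups) and
#'   `label`.
#' @export
peptide_group <- function(membership, groups) {
  stopifnot(length(membership) == length(groups))
  lv <- c("decreasing", "increasing", "nonmonotonous")
  pr <- vapply(lv, function(g) sum(membership[groups == g]), numeric(1))
  list(prob = pr, label = lv[which.max(pr)])
}

#' Detect an osmolyte-induced profile shape change
#'
#' Run on a joint clustering of control and osmolyte fitted profiles: a
#' peptide's shape changes when the probability of some main group differs
#' between conditions by more than 0.5.
#'
#' @param prob_control,prob_osmolyte named group-probability vectors for
#'   the peptide's control / osmolyte profile (from [peptide_group()]).
#' @return logical.
#' @export
detect_shape_change <- function(prob_control, prob_osmolyte) {
  stopifnot(identical(names(prob_control), names(prob_osmolyte)))
  max(abs(prob_control - prob_osmolyte)) > 0.5
}
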
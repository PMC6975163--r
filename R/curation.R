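# Curation-target analysis: collapse perfectly correlated genes, cluster
# essentiality profiles (k-means, k = 2), visualize with PCoA on Hamming
# distances, classify clusters from reaction content (random forest), and
# compute the two per-reaction curation metrics: fractional importance and
# cluster ratio.

#' Collapse perfectly correlated gene columns
#'
#' Drops constant essentiality columns (they carry no information for
#' clustering) and merges groups of genes with identical essentiality
#' predictions across all members into one representative column. Without
#' this aggregation, blocks of perfectly correlated genes dominate the
#' k-means distance and produce badly unbalanced clusters.
#'
#' @param essentiality a `gc_essentiality` or a logical members x genes
#'   matrix.
#' @return list with `reduced` (logical members x groups matrix, columns
#'   named after each group's first gene) and `groups` (list of gene-id
#'   vectors, one per retained column).
#' @export
collapse_correlated_genes <- function(essentiality) {
  v <- if (inherits(essentiality, "gc_essentiality")) essentiality$values
       else essentiality
  stopifnot(is.matrix(v), nrow(v) >= 1L)
  variable <- apply(v, 2, function(col) any(col) && !all(col))
  if (!any(variable))
    stop("no variable essentiality predictions: all gene columns are constant",
         call. = FALSE)
  vv <- v[, variable, drop = FALSE]
  keys <- apply(vv, 2, function(col) paste(as.integer(col), collapse = ""))
  groups <- split(colnames(vv), keys)
  # preserve first-appearance column order
  ord <- order(vapply(groups, function(g) match(g[[1L]], colnames(vv)),
                      integer(1)))
  groups <- unname(groups[ord])
  reps <- vapply(groups, `[[`, character(1), 1L)
  reduced <- vv[, reps, drop = FALSE]
  list(reduced = reduced, groups = groups)
}

#' Cluster ensemble members by essentiality profile (k-means)
#'
#' k-means on the collapsed binary profiles treated as reals, with multiple
#' random restarts; the best (lowest within-cluster sum of squares) fit is
#' kept. Labels are arbitrary up to permutation.
#'
#' @param reduced members x features matrix (from
#'   [collapse_correlated_genes()]).
#' @param k number of clusters (default 2).
#' @param seed RNG seed.
#' @param nstart random restarts (default 10).
#' @return list with `labels` (named integer vector in 1..k), `k`,
#'   `inertia` (total within-cluster sum of squares) and `centers`.
#' @export
cluster_members <- function(reduced, k = 2, seed = 1, nstart = 10) {
  X <- reduced * 1
  n_distinct <- nrow(unique(X))
  if (n_distinct < k)
    stop(sprintf("cannot form %d clusters from %d distinct member profiles",
                 k, n_distinct), call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, iter.max = 300, nstart = nstart)
  list(labels = stats::setNames(km$cluster, rownames(X)),
       k = k, inertia = km$tot.withinss, centers = km$centers)
}

#' Principal coordinate analysis of essentiality profiles (Hamming)
#'
#' Pairwise Hamming distance (fraction of differing positions) between
#' member profiles, double-centering of the squared distance matrix, and
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their eigenvalue. Negative eigenvalues (not expected for
#' Hamming on binary data, which is Euclidean-embeddable) are truncated to
#' zero and excluded from the explained-variance normalization.
#'
#' @param m logical/numeric members x features matrix, or a
#'   `gc_essentiality`.
#' @return list with `coordinates` (members x axes), `explained_fraction`
#'   and `eigenvalues`. All-identical members yield zero coordinates and
#'   explained fractions of 0.
#' @export
pcoa_hamming <- function(m) {
  if (inherits(m, "gc_essentiality")) m <- m$values
  X <- m * 1
  n <- nrow(X)
  stopifnot(n >= 2L)
  D <- as.matrix(stats::dist(X, method = "manhattan")) / ncol(X)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- eig$values
  lambda[lambda < 0] <- 0
  total <- sum(lambda)
  if (total <= .Machine$double.eps) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(X), "PCo1"))
    return(list(coordinates = coords,
                explained_fraction = 0, eigenvalues = lambda))
  }
  keep <- which(lambda > 1e-12 * max(lambda))
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lambda[keep]), length(keep))
  dimnames(coords) <- list(rownames(X), paste0("PCo", seq_along(keep)))
  list(coordinates = coords,
       explained_fraction = lambda[keep] / total,
       eigenvalues = lambda)
}

#' Train the cluster-membership classifier
#'
#' Random forest predicting the k-means cluster label of each member from
#' its binary variable-reaction content: 500 trees, Gini splits, no depth
#' limit, minimum 2 samples to split / 1 per leaf, sqrt(p) features per
#' split, bootstrap resampling — the standard classification defaults.
#' Out-of-bag accuracy is reported; an optional holdout split provides an
#' overfitting check.
#'
#' @param feature_matrix logical/numeric members x variable-reactions
#'   matrix.
#' @param labels cluster labels (vector coercible to factor), one per
#'   member.
#' @param seed RNG seed.
#' @param ntree number of trees (default 500).
#' @param holdout optional fraction (e.g. 0.3) held out to report test-set
#'   accuracy next to the OOB estimate.
#' @return list with `forest` (randomForest object), `oob_accuracy`, and
#'   `holdout_accuracy` (NA unless requested).
#' @export
train_cluster_classifier <- function(feature_matrix, labels, seed = 1,
                                     ntree = 500, holdout = NULL) {
  X <- as.data.frame(feature_matrix * 1)
  colnames(X) <- colnames(feature_matrix)
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("cluster labels are single-class; cannot train a classifier",
         call. = FALSE)
  if (min(table(y)) < 2L)
    stop("each cluster must contain at least 2 members", call. = FALSE)
  if (ncol(X) < 1L)
    stop("no variable reactions to classify from", call. = FALSE)
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = ntree,
    mtry = max(1L, floor(sqrt(ncol(X)))),
    nodesize = 1, replace = TRUE, importance = FALSE)
  oob <- mean(rf$predicted == y)
  hold_acc <- NA_real_
  if (!is.null(holdout)) {
    set.seed(seed + 1L)
    test_idx <- sample.int(nrow(X), max(1L, round(holdout * nrow(X))))
    rf_tr <- randomForest::randomForest(
      x = X[-test_idx, , drop = FALSE], y = y[-test_idx], ntree = ntree,
      mtry = max(1L, floor(sqrt(ncol(X)))), nodesize = 1, replace = TRUE)
    hold_acc <- mean(stats::predict(rf_tr, X[test_idx, , drop = FALSE]) ==
                       y[test_idx])
  }
  list(forest = rf, oob_accuracy = oob, holdout_accuracy = hold_acc)
}

#' Fractional importance of each variable reaction
#'
#' Gini mean-decrease-in-impurity importances of the cluster classifier,
#' normalized to sum to 1 ("fractional" because the importances of all
#' variable reactions sum to one per species).
#'
#' @param classifier result of [train_cluster_classifier()] or a
#'   randomForest object.
#' @return named numeric vector summing to 1.
#' @export
fractional_importance <- function(classifier) {
  rf <- if (inherits(classifier, "randomForest")) classifier
        else classifier$forest
  imp <- randomForest::importance(rf, type = 2)[, 1L]
  total <- sum(imp)
  if (total <= 0)
    stop("classifier has zero total importance; cannot normalize",
         call. = FALSE)
  imp / total
}

#' Cluster ratio of each variable reaction
#'
#' For each reaction, let f1 and f2 be the fractions of members of clusters
#' 1 and 2 that contain it. The cluster ratio 1 - min(f1,f2)/max(f1,f2) is
#' 1 when the reaction is confined to a single cluster, 0 when it is
#' equally frequent in both, and 0.5 when it is twice as frequent in one
#' cluster as in the other. Reactions present in neither cluster are
#' excluded (they are not variable).
#'
#' @param feature_matrix logical/numeric members x reactions matrix.
#' @param labels two-cluster labels, one per member.
#' @return data.frame with columns `reaction_id`, `cluster_ratio`, `f1`,
#'   `f2`.
#' @export
cluster_ratio <- function(feature_matrix, labels) {
  y <- factor(labels)
  if (nlevels(y) != 2L)
    stop("cluster_ratio requires exactly two clusters", call. = FALSE)
  if (any(table(y) == 0L)) stop("empty cluster", call. = FALSE)
  M <- feature_matrix * 1
  lev <- levels(y)
  f1 <- colMeans(M[y == lev[1L], , drop = FALSE])
  f2 <- colMeans(M[y == lev[2L], , drop = FALSE])
  keep <- (f1 + f2) > 0
  f1 <- f1[keep]; f2 <- f2[keep]
  ratio <- 1 - pmin(f1, f2) / pmax(f1, f2)
  data.frame(reaction_id = colnames(M)[keep],
             cluster_ratio = unname(ratio),
             f1 = unname(f1), f2 = unname(f2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ranked curation-target table
#'
#' Joins fractional importance and cluster ratio per variable reaction and
#' sorts by fractional importance (descending), breaking ties by cluster
#' ratio (descending) then reaction id. Reactions high in both metrics are
#' the top curation priorities.
#'
#' @param importance named vector from [fractional_importance()].
#' @param ratios data.frame from [cluster_ratio()].
#' @param n optional number of top rows to keep (default: all).
#' @return data.frame with columns `rank`, `reaction_id`,
#'   `fractional_importance`, `cluster_ratio`, `f1`, `f2`.
#' @export
curation_targets <- function(importance, ratios, n = NULL) {
  tab <- data.frame(reaction_id = names(importance),
                    fractional_importance = unname(importance),
                    stringsAsFactors = FALSE)
  tab <- merge(tab, ratios, by = "reaction_id", all.x = TRUE)
  ord <- order(-tab$fractional_importance,
               -ifelse(is.na(tab$cluster_ratio), -Inf, tab$cluster_ratio),
               tab$reaction_id)
  tab <- tab[ord, , drop = FALSE]
  if (!is.null(n)) tab <- utils::head(tab, n)
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' One-call curation analysis of an ensemble
#'
#' Runs the full analysis stage: collapse correlated genes, k-means
#' clustering (k = 2), PCoA for visualization, random-forest cluster
#' classification, and both curation metrics.
#'
#' @param ensemble a `gem_ensemble`.
#' @param essentiality a `gc_essentiality` for the same ensemble.
#' @param seed RNG seed for clustering and the forest.
#' @param holdout optional holdout fraction for the classifier check.
#' @return list with `collapsed`, `clusters`, `pcoa`, `classifier`,
#'   `importance`, `ratios` and `targets`.
#' @export
curation_metrics <- function(ensemble, essentiality, seed = 1,
                             holdout = NULL) {
  collapsed <- collapse_correlated_genes(essentiality)
  clusters <- cluster_members(collapsed$reduced, k = 2, seed = seed)
  pco <- pcoa_hamming(collapsed$reduced)
  clf <- train_cluster_classifier(ensemble$feature_matrix, clusters$labels,
                                  seed = seed, holdout = holdout)
  imp <- fractional_importance(clf)
  ratios <- cluster_ratio(ensemble$feature_matrix, clusters$labels)
  list(collapsed = collapsed,
       clusters = clusters,
       pcoa = pco,
       classifier = clf,
       importance = imp,
       ratios = ratios,
       targets = curation_targets(imp, ratios))
}
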
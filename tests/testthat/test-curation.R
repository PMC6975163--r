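ess_matrix <- function(..., genes = NULL, members = NULL) {
  m <- rbind(...)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  if (is.null(members)) members <- paste0("m", seq_len(nrow(m)))
  dimnames(m) <- list(members, genes)
  m == 1
}

test_that("perfectly correlated gene columns collapse to one variable", {
  m <- ess_matrix(c(1, 0, 1), c(1, 0, 1), c(0, 0, 1), c(1, 1, 1))
  m <- t(m)  # columns g1 = g2 = (1,0,1), g3 = (0,0,1), g4 all ones
  colnames(m) <- paste0("g", 1:4); rownames(m) <- paste0("m", 1:3)
  res <- collapse_correlated_genes(m)
  expect_equal(ncol(res$reduced), 2)
  expect_identical(res$groups, list(c("g1", "g2"), "g3"))
  expect_identical(colnames(res$reduced), c("g1", "g3"))  # constant g4 gone
  expect_error(collapse_correlated_genes(m[, 4, drop = FALSE]),
               "no variable essentiality")
})

test_that("collapsed columns equal equivalence classes under column equality", {
  # O(n^2) pairwise-comparison oracle on random binary matrices
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(rbinom(12 * 8, 1, 0.5), 12, 8,
                dimnames = list(paste0("m", 1:12), paste0("g", 1:8))) == 1
    variable <- which(apply(m, 2, function(col) any(col) && !all(col)))
    if (length(variable) == 0) next
    oracle_groups <- list()
    assigned <- logical(ncol(m))
    for (i in variable) {
      if (assigned[i]) next
      grp <- colnames(m)[i]
      for (j in variable[variable > i]) {
        if (!assigned[j] && all(m[, i] == m[, j])) {
          grp <- c(grp, colnames(m)[j]); assigned[j] <- TRUE
        }
      }
      assigned[i] <- TRUE
      oracle_groups[[length(oracle_groups) + 1]] <- grp
    }
    res <- collapse_correlated_genes(m)
    expect_identical(res$groups, oracle_groups, info = paste("seed", seed))
  }
})

test_that("k-means recovers point masses and matches the exhaustive 2-partition", {
  # two point masses of identical rows
  m <- ess_matrix(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0),
                  c(0, 0, 1), c(0, 0, 1))
  cl <- cluster_members(m, seed = 1)
  expect_length(unique(cl$labels[1:3]), 1)
  expect_length(unique(cl$labels[4:5]), 1)
  expect_false(cl$labels[1] == cl$labels[4])
  expect_equal(cl$inertia, 0)
  expect_error(cluster_members(m[c(1, 2), ][c(1, 1), ]), "distinct")

  # exhaustive best-2-partition oracle on random <=10-member matrices
  best_partition_inertia <- function(X) {
    n <- nrow(X)
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
      lab <- c(0, as.integer(intToBits(code))[seq_len(n - 1)])
      if (length(unique(lab)) < 2) next
      inert <- 0
      for (g in unique(lab)) {
        Y <- X[lab == g, , drop = FALSE]
        ctr <- colMeans(Y)
        inert <- inert + sum(sweep(Y, 2, ctr)^2)
      }
      best <- min(best, inert)
    }
    best
  }
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rbinom(8 * 5, 1, 0.4), 8, 5,
                dimnames = list(paste0("m", 1:8), paste0("g", 1:5)))
    if (nrow(unique(X)) < 2) next
    cl <- cluster_members(X, seed = seed, nstart = 25)
    expect_equal(cl$inertia, best_partition_inertia(X), tolerance = 1e-8,
                 info = paste("seed", seed))
  }
})

test_that("PCoA on Hamming distances matches classical scaling", {
  # two members differing everywhere: distance 1, one positive axis
  m <- ess_matrix(c(1, 1, 1, 1), c(0, 0, 0, 0))
  p <- pcoa_hamming(m)
  expect_equal(abs(p$coordinates[1, 1] - p$coordinates[2, 1]), 1)
  expect_equal(p$explained_fraction, 1)
  # identical members: zero coordinates, explained fractions 0
  ident <- ess_matrix(c(1, 0, 1), c(1, 0, 1))
  p0 <- pcoa_hamming(ident)
  expect_true(all(p0$coordinates == 0))
  expect_equal(p0$explained_fraction, 0)
  # oracle: stats::cmdscale on random matrices, coordinates up to sign
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rbinom(48, 1, 0.5), 6, 8,
                dimnames = list(paste0("m", 1:6), NULL))
    p <- pcoa_hamming(X)
    D <- as.matrix(dist(X, "manhattan")) / ncol(X)
    cm <- stats::cmdscale(D, k = min(5, ncol(p$coordinates)), eig = TRUE)
    for (ax in seq_len(ncol(cm$points))) {
      expect_lt(min(max(abs(p$coordinates[, ax] - cm$points[, ax])),
                    max(abs(p$coordinates[, ax] + cm$points[, ax]))),
                1e-8)
    }
    expect_true(all(diff(p$explained_fraction) <= 1e-12))
  }
})

test_that("cluster ratio reproduces its analytic anchor values", {
  # 10 members, feature frequencies engineered per cluster
  labels <- rep(c(1, 2), each = 5)
  feat <- cbind(twice = c(1, 1, 0, 0, 0, 1, 0, 0, 0, 0),   # f1=0.4, f2=0.2
                even = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0),    # f1=f2=0.2
                excl = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))    # f1=0.4, f2=0
  rownames(feat) <- paste0("m", 1:10)
  names(labels) <- rownames(feat)
  cr <- cluster_ratio(feat, labels)
  expect_equal(cr$cluster_ratio[cr$reaction_id == "twice"], 0.5)
  expect_equal(cr$cluster_ratio[cr$reaction_id == "even"], 0)
  expect_equal(cr$cluster_ratio[cr$reaction_id == "excl"], 1)
  # label swap and member reordering leave the metric unchanged
  swapped <- cluster_ratio(feat, 3 - labels)
  expect_equal(swapped$cluster_ratio, cr$cluster_ratio)
  perm <- sample(nrow(feat))
  reord <- cluster_ratio(feat[perm, ], labels[perm])
  expect_equal(reord[order(reord$reaction_id), "cluster_ratio"],
               cr[order(cr$reaction_id), "cluster_ratio"])
  # reactions absent from both clusters are excluded
  feat2 <- cbind(feat, ghost = 0)
  expect_false("ghost" %in% cluster_ratio(feat2, labels)$reaction_id)
  expect_error(cluster_ratio(feat, rep(1, 10)), "two clusters")
})

test_that("the cluster classifier separates labeled structure and not noise", {
  set.seed(77)
  n <- 200
  splitter <- rbinom(n, 1, 0.5)
  X <- cbind(splitter, matrix(rbinom(n * 8, 1, 0.5), n, 8))
  colnames(X) <- c("R_split", paste0("R_noise", 1:8))
  rownames(X) <- paste0("m", seq_len(n))
  labels <- splitter + 1
  clf <- train_cluster_classifier(X, labels, seed = 1)
  expect_gt(clf$oob_accuracy, 0.95)
  imp <- fractional_importance(clf)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_identical(names(which.max(imp)), "R_split")

  # permutation null: shuffled labels give chance-level OOB accuracy
  set.seed(5)
  null_labels <- sample(labels)
  clf0 <- train_cluster_classifier(X, null_labels, seed = 1)
  expect_lt(abs(clf0$oob_accuracy - 0.5), 0.1)

  # holdout check tracks the OOB estimate on separable data
  clf_h <- train_cluster_classifier(X, labels, seed = 1, holdout = 0.3)
  expect_gt(clf_h$holdout_accuracy, 0.95)
  expect_error(train_cluster_classifier(X, rep(1, n), seed = 1),
               "single-class")
})

test_that("single-feature classifiers concentrate all importance", {
  set.seed(12)
  x <- rbinom(60, 1, 0.5)
  X <- matrix(x, ncol = 1, dimnames = list(paste0("m", 1:60), "R_only"))
  clf <- train_cluster_classifier(X, x + 1, seed = 2)
  imp <- fractional_importance(clf)
  expect_equal(unname(imp), 1)
})

test_that("curation targets sort by importance with documented tie-breaks", {
  imp <- c(Rb = 0.3, Ra = 0.3, Rc = 0.4)
  ratios <- data.frame(reaction_id = c("Ra", "Rb", "Rc"),
                       cluster_ratio = c(0.2, 0.9, 0.5),
                       f1 = 0, f2 = 0, stringsAsFactors = FALSE)
  tab <- curation_targets(imp, ratios)
  expect_identical(tab$reaction_id, c("Rc", "Rb", "Ra"))
  expect_identical(tab$rank, 1:3)
  expect_equal(nrow(curation_targets(imp, ratios, n = 10)), 3)
  expect_equal(nrow(curation_targets(imp, ratios, n = 2)), 2)
})
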
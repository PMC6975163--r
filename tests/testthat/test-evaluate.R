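mini_ess <- function(values, genes, members = paste0("m", seq_len(nrow(values)))) {
  structure(list(values = matrix(values, nrow = length(members),
                                 dimnames = list(members, genes)),
                 genes = genes, member_ids = members,
                 threshold = 1e-6, medium_name = "complete"),
            class = "gc_essentiality")
}

test_that("precision and recall follow their confusion-matrix definitions", {
  genes <- c("a", "b", "c", "d", "e")
  truth <- c(a = TRUE, b = TRUE, d = TRUE, c = FALSE, e = FALSE)
  ess <- mini_ess(rbind(c(TRUE, TRUE, TRUE, FALSE, FALSE),   # pred {a,b,c}
                        c(TRUE, TRUE, FALSE, TRUE, FALSE),   # pred = truth
                        c(FALSE, FALSE, FALSE, FALSE, FALSE)),
                  genes)
  rep_ <- precision_recall(ess, truth)
  expect_equal(rep_$precision[1], 2 / 3)
  expect_equal(rep_$recall[1], 2 / 3)
  expect_equal(rep_$precision[2], 1)
  expect_equal(rep_$recall[2], 1)
  # no predicted essentials: precision undefined (NA), recall 0
  expect_true(is.na(rep_$precision[3]))
  expect_equal(rep_$recall[3], 0)
  # TP + FN equals the number of shared experimentally essential genes
  expect_true(all(rep_$TP + rep_$FN == 3))
})

test_that("genes outside the model are excluded; no overlap is an error", {
  ess <- mini_ess(rbind(c(TRUE, FALSE)), c("a", "b"))
  truth <- c(a = TRUE, zz = TRUE)   # zz never simulated
  rep_ <- precision_recall(ess, truth)
  expect_equal(rep_$TP + rep_$FN, 1)
  expect_error(precision_recall(ess, c(q1 = TRUE, q2 = FALSE)),
               "no genes shared")
})

test_that("cluster performance comparison uses Mann-Whitney with BH control", {
  # disjoint-support distributions: strongly significant
  rep_ <- data.frame(member = paste0("m", 1:40),
                     precision = c(runif(20, 0.8, 0.9), runif(20, 0.1, 0.2)),
                     recall = c(runif(20, 0.8, 0.9), runif(20, 0.1, 0.2)),
                     TP = 1, FP = 1, FN = 1,
                     cluster = rep(c(1, 2), each = 20))
  res <- compare_cluster_performance(rep_)
  expect_identical(res$metric, c("precision", "recall"))
  expect_true(all(res$p_adjusted < 0.001))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))

  # identical distributions: not significant
  set.seed(8)
  same <- rep_
  same$precision <- rep(runif(20, 0.4, 0.6), 2)[sample(40)]
  same$recall <- rep(runif(20, 0.4, 0.6), 2)[sample(40)]
  res0 <- compare_cluster_performance(same)
  expect_true(all(res0$p_adjusted > 0.05))
  expect_error(compare_cluster_performance(rep_[c(1, 21), ]), "at least 2")
})

test_that("small-sample Mann-Whitney p-values match exact enumeration", {
  # oracle: enumerate all group assignments of the pooled sample and count
  # U statistics at least as extreme (two-sided) as observed
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.3, 0.9, 4.0, 0.1)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_stat(1:4)
  combos <- utils::combn(8, 4, simplify = FALSE)
  n_xy <- 16
  dev_obs <- abs(obs - n_xy / 2)
  p_exact <- mean(vapply(combos, function(ix)
    abs(u_stat(ix) - n_xy / 2) >= dev_obs - 1e-12, logical(1)))
  wt <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(wt$p.value, p_exact, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(stats::p.adjust(c(0.01, 0.04), method = "BH"), c(0.02, 0.04))
})

test_that("pan-species aggregation averages over contributing species only", {
  metrics <- list(
    sp1 = data.frame(reaction_id = c("R1", "R2"),
                     fractional_importance = c(0.2, 0.8),
                     cluster_ratio = c(0.2, 1.0)),
    sp2 = data.frame(reaction_id = c("R1", "R3"),
                     fractional_importance = c(0.4, 0.6),
                     cluster_ratio = c(0.4, 0.0)))
  tab <- aggregate_pan_species(metrics)
  r1 <- tab[tab$reaction_id == "R1", ]
  expect_equal(r1$mean_fractional_importance, 0.3)
  expect_equal(r1$mean_cluster_ratio, 0.3)
  expect_equal(r1$n_species, 2)
  expect_equal(tab[tab$reaction_id == "R3", "n_species"], 1)
  expect_equal(tab[tab$reaction_id == "R3", "mean_fractional_importance"], 0.6)
  # species order must not matter
  tab_rev <- aggregate_pan_species(rev(metrics))
  expect_equal(tab_rev, tab)
  # minimum-species filter
  expect_identical(aggregate_pan_species(metrics, min_species = 2)$reaction_id,
                   "R1")
})

test_that("Dunn z for two groups squares to the Kruskal-Wallis statistic", {
  # independent oracle: with k = 2 groups the Dunn pairwise z satisfies
  # z^2 = H (the Kruskal-Wallis statistic, including tie correction)
  set.seed(14)
  for (rep_i in 1:4) {
    x <- c(round(rnorm(9, 0, 1), 1), round(rnorm(11, 0.8, 1), 1))  # ties likely
    g <- rep(c("a", "b"), c(9, 11))
    dt <- dunn_test(x, g)
    kw <- stats::kruskal.test(x, factor(g))
    expect_equal(dt$z^2, unname(kw$statistic), tolerance = 1e-10)
    expect_true(all(dt$p_adjusted >= dt$p_value - 1e-15))
    expect_true(all(dt$p_adjusted <= 1))
  }
})

test_that("subsystem stats expand multi-subsystem reactions and filter", {
  set.seed(3)
  n <- 12
  metrics <- data.frame(
    reaction_id = paste0("R", 1:(3 * n)),
    fractional_importance = c(runif(n, 0, 0.2), runif(n, 0, 0.2),
                              runif(n, 0.5, 0.7)),
    stringsAsFactors = FALSE)
  ann <- c(
    stats::setNames(rep(list("alpha"), n), paste0("R", 1:n)),
    stats::setNames(rep(list("beta"), n), paste0("R", (n + 1):(2 * n))),
    stats::setNames(rep(list("gamma"), n), paste0("R", (2 * n + 1):(3 * n))))
  # one reaction annotated to two subsystems counts once in each
  ann[["R1"]] <- c("alpha", "beta")
  ss <- subsystem_stats(metrics, ann, value = "fractional_importance",
                        min_reactions = 10)
  expect_equal(sum(ss$observations$reaction_id == "R1"), 2)
  expect_equal(ss$group_summary$n[ss$group_summary$subsystem == "beta"],
               n + 1)
  # the shifted subsystem is detected by omnibus and pairwise tests
  expect_lt(ss$omnibus$p.value, 0.01)
  gamma_rows <- ss$pairwise$group1 == "gamma" | ss$pairwise$group2 == "gamma"
  expect_true(all(ss$pairwise$p_adjusted[gamma_rows] < 0.05))
  # subsystems below the reaction floor are dropped; too few is an error
  ann_small <- ann
  ann_small[paste0("R", (2 * n + 1):(2 * n + 10))] <- rep(list("tiny"), 10)
  ss2 <- subsystem_stats(metrics, ann_small, min_reactions = n)
  # tiny (10 obs) and the residual gamma (2 obs) fall below the floor
  expect_setequal(ss2$group_summary$subsystem, c("alpha", "beta"))
  expect_error(subsystem_stats(metrics, ann, min_reactions = 1000),
               "fewer than 2 subsystems")
})

# (the omnibus test's type-I error under the null is exercised in the
# acceptance suite; no duplicate simulation here)
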
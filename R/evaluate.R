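# Evaluation against experimental essentiality, cluster-difference
# statistics, pan-species aggregation, and subsystem-level analysis.

#' Per-member precision and recall against an experimental screen
#'
#' Compares each member's predicted essential genes with an experimental
#' gene-essentiality table over the genes shared between the two gene
#' universes (genes assayed experimentally but absent from the model are
#' excluded). Experimentally essential is the positive class. Members that
#' predict no essential genes report precision NA (undefined) rather than
#' zero.
#'
#' @param essentiality a `gc_essentiality`.
#' @param experimental named logical vector (gene -> essential) or a
#'   data.frame with columns `gene` and `essential`.
#' @param labels optional cluster labels to carry through.
#' @return data.frame with columns `member`, `precision`, `recall`, `TP`,
#'   `FP`, `FN` and (if given) `cluster`.
#' @export
precision_recall <- function(essentiality, experimental, labels = NULL) {
  if (is.data.frame(experimental))
    experimental <- stats::setNames(as.logical(experimental$essential),
                                    experimental$gene)
  shared <- intersect(essentiality$genes, names(experimental))
  if (length(shared) == 0L)
    stop(sprintf(paste0("no genes shared between predictions (%d genes: %s ...) ",
                        "and experimental set (%d genes: %s ...)"),
                 length(essentiality$genes),
                 paste(utils::head(essentiality$genes, 3), collapse = ", "),
                 length(experimental),
                 paste(utils::head(names(experimental), 3), collapse = ", ")),
         call. = FALSE)
  truth <- experimental[shared]
  pred <- essentiality$values[, shared, drop = FALSE]
  rows <- lapply(seq_len(nrow(pred)), function(i) {
    p <- pred[i, ]
    tp <- sum(p & truth); fp <- sum(p & !truth); fn <- sum(!p & truth)
    data.frame(member = rownames(pred)[i],
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else 0,
               TP = tp, FP = fp, FN = fn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out$cluster <- unname(labels[out$member])
  rownames(out) <- NULL
  out
}

#' Compare predictive performance between simulation clusters
#'
#' Two-sided Mann-Whitney U tests on precision and on recall between the
#' two clusters, with Benjamini-Hochberg adjustment across the tests
#' performed in this invocation. Members with undefined precision are
#' dropped from the precision test only.
#'
#' @param report data.frame from [precision_recall()] including a `cluster`
#'   column.
#' @return data.frame with columns `metric`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_cluster_performance <- function(report) {
  if (is.null(report$cluster))
    stop("report must include a 'cluster' column", call. = FALSE)
  cl <- factor(report$cluster)
  if (nlevels(cl) != 2L)
    stop("exactly two clusters required", call. = FALSE)
  if (any(table(cl) < 2L))
    stop("each cluster must contain at least 2 members", call. = FALSE)
  lev <- levels(cl)
  one_test <- function(metric) {
    x <- report[[metric]][cl == lev[1L]]
    y <- report[[metric]][cl == lev[2L]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      # e.g. a cluster whose members all have undefined precision
      return(data.frame(metric = metric, statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = NULL))
    data.frame(metric = metric, statistic = unname(wt$statistic),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  }
  out <- rbind(one_test("precision"), one_test("recall"))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Aggregate curation metrics across species
#'
#' Means of fractional importance and cluster ratio per reaction over the
#' species in which the reaction was gap filled (species lacking the
#' reaction contribute nothing to its mean).
#'
#' @param metrics_list named list of per-species data.frames with columns
#'   `reaction_id`, `fractional_importance`, `cluster_ratio` (the `targets`
#'   table from [curation_metrics()] works directly).
#' @param min_species drop reactions gap filled in fewer species than this
#'   (default 1 = keep all).
#' @return data.frame with columns `reaction_id`,
#'   `mean_fractional_importance`, `mean_cluster_ratio`, `n_species`.
#' @export
aggregate_pan_species <- function(metrics_list, min_species = 1) {
  stopifnot(length(metrics_list) >= 1L)
  long <- do.call(rbind, lapply(metrics_list, function(df)
    df[, c("reaction_id", "fractional_importance", "cluster_ratio")]))
  agg <- do.call(rbind, lapply(split(long, long$reaction_id), function(d)
    data.frame(reaction_id = d$reaction_id[[1L]],
               mean_fractional_importance = mean(d$fractional_importance,
                                                 na.rm = TRUE),
               mean_cluster_ratio = mean(d$cluster_ratio, na.rm = TRUE),
               n_species = nrow(d), stringsAsFactors = FALSE)))
  agg <- agg[agg$n_species >= min_species, , drop = FALSE]
  agg <- agg[order(agg$reaction_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Dunn's post-hoc test of pairwise group differences in ranks
#'
#' Pairwise z statistics on mean ranks with the standard tie correction,
#' two-sided normal p-values, and (by default) Bonferroni adjustment capped
#' at 1. Companion to a Kruskal-Wallis omnibus test.
#'
#' @param x numeric response.
#' @param g group factor.
#' @param p_adjust adjustment method (default "bonferroni").
#' @return data.frame with columns `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(x, g, p_adjust = "bonferroni") {
  g <- factor(g)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n_g[[p[1L]]] + 1 / n_g[[p[2L]]]))
    z <- (mean_ranks[[p[1L]]] - mean_ranks[[p[2L]]]) / se
    data.frame(group1 = p[1L], group2 = p[2L], z = unname(z),
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, stats::p.adjust(out$p_value, method = p_adjust))
  rownames(out) <- NULL
  out
}

#' Subsystem-level differences in curation metrics
#'
#' Assigns each reaction's metric value to every subsystem the reaction is
#' annotated with (a reaction in two subsystems contributes one observation
#' to each), keeps only subsystems with at least `min_reactions`
#' observations, and tests for differences with a Kruskal-Wallis omnibus
#' test followed by pairwise Dunn tests with Bonferroni correction.
#'
#' @param metrics data.frame with `reaction_id` and the metric column.
#' @param annotation named list, reaction id -> character vector of
#'   subsystem names (see [read_subsystems()]).
#' @param value metric column name (default "mean_fractional_importance" if
#'   present, else "fractional_importance").
#' @param min_reactions minimum observations per subsystem (default 10).
#' @return list with `omnibus` (htest), `pairwise` (Dunn table),
#'   `group_summary` (per-subsystem n/mean/median) and `observations`.
#' @export
subsystem_stats <- function(metrics, annotation, value = NULL,
                            min_reactions = 10) {
  if (is.null(value)) {
    value <- if ("mean_fractional_importance" %in% names(metrics))
      "mean_fractional_importance" else "fractional_importance"
  }
  stopifnot(value %in% names(metrics))
  obs <- do.call(rbind, lapply(seq_len(nrow(metrics)), function(i) {
    rid <- metrics$reaction_id[[i]]
    subs <- annotation[[rid]]
    if (is.null(subs) || length(subs) == 0L) return(NULL)
    data.frame(reaction_id = rid, subsystem = subs,
               value = metrics[[value]][[i]], stringsAsFactors = FALSE)
  }))
  if (is.null(obs) || nrow(obs) == 0L)
    stop("no annotated reactions in the metrics table", call. = FALSE)
  counts <- table(obs$subsystem)
  keep <- names(counts)[counts >= min_reactions]
  if (length(keep) < 2L)
    stop(sprintf("fewer than 2 subsystems have >= %d gap-filled reactions",
                 min_reactions), call. = FALSE)
  obs <- obs[obs$subsystem %in% keep, , drop = FALSE]
  obs$subsystem <- factor(obs$subsystem)
  omnibus <- stats::kruskal.test(obs$value, obs$subsystem)
  pairwise <- dunn_test(obs$value, obs$subsystem, p_adjust = "bonferroni")
  summ <- do.call(rbind, lapply(split(obs, obs$subsystem), function(d)
    data.frame(subsystem = as.character(d$subsystem[[1L]]), n = nrow(d),
               mean = mean(d$value), median = stats::median(d$value),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(omnibus = omnibus, pairwise = pairwise, group_summary = summ,
       observations = obs)
}
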
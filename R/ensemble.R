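# Ensemble container, member materialization, ensemble-wide simulations and
# subsampling saturation diagnostics.

#' Construct an ensemble from gap-fill recipes
#'
#' An ensemble is a draft model plus a set of unique gap-fill recipes. The
#' boolean feature matrix covers the *variable* reactions only — reactions
#' present in at least one member and absent from at least one member;
#' reactions gap filled in every member are tracked separately in
#' `always_present`.
#'
#' @param base_model draft `metabolic_model`.
#' @param universal `universal_bag` the recipes draw from.
#' @param recipes list of character vectors (gap-filled reaction ids), one
#'   per member; must be unique as sets.
#' @param member_ids optional member names (default "member_0001", ...).
#' @param metadata list of provenance (seed, parameters, ...).
#' @return a `gem_ensemble`.
#' @export
new_ensemble <- function(base_model, universal, recipes, member_ids = NULL,
                         metadata = list()) {
  if (is.null(member_ids))
    member_ids <- sprintf("member_%04d", seq_along(recipes))
  stopifnot(length(member_ids) == length(recipes))
  keys <- vapply(recipes, function(x) paste(sort(x), collapse = "|"),
                 character(1))
  if (any(duplicated(keys)))
    stop("ensemble recipes must be unique as reaction sets", call. = FALSE)
  all_ids <- sort(unique(unlist(recipes)))
  unknown <- setdiff(all_ids, names(universal$reactions))
  if (length(unknown) > 0L)
    stop(sprintf("recipes reference reactions not in the universal bag: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  pres <- matrix(FALSE, length(recipes), length(all_ids),
                 dimnames = list(member_ids, all_ids))
  for (i in seq_along(recipes)) pres[i, recipes[[i]]] <- TRUE
  n_with <- colSums(pres)
  variable <- all_ids[n_with > 0 & n_with < length(recipes)]
  always <- all_ids[n_with == length(recipes)]
  structure(list(base_model = base_model,
                 universal = universal,
                 member_ids = member_ids,
                 recipes = stats::setNames(recipes, member_ids),
                 feature_matrix = pres[, variable, drop = FALSE],
                 variable_reactions = variable,
                 always_present = always,
                 metadata = metadata),
            class = "gem_ensemble")
}

#' @export
print.gem_ensemble <- function(x, ...) {
  cat(sprintf("gem_ensemble: %d members, %d variable reactions (+%d in all members)\n",
              length(x$member_ids), length(x$variable_reactions),
              length(x$always_present)))
  cat(sprintf("  base model: %s\n", x$base_model$id))
  invisible(x)
}

#' Number of ensemble members
#' @param ensemble a `gem_ensemble`.
#' @return integer.
#' @export
ensemble_size <- function(ensemble) length(ensemble$member_ids)

#' Materialize one ensemble member as a standalone model
#'
#' Returns the base model with the member's gap-filled reactions (variable
#' and always-present alike) added from the universal bag.
#'
#' @param ensemble a `gem_ensemble`.
#' @param member_id member name.
#' @return a `metabolic_model`.
#' @export
materialize_member <- function(ensemble, member_id) {
  if (!(member_id %in% ensemble$member_ids))
    stop(sprintf("unknown ensemble member '%s'", member_id), call. = FALSE)
  add_reactions(ensemble$base_model, ensemble$universal,
                ensemble$recipes[[member_id]])
}

#' Ensemble-wide single-gene essentiality simulation
#'
#' Runs [single_gene_knockouts()] on every materialized member, by default
#' in complete medium (all exchanges open at 1000 mmol/gDW/hr). The gene
#' universe is the union of genes over members; since gap-filled reactions
#' carry no gene rules this equals the draft model's gene set.
#'
#' @param ensemble a `gem_ensemble`.
#' @param medium a `gc_medium`, or NULL for complete medium.
#' @param threshold biomass flux cutoff for an essential call.
#' @return a `gc_essentiality`: list with `values` (logical members x genes
#'   matrix), `genes`, `member_ids`, `threshold` and `medium_name`.
#' @export
ensemble_essentiality <- function(ensemble, medium = NULL, threshold = 1e-6) {
  genes <- model_genes(ensemble$base_model)
  vals <- matrix(NA, ensemble_size(ensemble), length(genes),
                 dimnames = list(ensemble$member_ids, genes))
  for (mid in ensemble$member_ids) {
    mod <- materialize_member(ensemble, mid)
    med <- if (is.null(medium)) complete_medium(mod) else medium
    calls <- tryCatch(
      single_gene_knockouts(mod, med, threshold = threshold, genes = genes),
      error = function(e)
        stop(sprintf("essentiality simulation failed for member '%s': %s",
                     mid, conditionMessage(e)), call. = FALSE))
    vals[mid, calls$gene] <- calls$essential
  }
  structure(list(values = vals, genes = genes,
                 member_ids = ensemble$member_ids,
                 threshold = threshold,
                 medium_name = if (is.null(medium)) "complete" else medium$name),
            class = "gc_essentiality")
}

#' @export
print.gc_essentiality <- function(x, ...) {
  cat(sprintf("gc_essentiality: %d members x %d genes (medium: %s, threshold: %g)\n",
              nrow(x$values), ncol(x$values), x$medium_name, x$threshold))
  nc <- sum(apply(x$values, 2, function(col) any(col) && !all(col)))
  cat(sprintf("  non-consensus genes: %d\n", nc))
  invisible(x)
}

#' Genes with non-unanimous essentiality calls
#' @param essentiality a `gc_essentiality`.
#' @return character vector of gene ids whose call differs between at least
#'   two members.
#' @export
non_consensus_genes <- function(essentiality) {
  v <- essentiality$values
  essentiality$genes[apply(v, 2, function(col) any(col) && !all(col))]
}

#' Ensemble growth rates
#'
#' Maximum biomass flux per member, by default in complete medium.
#' @param ensemble a `gem_ensemble`.
#' @param medium a `gc_medium` or NULL for complete medium.
#' @return named numeric vector over members.
#' @export
ensemble_growth <- function(ensemble, medium = NULL) {
  vapply(ensemble$member_ids, function(mid) {
    mod <- materialize_member(ensemble, mid)
    med <- if (is.null(medium)) complete_medium(mod) else medium
    fba <- solve_fba(mod, med)
    if (fba$status == "optimal") fba$objective_value else 0
  }, numeric(1))
}

#' Subsampling saturation curve
#'
#' Draws members with replacement at increasing subsample sizes and reports
#' the mean and standard deviation of a summary statistic over the draws:
#' the number of variable reactions within the draw, the number of genes
#' with non-unanimous essentiality within the draw, or the variance of
#' member growth rates within the draw. A statistic that plateaus well
#' before the full ensemble size indicates the ensemble saturates the space
#' of alternative structures/predictions.
#'
#' @param ensemble a `gem_ensemble`.
#' @param statistic one of "variable_reactions", "non_consensus_genes",
#'   "growth_rate_variance".
#' @param essentiality `gc_essentiality`, required for
#'   "non_consensus_genes".
#' @param growth named numeric member growth vector (computed via
#'   [ensemble_growth()] if absent and needed).
#' @param step subsample size increment (default 20).
#' @param draws draws per size (default 1000).
#' @param seed RNG seed.
#' @return data.frame with columns `size`, `mean`, `sd`; attribute
#'   `statistic`.
#' @export
subsample_curve <- function(ensemble,
                            statistic = c("variable_reactions",
                                          "non_consensus_genes",
                                          "growth_rate_variance"),
                            essentiality = NULL, growth = NULL,
                            step = 20, draws = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  n <- ensemble_size(ensemble)
  stopifnot(n >= 1, step >= 1)
  M <- switch(statistic,
    variable_reactions = ensemble$feature_matrix * 1,
    non_consensus_genes = {
      if (is.null(essentiality))
        stop("essentiality matrix required for statistic 'non_consensus_genes'")
      essentiality$values * 1
    },
    growth_rate_variance = NULL)
  if (statistic == "growth_rate_variance" && is.null(growth))
    growth <- ensemble_growth(ensemble)

  sizes <- if (step >= n) n else unique(c(seq(step, n, by = step), n))
  set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    vals <- vapply(seq_len(draws), function(d) {
      idx <- sample.int(n, sz, replace = TRUE)
      if (statistic == "growth_rate_variance") {
        stats::var(growth[idx])
      } else {
        cs <- colSums(M[idx, , drop = FALSE])
        sum(cs > 0 & cs < sz)
      }
    }, numeric(1))
    data.frame(size = sz, mean = mean(vals), sd = stats::sd(vals))
  })
  out <- do.call(rbind, rows)
  attr(out, "statistic") <- statistic
  attr(out, "draws") <- draws
  out
}

## ---- ensemble serialization ------------------------------------------------

#' Write an ensemble to a directory
#'
#' Writes the base model JSON, the universal bag JSON, a member x reaction
#' feature table TSV (all gap-filled reactions, 0/1 cells) and a JSON
#' metadata file.
#' @param ensemble a `gem_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(ensemble$base_model, file.path(dir, "base_model.json"))
  ub_model <- metabolic_model(
    "universal",
    data.frame(id = unique(unlist(lapply(ensemble$universal$reactions,
                                         function(r) names(r$stoichiometry)))),
               name = "", compartment = "c", stringsAsFactors = FALSE),
    ensemble$universal$reactions,
    names(ensemble$universal$reactions)[[1L]])
  # universal bag serialized through the model dialect (biomass id is a
  # placeholder required by the schema)
  ub_model$metabolites$name <- ub_model$metabolites$id
  ub_model$metabolites$compartment <-
    sub("^.*_", "", ub_model$metabolites$id)
  write_model(ub_model, file.path(dir, "universal.json"))
  all_ids <- sort(unique(unlist(ensemble$recipes)))
  pres <- matrix(0L, length(ensemble$member_ids), length(all_ids),
                 dimnames = list(ensemble$member_ids, all_ids))
  for (i in seq_along(ensemble$recipes))
    pres[i, ensemble$recipes[[i]]] <- 1L
  tab <- data.frame(member = rownames(pres), pres, check.names = FALSE)
  utils::write.table(tab, file.path(dir, "members.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- ensemble$metadata
  meta$biomass_reaction_id <- ensemble$base_model$biomass_reaction_id
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an ensemble written by [write_ensemble()]
#' @param dir directory path.
#' @return a `gem_ensemble`.
#' @export
read_ensemble <- function(dir) {
  base <- read_model(file.path(dir, "base_model.json"))
  ub_model <- read_model(file.path(dir, "universal.json"))
  universal <- universal_bag(ub_model$reactions)
  tab <- utils::read.delim(file.path(dir, "members.tsv"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  member_ids <- tab$member
  rxn_cols <- setdiff(names(tab), "member")
  recipes <- lapply(seq_along(member_ids), function(i)
    rxn_cols[tab[i, rxn_cols] == 1L])
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"),
                             simplifyVector = TRUE)
  new_ensemble(base, universal, recipes, member_ids = member_ids,
               metadata = meta)
}
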
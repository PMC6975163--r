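# Parsimonious-flux gap filling and media-shuffled ensemble generation.
#
# The gap-filling program activates reactions from a universal bag with the
# minimum total absolute flux needed to reach a biomass production floor in
# a medium:
#
#   min sum_j |y_j|  over penalized universal reactions j
#   s.t. S v + U y = 0,  v_biomass >= floor,  bounds on v and y
#
# |y_j| is linearized by splitting each universal flux into nonnegative
# forward/reverse parts (y = y+ - y-) with objective sum(y+ + y-). Ensemble
# members are produced by shuffling the order of growth media and, within a
# member, removing the flux penalty from reactions activated in earlier
# conditions, which steers later conditions toward reusing them.

gc_error <- function(msg, class) {
  stop(structure(class = c(class, "gemcurate_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Gap fill a model for one growth condition
#'
#' Solves the parsimonious gap-filling LP for a single medium. Only
#' penalized universal reactions contribute to the objective; reactions in
#' `free` carry no penalty (used during iterative member construction).
#'
#' @param model draft `metabolic_model`.
#' @param universal a `universal_bag`; reaction ids must be disjoint from
#'   the model's.
#' @param medium a `gc_medium`.
#' @param free character vector of universal reaction ids exempt from the
#'   flux penalty.
#' @param biomass_floor minimum biomass flux to enable (default 0.05 /hr).
#' @param activation_cutoff absolute flux above which a penalized universal
#'   reaction counts as activated (default 1e-11).
#' @return list with `activated` (character vector of universal reaction
#'   ids), `objective` (optimal penalized flux sum), `condition` (medium
#'   name) and `universal_fluxes` (named vector over the universal bag).
#' @export
gapfill_condition <- function(model, universal, medium,
                              free = character(),
                              biomass_floor = 0.05,
                              activation_cutoff = 1e-11) {
  stopifnot(biomass_floor > 0, activation_cutoff > 0)
  uids <- names(universal$reactions)
  clash <- intersect(uids, names(model$reactions))
  if (length(clash) > 0L)
    stop(sprintf("universal bag shares reaction ids with the model: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  model <- apply_medium(model, medium)

  mids <- unique(c(model$metabolites$id,
                   unlist(lapply(universal$reactions,
                                 function(r) names(r$stoichiometry)))))
  n_v <- length(model$reactions)
  n_u <- length(uids)
  # columns: v (model) | y+ | y-
  A <- matrix(0, length(mids), n_v + 2L * n_u,
              dimnames = list(mids, NULL))
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    A[names(r$stoichiometry), i] <- r$stoichiometry
  }
  for (j in seq_len(n_u)) {
    r <- universal$reactions[[j]]
    A[names(r$stoichiometry), n_v + j] <- r$stoichiometry
    A[names(r$stoichiometry), n_v + n_u + j] <- -r$stoichiometry
  }
  lb_v <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub_v <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  bi <- match(model$biomass_reaction_id, names(model$reactions))
  lb_v[bi] <- max(lb_v[bi], biomass_floor)
  if (lb_v[bi] > ub_v[bi])
    gc_error(sprintf("biomass floor %g exceeds biomass upper bound", biomass_floor),
             "gemcurate_infeasible")
  u_lb <- vapply(universal$reactions, `[[`, numeric(1), "lower_bound")
  u_ub <- vapply(universal$reactions, `[[`, numeric(1), "upper_bound")
  lb <- c(lb_v, rep(0, 2L * n_u))
  ub <- c(ub_v, pmax(u_ub, 0), pmax(-u_lb, 0))
  penal <- !(uids %in% free)
  obj <- c(rep(0, n_v), as.numeric(penal), as.numeric(penal))

  sol <- lp_solve(obj, A, rep(0, length(mids)), lb, ub, sense = "min")
  if (sol$status != "optimal")
    gc_error(sprintf(paste0("no gap-fill solution exists for condition '%s' ",
                            "(status: %s): the universal bag cannot enable ",
                            "biomass >= %g"),
                     medium$name, sol$status, biomass_floor),
             "gemcurate_infeasible")
  y <- sol$x[n_v + seq_len(n_u)] - sol$x[n_v + n_u + seq_len(n_u)]
  names(y) <- uids
  activated <- uids[penal & abs(y) > activation_cutoff]
  list(activated = activated, objective = sol$objective,
       condition = medium$name, universal_fluxes = y)
}

#' Build one ensemble member by iterative, order-shuffled gap filling
#'
#' Shuffles the media order (unless `order` is given), gap fills condition
#' by condition, and after each condition removes the flux penalty from the
#' reactions it activated so later conditions can reuse them at no cost.
#' The returned recipe is the union of activated reactions; the draft plus
#' that union reaches the biomass floor in every input medium.
#'
#' @param model draft `metabolic_model`.
#' @param universal a `universal_bag`.
#' @param media list of `gc_medium` objects (at least one).
#' @param order optional explicit ordering (integer or character vector of
#'   medium names); by default a random shuffle using the session RNG.
#' @param biomass_floor,activation_cutoff see [gapfill_condition()].
#' @return list with `media_order` (character) and `gapfilled_reactions`
#'   (character vector, union over conditions).
#' @export
build_member <- function(model, universal, media, order = NULL,
                         biomass_floor = 0.05, activation_cutoff = 1e-11) {
  stopifnot(length(media) >= 1L)
  med_names <- vapply(media, `[[`, character(1), "name")
  if (is.null(order)) {
    ord <- sample.int(length(media))
  } else if (is.character(order)) {
    ord <- match(order, med_names)
    if (anyNA(ord)) stop("order names media not in the media list")
  } else ord <- as.integer(order)
  if (!setequal(ord, seq_along(media)))
    stop("order must be a permutation of the media list")

  free <- character()
  filled <- character()
  for (i in ord) {
    sol <- gapfill_condition(model, universal, media[[i]], free = free,
                             biomass_floor = biomass_floor,
                             activation_cutoff = activation_cutoff)
    filled <- union(filled, sol$activated)
    free <- union(free, sol$activated)
  }
  list(media_order = med_names[ord],
       gapfilled_reactions = sort(filled))
}

add_reactions <- function(model, universal, ids) {
  new_mets <- character()
  for (rid in ids) {
    r <- universal$reactions[[rid]]
    if (is.null(r)) stop(sprintf("reaction '%s' not in universal bag", rid))
    model$reactions[[rid]] <- r
    new_mets <- union(new_mets, names(r$stoichiometry))
  }
  missing <- setdiff(new_mets, model$metabolites$id)
  if (length(missing) > 0L) {
    comp <- sub("^.*_", "", missing)
    model$metabolites <- rbind(model$metabolites,
                               data.frame(id = missing, name = missing,
                                          compartment = comp,
                                          stringsAsFactors = FALSE))
  }
  model
}

#' Generate an ensemble of gap-filled models
#'
#' Runs [build_member()] `n` times with fresh media shuffles and the
#' original penalties restored each time, removes duplicate recipes
#' (identical gap-filled reaction sets; media order is ignored), and
#' assembles the unique members into an ensemble. Errors if fewer than
#' `min_unique` unique members are found, which indicates the growth data
#' admit too few alternative network hypotheses for ensemble analysis.
#'
#' @param model draft `metabolic_model`.
#' @param universal a `universal_bag`.
#' @param media list of `gc_medium` objects.
#' @param n number of gap-fill cycles (default 1000).
#' @param seed master RNG seed; per-member seeds are derived from it.
#' @param min_unique minimum number of unique members (default 3).
#' @param biomass_floor,activation_cutoff see [gapfill_condition()].
#' @return a `gem_ensemble` object; see [new_ensemble()].
#' @export
generate_ensemble <- function(model, universal, media, n = 1000, seed = 1,
                              min_unique = 3,
                              biomass_floor = 0.05,
                              activation_cutoff = 1e-11) {
  stopifnot(n >= 1)
  recipes <- vector("list", n)
  orders <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((seed + i) %% .Machine$integer.max)
    memb <- build_member(model, universal, media,
                         biomass_floor = biomass_floor,
                         activation_cutoff = activation_cutoff)
    recipes[[i]] <- memb$gapfilled_reactions
    orders[[i]] <- memb$media_order
  }
  keys <- vapply(recipes, function(x) paste(x, collapse = "|"), character(1))
  first <- !duplicated(keys)
  recipes <- recipes[first]
  orders <- orders[first]
  if (length(recipes) < min_unique)
    gc_error(sprintf(paste0("degenerate ensemble: only %d unique gap-fill ",
                            "solution(s) found across %d cycles (minimum %d)"),
                     length(recipes), n, min_unique),
             "gemcurate_degenerate")
  new_ensemble(model, universal, recipes,
               metadata = list(seed = seed, n_cycles = n,
                               biomass_floor = biomass_floor,
                               activation_cutoff = activation_cutoff,
                               media = vapply(media, `[[`, character(1), "name"),
                               media_orders = orders))
}

#' Exhaustive gap-fill oracle by universal-subset enumeration
#'
#' Independently computes the minimal penalized flux sum by enumerating
#' every subset of the universal bag (up to `max_size` reactions per
#' subset), solving the flux-sum-minimizing LP restricted to each subset,
#' and taking the minimum. Intended for verifying [gapfill_condition()] on
#' small universes; cost grows as 2^|universal|.
#'
#' @param model,universal,medium,biomass_floor,activation_cutoff as in
#'   [gapfill_condition()].
#' @param max_size largest subset cardinality to try (default: all).
#' @return list with `min_objective` and `solutions` (list of activated
#'   reaction-id sets achieving the minimum).
#' @export
enumerate_gapfill <- function(model, universal, medium,
                              biomass_floor = 0.05,
                              activation_cutoff = 1e-11,
                              max_size = NULL) {
  uids <- names(universal$reactions)
  if (length(uids) > 16L)
    stop("enumerate_gapfill is exhaustive; universal bag too large")
  if (is.null(max_size)) max_size <- length(uids)
  best <- Inf
  sols <- list()
  for (k in 0:max_size) {
    subsets <- if (k == 0L) list(character()) else
      utils::combn(uids, k, simplify = FALSE)
    for (sub in subsets) {
      bag <- universal_bag(universal$reactions[sub])
      res <- tryCatch(
        gapfill_condition(model, bag, medium,
                          biomass_floor = biomass_floor,
                          activation_cutoff = activation_cutoff),
        gemcurate_infeasible = function(e) NULL)
      if (is.null(res)) next
      if (res$objective < best - 1e-6) {
        best <- res$objective
        sols <- list(sort(res$activated))
      } else if (res$objective < best + 1e-6) {
        key <- paste(sort(res$activated), collapse = "|")
        have <- vapply(sols, function(s) paste(s, collapse = "|"), character(1))
        if (!(key %in% have)) sols <- c(sols, list(sort(res$activated)))
      }
    }
  }
  if (!is.finite(best))
    gc_error(sprintf("no gap-fill solution exists for condition '%s'",
                     medium$name), "gemcurate_infeasible")
  list(min_objective = best, solutions = sols)
}
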
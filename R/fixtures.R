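# Synthetic-data generator: toy metabolic universes with engineered gaps
# whose minimal gap-fill solutions are known analytically (and verifiable by
# exhaustive enumeration), plus gold-standard essentiality tables.
#
# The scaffold is a set of linear uptake pathways feeding a single biomass
# precursor X, with optional "split motifs" engineered so that the order of
# growth media during iterative gap filling decides whether a bypass
# reaction enters the member — which in turn flips the essentiality of one
# draft gene. Decoy reactions are dead ends that no minimal solution ever
# uses. No thermodynamic realism is attempted; the unit under test is the
# algorithmics.
#
# Split motif i (media B_i and C_i, cofactor pair Q_i/Q_i', bypass W_B_i):
#   on medium B_i alone the direct fix D_B_i is cheapest (bypass route costs
#   an extra cofactor-recycling flux); on medium C_i the C2_i + RQ_i route is
#   always cheapest and makes RQ_i penalty-free; if C_i precedes B_i in a
#   member's media order, the freed RQ_i makes the bypass W_B_i cheaper than
#   routing through X, so the member acquires W_B_i. Members with W_B_i can
#   make W_i without the draft reaction R_XW_i, so its gene gXW_i flips from
#   essential to nonessential.

#' Specification for a synthetic fixture universe
#'
#' @param n_pathways number of always-required linear uptake pathways
#'   (>= 1); each contributes one medium and one unconditionally gap-filled
#'   universal reaction.
#' @param n_decoy_reactions number of dead-end decoy reactions in the
#'   universal bag (never part of any minimal solution).
#' @param n_split_reactions number of split motifs; each contributes two
#'   media and one order-dependent bypass reaction that flips one gene's
#'   essentiality.
#' @param seed RNG seed used by downstream randomized fixtures.
#' @return a `fixture_spec` list; `n_media` is derived as
#'   `n_pathways + 2 * n_split_reactions`.
#' @export
fixture_spec <- function(n_pathways = 1, n_decoy_reactions = 2,
                         n_split_reactions = 0, seed = 1) {
  stopifnot(n_pathways >= 1, n_decoy_reactions >= 0, n_split_reactions >= 0)
  structure(list(n_pathways = n_pathways,
                 n_decoy_reactions = n_decoy_reactions,
                 n_split_reactions = n_split_reactions,
                 n_media = n_pathways + 2L * n_split_reactions,
                 seed = seed),
            class = "fixture_spec")
}

#' Build a toy gap-filling universe with known ground truth
#'
#' Constructs a draft model that cannot reach the biomass floor in any of
#' its media until specific universal reactions are added, together with the
#' universal bag, the media list, and a ground-truth record of the minimal
#' gap-fill solutions per medium. With `verify = TRUE` (the default when
#' the universal bag has at most 8 reactions) the analytic ground truth is
#' checked against exhaustive subset enumeration at generation time.
#'
#' @param spec a [fixture_spec()].
#' @param biomass_floor growth floor the ground truth refers to.
#' @param verify logical; cross-check ground truth by enumeration.
#' @return list with `model`, `universal`, `media`, `ground_truth`. The
#'   ground truth holds per-medium minimal objectives and solution sets,
#'   the expected constant and variable gap-filled reactions, the
#'   splitter-to-gene map, and the expected number of unique member types.
#' @export
make_toy_universe <- function(spec, biomass_floor = 0.05, verify = NULL) {
  np <- spec$n_pathways; nd <- spec$n_decoy_reactions
  ns <- spec$n_split_reactions
  mets <- data.frame(id = "X_c", name = "biomass precursor X",
                     compartment = "c", stringsAsFactors = FALSE)
  add_met <- function(id, name, comp) {
    mets <<- rbind(mets, data.frame(id = id, name = name, compartment = comp,
                                    stringsAsFactors = FALSE))
  }
  rxns <- list()
  add_rxn <- function(r) rxns[[r$id]] <<- r
  u_rxns <- list()
  add_u <- function(r) u_rxns[[r$id]] <<- r
  media <- list()

  source_block <- function(tag, gene) {
    e <- paste0(tag, "_e"); c_ <- paste0(tag, "_c")
    add_met(e, paste("extracellular", tag), "e")
    add_met(c_, paste("cytosolic", tag), "c")
    add_rxn(reaction(paste0("EX_", tag), stats::setNames(-1, e),
                     -1000, 1000))
    add_rxn(reaction(paste0("T_", tag),
                     stats::setNames(c(-1, 1), c(e, c_)),
                     0, 1000, gene_rule = gene))
    media[[length(media) + 1L]] <<-
      medium(tag, stats::setNames(10, paste0("EX_", tag)))
    c_
  }

  biomass_st <- stats::setNames(-1, "X_c")
  for (p in seq_len(np)) {
    a_c <- source_block(paste0("A", p), paste0("gTA", p))
    add_u(reaction(paste0("D_A", p), stats::setNames(c(-1, 1), c(a_c, "X_c")),
                   0, 1000))
  }
  splitters <- character(0)
  splitter_gene <- character(0)
  for (i in seq_len(ns)) {
    b_c <- source_block(paste0("B", i), paste0("gTB", i))
    c_c <- source_block(paste0("C", i), paste0("gTC", i))
    q <- paste0("Q", i, "_c"); qp <- paste0("Qp", i, "_c")
    w <- paste0("W", i, "_c")
    add_met(q, paste("cofactor", i, "reduced"), "c")
    add_met(qp, paste("cofactor", i, "oxidized"), "c")
    add_met(w, paste("biomass precursor W", i), "c")
    add_rxn(reaction(paste0("R_XW", i),
                     stats::setNames(c(-1, 1), c("X_c", w)),
                     0, 1000, gene_rule = paste0("gXW", i)))
    biomass_st[w] <- -1
    add_u(reaction(paste0("D_B", i),
                   stats::setNames(c(-1, 1), c(b_c, "X_c")), 0, 1000))
    add_u(reaction(paste0("W_B", i),
                   stats::setNames(c(-1, -1, 1.6, 1), c(b_c, q, w, qp)),
                   0, 1000))
    add_u(reaction(paste0("C2", i),
                   stats::setNames(c(-1, -1, 2, 1), c(c_c, q, "X_c", qp)),
                   0, 1000))
    add_u(reaction(paste0("D_C", i),
                   stats::setNames(c(-1, 0.8), c(c_c, "X_c")), 0, 1000))
    add_u(reaction(paste0("RQ", i),
                   stats::setNames(c(-1, 1), c(qp, q)), 0, 1000))
    splitters <- c(splitters, paste0("W_B", i))
    splitter_gene <- c(splitter_gene, paste0("gXW", i))
  }
  for (j in seq_len(nd)) {
    zid <- paste0("Z", j, "_c")
    add_u(reaction(paste0("DEC", j), stats::setNames(c(-1, 1), c("X_c", zid)),
                   0, 1000))
  }
  add_rxn(reaction("BIOMASS", biomass_st, 0, 1000))
  model <- metabolic_model("toy_draft", mets, rxns, "BIOMASS")
  universal <- universal_bag(u_rxns)
  names(media) <- vapply(media, `[[`, character(1), "name")

  # analytic ground truth: every medium needs (1 + n_split) units of X-flux
  # per unit biomass; all three route families cost that flux sum exactly
  # once, so all minimal objectives coincide at (1 + ns) * floor.
  g <- biomass_floor
  per_medium <- list()
  for (p in seq_len(np))
    per_medium[[paste0("A", p)]] <-
      list(min_objective = (1 + ns) * g,
           solutions = list(paste0("D_A", p)))
  for (i in seq_len(ns)) {
    per_medium[[paste0("B", i)]] <-
      list(min_objective = (1 + ns) * g,
           solutions = list(paste0("D_B", i)))
    per_medium[[paste0("C", i)]] <-
      list(min_objective = (1 + ns) * g,
           solutions = list(sort(c(paste0("C2", i), paste0("RQ", i)))))
  }
  ground_truth <- list(
    per_medium = per_medium,
    constant_reactions = sort(c(paste0("D_A", seq_len(np)),
                                if (ns > 0) c(paste0("D_B", seq_len(ns)),
                                              paste0("C2", seq_len(ns)),
                                              paste0("RQ", seq_len(ns))))),
    variable_reactions = splitters,
    splitter_gene = stats::setNames(splitter_gene, splitters),
    n_member_types = 2^ns,
    biomass_floor = biomass_floor)

  if (is.null(verify)) verify <- length(u_rxns) <= 8L
  if (verify) {
    for (mname in names(per_medium)) {
      enum <- enumerate_gapfill(model, universal, media[[mname]],
                                biomass_floor = biomass_floor, max_size = 3L)
      gt <- per_medium[[mname]]
      if (abs(enum$min_objective - gt$min_objective) > 1e-6)
        stop(sprintf("fixture self-check failed for medium '%s': %g vs %g",
                     mname, enum$min_objective, gt$min_objective))
      enum_keys <- sort(vapply(enum$solutions, paste, character(1),
                               collapse = "|"))
      gt_keys <- sort(vapply(gt$solutions, paste, character(1),
                             collapse = "|"))
      if (!identical(enum_keys, gt_keys))
        stop(sprintf("fixture self-check failed for medium '%s': solutions %s vs %s",
                     mname, paste(enum_keys, collapse = " / "),
                     paste(gt_keys, collapse = " / ")))
    }
  }
  list(model = model, universal = universal, media = media,
       ground_truth = ground_truth)
}

#' Build a synthetic ensemble with one phenotype-splitting reaction
#'
#' Constructs an ensemble directly from the single-split toy universe: the
#' constant gap-filled reactions are present in every member, the bypass
#' reaction `W_B1` and `n_decoys` dead-end decoy reactions are assigned to
#' members as independent fair coin flips (member rows deduplicated), and
#' the first two members are forced to the all-absent and all-present
#' patterns so every feature is variable. Essentiality simulated on this
#' ensemble is bimodal in exactly one gene (`gXW1`), flipped by the bypass.
#'
#' @param n_members number of unique members (default 200).
#' @param n_decoys decoy feature count (default 10).
#' @param seed RNG seed.
#' @return list with `ensemble`, `toy` (the underlying universe) and
#'   `ground_truth` (`splitter`, `split_gene`, per-member splitter
#'   presence).
#' @export
make_split_ensemble <- function(n_members = 200, n_decoys = 10, seed = 1) {
  spec <- fixture_spec(n_pathways = 1, n_decoy_reactions = n_decoys,
                       n_split_reactions = 1, seed = seed)
  toy <- make_toy_universe(spec, verify = FALSE)
  feat_ids <- c("W_B1", paste0("DEC", seq_len(n_decoys)))
  p <- length(feat_ids)
  if (n_members > 2^p - 0)
    stop("n_members exceeds the number of distinct feature patterns")
  set.seed(seed)
  rows <- matrix(0L, 0, p)
  rows <- rbind(rep(0L, p), rep(1L, p))
  while (nrow(rows) < n_members) {
    cand <- matrix(stats::rbinom((n_members - nrow(rows)) * p, 1, 0.5),
                   ncol = p)
    rows <- unique(rbind(rows, cand))
  }
  rows <- rows[seq_len(n_members), , drop = FALSE]
  colnames(rows) <- feat_ids
  recipes <- lapply(seq_len(n_members), function(i)
    sort(c(toy$ground_truth$constant_reactions, feat_ids[rows[i, ] == 1L])))
  ens <- new_ensemble(toy$model, toy$universal, recipes,
                      metadata = list(seed = seed, synthetic = TRUE,
                                      splitter = "W_B1"))
  list(ensemble = ens, toy = toy,
       ground_truth = list(splitter = "W_B1", split_gene = "gXW1",
                           has_splitter = stats::setNames(rows[, "W_B1"] == 1L,
                                                          ens$member_ids)))
}

#' Simulate a noisy experimental essentiality screen
#'
#' Takes one ensemble member's simulated essentiality as the underlying
#' truth and flips each gene's call independently with probability
#' `flip_fraction`, emulating the technical noise of in vitro screens.
#'
#' @param essentiality a `gc_essentiality`.
#' @param member_id the member whose calls serve as truth (default: first).
#' @param flip_fraction per-gene flip probability in [0, 1].
#' @param seed RNG seed.
#' @return data.frame with columns `gene`, `essential`.
#' @export
make_synthetic_essentiality <- function(essentiality,
                                        member_id = essentiality$member_ids[[1L]],
                                        flip_fraction = 0, seed = 1) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  truth <- essentiality$values[member_id, ]
  set.seed(seed)
  flip <- stats::rbinom(length(truth), 1, flip_fraction) == 1L
  data.frame(gene = essentiality$genes,
             essential = as.logical(xor(truth, flip)),
             stringsAsFactors = FALSE)
}

#' Write a fixture suite to disk
#'
#' Materializes a named fixture universe as the package's standard file
#' formats: draft model JSON, universal bag JSON, media TSV, and a
#' round-robin subsystem annotation TSV for the universal reactions.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_suite <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_universe(spec, verify = FALSE)
  write_model(toy$model, file.path(dir, "draft_model.json"))
  umets <- sort(unique(unlist(lapply(toy$universal$reactions,
                                     function(r) names(r$stoichiometry)))))
  u_model <- metabolic_model(
    "universal",
    data.frame(id = umets, name = umets,
               compartment = sub("^.*_", "", umets), stringsAsFactors = FALSE),
    toy$universal$reactions,
    names(toy$universal$reactions)[[1L]])
  write_model(u_model, file.path(dir, "universal.json"))
  write_media(toy$media, file.path(dir, "media.tsv"))
  subs <- c("carbon transport", "cofactor metabolism", "peripheral pathways")
  ann <- data.frame(reaction_id = names(toy$universal$reactions),
                    subsystem = subs[(seq_along(toy$universal$reactions) - 1L)
                                     %% length(subs) + 1L],
                    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(dir, "subsystems.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
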
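# Domain types for constraint-based metabolic models: metabolites,
# reactions, models, universal reaction bags, media, and readers/writers for
# the JSON model dialect, SBML Level 3 FBC, media TSV and subsystem TSV.
#
# Sign conventions follow the community standard: an exchange reaction is
# written A_e <=> (nothing), with negative flux meaning uptake. A medium
# therefore sets the exchange lower bound to -limit.

#' Construct a reaction
#'
#' @param id unique reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/hr.
#' @param gene_rule GPR string (may be empty).
#' @param subsystems character vector of subsystem names (may be empty).
#' @return a `gc_reaction` list.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000,
                     upper_bound = 1000, gene_rule = "",
                     subsystems = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L)
    stop(sprintf("reaction '%s': stoichiometry must be nonempty", id),
         call. = FALSE)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop(sprintf("reaction '%s': stoichiometry must be a named vector", id),
         call. = FALSE)
  if (lower_bound > upper_bound)
    stop(sprintf("reaction '%s': lower_bound (%g) > upper_bound (%g)",
                 id, lower_bound, upper_bound), call. = FALSE)
  structure(list(id = id,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene_rule = as.character(gene_rule),
                 subsystems = as.character(subsystems)),
            class = "gc_reaction")
}

#' Is a reaction an exchange reaction?
#'
#' A reaction is an exchange iff it has exactly one stoichiometric entry (a
#' boundary reaction importing/exporting a single metabolite). When a model
#' is supplied, the metabolite must additionally live in the extracellular
#' compartment ("e"), which distinguishes exchanges from single-metabolite
#' pseudo-reactions such as a biomass sink.
#' @param rxn a `gc_reaction`.
#' @param model optional `metabolic_model` for the compartment check.
#' @return logical scalar.
#' @export
is_exchange_reaction <- function(rxn, model = NULL) {
  if (length(rxn$stoichiometry) != 1L) return(FALSE)
  if (is.null(model)) return(TRUE)
  met <- names(rxn$stoichiometry)
  comp <- model$metabolites$compartment[match(met, model$metabolites$id)]
  isTRUE(comp == "e")
}

#' Construct a metabolic model
#'
#' @param id model id.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of [reaction()] objects.
#' @param biomass_reaction_id id of the biomass pseudo-reaction.
#' @return a validated `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass_reaction_id) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  mod <- structure(list(id = id,
                        metabolites = metabolites,
                        reactions = reactions,
                        biomass_reaction_id = biomass_reaction_id),
                   class = "metabolic_model")
  validate_model(mod)
  mod
}

#' Validate a metabolic model's invariants
#'
#' Checks id uniqueness, bound ordering, that every stoichiometry entry
#' resolves to a known metabolite, and that the biomass reaction exists.
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe every violation found.
#' @export
validate_model <- function(model) {
  errs <- character()
  mids <- model$metabolites$id
  if (any(duplicated(mids)))
    errs <- c(errs, paste0("duplicate metabolite ids: ",
                           paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  if (any(!nzchar(mids))) errs <- c(errs, "empty metabolite id")
  if (any(!nzchar(model$metabolites$compartment)))
    errs <- c(errs, "empty metabolite compartment")
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (any(duplicated(rids)))
    errs <- c(errs, paste0("duplicate reaction ids: ",
                           paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  for (rxn in model$reactions) {
    if (rxn$lower_bound > rxn$upper_bound)
      errs <- c(errs, sprintf("reaction '%s': lower_bound > upper_bound",
                              rxn$id))
    missing <- setdiff(names(rxn$stoichiometry), mids)
    if (length(missing) > 0L)
      errs <- c(errs, sprintf("reaction '%s': unknown metabolites %s",
                              rxn$id, paste(missing, collapse = ", ")))
  }
  if (!(model$biomass_reaction_id %in% rids))
    errs <- c(errs, sprintf("biomass reaction '%s' not found",
                            model$biomass_reaction_id))
  if (length(errs) > 0L)
    stop(paste0("invalid model '", model$id, "':\n  ",
                paste(errs, collapse = "\n  ")), call. = FALSE)
  invisible(model)
}

#' Gene ids of a model (union over all gene rules)
#' @param model a `metabolic_model`.
#' @return sorted character vector.
#' @export
model_genes <- function(model) {
  g <- unlist(lapply(model$reactions, function(r) gene_rule_genes(r$gene_rule)))
  sort(unique(g))
}

#' Exchange reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
exchange_ids <- function(model) {
  rids <- names(model$reactions)
  rids[vapply(model$reactions, is_exchange_reaction, logical(1),
              model = model)]
}

#' Stoichiometric matrix of a model
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoich_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (rxn in model$reactions)
    S[names(rxn$stoichiometry), rxn$id] <- rxn$stoichiometry
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(model_genes(x))))
  cat(sprintf("  biomass reaction: %s\n", x$biomass_reaction_id))
  invisible(x)
}

#' Construct a universal reaction bag
#'
#' Candidate reactions for gap filling. Reaction ids must be disjoint from
#' any model they are used to fill, and all bounds must be finite.
#' @param reactions list of [reaction()] objects (gene rules not required).
#' @return a `universal_bag`.
#' @export
universal_bag <- function(reactions) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (any(duplicated(names(reactions))))
    stop("duplicate reaction ids in universal bag", call. = FALSE)
  bounds <- unlist(lapply(reactions, function(r) c(r$lower_bound, r$upper_bound)))
  if (any(!is.finite(bounds)))
    stop("universal bag reactions must have finite bounds", call. = FALSE)
  structure(list(reactions = reactions), class = "universal_bag")
}

#' @export
print.universal_bag <- function(x, ...) {
  cat(sprintf("universal_bag: %d candidate reactions\n", length(x$reactions)))
  invisible(x)
}

#' Construct a growth medium
#'
#' @param name condition name.
#' @param uptake_limits named nonnegative numeric vector, exchange reaction
#'   id -> maximum uptake rate (mmol/gDW/hr).
#' @return a `gc_medium`.
#' @export
medium <- function(name, uptake_limits = numeric()) {
  if (length(uptake_limits) > 0L && any(uptake_limits < 0))
    stop(sprintf("medium '%s': negative uptake limit", name), call. = FALSE)
  structure(list(name = name, uptake_limits = uptake_limits),
            class = "gc_medium")
}

#' Complete (rich) medium for a model
#'
#' Allows uptake through every exchange reaction at the same limit,
#' defaulting to 1000 mmol/gDW/hr.
#' @param model a `metabolic_model`.
#' @param limit uptake limit applied to every exchange.
#' @return a `gc_medium` named "complete".
#' @export
complete_medium <- function(model, limit = 1000) {
  ex <- exchange_ids(model)
  medium("complete", stats::setNames(rep(as.numeric(limit), length(ex)), ex))
}

## ---- JSON model dialect ----------------------------------------------------

model_to_list <- function(model) {
  list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id,
           stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound,
           upper_bound = r$upper_bound,
           gene_rule = r$gene_rule,
           subsystems = as.list(r$subsystems))
    }),
    biomass_reaction_id = model$biomass_reaction_id)
}

#' Write a model to the canonical JSON dialect
#'
#' The writer emits a canonical field order so that
#' `write_model(read_model(x))` is byte-identical to a canonicalized `x`.
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  json <- jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE,
                           digits = NA, pretty = 2)
  writeLines(json, path)
  invisible(path)
}

read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("JSON parse error in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  need <- c("id", "metabolites", "reactions", "biomass_reaction_id")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0L)
    stop(sprintf("model JSON '%s' missing elements: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment, stringsAsFactors = FALSE)))
  rxns <- lapply(obj$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    reaction(id = r$id, stoichiometry = st,
             lower_bound = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
             upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
             gene_rule = if (is.null(r$gene_rule)) "" else r$gene_rule,
             subsystems = unlist(r$subsystems) %||% character())
  })
  metabolic_model(obj$id, mets, rxns, obj$biomass_reaction_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- SBML Level 3 FBC reader ----------------------------------------------

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop(sprintf("SBML parse error in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing"))
    stop(sprintf("SBML '%s': no <model> element found", path), call. = FALSE)
  mid <- xml2::xml_attr(model_node, "id") %||% "sbml_model"

  # global flux-bound parameters
  params <- xml2::xml_find_all(model_node, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  # gene products: id -> label
  gps <- xml2::xml_find_all(model_node, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(xml2::xml_attr(gps, "label"),
                              xml2::xml_attr(gps, "id"))
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]

  species <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)

  gpa_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      return(unname(gp_label[ref] %||% ref))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_rule, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx_nodes <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    sp_ref <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp, ns)
      if (length(refs) == 0L) return(numeric())
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    st <- c(sp_ref("./s:listOfReactants/s:speciesReference", -1),
            sp_ref("./s:listOfProducts/s:speciesReference", 1))
    if (length(st) == 0L)
      stop(sprintf("SBML '%s': reaction '%s' has empty stoichiometry",
                   path, rid), call. = FALSE)
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    if (is.na(lb_ref)) lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    if (is.na(ub_ref)) ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    rule <- if (inherits(gpa, "xml_missing")) "" else {
      gpa_to_rule(xml2::xml_children(gpa)[[1L]])
    }
    reaction(rid, st, lb, ub, gene_rule = rule)
  })

  obj_ref <- xml2::xml_find_first(
    model_node, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  biomass <- if (!inherits(obj_ref, "xml_missing")) {
    xml2::xml_attr(obj_ref, "reaction")
  } else {
    rids <- vapply(rxns, `[[`, character(1), "id")
    cand <- grep("biomass", rids, ignore.case = TRUE, value = TRUE)
    if (length(cand) == 0L)
      stop(sprintf("SBML '%s': no objective and no biomass-named reaction",
                   path), call. = FALSE)
    cand[[1L]]
  }
  metabolic_model(mid, mets, rxns, biomass)
}

#' Read a metabolic model from JSON or SBML
#'
#' @param path input file.
#' @param format "json" or "sbml"; guessed from the file extension by
#'   default (`.xml`/`.sbml` -> SBML).
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("model file '%s' does not exist", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

## ---- media and annotation tables -------------------------------------------

#' Read a media table
#'
#' TSV with exchange reaction ids in the first column and one column per
#' condition; cell values are maximum uptake rates. Missing or empty cells
#' are treated as zero uptake.
#' @param path TSV file path.
#' @return list of [medium()] objects, in column order.
#' @export
read_media <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 1L)
    stop(sprintf("media file '%s' has no columns", path), call. = FALSE)
  ex_ids <- as.character(tab[[1L]])
  conds <- names(tab)[-1L]
  lapply(conds, function(cn) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    v[is.na(v)] <- 0
    if (any(v < 0))
      stop(sprintf("media file '%s', condition '%s': negative uptake value",
                   path, cn), call. = FALSE)
    keep <- v != 0
    medium(cn, stats::setNames(v[keep], ex_ids[keep]))
  })
}

#' Write a media table
#' @param media list of [medium()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_media <- function(media, path) {
  ex <- sort(unique(unlist(lapply(media, function(m) names(m$uptake_limits)))))
  tab <- data.frame(exchange = ex, stringsAsFactors = FALSE)
  for (m in media) {
    v <- rep(0, length(ex))
    v[match(names(m$uptake_limits), ex)] <- m$uptake_limits
    tab[[m$name]] <- v
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reaction-to-subsystem annotation table
#'
#' TSV with columns `reaction_id` and `subsystem`; multiple rows per
#' reaction are allowed.
#' @param path TSV file path.
#' @return named list, reaction id -> character vector of subsystem names.
#' @export
read_subsystems <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "subsystem") %in% names(tab)))
    stop(sprintf("subsystem file '%s' must have columns reaction_id, subsystem",
                 path), call. = FALSE)
  split(tab$subsystem, tab$reaction_id)
}
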
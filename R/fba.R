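# Flux balance analysis and single-gene knockout essentiality.

#' Apply a medium to a model
#'
#' Resets every exchange reaction to "no uptake" (lower bound 0), then opens
#' uptake for the exchanges named in the medium by setting their lower bound
#' to `-limit`. Secretion bounds are left unchanged.
#'
#' @param model a `metabolic_model`.
#' @param medium a `gc_medium`.
#' @return the modified model.
#' @export
apply_medium <- function(model, medium) {
  ex <- exchange_ids(model)
  unknown <- setdiff(names(medium$uptake_limits), ex)
  if (length(unknown) > 0L)
    stop(sprintf("medium '%s' references unknown exchange reactions: %s",
                 medium$name, paste(unknown, collapse = ", ")), call. = FALSE)
  for (rid in ex)
    model$reactions[[rid]]$lower_bound <- max(model$reactions[[rid]]$lower_bound, 0)
  for (rid in names(medium$uptake_limits))
    model$reactions[[rid]]$lower_bound <- -medium$uptake_limits[[rid]]
  model
}

#' Flux balance analysis
#'
#' Solves the linear program max/min v_obj subject to S v = 0 and the
#' model's flux bounds, optionally under a medium.
#'
#' @param model a `metabolic_model`.
#' @param medium optional `gc_medium`; if NULL the model's bounds are used
#'   as-is.
#' @param objective objective reaction id (default: the biomass reaction).
#' @param sense "max" or "min".
#' @return a `flux_distribution`: list with `fluxes` (named vector),
#'   `objective_value` and `status` ("optimal", "infeasible" or
#'   "unbounded").
#' @export
solve_fba <- function(model, medium = NULL,
                      objective = model$biomass_reaction_id,
                      sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (!(objective %in% names(model$reactions)))
    stop(sprintf("objective reaction '%s' not in model", objective),
         call. = FALSE)
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(colnames(S) == objective)
  sol <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, sense = sense)
  fluxes <- sol$x
  names(fluxes) <- colnames(S)
  structure(list(fluxes = fluxes,
                 objective_value = sol$objective,
                 status = sol$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("flux_distribution: status=%s, objective=%s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Single-gene knockout essentiality screen
#'
#' For each gene of the model, constrains to zero every reaction whose gene
#' rule evaluates FALSE with that gene knocked out, maximizes biomass, and
#' calls the gene essential when the optimum falls below `threshold`
#' (infeasible problems count as zero biomass). The default threshold of
#' 1e-6 units of biomass/hr is deliberately low; calls are insensitive to
#' its exact value over several orders of magnitude.
#'
#' @param model a `metabolic_model`.
#' @param medium optional `gc_medium` (default: the model's current bounds).
#' @param threshold biomass flux below which a knockout is called lethal.
#' @param genes optional subset of genes to screen (default: all model
#'   genes).
#' @return data.frame with columns `gene`, `essential`, `biomass_flux`;
#'   attribute `threshold`.
#' @export
single_gene_knockouts <- function(model, medium = NULL, threshold = 1e-6,
                                  genes = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (is.null(genes)) genes <- model_genes(model)
  asts <- lapply(model$reactions, function(r) parse_gene_rule(r$gene_rule))
  rule_gene_sets <- lapply(asts, rule_genes_ast)
  res <- lapply(genes, function(g) {
    mod_ko <- model
    hit <- vapply(seq_along(asts), function(i) {
      g %in% rule_gene_sets[[i]] && !eval_rule_ast(asts[[i]], g)
    }, logical(1))
    for (rid in names(model$reactions)[hit]) {
      mod_ko$reactions[[rid]]$lower_bound <- 0
      mod_ko$reactions[[rid]]$upper_bound <- 0
    }
    fba <- solve_fba(mod_ko)
    flux <- if (fba$status == "optimal") fba$objective_value else 0
    data.frame(gene = g, essential = flux < threshold, biomass_flux = flux,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(), essential = logical(),
                      biomass_flux = numeric(), stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Write an essentiality screen result as TSV
#' @param calls data.frame from [single_gene_knockouts()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_essentiality <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
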
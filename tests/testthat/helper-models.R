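# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk unless a test writes it first.

# Linear chain: A_e --EX--> (uptake) --T_A(g1)--> A_c --R1--> B_c --BIOMASS.
chain_model <- function(r1_rule = "", t_rule = "g1") {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     name = c("A out", "A in", "precursor"),
                     compartment = c("e", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction("EX_A", c(A_e = -1), -1000, 1000),
    reaction("T_A", c(A_e = -1, A_c = 1), 0, 1000, gene_rule = t_rule),
    reaction("R1", c(A_c = -1, B_c = 1), 0, 1000, gene_rule = r1_rule),
    reaction("BIOMASS", c(B_c = -1), 0, 1000))
  metabolic_model("chain", mets, rxns, "BIOMASS")
}

glc_medium <- function(limit = 10) medium("glcA", c(EX_A = limit))

# Randomized small model for serialization round-trip properties.
random_model <- function(seed) {
  set.seed(seed)
  n_met <- sample(3:6, 1)
  mids <- paste0("m", seq_len(n_met), "_c")
  mets <- data.frame(id = mids, name = paste("met", seq_len(n_met)),
                     compartment = "c", stringsAsFactors = FALSE)
  rules <- c("", "gA", "gA and gB", "(gA or gB) and gC", "gB or gC")
  n_rxn <- sample(2:5, 1)
  rxns <- lapply(seq_len(n_rxn), function(i) {
    k <- sample(1:min(3, n_met), 1)
    st <- stats::setNames(round(stats::runif(k, -2, 2), 2) +
                            0.01, sample(mids, k))
    b <- sort(round(stats::runif(2, -100, 100), 2))
    reaction(paste0("R", i), st, b[1], b[2],
             gene_rule = sample(rules, 1),
             subsystems = sample(c("s1", "s2"), sample(0:2, 1)))
  })
  rxns <- c(rxns, list(reaction("BIOMASS", stats::setNames(-1, mids[1]),
                                0, 1000)))
  metabolic_model(paste0("rand", seed), mets, rxns, "BIOMASS")
}

minimal_sbml_lines <- function() {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="mini" fbc:strict="true">',
    '<listOfCompartments><compartment id="c" constant="true"/>',
    '<compartment id="e" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A_e" compartment="e" constant="false"/>',
    '<species id="A_c" name="A cyto" compartment="c" constant="false"/>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lb_ex" value="-10" constant="true"/>',
    '<parameter id="ub_def" value="1000" constant="true"/>',
    '<parameter id="zero" value="0" constant="true"/>',
    '</listOfParameters>',
    '<fbc:listOfGeneProducts>',
    '<fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>',
    '<fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>',
    '</fbc:listOfGeneProducts>',
    '<listOfReactions>',
    paste0('<reaction id="EX_A" reversible="true" ',
           'fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="ub_def">'),
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    paste0('<reaction id="T_A" reversible="false" ',
           'fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_def">'),
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfProducts>',
    '<fbc:geneProductAssociation><fbc:or>',
    '<fbc:geneProductRef fbc:geneProduct="G_g1"/>',
    '<fbc:geneProductRef fbc:geneProduct="G_g2"/>',
    '</fbc:or></fbc:geneProductAssociation>',
    '</reaction>',
    paste0('<reaction id="BIOMASS" reversible="false" ',
           'fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_def">'),
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives>',
    '<fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>',
    '</fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
    '</model></sbml>')
}

# A one-member essentiality container with many genes (for sampling checks).
mini_wide_essentiality <- function(n_genes) {
  set.seed(1)
  genes <- paste0("g", seq_len(n_genes))
  vals <- matrix(stats::rbinom(n_genes, 1, 0.5) == 1, nrow = 1,
                 dimnames = list("m1", genes))
  structure(list(values = vals, genes = genes, member_ids = "m1",
                 threshold = 1e-6, medium_name = "complete"),
            class = "gc_essentiality")
}

# All permutations of a character vector (tiny n only).
combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(combinat_perms(x[-i]), function(p) c(x[i], p)))
  out
}

# Build an ensemble directly from presence patterns over decoy reactions of
# a toy universe (for subsampling and metric tests that need controlled
# feature frequencies).
patterned_ensemble <- function(presence, toy = NULL) {
  if (is.null(toy)) {
    toy <- make_toy_universe(fixture_spec(1, ncol(presence), 0),
                             verify = FALSE)
  }
  feat_ids <- paste0("DEC", seq_len(ncol(presence)))
  colnames(presence) <- feat_ids
  recipes <- lapply(seq_len(nrow(presence)), function(i)
    sort(c("D_A1", feat_ids[presence[i, ] == 1])))
  new_ensemble(toy$model, toy$universal, recipes)
}
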
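test_that("toy chain model satisfies the domain invariants", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_length(m$reactions, 4)
  expect_equal(nrow(m$metabolites), 3)
  expect_identical(model_genes(m), "g1")
  expect_identical(exchange_ids(m), "EX_A")
  expect_true(is_exchange_reaction(m$reactions$EX_A))
  expect_false(is_exchange_reaction(m$reactions$T_A))
})

test_that("constructors reject invariant violations", {
  expect_error(reaction("bad", c(A_c = -1), 5, 1), "lower_bound")
  expect_error(reaction("bad", numeric()), "nonempty")
  mets <- data.frame(id = c("A_c", "A_c"), name = "a", compartment = "c",
                     stringsAsFactors = FALSE)
  expect_error(
    metabolic_model("dup", mets,
                    list(reaction("R", c(A_c = -1)),
                         reaction("BIOMASS", c(A_c = -1), 0, 1000)),
                    "BIOMASS"),
    "duplicate metabolite")
  expect_error(
    metabolic_model("m", data.frame(id = "A_c", name = "a",
                                    compartment = "c"),
                    list(reaction("R", c(Zmissing = -1))), "R"),
    "unknown metabolites")
  expect_error(
    metabolic_model("m", data.frame(id = "A_c", name = "a",
                                    compartment = "c"),
                    list(reaction("R", c(A_c = -1))), "NOPE"),
    "biomass")
})

test_that("JSON dialect round-trips losslessly and byte-identically", {
  dir <- withr::local_tempdir()
  m <- chain_model(r1_rule = "g2 or g3")
  p1 <- file.path(dir, "a.json"); p2 <- file.path(dir, "b.json")
  write_model(m, p1)
  m2 <- read_model(p1)
  write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(m2$reactions$R1$gene_rule, "g2 or g3")
  expect_identical(m2$biomass_reaction_id, "BIOMASS")

  # property: randomized models survive the round trip with all fields
  for (seed in 1:8) {
    rm <- random_model(seed)
    pa <- file.path(dir, "r1.json"); pb <- file.path(dir, "r2.json")
    write_model(rm, pa)
    rm2 <- read_model(pa)
    write_model(rm2, pb)
    expect_identical(readLines(pa), readLines(pb), info = paste("seed", seed))
    expect_equal(rm2$reactions, rm$reactions, info = paste("seed", seed))
  }
})

test_that("invalid model JSON is rejected with informative errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.json")
  writeLines('{"id": "x", "metabolites": []', bad)   # truncated
  expect_error(read_model(bad), "parse error")
  writeLines(jsonlite::toJSON(list(
    id = "x",
    metabolites = list(list(id = "A_c", name = "a", compartment = "c")),
    reactions = list(list(id = "R", stoichiometry = list(A_c = -1),
                          lower_bound = 5, upper_bound = 1)),
    biomass_reaction_id = "R"), auto_unbox = TRUE), bad)
  expect_error(read_model(bad), "lower_bound")
  expect_error(read_model(file.path(dir, "nope.json")), "does not exist")
})

test_that("SBML Level 3 FBC models read with bounds, GPRs and objective", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "mini.xml")
  writeLines(minimal_sbml_lines(), f)
  m <- read_model(f)                       # format guessed from extension
  expect_equal(m$reactions$EX_A$lower_bound, -10)
  expect_equal(m$reactions$T_A$lower_bound, 0)
  expect_identical(m$reactions$T_A$gene_rule, "(g1 or g2)")
  expect_identical(m$biomass_reaction_id, "BIOMASS")
  expect_setequal(model_genes(m), c("g1", "g2"))
  fba <- solve_fba(m)
  expect_equal(fba$objective_value, 10)    # limited by the SBML uptake bound
})

test_that("media tables parse with zero-filled gaps and preserved order", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "media.tsv")
  writeLines(c("exchange\tglcA\tempty", "EX_A\t10\t", "EX_B\t0\t"), f)
  media <- read_media(f)
  expect_length(media, 2)
  expect_identical(media[[1]]$name, "glcA")
  expect_equal(media[[1]]$uptake_limits, c(EX_A = 10))
  expect_length(media[[2]]$uptake_limits, 0)

  writeLines(c("exchange\tbad", "EX_A\t-5"), f)
  expect_error(read_media(f), "negative")

  # generator contract: n media, names preserved in order
  toy <- make_toy_universe(fixture_spec(2, 0, 1), verify = FALSE)
  write_media(toy$media, f)
  back <- read_media(f)
  expect_identical(vapply(back, `[[`, character(1), "name"),
                   names(toy$media))
})

test_that("complete medium opens every exchange at the stated limit", {
  m <- chain_model()
  cm <- complete_medium(m)
  expect_equal(cm$uptake_limits, c(EX_A = 1000))
  expect_equal(complete_medium(m, limit = 5)$uptake_limits, c(EX_A = 5))
  # no-exchange model yields an empty medium
  m2 <- metabolic_model("noex",
                        data.frame(id = c("A_c", "B_c"), name = "x",
                                   compartment = "c"),
                        list(reaction("R1", c(A_c = -1, B_c = 1), 0, 10),
                             reaction("BIOMASS", c(B_c = -1), 0, 10)),
                        "BIOMASS")
  expect_length(complete_medium(m2)$uptake_limits, 0)
})

test_that("subsystem annotation tables allow multiple rows per reaction", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "subs.tsv")
  writeLines(c("reaction_id\tsubsystem", "R1\trespiration",
               "R1\tnucleotides", "R2\trespiration"), f)
  ann <- read_subsystems(f)
  expect_setequal(ann$R1, c("respiration", "nucleotides"))
  expect_identical(ann$R2, "respiration")
})
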
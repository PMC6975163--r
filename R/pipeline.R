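# End-to-end pipeline orchestration with reproducibility metadata. The R
# functions (and this runner) are the package's interface; a thin Rscript
# wrapper around run_pipeline() ships in inst/cli for shell use.

#' Pipeline configuration
#'
#' Bundles the input paths and method parameters for [run_pipeline()]. The
#' defaults are the method's standard settings: 1000 gap-fill cycles, a
#' biomass floor of 0.05/hr, an activation cutoff of 1e-11, and an
#' essentiality threshold of 1e-6 units of biomass/hr.
#'
#' @param model_path draft model file (JSON or SBML).
#' @param universal_path universal reaction bag (model JSON dialect).
#' @param media_path media TSV.
#' @param essentiality_path optional experimental essentiality TSV (columns
#'   `gene`, `essential`).
#' @param annotation_path optional subsystem TSV.
#' @param out_dir output directory.
#' @param n_members gap-fill cycles (default 1000).
#' @param biomass_floor gap-fill growth floor (default 0.05 /hr).
#' @param activation_cutoff flux cutoff for reaction activation (default
#'   1e-11).
#' @param essentiality_threshold biomass cutoff for an essential call
#'   (default 1e-6).
#' @param subsample_step,subsample_draws subsampling parameters (defaults
#'   20 and 1000).
#' @param min_unique minimum unique ensemble members (default 3).
#' @param seed master RNG seed.
#' @return a `run_config` list.
#' @export
run_config <- function(model_path, universal_path, media_path,
                       essentiality_path = NULL, annotation_path = NULL,
                       out_dir = "gemcurate_out",
                       n_members = 1000, biomass_floor = 0.05,
                       activation_cutoff = 1e-11,
                       essentiality_threshold = 1e-6,
                       subsample_step = 20, subsample_draws = 1000,
                       min_unique = 3, seed = 1) {
  cfg <- list(model_path = model_path, universal_path = universal_path,
              media_path = media_path,
              essentiality_path = essentiality_path,
              annotation_path = annotation_path, out_dir = out_dir,
              n_members = n_members, biomass_floor = biomass_floor,
              activation_cutoff = activation_cutoff,
              essentiality_threshold = essentiality_threshold,
              subsample_step = subsample_step,
              subsample_draws = subsample_draws,
              min_unique = min_unique, seed = seed)
  stopifnot(cfg$n_members >= 1, cfg$biomass_floor > 0,
            cfg$activation_cutoff > 0, cfg$essentiality_threshold > 0)
  structure(cfg, class = "run_config")
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full curation-targeting pipeline
#'
#' Stages: (1) gap-fill ensemble generation, (2) ensemble gene-essentiality
#' simulation and subsampling diagnostics, (3) clustering/classification
#' and curation metrics, (4, optional) evaluation against an experimental
#' essentiality screen and subsystem statistics. All artifacts are written
#' under `config$out_dir` as TSV/JSON, along with a run manifest recording
#' parameters, seeds, package version and per-stage wall time. A stage
#' failure halts the run with the stage name; artifacts from completed
#' stages persist.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory `ensemble`, `essentiality`,
#'   `metrics`, optional `evaluation`, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("gemcurate")),
                   parameters = unclass(config), stages = list())
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<-
      list(status = "complete",
           seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  model <- read_model(config$model_path)
  universal <- universal_bag(read_model(config$universal_path)$reactions)
  media <- read_media(config$media_path)

  ensemble <- t_stage("gapfill_ensemble", function() {
    ens <- generate_ensemble(model, universal, media,
                             n = config$n_members, seed = config$seed,
                             min_unique = config$min_unique,
                             biomass_floor = config$biomass_floor,
                             activation_cutoff = config$activation_cutoff)
    write_ensemble(ens, file.path(config$out_dir, "ensemble"))
    ens
  })

  essentiality <- t_stage("simulate_essentiality", function() {
    ess <- ensemble_essentiality(ensemble,
                                 threshold = config$essentiality_threshold)
    write_tsv_(data.frame(member = rownames(ess$values),
                          ess$values * 1L, check.names = FALSE),
               file.path(config$out_dir, "essentiality_matrix.tsv"))
    for (stat in c("variable_reactions", "non_consensus_genes")) {
      crv <- subsample_curve(ensemble, statistic = stat,
                             essentiality = ess,
                             step = config$subsample_step,
                             draws = config$subsample_draws,
                             seed = config$seed)
      crv$statistic <- stat
      write_tsv_(crv, file.path(config$out_dir,
                                paste0("subsample_", stat, ".tsv")))
    }
    ess
  })

  metrics <- t_stage("analyze", function() {
    met <- curation_metrics(ensemble, essentiality, seed = config$seed)
    write_tsv_(met$targets, file.path(config$out_dir, "curation_targets.tsv"))
    write_tsv_(data.frame(member = names(met$clusters$labels),
                          cluster = unname(met$clusters$labels)),
               file.path(config$out_dir, "cluster_labels.tsv"))
    write_tsv_(data.frame(member = rownames(met$pcoa$coordinates),
                          met$pcoa$coordinates, check.names = FALSE),
               file.path(config$out_dir, "pcoa_coordinates.tsv"))
    met
  })

  evaluation <- NULL
  if (!is.null(config$essentiality_path)) {
    evaluation <- t_stage("evaluate", function() {
      exp_tab <- utils::read.delim(config$essentiality_path,
                                   stringsAsFactors = FALSE)
      report <- precision_recall(essentiality, exp_tab,
                                 labels = metrics$clusters$labels)
      write_tsv_(report, file.path(config$out_dir, "performance.tsv"))
      tests <- compare_cluster_performance(report)
      write_tsv_(tests, file.path(config$out_dir, "cluster_tests.tsv"))
      list(report = report, tests = tests)
    })
  }
  if (!is.null(config$annotation_path)) {
    t_stage("subsystems", function() {
      ann <- read_subsystems(config$annotation_path)
      ss <- tryCatch(subsystem_stats(metrics$targets, ann,
                                     value = "fractional_importance"),
                     error = function(e) NULL)
      if (!is.null(ss)) {
        write_tsv_(ss$pairwise, file.path(config$out_dir,
                                          "subsystem_pairwise.tsv"))
        write_tsv_(ss$group_summary, file.path(config$out_dir,
                                               "subsystem_summary.tsv"))
      }
      ss
    })
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(ensemble = ensemble, essentiality = essentiality,
                 metrics = metrics, evaluation = evaluation,
                 manifest = manifest))
}
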
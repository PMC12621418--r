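#' Pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()]. Either an
#' in-memory `msc_world` or a world directory (see [write_world()]) must be
#' supplied. All analysis parameters default to the canonical protocol:
#' elastic-net mixing 0.85, key-metabolite threshold 0.3, minimal
#' communities computed on basal medium.
#'
#' @param world An `msc_world`, or `NULL` when `world_dir` is given.
#' @param world_dir Directory containing a written world.
#' @param out_dir Output directory for artifacts; `NULL` disables writing.
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param penalty Cross-validation penalty rule (see [fit_elastic_net()]).
#' @param threshold Key-metabolite coefficient threshold (>= 0).
#' @param design Regression observation design (see [build_design()]).
#' @param mincom_condition Condition name used for minimal communities.
#' @param cap Solution-enumeration cap.
#' @param cluster_k Number of environmental-variable clusters to cut.
#' @param include_seeds Scope convention for the grid.
#' @param seed Integer seed for all seeded stages.
#' @return A `msc_pipeline_config` list.
#' @export
pipeline_config <- function(world = NULL, world_dir = NULL, out_dir = NULL,
                            alpha = 0.85, penalty = "1se", threshold = 0.3,
                            design = "simulation",
                            mincom_condition = "basal_medium",
                            cap = 10000L, cluster_k = 3L,
                            include_seeds = FALSE, seed = 1L) {
  if (is.null(world) && is.null(world_dir))
    stop2("either `world` or `world_dir` must be given")
  if (!is.null(world_dir) && !dir.exists(world_dir))
    stop2("world directory does not exist: ", world_dir)
  if (alpha < 0 || alpha > 1) stop2("alpha must lie in [0, 1]")
  if (threshold < 0) stop2("threshold must be >= 0")
  structure(list(world = world, world_dir = world_dir, out_dir = out_dir,
                 alpha = alpha, penalty = penalty, threshold = threshold,
                 design = design,
                 mincom_condition = mincom_condition, cap = as.integer(cap),
                 cluster_k = as.integer(cluster_k),
                 include_seeds = include_seeds, seed = as.integer(seed)),
            class = "msc_pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Stages, in order: simulation grid over all systems and conditions;
#' gap-fill artifact filter; collapse into metabolite groups; elastic-net
#' association with the environmental table; key-metabolite selection;
#' environmental-variable clustering; per-site target filtering, minimal
#' community solving and enumeration with key-species classification and
#' abundance summaries. Deterministic: identical configuration and seed
#' reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `msc_run`: all stage outputs plus `report`,
#'   a summary whose every number is recomputable from the stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "msc_pipeline_config"))
  world <- config$world %||% read_world(config$world_dir)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  # hash covers analysis parameters and the world's identity (its seed and
  # configuration), not filesystem paths, so identical runs from different
  # directories agree
  cfg_for_hash <- config[setdiff(names(config),
                                 c("world", "world_dir", "out_dir"))]
  cfg_for_hash$world_config <- unclass(world$config)
  config_hash <- object_hash(cfg_for_hash)

  # 1. simulation grid
  grid <- run_grid(world$systems, world$conditions,
                   include_seeds = config$include_seeds)

  # 2. gap-fill artifact filter
  filt <- withCallingHandlers(
    filter_gapfill_artifacts(grid),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  # 3. metabolite groups
  groups <- collapse_groups(filt$matrix)

  # 4. association
  env_std <- standardize_env(world$env)
  design <- build_design(groups, env_std, design = config$design)
  fits <- associate_all(design, alpha = config$alpha,
                        penalty = config$penalty, seed = config$seed)
  keyset <- select_key_metabolites(fits, groups, threshold = config$threshold)

  clusters <- NULL
  if (length(keyset$selected_groups) >= 1L) {
    clusters <- tryCatch(cluster_variables(keyset$coef_matrix, k = config$cluster_k),
                         error = function(e) { note(conditionMessage(e)); NULL })
  } else note("no metabolite group passed the key threshold; clustering skipped")

  # 5. minimal communities per site, on the genome-resolved systems
  mincom_cond <- world$conditions[[config$mincom_condition]] %||%
    stop2("unknown mincom condition '", config$mincom_condition, "'")
  gr_systems <- Filter(function(s) s$scale == "genome_resolved", world$systems)
  mincom <- list()
  if (length(keyset$key_metabolites)) {
    for (sys in gr_systems) {
      targets <- filter_targets(sys, mincom_cond, keyset$key_metabolites)
      if (!length(targets$producible)) {
        mincom[[sys$site]] <- list(targets = targets, solutions = NULL)
        next
      }
      sol <- enumerate_solutions(sys, mincom_cond, targets$producible,
                                 cap = config$cap)
      subst <- if (!sol$partial) substitutable_groups(sol) else NULL
      ab <- world$abundances[[sys$site]]
      abund <- if (!sol$partial && !is.null(ab) &&
                   all(sol$key_species %in% names(ab)))
        abundance_summary(sol, ab) else NULL
      mincom[[sys$site]] <- list(targets = targets, solutions = sol,
                                 substitutable = subst, abundance = abund)
    }
  } else note("no key metabolites selected; minimal communities skipped")

  report <- build_report(config_hash, world, grid, filt, groups, keyset,
                         clusters, mincom, warnings_log)
  run <- structure(list(world = world, grid = grid,
                        filtered = filt$matrix, removed = filt$removed,
                        groups = groups, env = env_std, design = design,
                        fits = fits, keyset = keyset, clusters = clusters,
                        mincom = mincom, report = report,
                        config = config),
                   class = "msc_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

build_report <- function(config_hash, world, grid, filt, groups, keyset,
                         clusters, mincom, warnings_log) {
  per_site <- lapply(mincom, function(m) {
    if (is.null(m$solutions)) return(list(producible_targets = 0L))
    s <- m$solutions
    list(requested_targets = length(m$targets$requested),
         producible_targets = length(m$targets$producible),
         k = s$k,
         n_solutions = if (s$partial) NA else length(s$solutions),
         n_key_species = if (s$partial) NA else length(s$key_species),
         n_essential = if (s$partial) NA else length(s$essential),
         n_alternative = if (s$partial) NA else length(s$alternative),
         mc_ks_percent = s$mc_ks_percent,
         key_species_abundance = if (!is.null(m$abundance))
           m$abundance$key_species_abundance else NA)
  })
  list(
    package_version = as.character(utils::packageVersion("metascope")),
    config_hash = config_hash,
    scope_convention = grid$convention,
    n_systems = length(world$systems),
    n_conditions = length(world$conditions),
    n_simulations = ncol(grid$values),
    scope_sizes = as.list(grid$scope_sizes),
    n_metabolites_unfiltered = nrow(grid$values),
    n_artifacts_removed = length(filt$removed),
    removed_artifacts = filt$removed,
    n_metabolites = nrow(filt$matrix$values),
    n_groups = length(groups),
    n_selected_groups = length(keyset$selected_groups),
    n_key_metabolites = length(keyset$key_metabolites),
    key_threshold = keyset$threshold,
    variable_clusters = if (!is.null(clusters)) as.list(clusters$clusters) else NULL,
    minimal_communities = per_site,
    warnings = warnings_log
  )
}

#' @export
print.msc_run <- function(x, ...) {
  r <- x$report
  cat("<pipeline run>\n")
  cat(sprintf("  simulations: %d | metabolites: %d (%d artifacts removed) | groups: %d\n",
              r$n_simulations, r$n_metabolites, r$n_artifacts_removed, r$n_groups))
  cat(sprintf("  selected groups: %d | key metabolites: %d (|coef| > %g)\n",
              r$n_selected_groups, r$n_key_metabolites, r$key_threshold))
  for (s in names(r$minimal_communities)) {
    m <- r$minimal_communities[[s]]
    if (!is.null(m$k))
      cat(sprintf("  %s: k = %d, %s solution(s), MC:KS = %.1f%%\n", s, m$k,
                  m$n_solutions, m$mc_ks_percent))
  }
  invisible(x)
}

#' Write pipeline artifacts to a run directory
#'
#' Fixed layout: `matrix.tsv`, `removed_artifacts.tsv`, `groups.tsv`,
#' `key_metabolites.tsv`, `coefficients.tsv`, per-site
#' `mincom/<site>.json`, and `report.json`.
#'
#' @param run An `msc_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(run$filtered, file.path(dir, "matrix.tsv"))
  writeLines(c("metabolite", run$removed), file.path(dir, "removed_artifacts.tsv"))
  write_groups_tsv(run$groups, file.path(dir, "groups.tsv"))
  write_keyset_tsv(run$keyset, file.path(dir, "coefficients.tsv"))
  writeLines(c("metabolite", run$keyset$key_metabolites),
             file.path(dir, "key_metabolites.tsv"))
  if (length(run$mincom)) {
    mdir <- file.path(dir, "mincom")
    dir.create(mdir, showWarnings = FALSE)
    for (s in names(run$mincom)) {
      m <- run$mincom[[s]]
      if (!is.null(m$solutions))
        write_solutions_json(m$solutions, file.path(mdir, paste0(s, ".json")),
                             substitutable = m$substitutable)
    }
  }
  write_json_canonical(run$report, file.path(dir, "report.json"))
  invisible(dir)
}
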
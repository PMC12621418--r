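# Synthetic-world generator: communities of organism networks whose union
# approximates a metagenome network plus unbinned reactions, with planted
# cross-feeding hand-offs, planted producer redundancy, MAG-only gap-fill
# artifacts, and metabolite producibility patterns correlated with synthetic
# environmental variables. Every planted structure is recorded in a manifest
# so the analysis modules can be benchmarked against ground truth.

#' Synthetic-world configuration
#'
#' Defaults emulate the canonical study design: six sites, two scales,
#' five nested nutrient conditions, 17 environmental variables, and
#' moderate cross-feeding and redundancy.
#'
#' @param n_sites Number of sites.
#' @param organisms_min,organisms_max Range of organisms (MAGs) per site.
#' @param universe_size Number of distinct non-seed product metabolites.
#' @param pathway_length_min,pathway_length_max Pathway length range
#'   (reactions per pathway template, uniform).
#' @param crossfeeding_split Probability that a pathway instance is split
#'   across two organisms (planting cooperation-only products).
#' @param redundancy_level Number of interchangeable organisms carrying a
#'   redundant pathway copy.
#' @param redundancy_prob Probability that an unsplit pathway instance is
#'   duplicated into `redundancy_level` organisms.
#' @param n_env_variables Number of environmental variables.
#' @param n_planted_associated_groups Number of pathway templates whose
#'   site-level producibility is planted to correlate with an
#'   environmental variable.
#' @param association_effect Planted effect size on the standardized scale.
#' @param response_noise_sd Residual noise sd of planted variables.
#' @param unbinned_reaction_fraction Fraction of extra metagenome-only
#'   pathway templates relative to `n_templates` (reactions that were
#'   never binned into a MAG).
#' @param mag_only_artifact_count Number of planted gap-fill artifacts
#'   (MAG-producible, metagenome-unreachable metabolites) per world.
#' @param n_templates Number of shared pathway templates.
#' @param template_site_prob Probability that a template occurs at a site.
#' @param condition_seed_fraction Fraction of templates requiring one
#'   condition-specific co-substrate (sugar or amino acid) in addition to
#'   basal seeds, so the five conditions differentiate scopes.
#' @param seed Integer random seed; the world is fully deterministic
#'   given the configuration.
#' @return A `msc_world_config` list.
#' @export
world_config <- function(n_sites = 6L,
                         organisms_min = 8L, organisms_max = 20L,
                         universe_size = 300L,
                         pathway_length_min = 2L, pathway_length_max = 6L,
                         crossfeeding_split = 0.3,
                         redundancy_level = 2L,
                         redundancy_prob = 0.15,
                         n_env_variables = 17L,
                         n_planted_associated_groups = 4L,
                         association_effect = 0.6,
                         response_noise_sd = 0.2,
                         unbinned_reaction_fraction = 0.2,
                         mag_only_artifact_count = 5L,
                         n_templates = 40L,
                         template_site_prob = 0.9,
                         condition_seed_fraction = 0.5,
                         seed = 42L) {
  cfg <- list(n_sites = as.integer(n_sites),
              organisms_min = as.integer(organisms_min),
              organisms_max = as.integer(organisms_max),
              universe_size = as.integer(universe_size),
              pathway_length_min = as.integer(pathway_length_min),
              pathway_length_max = as.integer(pathway_length_max),
              crossfeeding_split = crossfeeding_split,
              redundancy_level = as.integer(redundancy_level),
              redundancy_prob = redundancy_prob,
              n_env_variables = as.integer(n_env_variables),
              n_planted_associated_groups = as.integer(n_planted_associated_groups),
              association_effect = association_effect,
              response_noise_sd = response_noise_sd,
              unbinned_reaction_fraction = unbinned_reaction_fraction,
              mag_only_artifact_count = as.integer(mag_only_artifact_count),
              n_templates = as.integer(n_templates),
              template_site_prob = template_site_prob,
              condition_seed_fraction = condition_seed_fraction,
              seed = as.integer(seed))
  counts <- cfg[c("n_sites", "organisms_min", "organisms_max", "universe_size",
                  "pathway_length_min", "pathway_length_max", "redundancy_level",
                  "n_env_variables", "n_templates")]
  if (any(unlist(counts) <= 0L)) stop2("all counts must be positive")
  probs <- cfg[c("crossfeeding_split", "redundancy_prob", "template_site_prob",
                 "unbinned_reaction_fraction", "condition_seed_fraction")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop2("probabilities must lie in [0, 1]")
  if (cfg$organisms_min > cfg$organisms_max)
    stop2("organisms_min exceeds organisms_max")
  if (cfg$redundancy_level > cfg$organisms_min)
    stop2("redundancy_level exceeds the minimum number of organisms per site")
  if (cfg$n_planted_associated_groups > cfg$n_templates)
    stop2("more planted associated groups than templates")
  structure(cfg, class = "msc_world_config")
}

# Synthetic condition library with the canonical sizes (43/50/64/61/63)
# over an abstract seed universe.
synthetic_condition_library <- function() {
  basal <- sprintf("SEED_B%02d", 1:43)
  lib <- list(
    basal_medium = seed_condition("basal_medium", basal),
    simple_sugars = seed_condition("simple_sugars",
      c(basal, sprintf("SEED_SS%d", 1:7)), parent = "basal_medium"),
    complex_sugars = seed_condition("complex_sugars",
      c(basal, sprintf("SEED_CX%02d", 1:21)), parent = "basal_medium"),
    non_sulfured_amino_acids = seed_condition("non_sulfured_amino_acids",
      c(basal, sprintf("SEED_AA%02d", 1:18)), parent = "basal_medium"),
    all_amino_acids = seed_condition("all_amino_acids",
      c(basal, sprintf("SEED_AA%02d", 1:18), "SEED_CYS", "SEED_MET"),
      parent = "non_sulfured_amino_acids")
  )
  validate_condition_library(structure(lib, class = "msc_condition_library"))
}

# Conditions under which a template tier can fire.
TIER_CONDITIONS <- list(
  basal = c("basal_medium", "simple_sugars", "complex_sugars",
            "non_sulfured_amino_acids", "all_amino_acids"),
  simple = "simple_sugars",
  complex = "complex_sugars",
  nsaa = c("non_sulfured_amino_acids", "all_amino_acids"),
  sulfur = "all_amino_acids"
)

# The 17 variables measured in situ in the emulated design.
ENV_VARIABLE_NAMES <- c("pH", "EC", "OM", "N", "NH4", "NO3", "P", "K", "Mg",
                        "Ca", "Cu", "Fe", "Zn", "Mn", "B", "S", "Na")

#' Generate a synthetic world
#'
#' Builds, deterministically from the configuration seed, a full study
#' design: per site a collection of organism networks assembled from shared
#' pathway templates (some split across organisms, planting
#' cooperation-only metabolites; some duplicated, planting interchangeable
#' producers), a metagenome network (the union of the members plus
#' metagenome-only "unbinned" pathways), planted MAG-only gap-fill
#' artifacts, a synthetic environmental table with planted
#' group-to-variable associations, per-site organism abundances, and the
#' ground-truth manifest of every planted structure.
#'
#' @param config A [world_config()].
#' @param dir Optional directory; when given, the world is written to disk
#'   (SBML member and metagenome networks, conditions YAML, environment
#'   and abundance TSVs, manifest JSON) with byte-identical output for
#'   identical configurations.
#' @return An object of class `msc_world`: `config`, `conditions`,
#'   `systems` (list of `msc_system`, 2 per site), `env` (site x variable
#'   data.frame), `abundances` (per-site named vectors), `manifest`.
#' @export
generate_world <- function(config = world_config(), dir = NULL) {
  stopifnot(inherits(config, "msc_world_config"))
  set.seed(config$seed)
  conditions <- synthetic_condition_library()
  basal <- conditions$basal_medium$seeds
  cond_seed_pool <- list(
    simple = setdiff(conditions$simple_sugars$seeds, basal),
    complex = setdiff(conditions$complex_sugars$seeds, basal),
    nsaa = setdiff(conditions$non_sulfured_amino_acids$seeds, basal),
    sulfur = c("SEED_CYS", "SEED_MET")
  )
  sites <- sprintf("S%d", seq_len(config$n_sites))

  n_unbinned <- max(1L, round(config$unbinned_reaction_fraction * config$n_templates))
  pool <- sprintf("M%03d", seq_len(config$universe_size))
  lengths_needed <- config$n_templates + n_unbinned
  next_free <- 1L

  draw_products <- function(L) {
    if (next_free + L - 1L > length(pool))
      stop2("unsatisfiable config: metabolite universe exhausted; ",
            "increase universe_size or reduce templates")
    out <- pool[next_free:(next_free + L - 1L)]
    next_free <<- next_free + L
    out
  }

  make_template <- function(id, tier) {
    L <- sample(config$pathway_length_min:config$pathway_length_max, 1L)
    products <- draw_products(L)
    reactions <- vector("list", L)
    for (i in seq_len(L)) {
      inputs <- if (i == 1L) sample(basal, sample(1:2, 1L))
                else c(products[i - 1L],
                       if (stats::runif(1) < 0.3) sample(basal, 1L))
      if (i == 1L && tier != "basal")
        inputs <- c(inputs, sample(cond_seed_pool[[tier]], 1L))
      # irreversible only: ground-truth reachability is then exactly the
      # template combinatorics (reverse rules could regenerate seed ids and
      # silently enlarge the scope beyond the manifest)
      reactions[[i]] <- reaction(sprintf("%s_s%d", id, i), inputs, products[i])
    }
    list(id = id, tier = tier, length = L, products = products,
         reactions = reactions)
  }

  # tiers: guarantee enough basal templates to host the planted associations
  tier_names <- names(TIER_CONDITIONS)
  n_cond <- round(config$condition_seed_fraction * config$n_templates)
  n_basal <- config$n_templates - n_cond
  if (n_basal < config$n_planted_associated_groups)
    stop2("unsatisfiable config: not enough basal-tier templates to plant associations")
  tiers <- c(rep("basal", n_basal),
             sample(tier_names[-1L], n_cond, replace = TRUE))
  tiers <- sample(tiers)
  templates <- lapply(seq_len(config$n_templates), function(t)
    make_template(sprintf("T%02d", t), tiers[t]))
  names(templates) <- vapply(templates, `[[`, character(1), "id")
  unbinned <- lapply(seq_len(n_unbinned), function(u)
    make_template(sprintf("U%02d", u),
                  sample(tier_names, 1L, prob = c(0.6, rep(0.1, 4)))))
  names(unbinned) <- vapply(unbinned, `[[`, character(1), "id")

  # planted associated templates: basal tier, site patterns fixed below
  basal_ids <- names(templates)[vapply(templates, `[[`, character(1), "tier") == "basal"]
  planted_ids <- sort(sample(basal_ids, config$n_planted_associated_groups))

  # site presence of templates
  presence <- matrix(stats::runif(config$n_templates * config$n_sites) <
                       config$template_site_prob,
                     nrow = config$n_templates,
                     dimnames = list(names(templates), sites))
  # planted templates get distinct, balanced, mutually distinguishable site
  # patterns: pairwise overlap strictly between 0 and the pattern size, so
  # no two planted patterns are identical or complementary (which would make
  # their associations statistically inseparable at few sites)
  half <- max(1L, config$n_sites %/% 2L)
  chosen <- list()
  for (pid in planted_ids) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 10000L)
        stop2("unsatisfiable config: cannot plant ",
              config$n_planted_associated_groups,
              " mutually distinguishable site patterns over ",
              config$n_sites, " sites")
      p <- logical(config$n_sites)
      p[sample(config$n_sites, half)] <- TRUE
      ok <- all(vapply(chosen, function(q) {
        ov <- sum(p & q)
        ov >= 1L && ov < half
      }, logical(1)))
      if (ok) break
    }
    chosen[[length(chosen) + 1L]] <- p
    presence[pid, ] <- p
  }
  un_presence <- matrix(stats::runif(n_unbinned * config$n_sites) <
                          config$template_site_prob,
                        nrow = n_unbinned,
                        dimnames = list(names(unbinned), sites))
  for (s in seq_len(config$n_sites)) {   # every site hosts >= 1 template
    if (!any(presence[, s])) presence[sample(config$n_templates, 1L), s] <- TRUE
  }

  # per-site assembly
  manifest_coop <- list(); manifest_red <- list(); manifest_split <- list()
  systems <- list(); abundances <- list()
  site_member_reactions <- list()

  for (s in sites) {
    n_org <- sample(config$organisms_min:config$organisms_max, 1L)
    orgs <- sprintf("%s_org%02d", s, seq_len(n_org))
    org_rxns <- stats::setNames(vector("list", n_org), orgs)
    for (tid in rownames(presence)[presence[, s]]) {
      tmpl <- templates[[tid]]
      L <- tmpl$length
      # within-site assignment (split/redundancy) never changes community
      # producibility, so planted templates participate like any other
      do_split <- L >= 2L && n_org >= 2L &&
        stats::runif(1) < config$crossfeeding_split
      if (do_split) {
        cut <- sample(seq_len(L - 1L), 1L)
        ab <- sample(orgs, 2L)
        org_rxns[[ab[1L]]] <- c(org_rxns[[ab[1L]]], tmpl$reactions[seq_len(cut)])
        org_rxns[[ab[2L]]] <- c(org_rxns[[ab[2L]]],
                                tmpl$reactions[seq(cut + 1L, L)])
        tail_products <- tmpl$products[seq(cut + 1L, L)]
        manifest_coop[[length(manifest_coop) + 1L]] <- data.frame(
          site = s, template = tid, tier = tmpl$tier,
          metabolite = tail_products)
        manifest_split[[length(manifest_split) + 1L]] <- list(
          site = s, template = tid, tier = tmpl$tier,
          head_organism = ab[1L], tail_organism = ab[2L],
          tail_products = tail_products)
      } else {
        do_red <- stats::runif(1) < config$redundancy_prob
        holders <- sample(orgs, if (do_red) config$redundancy_level else 1L)
        for (h in holders) org_rxns[[h]] <- c(org_rxns[[h]], tmpl$reactions)
        if (do_red)
          manifest_red[[length(manifest_red) + 1L]] <- list(
            site = s, template = tid, tier = tmpl$tier, holders = sort(holders),
            end_product = tmpl$products[tmpl$length])
      }
    }
    site_member_reactions[[s]] <- org_rxns
    abund <- stats::runif(n_org)
    abundances[[s]] <- stats::setNames(round(100 * abund / sum(abund), 4), orgs)
  }

  # MAG-only gap-fill artifacts
  artifact_ids <- sprintf("A%02d", seq_len(config$mag_only_artifact_count))
  manifest_art <- list()
  for (a in artifact_ids) {
    s <- sample(sites, 1L)
    org <- sample(names(site_member_reactions[[s]]), 1L)
    rx <- reaction(paste0("GF_", a), sample(basal, 1L), a)
    site_member_reactions[[s]][[org]] <- c(site_member_reactions[[s]][[org]],
                                           list(rx))
    manifest_art[[a]] <- list(metabolite = a, site = s, organism = org)
  }

  # assemble systems: MAG collection + metagenome per site
  for (s in sites) {
    org_rxns <- site_member_reactions[[s]]
    members <- lapply(names(org_rxns), function(o) {
      rx <- org_rxns[[o]]
      # an organism may hold the same template reaction only once
      keys <- vapply(rx, reaction_key, character(1))
      metabolic_network(o, rx[!duplicated(keys)])
    })
    keep <- lengths(lapply(members, `[[`, "reactions")) > 0L
    members <- members[keep]
    abundances[[s]] <- abundances[[s]][vapply(members, `[[`, character(1), "id")]
    abundances[[s]] <- round(100 * abundances[[s]] / sum(abundances[[s]]), 4)
    systems[[paste(s, "genome_resolved", sep = "|")]] <-
      system_spec(s, "genome_resolved", members)

    meta_rxns <- list()
    for (tid in rownames(presence)[presence[, s]])
      meta_rxns <- c(meta_rxns, templates[[tid]]$reactions)
    for (uid in rownames(un_presence)[un_presence[, s]])
      meta_rxns <- c(meta_rxns, unbinned[[uid]]$reactions)
    meta <- metabolic_network(paste0(s, "_metagenome"), meta_rxns)
    systems[[paste(s, "metagenome", sep = "|")]] <-
      system_spec(s, "metagenome", list(meta))
  }

  # environmental table with planted associations
  env <- matrix(stats::rnorm(config$n_sites * config$n_env_variables),
                nrow = config$n_sites,
                dimnames = list(sites,
                                if (config$n_env_variables == 17L) ENV_VARIABLE_NAMES
                                else sprintf("var%02d", seq_len(config$n_env_variables))))
  planted_vars <- sort(sample(colnames(env), config$n_planted_associated_groups))
  manifest_assoc <- list()
  for (i in seq_along(planted_ids)) {
    pid <- planted_ids[i]; var <- planted_vars[i]
    z <- as.numeric(scale(as.integer(presence[pid, ])))
    sgn <- sample(c(-1, 1), 1L)
    env[, var] <- sgn * config$association_effect * z +
      stats::rnorm(config$n_sites, sd = config$response_noise_sd)
    manifest_assoc[[length(manifest_assoc) + 1L]] <- list(
      variable = var, template = pid, sign = sgn,
      members = templates[[pid]]$products,
      site_pattern = stats::setNames(as.integer(presence[pid, ]), sites))
  }
  env <- as.data.frame(round(env, 6))

  # expected reachable products, from template combinatorics (independent of
  # the expansion engine): a template's products are reachable at a site and
  # condition when the template is present and the condition supplies its tier.
  expected <- list()
  for (s in sites) for (cond in names(conditions)) {
    reg <- rownames(presence)[presence[, s]]
    reg <- reg[vapply(reg, function(t)
      cond %in% TIER_CONDITIONS[[templates[[t]]$tier]], logical(1))]
    mets <- unlist(lapply(templates[reg], `[[`, "products"), use.names = FALSE)
    site_art <- artifact_ids[vapply(manifest_art, function(a) a$site == s,
                                    logical(1))]
    expected[[sim_id(s, "genome_resolved", cond)]] <- sort_ids(c(mets, site_art))
    unb <- rownames(un_presence)[un_presence[, s]]
    unb <- unb[vapply(unb, function(u)
      cond %in% TIER_CONDITIONS[[unbinned[[u]]$tier]], logical(1))]
    umets <- unlist(lapply(unbinned[unb], `[[`, "products"), use.names = FALSE)
    expected[[sim_id(s, "metagenome", cond)]] <- sort_ids(c(mets, umets))
  }

  manifest <- list(
    config = unclass(config),
    sites = sites,
    templates = lapply(templates, function(t)
      t[c("id", "tier", "length", "products")]),
    presence = apply(presence, 2L, function(p) rownames(presence)[p],
                     simplify = FALSE),
    cooperation_only = if (length(manifest_coop))
      do.call(rbind, manifest_coop) else
      data.frame(site = character(0), template = character(0),
                 tier = character(0), metabolite = character(0)),
    splits = manifest_split,
    redundancy = manifest_red,
    artifacts = manifest_art,
    associations = manifest_assoc,
    expected_scopes = expected
  )

  systems <- systems[order_ids(names(systems))]
  world <- structure(list(config = config, conditions = conditions,
                          systems = systems, env = env,
                          abundances = abundances, manifest = manifest),
                     class = "msc_world")
  if (!is.null(dir)) write_world(world, dir)
  world
}

#' @export
print.msc_world <- function(x, ...) {
  cat(sprintf("<synthetic world: %d sites, %d systems, %d env variables, seed %d>\n",
              x$config$n_sites, length(x$systems), ncol(x$env), x$config$seed))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Layout: `conditions.yaml`, `env_table.tsv`, `abundances.tsv`,
#' `manifest.json`, and per site `sites/<site>/metagenome.sbml` plus
#' `sites/<site>/mags/<organism>.sbml`. Output is deterministic.
#'
#' @param world An `msc_world`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cond_yaml <- list(
    provenance = sprintf("synthetic world, seed %d", world$config$seed),
    conditions = lapply(unclass(world$conditions), function(cond) {
      if (is.null(cond$parent)) list(name = cond$name, members = as.list(cond$seeds))
      else {
        parent_seeds <- world$conditions[[cond$parent]]$seeds
        list(name = cond$name, parent = cond$parent,
             additions = as.list(setdiff(cond$seeds, parent_seeds)))
      }
    })
  )
  yaml::write_yaml(cond_yaml, file.path(dir, "conditions.yaml"))

  env_out <- data.frame(site = rownames(world$env), world$env,
                        check.names = FALSE)
  utils::write.table(env_out, file.path(dir, "env_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ab <- do.call(rbind, lapply(names(world$abundances), function(s)
    data.frame(site = s, organism = names(world$abundances[[s]]),
               abundance = as.numeric(world$abundances[[s]]))))
  utils::write.table(ab, file.path(dir, "abundances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_json_canonical(world$manifest, file.path(dir, "manifest.json"))

  for (sys in world$systems) {
    sdir <- file.path(dir, "sites", sys$site)
    if (sys$scale == "metagenome") {
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_sbml(sys$members[[1L]], file.path(sdir, "metagenome.sbml"))
    } else {
      mdir <- file.path(sdir, "mags")
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      for (m in sys$members)
        write_sbml(m, file.path(mdir, paste0(m$id, ".sbml")))
    }
  }
  invisible(dir)
}

#' Read a world directory written by [write_world()]
#'
#' @param dir World directory.
#' @return An `msc_world` (the manifest is reloaded as plain lists).
#' @export
read_world <- function(dir) {
  conditions <- load_condition_library(file.path(dir, "conditions.yaml"))
  env <- utils::read.delim(file.path(dir, "env_table.tsv"), check.names = FALSE)
  rownames(env) <- env$site
  env$site <- NULL
  ab <- utils::read.delim(file.path(dir, "abundances.tsv"))
  abundances <- lapply(split(ab, ab$site), function(d)
    stats::setNames(d$abundance, d$organism))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sites <- list.dirs(file.path(dir, "sites"), recursive = FALSE)
  systems <- list()
  for (sdir in sites) {
    s <- basename(sdir)
    meta <- parse_sbml(file.path(sdir, "metagenome.sbml"))
    systems[[paste(s, "metagenome", sep = "|")]] <-
      system_spec(s, "metagenome", list(meta))
    mag_files <- sort(list.files(file.path(sdir, "mags"), pattern = "\\.sbml$",
                                 full.names = TRUE), method = "radix")
    members <- lapply(mag_files, parse_sbml)
    systems[[paste(s, "genome_resolved", sep = "|")]] <-
      system_spec(s, "genome_resolved", members)
  }
  config <- do.call(world_config, manifest$config)
  systems <- systems[order(names(systems), method = "radix")]
  structure(list(config = config, conditions = conditions, systems = systems,
                 env = env, abundances = abundances, manifest = manifest),
            class = "msc_world")
}
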
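#' Scenario configuration for the synthetic-data generator
#'
#' Bundles the parameters of the community-assembly and trait-evolution
#' generator. Defaults emulate the structure of a temperate grassland survey:
#' 76 species on a dated Yule tree (root at 139 My), 27 plots split between 2
#' habitat types, abundances as occupied fractions of 10 quadrats, log10-scale
#' traits whose within-community components evolve by Brownian motion on the
#' tree while habitat affinity carries no phylogenetic signal, intraspecific
#' variation tracking the community gradient (`b_s_true = 1`), and ~2% of
#' trait records missing.
#'
#' @param n_species,n_plots,n_habitats,n_quadrats Community dimensions.
#' @param traits Trait names generated at the plant level.
#' @param constant_traits Traits generated as species-level constants (taken
#'   from `traits` if present there, e.g. height from a flora).
#' @param trait_means Named numeric vector of grand means on the log10 scale;
#'   missing names default to 0.
#' @param sigma_alpha SD of the phylogenetically conserved within-community
#'   trait component (log10 units).
#' @param beta_strength Coupling of species base values to habitat affinity
#'   (log10 units per affinity unit): the trait-turnover component.
#' @param plasticity Scale of the shared plastic response to the plot
#'   environment, used when `b_s_true >= 1` (log10 units per environment
#'   unit).
#' @param alpha_signal,habitat_signal Keep (`TRUE`) or destroy (`FALSE`, by
#'   tip shuffling) the phylogenetic signal of the alpha components / the
#'   habitat affinities.
#' @param niche_breadth,detectability Gaussian niche width on the affinity
#'   scale and maximal per-quadrat occupancy probability.
#' @param env_jitter SD of plot environments around their habitat centre.
#' @param b_s_true Target intraspecific slope along the realized community
#'   trait gradient (see Details in the methods vignette; values in `[0, 1]`).
#' @param noise_sd Residual SD of individual plant values (log10 units).
#' @param missing_fraction Fraction of species-plot trait cells left
#'   unmeasured (for imputation testing).
#' @param n_individuals Plants collected per species per plot.
#' @param root_age Tree depth (My).
#' @param seed Integer seed (mandatory).
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_species = 76, n_plots = 27, n_habitats = 2,
                            n_quadrats = 10,
                            traits = c("sla", "leaf_size", "leaf_thickness",
                                       "leaf_density", "srl", "root_density",
                                       "root_diameter"),
                            constant_traits = "height",
                            trait_means = c(height = 1.6, sla = 2.2,
                                            leaf_size = 0.7, leaf_thickness = -0.7,
                                            leaf_density = -0.6, srl = 1.9,
                                            root_density = -0.7, root_diameter = -0.5),
                            sigma_alpha = 0.2, beta_strength = 0.1,
                            plasticity = 0.3,
                            alpha_signal = TRUE, habitat_signal = FALSE,
                            niche_breadth = 0.5, detectability = 0.7,
                            env_jitter = 0.15,
                            b_s_true = 1, noise_sd = 0.05,
                            missing_fraction = 0.02, n_individuals = 1,
                            root_age = 139, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(n_species >= 2, n_plots >= 2, n_habitats >= 1, n_quadrats >= 1,
            niche_breadth > 0, detectability > 0, detectability <= 1,
            missing_fraction >= 0, missing_fraction < 1,
            b_s_true >= 0, b_s_true <= 1, n_individuals >= 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with `n_tips` tips (via [ape::rphylo()]), rescaled so the
#' root sits at `root_age`, tips relabelled `sp0001`, `sp0002`, ...
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param root_age Depth of the root (default 139 My).
#' @return An ultrametric `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, seed, root_age = 139) {
  if (n_tips < 2) abort("Need at least two tips.")
  tree <- withr::with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * root_age / depth
  tree$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  tree
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Gaussian increments along each branch with variance `rate` times branch
#' length (via [ape::rTraitCont()]).
#'
#' @param tree A `"phylo"` object.
#' @param rate Brownian rate (variance per unit branch length, >= 0).
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector over the tips.
#' @export
simulate_bm_traits <- function(tree, rate = 1, root_value = 0, seed = 1L) {
  if (rate < 0) abort("`rate` must be non-negative.")
  if (rate == 0)
    return(setNames(rep(root_value, ape::Ntip(tree)), tree$tip.label))
  withr::with_seed(seed, ape::rTraitCont(tree, model = "BM",
                                         sigma = sqrt(rate),
                                         root.value = root_value))
}

#' Assign habitat affinities to species
#'
#' Affinities are Brownian-motion values rank-rescaled to `[-1, 1]`. With
#' `signal = FALSE` (the default study condition: habitat associations carry
#' no phylogenetic signal) the values are shuffled across tips before
#' rescaling, which preserves their marginal distribution while destroying
#' the phylogenetic covariance.
#'
#' @param tree A `"phylo"` object.
#' @param signal Keep the phylogenetic signal? Default `FALSE`.
#' @param seed Integer seed.
#' @return Named numeric vector of affinities in `[-1, 1]`.
#' @export
assign_habitat_affinity <- function(tree, signal = FALSE, seed = 1L) {
  bm <- simulate_bm_traits(tree, rate = 1, seed = seed)
  if (!signal) {
    bm <- withr::with_seed(seed + 1L,
                           setNames(sample(unname(bm)), names(bm)))
  }
  n <- length(bm)
  aff <- 2 * (rank(bm, ties.method = "first") - 1) / (n - 1) - 1
  setNames(aff, names(bm))
}

#' Assemble communities by Gaussian habitat filtering
#'
#' Each plot receives an environment value on the affinity scale (its habitat
#' centre plus jitter); each species occupies each quadrat independently with
#' probability `detectability * exp(-(affinity - env)^2 / (2 * breadth^2))`,
#' and its abundance is the occupied fraction of quadrats. Plots that end up
#' empty are redrawn.
#'
#' @param affinity Named numeric vector of species habitat affinities.
#' @param cfg A [scenario_config()] (fields `n_plots`, `n_habitats`,
#'   `n_quadrats`, `niche_breadth`, `detectability`, `env_jitter` are used).
#' @param seed Integer seed.
#' @return A list with `community` (tibble `plot`, `species`, `abundance`)
#'   and `plots` (tibble `plot`, `site`, `habitat`, `env`).
#' @export
assemble_communities <- function(affinity, cfg, seed) {
  centers <- if (cfg$n_habitats == 1) 0 else
    seq(-0.5, 0.5, length.out = cfg$n_habitats)
  hab_idx <- rep(seq_len(cfg$n_habitats), length.out = cfg$n_plots)
  hab_idx <- sort(hab_idx)
  plots <- tibble(
    plot = sprintf("plot%02d", seq_len(cfg$n_plots)),
    habitat = paste0("habitat", hab_idx),
    site = paste0("site", hab_idx)
  )
  withr::with_seed(seed, {
    plots$env <- centers[hab_idx] + rnorm(cfg$n_plots, 0, cfg$env_jitter)
    rows <- vector("list", cfg$n_plots)
    redrawn <- character(0)
    for (i in seq_len(cfg$n_plots)) {
      for (try in 1:100) {
        p_occ <- cfg$detectability *
          exp(-(affinity - plots$env[i])^2 / (2 * cfg$niche_breadth^2))
        occ <- rbinom(length(affinity), cfg$n_quadrats, p_occ)
        if (any(occ > 0)) break
        redrawn <- c(redrawn, plots$plot[i])
      }
      if (all(occ == 0)) abort("Could not assemble a non-empty plot.")
      keep <- occ > 0
      rows[[i]] <- tibble(plot = plots$plot[i],
                          species = names(affinity)[keep],
                          abundance = occ[keep] / cfg$n_quadrats)
    }
    community <- bind_rows(rows)
    if (length(redrawn))
      inform(paste0("Redrew empty plot(s): ",
                    paste(unique(redrawn), collapse = ", ")))
    list(community = community, plots = plots)
  })
}

#' Attach simulated trait values to an assembled community
#'
#' Generates per-plant trait values with the alpha/beta structure of
#' trait-gradient analysis: each species' base value is a phylogenetically
#' conserved within-community component (Brownian motion on the tree, shuffled
#' if `alpha_signal = FALSE`) plus a habitat-linked turnover component
#' (`beta_strength * affinity`); individual plants add a shared
#' community-gradient shift scaled by `b_s_true` and Gaussian noise; a
#' `missing_fraction` of species-plot cells is left unmeasured. Species
#' constants (e.g. height) are generated once per species from the same
#' Brownian model.
#'
#' The within-species shift is implemented so that the OLS slope of plant
#' values on the realized community mean equals `b_s_true` in expectation:
#' for `b_s_true < 1` the shift is `b/(1-b)` times the (centred) turnover
#' gradient; for `b_s_true = 1` it is `plasticity * env`, which yields slopes
#' of 1 when the trait's turnover coupling is zero (see the methods
#' vignette).
#'
#' @param comm The list returned by [assemble_communities()].
#' @param tree The species tree (tips must cover the community's species).
#' @param affinity Named affinity vector used to assemble the community.
#' @param cfg A [scenario_config()].
#' @param seed Integer seed.
#' @return An [occurrence_table()] (traits already on the log10 scale) with a
#'   `"truth"` attribute recording the generating alpha components, plot
#'   environments and parameters.
#' @export
attach_traits <- function(comm, tree, affinity, cfg, seed) {
  community <- comm$community
  plots <- comm$plots
  spp <- sort(unique(community$species))
  if (!all(spp %in% tree$tip.label))
    abort("Community species missing from the tree.")
  env <- setNames(plots$env, plots$plot)

  truth <- list(affinity = affinity, env = env, b_s_true = cfg$b_s_true,
                alpha = list())
  plant_traits <- setdiff(cfg$traits, cfg$constant_traits)
  const_traits <- cfg$constant_traits

  # plant records: one row per individual per occupied (species, plot)
  base_rows <- community[rep(seq_len(nrow(community)), each = cfg$n_individuals),
                         c("species", "plot")]
  plants <- tibble(
    plant_id = sprintf("pl%05d", seq_len(nrow(base_rows))),
    species = base_rows$species, plot = base_rows$plot
  )

  # weights for the turnover (no-plasticity) community means
  wtab <- community |>
    group_by(.data$plot) |>
    mutate(w = .data$abundance / sum(.data$abundance)) |>
    ungroup()

  constants <- tibble(species = spp)
  all_traits <- union(cfg$traits, cfg$constant_traits)
  for (i in seq_along(all_traits)) {
    tr <- all_traits[i]
    sub <- seed + 1000L * i
    mu <- if (tr %in% names(cfg$trait_means)) cfg$trait_means[[tr]] else 0

    z <- simulate_bm_traits(tree, rate = 1, seed = sub)
    z <- (z - mean(z)) / sd(z)
    if (!cfg$alpha_signal)
      z <- withr::with_seed(sub + 1L, setNames(sample(unname(z)), names(z)))
    alpha_s <- cfg$sigma_alpha * z[spp]
    truth$alpha[[tr]] <- alpha_s

    if (tr %in% const_traits) {
      constants[[tr]] <- mu + alpha_s + cfg$beta_strength * affinity[spp]
      next
    }

    base_s <- mu + alpha_s + cfg$beta_strength * affinity[spp]
    t0 <- wtab |>
      mutate(base = base_s[.data$species]) |>
      group_by(.data$plot) |>
      summarise(t0 = sum(.data$w * .data$base), .groups = "drop")
    t0_p <- setNames(t0$t0, t0$plot)

    shift_p <- if (cfg$b_s_true < 1) {
      (cfg$b_s_true / (1 - cfg$b_s_true)) * (t0_p - mean(t0_p))
    } else {
      cfg$plasticity * env[names(t0_p)]
    }
    noise <- withr::with_seed(sub + 2L,
                              rnorm(nrow(plants), 0, cfg$noise_sd))
    plants[[tr]] <- base_s[plants$species] + shift_p[plants$plot] + noise

    if (cfg$missing_fraction > 0) {
      cells <- distinct(plants, .data$species, .data$plot)
      drop <- withr::with_seed(sub + 3L,
        runif(nrow(cells)) < cfg$missing_fraction)
      # never remove a species' last measured plot
      keep_one <- cells |>
        mutate(drop = drop) |>
        group_by(.data$species) |>
        mutate(drop = .data$drop & (sum(!.data$drop) > 0)) |>
        ungroup()
      gone <- keep_one |> filter(.data$drop)
      if (nrow(gone)) {
        idx <- paste(plants$species, plants$plot) %in%
          paste(gone$species, gone$plot)
        plants[[tr]][idx] <- NA_real_
      }
    }
  }

  occ <- occurrence_table(
    community = community, plants = plants, plots = plots,
    species_constants = if (length(const_traits)) constants else NULL,
    log10_traits = FALSE
  )
  attr(occ, "truth") <- truth
  occ
}

#' Simulate a complete study scenario
#'
#' Tree, habitat affinities, community assembly and trait generation in one
#' call; the one-stop entry point for power and calibration studies.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `occ` (the [occurrence_table()]), `tree`, `affinity`
#'   and `cfg`.
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  tree <- simulate_tree(cfg$n_species, seed = cfg$seed, root_age = cfg$root_age)
  affinity <- assign_habitat_affinity(tree, signal = cfg$habitat_signal,
                                      seed = cfg$seed + 1L)
  comm <- assemble_communities(affinity, cfg, seed = cfg$seed + 2L)
  occ <- attach_traits(comm, tree, affinity, cfg, seed = cfg$seed + 3L)
  list(occ = occ, tree = tree, affinity = affinity, cfg = cfg)
}

#' Write a small packaged example dataset
#'
#' Generates a 12-species, 6-plot scenario and writes it as the plain-text
#' files the pipeline reads: `tree.nwk`, `community.csv`, `plants.csv`,
#' `plots.csv`, `species_constants.csv`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 42).
#' @return Invisibly, a named character vector of file paths.
#' @export
make_fixture <- function(dir, seed = 42L) {
  cfg <- scenario_config(n_species = 12, n_plots = 6, n_habitats = 2,
                         traits = c("sla", "leaf_size", "srl"),
                         constant_traits = "height",
                         missing_fraction = 0.05, seed = seed)
  sc <- simulate_scenario(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    tree = file.path(dir, "tree.nwk"),
    community = file.path(dir, "community.csv"),
    plants = file.path(dir, "plants.csv"),
    plots = file.path(dir, "plots.csv"),
    species_constants = file.path(dir, "species_constants.csv")
  )
  write_newick(sc$tree, paths["tree"])
  readr::write_csv(sc$occ$community, paths["community"])
  readr::write_csv(sc$occ$plants, paths["plants"])
  readr::write_csv(sc$occ$plots, paths["plots"])
  readr::write_csv(sc$occ$constants, paths["species_constants"])
  invisible(paths)
}

#' Configuration preset for intraspecific-slope calibration studies
#'
#' A single-trait scenario in which the OLS slope of plant values on the
#' realized community mean is `b_s_true` in expectation. For `b_s_true = 1`
#' the community gradient is generated entirely by a strong shared plastic
#' response to the plot environment and the trait's turnover coupling is
#' switched off: any noise in the realized community means attenuates the
#' slopes (errors-in-variables) and correlates the species' slope errors
#' within a run, so the phylogenetic component is kept small and the plastic
#' gradient strong. For `b_s_true < 1` the shift is generated against the
#' trait's turnover gradient (see [attach_traits()]).
#'
#' @param b_s_true Target slope (default 1).
#' @param seed Integer seed.
#' @param n_species,n_plots Community dimensions (defaults 64 and 24).
#' @param ... Further overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
slope_calibration_config <- function(b_s_true = 1, seed, n_species = 64,
                                     n_plots = 24, ...) {
  if (b_s_true >= 1) {
    scenario_config(n_species = n_species, n_plots = n_plots,
                    traits = "sla", constant_traits = character(0),
                    beta_strength = 0, sigma_alpha = 0.03, plasticity = 0.8,
                    noise_sd = 0.12, missing_fraction = 0,
                    b_s_true = b_s_true, seed = seed, ...)
  } else {
    scenario_config(n_species = n_species, n_plots = n_plots,
                    traits = "sla", constant_traits = character(0),
                    missing_fraction = 0, b_s_true = b_s_true, seed = seed, ...)
  }
}
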
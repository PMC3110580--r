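#' Read the pipeline's input files into an occurrence table and tree
#'
#' @param tree Path to a Newick tree, or a `"phylo"` object.
#' @param community Path to the community CSV (`plot`, `species`,
#'   `abundance`) or a data frame.
#' @param plants Path to the plant-trait CSV or a data frame (optional).
#' @param plots Plot metadata CSV/data frame (optional).
#' @param species_constants Species-constant trait CSV/data frame (optional).
#' @param log10_traits Passed to [occurrence_table()].
#' @return A list with `occ` (an [occurrence_table()]) and `tree`.
#' @export
read_inputs <- function(tree, community, plants = NULL, plots = NULL,
                        species_constants = NULL, log10_traits = TRUE) {
  read_maybe <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    readr::read_csv(x, show_col_types = FALSE)
  }
  tree <- if (inherits(tree, "phylo")) tree else read_newick(tree)
  occ <- occurrence_table(
    community = read_maybe(community), plants = read_maybe(plants),
    plots = read_maybe(plots), species_constants = read_maybe(species_constants),
    log10_traits = log10_traits
  )
  list(occ = occ, tree = tree)
}

#' Cross-check tree, community and trait inputs
#'
#' Report-only validation: species present in the community but absent from
#' the tree (fatal for comparative analyses), tips absent from the community
#' (they are pruned), species without any trait measurement, and the count of
#' species-plot occurrences lacking a measurement (candidates for
#' imputation).
#'
#' @param occ An [occurrence_table()].
#' @param tree A `"phylo"` object.
#' @return A list of class `"validation_report"` with `fatal` (character),
#'   `warnings` (character) and counts; printed nicely.
#' @export
validate_inputs <- function(occ, tree) {
  stopifnot(inherits(occ, "occurrence_table"), inherits(tree, "phylo"))
  comm_sp <- unique(occ$community$species)
  fatal <- character(0)
  warnings <- character(0)

  not_in_tree <- setdiff(comm_sp, tree$tip.label)
  if (length(not_in_tree))
    fatal <- c(fatal, paste0("Community species missing from tree: ",
                             paste(not_in_tree, collapse = ", ")))
  extra_tips <- setdiff(tree$tip.label, comm_sp)
  if (length(extra_tips))
    warnings <- c(warnings, paste0(length(extra_tips),
                                   " tree tip(s) absent from the community (will be pruned)."))

  n_missing <- 0L
  for (tr in occ$traits) {
    vals <- occurrence_values(occ, tr)
    n_missing <- n_missing + sum(is.na(vals$value))
  }
  n_cells <- nrow(occ$community) * max(length(occ$traits), 1L)
  if (n_missing > 0)
    warnings <- c(warnings, sprintf(
      "%d of %d species-plot trait cells lack a measurement (%.1f%%); run impute_missing_traits().",
      n_missing, n_cells, 100 * n_missing / n_cells))

  structure(list(fatal = fatal, warnings = warnings,
                 n_species = length(comm_sp),
                 n_plots = length(unique(occ$community$plot)),
                 n_missing_cells = n_missing, n_cells = n_cells),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$n_species, "species,", x$n_plots, "plots\n")
  if (length(x$fatal)) cat("  FATAL:", paste(x$fatal, collapse = "\n         "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  if (!length(x$fatal) && !length(x$warnings)) cat("  no issues\n")
  invisible(x)
}

#' Run the full trait-gradient and comparative analysis
#'
#' End-to-end pipeline: impute missing trait cells, run the trait-gradient
#' partition for every trait, ordinate the communities (Bray-Curtis NMDS) and
#' correlate plot-mean traits with axis 1, estimate intraspecific slopes and
#' test their mean against 1, build ahistorical/PIC correlation matrices for
#' the within-community (alpha), among-community (beta) and total components,
#' and test every component of every trait -- plus the species habitat
#' affinities (NMDS axis-1 species scores) -- for phylogenetic signal.
#'
#' @param occ An [occurrence_table()].
#' @param tree A `"phylo"` object covering the community's species.
#' @param traits Traits to analyse (default: all in `occ`).
#' @param n_perm Tip shuffles for the signal tests (default 999).
#' @param n_starts NMDS random starts (default 20).
#' @param min_plots Minimum plots for an intraspecific slope (default 3).
#' @param seed Integer seed (polytomy resolution, permutations, NMDS).
#' @param branch_lengths `"equal"` (default; all branch lengths set to 1
#'   before contrasts and signal tests) or `"dated"` (use the tree as given).
#' @param holm Apply a Holm adjustment to the correlation-matrix P values
#'   (default `FALSE`: raw P values, as is conventional for these tables).
#' @param out_dir Optional directory; when given, all result tables are also
#'   written as CSV files with deterministic formatting.
#' @return A list of class `"tga_run"`: `table1` (trait-environment
#'   correlations, slopes, within-species variance), `table2` (per-component
#'   combined correlation matrices), `table3` (per-component signal tests and
#'   component R2), `habitat_signal`, `ordination`, `gradients` (the
#'   per-trait `"trait_gradient"` objects), `log`.
#' @export
run_full_analysis <- function(occ, tree, traits = NULL, n_perm = 999,
                              n_starts = 20, min_plots = 3, seed = 1L,
                              branch_lengths = c("equal", "dated"),
                              holm = FALSE, out_dir = NULL) {
  stopifnot(inherits(occ, "occurrence_table"), inherits(tree, "phylo"))
  branch_lengths <- match.arg(branch_lengths)
  traits <- traits %||% c(occ$traits, occ$constant_traits)

  report <- validate_inputs(occ, tree)
  if (length(report$fatal))
    abort(paste0("Input validation failed:\n", paste(report$fatal, collapse = "\n")))

  occ <- impute_missing_traits(occ)
  comm_sp <- sort(unique(occ$community$species))
  tree <- ape::keep.tip(tree, comm_sp)
  ctree <- resolve_polytomies(tree, seed = seed)
  if (branch_lengths == "equal") ctree <- set_equal_branch_lengths(ctree, 1)

  # ordination and habitat affinity
  ord <- nmds_ordination(occ, k = 2, n_starts = n_starts, seed = seed)
  affinity <- setNames(ord$species_scores$axis1, ord$species_scores$species)

  gradients <- lapply(traits, function(tr)
    trait_gradient(occ, tr, min_plots = min_plots))
  names(gradients) <- traits

  # Table 1: plot-mean vs axis 1, b_s summary, within-species variance
  plot_means <- purrr::map_dfr(gradients, function(g)
    mutate(g$plots[c("plot", "p_bar")], trait = g$trait))
  t1_cor <- trait_env_correlation(ord$plot_scores, plot_means)
  t1_rows <- purrr::map_dfr(traits, function(tr) {
    g <- gradients[[tr]]
    bs <- g$species$b_s[!is.na(g$species$b_s)]
    bt <- if (length(bs) >= 2 && sd(bs) > 0) test_bs(bs) else NULL
    tibble(
      trait = tr,
      bs_n = length(bs),
      bs_mean = if (length(bs)) mean(bs) else NA_real_,
      bs_sd = if (length(bs) >= 2) sd(bs) else NA_real_,
      bs_p = if (!is.null(bt)) bt$p_value else NA_real_,
      var_within_species_pct = 100 * g$variance$fraction_within_species
    )
  })
  table1 <- t1_cor |>
    rename(axis1_r = "r", axis1_p = "p_value", axis1_n = "n") |>
    left_join(t1_rows, by = "trait") |>
    arrange(match(.data$trait, traits))

  # component matrices per species
  comp_values <- function(g, comp)
    setNames(g$species[[comp]], g$species$species)
  components <- c(alpha = "alpha", beta = "beta", total = "t_bar")

  table2 <- list()
  table3 <- list()
  for (cn in names(components)) {
    comp <- components[[cn]]
    mats <- sapply(traits, function(tr) {
      v <- comp_values(gradients[[tr]], comp)
      v[comm_sp]
    })
    rownames(mats) <- comm_sp
    keep <- complete.cases(mats)
    mat <- mats[keep, , drop = FALSE]
    sub_tree <- ape::keep.tip(ctree, rownames(mat))
    table2[[cn]] <- correlation_matrix(mat, sub_tree)
    table3[[cn]] <- purrr::map_dfr(traits, function(tr) {
      v <- setNames(mat[, tr], rownames(mat))
      st <- signal_test(sub_tree, v, n_perm = n_perm, seed = seed)
      tibble(component = cn, trait = tr, K = st$K, p_value = st$p_value,
             r2 = if (comp == "t_bar") NA_real_
                  else gradients[[tr]]$r2[[paste0("r2_", cn)]])
    })
  }
  table3 <- bind_rows(table3)
  if (holm) {
    for (cn in names(table2)) {
      table2[[cn]]$p_ahistorical[] <- stats::p.adjust(table2[[cn]]$p_ahistorical, "holm")
      table2[[cn]]$p_pic[] <- stats::p.adjust(table2[[cn]]$p_pic, "holm")
    }
  }

  hab_tree <- ape::keep.tip(ctree, intersect(comm_sp, names(affinity)))
  habitat_signal <- signal_test(hab_tree, affinity[hab_tree$tip.label],
                                n_perm = n_perm, seed = seed)

  res <- structure(
    list(table1 = table1, table2 = table2, table3 = table3,
         habitat_signal = habitat_signal, ordination = ord,
         gradients = gradients, validation = report,
         log = list(imputed = imputation_log(occ), seed = seed,
                    branch_lengths = branch_lengths, n_perm = n_perm,
                    n_starts = n_starts, min_plots = min_plots)),
    class = "tga_run"
  )
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.tga_run <- function(x, ...) {
  cat("<tga_run>", nrow(x$table1), "trait(s);",
      nrow(x$ordination$plot_scores), "plots\n")
  cat(sprintf("  NMDS stress %.2f; habitat affinity K = %.3f (P = %.3g)\n",
              x$ordination$stress, x$habitat_signal$K, x$habitat_signal$p_value))
  invisible(x)
}

#' @keywords internal
write_run <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fmt <- function(df) mutate(df, across(dplyr::where(is.numeric),
                                        ~ signif(.x, 10)))
  readr::write_csv(fmt(res$table1), file.path(out_dir, "table1_trait_environment.csv"))
  for (cn in names(res$table2)) {
    m <- res$table2[[cn]]$r
    df <- as_tibble(cbind(trait = rownames(m), as.data.frame(signif(m, 10))))
    readr::write_csv(df, file.path(out_dir, paste0("table2_correlations_", cn, ".csv")))
  }
  readr::write_csv(fmt(res$table3), file.path(out_dir, "table3_phylogenetic_signal.csv"))
  readr::write_csv(fmt(tidy(res$habitat_signal)),
                   file.path(out_dir, "habitat_affinity_signal.csv"))
  readr::write_csv(fmt(res$ordination$plot_scores), file.path(out_dir, "nmds_plot_scores.csv"))
  readr::write_csv(fmt(res$ordination$species_scores), file.path(out_dir, "nmds_species_scores.csv"))
  sp_all <- purrr::map_dfr(res$gradients, function(g)
    mutate(g$species, trait = g$trait))
  readr::write_csv(fmt(sp_all), file.path(out_dir, "species_components.csv"))
  pl_all <- purrr::map_dfr(res$gradients, function(g)
    mutate(g$plots, trait = g$trait))
  readr::write_csv(fmt(pl_all), file.path(out_dir, "plot_means.csv"))
  readr::write_csv(res$log$imputed, file.path(out_dir, "imputation_log.csv"))
  invisible(out_dir)
}
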
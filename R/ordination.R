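#' Bray-Curtis dissimilarities between plots
#'
#' \eqn{d(p,q) = 1 - 2\sum_s \min(a_{sp}, a_{sq}) /
#' (\sum_s a_{sp} + \sum_s a_{sq})}, computed with [vegan::vegdist()].
#'
#' @param community A plot-by-species abundance matrix (plots as rows), or a
#'   long data frame with columns `plot`, `species`, `abundance`, or an
#'   [occurrence_table()].
#' @return A `"dist"` object over plots, values in `[0, 1]`.
#' @export
bray_curtis <- function(community) {
  m <- community_matrix(community)
  if (any(m < 0)) abort("Abundances must be non-negative.")
  zero <- rowSums(m) == 0
  if (any(zero)) abort(paste0("All-zero plot(s): ",
                              paste(rownames(m)[zero], collapse = ", ")))
  vegan::vegdist(m, method = "bray")
}

#' @keywords internal
community_matrix <- function(community) {
  if (inherits(community, "occurrence_table")) community <- community$community
  if (is.data.frame(community) &&
      all(c("plot", "species", "abundance") %in% names(community))) {
    wide <- tidyr::pivot_wider(
      as_tibble(community)[c("plot", "species", "abundance")],
      names_from = "species", values_from = "abundance", values_fill = 0
    ) |> arrange(.data$plot)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$plot
    m <- m[, order(colnames(m)), drop = FALSE]
    return(m)
  }
  m <- as.matrix(community)
  if (is.null(rownames(m))) rownames(m) <- sprintf("plot%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sp%04d", seq_len(ncol(m)))
  m
}

#' Non-metric multidimensional scaling with multiple random starts
#'
#' Kruskal NMDS (via [vegan::monoMDS()], global model) repeated from
#' `n_starts` starting configurations (the first is the metric-scaling
#' solution, the rest random), keeping the lowest-stress solution. Stress is
#' reported as Kruskal stress-1 multiplied by 100. Species scores are the
#' abundance-weighted averages of the plot scores ([vegan::wascores()]), so a
#' species confined to one plot sits exactly on that plot.
#'
#' Because NMDS axes are defined only up to rotation/reflection, axis 1 is
#' oriented so that increasing scores follow the second `habitat` level (in
#' sorted order) when habitat labels are supplied, otherwise so that the plot
#' scores correlate positively with lexicographic plot order.
#'
#' @param community As in [bray_curtis()]; used for species scores and, when
#'   an [occurrence_table()], for habitat orientation.
#' @param k Number of dimensions (default 2); must be < number of plots.
#' @param n_starts Number of starting configurations (default 20).
#' @param seed Integer seed.
#' @param habitat Optional named character vector (plot -> habitat label)
#'   overriding the table's metadata.
#' @return An object of class `"nmds_ordination"`: list with `plot_scores`
#'   and `species_scores` tibbles, `stress` (stress-1 x 100), `k`,
#'   `n_starts`, `seed`, and `start_stresses`.
#' @export
nmds_ordination <- function(community, k = 2, n_starts = 20, seed = 1L,
                            habitat = NULL) {
  m <- community_matrix(community)
  if (k >= nrow(m)) abort("`k` must be smaller than the number of plots.")
  if (is.null(habitat) && inherits(community, "occurrence_table")) {
    habitat <- setNames(community$plots$habitat, community$plots$plot)
    if (all(is.na(habitat))) habitat <- NULL
  }
  d <- bray_curtis(m)

  fits <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      init <- if (i == 1) {
        cmdscale(d, k = k)
      } else {
        matrix(runif(nrow(m) * k, -1, 1), ncol = k)
      }
      vegan::monoMDS(d, y = init, k = k, model = "global")
    })
  })
  stresses <- vapply(fits, function(f) f$stress, numeric(1))
  best <- fits[[which.min(stresses)]]
  pts <- best$points
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("axis", seq_len(k))

  # orient axis 1 deterministically
  flip <- FALSE
  if (!is.null(habitat)) {
    hab <- habitat[rownames(pts)]
    lev <- sort(unique(hab[!is.na(hab)]))
    if (length(lev) >= 2) {
      ind <- as.numeric(hab == lev[length(lev)])
      cc <- suppressWarnings(cor(pts[, 1], ind))
      if (is.finite(cc) && cc < 0) flip <- TRUE
    }
  } else {
    cc <- suppressWarnings(cor(pts[, 1], order(order(rownames(pts)))))
    if (is.finite(cc) && cc < 0) flip <- TRUE
  }
  if (flip) pts[, 1] <- -pts[, 1]

  sp <- vegan::wascores(pts, m, expand = FALSE)
  structure(
    list(
      plot_scores = tibble(plot = rownames(pts)) |>
        dplyr::bind_cols(as_tibble(pts)),
      species_scores = tibble(species = rownames(sp)) |>
        dplyr::bind_cols(as_tibble(sp)),
      stress = min(stresses) * 100,
      start_stresses = stresses * 100,
      k = as.integer(k), n_starts = as.integer(n_starts),
      seed = as.integer(seed)
    ),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("<nmds_ordination> k = %d, stress = %.2f (best of %d starts, seed %d)\n",
              x$k, x$stress, x$n_starts, x$seed))
  invisible(x)
}

#' @rdname nmds_ordination
#' @param x,object An `"nmds_ordination"` object.
#' @param ... Unused.
#' @method tidy nmds_ordination
#' @export
tidy.nmds_ordination <- function(x, ...) {
  bind_rows(
    x$plot_scores |> mutate(score = "plot") |> rename(label = "plot"),
    x$species_scores |> mutate(score = "species") |> rename(label = "species")
  )
}

#' @rdname nmds_ordination
#' @method glance nmds_ordination
#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble(k = x$k, stress = x$stress, n_starts = x$n_starts,
         n_plots = nrow(x$plot_scores), n_species = nrow(x$species_scores),
         seed = x$seed)
}

#' @rdname nmds_ordination
#' @method autoplot nmds_ordination
#' @export
autoplot.nmds_ordination <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1,
                                   y = if (object$k >= 2) .data$axis2 else 0,
                                   colour = .data$score, shape = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "NMDS axis 1", y = if (object$k >= 2) "NMDS axis 2" else NULL,
                  title = sprintf("NMDS (stress = %.1f)", object$stress)) +
    ggplot2::theme_minimal()
}

#' Monte-Carlo test of NMDS stress
#'
#' Compares the observed best-of-starts stress with a null distribution
#' obtained by independently shuffling each species' abundance vector across
#' plots (which preserves every species' occupancy frequencies while
#' destroying plot structure). P is the add-one rank of the observed stress
#' among the null stresses.
#'
#' @inheritParams nmds_ordination
#' @param n_runs Number of null randomizations (default 999).
#' @return A one-row tibble `stress`, `p_value`, `n_runs`, `k`.
#' @export
stress_montecarlo <- function(community, k = 2, n_runs = 999, seed = 1L,
                              n_starts = 5) {
  if (n_runs < 1) abort("`n_runs` must be at least 1.")
  m <- community_matrix(community)
  obs <- nmds_ordination(m, k = k, n_starts = n_starts, seed = seed)$stress
  null <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_runs), function(i) {
      perm <- apply(m, 2, sample)
      rownames(perm) <- rownames(m)
      keep <- rowSums(perm) > 0
      nmds_ordination(perm[keep, , drop = FALSE], k = k,
                      n_starts = n_starts, seed = seed)$stress
    }, numeric(1))
  })
  tibble(stress = obs, p_value = (sum(null <= obs) + 1) / (n_runs + 1),
         n_runs = as.integer(n_runs), k = as.integer(k))
}

#' Correlation of plot mean traits with ordination axis 1
#'
#' Pearson correlation (with two-sided test) between each trait's
#' abundance-weighted plot mean and the plot scores on NMDS axis 1 — the
#' trait-environment summary of the ordination.
#'
#' @param plot_scores Tibble (`plot`, `axis1`), e.g. from
#'   [nmds_ordination()]`$plot_scores`.
#' @param plot_means Tibble (`plot`, one column per trait, or long with
#'   `trait`/`p_bar` columns).
#' @return A tibble with one row per trait: `trait`, `r`, `p_value`, `n`.
#' @export
trait_env_correlation <- function(plot_scores, plot_means) {
  plot_scores <- as_tibble(plot_scores)
  plot_means <- as_tibble(plot_means)
  if (all(c("trait", "p_bar") %in% names(plot_means))) {
    long <- plot_means
  } else {
    long <- tidyr::pivot_longer(plot_means, -dplyr::all_of("plot"),
                                names_to = "trait", values_to = "p_bar")
  }
  df <- inner_join(long, plot_scores[c("plot", "axis1")], by = "plot")
  df |>
    group_by(.data$trait) |>
    summarise(
      n = sum(complete.cases(.data$p_bar, .data$axis1)),
      r = {
        ok <- complete.cases(.data$p_bar, .data$axis1)
        if (sum(ok) < 3 || sd(.data$p_bar[ok]) == 0) NA_real_
        else unname(cor.test(.data$p_bar[ok], .data$axis1[ok])$estimate)
      },
      p_value = {
        ok <- complete.cases(.data$p_bar, .data$axis1)
        if (sum(ok) < 3 || sd(.data$p_bar[ok]) == 0) NA_real_
        else cor.test(.data$p_bar[ok], .data$axis1[ok])$p.value
      },
      .groups = "drop"
    )
}
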
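#' @keywords internal
#' one value per occurrence: plot-level species means of measured plants,
#' imputed cells, or species constants
occurrence_values <- function(occ, trait) {
  stopifnot(inherits(occ, "occurrence_table"))
  if (trait %in% occ$constant_traits) {
    vals <- occ$community |>
      left_join(select(occ$constants, "species", value = dplyr::all_of(trait)),
                by = "species") |>
      mutate(source = "constant")
    return(vals)
  }
  if (!trait %in% occ$traits)
    abort(paste0("Unknown trait `", trait, "`."))
  measured <- occ$plants |>
    filter(!is.na(.data[[trait]])) |>
    group_by(.data$species, .data$plot) |>
    summarise(value = mean(.data[[trait]]), .groups = "drop") |>
    mutate(source = "measured")
  imput <- occ$imputed |>
    filter(.data$trait == !!trait) |>
    select("species", "plot", "value") |>
    mutate(source = "imputed")
  occ$community |>
    left_join(bind_rows(measured, imput), by = c("species", "plot"))
}

#' @keywords internal
#' abundance-weighted plot means, species means and the alpha/beta partition
tg_core <- function(vals) {
  plot_tab <- vals |>
    group_by(.data$plot) |>
    summarise(
      p_bar = sum(.data$abundance * .data$value) / sum(.data$abundance),
      n_species = n(),
      total_abundance = sum(.data$abundance),
      .groups = "drop"
    )
  sp_tab <- vals |>
    left_join(select(plot_tab, "plot", "p_bar"), by = "plot") |>
    group_by(.data$species) |>
    summarise(
      n_plots = n(),
      t_bar = sum(.data$abundance * .data$value) / sum(.data$abundance),
      beta = sum(.data$abundance * .data$p_bar) / sum(.data$abundance),
      .groups = "drop"
    ) |>
    mutate(alpha = .data$t_bar - .data$beta)
  list(species = sp_tab, plots = plot_tab)
}

#' Trait-gradient analysis
#'
#' Additively partitions each species' mean trait value into a
#' within-community (alpha) and an among-community (beta) component along the
#' gradient of abundance-weighted community mean trait values. With
#' \eqn{t_{sp}} the (log-scale) trait value of species \eqn{s} in plot
#' \eqn{p} and \eqn{a_{sp}} its abundance,
#' \deqn{\bar t_s = \sum_p a_{sp} t_{sp} / \sum_p a_{sp}, \qquad
#'       \bar p_p = \sum_s a_{sp} t_{sp} / \sum_s a_{sp},}
#' \deqn{\beta_s = \sum_p a_{sp} \bar p_p / \sum_p a_{sp}, \qquad
#'       \alpha_s = \bar t_s - \beta_s,}
#' so \eqn{\alpha_s + \beta_s = \bar t_s} holds by construction. Within each
#' plot, multiple individuals of a species are averaged before weighting;
#' individual values are retained for the intraspecific slope and
#' within-species variance summaries.
#'
#' @param occ An [occurrence_table()], imputed with
#'   [impute_missing_traits()] if any occurrence lacks a measurement.
#' @param trait Trait name (plant-level or species-constant).
#' @param min_plots Minimum number of plots with measured values for a species
#'   to receive an intraspecific slope (default 3).
#' @return An object of class `"trait_gradient"` with tibbles `species`
#'   (`t_bar`, `alpha`, `beta`, `b_s`, ...), `plots` (`p_bar`, ...),
#'   `variance` (variance-partition fractions) and `r2` (variance in species
#'   means explained by each component).
#' @export
trait_gradient <- function(occ, trait, min_plots = 3) {
  vals <- occurrence_values(occ, trait)
  miss_sp <- unique(vals$species[is.na(vals$value)])
  never <- miss_sp[!miss_sp %in% vals$species[!is.na(vals$value)]]
  if (length(never)) {
    inform(paste0("Dropping ", length(never), " species with no `", trait,
                  "` value anywhere: ", paste(head(never, 5), collapse = ", "),
                  if (length(never) > 5) ", ..." else ""))
    vals <- filter(vals, !.data$species %in% never)
  }
  if (anyNA(vals$value))
    abort(paste0("Some occurrences lack a `", trait,
                 "` value; run impute_missing_traits() first."))
  if (!nrow(vals)) abort("No occurrences left to analyse.")

  core <- tg_core(vals)
  slopes <- if (trait %in% occ$constant_traits) {
    tibble(species = character(), n_bs_plots = integer(), b_s = double())
  } else {
    intraspecific_slopes(occ, trait, min_plots = min_plots,
                         plot_means = core$plots) |>
      rename(n_bs_plots = "n_plots")
  }
  species <- left_join(core$species, slopes, by = "species")
  if (!"b_s" %in% names(species)) species$b_s <- NA_real_

  vp <- variance_partition(occ, trait)
  r2 <- if (nrow(species) >= 3) component_r2(species) else
    tibble(r2_alpha = NA_real_, r2_beta = NA_real_,
           alpha_degenerate = NA, beta_degenerate = NA)

  structure(
    list(trait = trait, species = species, plots = core$plots,
         occurrences = vals, variance = vp, r2 = r2,
         min_plots = min_plots),
    class = "trait_gradient"
  )
}

#' @export
print.trait_gradient <- function(x, ...) {
  cat("<trait_gradient>", x$trait, "\n")
  cat("  ", nrow(x$species), "species,", nrow(x$plots), "plots\n")
  cat(sprintf("   among-plot variance fraction: %.3f\n", x$variance$fraction_among_plots))
  if (!is.na(x$variance$fraction_within_species))
    cat(sprintf("   within-species variance fraction: %.3f\n",
                x$variance$fraction_within_species))
  cat(sprintf("   R2(t_bar ~ alpha) = %.3f, R2(t_bar ~ beta) = %.3f\n",
              x$r2$r2_alpha, x$r2$r2_beta))
  invisible(x)
}

#' @rdname trait_gradient
#' @param x A `"trait_gradient"` object.
#' @param ... Unused.
#' @method tidy trait_gradient
#' @export
tidy.trait_gradient <- function(x, ...) x$species

#' @rdname trait_gradient
#' @method glance trait_gradient
#' @export
glance.trait_gradient <- function(x, ...) {
  bs <- x$species$b_s[!is.na(x$species$b_s)]
  tibble(
    trait = x$trait,
    n_species = nrow(x$species),
    n_plots = nrow(x$plots),
    fraction_among_plots = x$variance$fraction_among_plots,
    fraction_within_plots = x$variance$fraction_within_plots,
    fraction_within_species = x$variance$fraction_within_species,
    r2_alpha = x$r2$r2_alpha,
    r2_beta = x$r2$r2_beta,
    n_bs = length(bs),
    bs_mean = if (length(bs)) mean(bs) else NA_real_
  )
}

#' @rdname trait_gradient
#' @param object A `"trait_gradient"` object.
#' @method autoplot trait_gradient
#' @export
autoplot.trait_gradient <- function(object, ...) {
  df <- left_join(object$occurrences,
                  select(object$plots, "plot", "p_bar"), by = "plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_bar, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "community mean trait (log10)",
      y = paste0(object$trait, " (log10)"),
      title = paste0("Trait gradient: ", object$trait)
    ) +
    ggplot2::theme_minimal()
}

#' Intraspecific trait-variation slopes along the community trait gradient
#'
#' For each species measured in at least `min_plots` plots, the ordinary
#' least-squares slope \eqn{b_s} of its plot-level trait values \eqn{t_{sp}}
#' against the community mean trait values \eqn{\bar p_p} of the plots it
#' occupies. A slope of 1 means trait values shift within the species at the
#' same rate as community means shift along the gradient. Only measured (not
#' imputed) values enter the regressions.
#'
#' @inheritParams trait_gradient
#' @param plot_means Optional tibble (`plot`, `p_bar`); computed from the
#'   (imputed) table when omitted.
#' @return A tibble with `species`, `n_plots` (plots with measured values) and
#'   `b_s`. Species whose occupied plots show zero gradient variance are
#'   excluded and listed in `attr(, "excluded")`.
#' @export
intraspecific_slopes <- function(occ, trait, min_plots = 3, plot_means = NULL) {
  stopifnot(inherits(occ, "occurrence_table"))
  if (trait %in% occ$constant_traits)
    abort("Species-constant traits have no intraspecific slope.")
  if (is.null(plot_means)) {
    vals <- occurrence_values(occ, trait)
    vals <- filter(vals, !is.na(.data$value))
    plot_means <- tg_core(vals)$plots
  }
  measured <- occ$plants |>
    filter(!is.na(.data[[trait]])) |>
    group_by(.data$species, .data$plot) |>
    summarise(value = mean(.data[[trait]]), .groups = "drop") |>
    left_join(select(plot_means, "plot", "p_bar"), by = "plot")

  res <- measured |>
    group_by(.data$species) |>
    summarise(
      n_plots = n(),
      sxx = sum((.data$p_bar - mean(.data$p_bar))^2),
      sxy = sum((.data$p_bar - mean(.data$p_bar)) * (.data$value - mean(.data$value))),
      b_s = ifelse(sxx > 0, sxy / sxx, NA_real_),
      .groups = "drop"
    ) |>
    filter(.data$n_plots >= min_plots)
  excluded <- filter(res, .data$sxx <= 0)
  if (nrow(excluded))
    inform(paste0(nrow(excluded),
                  " species excluded from b_s (no gradient variance)."))
  res <- res |> filter(.data$sxx > 0) |> select("species", "n_plots", "b_s")
  attr(res, "excluded") <- excluded$species
  res
}

#' One-sample t-test of intraspecific slopes against 1
#'
#' Under the expectation that trait values change at the same rate within
#' species as community means do along the gradient, the expected value of
#' \eqn{b_s} is 1; this tests the mean slope against that value.
#'
#' @param slopes A numeric vector of slopes, or the tibble returned by
#'   [intraspecific_slopes()] (column `b_s`).
#' @param mu Null value (default 1).
#' @return A one-row tibble: `n`, `mean`, `sd`, `df`, `statistic`, `p_value`.
#' @export
test_bs <- function(slopes, mu = 1) {
  b <- if (is.data.frame(slopes)) slopes$b_s else slopes
  b <- b[is.finite(b)]
  if (length(b) < 2) abort("Need at least two finite slopes.")
  if (sd(b) == 0) abort("Slopes have zero variance; t-test undefined.")
  ht <- stats::t.test(b, mu = mu)
  tibble(
    n = length(b), mean = mean(b), sd = sd(b),
    df = unname(ht$parameter), statistic = unname(ht$statistic),
    p_value = ht$p.value
  )
}

#' Partition trait variance among and within plots and species
#'
#' Two unweighted sum-of-squares decompositions: (1) occurrence-level trait
#' values (one per species-plot pair) partitioned among versus within plots —
#' the "how much community-level trait variation lies within communities"
#' summary; (2) individual-plant values partitioned within versus among
#' species — the magnitude of intraspecific variation. An abundance-weighted
#' variant of (1) is available via `weighted = TRUE`.
#'
#' @inheritParams trait_gradient
#' @param weighted Weight the plot decomposition by abundance (default
#'   `FALSE`: simple sums of squares over occurrence records).
#' @return A one-row tibble: `fraction_among_plots`, `fraction_within_plots`,
#'   `fraction_within_species`, `fraction_among_species`.
#' @export
variance_partition <- function(occ, trait, weighted = FALSE) {
  vals <- occurrence_values(occ, trait) |> filter(!is.na(.data$value))
  if (dplyr::n_distinct(vals$plot) < 2) abort("Need at least two plots.")

  w <- if (weighted) vals$abundance else rep(1, nrow(vals))
  gm <- sum(w * vals$value) / sum(w)
  ss_total <- sum(w * (vals$value - gm)^2)
  pm <- vals |>
    mutate(w = w) |>
    group_by(.data$plot) |>
    summarise(m = sum(.data$w * .data$value) / sum(.data$w),
              wsum = sum(.data$w), .groups = "drop")
  ss_among <- sum(pm$wsum * (pm$m - gm)^2)
  if (ss_total <= 0) {
    warn("Degenerate input (all trait values equal); plot fractions set to 0.")
    f_among <- 0; f_within <- 0
  } else {
    f_among <- ss_among / ss_total
    f_within <- 1 - f_among
  }

  f_within_sp <- NA_real_; f_among_sp <- NA_real_
  if (trait %in% occ$traits) {
    ind <- occ$plants |> filter(!is.na(.data[[trait]]))
    if (nrow(ind) >= 2) {
      x <- ind[[trait]]
      ss_tot_ind <- sum((x - mean(x))^2)
      sp_mean <- stats::ave(x, ind$species)
      ss_within <- sum((x - sp_mean)^2)
      if (ss_tot_ind <= 0) {
        warn("Degenerate input (all plant values equal); species fractions set to 0.")
        f_within_sp <- 0; f_among_sp <- 0
      } else {
        f_within_sp <- ss_within / ss_tot_ind
        f_among_sp <- 1 - f_within_sp
      }
    }
  }
  tibble(
    fraction_among_plots = f_among,
    fraction_within_plots = f_within,
    fraction_within_species = f_within_sp,
    fraction_among_species = f_among_sp
  )
}

#' Variance in species mean traits explained by each component
#'
#' Squared Pearson correlations between species mean trait values and their
#' within-community (alpha) and among-community (beta) components.
#'
#' @param x A `"trait_gradient"` object, or a data frame with columns
#'   `t_bar`, `alpha`, `beta`.
#' @return A one-row tibble `r2_alpha`, `r2_beta`, with logical columns
#'   `alpha_degenerate`/`beta_degenerate` flagging zero-variance components
#'   (whose R2 is reported as 0).
#' @export
component_r2 <- function(x) {
  df <- if (inherits(x, "trait_gradient")) x$species else as_tibble(x)
  if (nrow(df) < 3) abort("Need at least three species.")
  r2_of <- function(comp) {
    if (sd(df[[comp]]) == 0 || sd(df$t_bar) == 0) {
      list(r2 = 0, degenerate = TRUE)
    } else {
      list(r2 = cor(df$t_bar, df[[comp]])^2, degenerate = FALSE)
    }
  }
  a <- r2_of("alpha"); b <- r2_of("beta")
  tibble(r2_alpha = a$r2, r2_beta = b$r2,
         alpha_degenerate = a$degenerate, beta_degenerate = b$degenerate)
}
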
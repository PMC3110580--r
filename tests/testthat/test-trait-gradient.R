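test_that("trait derivation applies the standard formulas with unit handling", {
  raw <- data.frame(
    plant_id = c("a", "b"), species = c("s1", "s1"), plot = c("p1", "p1"),
    leaf_area_cm2 = c(10, 20), leaf_mass_g = c(0.05, 0.1),
    leaf_thickness_mm = c(0.2, 0.4),
    root_length_m = c(2, 1), root_mass_g = c(0.01, 0.02),
    root_volume_mm3 = c(40, 80), root_diameter_mm = c(0.3, 0.5)
  )
  out <- derive_traits(raw)
  expect_equal(out$sla, c(200, 200))                    # area/mass
  expect_equal(out$leaf_density[1], 0.25)               # 50 mg / 200 mm3
  expect_equal(out$srl, c(200, 50))                     # length/mass
  expect_equal(out$root_density, c(0.25, 0.25))         # mg/mm3
  expect_equal(out$leaf_size, raw$leaf_area_cm2)
  expect_equal(nrow(attr(out, "dropped")), 0)
})

test_that("records with non-positive masses or volumes are excluded and logged", {
  raw <- data.frame(
    plant_id = c("a", "b", "c"), species = "s", plot = "p",
    leaf_area_cm2 = c(10, 10, 10), leaf_mass_g = c(0.05, 0, 0.05),
    leaf_thickness_mm = c(0.2, 0.2, -1)
  )
  expect_warning(out <- derive_traits(raw), "excluded")
  expect_equal(nrow(out), 1)
  expect_equal(sort(attr(out, "dropped")$row), c(2L, 3L))
})

test_that("imputation fills unmeasured occurrences with same-site species means", {
  community <- data.frame(
    plot = c("p1", "p2", "p3"), species = "A", abundance = 0.5
  )
  plants <- data.frame(
    species = c("A", "A"), plot = c("p1", "p2"), trait1 = c(1, 3)
  )
  occ <- occurrence_table(community, plants, log10_traits = FALSE)
  occ2 <- impute_missing_traits(occ)
  log <- imputation_log(occ2)
  expect_equal(nrow(log), 1)
  expect_equal(log$plot, "p3")
  expect_equal(log$value, 2) # mean of 1 and 3
  expect_equal(log$note, "same_site")

  # no missing cells: identity, empty log
  occ3 <- impute_missing_traits(occ2)
  expect_equal(nrow(imputation_log(occ3)), 1) # unchanged

  # species never measured: warned, left missing
  community2 <- rbind(community, data.frame(plot = "p1", species = "B", abundance = 0.2))
  occB <- occurrence_table(community2, plants, log10_traits = FALSE)
  expect_warning(occB2 <- impute_missing_traits(occB), "never measured")
  expect_message(g <- trait_gradient(occB2, "trait1"), "Dropping 1 species")
  expect_false("B" %in% g$species$species)
})

test_that("the alpha/beta partition matches the worked example", {
  g <- trait_gradient(worked_occ(), "trait1")
  plots <- arrange(g$plots, plot)
  expect_equal(plots$p_bar, c(3, 2))
  sp <- arrange(g$species, species)
  expect_equal(sp$t_bar, c(2, 4))
  expect_equal(sp$beta, c(2.5, 3))
  expect_equal(sp$alpha, c(-0.5, 1))
})

test_that("species occurring alone have alpha = 0 and beta = t_bar", {
  community <- data.frame(plot = c("p1", "p2"), species = c("A", "B"),
                          abundance = c(0.4, 0.9))
  plants <- data.frame(species = c("A", "B"), plot = c("p1", "p2"),
                       trait1 = c(1.5, -2))
  g <- trait_gradient(occurrence_table(community, plants, log10_traits = FALSE),
                      "trait1")
  expect_equal(g$species$alpha, c(0, 0))
  expect_equal(g$species$beta, g$species$t_bar)
})

test_that("partition identities hold on random tables and survive record shuffling", {
  for (seed in 1:50) {
    occ <- random_occ(seed)
    g <- trait_gradient(occ, "trait1")
    expect_lt(max(abs(g$species$alpha + g$species$beta - g$species$t_bar)), 1e-10)
    # weighted residuals around each plot mean sum to zero
    resid <- g$occurrences |>
      dplyr::left_join(g$plots[c("plot", "p_bar")], by = "plot") |>
      dplyr::group_by(plot) |>
      dplyr::summarise(z = sum(abundance * (value - p_bar)))
    expect_lt(max(abs(resid$z)), 1e-10)
    # plot means bounded by occurring species values
    rng <- g$occurrences |>
      dplyr::group_by(plot) |>
      dplyr::summarise(lo = min(value), hi = max(value)) |>
      dplyr::left_join(g$plots[c("plot", "p_bar")], by = "plot")
    expect_true(all(rng$p_bar >= rng$lo - 1e-12 & rng$p_bar <= rng$hi + 1e-12))
  }

  # permuting record order leaves outputs unchanged
  occ <- random_occ(99)
  shuffled <- withr::with_seed(1, occurrence_table(
    occ$community[sample(nrow(occ$community)), ],
    occ$plants[sample(nrow(occ$plants)), ],
    log10_traits = FALSE
  ))
  g1 <- trait_gradient(occ, "trait1")
  g2 <- trait_gradient(shuffled, "trait1")
  expect_identical(g1$species, g2$species)
  expect_identical(g1$plots, g2$plots)
})

test_that("intraspecific slopes are ordinary least squares on plot means", {
  mk <- function(tvals) {
    # species X measured in 3 plots; a partner species pins down the plot means
    community <- data.frame(
      plot = rep(c("p1", "p2", "p3"), each = 2),
      species = rep(c("X", "Y"), 3),
      abundance = rep(c(0.5, 0.5), 3)
    )
    plants <- data.frame(
      species = rep(c("X", "Y"), 3), plot = rep(c("p1", "p2", "p3"), each = 2),
      trait1 = as.vector(rbind(tvals, c(1, 3, 5) * 2 - tvals)) # plot means 1,3,5
    )
    occurrence_table(community, plants, log10_traits = FALSE)
  }
  # constant trait across varying plot means: slope 0
  s0 <- intraspecific_slopes(mk(c(2, 2, 2)), "trait1")
  expect_equal(s0$b_s[s0$species == "X"], 0)
  # trait equal to the plot mean: slope 1
  s1 <- intraspecific_slopes(mk(c(1, 3, 5)), "trait1")
  expect_equal(s1$b_s[s1$species == "X"], 1)
  # hand OLS through (1,1),(3,5),(5,9): slope 2
  s2 <- intraspecific_slopes(mk(c(1, 5, 9)), "trait1")
  expect_equal(s2$b_s[s2$species == "X"], 2)
  # min_plots excludes sparsely measured species
  occ <- mk(c(1, 3, 5))
  expect_false("X" %in% intraspecific_slopes(occ, "trait1", min_plots = 4)$species)
})

test_that("the slope t-test matches hand computations and guards its contract", {
  res <- test_bs(c(0, 2, 1, 1))
  expect_equal(res$mean, 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  tiny <- test_bs(c(0.001, -0.001, 0.0005, 0))
  expect_lt(tiny$p_value, 0.001)

  expect_error(test_bs(1), "at least two")
  expect_error(test_bs(c(1, 1, 1)), "zero variance")
})

test_that("variance partition reproduces hand sums of squares and edge cases", {
  community <- data.frame(plot = c("p1", "p1", "p2", "p2"),
                          species = c("A", "B", "C", "D"),
                          abundance = 0.5)
  plants <- data.frame(species = c("A", "B", "C", "D"),
                       plot = c("p1", "p1", "p2", "p2"),
                       trait1 = c(0, 2, 4, 6))
  occ <- occurrence_table(community, plants, log10_traits = FALSE)
  vp <- variance_partition(occ, "trait1")
  expect_equal(vp$fraction_among_plots, 0.8) # 16/20
  expect_equal(vp$fraction_within_plots, 0.2)
  expect_equal(vp$fraction_among_plots + vp$fraction_within_plots, 1)
  expect_equal(vp$fraction_within_species + vp$fraction_among_species, 1)

  # equal plot means, variation within: among-plot fraction 0
  plants2 <- transform(plants, trait1 = c(0, 2, 2, 0))
  vp2 <- variance_partition(
    occurrence_table(community, plants2, log10_traits = FALSE), "trait1")
  expect_equal(vp2$fraction_among_plots, 0)

  # one species-value per plot: within-plot fraction 0
  community3 <- data.frame(plot = c("p1", "p2"), species = c("A", "B"),
                           abundance = 0.5)
  plants3 <- data.frame(species = c("A", "B"), plot = c("p1", "p2"),
                        trait1 = c(1, 4))
  vp3 <- variance_partition(
    occurrence_table(community3, plants3, log10_traits = FALSE), "trait1")
  expect_equal(vp3$fraction_within_plots, 0)

  # degenerate: all equal
  plants4 <- transform(plants, trait1 = 5)
  # both decompositions warn on fully constant input
  expect_warning(expect_warning(
    vp4 <- variance_partition(
      occurrence_table(community, plants4, log10_traits = FALSE), "trait1"),
    "Degenerate"), "Degenerate")
  expect_equal(vp4$fraction_among_plots, 0)
})

test_that("component R2 reflects which component carries the variation", {
  # beta constant: t_bar = alpha + const, so R2(alpha) = 1
  df <- tibble::tibble(t_bar = c(1, 2, 3, 5), beta = 2,
                       alpha = t_bar - beta)
  r2 <- component_r2(df)
  expect_equal(r2$r2_alpha, 1)
  expect_equal(r2$r2_beta, 0)
  expect_true(r2$beta_degenerate)

  df2 <- tibble::tibble(t_bar = c(1, 2, 3, 5), alpha = 0.7,
                        beta = t_bar - alpha)
  r22 <- component_r2(df2)
  expect_equal(r22$r2_beta, 1)

  # independent equal-variance components: both R2 near 0.5
  withr::with_seed(42, {
    a <- rnorm(10000); b <- rnorm(10000)
    df3 <- tibble::tibble(alpha = a, beta = b, t_bar = a + b)
  })
  r23 <- component_r2(df3)
  expect_equal(r23$r2_alpha, 0.5, tolerance = 0.05)
  expect_equal(r23$r2_beta, 0.5, tolerance = 0.05)
})

test_that("percent abundances are rescaled and invariants enforced at ingest", {
  community <- data.frame(plot = c("p1", "p1"), species = c("A", "B"),
                          abundance = c(50, 100))
  occ <- occurrence_table(community, log10_traits = FALSE)
  expect_equal(sort(occ$community$abundance), c(0.5, 1))
  expect_error(
    occurrence_table(data.frame(plot = "p1", species = c("A", "A"),
                                abundance = c(0.1, 0.2))),
    "Duplicate")
  expect_error(
    occurrence_table(data.frame(plot = "p1", species = "A", abundance = 0)),
    "positive")
  expect_error(
    occurrence_table(data.frame(plot = "p1", species = "A", abundance = 0.5),
                     data.frame(species = "A", plot = "p1", trait1 = -2),
                     log10_traits = TRUE),
    "non-positive")
})
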
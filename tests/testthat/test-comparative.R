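test_that("contrasts match single-step and hand-pruned values", {
  # 2-tip tree, unit branches: one contrast, |standardized| = 2/sqrt(2)
  cs <- independent_contrasts(read_newick("(A:1,B:1);"), c(A = 0, B = 2))
  expect_equal(nrow(cs), 1)
  expect_equal(abs(cs$contrast), sqrt(2))

  # ((A:1,B:1):1,C:1): node AB then root with lengthened branch 1.5
  cs2 <- independent_contrasts(read_newick("((A:1,B:1):1,C:1);"),
                               c(A = 1, B = 3, C = 6))
  cs2 <- cs2[order(cs2$node), ]
  expect_equal(cs2$raw, c(2 - 6, 1 - 3))          # root contrast uses node value 2
  expect_equal(cs2$sd, c(sqrt(2.5), sqrt(2)))
  expect_equal(cs2$contrast, c(-4 / sqrt(2.5), -2 / sqrt(2)))

  # constant trait: all contrasts zero; N = tips - 1
  tr <- simulate_tree(12, seed = 4)
  csc <- independent_contrasts(tr, setNames(rep(3, 12), tr$tip.label))
  expect_equal(nrow(csc), 11)
  expect_lt(max(abs(csc$contrast)), 1e-12)

  expect_error(independent_contrasts(read_newick("(A:1,B:1,C:1);"),
                                     c(A = 1, B = 2, C = 3)), "bifurcating")
  expect_error(independent_contrasts(read_newick("(A:1,B:1);"), c(A = 1, X = 2)),
               "tip labels")
})

test_that("contrasts agree with the brute-force pruning oracle on small trees", {
  # exhaustive topologies at 4 and 5 tips
  for (n in 4:5) {
    tops <- phangorn::allTrees(n, rooted = TRUE,
                               tip.label = paste0("t", seq_len(n)))
    for (i in seq_along(tops)) {
      tr <- tops[[i]]
      tr$edge.length <- withr::with_seed(i, runif(nrow(tr$edge), 0.2, 2))
      x <- withr::with_seed(1000 + i, setNames(rnorm(n), tr$tip.label))
      mine <- independent_contrasts(tr, x)
      ora <- oracle_pic(tr, x)
      expect_equal(mine$contrast[order(mine$node)], ora$contrast, tolerance = 1e-10)
      expect_equal(mine$sd[order(mine$node)], ora$sd, tolerance = 1e-10)
    }
  }
  # random trees at 6-8 tips
  for (n in 6:8) for (seed in 1:10) {
    tr <- simulate_tree(n, seed = seed * n, root_age = 1)
    x <- withr::with_seed(seed + 77 * n, setNames(rnorm(n), tr$tip.label))
    mine <- independent_contrasts(tr, x)
    ora <- oracle_pic(tr, x)
    expect_equal(mine$contrast[order(mine$node)], ora$contrast, tolerance = 1e-10)
  }
})

test_that("contrast diagnostics are centred at zero under Brownian motion", {
  tr <- simulate_tree(64, seed = 31)
  rs <- vapply(1:200, function(i) {
    x <- simulate_bm_traits(tr, rate = 0.01, seed = i)
    contrast_diagnostics(independent_contrasts(tr, x))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)

  # constant SDs: flagged not-applicable
  expect_true(is.na(contrast_diagnostics(
    structure(tibble::tibble(node = 1:3, raw = c(1, 2, 3),
                             sd = c(2, 2, 2), contrast = c(0.5, 1, 1.5)),
              class = c("contrast_set", "tbl_df", "tbl", "data.frame")))$r))

  # invariant to trait sign flip
  x <- simulate_bm_traits(tr, rate = 1, seed = 5)
  d1 <- contrast_diagnostics(independent_contrasts(tr, x))
  d2 <- contrast_diagnostics(independent_contrasts(tr, -x))
  expect_equal(d1$r, d2$r)
})

test_that("through-origin PIC correlation matches the hand formula", {
  mk_cs <- function(v) structure(
    tibble::tibble(node = seq_along(v) + 10L, raw = v, sd = 1, contrast = v),
    class = c("contrast_set", "tbl_df", "tbl", "data.frame"))

  # proportional contrasts: r = 1
  expect_equal(correlation_pic(mk_cs(c(1, -2, 3)), mk_cs(c(2, -4, 6)))$r, 1)
  # orthogonal: r = 0
  expect_equal(correlation_pic(mk_cs(c(1, 1)), mk_cs(c(1, -1)))$r, 0)
  # hand value: sum(xy)/sqrt(sum(x^2) sum(y^2)) = 25/sqrt(630)
  res <- correlation_pic(mk_cs(c(1, -2, 3)), mk_cs(c(2, -4, 5)))
  expect_equal(res$r, 25 / sqrt(14 * 45), tolerance = 1e-12)
  expect_equal(res$df, 2L)
  # sign convention irrelevance: flipping both contrasts at one node
  a <- c(1, -2, 3); b <- c(2, -4, 5)
  a2 <- a * c(-1, 1, 1); b2 <- b * c(-1, 1, 1)
  expect_equal(correlation_pic(mk_cs(a2), mk_cs(b2))$r, res$r)
})

test_that("ahistorical correlations are plain Pearson with n-2 df", {
  x <- setNames(c(1, 2, 3, 5, 8), paste0("s", 1:5))
  expect_equal(correlation_ahistorical(x, x)$r, 1)
  withr::with_seed(8, {
    a <- setNames(rnorm(10000), paste0("s", 1:10000))
    b <- setNames(rnorm(10000), paste0("s", 1:10000))
  })
  expect_lt(abs(correlation_ahistorical(a, b)$r), 0.05)
  expect_error(correlation_ahistorical(x, setNames(rep(1, 5), names(x))),
               "Zero variance")
})

test_that("PIC correlation on a star equals the centred Pearson correlation", {
  n <- 16
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:n), collapse = ","), ");"))
  # random zero-length resolution: tip branches stay 1, interior branches 0
  # (floored at 1e-8 inside the contrast computation)
  rstar <- resolve_polytomies(star, seed = 3)
  withr::with_seed(21, {
    x <- setNames(rnorm(n), star$tip.label)
    y <- setNames(rnorm(n), star$tip.label)
  })
  r_pic <- correlation_pic(independent_contrasts(rstar, x),
                           independent_contrasts(rstar, y))$r
  expect_equal(r_pic, cor(x, y), tolerance = 1e-6)
})

test_that("Blomberg's K matches its independent oracle and the star identity", {
  # star phylogeny: K = 1 exactly for any non-constant trait
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  for (seed in 1:5) {
    x <- withr::with_seed(seed, setNames(rnorm(5), star$tip.label))
    expect_equal(blomberg_k(star, x), 1, tolerance = 1e-12)
  }

  # independent cross-check at <= 8 tips and at realistic size
  for (n in c(4, 6, 8, 32)) {
    tr <- simulate_tree(n, seed = n + 1)
    x <- simulate_bm_traits(tr, rate = 0.01, seed = n)
    expect_equal(blomberg_k(tr, x),
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("tip shuffling lowers K on an imbalanced tree", {
  tr <- ape::compute.brlen(ape::stree(32, type = "left"), method = "Grafen")
  kk <- vapply(1:100, function(i) {
    x <- simulate_bm_traits(tr, rate = 1, seed = i)
    xs <- withr::with_seed(i + 500, setNames(sample(unname(x)), names(x)))
    c(blomberg_k(tr, x) > blomberg_k(tr, xs))
  }, logical(1))
  expect_gte(mean(kk), 0.9)
})

test_that("the permutation signal test is seeded, bounded and directionally sound", {
  tr <- simulate_tree(32, seed = 6)
  x <- simulate_bm_traits(tr, rate = 0.01, seed = 2)
  s1 <- signal_test(tr, x, n_perm = 99, seed = 11)
  s2 <- signal_test(tr, x, n_perm = 99, seed = 11)
  expect_identical(s1$p_value, s2$p_value)
  expect_gte(s1$p_value, 1 / 100)
  expect_lte(s1$p_value, 1)

  # BM traits give low P and higher K than tip-shuffled ones, on average
  comp <- vapply(1:30, function(i) {
    xb <- simulate_bm_traits(tr, rate = 1, seed = 100 + i)
    xs <- withr::with_seed(i, setNames(sample(unname(xb)), names(xb)))
    sb <- signal_test(tr, xb, n_perm = 99, seed = i)
    ss <- signal_test(tr, xs, n_perm = 99, seed = i)
    c(sb$p_value <= 0.05, sb$K > ss$K)
  }, logical(2))
  expect_gte(mean(comp[1, ]), 0.8)
  expect_gte(mean(comp[2, ]), 0.8)
  expect_error(signal_test(tr, x, n_perm = 0), "at least 1")
})

test_that("the combined correlation matrix has the published layout", {
  tr <- simulate_tree(20, seed = 9)
  tm <- sapply(1:4, function(j) simulate_bm_traits(tr, rate = 1, seed = 40 + j))
  colnames(tm) <- paste0("tr", 1:4)
  cm <- correlation_matrix(tm, tr)
  expect_equal(dim(cm$r), c(4, 4))
  expect_true(all(is.na(diag(cm$r))))
  expect_true(all(!is.na(cm$r[lower.tri(cm$r)])))
  expect_true(all(!is.na(cm$r[upper.tri(cm$r)])))
  expect_true(all(abs(cm$r[!is.na(cm$r)]) <= 1))
})
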
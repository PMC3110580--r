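#' Phylogenetically independent contrasts
#'
#' Standardized contrasts at each internal node of a bifurcating tree,
#' computed by Felsenstein's pruning algorithm (via [ape::pic()]): at a node
#' joining subtrees with values \eqn{x_i, x_j} and adjusted branch lengths
#' \eqn{b_i, b_j}, the contrast is \eqn{x_i - x_j} with variance
#' \eqn{b_i + b_j}; the node is assigned value
#' \eqn{(x_i/b_i + x_j/b_j)/(1/b_i + 1/b_j)} and its parent branch is
#' lengthened by \eqn{b_i b_j/(b_i + b_j)}. Zero-length branches (e.g. from
#' random polytomy resolution) are floored at `min_brlen` so contrast
#' variances stay positive.
#'
#' @param tree A bifurcating `"phylo"` object with branch lengths.
#' @param trait Named numeric vector; names must equal the tip labels.
#' @param min_brlen Floor applied to zero-length branches (default 1e-8).
#' @return A tibble of class `"contrast_set"` with one row per internal node:
#'   `node`, `raw` (unstandardized contrast), `sd` (square root of the
#'   contrast variance) and `contrast` (standardized, `raw/sd`).
#' @export
independent_contrasts <- function(tree, trait, min_brlen = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    abort("Tree is not rooted and bifurcating; resolve_polytomies() first.")
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (is.null(names(trait)) || !setequal(names(trait), tree$tip.label))
    abort("`trait` must be named by the tree's tip labels (same set).")
  if (anyNA(trait)) abort("`trait` contains missing values.")
  tree$edge.length[tree$edge.length < min_brlen] <- min_brlen
  x <- trait[tree$tip.label]
  p <- ape::pic(x, tree, scaled = TRUE, var.contrasts = TRUE)
  out <- tibble(
    node = as.integer(rownames(p) %||% seq(ape::Ntip(tree) + 1L, length.out = nrow(p))),
    raw = unname(p[, 1] * sqrt(p[, 2])),
    sd = unname(sqrt(p[, 2])),
    contrast = unname(p[, 1])
  )
  class(out) <- c("contrast_set", class(out))
  out
}

#' Contrast diagnostics: are absolute contrasts independent of their SDs?
#'
#' Pearson correlation between the absolute standardized contrasts and their
#' expected standard deviations. A significant correlation indicates the
#' branch lengths do not adequately standardize the contrasts and a
#' transformation (e.g. equal branch lengths) should be considered.
#'
#' @param cs A `"contrast_set"` from [independent_contrasts()].
#' @return A one-row tibble `r`, `p_value`, `n`, `applicable` (`FALSE` when
#'   the SDs are constant, e.g. on a star tree, in which case `r` is `NA`).
#' @export
contrast_diagnostics <- function(cs) {
  stopifnot(inherits(cs, "contrast_set"))
  if (nrow(cs) < 3) abort("Need at least three contrasts.")
  if (sd(cs$sd) == 0 || sd(abs(cs$contrast)) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = nrow(cs), applicable = FALSE))
  }
  ht <- cor.test(abs(cs$contrast), cs$sd)
  tibble(r = unname(ht$estimate), p_value = ht$p.value, n = nrow(cs),
         applicable = TRUE)
}

#' Ahistorical (cross-species) Pearson correlation
#'
#' Ordinary Pearson correlation between two species-level trait vectors,
#' ignoring phylogeny; the non-phylogenetic counterpart of
#' [correlation_pic()].
#'
#' @param x,y Named numeric vectors (species names); only shared species are
#'   used.
#' @return A one-row tibble `r`, `p_value`, `n`, `df`.
#' @export
correlation_ahistorical <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3) abort("Need at least three shared species.")
  xv <- x[shared]; yv <- y[shared]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("Need at least three complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) abort("Zero variance in a trait.")
  ht <- cor.test(xv, yv)
  tibble(r = unname(ht$estimate), p_value = ht$p.value,
         n = length(xv), df = length(xv) - 2L)
}

#' Through-origin correlation of independent contrasts
#'
#' Evolutionary correlation between two traits from their standardized
#' contrasts on the same tree. Because the sign of each contrast is arbitrary,
#' the correlation is computed through the origin,
#' \eqn{r = \sum c_x c_y / \sqrt{\sum c_x^2 \sum c_y^2}}, with degrees of
#' freedom reduced to \eqn{N - 1}.
#'
#' @param cx,cy `"contrast_set"` objects on the same tree (same nodes).
#' @return A one-row tibble `r`, `p_value`, `df`, `n`.
#' @export
correlation_pic <- function(cx, cy) {
  stopifnot(inherits(cx, "contrast_set"), inherits(cy, "contrast_set"))
  if (nrow(cx) != nrow(cy) || !all(cx$node == cy$node))
    abort("Contrast sets are not on the same tree/nodes.")
  if (nrow(cx) < 2) abort("Need at least two contrasts.")
  a <- cx$contrast; b <- cy$contrast
  if (all(a == 0) || all(b == 0)) abort("All contrasts are zero in one set.")
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  df <- nrow(cx) - 1L
  tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  tibble(r = r, p_value = 2 * pt(-abs(tstat), df), df = df, n = nrow(cx))
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Measures the amount of variation in a quantitative trait relative to the
#' expectation under Brownian motion on the tree. With phylogenetic
#' covariance matrix \eqn{C} (see [phylo_covariance()]) and phylogenetically
#' weighted mean \eqn{\hat a = (1'C^{-1}x)/(1'C^{-1}1)},
#' \deqn{K = \frac{(x-\hat a)'(x-\hat a) / (x-\hat a)'C^{-1}(x-\hat a)}
#'   {[\mathrm{tr}(C) - n/(1'C^{-1}1)]/(n-1)}.}
#' K = 1 is the Brownian expectation; K < 1 indicates less resemblance among
#' relatives than expected, K > 1 more.
#'
#' @param tree A rooted `"phylo"` object with branch lengths (n >= 3 tips).
#' @param trait Named numeric vector over the tips.
#' @return The K value (a single non-negative number).
#' @export
blomberg_k <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 3) abort("Need at least three tips.")
  if (is.null(names(trait)) || !setequal(names(trait), tree$tip.label))
    abort("`trait` must be named by the tree's tip labels (same set).")
  C <- phylo_covariance(tree)
  x <- trait[rownames(C)]
  Cinv <- tryCatch(solve(C), error = function(e)
    abort("Phylogenetic covariance matrix is singular (identical zero-length tips?)."))
  one <- rep(1, n)
  ahat <- as.numeric(one %*% Cinv %*% x) / as.numeric(one %*% Cinv %*% one)
  d <- x - ahat
  mse0 <- sum(d * d) / (n - 1)
  mse <- as.numeric(d %*% Cinv %*% d) / (n - 1)
  expected <- (sum(diag(C)) - n / as.numeric(one %*% Cinv %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test of phylogenetic signal
#'
#' Tests for phylogenetic signal by comparing the variance of standardized
#' independent contrasts of the observed trait with its null distribution
#' obtained by shuffling trait values across the tips of the tree. Low
#' contrast variance relative to the shuffled data indicates that close
#' relatives have similar trait values. Blomberg's K is reported alongside.
#'
#' @inheritParams independent_contrasts
#' @param n_perm Number of tip shuffles (default 999).
#' @param seed Integer seed for the shuffles.
#' @return An object of class `"signal_test"`: list with `K`, `p_value`,
#'   `observed` (variance of standardized contrasts), `n_perm`, `seed`, `n`.
#' @export
signal_test <- function(tree, trait, n_perm = 999, seed = 1L, min_brlen = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- resolve_polytomies(tree, seed = seed)
  if (is.null(names(trait)) || !setequal(names(trait), tree$tip.label))
    abort("`trait` must be named by the tree's tip labels (same set).")
  tree$edge.length[tree$edge.length < min_brlen] <- min_brlen
  x <- trait[tree$tip.label]
  contrast_var <- function(v) var(ape::pic(v, tree, scaled = TRUE))
  obs <- contrast_var(x)
  null <- withr::with_seed(seed, vapply(
    seq_len(n_perm),
    function(i) contrast_var(setNames(sample(x), names(x))),
    numeric(1)
  ))
  p <- (sum(null <= obs) + 1) / (n_perm + 1)
  structure(
    list(K = blomberg_k(tree, x), p_value = p, observed = obs,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         n = ape::Ntip(tree)),
    class = "signal_test"
  )
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("<signal_test> K = %.3f, P = %.4g (%d tip shuffles, seed %d)\n",
              x$K, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' @rdname signal_test
#' @param x A `"signal_test"` object.
#' @param ... Unused.
#' @method tidy signal_test
#' @export
tidy.signal_test <- function(x, ...) {
  tibble(K = x$K, p_value = x$p_value, observed = x$observed,
         n_perm = x$n_perm, n = x$n, seed = x$seed)
}

#' Combined ahistorical / PIC correlation matrix
#'
#' Builds the publication-style square correlation matrix across a set of
#' traits: ahistorical Pearson correlations below the diagonal,
#' contrast-based through-origin correlations above.
#'
#' @param trait_mat Species-by-trait matrix or data frame (species as row
#'   names).
#' @param tree Bifurcating `"phylo"` covering the species.
#' @return A list with `r` (the combined matrix), `p_ahistorical` and
#'   `p_pic` matrices.
#' @export
correlation_matrix <- function(trait_mat, tree) {
  trait_mat <- as.matrix(trait_mat)
  traits <- colnames(trait_mat)
  cs <- lapply(traits, function(tr)
    independent_contrasts(tree, setNames(trait_mat[, tr], rownames(trait_mat))))
  names(cs) <- traits
  k <- length(traits)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  pa <- r; pp <- r
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (i > j) { # lower triangle: ahistorical
      res <- correlation_ahistorical(
        setNames(trait_mat[, i], rownames(trait_mat)),
        setNames(trait_mat[, j], rownames(trait_mat)))
      r[i, j] <- res$r; pa[i, j] <- res$p_value
    } else {     # upper triangle: PIC
      res <- correlation_pic(cs[[i]], cs[[j]])
      r[i, j] <- res$r; pp[i, j] <- res$p_value
    }
  }
  list(r = r, p_ahistorical = pa, p_pic = pp)
}
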
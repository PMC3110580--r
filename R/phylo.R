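#' Read a phylogeny from a Newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees are returned as
#' standard `"phylo"` objects so they interoperate with the wider comparative
#' methods ecosystem. Duplicate tip labels are an error (downstream trait maps
#' are keyed by tip label), and missing branch lengths are flagged with a
#' message rather than silently zeroed.
#'
#' @param x A Newick string, or the path to a file containing one tree.
#' @return An object of class `"phylo"`. If any branch length was absent in
#'   the input, the attribute `"missing_brlen"` is set to `TRUE`.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (file.exists(x) && !grepl("\\(", x)) paste(readLines(x, warn = FALSE), collapse = "") else x
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("Newick parse error: input did not contain a tree.")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("Duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(tree$tip.label))) abort("Empty tip labels are not allowed.")
  if (is.null(tree$edge.length)) {
    inform("Tree has no branch lengths; they are left unset (not zeroed).")
    attr(tree, "missing_brlen") <- TRUE
  } else if (anyNA(tree$edge.length)) {
    inform("Some branch lengths are missing; they are left as NA (not zeroed).")
    attr(tree, "missing_brlen") <- TRUE
  } else if (any(tree$edge.length < 0)) {
    abort("Negative branch lengths are not allowed.")
  }
  tree
}

# cheap structural pre-check so parse failures report a character position
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(paste0("Newick parse error at position ", i, ": unmatched ')'."))
    }
  }
  if (depth != 0L) abort(paste0(
    "Newick parse error at position ", length(chars), ": ", depth, " unclosed '('."
  ))
  if (!grepl(";", text)) abort("Newick parse error: missing terminating ';'.")
  invisible(TRUE)
}

#' Write a phylogeny to a Newick string or file
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` (default) the Newick string is
#'   returned invisibly visible.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Set every branch length to a common value
#'
#' Transforming all branch lengths to an equal length is a standard
#' preprocessing step before computing independent contrasts when contrast
#' diagnostics reject the original (e.g. time-calibrated) branch lengths.
#' Topology and tip set are unchanged.
#'
#' @param tree A `"phylo"` object.
#' @param value Positive branch length assigned to every edge (default 1).
#' @return The tree with constant branch lengths.
#' @export
set_equal_branch_lengths <- function(tree, value = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    abort("`value` must be a single positive number.")
  tree$edge.length <- rep(value, nrow(tree$edge))
  tree
}

#' Interpolate undated node ages by even spacing
#'
#' Assigns an age (time before present) to every internal node of a rooted
#' tree given a set of fixed node ages, by spacing undated nodes evenly along
#' each root-to-tip path segment between consecutive dated nodes (the strategy
#' used to minimise tree-wide variance in branch lengths when only some nodes
#' carry fossil or secondary calibrations). Tips are fixed at age 0. Branch
#' lengths are recomputed as parent age minus child age, so when all tips are
#' extant the result is ultrametric.
#'
#' A node lying on several dated segments is assigned once; segments are
#' processed in order of decreasing dated-ancestor age (ties broken by node
#' number), which makes the assignment deterministic.
#'
#' @param tree A rooted `"phylo"` object. Internal nodes referenced by
#'   `fixed_ages` must carry node labels (`tree$node.label`).
#' @param fixed_ages Named numeric vector of ages (My before present); names
#'   are internal-node labels (or tip labels, which must then be 0). Must
#'   include the root.
#' @param root_age Convenience shortcut: age of the root node, merged into
#'   `fixed_ages`.
#' @return The tree with `edge.length` recomputed from interpolated ages and
#'   a `"node_ages"` attribute (ages indexed by node number, tips first).
#' @export
interpolate_node_ages <- function(tree, fixed_ages = NULL, root_age = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  root <- ntip + 1L

  age <- rep(NA_real_, ntot)
  age[seq_len(ntip)] <- 0

  labels <- c(tree$tip.label, tree$node.label %||% rep(NA_character_, nnode))
  fixed_ages <- fixed_ages %||% numeric(0)
  if (!is.null(root_age)) {
    age[root] <- root_age
  }
  if (length(fixed_ages)) {
    if (is.null(names(fixed_ages)) || any(!nzchar(names(fixed_ages))))
      abort("`fixed_ages` must be a named numeric vector.")
    idx <- match(names(fixed_ages), labels)
    if (anyNA(idx)) abort(paste0(
      "Unknown node label(s) in `fixed_ages`: ",
      paste(names(fixed_ages)[is.na(idx)], collapse = ", ")
    ))
    bad_tip <- idx <= ntip & fixed_ages != 0
    if (any(bad_tip)) abort("Tips must have age 0.")
    age[idx] <- unname(fixed_ages)
  }
  if (is.na(age[root])) abort("The root must have a fixed age (use `root_age`).")

  parent <- integer(ntot)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])

  # consistency of the fixed ages: every dated ancestor strictly older than
  # its dated proper descendants
  dated <- which(!is.na(age))
  for (nd in setdiff(dated, seq_len(ntip))) {
    anc <- parent[nd]
    while (anc != 0L) {
      if (!is.na(age[anc]) && age[anc] <= age[nd]) abort(paste0(
        "Inconsistent fixed ages: node ", nd, " (", age[nd],
        ") is not younger than its ancestor ", anc, " (", age[anc], ")."
      ))
      anc <- if (anc == root) 0L else parent[anc]
    }
  }

  # iteratively space undated nodes evenly along segments between consecutive
  # dated nodes; after each assignment the newly dated nodes subdivide the
  # remaining segments, which keeps ages monotone along every path. Segments
  # are taken in order of decreasing dated-ancestor age (deterministic
  # tie-breaks), so each node is assigned exactly once.
  find_segments <- function() {
    segs <- list()
    for (a in which(!is.na(age))) {
      kids <- children[[as.character(a)]]
      if (is.null(kids)) next
      stack <- lapply(kids, function(k) list(node = k, chain = integer(0)))
      while (length(stack)) {
        item <- stack[[1]]; stack <- stack[-1]
        nd <- item$node
        if (!is.na(age[nd])) {
          if (length(item$chain)) {
            segs[[length(segs) + 1L]] <-
              list(from = a, to = nd, interior = item$chain)
          }
        } else {
          kk <- children[[as.character(nd)]]
          stack <- c(stack, lapply(kk, function(k)
            list(node = k, chain = c(item$chain, nd))))
        }
      }
    }
    segs
  }
  while (anyNA(age)) {
    segs <- find_segments()
    if (!length(segs)) abort("Internal error: some nodes were not assigned an age.")
    key <- vapply(segs, function(s) age[s$from], numeric(1))
    ord <- order(-key,
                 vapply(segs, function(s) s$from, integer(1)),
                 vapply(segs, function(s) s$to, integer(1)))
    seg <- segs[[ord[1]]]
    k <- length(seg$interior)
    step <- (age[seg$from] - age[seg$to]) / (k + 1)
    for (i in seq_len(k)) age[seg$interior[i]] <- age[seg$from] - i * step
  }

  el <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(el < -1e-9)) abort("Inconsistent ages produced a negative branch length.")
  tree$edge.length <- pmax(el, 0)
  attr(tree, "node_ages") <- age
  tree
}

#' Resolve polytomies randomly with zero-length branches
#'
#' Multifurcations are resolved into an arbitrary bifurcating arrangement with
#' inserted internal branches of length zero, so root-to-tip path lengths are
#' unchanged. The resolution is deterministic given `seed`.
#'
#' @param tree A `"phylo"` object, possibly multifurcating.
#' @param seed Integer seed controlling the resolution.
#' @return A strictly bifurcating `"phylo"` object with attribute
#'   `"resolution_seed"`.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  out <- if (ape::is.binary(tree) && ape::is.rooted(tree)) tree else
    withr::with_seed(seed, ape::multi2di(tree, random = TRUE))
  attr(out, "resolution_seed") <- as.integer(seed)
  out
}

#' Phylogenetic covariance matrix
#'
#' Matrix of expected trait covariances under Brownian motion: entry (i, j) is
#' the shared path length from the root to the most recent common ancestor of
#' tips i and j; the diagonal holds root-to-tip distances. Computed with
#' [ape::vcv.phylo()].
#'
#' @param tree A rooted `"phylo"` object with non-negative branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (any(tree$edge.length < 0)) abort("Negative branch lengths are not allowed.")
  ape::vcv.phylo(tree)
}
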
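suppressPackageStartupMessages(library(dplyr))

# Independent brute-force pruning oracle for contrasts: plain recursive
# implementation, deliberately separate from the package's code path.
oracle_pic <- function(tree, x) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- numeric(ntip + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  val <- c(x[tree$tip.label], rep(NA_real_, tree$Nnode))
  adj <- blen
  out <- list()
  rec <- function(node) {
    if (node <= ntip) return(NULL)
    ch <- kids[[as.character(node)]]
    for (c in ch) rec(c)
    b1 <- adj[ch[1]]; b2 <- adj[ch[2]]
    raw <- val[ch[1]] - val[ch[2]]
    v <- b1 + b2
    out[[length(out) + 1L]] <<- c(node = node, raw = raw, sd = sqrt(v),
                                  contrast = raw / sqrt(v))
    val[node] <<- (val[ch[1]] / b1 + val[ch[2]] / b2) / (1 / b1 + 1 / b2)
    adj[node] <<- blen[node] + b1 * b2 / (b1 + b2)
    NULL
  }
  rec(ntip + 1L)
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$node), ]
}

# small random occurrence table (plant-level traits already on log scale)
random_occ <- function(seed, n_species = 8, n_plots = 5) {
  withr::with_seed(seed, {
    sp <- sprintf("s%02d", seq_len(n_species))
    rows <- do.call(rbind, lapply(seq_len(n_plots), function(p) {
      k <- sample(2:n_species, 1)
      data.frame(plot = sprintf("p%02d", p),
                 species = sample(sp, k),
                 abundance = sample(1:10, k, replace = TRUE) / 10)
    }))
    plants <- rows[c("species", "plot")]
    plants$trait1 <- rnorm(nrow(plants))
    occurrence_table(rows, plants, log10_traits = FALSE)
  })
}

# deterministic 3-species table from the worked partition example:
# plot1: A(a=1, t=2), B(a=1, t=4); plot2: A(a=1, t=2)
worked_occ <- function() {
  community <- data.frame(
    plot = c("p1", "p1", "p2"), species = c("A", "B", "A"),
    abundance = c(1, 1, 1)
  )
  plants <- data.frame(
    species = c("A", "B", "A"), plot = c("p1", "p1", "p2"),
    trait1 = c(2, 4, 2)
  )
  occurrence_table(community, plants, log10_traits = FALSE)
}
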
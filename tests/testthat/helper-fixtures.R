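# Shared fixture builders; everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")

# Uniform substitution to a different base, for building test alignments
# independently of the package's own simulator.
mutate_seq <- function(s, rate) {
  hit <- which(runif(length(s)) < rate)
  if (length(hit)) {
    cur <- match(s[hit], BASES)
    s[hit] <- BASES[(cur - 1L + sample.int(3L, length(hit), TRUE)) %% 4L + 1L]
  }
  s
}

# Two tight sequence clusters at a given between/within divergence.
two_cluster_alignment <- function(n_per = 5, len = 500,
                                  between = 0.10, within = 0.001) {
  anc <- sample(BASES, len, replace = TRUE)
  anc2 <- mutate_seq(anc, between)
  seqs <- c(
    lapply(seq_len(n_per), function(i) mutate_seq(anc, within)),
    lapply(seq_len(n_per), function(i) mutate_seq(anc2, within)))
  names(seqs) <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  alignment_block(vapply(seqs, paste, "", collapse = ""))
}

# Random phylo tree with strictly positive branch lengths.
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.01, 0.5)
  tr
}

# Brute-force patristic distance: sum branch lengths along the path found
# by walking each leaf up to the root and joining at the deepest shared
# ancestor.  Independent of stats::cophenetic.
brute_force_patristic <- function(tree) {
  tr <- ape::reorder.phylo(tree)
  root <- ape::Ntip(tr) + 1L
  parent_of <- integer(max(tr$edge))
  len_to_parent <- numeric(max(tr$edge))
  for (k in seq_len(nrow(tr$edge))) {
    parent_of[tr$edge[k, 2]] <- tr$edge[k, 1]
    len_to_parent[tr$edge[k, 2]] <- tr$edge.length[k]
  }
  path_up <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent_of[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  n <- ape::Ntip(tr)
  d <- matrix(0, n, n, dimnames = list(tr$tip.label, tr$tip.label))
  for (i in seq_len(n - 1)) {
    pi <- path_up(i)
    for (j in (i + 1):n) {
      pj <- path_up(j)
      mrca <- intersect(pi, pj)[[1]]
      seg <- function(p) {
        idx <- seq_len(which(p == mrca) - 1L)
        sum(len_to_parent[p[idx]])
      }
      d[i, j] <- d[j, i] <- seg(pi) + seg(pj)
    }
  }
  d
}

# Gridded temperature field over a small lat/lon block, one depth.
flat_grid <- function(lats, lons, depth = 0, temp = 12) {
  g <- expand.grid(lat = lats, lon = lons)
  data.frame(lat = g$lat, lon = g$lon, depth = depth, temp = temp)
}
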
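#' Observed (p-) distance matrix of an alignment
#'
#' Proportion of differing sites per sequence pair, over retained columns
#' only, with pairwise deletion: a column contributes to a pair only when
#' both rows carry an unambiguous base (A/C/G/T); gaps and ambiguity codes
#' are excluded for that pair.
#'
#' @param align an `alignment_block`.
#' @return symmetric numeric matrix (substitutions per site) with zero
#'   diagonal, labelled by sequence id.
#' @export
p_distance_matrix <- function(align) {
  stopifnot(inherits(align, "alignment_block"))
  m <- align$matrix[, align$retained, drop = FALSE]
  if (nrow(m) < 2) stop("need at least two sequences", call. = FALSE)
  n <- nrow(m)
  code <- matrix(match(m, c("A", "C", "G", "T")), n, ncol(m))
  ok <- !is.na(code)
  # pairwise match and comparable-site counts via one-hot cross-products
  matches <- matrix(0, n, n)
  for (b in 1:4) {
    ind <- (code == b) & ok
    mode(ind) <- "numeric"
    matches <- matches + tcrossprod(ind)
  }
  mode(ok) <- "numeric"
  comparable <- tcrossprod(ok)
  off <- comparable == 0 & !diag(TRUE, n)
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1, ]
    stop("no comparable sites between ", rownames(m)[ij[[1]]], " and ",
         rownames(m)[ij[[2]]], call. = FALSE)
  }
  d <- (comparable - matches) / pmax(comparable, 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# p-distances straight from a character matrix (bootstrap internals).
.p_dist_from_matrix <- function(m) {
  p_distance_matrix(structure(list(matrix = m, retained = rep(TRUE, ncol(m)),
                                   meta = NULL), class = "alignment_block"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}); negative branch
#' lengths are clamped to zero and the total clamped deficit is recorded
#' in the `"clamped_deficit"` attribute.
#'
#' @param dm symmetric labelled distance matrix (or `dist`).
#' @return an \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  tr <- ape::nj(as.dist(dm))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Nonparametric bootstrap support for an alignment's NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree per
#' pseudo-replicate, and reports for each internal node of the original
#' tree the percentage of replicates containing its bipartition.
#'
#' @param align an `alignment_block` (>= 4 rows).
#' @param n_replicates number of pseudo-replicates (default 500).
#' @param seed integer seed; the resampling stream is fully reproducible.
#' @return the original NJ `phylo` tree with percent supports in
#'   `node.label`.
#' @export
bootstrap_support <- function(align, n_replicates = 500, seed = 1) {
  stopifnot(inherits(align, "alignment_block"))
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  m <- align$matrix[, align$retained, drop = FALSE]
  if (nrow(m) < 4) stop("need at least 4 sequences", call. = FALSE)
  build <- function(x) nj_tree(.p_dist_from_matrix(x))
  phy <- build(m)
  set.seed(seed)
  counts <- ape::boot.phylo(phy, m, build, B = n_replicates,
                            quiet = TRUE, rooted = FALSE)
  phy$node.label <- round(100 * counts / n_replicates, 1)
  phy
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths on the unique leaf-to-leaf path, for every leaf
#' pair.  Works on any leaf-labelled tree with branch lengths, e.g. an
#' externally computed maximum-likelihood tree read from newick.
#'
#' @param tree an \pkg{ape} `phylo` tree with branch lengths.
#' @return symmetric labelled numeric matrix (substitutions per site).
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  bad <- which(is.na(tree$edge.length))
  if (length(bad))
    stop("missing branch length on edge(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  as.matrix(stats::cophenetic(tree))
}

# Summary statistics of a multiset of pairwise distances.
.dist_summary <- function(vals) {
  if (!length(vals)) stop("empty distance set", call. = FALSE)
  q <- unname(quantile(vals, c(0.025, 0.975), type = 7))
  structure(list(median = median(vals), ci_low = q[[1]], ci_high = q[[2]],
                 min = min(vals), max = max(vals), n_pairs = length(vals)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("median %.3g  95%% CI [%.3g, %.3g]  min-max [%.3g, %.3g]  (n = %d pairs)\n",
              x$median, x$ci_low, x$ci_high, x$min, x$max, x$n_pairs))
  invisible(x)
}

.pair_values <- function(dm, labs1, labs2, within) {
  if (within) {
    labs1 <- intersect(labs1, rownames(dm))
    if (length(labs1) < 2) return(numeric(0))
    sub <- dm[labs1, labs1, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    labs1 <- intersect(labs1, rownames(dm))
    labs2 <- intersect(labs2, rownames(dm))
    if (!length(labs1) || !length(labs2)) return(numeric(0))
    as.vector(dm[labs1, labs2, drop = FALSE])
  }
}

#' Within- or between-group summary of pairwise distances
#'
#' Median, 95% nonparametric confidence interval (2.5th/97.5th percentiles
#' of the pooled pairwise-distance distribution, linear interpolation),
#' and extremes, computed over the eligible pair multiset: self-pairs are
#' excluded in within mode; all cross pairs are used in between mode.
#'
#' @param dm labelled symmetric distance matrix.
#' @param groups named character vector mapping labels to group names.
#' @param mode `"within"` or `"between"`.
#' @param g group name (within mode) or two group names (between mode).
#' @return a `distance_summary`.
#' @export
group_summary <- function(dm, groups, mode = c("within", "between"), g) {
  mode <- match.arg(mode)
  if (mode == "within") {
    vals <- .pair_values(dm, names(groups)[groups == g[[1]]], NULL, TRUE)
  } else {
    if (length(g) != 2) stop("between mode needs two group names", call. = FALSE)
    vals <- .pair_values(dm, names(groups)[groups == g[[1]]],
                         names(groups)[groups == g[[2]]], FALSE)
  }
  if (!length(vals))
    stop("no eligible pairs for mode ", mode, " on group(s) ",
         paste(g, collapse = " vs "), call. = FALSE)
  .dist_summary(vals)
}

#' Per-specimen intra-individual distance summaries
#'
#' Restricts the pairwise distances to clone pairs of the same specimen
#' and summarizes each multi-clone specimen separately, quantifying
#' intragenomic rDNA variation.
#'
#' @param dm labelled symmetric distance matrix over clones.
#' @param specimens named character vector mapping clone labels to
#'   specimen ids.
#' @return named list of `distance_summary`, one per specimen with >= 2
#'   clones.
#' @export
intra_individual_summary <- function(dm, specimens) {
  specs <- unique(specimens)
  out <- list()
  for (s in specs) {
    clones <- names(specimens)[specimens == s]
    vals <- .pair_values(dm, clones, NULL, TRUE)
    if (length(vals)) out[[s]] <- .dist_summary(vals)
  }
  if (!length(out))
    stop("no specimen with at least two clones", call. = FALSE)
  out
}

#' Barcode-gap delimitation of two genotype groups
#'
#' Declares the two groups delimited when the minimum between-group
#' distance exceeds the larger of the two within-group 97.5th percentiles
#' -- i.e. the between-group distances sit clearly beyond the within-group
#' distributions, the pattern expected of distinct species rather than
#' populations of one.
#'
#' @param dm labelled symmetric distance matrix.
#' @param groups named character vector mapping labels to exactly two
#'   group names; each group needs >= 2 members.
#' @return list with `delimited` (logical), `between_min`,
#'   `within_ci_max`, and `summaries` (within each group and between).
#' @export
delimit <- function(dm, groups) {
  gs <- unique(groups)
  if (length(gs) != 2) stop("delimit needs exactly two groups", call. = FALSE)
  w1 <- group_summary(dm, groups, "within", gs[[1]])
  w2 <- group_summary(dm, groups, "within", gs[[2]])
  b <- group_summary(dm, groups, "between", gs)
  within_ci_max <- max(w1$ci_high, w2$ci_high)
  list(delimited = b$min > within_ci_max,
       between_min = b$min, within_ci_max = within_ci_max,
       summaries = setNames(list(w1, w2, b),
                            c(paste0("within_", gs), "between")))
}

#' Read and write newick trees
#'
#' Thin wrappers around \pkg{ape}'s newick parser.  On input, bracketed
#' comments directly following a closing parenthesis (a common dialect for
#' bootstrap supports) are converted to internal-node labels before
#' parsing; other comments are stripped.
#'
#' @param path file path.
#' @return a `phylo` tree (reader) / `path` invisibly (writer).
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\)\\[([^]]*)\\]", ")\\1", txt)
  txt <- gsub("\\[[^]]*\\]", "", txt)
  ape::read.tree(text = txt)
}

#' @rdname read_newick
#' @param tree a `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
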
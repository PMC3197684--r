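test_that("p-distances handle identity, simple mismatch, and pairwise deletion", {
  aln <- alignment_block(c(a = "ACGT", b = "ACGT"))
  expect_equal(unname(p_distance_matrix(aln)["a", "b"]), 0)

  aln2 <- alignment_block(c(a = "ACGT", b = "ACGA"))
  expect_equal(unname(p_distance_matrix(aln2)["a", "b"]), 0.25)

  # gap and N columns dropped pairwise
  aln3 <- alignment_block(c(a = "AC-TN", b = "ACGAC"))
  expect_equal(unname(p_distance_matrix(aln3)["a", "b"]), 1 / 3)

  aln4 <- alignment_block(c(a = "NN", b = "AC"))
  expect_error(p_distance_matrix(aln4), "no comparable sites")
})

test_that("p-distance matrix agrees with a naive double-loop recount", {
  set.seed(21)
  n <- 10
  len <- 60
  chars <- c(BASES, "-", "N")
  m <- matrix(sample(chars, n * len, TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
              n, len, dimnames = list(paste0("s", 1:n), NULL))
  aln <- alignment_block(setNames(apply(m, 1, paste, collapse = ""),
                                  rownames(m)))
  d <- p_distance_matrix(aln)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% BASES & m[j, ] %in% BASES
      expect_equal(unname(d[i, j]), sum(m[i, ok] != m[j, ok]) / sum(ok))
    }
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("retained-column mask restricts the distance computation", {
  aln <- alignment_block(c(a = "AAAA", b = "TTAA"),
                         retained = c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(p_distance_matrix(aln)["a", "b"]), 1 / 3)
})

test_that("neighbor joining reproduces the three-point closed form", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["A", "C"] <- d["C", "A"] <- 0.3
  d["B", "C"] <- d["C", "B"] <- 0.4
  tr <- nj_tree(d)
  tip_edge <- function(tree, tip) {
    tree$edge.length[tree$edge[, 2] == which(tree$tip.label == tip)]
  }
  expect_equal(tip_edge(tr, "A"), 0.05)
  expect_equal(tip_edge(tr, "B"), 0.15)
  expect_equal(tip_edge(tr, "C"), 0.25)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive matrices exactly: patristic(nj(dm)) == dm", {
  set.seed(22)
  for (rep in 1:10) {
    tr <- random_tree(6)
    dm <- as.matrix(stats::cophenetic(tr))
    rec <- nj_tree(dm)
    expect_identical(attr(rec, "clamped_deficit"), 0)
    pat <- patristic_matrix(rec)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(pat - dm)), 1e-9)
    expect_true(ape::all.equal.phylo(ape::unroot(tr), rec,
                                     use.edge.length = FALSE))
  }
})

test_that("ultrametric four-taxon matrices give the balanced topology", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 1
  tr <- nj_tree(d)
  split <- ape::prop.part(tr)
  tips <- tr$tip.label
  inner <- split[[which(lengths(split) == 2)[1]]]
  expect_true(setequal(tips[inner], c("a", "b")) ||
                setequal(tips[inner], c("c", "d")))
})

test_that("patristic distances equal brute-force path sums on random trees", {
  set.seed(23)
  for (rep in 1:5) {
    tr <- random_tree(8)
    pat <- patristic_matrix(tr)
    bf <- brute_force_patristic(tr)
    expect_lt(max(abs(pat[rownames(bf), colnames(bf)] - bf)), 1e-12)
  }
})

test_that("patristic edge cases: two leaves, ultrametric height, missing lengths", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.3);")
  expect_equal(unname(patristic_matrix(tr)["a", "b"]), 0.4)

  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  pat <- patristic_matrix(bal)
  expect_equal(unname(pat["a", "c"]), 4)  # tree height 2: all cross pairs 2h

  bad <- ape::read.tree(text = "(a:0.1,b:0.3);")
  bad$edge.length[2] <- NA
  expect_error(patristic_matrix(bad), "missing branch length")
  bad$edge.length <- NULL
  expect_error(patristic_matrix(bad), "no branch lengths")
})

test_that("group summaries match direct sort-and-interpolate computation", {
  vals <- c(1, 2, 3, 4, 100)
  # five labelled points on a line so that within-group distances are vals
  labs <- paste0("x", 1:5)
  dm <- matrix(0, 5, 5, dimnames = list(labs, labs))
  # construct a matrix whose upper triangle within group g is exactly vals
  dm[upper.tri(dm)] <- c(1, 2, 3, 4, 100, 5, 6, 7, 8, 9)
  dm <- dm + t(dm)
  groups <- setNames(c("g", "g", "g", "h", "h"), labs)
  # within g: pairs (1,2),(1,3),(2,3) -> 1, 2, 3
  sg <- group_summary(dm, groups, "within", "g")
  expect_equal(sg$median, 2)
  expect_identical(sg$n_pairs, 3L)

  s <- planktotyper:::.dist_summary(vals)
  expect_equal(s$median, 3)
  expect_equal(s$ci_low, unname(quantile(vals, 0.025, type = 7)))
  expect_equal(s$ci_high, unname(quantile(vals, 0.975, type = 7)))
  expect_equal(c(s$min, s$max), c(1, 100))
  expect_true(s$min <= s$ci_low && s$ci_low <= s$median &&
                s$median <= s$ci_high && s$ci_high <= s$max)

  sconst <- planktotyper:::.dist_summary(rep(0.3, 10))
  expect_equal(unlist(sconst[c("median", "ci_low", "ci_high", "min", "max")]),
               setNames(rep(0.3, 5), c("median", "ci_low", "ci_high", "min", "max")))
})

test_that("group summaries are invariant under label permutation", {
  set.seed(24)
  n <- 12
  labs <- paste0("s", 1:n)
  dm <- matrix(0, n, n, dimnames = list(labs, labs))
  dm[upper.tri(dm)] <- runif(n * (n - 1) / 2)
  dm <- dm + t(dm)
  groups <- setNames(sample(c("I", "II"), n, TRUE), labs)
  ref <- group_summary(dm, groups, "between", c("I", "II"))
  perm <- sample(n)
  dmp <- dm[perm, perm]
  refp <- group_summary(dmp, groups, "between", c("I", "II"))
  expect_equal(refp, ref)
})

test_that("intra-individual summaries restrict to same-specimen clone pairs", {
  labs <- c("c1", "c2", "c3", "c4", "c5")
  dm <- matrix(0, 5, 5, dimnames = list(labs, labs))
  dm[upper.tri(dm)] <- c(0.1, 0.2, 0.25, 5, 5, 5, 5, 5, 5, 0.4)
  dm <- dm + t(dm)
  specs <- setNames(c("A", "A", "A", "B", "B"), labs)
  # A clones: pairs (c1,c2)=0.1, (c1,c3)=0.2, (c2,c3)=0.25; B: (c4,c5)=0.4
  out <- intra_individual_summary(dm, specs)
  expect_equal(out$A$median, 0.2)
  expect_identical(out$A$n_pairs, 3L)
  expect_equal(out$B$median, 0.4)
  expect_error(intra_individual_summary(dm, setNames(letters[1:5], labs)),
               "at least two clones")
})

test_that("barcode-gap delimitation separates structured data from null splits", {
  cfg <- sim_config(seed = 31, n_individuals_per_type = 10,
                    clones_per_individual = 2)
  seqs <- generate_sequences(cfg)
  its <- seqs[seqs$marker == "ITS", ]
  dm <- p_distance_matrix(alignment_block(its))
  groups <- setNames(its$type, its$id)
  res <- delimit(dm, groups)
  expect_true(res$delimited)
  expect_gt(res$between_min, res$within_ci_max)

  # identical sequences in both groups: no gap
  labs <- paste0("z", 1:6)
  dm0 <- matrix(0, 6, 6, dimnames = list(labs, labs))
  g0 <- setNames(rep(c("I", "II"), each = 3), labs)
  expect_false(delimit(dm0, g0)$delimited)

  expect_error(delimit(dm0, setNames(rep("I", 6), labs)), "two groups")
})

test_that("bootstrap supports are reproducible and bound to the data structure", {
  set.seed(32)
  aln <- two_cluster_alignment(n_per = 5, len = 400,
                               between = 0.10, within = 0.001)
  tr1 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  tr2 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  expect_identical(tr1$node.label, tr2$node.label)
  # the central split between the two clusters is essentially certain
  expect_gte(max(tr1$node.label, na.rm = TRUE), 98)

  tr3 <- bootstrap_support(aln, n_replicates = 1, seed = 5)
  lab <- tr3$node.label[!is.na(tr3$node.label)]  # root support is undefined
  expect_true(all(lab %in% c(0, 100)))
  expect_error(bootstrap_support(aln, n_replicates = 0), ">= 1")
})

test_that("newick trees round-trip, including comment-style supports", {
  tr <- ape::read.tree(text = "((a:1,b:2)90:0.5,c:3);")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(stats::cophenetic(back), stats::cophenetic(tr))

  writeLines("((a:1,b:2)[95]:0.5,c:3);", path)
  commented <- read_newick(path)
  expect_identical(commented$node.label[2], "95")
})
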
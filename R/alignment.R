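#' Construct an alignment block
#'
#' An alignment block is an aligned character matrix (rows = sequences,
#' columns = sites) plus a logical retained-column mask.  The mask carries
#' an externally produced block selection (e.g. the output of an
#' ambiguous-region filter); all distance and consensus operations respect
#' it.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (IUPAC codes plus `-`), or a seq_records `data.frame` whose `seq`
#'   column is aligned.
#' @param retained logical vector, one per column; defaults to all `TRUE`.
#' @return an object of class `alignment_block` with elements `matrix`
#'   (character matrix with sequence ids as rownames), `retained`, and
#'   `meta` (per-row metadata if constructed from records).
#' @export
alignment_block <- function(seqs, retained = NULL) {
  meta <- NULL
  if (is.data.frame(seqs)) {
    meta <- seqs[setdiff(names(seqs), "seq")]
    v <- setNames(seqs$seq, seqs$id)
  } else {
    v <- seqs
  }
  if (length(v) == 0) stop("empty alignment", call. = FALSE)
  if (is.null(names(v)) || anyDuplicated(names(v)))
    stop("aligned sequences must have unique names", call. = FALSE)
  v <- .normalize_bases(v)
  .check_bases(v, names(v))
  lens <- nchar(v)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must all have the same length", call. = FALSE)
  m <- do.call(rbind, strsplit(v, ""))
  rownames(m) <- names(v)
  if (is.null(retained)) retained <- rep(TRUE, ncol(m))
  if (length(retained) != ncol(m))
    stop("retained mask length must equal alignment length", call. = FALSE)
  structure(list(matrix = m, retained = as.logical(retained), meta = meta),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("alignment_block:", nrow(x$matrix), "sequences x", ncol(x$matrix),
      "columns (", sum(x$retained), "retained )\n")
  invisible(x)
}

.ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# Per-column homology statements: for each column, the vector (over
# sequences, in a fixed id order) of ungapped residue indices, NA for gaps.
# Two columns from two alignments of the same sequences are homologous iff
# these vectors are identical.
.homology_keys <- function(m, id_order) {
  m <- m[id_order, , drop = FALSE]
  idx <- matrix(NA_integer_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    nongap <- m[i, ] != "-"
    idx[i, nongap] <- seq_len(sum(nongap))
  }
  apply(idx, 2, paste, collapse = ",")
}

#' Merge two alternative alignments of the same sequences
#'
#' Builds the consensus of two alignments (e.g. a manual and an automatic
#' alignment of the same sequence set) by keeping exactly the columns of
#' `align_a` whose homology statement -- the mapping from sequence id to
#' ungapped residue index, with gap treated as absent -- also occurs in
#' `align_b`.  Columns on which the two alignments disagree are removed.
#' The retained mask of `align_a` is subset along with its columns.
#'
#' @param align_a,align_b `alignment_block`s over the same sequences.
#' @return an `alignment_block` with the concordant columns of `align_a`,
#'   in `align_a` order.
#' @export
merge_alignments <- function(align_a, align_b) {
  stopifnot(inherits(align_a, "alignment_block"),
            inherits(align_b, "alignment_block"))
  ids_a <- rownames(align_a$matrix)
  ids_b <- rownames(align_b$matrix)
  if (!setequal(ids_a, ids_b))
    stop("alignments carry different sequence sets", call. = FALSE)
  ua <- vapply(ids_a, function(i) .ungap(paste(align_a$matrix[i, ], collapse = "")), "")
  ub <- vapply(ids_a, function(i) .ungap(paste(align_b$matrix[i, ], collapse = "")), "")
  if (!identical(ua, ub))
    stop("ungapped sequences differ for id(s): ",
         paste(ids_a[ua != ub], collapse = ", "), call. = FALSE)
  keys_a <- .homology_keys(align_a$matrix, ids_a)
  keys_b <- .homology_keys(align_b$matrix, ids_a)
  keep <- keys_a %in% keys_b
  structure(list(matrix = align_a$matrix[, keep, drop = FALSE],
                 retained = align_a$retained[keep],
                 meta = align_a$meta),
            class = "alignment_block")
}

#' Majority consensus sequence of an alignment group
#'
#' Per column, the most frequent non-gap residue is reported if its
#' frequency (gaps counting toward the denominator) is at least
#' `threshold`; otherwise the column is `N`.
#'
#' @param align an `alignment_block`.
#' @param group_rows row names or indices of the group; defaults to all.
#' @param threshold consensus proportion in (0.5, 1]; default 0.6.
#' @return object of class `consensus_sequence`: list with `symbols`
#'   (character vector, one per alignment column) and `threshold`.
#' @export
consensus_sequence <- function(align, group_rows = NULL, threshold = 0.6) {
  stopifnot(inherits(align, "alignment_block"))
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  m <- align$matrix
  if (!is.null(group_rows)) m <- m[group_rows, , drop = FALSE]
  if (nrow(m) == 0) stop("empty consensus group", call. = FALSE)
  n <- nrow(m)
  symbols <- apply(m, 2, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return("N")
    tab <- sort(table(res), decreasing = TRUE)
    if (tab[[1]] / n >= threshold) names(tab)[[1]] else "N"
  })
  structure(list(symbols = unname(symbols), threshold = threshold),
            class = "consensus_sequence")
}

#' Classify the sites of a query sequence against two group consensuses
#'
#' Each eligible column (retained by `mask`, both consensuses informative,
#' query non-gap) is classified: where the two consensuses differ, a query
#' matching consensus A is a synapomorphy shared with group A, a query
#' matching consensus B a synapomorphy shared with group B; a query
#' differing from both consensuses is an autapomorphy.  Whether columns on
#' which the two consensuses agree can contribute autapomorphies is
#' controlled by `autapomorphy_when_equal` (default `TRUE`: any query
#' residue differing from both consensuses counts, the strict reading; set
#' `FALSE` to restrict autapomorphies to columns where the consensuses
#' disagree).
#'
#' @param query aligned character vector or string (the query row).
#' @param cons_a,cons_b `consensus_sequence`s of the two groups.
#' @param mask logical column mask; defaults to all columns.
#' @param autapomorphy_when_equal logical, see Description.
#' @return object of class `site_classification`: counts and column
#'   indices per class.
#' @export
classify_sites <- function(query, cons_a, cons_b, mask = NULL,
                           autapomorphy_when_equal = TRUE) {
  if (is.character(query) && length(query) == 1) query <- strsplit(query, "")[[1]]
  a <- cons_a$symbols
  b <- cons_b$symbols
  if (length(query) != length(a) || length(a) != length(b))
    stop("query and consensus lengths differ", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(query))
  if (length(mask) != length(query))
    stop("mask length differs from alignment length", call. = FALSE)
  eligible <- mask & a != "N" & b != "N" & query != "-"
  differ <- a != b
  syn_a <- which(eligible & differ & query == a)
  syn_b <- which(eligible & differ & query == b)
  if (autapomorphy_when_equal) {
    aut <- which(eligible & query != a & query != b)
  } else {
    aut <- which(eligible & differ & query != a & query != b)
  }
  structure(list(
    n_synapomorphy_with_a = length(syn_a),
    n_synapomorphy_with_b = length(syn_b),
    n_autapomorphy = length(aut),
    positions = list(with_a = syn_a, with_b = syn_b, autapomorphy = aut)
  ), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("site classification: ", x$n_synapomorphy_with_a,
      " synapomorphies with group A, ", x$n_synapomorphy_with_b,
      " with group B, ", x$n_autapomorphy, " autapomorphies\n", sep = "")
  invisible(x)
}
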
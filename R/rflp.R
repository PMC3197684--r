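#' Restriction enzymes for in-silico RFLP
#'
#' A restriction enzyme is described by its IUPAC recognition motif and the
#' cut offset (number of motif bases 5' of the cut on the top strand).
#' `bstni()` returns the BstNI enzyme, which cuts CC/WGG (W = A or T) with
#' offset 2 -- the assay used to genotype ITS rDNA amplicons: the Type I
#' amplicon carries the site and is cut into a characteristic two-band
#' pattern (about 400 and 600 bp on a ~1000 bp amplicon), while the Type
#' II amplicon is not cut.
#'
#' @param name enzyme name.
#' @param recognition IUPAC motif.
#' @param cut_offset bases from motif start to the cut, in `[0, motif length]`.
#' @return an object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- .normalize_bases(recognition)
  if (nchar(recognition) < 1) stop("empty recognition motif", call. = FALSE)
  .check_bases(recognition, name, allow_gap = FALSE)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the motif", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
bstni <- function() restriction_enzyme("BstNI", "CCWGG", 2L)

#' Find recognition sites of an enzyme in a sequence
#'
#' Scans every position (overlapping matches all reported) with IUPAC
#' expansion on both the motif and the sequence: a motif symbol matches a
#' sequence symbol when their base sets intersect.  Returns the 1-based
#' start positions of the matches; the corresponding cut coordinates
#' (number of bases 5' of the cut) are `position + cut_offset - 1`.
#'
#' @param seq ungapped IUPAC nucleotide string.
#' @param enzyme a `restriction_enzyme`.
#' @return integer vector of 1-based match start positions.
#' @export
find_sites <- function(seq, enzyme = bstni()) {
  seq <- .normalize_bases(seq)
  if (grepl("-", seq, fixed = TRUE))
    stop("gapped sequence: ungap before digestion", call. = FALSE)
  .check_bases(seq, allow_gap = FALSE)
  s <- strsplit(seq, "")[[1]]
  motif <- strsplit(enzyme$recognition, "")[[1]]
  k <- length(motif)
  n <- length(s)
  if (n < k) return(integer(0))
  hit <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    hit <- hit & .iupac_match(motif[[j]], s[seq_len(n - k + 1L) + j - 1L])
  }
  unname(which(hit))
}

#' Digest a sequence with a restriction enzyme
#'
#' Linear (PCR-product) topology: fragments are the runs between
#' consecutive cut coordinates and the sequence ends; with no site the
#' single fragment is the full amplicon.
#'
#' @inheritParams find_sites
#' @return object of class `digest_result`: list with `cut_positions`
#'   (sorted cut coordinates, bases 5' of each cut) and `fragment_lengths`
#'   (sorted decreasing; sums to the amplicon length).
#' @export
digest_sequence <- function(seq, enzyme = bstni()) {
  sites <- find_sites(seq, enzyme)
  n <- nchar(.normalize_bases(seq))
  cuts <- sort(unique(sites + enzyme$cut_offset - 1L))
  cuts <- cuts[cuts > 0L & cuts < n]
  frags <- diff(c(0L, cuts, n))
  structure(list(cut_positions = cuts,
                 fragment_lengths = sort(frags, decreasing = TRUE),
                 amplicon_length = n),
            class = "digest_result")
}

#' Call the genotype from a digest band pattern
#'
#' Lenient rule (default): two or more fragments call Type I, a single
#' uncut fragment spanning the amplicon calls Type II.  The strict rule
#' additionally requires the two largest fragments to fall within
#' `tolerance_bp` of the canonical 400/600 bp bands, else the call is
#' ambiguous.  A third band from ITS length polymorphism is tolerated in
#' both modes.
#'
#' @param digest a `digest_result`.
#' @param amplicon_length expected amplicon length; defaults to the
#'   digested length.
#' @param strict logical; use the band-size rule.
#' @param expected_bands canonical fragment sizes for the cut genotype.
#' @param tolerance_bp band-size tolerance in strict mode.
#' @return object of class `genotype_call`: list with `call` (`"TypeI"`,
#'   `"TypeII"` or `"ambiguous"`), `method` (`"RFLP"`) and `evidence`
#'   (band count).
#' @export
call_genotype <- function(digest, amplicon_length = digest$amplicon_length,
                          strict = FALSE, expected_bands = c(400, 600),
                          tolerance_bp = 50) {
  if (!length(digest$fragment_lengths)) stop("empty digest", call. = FALSE)
  nfrag <- length(digest$fragment_lengths)
  call <- if (nfrag >= 2L) {
    "TypeI"
  } else if (digest$fragment_lengths[[1]] == amplicon_length) {
    "TypeII"
  } else {
    "ambiguous"
  }
  if (strict && call == "TypeI") {
    two <- sort(digest$fragment_lengths, decreasing = TRUE)[1:2]
    ok <- all(abs(sort(two) - sort(expected_bands)) <= tolerance_bp)
    if (!ok) call <- "ambiguous"
  }
  structure(list(call = call, method = "RFLP", evidence = nfrag),
            class = "genotype_call")
}

#' Co-migrating gel bands from a digest
#'
#' Models agarose visualization: fragments closer than the gel resolution
#' co-migrate into one band.  Fragments are sorted and chained into bands
#' whenever consecutive lengths differ by at most `resolution_bp`; with
#' resolution 0 every distinct length is its own band.
#'
#' @param digest a `digest_result`.
#' @param resolution_bp gel resolution in base pairs (>= 0).
#' @return `data.frame` with `length` (mean fragment length of the band)
#'   and `weight` (number of co-migrating fragments).
#' @export
gel_bands <- function(digest, resolution_bp) {
  if (resolution_bp < 0) stop("resolution_bp must be >= 0", call. = FALSE)
  f <- sort(digest$fragment_lengths)
  grp <- cumsum(c(1L, as.integer(diff(f) > resolution_bp)))
  data.frame(
    length = as.numeric(tapply(f, grp, mean)),
    weight = as.integer(tapply(f, grp, length)),
    row.names = NULL
  )
}

#' RFLP-genotype a set of sequence records
#'
#' Digests each (ungapped) sequence and calls its genotype; one row per
#' record, suitable for CSV export.
#'
#' @param records seq_records `data.frame`.
#' @param enzyme a `restriction_enzyme`.
#' @param strict logical; passed to [call_genotype()].
#' @return `data.frame` with id, call, band count, and fragment lengths
#'   (semicolon-separated).
#' @export
rflp_genotype <- function(records, enzyme = bstni(), strict = FALSE) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    d <- digest_sequence(.ungap(records$seq[[i]]), enzyme)
    g <- call_genotype(d, strict = strict)
    data.frame(id = records$id[[i]], call = g$call, n_bands = g$evidence,
               fragments = paste(d$fragment_lengths, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
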
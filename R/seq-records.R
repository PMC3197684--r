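#' @name seq_records
#' @title Sequence records
#'
#' @description
#' Cloned rDNA sequences are carried as a plain `data.frame` with one row
#' per clone and columns `id`, `specimen`, `station`, `marker` (`"SSU"` or
#' `"ITS"`), `type` (genotype label, possibly `NA`) and `seq` (uppercase
#' IUPAC nucleotide string; `-` allowed only inside alignments).
#' Provenance travels in the FASTA description line as space-separated
#' `key=value` pairs, e.g.
#' `>cloneA specimen=Oi375 station=S01 marker=ITS type=I`.
NULL

# IUPAC nucleotide codes as ACGT bitmasks (A=1, C=2, G=4, T=8).
.iupac_masks <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.valid_chars <- c(names(.iupac_masks), "-")

.normalize_bases <- function(x) chartr("U", "T", toupper(x))

.check_bases <- function(x, ids = NULL, allow_gap = TRUE) {
  ok <- .valid_chars
  if (!allow_gap) ok <- setdiff(ok, "-")
  for (i in seq_along(x)) {
    chars <- unique(strsplit(x[[i]], "")[[1]])
    bad <- setdiff(chars, ok)
    if (length(bad)) {
      who <- if (is.null(ids)) paste0("sequence ", i) else ids[[i]]
      stop("invalid nucleotide code(s) ", paste(sQuote(bad), collapse = ", "),
           " in ", who, call. = FALSE)
    }
  }
  invisible(x)
}

.parse_description <- function(desc) {
  fields <- strsplit(trimws(desc), "\\s+")[[1]]
  id <- fields[[1]]
  kv <- fields[-1]
  out <- list(id = id, specimen = NA_character_, station = NA_character_,
              marker = NA_character_, type = NA_character_)
  for (f in kv) {
    parts <- strsplit(f, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[[1]] %in% names(out)) {
      out[[parts[[1]]]] <- parts[[2]]
    }
  }
  out
}

.format_description <- function(rec) {
  kv <- character(0)
  for (key in c("specimen", "station", "marker", "type")) {
    val <- rec[[key]]
    if (!is.na(val) && nzchar(val)) kv <- c(kv, paste0(key, "=", val))
  }
  paste(c(rec[["id"]], kv), collapse = " ")
}

#' Read sequence records from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T` on input.  Description
#' metadata (`specimen=`, `station=`, `marker=`, `type=`) is parsed into
#' columns.  Non-IUPAC characters raise an error naming the record.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` of sequence records (see [seq_records]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(empty_seq_records())
  descs <- names(set)
  seqs <- .normalize_bases(as.character(set))
  meta <- lapply(descs, .parse_description)
  out <- data.frame(
    id       = vapply(meta, `[[`, "", "id"),
    specimen = vapply(meta, `[[`, "", "specimen"),
    station  = vapply(meta, `[[`, "", "station"),
    marker   = vapply(meta, `[[`, "", "marker"),
    type     = vapply(meta, `[[`, "", "type"),
    seq      = unname(seqs),
    stringsAsFactors = FALSE
  )
  .check_bases(out$seq, out$id)
  out
}

#' @rdname read_fasta
#' @param records a seq_records `data.frame`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  .check_bases(records$seq, records$id)
  lines <- character(2L * nrow(records))
  for (i in seq_len(nrow(records))) {
    lines[2L * i - 1L] <- paste0(">", .format_description(records[i, ]))
    lines[2L * i] <- records$seq[[i]]
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
empty_seq_records <- function() {
  data.frame(id = character(0), specimen = character(0),
             station = character(0), marker = character(0),
             type = character(0), seq = character(0),
             stringsAsFactors = FALSE)
}

# Does IUPAC symbol a intersect IUPAC symbol b?  Gap never matches.
.iupac_match <- function(a, b) {
  ma <- .iupac_masks[a]
  mb <- .iupac_masks[b]
  !is.na(ma) & !is.na(mb) & bitwAnd(ma, mb) > 0L
}
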
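#' Rare-genotype detection probability
#'
#' Under binomial sampling, the probability of not collecting a single
#' representative of a genotype of relative abundance `p` among `N`
#' sampled individuals is `q = (1 - p)^N`.  These are the quantities used
#' to justify treating an un-genotyped population sampled on one side of a
#' hydrographic front as a single-genotype population.
#'
#' @param p relative abundance of the rare genotype, in `[0, 1]`.
#' @param N number of collected individuals (>= 1).
#' @return `q`, the probability of missing the rare genotype entirely.
#' @export
miss_probability <- function(p, N) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  (1 - p)^N
}

#' Largest undetectable rare-genotype abundance
#'
#' The largest relative abundance `p_max` a rare genotype could have and
#' still, with probability `1 - confidence`, leave no representative among
#' `N` sampled individuals: `p_max = 1 - (1 - confidence)^(1/N)`.  It
#' inverts [miss_probability()]: `miss_probability(p_max, N) = 1 -
#' confidence`.
#'
#' @param N number of collected individuals (>= 1).
#' @param confidence confidence level in (0, 1); default 0.95.
#' @return `p_max`, the detection bound on the rare genotype's abundance.
#' @export
undetected_fraction <- function(N, confidence = 0.95) {
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  if (any(confidence <= 0 | confidence >= 1))
    stop("confidence must lie in (0, 1)", call. = FALSE)
  1 - (1 - confidence)^(1 / N)
}

#' Sampling-sufficiency report per station and pooled by side
#'
#' For each station (and for the pooled north/south sides of the front)
#' reports the number of genotyped individuals, the observed genotype, and
#' the detection bound `p_max` from [undetected_fraction()].  The row with
#' the largest `p_max` (the weakest-sampled unit) is flagged.
#'
#' @param stations `data.frame` with columns `station`, `side`
#'   (`"north"`/`"south"`), `n_type1`, `n_type2` (genotyped counts).
#' @param confidence confidence level; default 0.95.
#' @return `data.frame` with one row per station plus one per pooled side:
#'   `unit`, `side`, `N`, `observed_genotype`, `p_max`, `worst` (logical).
#' @export
station_report <- function(stations, confidence = 0.95) {
  need <- c("station", "side", "n_type1", "n_type2")
  stopifnot(all(need %in% names(stations)))
  obs_label <- function(n1, n2) {
    if (n1 > 0 && n2 > 0) "mixed" else if (n1 > 0) "TypeI"
    else if (n2 > 0) "TypeII" else "none"
  }
  rows <- list()
  for (i in seq_len(nrow(stations))) {
    N <- stations$n_type1[[i]] + stations$n_type2[[i]]
    if (N == 0) {
      warning("station ", stations$station[[i]],
              " has no genotyped individuals; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      unit = as.character(stations$station[[i]]),
      side = stations$side[[i]], N = N,
      observed_genotype = obs_label(stations$n_type1[[i]], stations$n_type2[[i]]),
      p_max = undetected_fraction(N, confidence),
      stringsAsFactors = FALSE)
  }
  for (s in unique(stations$side)) {
    sub <- stations[stations$side == s, ]
    N <- sum(sub$n_type1 + sub$n_type2)
    if (N == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      unit = paste0("pooled_", s), side = s, N = N,
      observed_genotype = obs_label(sum(sub$n_type1), sum(sub$n_type2)),
      p_max = undetected_fraction(N, confidence),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$worst <- out$p_max == max(out$p_max)
  out
}
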
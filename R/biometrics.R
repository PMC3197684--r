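#' Morphometric descriptors of a shell
#'
#' From the three measured lengths -- specimen major axis in edge view,
#' terminal-chamber major axis, and aperture major axis -- computes
#' `log_size = log(major_axis)`, the size-normalized apertural length
#' `log_ratio_apc = log(aperture / chamber)`, and their contrast
#' `log_ratio_combined = log_ratio_apc - log_size` (the log-ratio between
#' the aperture/chamber ratio and the specimen major axis).  Natural
#' logarithms.
#'
#' @param specimens `data.frame` with positive columns `major_axis`,
#'   `chamber_axis`, `aperture_axis` (any consistent length unit).
#' @return the input with the three descriptor columns appended.
#' @export
morpho_descriptors <- function(specimens) {
  need <- c("major_axis", "chamber_axis", "aperture_axis")
  stopifnot(all(need %in% names(specimens)))
  if (any(as.matrix(specimens[need]) <= 0))
    stop("all shell measurements must be strictly positive", call. = FALSE)
  specimens$log_size <- log(specimens$major_axis)
  specimens$log_ratio_apc <- log(specimens$aperture_axis / specimens$chamber_axis)
  specimens$log_ratio_combined <- specimens$log_ratio_apc - specimens$log_size
  specimens
}

#' Two-group linear discriminant analysis
#'
#' Fisher linear discriminant on a feature matrix (by default the pair
#' log shell size, log aperture/chamber ratio) between two groups, with
#' Wilks' lambda = det(W)/det(T) (within- over total-scatter
#' determinants), the corresponding F statistic
#' `F = ((1 - lambda)/lambda) * (N - p - 1)/p` on `(p, N - p - 1)` degrees
#' of freedom, the resubstitution classification rate at the midpoint cut
#' of the group mean discriminant scores, and a leave-one-out
#' cross-validated rate.
#'
#' @param features numeric matrix or data.frame, specimens x p variables.
#' @param groups factor or character vector with exactly two levels.
#' @return list of class `discrimination_result`: `wilks_lambda`,
#'   `f_stat`, `df` (length 2), `p_value`, `weights`,
#'   `classification_rate` (percent, resubstitution),
#'   `classification_rate_cv` (percent, leave-one-out), `confusion`
#'   (2 x 2 counts).
#' @export
two_group_lda <- function(features, groups) {
  x <- as.matrix(features)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(g) < 3)) stop("need >= 3 specimens per group", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  lev <- levels(g)
  x1 <- x[g == lev[[1]], , drop = FALSE]
  x2 <- x[g == lev[[2]], , drop = FALSE]
  sscp <- function(m) {
    c0 <- sweep(m, 2, colMeans(m))
    crossprod(c0)
  }
  w <- sscp(x1) + sscp(x2)
  tot <- sscp(x)
  if (abs(det(w)) < .Machine$double.eps * n)
    stop("singular within-group covariance; jitter or drop a variable",
         call. = FALSE)
  lambda <- det(w) / det(tot)
  df <- c(p, n - p - 1)
  f_stat <- ((1 - lambda) / lambda) * df[[2]] / df[[1]]
  p_value <- pf(f_stat, df[[1]], df[[2]], lower.tail = FALSE)

  fisher_rule <- function(a, b) {
    sw <- (sscp(a) + sscp(b)) / (nrow(a) + nrow(b) - 2)
    wt <- solve(sw, colMeans(a) - colMeans(b))
    cut <- sum(wt * (colMeans(a) + colMeans(b)) / 2)
    list(weights = wt, cut = cut)
  }
  rule <- fisher_rule(x1, x2)
  classify <- function(m, r) ifelse(as.vector(m %*% r$weights) > r$cut,
                                    lev[[1]], lev[[2]])
  pred <- classify(x, rule)
  confusion <- table(observed = g, predicted = factor(pred, levels = lev))
  rate <- 100 * mean(pred == g)

  cv_hits <- logical(n)
  for (i in seq_len(n)) {
    gi <- g[-i]
    ri <- fisher_rule(x[-i, , drop = FALSE][gi == lev[[1]], , drop = FALSE],
                      x[-i, , drop = FALSE][gi == lev[[2]], , drop = FALSE])
    cv_hits[[i]] <- classify(x[i, , drop = FALSE], ri) == g[[i]]
  }

  structure(list(wilks_lambda = lambda, f_stat = f_stat, df = df,
                 p_value = p_value, weights = rule$weights,
                 classification_rate = rate,
                 classification_rate_cv = 100 * mean(cv_hits),
                 confusion = confusion),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.3f; F = %.2f; df = %d, %d; p = %.3g\n",
              x$wilks_lambda, x$f_stat, x$df[[1]], x$df[[2]], x$p_value))
  cat(sprintf("classification: %.1f%% (resubstitution), %.1f%% (LOO CV)\n",
              x$classification_rate, x$classification_rate_cv))
  invisible(x)
}

#' Nonparametric two-group distribution tests
#'
#' Mann-Whitney U (equal-median null) and two-sample Kolmogorov-Smirnov D
#' (same-distribution null) on a univariate descriptor.  U is reported
#' direction-free as `min(U, n1*n2 - U)`; its p-value uses exact
#' enumeration for small groups (both below 20) and the normal
#' approximation otherwise.  D uses the asymptotic Kolmogorov
#' distribution.
#'
#' @param values numeric descriptor per specimen.
#' @param groups two-level factor or character vector.
#' @return list of two elements, `mann_whitney` and `kolmogorov_smirnov`,
#'   each with `statistic`, `p_value` and `test`.
#' @export
rank_tests <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  v1 <- values[g == levels(g)[[1]]]
  v2 <- values[g == levels(g)[[2]]]
  if (!length(v1) || !length(v2)) stop("empty group", call. = FALSE)
  exact <- length(v1) < 20 && length(v2) < 20
  mw <- suppressWarnings(wilcox.test(v1, v2, exact = exact, correct = !exact))
  u <- min(unname(mw$statistic), length(v1) * length(v2) - unname(mw$statistic))
  ks <- suppressWarnings(ks.test(v1, v2, exact = FALSE))
  list(
    mann_whitney = list(statistic = u, p_value = mw$p.value,
                        test = "mann_whitney"),
    kolmogorov_smirnov = list(statistic = unname(ks$statistic),
                              p_value = ks$p.value,
                              test = "kolmogorov_smirnov")
  )
}

#' Gaussian kernel density of a descriptor
#'
#' Gaussian-kernel density estimate on a regular grid padded three
#' bandwidths beyond the data range; the returned curve integrates to 1.
#'
#' @param values numeric vector (>= 2 values).
#' @param bandwidth kernel standard deviation; `NULL` uses Silverman's
#'   rule of thumb.
#' @param n_grid number of grid points.
#' @return `data.frame` with columns `x` and `density`.
#' @export
kernel_density <- function(values, bandwidth = NULL, n_grid = 512) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (!is.null(bandwidth) && bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  d <- if (is.null(bandwidth)) {
    density(values, kernel = "gaussian", n = n_grid, cut = 3)
  } else {
    density(values, bw = bandwidth, kernel = "gaussian", n = n_grid, cut = 3)
  }
  data.frame(x = d$x, density = d$y)
}
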
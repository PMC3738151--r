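# Replicate concordance, dynamic-range summaries, and the rank test
# comparing disputed-target z-scores to randomly sampled probes.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (midranks for ties), via
#' `stats::cor`. Input validation enforces the preconditions that make
#' the coefficient meaningful for replicate tracks.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input has no rank correlation", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Fraction of probes below a z threshold
#'
#' Summarises dynamic range as the fraction of probes with z-scores
#' strictly below `threshold` — a dataset effective only at strong
#' interactions keeps nearly all probes under the noise boundary.
#'
#' @param z A `z_track`.
#' @param threshold z threshold (default 3).
#' @return List with `frac_below_threshold`, `threshold`, `n_probes`.
#' @export
dynamic_range_summary <- function(z, threshold = 3) {
  stopifnot(inherits(z, "z_track"), length(z$zscores) > 0L)
  list(frac_below_threshold = mean(z$zscores < threshold),
       threshold = threshold, n_probes = length(z$zscores))
}

#' Mann-Whitney U test
#'
#' The U statistic for sample `a` is computed from midranks. For tie-free
#' data with `n_a + n_b <= exact_limit` the p-value is exact, by
#' enumeration of all `choose(n_a + n_b, n_a)` labelings; otherwise a
#' normal approximation with tie and continuity corrections is used.
#'
#' @param a,b Numeric samples (nonempty).
#' @param alternative `"greater"` (a tends larger), `"less"`, or
#'   `"two_sided"`.
#' @param exact_limit Largest `n_a + n_b` for the exact branch
#'   (default 14, i.e. at most 3,432 labelings).
#' @return Object of class `mwu_result`: list with `U`, `n_a`, `n_b`,
#'   `p_value`, `method` (`"exact"` or `"normal_approximation"`),
#'   `alternative`, `seed` (`NA` unless set by a sampling wrapper).
#' @export
mwu_test <- function(a, b, alternative = c("greater", "less", "two_sided"),
                     exact_limit = 14L) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("NA values in samples", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  comb <- c(a, b)
  r <- rank(comb) # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(comb) > 0L
  if (N <= exact_limit && !ties) {
    sets <- utils::combn(N, na)
    u_all <- colSums(matrix(seq_len(N)[sets], nrow = na)) - na * (na + 1) / 2
    pg <- mean(u_all >= U - 1e-9)
    pl <- mean(u_all <= U + 1e-9)
    p <- switch(alternative, greater = pg, less = pl,
                two_sided = min(1, 2 * min(pg, pl)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tt <- table(comb)
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    sig2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) {
      # all observations identical: no rank information
      p <- 1
    } else {
      s <- sqrt(sig2)
      p <- switch(alternative,
        greater = stats::pnorm((U - mu - 0.5) / s, lower.tail = FALSE),
        less = stats::pnorm((U - mu + 0.5) / s),
        two_sided = min(1, 2 * stats::pnorm(max(0, abs(U - mu) - 0.5) / s,
                                            lower.tail = FALSE)))
    }
    method <- "normal_approximation"
  }
  structure(list(U = U, n_a = na, n_b = nb, p_value = p, method = method,
                 alternative = alternative, seed = NA_integer_),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("<mwu_result> U = %g (n_a = %d, n_b = %d): p = %.4g (%s, %s)\n",
              x$U, x$n_a, x$n_b, x$p_value, x$alternative, x$method))
  invisible(x)
}

#' Compare disputed-target z-scores with randomly selected probes
#'
#' Sample A is the z-score at the nearest probe to each disputed-target
#' coordinate (the probe grids of the two studies differ); sample B is
#' the z-scores of `n_random` probes drawn uniformly without replacement
#' under the given seed. A one-sided Mann-Whitney U test asks whether
#' the disputed targets score higher than random probes — the signature
#' of genuine but sub-threshold binding.
#'
#' @param z A `z_track`.
#' @param dst_positions Integer positions (bp), or a `coordinate_table`
#'   with a `position` column.
#' @param n_random Number of random probes (default 1000).
#' @param seed Integer seed for the random draw (mandatory:
#'   reproducibility is part of the result).
#' @return An `mwu_result` with the seed and `n_random` recorded.
#' @export
dst_vs_random_test <- function(z, dst_positions, n_random = 1000L, seed) {
  stopifnot(inherits(z, "z_track"))
  if (is.data.frame(dst_positions)) dst_positions <- dst_positions$position
  dst_positions <- as.integer(dst_positions)
  if (length(dst_positions) == 0L) stop("no disputed-target positions", call. = FALSE)
  n <- length(z$zscores)
  if (n_random >= n) stop("n_random must be below the probe count", call. = FALSE)
  a <- vapply(dst_positions, function(p) nearest_probe(z, p)$z, 0)
  idx <- with_seed(seed, sample.int(n, n_random, replace = FALSE))
  res <- mwu_test(a, z$zscores[idx], alternative = "greater")
  res$seed <- as.integer(seed)
  res$n_random <- as.integer(n_random)
  res
}

#' Replicate concordance report
#'
#' Spearman correlation of paired z-scores of two replicates on an
#' identical probe grid, plus the dynamic-range fraction (computed on
#' `z1`).
#'
#' @param z1,z2 `z_track`s on identical probe grids.
#' @param threshold z threshold for the dynamic-range fraction.
#' @return Object of class `concordance_report`: list with
#'   `spearman_rho`, `n_probes`, `frac_below_threshold`, `threshold`.
#' @export
replicate_concordance <- function(z1, z2, threshold = 3) {
  stopifnot(inherits(z1, "z_track"), inherits(z2, "z_track"))
  if (!identical(z1$track$start, z2$track$start) ||
      !identical(z1$track$end, z2$track$end)) {
    stop("probe grids differ; intersect tracks by position before comparing replicates",
         call. = FALSE)
  }
  structure(
    list(spearman_rho = spearman(z1$zscores, z2$zscores),
         n_probes = length(z1$zscores),
         frac_below_threshold = mean(z1$zscores < threshold),
         threshold = threshold),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> rho = %.3f over %d probes; %.1f%% below z = %g\n",
              x$spearman_rho, x$n_probes, 100 * x$frac_below_threshold, x$threshold))
  invisible(x)
}
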
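# Target calling, cross-study arbitration, genomic-context classification
# and positional enrichment testing.

#' Call target regions from a z-track
#'
#' Probes with `z >= threshold` are grouped into regions whenever
#' successive above-threshold probe midpoints lie within
#' `merge_distance`; each region contributes exactly one target whose
#' peak is its maximum-z probe, so high-scoring probes adjacent to an
#' even higher-scoring probe are suppressed. The leftmost probe wins z
#' ties.
#'
#' @param z A `z_track` (see [compute_zscores()]).
#' @param threshold Calling threshold in z units (default 3, the
#'   conventional noise boundary for these data).
#' @param merge_distance Maximum midpoint gap (bp) joining successive
#'   above-threshold probes into one region (default 500, the sonication
#'   fragment scale).
#' @param name_prefix Prefix for generated target names.
#' @return Data frame of class `target_table` with columns
#'   `sequence_id`, `name`, `region_start`, `region_end`,
#'   `peak_position`, `peak_z`, `context` (filled by
#'   [classify_targets()], `"unclassified"` here). Empty (zero-row) when
#'   no probe passes the threshold.
#' @export
call_targets <- function(z, threshold = 3, merge_distance = 500L,
                         name_prefix = "target") {
  stopifnot(inherits(z, "z_track"))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (merge_distance < 0) stop("merge_distance must be >= 0", call. = FALSE)
  if (length(z$zscores) == 0L) stop("empty track", call. = FALSE)
  mids <- probe_midpoints(z$track)
  idx <- which(z$zscores >= threshold)
  empty <- data.frame(sequence_id = character(), name = character(),
                      region_start = integer(), region_end = integer(),
                      peak_position = integer(), peak_z = numeric(),
                      context = character(), stringsAsFactors = FALSE)
  class(empty) <- c("target_table", "data.frame")
  if (length(idx) == 0L) return(empty)
  gap_new <- c(TRUE, diff(mids[idx]) > merge_distance)
  grp <- cumsum(gap_new)
  rows <- lapply(split(idx, grp), function(g) {
    peak <- g[which.max(z$zscores[g])] # which.max: leftmost tie wins
    data.frame(sequence_id = z$track$sequence_id,
               name = NA_character_,
               region_start = z$track$start[g[1L]],
               region_end = z$track$end[g[length(g)]],
               peak_position = mids[peak],
               peak_z = z$zscores[peak],
               context = "unclassified",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_position), , drop = FALSE]
  out$name <- sprintf("%s_%03d", name_prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("target_table", "data.frame")
  out
}

#' Nearest probe to a genomic coordinate
#'
#' Used to map target coordinates between studies whose microarray probe
#' grids differ: the probe whose midpoint minimises the distance to
#' `position` is chosen, the leftmost winning exact ties.
#'
#' @param z A `z_track`.
#' @param position Genomic coordinate (bp).
#' @return List with `index`, `z` (the probe's z-score) and `distance`
#'   (bp).
#' @export
nearest_probe <- function(z, position) {
  stopifnot(inherits(z, "z_track"), length(z$zscores) > 0L)
  mids <- probe_midpoints(z$track)
  d <- abs(mids - as.numeric(position))
  i <- which.min(d) # leftmost minimum
  list(index = i, z = z$zscores[i], distance = as.integer(d[i]))
}

#' Match targets between two studies; derive disputed targets
#'
#' Each non-excluded study-A target is matched to the nearest study-B
#' target when the peak-to-peak distance is at most `tolerance`; several
#' A targets may match the same B target. Unmatched A targets are the
#' disputed set. Targets named in `exclude` (e.g. peaks in repetitive
#' sequence, where array signal cannot be attributed to a single locus)
#' are removed before the analysis and reported separately.
#'
#' @param targets_a,targets_b `target_table` data frames.
#' @param tolerance Maximum peak-to-peak distance (bp) to call a match
#'   (default 500).
#' @param exclude Character vector of A-target names to set aside.
#' @return Object of class `study_comparison`: list with `matched`
#'   (data frame `name_a`, `name_b`, `distance`), `disputed`
#'   (`target_table` subset of A), `excluded` (names), `tolerance`.
#' @export
compare_studies <- function(targets_a, targets_b, tolerance = 500L,
                            exclude = character()) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (anyDuplicated(targets_a$name) || anyDuplicated(targets_b$name)) {
    stop("duplicate target names", call. = FALSE)
  }
  keep <- !(targets_a$name %in% exclude)
  a <- targets_a[keep, , drop = FALSE]
  if (nrow(a) == 0L || nrow(targets_b) == 0L) {
    matched <- data.frame(name_a = character(), name_b = character(),
                          distance = integer(), stringsAsFactors = FALSE)
    disputed <- a
  } else {
    d <- abs(outer(a$peak_position, targets_b$peak_position, "-"))
    j <- apply(d, 1L, which.min)
    dist <- d[cbind(seq_len(nrow(a)), j)]
    hit <- dist <= tolerance
    matched <- data.frame(name_a = a$name[hit], name_b = targets_b$name[j[hit]],
                          distance = as.integer(dist[hit]), stringsAsFactors = FALSE)
    disputed <- a[!hit, , drop = FALSE]
  }
  rownames(disputed) <- NULL
  structure(list(matched = matched, disputed = disputed,
                 excluded = intersect(targets_a$name, exclude),
                 tolerance = as.integer(tolerance)),
            class = "study_comparison")
}

#' @export
print.study_comparison <- function(x, ...) {
  cat(sprintf("<study_comparison> %d matched, %d disputed, %d excluded (tolerance %d bp)\n",
              nrow(x$matched), nrow(x$disputed), length(x$excluded), x$tolerance))
  invisible(x)
}

#' Classify a genomic position by gene context
#'
#' A position is `genic` when inside any annotated gene interval (strand
#' ignored), otherwise `intergenic`. Intergenic positions are refined to
#' `intergenic_convergent` when the nearest flanking gene on the left
#' lies on the `+` strand and the nearest on the right on the `-` strand,
#' i.e. both 3' ends face the gap. Gaps at the sequence ends are plain
#' `intergenic`.
#'
#' @param ann A [gene_annotation()].
#' @param position Coordinate in `[0, genome_length)`.
#' @return One of `"genic"`, `"intergenic"`, `"intergenic_convergent"`.
#' @export
classify_position <- function(ann, position) {
  stopifnot(inherits(ann, "gene_annotation"))
  position <- as.integer(position)
  if (position < 0L || position >= ann$genome_length) {
    stop("position outside [0, genome_length)", call. = FALSE)
  }
  g <- ann$genes
  if (nrow(g) == 0L) return("intergenic")
  inside <- g$start <= position & position < g$end
  if (any(inside)) return("genic")
  left <- which(g$end <= position)
  right <- which(g$start > position)
  if (length(left) && length(right)) {
    lg <- left[which.max(g$end[left])]
    rg <- right[which.min(g$start[right])]
    if (g$strand[lg] == "+" && g$strand[rg] == "-") return("intergenic_convergent")
  }
  "intergenic"
}

#' Classify every target in a table
#'
#' Context is assigned from the peak probe midpoint only.
#'
#' @param targets A `target_table`.
#' @param ann A [gene_annotation()].
#' @return The table with its `context` column filled.
#' @export
classify_targets <- function(targets, ann) {
  if (nrow(targets)) {
    targets$context <- vapply(targets$peak_position, function(p)
      classify_position(ann, p), "")
  }
  targets
}

#' Genic fraction of a genome
#'
#' Length of the strand-ignored union of all gene intervals divided by
#' the genome length.
#'
#' @param ann A [gene_annotation()].
#' @return Fraction in `[0, 1]`.
#' @export
genic_fraction <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"), ann$genome_length > 0L)
  if (nrow(ann$genes) == 0L) return(0)
  ir <- IRanges::IRanges(start = ann$genes$start + 1L, end = ann$genes$end)
  sum(IRanges::width(IRanges::reduce(ir))) / ann$genome_length
}

#' Binomial test for positional enrichment
#'
#' Probability of observing at least `k` of `n` targets in a position
#' class of null probability `p0` when target placement is unbiased with
#' respect to genes. The upper tail
#' \deqn{p = \sum_{j=k}^{n} \binom{n}{j} p_0^j (1-p_0)^{n-j}}
#' is summed directly in log space. The one-sided upper tail is the
#' default because the claim being tested is enrichment; a two-sided
#' variant (summing all outcomes no more probable than `k`) is available.
#'
#' @param k Observed successes (e.g. intergenic disputed targets).
#' @param n Trials (e.g. total disputed targets).
#' @param p0 Null success probability (e.g. the intergenic genome
#'   fraction).
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return Object of class `binomial_result`: list with `k`, `n`, `p0`,
#'   `p_value`, `expected` (`n * p0`), `alternative`.
#' @export
positional_enrichment_test <- function(k, n, p0, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  k <- as.integer(k); n <- as.integer(n)
  if (is.na(k) || is.na(n) || k < 0L || n < 0L || k > n) {
    stop("need 0 <= k <= n", call. = FALSE)
  }
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("need 0 < p0 < 1", call. = FALSE)
  if (alternative == "greater") {
    j <- k:n
    lt <- lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
    p <- min(1, exp(logsumexp(lt)))
  } else {
    # all outcomes with probability <= that of k (standard two-sided rule)
    dk <- stats::dbinom(k, n, p0)
    d <- stats::dbinom(0:n, n, p0)
    p <- min(1, sum(d[d <= dk * (1 + 1e-7)]))
  }
  structure(list(k = k, n = n, p0 = p0, p_value = p, expected = n * p0,
                 alternative = alternative),
            class = "binomial_result")
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf("<binomial_result> k = %d of n = %d (expected %.2f at p0 = %.3g): p = %.4g (%s)\n",
              x$k, x$n, x$expected, x$p0, x$p_value, x$alternative))
  invisible(x)
}

#' Count disputed targets among the weakest-ranked targets
#'
#' Sorts targets by ascending peak z-score (ties broken by position) and
#' counts how many of the lowest `bottom_count` are in the disputed set —
#' the pattern expected when one study's calls are limited by
#' sensitivity: the targets it misses are the weakest in the other.
#'
#' @param targets A `target_table`.
#' @param disputed_names Character vector of disputed-target names.
#' @param bottom_count Number of lowest-ranked targets to inspect.
#' @return List with `disputed_in_bottom`, `bottom_count`.
#' @export
rank_analysis <- function(targets, disputed_names, bottom_count) {
  bottom_count <- as.integer(bottom_count)
  if (bottom_count > nrow(targets)) {
    stop("bottom_count exceeds the number of targets", call. = FALSE)
  }
  unknown <- setdiff(disputed_names, targets$name)
  if (length(unknown)) {
    warning("ignoring unknown disputed names: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    disputed_names <- setdiff(disputed_names, unknown)
  }
  o <- order(targets$peak_z, targets$peak_position)
  bottom <- targets$name[o][seq_len(bottom_count)]
  list(disputed_in_bottom = sum(bottom %in% disputed_names),
       bottom_count = bottom_count)
}
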
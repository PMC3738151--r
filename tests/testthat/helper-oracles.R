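# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the code paths they check.

# O(n^2) reference peak caller: cluster above-threshold probes by
# transitive closure of "midpoints within merge_distance", then take the
# leftmost argmax of each cluster.
oracle_call_targets <- function(mids, z, threshold, merge_distance) {
  idx <- which(z >= threshold)
  if (length(idx) == 0L) {
    return(data.frame(peak_position = integer(), peak_z = numeric()))
  }
  cl <- seq_along(idx)
  repeat {
    changed <- FALSE
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (abs(mids[idx[i]] - mids[idx[j]]) <= merge_distance && cl[i] != cl[j]) {
        cl[cl == max(cl[i], cl[j])] <- min(cl[i], cl[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # transitive closure above links any pair within merge_distance; the
  # caller's rule links only successive probes -- identical on sorted
  # midpoints because betweenness makes the chain equivalent.
  peaks <- lapply(split(idx, cl), function(g) {
    zi <- z[g]
    p <- g[which(zi == max(zi))][1L]
    data.frame(peak_position = mids[p], peak_z = z[p])
  })
  out <- do.call(rbind, peaks)
  out[order(out$peak_position), , drop = FALSE]
}

# Per-base-pair genic fraction oracle.
oracle_genic_fraction <- function(genes, genome_length) {
  covered <- logical(genome_length)
  for (i in seq_len(nrow(genes))) {
    if (genes$end[i] > genes$start[i]) {
      covered[(genes$start[i] + 1L):genes$end[i]] <- TRUE # 0-based half-open
    }
  }
  mean(covered)
}

# Random non-overlapping annotation on a small genome.
random_annotation <- function(genome_length = 10000L, n_genes = 5L) {
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(n_genes)) {
    for (try in 1:200) {
      L <- sample(100:min(1500L, genome_length %/% 2L), 1L)
      s <- sample.int(genome_length - L, 1L) - 1L
      if (!any(s < ends & s + L > starts)) {
        starts <- c(starts, s); ends <- c(ends, s + L)
        break
      }
    }
  }
  gene_annotation(data.frame(
    sequence_id = rep("chr", length(starts)), start = starts, end = ends,
    strand = sample(c("+", "-"), length(starts), replace = TRUE),
    name = sprintf("g%03d", seq_along(starts)), stringsAsFactors = FALSE),
    genome_length)
}

# Small probe track with given z-like values at regular spacing.
toy_ztrack <- function(values, spacing = 100L, probe_len = 50L, start0 = 100L) {
  n <- length(values)
  starts <- start0 + spacing * (seq_len(n) - 1L)
  tr <- probe_track("chr", starts, starts + probe_len, values, label = "toy")
  fit <- structure(list(mode = 0, sigma = 1, n_below = n, n_total = n,
                        method = "kde", bandwidth = NA_real_, grid_n = 2048L),
                   class = "null_fit")
  compute_zscores(tr, fit)
}

# Minimal valid qPCR measurement table builder.
toy_qpcr <- function(ct_ip_target, ct_ip_ctrl, ct_in_target, ct_in_ctrl,
                     region = "site", condition = "baseline", reps = NULL) {
  n <- length(ct_ip_target)
  if (is.null(reps)) reps <- seq_len(n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      region = c(region, region, "ctrl", "ctrl"),
      sample_type = c("IP", "input", "IP", "input"),
      condition = condition, replicate = reps[i],
      ct = c(ct_ip_target[i], ct_in_target[i], ct_ip_ctrl[i], ct_in_ctrl[i]),
      stringsAsFactors = FALSE)
  }))
}
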
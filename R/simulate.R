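# Synthetic data generator: an annotated genome, spiked binding sites,
# two studies x two replicates of tiling-array signal, and qPCR Ct
# tables derived from the true enrichment — all with recorded ground
# truth so every pipeline stage can be exercised without the original
# microarray data.
#
# Noise model. A probe's null signal is null_mean plus two Gaussian
# parts: a probe-level affinity bias (shared by the replicates of a
# study — the sequence-dependent component that makes real replicates
# correlate across mostly-null probes) and per-replicate noise. Their
# variances sum to null_sd^2, so the marginal null distribution has the
# configured sd. Binding sites add a triangular enrichment term of
# configurable halfwidth; study B attenuates every enrichment term
# (reduced assay sensitivity) and adds extra per-replicate noise.

#' Simulation configuration
#'
#' Defaults describe a desk-scale bacterial study: 500 kb genome, 200 bp
#' probe spacing (~2,500 probes), 40 genes, 30 spiked binding sites with
#' amplitudes spanning a wide dynamic range, and a second study with
#' attenuated sensitivity and extra noise.
#'
#' @param genome_length Genome length (bp).
#' @param n_genes Number of non-overlapping genes to place.
#' @param gene_length_mean Mean gene length (bp).
#' @param probe_spacing Distance between probe starts (bp).
#' @param probe_length Probe length (bp).
#' @param null_mean,null_sd Null signal mean and sd (arbitrary units).
#' @param n_sites Number of binding sites.
#' @param amplitude_range Site amplitudes (uniform draw), in multiples of
#'   `null_sd`.
#' @param frac_intergenic_sites Fraction of sites placed in intergenic
#'   positions.
#' @param peak_halfwidth Half-width of the triangular (linear-decay)
#'   enrichment peak (bp).
#' @param replicate_noise_sd Per-replicate noise sd (signal units); must
#'   be below `null_sd`, the remainder being the shared probe bias.
#' @param study_b_attenuation Multiplier in `(0, 1]` on every site's
#'   enrichment in study B.
#' @param study_b_extra_noise_sd Extra per-replicate noise in study B, in
#'   multiples of `null_sd`.
#' @param qpcr_ct_noise_sd Gaussian Ct noise sd (cycles).
#' @param qpcr_n_regions Number of target regions carried into the qPCR
#'   table (plus one unenriched control region).
#' @param qpcr_n_replicates Biological replicates per condition.
#' @param induction_factor Fold change in enrichment between the
#'   baseline and heat-shock-like condition.
#' @param site_min_separation Minimum distance between sites (bp).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 500000L, n_genes = 40L,
                              gene_length_mean = 5000L, probe_spacing = 200L,
                              probe_length = 50L, null_mean = 6, null_sd = 1,
                              n_sites = 30L, amplitude_range = c(3, 40),
                              frac_intergenic_sites = 1 / 3,
                              peak_halfwidth = 300L,
                              replicate_noise_sd = sqrt(3) / 2,
                              study_b_attenuation = 0.4,
                              study_b_extra_noise_sd = 1,
                              qpcr_ct_noise_sd = 0.1, qpcr_n_regions = 4L,
                              qpcr_n_replicates = 3L, induction_factor = 3,
                              site_min_separation = 2000L, seed = 17L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              gene_length_mean = as.integer(gene_length_mean),
              probe_spacing = as.integer(probe_spacing),
              probe_length = as.integer(probe_length),
              null_mean = null_mean, null_sd = null_sd,
              n_sites = as.integer(n_sites),
              amplitude_range = as.numeric(amplitude_range),
              frac_intergenic_sites = frac_intergenic_sites,
              peak_halfwidth = as.integer(peak_halfwidth),
              replicate_noise_sd = replicate_noise_sd,
              study_b_attenuation = study_b_attenuation,
              study_b_extra_noise_sd = study_b_extra_noise_sd,
              qpcr_ct_noise_sd = qpcr_ct_noise_sd,
              qpcr_n_regions = as.integer(qpcr_n_regions),
              qpcr_n_replicates = as.integer(qpcr_n_replicates),
              induction_factor = induction_factor,
              site_min_separation = as.integer(site_min_separation),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(genome_length > 0L, probe_spacing > 0L, probe_length > 0L,
              gene_length_mean > 0L, n_sites >= 0L, peak_halfwidth > 0L,
              null_sd > 0, replicate_noise_sd >= 0,
              amplitude_range[1] < amplitude_range[2],
              frac_intergenic_sites >= 0, frac_intergenic_sites <= 1,
              study_b_attenuation > 0, study_b_attenuation <= 1,
              study_b_extra_noise_sd >= 0)
    if (replicate_noise_sd >= null_sd) {
      stop("replicate_noise_sd must be below null_sd (the remainder is shared probe bias)",
           call. = FALSE)
    }
  })
  class(cfg) <- "simulation_config"
  cfg
}

# Study probe grid: study A starts at 0, study B is offset by half the
# spacing so the two studies have different probes (as in real pairs of
# array designs).
.probe_grid <- function(config, study) {
  offset <- if (study == "A") 0L else config$probe_spacing %/% 2L
  starts <- seq.int(offset, config$genome_length - config$probe_length,
                    by = config$probe_spacing)
  list(start = as.integer(starts),
       end = as.integer(starts + config$probe_length))
}

#' Simulate an annotated genome with spiked binding sites
#'
#' Genes are placed uniformly without overlap with random strands. Sites
#' are placed at study-A probe midpoints (making the amplitude-to-z
#' mapping exact at the peak probe) so that the realised intergenic site
#' fraction matches `frac_intergenic_sites` to within one site, with a
#' minimum separation preventing merged regions.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (default derived from `config$seed`).
#' @return List with `annotation` (a [gene_annotation()]) and `sites`
#'   (data frame `name`, `position`, `amplitude`, `context`, `true_fe`).
#' @export
simulate_genome <- function(config, seed = derive_seed(config$seed, "genome")) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    # --- genes ---
    lens <- pmax(200L, as.integer(round(stats::rnorm(
      config$n_genes, config$gene_length_mean, 0.2 * config$gene_length_mean))))
    starts <- integer(0); ends <- integer(0)
    tries <- 0L
    for (L in lens) {
      repeat {
        tries <- tries + 1L
        if (tries > 20000L) {
          stop("cannot fit genes; reduce n_genes or increase genome_length",
               call. = FALSE)
        }
        s <- sample.int(config$genome_length - L, 1L) - 1L
        if (!any(s < ends + 1L & s + L > starts - 1L)) break
      }
      starts <- c(starts, s); ends <- c(ends, s + L)
    }
    genes <- data.frame(
      sequence_id = rep("chr", length(starts)), start = starts, end = ends,
      strand = sample(c("+", "-"), length(starts), replace = TRUE),
      name = sprintf("gene_%03d", seq_along(starts)),
      stringsAsFactors = FALSE)
    genes <- genes[order(genes$start), , drop = FALSE]
    genes$name <- sprintf("gene_%03d", seq_len(nrow(genes)))
    ann <- gene_annotation(genes, config$genome_length)

    # --- sites at probe midpoints, split genic / intergenic ---
    grid <- .probe_grid(config, "A")
    mids <- as.integer((grid$start + grid$end) %/% 2L)
    ctx <- vapply(mids, function(p) classify_position(ann, p), "")
    margin <- config$peak_halfwidth + config$probe_spacing
    ok <- mids > margin & mids < config$genome_length - margin
    pool_int <- mids[ok & ctx != "genic"]
    pool_gen <- mids[ok & ctx == "genic"]
    n_int <- round(config$frac_intergenic_sites * config$n_sites)
    n_gen <- config$n_sites - n_int
    if (length(pool_int) < n_int || length(pool_gen) < n_gen) {
      stop("not enough eligible probe positions for the requested site mix",
           call. = FALSE)
    }
    pick <- function(pool, n) {
      chosen <- integer(0)
      cand <- sample(pool)
      for (p in cand) {
        if (length(chosen) == n) break
        if (!any(abs(chosen - p) < config$site_min_separation)) {
          chosen <- c(chosen, p)
        }
      }
      if (length(chosen) < n) {
        stop("cannot place sites with the configured minimum separation",
             call. = FALSE)
      }
      chosen
    }
    pos_gen <- pick(pool_gen, n_gen)
    # keep intergenic sites clear of the genic ones too
    pool_int2 <- pool_int[vapply(pool_int, function(p)
      all(abs(pos_gen - p) >= config$site_min_separation), TRUE)]
    pos_int <- pick(pool_int2, n_int)
    pos <- c(pos_gen, pos_int)
    amp <- stats::runif(length(pos), config$amplitude_range[1],
                        config$amplitude_range[2])
    o <- order(pos)
    sites <- data.frame(
      name = sprintf("site_%03d", seq_along(pos)),
      position = pos[o], amplitude = amp[o],
      context = vapply(pos[o], function(p) classify_position(ann, p), ""),
      stringsAsFactors = FALSE)
    sites$true_fe <- 1 + sites$amplitude
    list(annotation = ann, sites = sites)
  })
}

#' Simulate replicate probe tracks for two studies
#'
#' @param truth Output of [simulate_genome()].
#' @param config A [simulation_config()].
#' @param seed Integer seed (default derived from `config$seed`).
#' @return Named list of [probe_track()]s: `A_rep1`, `A_rep2`, `B_rep1`,
#'   `B_rep2`.
#' @export
simulate_tracks <- function(truth, config, seed = derive_seed(config$seed, "tracks")) {
  stopifnot(inherits(config, "simulation_config"))
  bias_sd <- sqrt(config$null_sd^2 - config$replicate_noise_sd^2)
  with_seed(seed, {
    out <- list()
    for (study in c("A", "B")) {
      grid <- .probe_grid(config, study)
      mids <- (grid$start + grid$end) / 2
      n <- length(mids)
      sig <- numeric(n)
      for (i in seq_len(nrow(truth$sites))) {
        tri <- pmax(0, 1 - abs(mids - truth$sites$position[i]) / config$peak_halfwidth)
        sig <- sig + truth$sites$amplitude[i] * config$null_sd * tri
      }
      atten <- if (study == "B") config$study_b_attenuation else 1
      extra <- if (study == "B") config$study_b_extra_noise_sd * config$null_sd else 0
      bias <- stats::rnorm(n, 0, bias_sd)
      for (rep in 1:2) {
        v <- config$null_mean + bias + atten * sig +
          stats::rnorm(n, 0, config$replicate_noise_sd)
        if (extra > 0) v <- v + stats::rnorm(n, 0, extra)
        out[[sprintf("%s_rep%d", study, rep)]] <-
          probe_track("chr", grid$start, grid$end, v,
                      label = sprintf("study%s_rep%d", study, rep))
      }
    }
    out
  })
}

#' Simulate a ChIP/qPCR Ct table from true enrichment
#'
#' Regions are the strongest site plus evenly amplitude-spaced weaker
#' sites and one unenriched control region. Two conditions are emitted:
#' a baseline where each site's enrichment is its true value divided by
#' `induction_factor`, and a heat-shock-like condition at the full true
#' value. Ct values are constructed so the noiseless table inverts
#' exactly to the true fold enrichment (input relative quantity 1),
#' then jittered with Gaussian noise of sd `qpcr_ct_noise_sd`.
#'
#' @param truth Output of [simulate_genome()].
#' @param config A [simulation_config()].
#' @param seed Integer seed (default derived from `config$seed`).
#' @return A [qpcr_table()] with attributes `true_fe` (data frame
#'   `region`, `condition`, `fe`) and `conditions`.
#' @export
simulate_qpcr <- function(truth, config, seed = derive_seed(config$seed, "qpcr")) {
  stopifnot(inherits(config, "simulation_config"))
  s <- truth$sites[order(-truth$sites$amplitude), , drop = FALSE]
  k <- min(config$qpcr_n_regions, nrow(s))
  idx <- unique(as.integer(round(seq(1, nrow(s), length.out = k))))
  regions <- s[idx, , drop = FALSE]
  conds <- c("baseline", "heat_shock")
  ctrl <- "control"
  eff <- 2
  truth_fe <- do.call(rbind, lapply(conds, function(cond) {
    mult <- if (cond == "heat_shock") 1 else 1 / config$induction_factor
    data.frame(region = regions$name, condition = cond,
               fe = 1 + (regions$true_fe - 1) * mult, stringsAsFactors = FALSE)
  }))
  rows <- list()
  with_seed(seed, {
    for (cond in conds) {
      for (rep in seq_len(config$qpcr_n_replicates)) {
        add <- function(region, type, ct) {
          rows[[length(rows) + 1L]] <<- data.frame(
            region = region, sample_type = type, condition = cond,
            replicate = rep, ct = ct + stats::rnorm(1, 0, config$qpcr_ct_noise_sd),
            stringsAsFactors = FALSE)
        }
        add(ctrl, "IP", 20); add(ctrl, "input", 22)
        for (i in seq_len(nrow(regions))) {
          fe <- truth_fe$fe[truth_fe$region == regions$name[i] &
                              truth_fe$condition == cond]
          add(regions$name[i], "IP", 20 - log(fe) / log(eff))
          add(regions$name[i], "input", 22)
        }
      }
    }
  })
  tab <- qpcr_table(do.call(rbind, rows), control_region = ctrl, efficiency = eff)
  attr(tab, "true_fe") <- truth_fe
  attr(tab, "conditions") <- conds
  tab
}

#' Run the whole generator and optionally write files
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, writes `genome.gff3`,
#'   `truth_sites.tsv`, `{A,B}_rep{1,2}.bedGraph`, `qpcr_ct.csv` and
#'   `manifest.tsv`.
#' @return List with `truth`, `tracks`, `qpcr`, `config` and (when
#'   written) `files`.
#' @export
simulate_study <- function(config = simulation_config(), outdir = NULL) {
  truth <- simulate_genome(config)
  tracks <- simulate_tracks(truth, config)
  qpcr <- simulate_qpcr(truth, config)
  out <- list(truth = truth, tracks = tracks, qpcr = qpcr, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(genome = file.path(outdir, "genome.gff3"),
               sites = file.path(outdir, "truth_sites.tsv"),
               qpcr = file.path(outdir, "qpcr_ct.csv"),
               manifest = file.path(outdir, "manifest.tsv"))
    write_annotation(truth$annotation, files[["genome"]])
    write_table(truth$sites, files[["sites"]])
    utils::write.csv(as.data.frame(qpcr), files[["qpcr"]], row.names = FALSE,
                     quote = FALSE)
    for (nm in names(tracks)) {
      f <- file.path(outdir, paste0(nm, ".bedGraph"))
      write_probe_track(tracks[[nm]], f)
      files[[nm]] <- f
    }
    manifest <- data.frame(key = names(files), path = basename(unlist(files)),
                           stringsAsFactors = FALSE)
    manifest <- rbind(manifest, data.frame(key = "seed",
                                           path = as.character(config$seed)))
    write_table(manifest, files[["manifest"]])
    out$files <- files
  }
  out
}
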
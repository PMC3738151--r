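cfg_small <- function(...) {
  args <- list(genome_length = 100000L, n_genes = 10L,
               gene_length_mean = 3000L, n_sites = 8L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

test_that("genome simulation is deterministic and honours the site mix", {
  cfg <- cfg_small(seed = 5L)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$sites), 8L)
  # realised intergenic fraction within one site of the request
  n_int <- sum(t1$sites$context != "genic")
  expect_lte(abs(n_int - round(cfg$frac_intergenic_sites * 8)), 1)
  # recorded contexts agree with the classifier
  expect_equal(t1$sites$context,
               vapply(t1$sites$position, function(p)
                 classify_position(t1$annotation, p), ""))

  all_int <- simulate_genome(cfg_small(frac_intergenic_sites = 1, seed = 6L))
  expect_true(all(all_int$sites$context != "genic"))

  no_genes <- simulate_genome(cfg_small(n_genes = 0L, frac_intergenic_sites = 1,
                                        seed = 7L))
  expect_equal(genic_fraction(no_genes$annotation), 0)
  expect_true(all(no_genes$sites$context == "intergenic"))
})

test_that("track simulation recovers the configured null and amplitudes", {
  # no sites, no study-B degradation: the null fit recovers the inputs
  cfg <- simulation_config(genome_length = 400000L, n_genes = 0L, n_sites = 0L,
                           frac_intergenic_sites = 0,
                           study_b_attenuation = 1, study_b_extra_noise_sd = 0,
                           seed = 8L)
  truth <- simulate_genome(cfg)
  tracks <- simulate_tracks(truth, cfg)
  f <- estimate_null(tracks$A_rep1$value)
  # KDE mode sampling error at ~2,000 probes is ~0.1 signal units
  expect_lt(abs(f$mode - cfg$null_mean), 0.2)
  expect_lt(abs(f$sigma - cfg$null_sd) / cfg$null_sd, 0.1)

  # a site of amplitude 10 at a probe midpoint scores z ~ 10
  peak_z <- vapply(1:20, function(s) {
    cfg <- simulation_config(genome_length = 200000L, n_genes = 0L,
                             n_sites = 1L, frac_intergenic_sites = 1,
                             amplitude_range = c(10 - 1e-6, 10 + 1e-6),
                             seed = as.integer(s))
    truth <- simulate_genome(cfg)
    z <- compute_zscores(simulate_tracks(truth, cfg)$A_rep1)
    nearest_probe(z, truth$sites$position[1])$z
  }, 0)
  expect_lt(abs(mean(peak_z) - 10) / 10, 0.15)

  # identity limit: study B indistinguishable from study A
  rho <- lapply(c("A", "B"), function(study) NULL)
  cfg_id <- simulation_config(genome_length = 400000L, n_genes = 0L,
                              n_sites = 0L, frac_intergenic_sites = 0,
                              study_b_attenuation = 1,
                              study_b_extra_noise_sd = 0, seed = 9L)
  tr <- simulate_tracks(simulate_genome(cfg_id), cfg_id)
  rho_a <- replicate_concordance(compute_zscores(tr$A_rep1),
                                 compute_zscores(tr$A_rep2))$spearman_rho
  rho_b <- replicate_concordance(compute_zscores(tr$B_rep1),
                                 compute_zscores(tr$B_rep2))$spearman_rho
  expect_lt(abs(rho_a - rho_b), 0.05)
})

test_that("replicate concordance degrades monotonically with extra study-B noise", {
  grid <- c(0, 1, 2.5)
  mean_rho <- vapply(grid, function(xn) {
    mean(vapply(1:8, function(s) {
      cfg <- simulation_config(genome_length = 200000L, n_genes = 0L,
                               n_sites = 0L, frac_intergenic_sites = 0,
                               study_b_extra_noise_sd = xn, seed = s)
      tr <- simulate_tracks(simulate_genome(cfg), cfg)
      replicate_concordance(compute_zscores(tr$B_rep1),
                            compute_zscores(tr$B_rep2))$spearman_rho
    }, 0))
  }, 0)
  expect_true(all(diff(mean_rho) < 0))
})

test_that("simulated qPCR tables invert exactly without noise and are seeded", {
  cfg <- cfg_small(qpcr_ct_noise_sd = 0, seed = 10L)
  truth <- simulate_genome(cfg)
  tab <- simulate_qpcr(truth, cfg)
  occ <- summarize_occupancy(tab)
  want <- attr(tab, "true_fe")
  for (i in seq_len(nrow(occ))) {
    fe <- want$fe[want$region == occ$region[i] & want$condition == occ$condition[i]]
    expect_equal(occ$occupancy_mean[i], fe - 1, tolerance = 1e-9)
    expect_equal(occ$occupancy_sd[i], 0)
  }
  expect_identical(simulate_qpcr(truth, cfg), tab)
})

test_that("every emitted file parses back through the readers", {
  dir <- withr::local_tempdir()
  cfg <- cfg_small(seed = 11L)
  sim <- simulate_study(cfg, outdir = dir)
  ann <- read_annotation(file.path(dir, "genome.gff3"))
  expect_equal(ann$genome_length, cfg$genome_length)
  expect_equal(nrow(ann$genes), nrow(sim$truth$annotation$genes))
  sites <- read_table_tsv(file.path(dir, "truth_sites.tsv"))
  expect_equal(sites$position, sim$truth$sites$position)
  for (nm in names(sim$tracks)) {
    tr <- expect_silent(read_probe_track(file.path(dir, paste0(nm, ".bedGraph"))))
    expect_equal(tr$start, sim$tracks[[nm]]$start)
    expect_equal(tr$value, sim$tracks[[nm]]$value, tolerance = 1e-5)
  }
  q <- read_qpcr_table(file.path(dir, "qpcr_ct.csv"), control_region = "control")
  expect_s3_class(q, "qpcr_table")
})

test_that("the pipeline recovers strong spiked sites without false calls", {
  # strong sites (amplitude >= 5 null sd) must be recovered and no target
  # may fall outside a peak halfwidth of any true site
  runs <- vapply(1:25, function(s) {
    cfg <- simulation_config(seed = as.integer(1000 + s))
    truth <- simulate_genome(cfg)
    tracks <- simulate_tracks(truth, cfg)
    z1 <- compute_zscores(tracks$A_rep1)
    z2 <- compute_zscores(tracks$A_rep2)
    zmin <- z_track(z1$track, pmin(z1$zscores, z2$zscores), z1$fit)
    called <- call_targets(zmin, threshold = 3, merge_distance = 500L)
    strong <- truth$sites[truth$sites$amplitude >= 5, ]
    recovered <- vapply(strong$position, function(p)
      any(abs(called$peak_position - p) <= cfg$peak_halfwidth), TRUE)
    false_calls <- vapply(called$peak_position, function(p)
      all(abs(truth$sites$position - p) > cfg$peak_halfwidth), TRUE)
    (mean(recovered) >= 0.95) && !any(false_calls)
  }, TRUE)
  expect_gte(mean(runs), 0.9)
})
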
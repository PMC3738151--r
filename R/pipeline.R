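# One-config orchestration of the full analysis: normalize -> call ->
# cross-study comparison -> context classification -> enrichment and
# rank tests -> concordance -> optional qPCR stage, with deterministic
# seeded behaviour and TSV/YAML outputs.

#' Pipeline run configuration
#'
#' Tracks may be given as file paths (bedGraph) or in-memory
#' [probe_track()] objects; the annotation as a path (GFF3/BED) or a
#' [gene_annotation()]. Study-B targets may be supplied as a published
#' table instead of being called from study-B tracks.
#'
#' @param tracks_a,tracks_b Lists of two replicates each (paths or
#'   `probe_track`s).
#' @param annotation Path or [gene_annotation()].
#' @param targets_b Optional pre-called study-B target table (path to
#'   TSV or `target_table`); when `NULL`, study-B targets are called
#'   from its tracks with the same parameters as study A.
#' @param exclude Character vector of study-A target names to exclude
#'   from the comparison (e.g. repetitive-region peaks).
#' @param threshold z threshold for target calling.
#' @param merge_distance Region merge distance (bp).
#' @param tolerance Cross-study peak match tolerance (bp).
#' @param n_random Random probes for the disputed-vs-random test.
#' @param combine_replicates How to combine the two replicate z-tracks
#'   of a study before calling: `"min"` (replicate agreement: a probe
#'   passes only at the level both replicates support; the default),
#'   `"mean"`, or `"rep1"`.
#' @param mode_method Mode estimator, `"kde"` or `"hist"`.
#' @param bottom_fraction Fraction of lowest-ranked targets inspected by
#'   the rank analysis (default 1/3).
#' @param seed Master seed for the random-probe draw.
#' @param qpcr Optional list: `table` (path or [qpcr_table()]),
#'   `control_region`, `efficiency`, `background`, `compare` (list with
#'   `condition_a`, `condition_b`, `alternative`).
#' @param genome_length Genome length, required when `annotation` is a
#'   BED path.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tracks_a, tracks_b, annotation, targets_b = NULL,
                       exclude = character(), threshold = 3,
                       merge_distance = 500L, tolerance = 500L,
                       n_random = 1000L,
                       combine_replicates = c("min", "mean", "rep1"),
                       mode_method = c("kde", "hist"),
                       bottom_fraction = 1 / 3, seed = 17L, qpcr = NULL,
                       genome_length = NULL) {
  cfg <- list(tracks_a = tracks_a, tracks_b = tracks_b,
              annotation = annotation, targets_b = targets_b,
              exclude = exclude, threshold = threshold,
              merge_distance = as.integer(merge_distance),
              tolerance = as.integer(tolerance),
              n_random = as.integer(n_random),
              combine_replicates = match.arg(combine_replicates),
              mode_method = match.arg(mode_method),
              bottom_fraction = bottom_fraction,
              seed = as.integer(seed), qpcr = qpcr,
              genome_length = genome_length)
  for (p in c(cfg$tracks_a, cfg$tracks_b, list(cfg$annotation))) {
    if (is.character(p) && !file.exists(p)) {
      stop(sprintf("input file does not exist: %s", p), call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Paths in the file are resolved relative to the file's directory.
#'
#' @param path Path to a YAML config.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  run_config(
    tracks_a = lapply(y$tracks_a, rel),
    tracks_b = lapply(y$tracks_b, rel),
    annotation = rel(y$annotation),
    targets_b = rel(y$targets_b),
    exclude = y$exclude %||% character(),
    threshold = y$threshold %||% 3,
    merge_distance = y$merge_distance %||% 500L,
    tolerance = y$tolerance %||% 500L,
    n_random = y$n_random %||% 1000L,
    combine_replicates = y$combine_replicates %||% "min",
    mode_method = y$mode_method %||% "kde",
    bottom_fraction = y$bottom_fraction %||% (1 / 3),
    seed = y$seed %||% 17L,
    qpcr = if (is.null(y$qpcr)) NULL else {
      q <- y$qpcr; q$table <- rel(q$table); q
    },
    genome_length = y$genome_length
  )
}

.load_track <- function(x, label) {
  if (inherits(x, "probe_track")) return(x)
  read_probe_track(x, label = label)
}

.combine_z <- function(z1, z2, how) {
  zc <- switch(how,
               min = pmin(z1$zscores, z2$zscores),
               mean = (z1$zscores + z2$zscores) / 2,
               rep1 = z1$zscores)
  z_track(z1$track, zc, z1$fit)
}

#' Run the full arbitration pipeline
#'
#' Executes: per-replicate null fit and z-scoring; replicate-combined
#' target calling for study A (and study B unless its targets are
#' supplied); cross-study matching with disputed-target derivation;
#' genomic-context classification of disputed targets; a binomial test
#' for intergenic enrichment of disputed targets; a disputed-vs-random
#' Mann-Whitney test on each study-B replicate; replicate concordance
#' per study; a rank analysis of disputed targets among the weakest
#' study-A calls; and an optional qPCR occupancy stage. Raw p-values are
#' reported without multiple-testing correction, matching how these
#' per-question tests are conventionally read.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, all tables are
#'   written as TSV plus a YAML `report.yaml`. Outputs are bit-identical
#'   across runs for a fixed config.
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  report <- NULL
  tryCatch({
    tracks <- list(
      A_rep1 = .load_track(config$tracks_a[[1]], "studyA_rep1"),
      A_rep2 = .load_track(config$tracks_a[[2]], "studyA_rep2"),
      B_rep1 = .load_track(config$tracks_b[[1]], "studyB_rep1"),
      B_rep2 = .load_track(config$tracks_b[[2]], "studyB_rep2"))
    ann <- if (inherits(config$annotation, "gene_annotation")) config$annotation
           else read_annotation(config$annotation, genome_length = config$genome_length)

    stage <- "normalize"
    z <- lapply(tracks, function(tr)
      compute_zscores(tr, method = config$mode_method))
    fits <- do.call(rbind, lapply(names(z), function(nm) {
      f <- z[[nm]]$fit
      data.frame(track = nm, mode = f$mode, sigma = f$sigma,
                 n_below = f$n_below, n_total = f$n_total, method = f$method,
                 stringsAsFactors = FALSE)
    }))

    stage <- "call"
    zA <- .combine_z(z$A_rep1, z$A_rep2, config$combine_replicates)
    targets_a <- call_targets(zA, config$threshold, config$merge_distance,
                              name_prefix = "A")
    targets_a <- classify_targets(targets_a, ann)
    if (is.null(config$targets_b)) {
      zB <- .combine_z(z$B_rep1, z$B_rep2, config$combine_replicates)
      targets_b <- call_targets(zB, config$threshold, config$merge_distance,
                                name_prefix = "B")
      targets_b_mode <- "called_from_tracks"
    } else if (is.character(config$targets_b)) {
      targets_b <- read_table_tsv(config$targets_b)
      targets_b_mode <- "supplied_table"
    } else {
      targets_b <- config$targets_b
      targets_b_mode <- "supplied_table"
    }

    stage <- "compare"
    comparison <- compare_studies(targets_a, targets_b, config$tolerance,
                                  config$exclude)
    disputed <- comparison$disputed

    stage <- "context"
    genic <- genic_fraction(ann)
    binom <- NULL
    if (nrow(disputed) > 0L && genic > 0 && genic < 1) {
      k <- sum(disputed$context != "genic")
      binom <- positional_enrichment_test(k, nrow(disputed), p0 = 1 - genic)
    }

    stage <- "dst_test"
    mwu <- list()
    if (nrow(disputed) > 0L) {
      for (nm in c("B_rep1", "B_rep2")) {
        mwu[[nm]] <- dst_vs_random_test(
          z[[nm]], disputed$peak_position,
          n_random = min(config$n_random, length(z[[nm]]$zscores) - 1L),
          seed = derive_seed(config$seed, paste0("dst_", nm)))
      }
    }

    stage <- "concordance"
    conc <- list(A = replicate_concordance(z$A_rep1, z$A_rep2, config$threshold),
                 B = replicate_concordance(z$B_rep1, z$B_rep2, config$threshold))

    stage <- "rank"
    rank_res <- NULL
    if (nrow(targets_a) > 0L) {
      bottom <- max(1L, as.integer(floor(config$bottom_fraction * nrow(targets_a))))
      rank_res <- rank_analysis(targets_a, disputed$name, bottom)
    }

    stage <- "qpcr"
    occupancy_tab <- NULL; qpcr_tests <- NULL
    if (!is.null(config$qpcr)) {
      q <- config$qpcr
      tab <- if (inherits(q$table, "qpcr_table")) q$table
             else read_qpcr_table(q$table, q$control_region,
                                  q$efficiency %||% 2)
      occupancy_tab <- summarize_occupancy(tab, q$background %||% list(constant = 1))
      if (!is.null(q$compare)) {
        regions <- setdiff(unique(occupancy_tab$region), character(0))
        qpcr_tests <- do.call(rbind, lapply(regions, function(rg) {
          oa <- occupancy_tab$per_replicate[[which(
            occupancy_tab$region == rg &
              occupancy_tab$condition == q$compare$condition_a)]]
          ob <- occupancy_tab$per_replicate[[which(
            occupancy_tab$region == rg &
              occupancy_tab$condition == q$compare$condition_b)]]
          cc <- condition_compare(oa, ob, q$compare$alternative %||% "greater")
          data.frame(region = rg, t = cc$t, df = cc$df, p_value = cc$p_value,
                     alternative = cc$alternative, stringsAsFactors = FALSE)
        }))
      }
    }

    stage <- "report"
    counts <- list(
      probes = vapply(tracks, function(t) length(t$value), 0L),
      targets_a = nrow(targets_a), targets_b = nrow(targets_b),
      matched = nrow(comparison$matched), disputed = nrow(disputed),
      excluded = length(comparison$excluded))
    provenance <- list(
      package_version = as.character(utils::packageVersion("chiparbiter")),
      seed = config$seed,
      targets_b_mode = targets_b_mode,
      combine_replicates = config$combine_replicates,
      config_hash = sprintf("%08x", as.integer(fnv1a32(paste(deparse(
        config[setdiff(names(config), c("tracks_a", "tracks_b", "annotation",
                                        "targets_b", "qpcr"))]),
        collapse = "")) %% 2147483648)))
    report <- structure(
      list(null_fits = fits, targets_a = targets_a, targets_b = targets_b,
           comparison = comparison, binomial = binom, mwu = mwu,
           concordance = conc, rank = rank_res, occupancy = occupancy_tab,
           qpcr_tests = qpcr_tests, counts = counts, genic_fraction = genic,
           provenance = provenance),
      class = "run_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  targets: A = %d, B = %d; matched = %d, disputed = %d, excluded = %d\n",
              x$counts$targets_a, x$counts$targets_b, x$counts$matched,
              x$counts$disputed, x$counts$excluded))
  cat(sprintf("  concordance rho: A = %.3f, B = %.3f\n",
              x$concordance$A$spearman_rho, x$concordance$B$spearman_rho))
  if (!is.null(x$binomial)) {
    cat(sprintf("  intergenic enrichment of disputed targets: k = %d/%d, p = %.3g\n",
                x$binomial$k, x$binomial$n, x$binomial$p_value))
  }
  for (nm in names(x$mwu)) {
    cat(sprintf("  disputed vs random (%s): p = %.3g\n", nm, x$mwu[[nm]]$p_value))
  }
  if (!is.null(x$rank)) {
    cat(sprintf("  rank analysis: %d of the bottom %d targets are disputed\n",
                x$rank$disputed_in_bottom, x$rank$bottom_count))
  }
  invisible(x)
}

#' Write every table of a run report plus a YAML summary
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_table(df, file.path(outdir, name))
  w(report$null_fits, "null_fits.tsv")
  w(report$targets_a, "targets_a.tsv")
  w(report$targets_b, "targets_b.tsv")
  w(report$comparison$matched, "comparison_matched.tsv")
  w(report$comparison$disputed, "comparison_disputed.tsv")
  conc <- do.call(rbind, lapply(names(report$concordance), function(nm) {
    cr <- report$concordance[[nm]]
    data.frame(study = nm, spearman_rho = cr$spearman_rho,
               n_probes = cr$n_probes,
               frac_below_threshold = cr$frac_below_threshold,
               threshold = cr$threshold, stringsAsFactors = FALSE)
  }))
  w(conc, "concordance.tsv")
  if (length(report$mwu)) {
    w(do.call(rbind, lapply(names(report$mwu), function(nm) {
      m <- report$mwu[[nm]]
      data.frame(track = nm, U = m$U, n_a = m$n_a, n_b = m$n_b,
                 p_value = m$p_value, method = m$method,
                 alternative = m$alternative, seed = m$seed,
                 stringsAsFactors = FALSE)
    })), "dst_vs_random.tsv")
  }
  if (!is.null(report$binomial)) {
    b <- report$binomial
    w(data.frame(k = b$k, n = b$n, p0 = b$p0, expected = b$expected,
                 p_value = b$p_value, alternative = b$alternative),
      "binomial.tsv")
  }
  if (!is.null(report$rank)) {
    w(data.frame(disputed_in_bottom = report$rank$disputed_in_bottom,
                 bottom_count = report$rank$bottom_count), "rank_analysis.tsv")
  }
  if (!is.null(report$occupancy)) w(report$occupancy, "occupancy.tsv")
  if (!is.null(report$qpcr_tests)) w(report$qpcr_tests, "qpcr_tests.tsv")
  summary <- list(
    counts = lapply(report$counts, function(x) as.list(as.integer(x))),
    genic_fraction = report$genic_fraction,
    concordance = list(A = report$concordance$A$spearman_rho,
                       B = report$concordance$B$spearman_rho),
    provenance = report$provenance)
  yaml::write_yaml(summary, file.path(outdir, "report.yaml"))
  invisible(outdir)
}
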
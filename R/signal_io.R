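# Reading/writing the formats the pipeline touches. One coordinate
# convention everywhere: 0-based half-open, as in BED/bedGraph. GFF3 is
# converted at the boundary.

#' Construct a probe track
#'
#' A probe track holds the ordered per-probe signal of one microarray
#' replicate on a single sequence (one bacterial chromosome).
#'
#' @param sequence_id Sequence (chromosome) name.
#' @param start,end Integer probe coordinates, 0-based half-open.
#' @param value Numeric signal, one per probe (arbitrary units).
#' @param label Study/replicate identifier.
#' @return An object of class `probe_track` with fields `sequence_id`,
#'   `start`, `end`, `value`, `label`.
#' @export
probe_track <- function(sequence_id, start, end, value, label = "") {
  start <- as.integer(start); end <- as.integer(end); value <- as.numeric(value)
  if (length(start) != length(end) || length(start) != length(value)) {
    stop("start, end and value must have equal length", call. = FALSE)
  }
  if (length(start) == 0L) stop("probe track is empty", call. = FALSE)
  o <- order(start)
  start <- start[o]; end <- end[o]; value <- value[o]
  if (any(diff(start) <= 0L)) {
    stop("probe starts must be strictly increasing (duplicated probe?)", call. = FALSE)
  }
  if (any(end <= start)) stop("probe end must exceed probe start", call. = FALSE)
  if (any(start[-1L] < end[-length(end)])) {
    stop("overlapping probe intervals are not allowed", call. = FALSE)
  }
  if (anyNA(value)) stop("NA signal values must be dropped before construction", call. = FALSE)
  structure(
    list(sequence_id = as.character(sequence_id)[1L], start = start, end = end,
         value = value, label = as.character(label)[1L]),
    class = "probe_track"
  )
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("<probe_track> %s: %d probes on %s, signal range [%.4g, %.4g]\n",
              x$label, length(x$value), x$sequence_id, min(x$value), max(x$value)))
  invisible(x)
}

#' Probe midpoints of a track
#'
#' @param track A [probe_track()].
#' @return Integer vector of probe midpoints (bp).
#' @export
probe_midpoints <- function(track) {
  as.integer((track$start + track$end) %/% 2L)
}

#' Read a bedGraph signal track
#'
#' Expects the 4-column bedGraph format (sequence, start, end, value);
#' optional `track`/`#` header lines are skipped. Probes are sorted by
#' start; records with missing values are dropped and the count reported
#' via a message.
#'
#' @param path Path to a bedGraph file covering a single sequence.
#' @param label Study/replicate identifier attached to the track.
#' @return A [probe_track()].
#' @export
read_probe_track <- function(path, label = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("'%s': empty bedGraph file", path), call. = FALSE)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- lineno[which(nf != 4L)[1L]]
    stop(sprintf("'%s' line %d: expected 4 bedGraph columns, found %d",
                 path, bad, nf[which(nf != 4L)[1L]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("'%s' line %d: non-integer coordinate", path, bad), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(ifelse(m[, 4L] %in% c("NA", "nan", "NaN", ""),
                                              NA, m[, 4L])))
  seqs <- unique(m[, 1L])
  if (length(seqs) > 1L) {
    stop(sprintf("'%s' contains %d sequences; split multi-sequence input first (see split_by_sequence)",
                 path, length(seqs)), call. = FALSE)
  }
  drop <- is.na(value)
  if (any(drop)) {
    message(sprintf("read_probe_track: dropped %d probe(s) with missing values from '%s'",
                    sum(drop), path))
  }
  if (all(drop)) stop(sprintf("'%s': no probes with finite values", path), call. = FALSE)
  if (is.unsorted(start[!drop], strictly = TRUE)) {
    warning(sprintf("'%s': probes were not sorted by start; sorting", path), call. = FALSE)
  }
  tr <- probe_track(seqs, start[!drop], end[!drop], value[!drop], label = label)
  attr(tr, "n_dropped") <- sum(drop)
  tr
}

#' Write a probe track as bedGraph
#'
#' @param track A [probe_track()]; for z-score output pass a `z_track`'s
#'   values via `values`.
#' @param path Output path.
#' @param values Optional numeric vector to write in place of the raw
#'   signal (e.g. z-scores).
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path, values = NULL) {
  v <- if (is.null(values)) track$value else as.numeric(values)
  stopifnot(length(v) == length(track$start))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(track$sequence_id, track$start, track$end, format_num(v),
                   sep = "\t"), con)
  invisible(path)
}

#' Construct a gene annotation
#'
#' @param genes Data frame with columns `sequence_id`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `name`.
#' @param genome_length Total genome length in bp.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, genome_length) {
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length > 0L)
  need <- c("sequence_id", "start", "end", "strand", "name")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    if (any(genes$start < 0L | genes$end <= genes$start | genes$end > genome_length)) {
      stop("gene coordinates must satisfy 0 <= start < end <= genome_length", call. = FALSE)
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      stop("unknown strand symbol; expected '+' or '-'", call. = FALSE)
    }
    if (anyDuplicated(genes$name)) stop("gene names must be unique", call. = FALSE)
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(genes = genes, genome_length = genome_length),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes, genome %d bp, genic fraction %.3f\n",
              nrow(x$genes), x$genome_length, genic_fraction(x)))
  invisible(x)
}

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED is used as-is. For GFF3 the genome
#' length is taken from the `##sequence-region` directive when present.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @param genome_length Genome length in bp; required for BED, optional
#'   for GFF3 with a sequence-region directive.
#' @param feature_type For GFF3, the feature type to keep (default
#'   `"gene"`; all features kept if none match).
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, genome_length = NULL, feature_type = "gene") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) && "type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == feature_type)) {
      gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
    }
    if (is.null(genome_length)) {
      sl <- GenomeInfoDb::seqlengths(gr)
      if (length(sl) && !is.na(sl[1L])) genome_length <- unname(sl[1L])
    }
    if (is.null(genome_length)) {
      # ##sequence-region <seqid> <start> <end> directive in the header
      hdr <- grep("^##sequence-region", readLines(path, n = 100L), value = TRUE)
      if (length(hdr)) {
        genome_length <- as.integer(strsplit(trimws(hdr[1L]), "[ \t]+")[[1L]][4L])
      }
    }
    if (is.null(genome_length)) {
      stop("genome_length not found in GFF3 header; pass it explicitly", call. = FALSE)
    }
    nm <- S4Vectors::mcols(gr)$Name
    if (is.null(nm)) nm <- S4Vectors::mcols(gr)$ID
    if (is.null(nm) || anyNA(nm)) nm <- paste0("gene_", seq_along(gr))
    genes <- data.frame(
      sequence_id = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L, # GFF3 1-based inclusive -> 0-based half-open
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      name = as.character(nm),
      stringsAsFactors = FALSE
    )
  } else if (ext == "bed") {
    if (is.null(genome_length)) {
      stop("genome_length must be given for BED input", call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "bed")
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm) || anyNA(nm)) nm <- paste0("gene_", seq_along(gr))
    genes <- data.frame(
      sequence_id = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L, # GRanges is 1-based inclusive internally
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      name = as.character(nm),
      stringsAsFactors = FALSE
    )
  } else {
    stop("unsupported annotation format: .", ext, call. = FALSE)
  }
  if (any(genes$strand == "*")) {
    stop("unknown strand symbol in annotation; every gene needs '+' or '-'", call. = FALSE)
  }
  gene_annotation(genes, genome_length)
}

#' Write a gene annotation as GFF3
#'
#' @param ann A [gene_annotation()].
#' @param path Output path (`.gff3`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann$genes)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ann$genes$sequence_id[1L],
                       ann$genome_length), con)
    writeLines(sprintf("%s\tchiparbiter\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       ann$genes$sequence_id, ann$genes$start + 1L, ann$genes$end,
                       ann$genes$strand, ann$genes$name, ann$genes$name), con)
  }
  invisible(path)
}

#' Read a coordinate table (e.g. disputed-target positions)
#'
#' A TSV with header and at least columns `sequence_id`, `position`
#' (0-based bp) and `name`; an optional `flags` column holds
#' comma-separated tags.
#'
#' @param path Path to the TSV file.
#' @param annotation Optional [gene_annotation()] used to bounds-check
#'   positions.
#' @return A data frame of class `coordinate_table`.
#' @export
read_coordinate_table <- function(path, annotation = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sequence_id", "position", "name")
  if (!all(need %in% names(df))) {
    stop("coordinate table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$position <- as.integer(df$position)
  if (!is.null(annotation)) {
    if (any(df$position < 0L | df$position >= annotation$genome_length)) {
      stop("coordinate outside [0, genome_length)", call. = FALSE)
    }
  }
  if (is.null(df$flags)) df$flags <- ""
  class(df) <- c("coordinate_table", "data.frame")
  df
}

#' Write any tabular result as TSV
#'
#' Floating-point values are written at 6 significant digits; list
#' columns are flattened to comma-separated strings. An empty table
#' yields a header-only file.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) paste(format_num(v), collapse = ","), "")
    } else if (is.double(out[[j]])) {
      out[[j]] <- format_num(out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

#' Split a multi-sequence bedGraph data frame into per-sequence tracks
#'
#' @param path Path to a bedGraph file that may cover several sequences.
#' @param label Base label; the sequence name is appended.
#' @return Named list of [probe_track()] objects, one per sequence.
#' @export
split_by_sequence <- function(path, label = basename(path)) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("seq", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$seq), function(d) {
    d <- d[!is.na(suppressWarnings(as.numeric(d$value))), , drop = FALSE]
    probe_track(d$seq[1L], d$start, d$end, as.numeric(d$value),
                label = paste0(label, ":", d$seq[1L]))
  })
  out
}
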
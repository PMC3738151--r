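# ChIP/qPCR occupancy computation: Ct values -> relative quantities ->
# input-normalised fold enrichment -> background-subtracted occupancy
# units, plus the one-tailed two-sample t comparison between conditions.

#' Relative quantity of a target amplicon within one sample
#'
#' Abundance of the target amplicon relative to the control amplicon in
#' the same sample: `efficiency^(ct_control - ct_target)`. With perfect
#' doubling (efficiency 2) this is the familiar `2^dCt`.
#'
#' @param ct_target,ct_control Ct values (cycles).
#' @param efficiency Per-cycle amplification factor in `(1, 2]`
#'   (default 2).
#' @return Relative quantity (dimensionless).
#' @export
relative_quantity <- function(ct_target, ct_control, efficiency = 2) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_control))) {
    stop("non-finite Ct value", call. = FALSE)
  }
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    stop("efficiency must be in (1, 2]", call. = FALSE)
  }
  efficiency^(ct_control - ct_target)
}

#' Input-normalised fold enrichment
#'
#' @param rq_ip Relative quantity in the IP sample.
#' @param rq_input Relative quantity in the input sample (> 0).
#' @return `rq_ip / rq_input`.
#' @export
fold_enrichment <- function(rq_ip, rq_input) {
  if (any(rq_input <= 0)) stop("rq_input must be > 0", call. = FALSE)
  rq_ip / rq_input
}

#' Background-subtracted occupancy
#'
#' Occupancy units are fold enrichment minus the background fold
#' enrichment of an unenriched region. Negative values are permitted
#' (they indicate de-enrichment relative to background) and are flagged
#' downstream rather than clipped.
#'
#' @param fe Fold enrichment.
#' @param background_fe Background fold enrichment (> 0; default 1, the
#'   fold enrichment of an unenriched region).
#' @return Occupancy in occupancy units.
#' @export
occupancy <- function(fe, background_fe = 1) {
  if (any(background_fe <= 0)) stop("background_fe must be > 0", call. = FALSE)
  fe - background_fe
}

#' Construct and validate a qPCR Ct table
#'
#' @param measurements Data frame with columns `region`, `sample_type`
#'   (`"IP"` or `"input"`), `condition`, `replicate`, `ct`.
#' @param control_region Name of the control region (a transcriptionally
#'   silent locus) present in `measurements`.
#' @param efficiency Amplification efficiency in `(1, 2]` (default 2),
#'   recycled over primer pairs.
#' @return Object of class `qpcr_table` (the data frame with metadata
#'   attributes).
#' @export
qpcr_table <- function(measurements, control_region, efficiency = 2) {
  need <- c("region", "sample_type", "condition", "replicate", "ct")
  if (!all(need %in% names(measurements))) {
    stop("qPCR table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(measurements$sample_type %in% c("IP", "input"))) {
    stop("sample_type must be 'IP' or 'input'", call. = FALSE)
  }
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    stop("efficiency must be in (1, 2]", call. = FALSE)
  }
  if (!control_region %in% measurements$region) {
    stop(sprintf("control region '%s' absent from table", control_region), call. = FALSE)
  }
  if (!all(is.finite(measurements$ct))) stop("non-finite Ct value", call. = FALSE)
  key <- with(measurements, interaction(region, condition, replicate, drop = TRUE))
  for (k in levels(key)) {
    st <- measurements$sample_type[key == k]
    if (!all(c("IP", "input") %in% st)) {
      stop(sprintf("missing IP/input pairing for (region, condition, replicate) = %s", k),
           call. = FALSE)
    }
  }
  structure(as.data.frame(measurements),
            control_region = control_region, efficiency = efficiency,
            class = c("qpcr_table", "data.frame"))
}

#' Read a qPCR Ct table from CSV or TSV
#'
#' @param path Path to a delimited file with columns `region`,
#'   `sample_type`, `condition`, `replicate`, `ct`.
#' @param control_region,efficiency Passed to [qpcr_table()].
#' @return A `qpcr_table`.
#' @export
read_qpcr_table <- function(path, control_region, efficiency = 2) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "")
  qpcr_table(df, control_region = control_region, efficiency = efficiency)
}

# Per-replicate fold enrichment of every non-control region.
.qpcr_fe <- function(table) {
  ctrl <- attr(table, "control_region")
  eff <- attr(table, "efficiency")
  df <- as.data.frame(table)
  out <- list()
  for (cond in unique(df$condition)) {
    dc <- df[df$condition == cond, , drop = FALSE]
    for (rep in unique(dc$replicate)) {
      dr <- dc[dc$replicate == rep, , drop = FALSE]
      ct <- function(region, type) {
        v <- dr$ct[dr$region == region & dr$sample_type == type]
        if (length(v) != 1L) {
          stop(sprintf("expected one Ct for (%s, %s, %s, replicate %s), found %d",
                       region, type, cond, rep, length(v)), call. = FALSE)
        }
        v
      }
      for (region in setdiff(unique(dr$region), ctrl)) {
        rq_ip <- relative_quantity(ct(region, "IP"), ct(ctrl, "IP"), eff)
        rq_in <- relative_quantity(ct(region, "input"), ct(ctrl, "input"), eff)
        out[[length(out) + 1L]] <- data.frame(
          region = region, condition = cond, replicate = rep,
          fe = fold_enrichment(rq_ip, rq_in), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Summarise occupancy per region and condition
#'
#' Per replicate, fold enrichment of each region is computed relative to
#' the control amplicon and normalised to input DNA; the background is
#' then subtracted. Mean and sample (n-1) standard deviation over
#' biological replicates are reported.
#'
#' @param table A [qpcr_table()].
#' @param background Either `list(constant = x)` (default
#'   `list(constant = 1)`, the fold enrichment of an unenriched region)
#'   or `list(untagged_table = <qpcr_table>)`, in which case the mean
#'   fold enrichment of the untagged-strain control is subtracted per
#'   region.
#' @return Data frame of class `occupancy_table` with columns `region`,
#'   `condition`, `occupancy_mean`, `occupancy_sd`, `n_replicates`,
#'   `any_negative`, and a `per_replicate` list column; attribute
#'   `background_mode` records the subtraction mode.
#' @export
summarize_occupancy <- function(table, background = list(constant = 1)) {
  stopifnot(inherits(table, "qpcr_table"))
  fe <- .qpcr_fe(table)
  if (!is.null(background$constant)) {
    fe$bg <- background$constant
    mode <- sprintf("constant:%g", background$constant)
  } else if (!is.null(background$untagged_table)) {
    ufe <- .qpcr_fe(background$untagged_table)
    bg_by_region <- tapply(ufe$fe, ufe$region, mean)
    if (!all(fe$region %in% names(bg_by_region))) {
      stop("untagged background table lacks some regions", call. = FALSE)
    }
    fe$bg <- as.numeric(bg_by_region[fe$region])
    mode <- "untagged_table"
  } else {
    stop("background must be list(constant=) or list(untagged_table=)", call. = FALSE)
  }
  fe$occ <- occupancy(fe$fe, fe$bg)
  keys <- unique(fe[c("region", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    v <- fe$occ[fe$region == keys$region[i] & fe$condition == keys$condition[i]]
    data.frame(region = keys$region[i], condition = keys$condition[i],
               occupancy_mean = mean(v),
               occupancy_sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n_replicates = length(v),
               any_negative = any(v < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$per_replicate <- lapply(seq_len(nrow(keys)), function(i)
    fe$occ[fe$region == keys$region[i] & fe$condition == keys$condition[i]])
  attr(out, "background_mode") <- mode
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' One-tailed two-sample t comparison of occupancy between conditions
#'
#' Student t with pooled variance and `n_a + n_b - 2` degrees of
#' freedom, one-tailed in the stated direction — the conventional
#' reading of a one-tailed t-test on a handful of biological replicates.
#'
#' @param occ_a,occ_b Numeric occupancy values per replicate (length
#'   >= 2 each).
#' @param alternative `"greater"` (a exceeds b) or `"less"`.
#' @return List with `t`, `df`, `p_value`, `alternative`.
#' @export
condition_compare <- function(occ_a, occ_b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  occ_a <- as.numeric(occ_a); occ_b <- as.numeric(occ_b)
  if (length(occ_a) < 2L || length(occ_b) < 2L) {
    stop("need at least 2 replicates per condition", call. = FALSE)
  }
  if (!all(is.finite(occ_a)) || !all(is.finite(occ_b))) {
    stop("non-finite occupancy values", call. = FALSE)
  }
  na <- length(occ_a); nb <- length(occ_b)
  sp2 <- ((na - 1) * stats::var(occ_a) + (nb - 1) * stats::var(occ_b)) / (na + nb - 2)
  if (sp2 <= 0) {
    stop(sprintf("zero pooled variance: occ_a = (%s), occ_b = (%s) carry no spread",
                 paste(format_num(occ_a), collapse = ", "),
                 paste(format_num(occ_b), collapse = ", ")), call. = FALSE)
  }
  tstat <- (mean(occ_a) - mean(occ_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- switch(alternative,
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  list(t = tstat, df = df, p_value = p, alternative = alternative)
}
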
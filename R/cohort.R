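#' @name cohort
#' @title Cohort-level PSI assembly, filtering, summaries and rankings
#'
#' @description
#' Per-sample PSI tables are assembled into an events-by-samples matrix
#' annotated with sample groups (e.g. tumor types) and tumor/normal status.
#' Events that depend on a novel (unannotated) splice are reported only
#' when that splice is sufficiently expressed in enough samples.  Group
#' summaries give per-group mean PSI over tumor samples, adjacent-normal
#' means, tumor-normal deltas, and the cross-group variance used to rank
#' events by splice variation.
NULL

#' Read a sample sheet
#'
#' Tab-delimited with columns `sample_id`, `group`, `tissue_class`
#' (`tumor` or `normal`).
#'
#' @param file Path to the sheet.
#' @return Validated `data.frame`.
#' @export
read_sample_sheet <- function(file) {
  sheet <- utils::read.delim(file, stringsAsFactors = FALSE)
  .check_sheet(sheet)
  sheet
}

.check_sheet <- function(sheet) {
  need <- c("sample_id", "group", "tissue_class")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!all(sheet$tissue_class %in% c("tumor", "normal")))
    stop("tissue_class must be 'tumor' or 'normal'")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet")
  invisible(sheet)
}

#' Assemble the events-by-samples PSI matrix
#'
#' @param tables A list of per-sample PSI tables from [psi_table()] (or one
#'   long `data.frame` with a `sample_id` column).
#' @param sample_sheet `data.frame` mapping every sample to `group` and
#'   `tissue_class`; samples present in the tables but absent from the
#'   sheet are an error.
#' @return An object of class `psi_matrix`: `values` (numeric matrix,
#'   events x samples, NA = missing), `events` (annotation, one row per
#'   event) and `samples` (annotation, one row per column).
#' @export
assemble_psi_matrix <- function(tables, sample_sheet) {
  .check_sheet(sample_sheet)
  long <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  samples <- unique(long$sample_id)
  missing <- setdiff(samples, sample_sheet$sample_id)
  if (length(missing))
    stop("sample(s) absent from sample sheet: ", paste(missing, collapse = ", "))
  events <- unique(long[, c("event_id", "symbol", "gene_id", "event_type",
                            "exons", "novel")])
  if (anyDuplicated(events$event_id))
    stop("inconsistent event annotations across samples")
  values <- matrix(NA_real_, nrow(events), length(samples),
                   dimnames = list(events$event_id, samples))
  values[cbind(match(long$event_id, events$event_id),
               match(long$sample_id, samples))] <- long$psi
  sam <- sample_sheet[match(samples, sample_sheet$sample_id), , drop = FALSE]
  rownames(events) <- rownames(sam) <- NULL
  structure(list(values = values, events = events, samples = sam),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat("psi_matrix:", nrow(x$values), "events x", ncol(x$values), "samples;",
      sum(is.na(x$values)), "missing cells\n")
  cat("  groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' Apply the cohort-level novel-splice reporting filter
#'
#' Events whose include or exclude elements contain a novel splice are kept
#' only if, in at least `min_samples` samples, the novel splice's reads make
#' up at least `min_fraction` of the event's total covering reads.  Events
#' built solely from annotated elements pass unconditionally.
#'
#' @param pm A `psi_matrix`.
#' @param events The `splice_event_list` the matrix was built from.
#' @param counts List of `sample_counts`, one per sample in the matrix.
#' @param min_fraction Minimum within-sample read share (default 0.01).
#' @param min_samples Minimum number of qualifying samples (default 10).
#' @return The filtered `psi_matrix`.
#' @export
apply_novel_event_filter <- function(pm, events, counts,
                                     min_fraction = 0.01, min_samples = 10) {
  stopifnot(inherits(pm, "psi_matrix"))
  ids <- vapply(events, `[[`, "", "event_id")
  keep <- rownames(pm$values)
  for (e in events) {
    if (!e$novel || !(e$event_id %in% keep)) next
    qualifying <- 0L
    for (ct in counts) {
      novel_ids <- ct$splices$splice_id[ct$splices$novel &
                                          ct$splices$gene_id == e$gene_id]
      nel <- intersect(c(e$include, e$exclude), novel_ids)
      nreads <- if (length(nel)) .element_reads(e$gene_id, nel, ct) else 0
      total <- .element_reads(e$gene_id, e$include, ct) +
        .element_reads(e$gene_id, e$exclude, ct)
      if (total > 0 && nreads / total >= min_fraction)
        qualifying <- qualifying + 1L
    }
    if (qualifying < min_samples) keep <- setdiff(keep, e$event_id)
  }
  sel <- rownames(pm$values) %in% keep
  pm$values <- pm$values[sel, , drop = FALSE]
  pm$events <- pm$events[sel, , drop = FALSE]
  pm
}

#' Summarize PSI by sample group
#'
#' Group means are unweighted means over non-missing tumor samples of the
#' group (all-missing groups are reported as NA with n = 0); adjacent-normal
#' means and the tumor-normal delta are reported where the group has both
#' strata.  The cross-group variance of group means drives the
#' tissue-difference ranking.
#'
#' @param pm A `psi_matrix`.
#' @return An object of class `group_summary` with `by_group` (one row per
#'   event x group) and `by_event` (cross-group variance of group means).
#' @export
summarize_groups <- function(pm) {
  stopifnot(inherits(pm, "psi_matrix"))
  groups <- unique(pm$samples$group)
  rows <- list()
  for (g in groups) {
    tum <- pm$samples$sample_id[pm$samples$group == g &
                                  pm$samples$tissue_class == "tumor"]
    nor <- pm$samples$sample_id[pm$samples$group == g &
                                  pm$samples$tissue_class == "normal"]
    vt <- pm$values[, tum, drop = FALSE]
    vn <- pm$values[, nor, drop = FALSE]
    nt <- rowSums(!is.na(vt)); nn <- rowSums(!is.na(vn))
    mt <- ifelse(nt > 0, rowMeans(vt, na.rm = TRUE), NA_real_)
    mn <- ifelse(nn > 0, rowMeans(vn, na.rm = TRUE), NA_real_)
    rows[[g]] <- data.frame(event_id = rownames(pm$values), group = g,
                            mean_psi = mt, n = nt,
                            mean_normal = mn, n_normal = nn,
                            delta = mt - mn, stringsAsFactors = FALSE)
  }
  by_group <- do.call(rbind, rows)
  rownames(by_group) <- NULL
  mmat <- vapply(groups, function(g)
    by_group$mean_psi[by_group$group == g], numeric(nrow(pm$values)))
  if (is.null(dim(mmat))) mmat <- matrix(mmat, nrow = nrow(pm$values))
  var_groups <- apply(mmat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::var(v)
  })
  by_event <- data.frame(event_id = rownames(pm$values),
                         var_groups = var_groups, stringsAsFactors = FALSE)
  structure(list(by_group = by_group, by_event = by_event, groups = groups),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group_summary:", nrow(x$by_event), "events x", length(x$groups),
      "groups\n")
  invisible(x)
}

#' Rank events by splice variation across tumor types
#'
#' Events are sorted descending by the variance of their per-group mean PSI
#' across the selected groups, ties broken by event id.
#'
#' @param summary A `group_summary` from [summarize_groups()].
#' @param groups Groups to consider (default: all with data); at least two
#'   are required.
#' @return `data.frame` of `event_id`, `variance`, `n_groups`, ordered.
#' @export
rank_tissue_difference <- function(summary, groups = NULL) {
  stopifnot(inherits(summary, "group_summary"))
  if (is.null(groups)) groups <- summary$groups
  groups <- intersect(groups, summary$groups)
  if (length(groups) < 2)
    stop("at least two selected groups with data are required")
  bg <- summary$by_group[summary$by_group$group %in% groups, , drop = FALSE]
  ids <- unique(bg$event_id)
  score <- vapply(ids, function(id) {
    v <- bg$mean_psi[bg$event_id == id]
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::var(v)
  }, 0)
  ng <- vapply(ids, function(id)
    sum(!is.na(bg$mean_psi[bg$event_id == id])), 0L)
  out <- data.frame(event_id = ids, variance = score, n_groups = ng,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$variance, out$event_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank events by tumor versus adjacent-normal shift
#'
#' The shift score of an event is, by default, the maximum over the
#' selected groups of the absolute difference between the group's tumor and
#' adjacent-normal mean PSI.
#'
#' @param summary A `group_summary`.
#' @param groups Groups to consider (default: all).
#' @param method `"max"` (default) or `"mean"` absolute per-group delta.
#' @return `data.frame` of `event_id`, `shift`, ordered descending with
#'   ties broken by event id.
#' @export
rank_tumor_normal <- function(summary, groups = NULL,
                              method = c("max", "mean")) {
  stopifnot(inherits(summary, "group_summary"))
  method <- match.arg(method)
  if (is.null(groups)) groups <- summary$groups
  groups <- intersect(groups, summary$groups)
  bg <- summary$by_group[summary$by_group$group %in% groups, , drop = FALSE]
  if (!any(bg$n > 0 & bg$n_normal > 0))
    stop("no selected group has both tumor and adjacent-normal samples")
  ids <- unique(bg$event_id)
  score <- vapply(ids, function(id) {
    d <- abs(bg$delta[bg$event_id == id])
    d <- d[!is.na(d)]
    if (!length(d)) NA_real_
    else if (method == "max") max(d) else mean(d)
  }, 0)
  out <- data.frame(event_id = ids, shift = score, stringsAsFactors = FALSE)
  out <- out[order(-out$shift, out$event_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export sample-level PSI values as a tab-delimited download
#'
#' Columns are the selected samples, headed `group|tissue_class|sample_id`;
#' cells hold PSI at full precision or NA.  Rows can be restricted to one
#' gene and/or one event type.
#'
#' @param pm A `psi_matrix`.
#' @param file Optional output path.
#' @param gene Optional gene symbol filter (unknown symbols raise an error
#'   listing near matches).
#' @param event_type Optional event-type filter (e.g. `"ME"`).
#' @param groups Optional group selection (default: all samples).
#' @return The exported `data.frame`, invisibly when `file` is given.
#' @export
export_psi_download <- function(pm, file = NULL, gene = NULL,
                                event_type = NULL, groups = NULL) {
  stopifnot(inherits(pm, "psi_matrix"))
  sel <- rep(TRUE, nrow(pm$events))
  if (!is.null(gene)) {
    if (!gene %in% pm$events$symbol) {
      near <- unique(pm$events$symbol[agrepl(gene, pm$events$symbol,
                                             ignore.case = TRUE)])
      stop("unknown gene symbol '", gene, "'",
           if (length(near)) paste0("; did you mean: ",
                                    paste(near, collapse = ", "), "?") else "")
    }
    sel <- sel & pm$events$symbol == gene
  }
  if (!is.null(event_type)) sel <- sel & pm$events$event_type %in% event_type
  cols <- if (is.null(groups)) seq_len(nrow(pm$samples)) else
    which(pm$samples$group %in% groups)
  sam <- pm$samples[cols, , drop = FALSE]
  vals <- pm$values[sel, cols, drop = FALSE]
  out <- data.frame(symbol = pm$events$symbol[sel],
                    event_id = pm$events$event_id[sel],
                    event_type = pm$events$event_type[sel],
                    exons = pm$events$exons[sel],
                    stringsAsFactors = FALSE, check.names = FALSE)
  hdr <- paste(sam$group, sam$tissue_class, sam$sample_id, sep = "|")
  for (j in seq_along(cols))
    out[[hdr[j]]] <- ifelse(is.na(vals[, j]), NA,
                            sprintf("%.17g", vals[, j]))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(out))
  }
  out
}

#' Re-import a PSI download file
#'
#' Reverses [export_psi_download()]; the reconstructed matrix is lossless
#' for PSI values written at full precision.
#'
#' @param file Path to a file written by [export_psi_download()].
#' @return A `psi_matrix` (novel flags are not recorded in the download and
#'   come back as NA).
#' @export
read_psi_download <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("symbol", "event_id", "event_type", "exons")
  samcols <- setdiff(names(df), meta)
  parts <- strsplit(samcols, "|", fixed = TRUE)
  sam <- data.frame(sample_id = vapply(parts, `[[`, "", 3),
                    group = vapply(parts, `[[`, "", 1),
                    tissue_class = vapply(parts, `[[`, "", 2),
                    stringsAsFactors = FALSE)
  values <- as.matrix(df[, samcols, drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- list(df$event_id, sam$sample_id)
  events <- data.frame(event_id = df$event_id, symbol = df$symbol,
                       gene_id = NA_character_, event_type = df$event_type,
                       exons = df$exons, novel = NA,
                       stringsAsFactors = FALSE)
  structure(list(values = values, events = events, samples = sam),
            class = "psi_matrix")
}
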
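#' @name quantify
#' @title Read counting and PSI computation
#'
#' @description
#' Reads are attributed to splice-graph elements so that each alignment
#' supports a single interpretation: a spliced alignment counts toward every
#' junction it spans with at least `min_anchor` aligned bases on both sides;
#' an unspliced alignment counts toward every exon part it overlaps by at
#' least `min_anchor` bases.  Percent Spliced In for an event is the sum of
#' raw counts over its include elements divided by the total over include
#' plus exclude elements, reported only when that total reaches
#' `min_coverage` (default 8) reads.
NULL

# SAM input is converted (sorted + indexed) via samtools through Rsamtools;
# BAM input must already be coordinate-sorted.
.prepare_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE))
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
  hd <- hdr[names(hdr) == "@HD"]
  if (length(hd)) {
    so <- grep("^SO:", hd[[1]], value = TRUE)
    if (length(so) && so != "SO:coordinate")
      stop("alignments are not coordinate-sorted; run 'samtools sort' ",
           "and 'samtools index' first")
  }
  path
}

.primary_flag <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE)
}

# load primary alignments once: unspliced read intervals and anchored
# junctions, plus the sample-wide aligned-read total
.load_alignments <- function(path, min_anchor) {
  bam <- .prepare_bam(path)
  param <- Rsamtools::ScanBamParam(flag = .primary_flag())
  total <- Rsamtools::countBam(bam, param = param)$records
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  nj <- GenomicAlignments::njunc(ga)
  chrom <- as.character(GenomeInfoDb::seqnames(ga))
  us <- which(nj == 0)
  unspliced <- data.frame(chrom = chrom[us],
                          start = BiocGenerics::start(ga)[us],
                          end = BiocGenerics::end(ga)[us],
                          stringsAsFactors = FALSE)
  sp <- which(nj > 0)
  if (length(sp)) {
    jl <- GenomicAlignments::junctions(ga[sp])
    bl <- GenomicAlignments::grglist(ga[sp])
    wl <- lapply(seq_along(bl), function(i) BiocGenerics::width(bl[[i]]))
    leftw <- unlist(lapply(wl, function(w) w[-length(w)]))
    rightw <- unlist(lapply(wl, function(w) w[-1]))
    ju <- BiocGenerics::unlist(jl)
    junc <- data.frame(chrom = rep(chrom[sp], nj[sp]),
                       jstart = BiocGenerics::start(ju) - 1,  # 0-based intron
                       jend = BiocGenerics::end(ju),
                       anchored = leftw >= min_anchor & rightw >= min_anchor,
                       stringsAsFactors = FALSE)
  } else {
    junc <- data.frame(chrom = character(), jstart = numeric(),
                       jend = numeric(), anchored = logical())
  }
  list(total = total, unspliced = unspliced, junctions = junc)
}

#' Count exon-body and junction reads on splice graphs
#'
#' @param alignments Path to a coordinate-sorted SAM or BAM file of spliced,
#'   genome-aligned reads.  SAM input is converted on the fly.
#' @param graphs A `splice_graph` or list of them.
#' @param min_anchor Minimum aligned bases required on each side of a
#'   junction, and minimum overlap for an exon-body read (default 4).
#' @param sample_id Sample label stored with the counts; defaults to the
#'   file name.
#' @return A `sample_counts` object: raw per-part and per-splice counts,
#'   the sample-wide number of primary aligned reads, and (after
#'   [normalize_counts()]) normalized observation values.
#' @export
count_reads <- function(alignments, graphs, min_anchor = 4, sample_id = NULL) {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  if (is.null(sample_id))
    sample_id <- sub("\\.(sam|bam)$", "", basename(alignments),
                     ignore.case = TRUE)
  al <- .load_alignments(alignments, min_anchor)
  parts_l <- list(); spl_l <- list()
  for (g in graphs) {
    p <- g$parts
    us <- al$unspliced[al$unspliced$chrom == g$chrom, , drop = FALSE]
    praw <- integer(nrow(p))
    if (nrow(us)) {
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(p$start + 1, p$end),
        IRanges::IRanges(us$start, us$end),
        minoverlap = min_anchor)
      tab <- table(S4Vectors::queryHits(hits))
      praw[as.integer(names(tab))] <- as.integer(tab)
    }
    parts_l[[length(parts_l) + 1]] <-
      data.frame(gene_id = g$gene_id, part_id = p$part_id,
                 length = p$length, raw = praw, obs = NA_real_,
                 stringsAsFactors = FALSE)
    s <- g$splices
    sraw <- integer(nrow(s))
    jc <- al$junctions[al$junctions$chrom == g$chrom & al$junctions$anchored, ,
                       drop = FALSE]
    if (nrow(s) && nrow(jc)) {
      m <- match(paste(jc$jstart, jc$jend), paste(s$intron_start, s$intron_end))
      tab <- table(m[!is.na(m)])
      sraw[as.integer(names(tab))] <- as.integer(tab)
    }
    spl_l[[length(spl_l) + 1]] <-
      data.frame(gene_id = g$gene_id, splice_id = s$splice_id,
                 from = s$from, to = s$to,
                 intron_start = s$intron_start, intron_end = s$intron_end,
                 novel = s$novel, raw = sraw, obs = NA_real_,
                 stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id,
                 total_aligned_reads = al$total,
                 parts = do.call(rbind, parts_l),
                 splices = do.call(rbind, spl_l),
                 min_anchor = min_anchor,
                 normalized = FALSE),
            class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("sample_counts for", x$sample_id, "-", x$total_aligned_reads,
      "aligned reads\n ", nrow(x$parts), "parts (", sum(x$parts$raw),
      "reads ),", nrow(x$splices), "splices (", sum(x$splices$raw),
      "reads )\n")
  invisible(x)
}

#' Normalize raw counts by exon length and sequencing depth
#'
#' Exon-part observations are reads per 1000 bases of exon per million
#' aligned reads; junction observations are reads per million aligned reads
#' (junctions have no length term).
#'
#' @param counts A `sample_counts` object.
#' @return The object with `obs` columns filled.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "sample_counts"))
  M <- counts$total_aligned_reads
  if (M <= 0) stop("sample has no aligned reads; cannot normalize")
  counts$parts$obs <- counts$parts$raw / (counts$parts$length / 1000) / (M / 1e6)
  counts$splices$obs <- counts$splices$raw / (M / 1e6)
  counts$normalized <- TRUE
  counts
}

#' Export per-sample element counts
#'
#' @param counts A `sample_counts` object (normalized or not).
#' @param file Optional tab-delimited output path.
#' @return Long-format `data.frame`: gene, element class, element id, raw
#'   count and normalized observation.
#' @export
export_counts_table <- function(counts, file = NULL) {
  out <- rbind(
    data.frame(gene_id = counts$parts$gene_id, element = "part",
               id = counts$parts$part_id, raw = counts$parts$raw,
               obs = counts$parts$obs, stringsAsFactors = FALSE),
    data.frame(gene_id = counts$splices$gene_id, element = "splice",
               id = counts$splices$splice_id, raw = counts$splices$raw,
               obs = counts$splices$obs, stringsAsFactors = FALSE))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Discover unannotated junctions and add them to the splice graph
#'
#' Spliced alignments whose junctions are absent from the annotation-derived
#' graph are added as novel splices when both junction endpoints fall on
#' existing exon-part boundaries or strictly inside existing parts (in which
#' case the part is split).  Junctions with either end outside all known
#' exonic territory are discarded: novel exons are never inferred.
#'
#' @inheritParams count_reads
#' @param min_reads Minimum anchored junction reads supporting a candidate
#'   (default 1).
#' @return The augmented `splice_graph` (or list of graphs).
#' @export
discover_novel_junctions <- function(alignments, graphs, min_anchor = 4,
                                     min_reads = 1) {
  single <- inherits(graphs, "splice_graph")
  if (single) graphs <- list(graphs)
  al <- .load_alignments(alignments, min_anchor)
  out <- lapply(graphs, function(g) {
    jc <- al$junctions[al$junctions$chrom == g$chrom & al$junctions$anchored, ,
                       drop = FALSE]
    if (!nrow(jc)) return(g)
    key <- paste(jc$jstart, jc$jend)
    tab <- table(key)
    cand <- do.call(rbind, lapply(names(tab[tab >= min_reads]), function(k) {
      as.numeric(strsplit(k, " ")[[1]])
    }))
    known <- paste(g$splices$intron_start, g$splices$intron_end)
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% known), , drop = FALSE]
    if (!nrow(cand)) return(g)
    p <- g$parts
    in_part <- function(pos) any(p$start <= pos & p$end > pos)
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      in_part(cand[i, 1] - 1) && in_part(cand[i, 2])
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) return(g)
    .augment_graph(g, cand)
  })
  if (single) out[[1]] else out
}

# re-fragment the graph at novel junction endpoints and re-attach all novel
# splices (previous and new) to the refreshed part labels
.augment_graph <- function(graph, new_introns) {
  old_novel <- graph$splices[graph$splices$novel, c("intron_start", "intron_end"),
                             drop = FALSE]
  introns <- unique(rbind(as.matrix(old_novel),
                          matrix(new_introns, ncol = 2)))
  bounds <- sort(unique(c(graph$extra_boundaries, introns[, 1], introns[, 2])))
  g2 <- build_splice_graph(graph$transcripts, extra_boundaries = bounds)
  p <- g2$parts
  for (i in seq_len(nrow(introns))) {
    is0 <- introns[i, 1]; ie0 <- introns[i, 2]
    if (g2$strand == "+") {
      from <- p$part_id[p$end == is0]; to <- p$part_id[p$start == ie0]
      donor <- is0; acceptor <- ie0
    } else {
      from <- p$part_id[p$start == ie0]; to <- p$part_id[p$end == is0]
      donor <- ie0; acceptor <- is0
    }
    if (!length(from) || !length(to)) next
    if (paste0(from, "->", to) %in% g2$splices$splice_id) next
    g2$splices <- rbind(g2$splices,
                        data.frame(from = from, to = to,
                                   intron_start = is0, intron_end = ie0,
                                   donor_pos = donor, acceptor_pos = acceptor,
                                   novel = TRUE,
                                   splice_id = paste0(from, "->", to),
                                   stringsAsFactors = FALSE))
  }
  g2$splices <- .finish_splices(g2$splices[, setdiff(names(g2$splices),
                                                     "splice_id")], p)
  g2
}

#' Compute Percent Spliced In for one event in one sample
#'
#' PSI is the ratio of reads evidencing the presence of the transcript
#' element (`include` elements) to the total reads covering the event.  The
#' value is withheld (NA) unless include plus exclude reads reach
#' `min_coverage`.
#'
#' @param event A `splice_event`.
#' @param counts A `sample_counts` object covering the event's gene.
#' @param min_coverage Minimum covering reads for a reported PSI (default 8).
#' @return A `psi_value`: event id, sample id, psi (or NA), include,
#'   exclude and total read counts.
#' @export
compute_psi <- function(event, counts, min_coverage = 8) {
  stopifnot(inherits(event, "splice_event"), inherits(counts, "sample_counts"))
  inc <- .element_reads(event$gene_id, event$include, counts)
  exc <- .element_reads(event$gene_id, event$exclude, counts)
  total <- inc + exc
  structure(list(event_id = event$event_id, sample_id = counts$sample_id,
                 psi = if (total >= min_coverage) inc / total else NA_real_,
                 include_reads = inc, exclude_reads = exc,
                 total_reads = total),
            class = "psi_value")
}

.element_reads <- function(gene_id, elements, counts) {
  is_splice <- grepl("->", elements, fixed = TRUE)
  total <- 0L
  if (any(is_splice)) {
    s <- counts$splices[counts$splices$gene_id == gene_id, , drop = FALSE]
    m <- match(elements[is_splice], s$splice_id)
    if (anyNA(m)) stop("unknown splice element(s): ",
                       paste(elements[is_splice][is.na(m)], collapse = ", "))
    total <- total + sum(s$raw[m])
  }
  if (any(!is_splice)) {
    p <- counts$parts[counts$parts$gene_id == gene_id, , drop = FALSE]
    m <- match(elements[!is_splice], p$part_id)
    if (anyNA(m)) stop("unknown part element(s): ",
                       paste(elements[!is_splice][is.na(m)], collapse = ", "))
    total <- total + sum(p$raw[m])
  }
  total
}

#' @export
print.psi_value <- function(x, ...) {
  cat(sprintf("psi_value %s @ %s: psi=%s (include=%d exclude=%d)\n",
              x$event_id, x$sample_id,
              ifelse(is.na(x$psi), "NA", format(x$psi)),
              x$include_reads, x$exclude_reads))
  invisible(x)
}

#' Per-sample PSI table over an event catalog
#'
#' @param events A `splice_event_list` (or list of them, one per gene).
#' @param counts A `sample_counts` object.
#' @param min_coverage Minimum covering reads for a reported PSI (default 8).
#' @return `data.frame` with one row per event: identifiers, psi (NA when
#'   coverage is insufficient) and the include/exclude/total read counts.
#' @export
psi_table <- function(events, counts, min_coverage = 8) {
  if (!inherits(events, "splice_event_list"))
    events <- structure(do.call(c, lapply(events, unclass)),
                        class = "splice_event_list")
  rows <- lapply(events, function(e) {
    pv <- compute_psi(e, counts, min_coverage)
    data.frame(event_id = e$event_id, symbol = e$gene_symbol,
               gene_id = e$gene_id, event_type = e$event_type,
               exons = e$exons, novel = e$novel,
               sample_id = counts$sample_id, psi = pv$psi,
               include_reads = pv$include_reads,
               exclude_reads = pv$exclude_reads,
               total_reads = pv$total_reads, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(), symbol = character(),
               gene_id = character(), event_type = character(),
               exons = character(), novel = logical(),
               sample_id = character(), psi = numeric(),
               include_reads = integer(), exclude_reads = integer(),
               total_reads = integer())
  rownames(out) <- NULL
  out
}
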
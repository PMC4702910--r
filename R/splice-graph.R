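#' Construct a transcript model
#'
#' A `transcript_model` holds one transcript's exon (and optionally CDS)
#' structure.  Coordinates are stored 0-based half-open internally; the GTF
#' reader and all exported tables convert to/from the 1-based inclusive
#' convention at the I/O boundary.
#'
#' @param transcript_id,gene_id,gene_symbol Identifier strings.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon `start`,`end`
#'   coordinates, 0-based half-open, sorted by genomic position and
#'   non-overlapping.  Bookended intervals are merged.
#' @param cds Optional CDS intervals in the same convention; each must be
#'   contained in an exon.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_symbol = gene_id,
                             chrom, strand = c("+", "-"),
                             exons, cds = NULL) {
  strand <- match.arg(strand)
  exons <- .as_intervals(exons, "exons")
  exons <- .merge_bookended(exons)
  if (any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("exon intervals of transcript ", transcript_id, " overlap")
  if (!is.null(cds) && nrow(cds <- .as_intervals(cds, "cds"))) {
    cds <- .merge_bookended(cds)
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1] <= cds[i, 1] & exons[, 2] >= cds[i, 2])
    }, logical(1))
    if (!all(inside))
      stop("CDS interval outside exons for transcript ", transcript_id)
  } else {
    cds <- matrix(numeric(0), ncol = 2)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_symbol = gene_symbol, chrom = chrom, strand = strand,
                 exons = exons, cds = cds),
            class = "transcript_model")
}

.as_intervals <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop(what, " must have two columns (start, end)")
  storage.mode(x) <- "double"
  if (nrow(x)) {
    x <- x[order(x[, 1]), , drop = FALSE]
    if (any(x[, 2] <= x[, 1])) stop(what, " contain an empty interval")
  }
  dimnames(x) <- list(NULL, c("start", "end"))
  x
}

.merge_bookended <- function(x) {
  if (nrow(x) < 2) return(x)
  out <- x[1, , drop = FALSE]
  for (i in 2:nrow(x)) {
    if (x[i, 1] <= out[nrow(out), 2]) out[nrow(out), 2] <- max(out[nrow(out), 2], x[i, 2])
    else out <- rbind(out, x[i, , drop = FALSE])
  }
  out
}

#' Read gene models from a GTF file
#'
#' Parses exon and CDS features into [transcript_model] objects.  By default
#' only protein-coding transcripts (those carrying at least one CDS feature)
#' are kept, matching the scope of coding-gene splice analysis.  Transcripts
#' whose exons disagree on chromosome or strand (e.g. trans-spliced
#' annotations) are rejected with a warning.
#'
#' @param gtf Path to a GTF file with `gene_id`, `transcript_id` and
#'   (optionally) `gene_name` attributes.
#' @param coding_only Drop transcripts without CDS features (default `TRUE`).
#' @return Named list of [transcript_model] objects (names = transcript ids).
#' @export
read_gene_models <- function(gtf, coding_only = TRUE) {
  if (!file.exists(gtf)) stop("GTF file not found: ", gtf)
  lines <- readLines(gtf)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- vapply(strsplit(lines[data_idx], "\t", fixed = TRUE), length, 0L)
  if (any(nfield < 9))
    stop("malformed GTF line ", data_idx[which(nfield < 9)[1]],
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(gtf, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (!length(gr)) return(list())
  sym <- if ("gene_name" %in% names(meta)) meta$gene_name else meta$gene_id
  sym <- ifelse(is.na(sym), meta$gene_id, sym)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,   # to 0-based half-open
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = as.character(meta$type),
                   gene_id = meta$gene_id,
                   transcript_id = meta$transcript_id,
                   gene_symbol = sym,
                   stringsAsFactors = FALSE)
  out <- list()
  for (tx in unique(df$transcript_id)) {
    d <- df[df$transcript_id == tx, , drop = FALSE]
    if (length(unique(d$chrom)) > 1 || length(unique(d$strand)) > 1 ||
        !all(d$strand %in% c("+", "-"))) {
      warning("transcript ", tx, " has inconsistent chromosome/strand; skipped")
      next
    }
    ex <- d[d$type == "exon", c("start", "end"), drop = FALSE]
    cd <- d[d$type == "CDS", c("start", "end"), drop = FALSE]
    if (!nrow(ex)) {
      warning("transcript ", tx, " has no exon features; skipped")
      next
    }
    if (coding_only && !nrow(cd)) next
    out[[tx]] <- transcript_model(tx, d$gene_id[1], d$gene_symbol[1],
                                  d$chrom[1], d$strand[1], ex,
                                  if (nrow(cd)) cd else NULL)
  }
  out
}

#' Build the unified splice graph of one gene
#'
#' Exon intervals from all transcripts are fragmented at every distinct
#' transcript boundary (donor, acceptor, transcript start/end) so that
#' overlapping exon variants resolve into shared and private *exon parts*:
#' every genomic base covered by any transcript exon lies in exactly one
#' part.  Splices are derived from each transcript's consecutive exon pairs;
#' each transcript's exon set is exactly recoverable from its path through
#' the parts.
#'
#' @param transcripts List of [transcript_model] objects for one gene (same
#'   `gene_id`, chromosome and strand).
#' @param extra_boundaries Optional additional genomic positions (0-based) at
#'   which to fragment parts; used when unannotated junctions fall inside
#'   annotated exons.
#' @return An object of class `splice_graph` with elements `parts` (one row
#'   per exon part, transcription order), `splices`, `transcript_paths`, and
#'   the input `transcripts` (kept so the graph can be re-fragmented).
#' @export
build_splice_graph <- function(transcripts, extra_boundaries = numeric()) {
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  if (!length(transcripts)) stop("no transcripts supplied")
  gid <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  if (length(gid) != 1)
    stop("transcripts belong to multiple genes: ", paste(gid, collapse = ", "))
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chrom) != 1) stop("transcripts of ", gid, " span multiple chromosomes")
  if (length(strand) != 1) stop("transcripts of ", gid, " are on mixed strands")
  sym <- transcripts[[1]]$gene_symbol

  exon_list <- lapply(transcripts, `[[`, "exons")
  bounds <- sort(unique(c(unlist(lapply(exon_list, as.numeric)), extra_boundaries)))
  seg <- cbind(start = bounds[-length(bounds)], end = bounds[-1])
  covered <- vapply(seq_len(nrow(seg)), function(i) {
    any(vapply(exon_list, function(e)
      any(e[, 1] <= seg[i, 1] & e[, 2] >= seg[i, 2]), logical(1)))
  }, logical(1))
  seg <- seg[covered, , drop = FALSE]
  if (!nrow(seg)) stop("gene ", gid, " has no exonic territory")

  cds_all <- do.call(rbind, lapply(transcripts, `[[`, "cds"))
  coding <- vapply(seq_len(nrow(seg)), function(i) {
    !is.null(cds_all) && nrow(cds_all) > 0 &&
      any(cds_all[, 1] < seg[i, 2] & cds_all[, 2] > seg[i, 1])
  }, logical(1))

  parts <- data.frame(start = seg[, 1], end = seg[, 2],
                      length = seg[, 2] - seg[, 1],
                      coding = coding, novel = FALSE,
                      stringsAsFactors = FALSE)
  parts <- .label_parts(parts, strand)

  # transcript paths: parts contained in a transcript's exons, transcription order
  paths <- lapply(transcripts, function(t) {
    inside <- vapply(seq_len(nrow(parts)), function(i) {
      any(t$exons[, 1] <= parts$start[i] & t$exons[, 2] >= parts$end[i])
    }, logical(1))
    parts$part_id[inside]                 # parts already in transcription order
  })
  names(paths) <- vapply(transcripts, `[[`, "", "transcript_id")

  # splices from consecutive exon pairs in transcription order
  sp <- list()
  for (t in transcripts) {
    ex <- t$exons
    ord <- if (strand == "+") order(ex[, 1]) else order(-ex[, 1])
    ex <- ex[ord, , drop = FALSE]
    if (nrow(ex) < 2) next
    for (i in seq_len(nrow(ex) - 1)) {
      up <- ex[i, ]; dn <- ex[i + 1, ]
      if (strand == "+") {
        intron <- c(up[2], dn[1])
        from <- parts$part_id[parts$end == up[2]]
        to <- parts$part_id[parts$start == dn[1]]
        donor <- intron[1]; acceptor <- intron[2]
      } else {
        intron <- c(dn[2], up[1])
        from <- parts$part_id[parts$start == up[1]]
        to <- parts$part_id[parts$end == dn[2]]
        donor <- intron[2]; acceptor <- intron[1]
      }
      sp[[length(sp) + 1]] <- data.frame(
        from = from, to = to, intron_start = intron[1], intron_end = intron[2],
        donor_pos = donor, acceptor_pos = acceptor, novel = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  splices <- if (length(sp)) unique(do.call(rbind, sp)) else
    data.frame(from = character(), to = character(), intron_start = numeric(),
               intron_end = numeric(), donor_pos = numeric(),
               acceptor_pos = numeric(), novel = logical())
  splices <- .finish_splices(splices, parts)

  g <- structure(list(gene_id = gid, gene_symbol = sym, chrom = chrom,
                      strand = strand, parts = parts, splices = splices,
                      transcript_paths = paths, transcripts = transcripts,
                      extra_boundaries = sort(unique(extra_boundaries))),
                 class = "splice_graph")
  number_exons(g)
}

.finish_splices <- function(splices, parts) {
  if (nrow(splices)) {
    splices$splice_id <- paste0(splices$from, "->", splices$to)
    tx <- match(splices$from, parts$part_id)
    splices <- splices[order(tx, splices$intron_end - splices$intron_start), ,
                       drop = FALSE]
    rownames(splices) <- NULL
  } else splices$splice_id <- character(0)
  splices
}

# assign part labels N / N.k: regions are maximal genomically contiguous runs,
# numbered in transcription order; sub-parts numbered in transcription order.
.label_parts <- function(parts, strand) {
  parts <- parts[order(parts$start), , drop = FALSE]
  n <- nrow(parts)
  brk <- c(TRUE, parts$start[-1] != parts$end[-n])
  region_g <- cumsum(brk)                      # genomic region index
  nreg <- max(region_g)
  if (strand == "+") {
    region <- region_g
    ord <- order(parts$start)
  } else {
    region <- nreg - region_g + 1L
    ord <- order(-parts$start)
  }
  sub <- integer(n)
  for (r in unique(region_g)) {
    idx <- which(region_g == r)
    if (strand == "-") idx <- rev(idx)
    sub[idx] <- seq_along(idx)
  }
  size <- as.vector(table(region_g)[as.character(region_g)])
  parts$region <- region
  parts$part_id <- ifelse(size == 1, as.character(region),
                          paste0(region, ".", sub))
  parts <- parts[ord, , drop = FALSE]          # transcription order
  rownames(parts) <- NULL
  parts[, c("part_id", "region", "start", "end", "length", "coding", "novel")]
}

#' (Re)number the exon parts of a splice graph
#'
#' Exon ordinals are assigned in transcription order (reverse genomic order
#' on the minus strand); contiguous parts arising from one exonic region
#' share an ordinal and receive sub-labels `N.1`, `N.2`, ... in transcription
#' order.  Idempotent: graphs built by [build_splice_graph()] are already
#' numbered.
#'
#' @param graph A `splice_graph`.
#' @return The graph with refreshed part labels (splices and transcript
#'   paths remapped accordingly).
#' @export
number_exons <- function(graph) {
  stopifnot(inherits(graph, "splice_graph"))
  old <- graph$parts
  new <- .label_parts(old[, c("start", "end", "length", "coding", "novel")],
                      graph$strand)
  map <- new$part_id[match(old$start, new$start)]
  names(map) <- old$part_id
  graph$parts <- new
  if (nrow(graph$splices)) {
    graph$splices$from <- unname(map[graph$splices$from])
    graph$splices$to <- unname(map[graph$splices$to])
    graph$splices$splice_id <- paste0(graph$splices$from, "->", graph$splices$to)
  }
  graph$transcript_paths <- lapply(graph$transcript_paths,
                                   function(p) unname(map[p]))
  graph
}

#' Build splice graphs for every gene in a set of transcript models
#'
#' @param models List of [transcript_model] objects (as returned by
#'   [read_gene_models()]), possibly spanning many genes.
#' @return Named list of `splice_graph` objects, one per `gene_id`.
#' @export
build_splice_graphs <- function(models) {
  gid <- vapply(models, `[[`, "", "gene_id")
  lapply(split(models, gid), build_splice_graph)
}

#' @export
print.splice_graph <- function(x, ...) {
  cat("splice_graph:", x$gene_symbol, sprintf("(%s)", x$gene_id),
      "on", x$chrom, x$strand, "\n")
  cat(" ", nrow(x$parts), "exon parts,", nrow(x$splices), "splices (",
      sum(x$splices$novel), "novel ),", length(x$transcript_paths),
      "transcripts\n")
  invisible(x)
}

#' Export the exon-part coordinate reference table
#'
#' One row per exon part with 1-based inclusive genomic coordinates, for
#' cross-referencing part labels against other gene models or exon-naming
#' schemes.
#'
#' @param graphs A `splice_graph` or list of them.
#' @param file Optional path; when given the table is written tab-delimited.
#' @return The reference `data.frame`, invisibly when `file` is given.
#' @export
export_exon_reference <- function(graphs, file = NULL) {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  out <- do.call(rbind, lapply(graphs, function(g) {
    data.frame(symbol = g$gene_symbol, part_id = g$parts$part_id,
               chrom = g$chrom, start = g$parts$start + 1, end = g$parts$end,
               strand = g$strand, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Serialize splice graphs as JSON-lines
#'
#' One gene per line, round-trippable with [read_splice_graphs()].
#'
#' @param graphs A `splice_graph` or list of them.
#' @param path Output file path.
#' @export
write_splice_graphs <- function(graphs, path) {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in graphs) {
    rec <- list(gene_id = g$gene_id, gene_symbol = g$gene_symbol,
                chrom = g$chrom, strand = g$strand,
                parts = g$parts, splices = g$splices,
                transcript_paths = g$transcript_paths,
                extra_boundaries = g$extra_boundaries,
                transcripts = lapply(g$transcripts, function(t)
                  list(transcript_id = t$transcript_id, gene_id = t$gene_id,
                       gene_symbol = t$gene_symbol, chrom = t$chrom,
                       strand = t$strand,
                       exons = unclass(t$exons), cds = unclass(t$cds))))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read splice graphs from a JSON-lines file
#'
#' @param path File written by [write_splice_graphs()].
#' @return Named list of `splice_graph` objects.
#' @export
read_splice_graphs <- function(path) {
  lines <- readLines(path)
  df_of <- function(recs, template) {
    if (!length(recs)) return(template)
    out <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r[names(template)], stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  }
  part_tpl <- data.frame(part_id = character(), region = integer(),
                         start = numeric(), end = numeric(),
                         length = numeric(), coding = logical(),
                         novel = logical())
  spl_tpl <- data.frame(from = character(), to = character(),
                        intron_start = numeric(), intron_end = numeric(),
                        donor_pos = numeric(), acceptor_pos = numeric(),
                        novel = logical(), splice_id = character())
  out <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    txs <- lapply(rec$transcripts, function(t) {
      as_mat <- function(x) if (!length(x)) NULL else
        do.call(rbind, lapply(x, as.numeric))
      transcript_model(t$transcript_id, t$gene_id, t$gene_symbol, t$chrom,
                       t$strand, as_mat(t$exons), as_mat(t$cds))
    })
    paths <- lapply(rec$transcript_paths, function(p)
      vapply(p, as.character, ""))
    structure(list(gene_id = rec$gene_id, gene_symbol = rec$gene_symbol,
                   chrom = rec$chrom, strand = rec$strand,
                   parts = df_of(rec$parts, part_tpl),
                   splices = df_of(rec$splices, spl_tpl),
                   transcript_paths = paths,
                   transcripts = txs,
                   extra_boundaries = as.numeric(unlist(rec$extra_boundaries))),
              class = "splice_graph")
  })
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Flip the reading direction of transcript models
#'
#' Keeps every genomic interval in place but swaps the strand, i.e. reads
#' the same geometry in the opposite transcription direction.  Useful for
#' strand-symmetry checks: flipping maps alternate donors to alternate
#' acceptors, alternate first exons to alternate last exons, and vice
#' versa, while preserving exon-skip, retained-intron and
#' mutually-exclusive topologies.
#'
#' @param transcripts List of [transcript_model] objects.
#' @return The same models with opposite strand.
#' @export
reflect_transcripts <- function(transcripts) {
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  lapply(transcripts, function(t) {
    transcript_model(t$transcript_id, t$gene_id, t$gene_symbol, t$chrom,
                     if (t$strand == "+") "-" else "+", t$exons, t$cds)
  })
}
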
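#' @name fixtures
#' @title Synthetic gene models and spliced reads with known truth
#'
#' @description
#' The fixture generator builds a gene whose splice graph contains exactly a
#' requested set of alternative-splicing patterns, realized by two isoforms
#' (`A` and `B`), and simulates error-free, uniquely-mappable spliced reads
#' from a known isoform mixture.  Alongside the SAM records it emits a
#' truth table of exact per-element counts (computed by independent
#' transcript-coordinate bookkeeping) and the true inclusion fraction of
#' each event, so every downstream module can be validated without any
#' external data.
NULL

#' Define a fixture gene recipe
#'
#' @param events Character vector of event patterns to engineer, from
#'   `ES`, `AD`, `AA`, `RI`, `ME`, `AT`, `AL`.  Internal patterns may be
#'   repeated; `AT`/`AL` at most once each.  Empty vector gives a
#'   single-transcript gene with no events.
#' @param mixture Named fractions for isoforms `A` and `B`, summing to 1.
#' @param depth Expected number of anchored reads covering each splice
#'   junction at mixture fraction 1 (scales the total read count).
#' @param read_length Read length in bases.
#' @param seed Default random seed for [simulate_reads()].
#' @param exon_length,intron_length,ext_length Geometry in bases; exon and
#'   extension lengths must be at least `read_length` so exon-body reads are
#'   feasible.
#' @param gene_id,gene_symbol,chrom,strand Gene identity and placement.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(events = character(),
                         mixture = c(A = 0.5, B = 0.5),
                         depth = 100, read_length = 50, seed = 1,
                         exon_length = 100, intron_length = 100,
                         ext_length = 60,
                         gene_id = "GENE1", gene_symbol = gene_id,
                         chrom = "chrS", strand = c("+", "-")) {
  strand <- match.arg(strand)
  bad <- setdiff(events, c("ES", "AD", "AA", "RI", "ME", "AT", "AL"))
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  if (sum(events == "AT") > 1 || sum(events == "AL") > 1)
    stop("AT and AL patterns can appear at most once")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  if (!all(c("A", "B") %in% names(mixture)))
    stop("mixture must name isoforms A and B")
  if (exon_length < read_length || ext_length < read_length)
    stop("exon and extension lengths must be >= read_length")
  structure(list(events = events, mixture = mixture, depth = depth,
                 read_length = read_length, seed = seed,
                 exon_length = exon_length, intron_length = intron_length,
                 ext_length = ext_length, gene_id = gene_id,
                 gene_symbol = gene_symbol, chrom = chrom, strand = strand),
            class = "fixture_spec")
}

#' Generate a gene model realizing a fixture recipe
#'
#' Lays the requested patterns along the gene in transcription order with a
#' shared linker exon between consecutive patterns, builds two transcripts
#' (`A` carries the inclusion/long/first form of each internal pattern), and
#' renders GTF content.  On the minus strand the geometry is reflected so
#' transcription-relative semantics are preserved.  By default the
#' resulting splice graph is verified to yield exactly the requested event
#' pattern counts.
#'
#' @param spec A [fixture_spec].
#' @param verify Cross-check the detected event catalog against the recipe.
#' @return An object of class `fixture_model`: the transcripts, built
#'   `splice_graph`, GTF lines, chromosome length, and per-event truth
#'   (include-form isoform and true inclusion fraction).
#' @export
generate_gene_model <- function(spec, verify = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  E <- spec$exon_length; I <- spec$intron_length; X <- spec$ext_length
  has_AT <- "AT" %in% spec$events
  has_AL <- "AL" %in% spec$events
  internal <- spec$events[!spec$events %in% c("AT", "AL")]

  A <- list(); B <- list(); cur <- 0
  truth <- list()
  push <- function(iso, s, e) {
    if (iso == "A") A[[length(A) + 1]] <<- c(s, e)
    else B[[length(B) + 1]] <<- c(s, e)
  }
  note <- function(type, include_tx)
    truth[[length(truth) + 1]] <<- data.frame(
      type = type, include_tx = include_tx,
      p_include = unname(spec$mixture[include_tx]),
      stringsAsFactors = FALSE)

  if (length(spec$events) == 0) {
    for (k in 1:3) { push("A", cur, cur + E); cur <- cur + E + I }
    B <- NULL
  } else {
    if (has_AT) {
      push("A", cur, cur + E)
      push("B", cur + E + I, cur + 2 * E + I)
      cur <- cur + 2 * E + 2 * I
      note("AT", "B")              # canonical = transcription-first = A's
    }
    push("A", cur, cur + E); push("B", cur, cur + E)   # linker
    cur <- cur + E + I
    for (ev in internal) {
      switch(ev,
        ES = { push("A", cur, cur + E); cur <- cur + E + I
               note("ES", "A") },
        AD = { push("A", cur, cur + E + X); push("B", cur, cur + E)
               cur <- cur + E + X + I
               note("AD", "A") },
        AA = { push("A", cur, cur + X + E); push("B", cur + X, cur + X + E)
               cur <- cur + X + E + I
               note("AA", "A") },
        RI = { push("A", cur, cur + E); push("A", cur + E + I, cur + 2 * E + I)
               push("B", cur, cur + 2 * E + I)
               cur <- cur + 2 * E + 2 * I
               note("RI", "B") },
        ME = { push("A", cur, cur + E)
               push("B", cur + E + I, cur + 2 * E + I)
               cur <- cur + 2 * E + 2 * I
               note("ME", "A") })
      push("A", cur, cur + E); push("B", cur, cur + E)  # linker
      cur <- cur + E + I
    }
    if (has_AL) {
      push("A", cur, cur + E)
      push("B", cur + E + I, cur + 2 * E + I)
      cur <- cur + 2 * E + 2 * I
      note("AL", "A")              # canonical = transcription-last = B's
    }
  }
  span <- cur
  chrom_len <- span + 1000

  finish_tx <- function(ex_list, id) {
    ex <- do.call(rbind, ex_list)
    # CDS: trim 30 bases from the transcription start of the first exon and
    # the transcription end of the last exon (UTR stubs)
    cds <- ex
    n <- nrow(cds)
    cds[1, 1] <- cds[1, 1] + 30
    cds[n, 2] <- cds[n, 2] - 30
    if (spec$strand == "-") {
      ex <- cbind(span - ex[, 2], span - ex[, 1])
      cds <- cbind(span - cds[, 2], span - cds[, 1])
    }
    transcript_model(id, spec$gene_id, spec$gene_symbol, spec$chrom,
                     spec$strand, ex, cds)
  }
  txs <- list(A = finish_tx(A, paste0(spec$gene_id, ".A")))
  if (!is.null(B) && length(B))
    txs$B <- finish_tx(B, paste0(spec$gene_id, ".B"))

  graph <- build_splice_graph(unname(txs))
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(), include_tx = character(),
               p_include = numeric())

  if (verify) {
    got <- table(vapply(detect_events(graph), `[[`, "", "event_type"))
    want <- table(spec$events)
    if (!identical(sort(names(got)), sort(names(want))) ||
        !all(as.integer(got[names(want)]) == as.integer(want)))
      stop("fixture geometry did not realize the requested events (wanted: ",
           paste(names(want), want, collapse = " "), "; got: ",
           paste(names(got), got, collapse = " "), ")")
  }

  structure(list(spec = spec, transcripts = txs, graph = graph,
                 gtf = .render_gtf(txs, spec, chrom_len),
                 chrom_len = chrom_len, truth_events = truth_df),
            class = "fixture_model")
}

.render_gtf <- function(txs, spec, chrom_len) {
  lines <- c(sprintf("#!chrom length %d", chrom_len))
  attr9 <- function(tx) sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
    spec$gene_id, tx$transcript_id, spec$gene_symbol)
  feat <- function(type, s0, e0, tx) paste(
    spec$chrom, "psiquant", type, sprintf("%d", as.integer(s0 + 1)),
    sprintf("%d", as.integer(e0)), ".", spec$strand, ".",
    attr9(tx), sep = "\t")
  for (tx in txs) {
    lines <- c(lines, feat("transcript", min(tx$exons[, 1]),
                           max(tx$exons[, 2]), tx))
    for (i in seq_len(nrow(tx$exons)))
      lines <- c(lines, feat("exon", tx$exons[i, 1], tx$exons[i, 2], tx))
    for (i in seq_len(nrow(tx$cds)))
      lines <- c(lines, feat("CDS", tx$cds[i, 1], tx$cds[i, 2], tx))
  }
  lines
}

#' Write fixture GTF content to a file
#'
#' @param model A `fixture_model`.
#' @param path Output path.
#' @export
write_gtf <- function(model, path) {
  writeLines(model$gtf, path)
  invisible(path)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate spliced reads from a fixture gene
#'
#' Reads are sampled uniformly along each isoform, with isoform read counts
#' multinomial in mixture fraction times the number of valid start
#' positions, and emitted as coordinate-sorted SAM records with
#' reference-skip (`N`) operations at introns.  Reads are error-free and
#' uniquely mappable by construction.  A truth table records, by direct
#' transcript-coordinate arithmetic, the exact count every graph element
#' should receive under the read-attribution rules (spliced reads to their
#' anchored junctions; unspliced reads to every part overlapped by at least
#' `min_anchor` bases).
#'
#' @param model A `fixture_model`.
#' @param sample_id Sample name for the SAM/truth records.
#' @param mixture,depth,read_length,seed Override the spec's values.
#' @param min_anchor Anchor used for the truth table (default 4).
#' @return An object of class `sim_reads`: `sam` (character lines), `truth`
#'   (per-element counts and per-event true inclusion fraction `p`),
#'   `n_reads`, and per-isoform read counts.
#' @export
simulate_reads <- function(model, sample_id = "S1", mixture = NULL,
                           depth = NULL, read_length = NULL, seed = NULL,
                           min_anchor = 4) {
  stopifnot(inherits(model, "fixture_model"))
  spec <- model$spec
  if (is.null(mixture)) mixture <- spec$mixture
  if (is.null(depth)) depth <- spec$depth
  if (is.null(read_length)) read_length <- spec$read_length
  if (is.null(seed)) seed <- spec$seed
  R <- read_length; a <- min_anchor
  iso <- model$transcripts[names(model$transcripts) %in% names(mixture)]
  iso <- iso[mixture[names(iso)] > 0]
  frac <- mixture[names(iso)]

  # transcription-order exon blocks and cumulative transcript offsets
  layout <- lapply(iso, function(t) {
    ex <- t$exons
    if (t$strand == "-") ex <- ex[order(-ex[, 1]), , drop = FALSE]
    lens <- ex[, 2] - ex[, 1]
    list(ex = ex, lens = lens, off = cumsum(c(0, lens)),
         L = sum(lens))
  })
  w <- vapply(layout, function(l) l$L - R + 1, 0)
  if (any(w < 1)) stop("read_length exceeds an isoform length")
  N <- max(1L, as.integer(round(depth * sum(frac * w) / (R - 2 * a + 1))))

  g <- model$graph
  truth_parts <- stats::setNames(numeric(nrow(g$parts)), g$parts$part_id)
  truth_splices <- stats::setNames(numeric(nrow(g$splices)), g$splices$splice_id)
  recs <- list()

  .with_seed(seed, {
    n_iso <- as.vector(stats::rmultinom(1, N, prob = frac * w))
    names(n_iso) <- names(iso)
    for (k in seq_along(iso)) {
      if (n_iso[k] == 0) next
      lay <- layout[[k]]
      starts <- sample.int(w[k], n_iso[k], replace = TRUE) - 1
      for (s in starts) {
        rd <- .read_blocks(lay, s, R, g$strand)
        # truth bookkeeping in transcript coordinates
        jb <- lay$off[-c(1, length(lay$off))]       # junction offsets
        crossed <- jb > s & jb < s + R
        if (any(crossed)) {
          anchored <- which(crossed & (jb - s) >= a & (s + R - jb) >= a)
          for (j in anchored) {
            key <- .intron_key(lay, j, g$strand)
            m <- match(key, paste(g$splices$intron_start, g$splices$intron_end))
            if (!is.na(m)) {
              sid <- g$splices$splice_id[m]
              truth_splices[sid] <- truth_splices[sid] + 1
            }
          }
        } else {
          ov <- pmin(rd$blocks[, 2], g$parts$end) -
            pmax(rd$blocks[, 1], g$parts$start)
          hit <- which(ov >= a)
          truth_parts[hit] <- truth_parts[hit] + 1
        }
        recs[[length(recs) + 1]] <- list(pos = rd$pos, cigar = rd$cigar)
      }
    }
  })

  sam <- .render_sam(recs, spec$chrom, model$chrom_len, R)
  ev <- detect_events(g)
  truth_p <- if (length(ev)) data.frame(
    event_id = vapply(ev, `[[`, "", "event_id"),
    event_type = vapply(ev, `[[`, "", "event_type"),
    p = model$truth_events$p_include[match(
      vapply(ev, `[[`, "", "event_type"), model$truth_events$type)],
    stringsAsFactors = FALSE) else
      data.frame(event_id = character(), event_type = character(),
                 p = numeric())
  # mixture overrides re-derive p from the include-form isoform
  if (nrow(truth_p)) {
    inc_tx <- model$truth_events$include_tx[match(truth_p$event_type,
                                                  model$truth_events$type)]
    truth_p$p <- unname(mixture[inc_tx])
  }
  structure(list(sam = sam, sample_id = sample_id, n_reads = N,
                 n_per_isoform = if (exists("n_iso")) n_iso else NULL,
                 truth = list(parts = truth_parts, splices = truth_splices,
                              events = truth_p)),
            class = "sim_reads")
}

# genomic blocks (ascending), SAM POS and CIGAR for a read at transcript
# offset s
.read_blocks <- function(lay, s, R, strand) {
  hits <- which(lay$off[-length(lay$off)] < s + R & lay$off[-1] > s)
  blocks <- t(vapply(hits, function(k) {
    aa <- max(s, lay$off[k]); bb <- min(s + R, lay$off[k + 1])
    ex <- lay$ex[k, ]
    if (strand == "+")
      c(ex[1] + (aa - lay$off[k]), ex[1] + (bb - lay$off[k]))
    else
      c(ex[2] - (bb - lay$off[k]), ex[2] - (aa - lay$off[k]))
  }, numeric(2)))
  blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  gaps <- blocks[-1, 1] - blocks[-nrow(blocks), 2]
  cig <- paste0(blocks[1, 2] - blocks[1, 1], "M")
  if (nrow(blocks) > 1)
    for (i in 2:nrow(blocks))
      cig <- paste0(cig, gaps[i - 1], "N", blocks[i, 2] - blocks[i, 1], "M")
  list(pos = blocks[1, 1] + 1, cigar = cig, blocks = blocks)
}

# genomic intron "start end" (0-based half-open) for junction j of an isoform
.intron_key <- function(lay, j, strand) {
  e1 <- lay$ex[j, ]; e2 <- lay$ex[j + 1, ]
  if (strand == "+") paste(e1[2], e2[1]) else paste(e2[2], e1[1])
}

.render_sam <- function(recs, chrom, chrom_len, R) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  if (!length(recs)) return(hdr)
  pos <- vapply(recs, function(r) r$pos, 0)
  ord <- order(pos)
  body <- vapply(seq_along(ord), function(i) {
    r <- recs[[ord[i]]]
    paste(sprintf("r%06d", i), 0, chrom, sprintf("%d", as.integer(r$pos)),
          60, r$cigar, "*", 0, 0, strrep("A", R), "*", sep = "\t")
  }, "")
  c(hdr, body)
}

#' Write simulated reads to a SAM file
#'
#' @param sim A `sim_reads` object.
#' @param path Output path (conventionally `.sam`).
#' @export
write_sam <- function(sim, path) {
  writeLines(sim$sam, path)
  invisible(path)
}

#' Append split reads spanning an unannotated junction
#'
#' Adds `n_reads` spliced records across the given intron (0-based
#' half-open) to a simulated sample, for novel-junction discovery tests.
#' Both junction endpoints must flank known exonic territory of the graph;
#' otherwise an error is raised, since novel exons must remain
#' undiscoverable.
#'
#' @param sim A `sim_reads` object.
#' @param graph The gene's `splice_graph`.
#' @param intron_start,intron_end Genomic intron coordinates, 0-based
#'   half-open.
#' @param n_reads Number of junction reads to plant.
#' @param read_length Read length (default: the spec's).
#' @return The modified `sim_reads` object (records re-sorted).
#' @export
plant_novel_junction <- function(sim, graph, intron_start, intron_end,
                                 n_reads = 5, read_length = 50) {
  stopifnot(inherits(sim, "sim_reads"), inherits(graph, "splice_graph"))
  p <- graph$parts
  up <- which(p$start <= intron_start - 1 & p$end > intron_start - 1)
  dn <- which(p$start <= intron_end & p$end > intron_end)
  if (!length(up) || !length(dn))
    stop("junction endpoint outside known exonic territory; ",
         "novel exons cannot be introduced")
  h <- floor(read_length / 2)
  h <- min(h, intron_start - p$start[up])
  h2 <- min(read_length - h, p$end[dn] - intron_end)
  if (h < 1 || h2 < 1) stop("anchors do not fit inside flanking exon parts")
  pos <- intron_start - h + 1
  cigar <- sprintf("%dM%dN%dM", h, intron_end - intron_start, h2)
  if (n_reads > 0) {
    body <- vapply(seq_len(n_reads), function(i)
      paste(sprintf("nv%04d", i), 0, graph$chrom,
            sprintf("%d", as.integer(pos)), 60, cigar,
            "*", 0, 0, strrep("A", h + h2), "*", sep = "\t"), "")
    hdr <- grep("^@", sim$sam, value = TRUE)
    rec <- c(grep("^@", sim$sam, value = TRUE, invert = TRUE), body)
    pos_of <- as.numeric(vapply(strsplit(rec, "\t", fixed = TRUE), `[[`, "", 4))
    sim$sam <- c(hdr, rec[order(pos_of)])
  }
  sim
}

#' @export
print.fixture_model <- function(x, ...) {
  cat("fixture_model:", x$spec$gene_symbol, "strand", x$spec$strand,
      "- patterns:", if (length(x$spec$events))
        paste(x$spec$events, collapse = ", ") else "(none)", "\n")
  print(x$graph)
  invisible(x)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", x$n_reads, "reads for sample", x$sample_id, "\n")
  invisible(x)
}
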
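# shared helpers: handcrafted genes, SAM writers, brute-force oracles

ALL_TYPES <- c("ES", "AD", "AA", "RI", "ME", "AT", "AL")

event_types <- function(ev) sort(vapply(ev, `[[`, "", "event_type"))

# the worked four-exon skip gene: exons at 0-100, 200-300, 400-500, 600-700;
# one transcript includes exon 3, the other bridges 2->4
figure_skip_gene <- function() {
  ex4 <- rbind(c(0, 100), c(200, 300), c(400, 500), c(600, 700))
  t1 <- transcript_model("T1", "SKP", "SKP", "chrF", "+", ex4,
                         cbind(ex4[, 1] + 10, ex4[, 2] - 10))
  t2 <- transcript_model("T2", "SKP", "SKP", "chrF", "+",
                         ex4[-3, , drop = FALSE],
                         cbind(ex4[-3, 1] + 10, ex4[-3, 2] - 10))
  build_splice_graph(list(t1, t2))
}

# write a SAM file from (pos, cigar) records; pos is 1-based
write_sam_records <- function(recs, chrom = "chrF", len = 10000,
                              path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
  recs <- recs[order(recs$pos), , drop = FALSE]
  body <- vapply(seq_len(nrow(recs)), function(i)
    paste(sprintf("q%04d", i), 0, chrom, recs$pos[i], 60, recs$cigar[i],
          "*", 0, 0, "*", "*", sep = "\t"), "")
  writeLines(c(hdr, body), path)
  path
}

# reads realizing the worked example: 4 exon-3 body reads, 2 junction 2-3,
# 2 junction 3-4, and 2 skip-junction 2-4 reads (50 bp, 25 bp anchors)
figure_skip_sam <- function() {
  write_sam_records(data.frame(
    pos = c(rep(411, 4), 276, 276, 476, 476, 276, 276),
    cigar = c(rep("50M", 4), rep("25M100N25M", 2), rep("25M100N25M", 2),
              rep("25M300N25M", 2)),
    stringsAsFactors = FALSE))
}

# brute-force fragmentation oracle: scan every covered base; parts are
# maximal runs of contiguous bases with a constant set of covering exons
frag_oracle <- function(exon_list) {
  lo <- min(vapply(exon_list, function(e) min(e[, 1]), 0))
  hi <- max(vapply(exon_list, function(e) max(e[, 2]), 0))
  bases <- lo:(hi - 1)
  sig <- vapply(bases, function(b) {
    paste(vapply(seq_along(exon_list), function(i)
      any(exon_list[[i]][, 1] <= b & exon_list[[i]][, 2] > b), logical(1)),
      collapse = "")
  }, "")
  covered <- grepl("TRUE", sig)
  runs <- list()
  i <- 1
  while (i <= length(bases)) {
    if (!covered[i]) { i <- i + 1; next }
    j <- i
    while (j + 1 <= length(bases) && covered[j + 1] && sig[j + 1] == sig[i])
      j <- j + 1
    runs[[length(runs) + 1]] <- c(bases[i], bases[j] + 1)
    i <- j + 1
  }
  do.call(rbind, runs)
}

# exhaustive base scan: how many exon parts contain each covered base
parts_per_base <- function(graph) {
  cov <- sort(unique(unlist(lapply(graph$transcripts, function(t)
    unlist(lapply(seq_len(nrow(t$exons)), function(i)
      seq(t$exons[i, 1], t$exons[i, 2] - 1)))))))
  vapply(cov, function(b)
    sum(graph$parts$start <= b & graph$parts$end > b), 0L)
}

# minimal in-memory counts object for arithmetic-level PSI tests
mock_counts <- function(part_raw = numeric(), splice_raw = numeric(),
                        gene_id = "G", total = 1e6, sample_id = "mock",
                        part_length = 100) {
  structure(list(
    sample_id = sample_id, total_aligned_reads = total,
    parts = data.frame(gene_id = gene_id, part_id = names(part_raw),
                       length = part_length, raw = unname(part_raw),
                       obs = NA_real_, stringsAsFactors = FALSE),
    splices = data.frame(gene_id = gene_id, splice_id = names(splice_raw),
                         from = NA, to = NA, intron_start = NA,
                         intron_end = NA, novel = FALSE,
                         raw = unname(splice_raw), obs = NA_real_,
                         stringsAsFactors = FALSE),
    min_anchor = 4, normalized = FALSE), class = "sample_counts")
}

mock_event <- function(include, exclude, gene_id = "G", type = "ES",
                       id = paste0("G_", type, "_x")) {
  structure(list(event_id = id, gene_id = gene_id, gene_symbol = gene_id,
                 event_type = type, exons = "x", include = include,
                 exclude = exclude, anchor = character(), novel = FALSE),
            class = "splice_event")
}

# full pipeline for one simulated sample: SAM -> counts -> PSI table
sim_psi_table <- function(model, events, sample_id, seed, mixture = NULL,
                          depth = NULL) {
  sim <- simulate_reads(model, sample_id = sample_id, seed = seed,
                        mixture = mixture, depth = depth)
  f <- tempfile(fileext = ".sam")
  write_sam(sim, f)
  on.exit(unlink(f))
  psi_table(events, count_reads(f, model$graph, sample_id = sample_id))
}
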
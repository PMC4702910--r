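test_that("the worked skip example yields PSI 0.8 from real alignments", {
  g <- figure_skip_gene()
  sam <- figure_skip_sam()
  ct <- count_reads(sam, g, sample_id = "fig")
  praw <- stats::setNames(ct$parts$raw, ct$parts$part_id)
  sraw <- stats::setNames(ct$splices$raw, ct$splices$splice_id)
  expect_equal(unname(praw["3"]), 4)
  expect_equal(unname(sraw[c("2->3", "3->4", "2->4")]), c(2, 2, 2))
  expect_equal(ct$total_aligned_reads, 10)
  ev <- detect_events(g)
  expect_equal(event_types(ev), "ES")
  pv <- compute_psi(ev[[1]], ct)
  expect_identical(pv$psi, 0.8)
  expect_equal(pv$include_reads, 8)
  expect_equal(pv$exclude_reads, 2)
})

test_that("junction reads require exact splice coordinates and anchors", {
  g <- figure_skip_gene()
  # 3-base anchor fails the default min_anchor of 4; 4 bases passes
  sam <- write_sam_records(data.frame(
    pos = c(298, 297, 280),
    cigar = c("3M100N47M", "4M100N46M", "20M101N30M"),  # last: off-by-one gap
    stringsAsFactors = FALSE))
  ct <- count_reads(sam, g)
  expect_equal(sum(ct$splices$raw), 1)
  expect_equal(ct$splices$raw[ct$splices$splice_id == "2->3"], 1)
  ct3 <- count_reads(sam, g, min_anchor = 3)
  expect_equal(ct3$splices$raw[ct3$splices$splice_id == "2->3"], 2)
  # spliced reads never contribute to exon-body counts
  expect_equal(sum(ct$parts$raw), 0)
})

test_that("body reads need min_anchor overlap and off-graph reads only count toward depth", {
  g <- figure_skip_gene()
  # exon 3 is 401..500 (1-based): overlaps of 3 and 4 bases at its 5' edge
  sam <- write_sam_records(data.frame(
    pos = c(354, 355, 51),
    cigar = c("50M", "50M", "50M"),
    stringsAsFactors = FALSE))
  ct <- count_reads(sam, g)
  p <- stats::setNames(ct$parts$raw, ct$parts$part_id)
  expect_equal(unname(p["3"]), 1)      # only the 4-base overlap qualifies
  expect_equal(unname(p["1"]), 1)
  expect_equal(sum(ct$parts$raw), 2)
  # a read on a chromosome absent from the graph still counts toward totals
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chrF\tLN:10000", "@SQ\tSN:chrZ\tLN:10000",
               paste("r1", 0, "chrF", 411, 60, "50M", "*", 0, 0, "*", "*",
                     sep = "\t"),
               paste("r2", 0, "chrZ", 100, 60, "50M", "*", 0, 0, "*", "*",
                     sep = "\t")), path)
  ct2 <- count_reads(path, g)
  expect_equal(ct2$total_aligned_reads, 2)
  expect_equal(sum(ct2$parts$raw), 1)
})

test_that("simulated fixtures reproduce their truth tables exactly", {
  for (t in list("ES", "ME", c("AT", "AD", "RI"))) {
    m <- generate_gene_model(fixture_spec(events = t, depth = 40))
    sim <- simulate_reads(m, seed = 11)
    f <- tempfile(fileext = ".sam")
    write_sam(sim, f)
    ct <- count_reads(f, m$graph)
    praw <- stats::setNames(ct$parts$raw, ct$parts$part_id)
    sraw <- stats::setNames(ct$splices$raw, ct$splices$splice_id)
    expect_equal(praw[names(sim$truth$parts)], sim$truth$parts,
                 ignore_attr = TRUE,
                 label = paste("parts", paste(t, collapse = "+")))
    expect_equal(sraw[names(sim$truth$splices)], sim$truth$splices,
                 ignore_attr = TRUE,
                 label = paste("splices", paste(t, collapse = "+")))
    expect_equal(ct$total_aligned_reads, sim$n_reads)
  }
})

test_that("normalization follows the per-kilobase per-million formula", {
  ct <- mock_counts(part_raw = c(p = 10), splice_raw = c(`a->b` = 7),
                    total = 1e6, part_length = 1000)
  n <- normalize_counts(ct)
  expect_identical(n$parts$obs, 10)      # unit-scale case
  expect_identical(n$splices$obs, 7)
  ct2 <- ct; ct2$total_aligned_reads <- 2e6
  n2 <- normalize_counts(ct2)
  expect_equal(n2$parts$obs, 5)          # doubling depth halves obs
  expect_equal(n2$splices$obs, 3.5)
  ct0 <- ct; ct0$total_aligned_reads <- 0
  expect_error(normalize_counts(ct0), "no aligned reads")

  # formula oracle on a simulated sample
  m <- generate_gene_model(fixture_spec(events = "ES", depth = 30))
  sim <- simulate_reads(m, seed = 3)
  f <- tempfile(fileext = ".sam"); write_sam(sim, f)
  ct3 <- normalize_counts(count_reads(f, m$graph))
  M <- ct3$total_aligned_reads
  expect_equal(ct3$parts$obs,
               ct3$parts$raw * 1000 / ct3$parts$length * 1e6 / M)
  expect_equal(ct3$splices$obs, ct3$splices$raw * 1e6 / M)
})

test_that("PSI is withheld below 8 covering reads and reported at 8", {
  e <- mock_event(include = c("3", "2->3", "3->4"), exclude = "2->4")
  ct7 <- mock_counts(part_raw = c(`3` = 3), splice_raw = c(`2->3` = 1,
                                                           `3->4` = 1,
                                                           `2->4` = 2))
  expect_true(is.na(compute_psi(e, ct7)$psi))
  expect_equal(compute_psi(e, ct7)$total_reads, 7)
  ct8 <- mock_counts(part_raw = c(`3` = 4), splice_raw = c(`2->3` = 1,
                                                           `3->4` = 1,
                                                           `2->4` = 2))
  pv <- compute_psi(e, ct8)
  expect_equal(pv$psi, 6 / 8)
  # the boundary is configurable
  expect_false(is.na(compute_psi(e, ct7, min_coverage = 7)$psi))
  # exclusive form absent
  ct12 <- mock_counts(part_raw = c(`3` = 12),
                      splice_raw = c(`2->3` = 0, `3->4` = 0, `2->4` = 0))
  expect_equal(compute_psi(e, ct12)$psi, 1)
})

test_that("PSI is monotone in include and exclude evidence and bounded", {
  e <- mock_event(include = c("3", "2->3"), exclude = "1->3")
  for (inc in c(4, 9, 20)) for (exc in c(4, 9, 20)) {
    base <- compute_psi(e, mock_counts(part_raw = c(`3` = inc),
                                       splice_raw = c(`2->3` = 0, `1->3` = exc)))
    up <- compute_psi(e, mock_counts(part_raw = c(`3` = inc),
                                     splice_raw = c(`2->3` = 5, `1->3` = exc)))
    dn <- compute_psi(e, mock_counts(part_raw = c(`3` = inc),
                                     splice_raw = c(`2->3` = 0, `1->3` = exc + 5)))
    expect_gte(up$psi, base$psi)
    expect_lte(dn$psi, base$psi)
    expect_true(base$psi >= 0 && base$psi <= 1)
  }
  expect_error(compute_psi(mock_event("nope", "1->3"), mock_counts(
    part_raw = c(`3` = 1), splice_raw = c(`1->3` = 1))), "unknown part")
})

test_that("novel junctions are added only inside known exonic territory", {
  m <- generate_gene_model(fixture_spec(events = character()))
  g <- m$graph
  sim <- simulate_reads(m, depth = 20, seed = 5)

  # planted skip junction on exact part boundaries
  s1 <- plant_novel_junction(sim, g, g$parts$end[1], g$parts$start[3],
                             n_reads = 4)
  f1 <- tempfile(fileext = ".sam"); write_sam(s1, f1)
  g1 <- discover_novel_junctions(f1, g)
  expect_equal(sum(g1$splices$novel), 1L)
  expect_equal(g1$splices$from[g1$splices$novel], "1")
  expect_equal(g1$splices$to[g1$splices$novel], "3")
  ev <- detect_events(g1)
  expect_equal(event_types(ev), "ES")
  expect_true(ev[[1]]$novel)

  # endpoint strictly inside a part splits the part
  mid <- g$parts$start[3] + 40
  s2 <- plant_novel_junction(sim, g, g$parts$end[1], mid, n_reads = 4)
  f2 <- tempfile(fileext = ".sam"); write_sam(s2, f2)
  g2 <- discover_novel_junctions(f2, g)
  expect_true("3.2" %in% g2$parts$part_id)
  expect_equal(g2$splices$to[g2$splices$novel], "3.2")
  expect_true(all(parts_per_base(g2) == 1L))     # uniqueness survives splitting

  # intergenic junction end: graph unchanged, and planting it is refused
  expect_error(plant_novel_junction(sim, g, g$parts$end[1],
                                    max(g$parts$end) + 500),
               "outside known exonic territory")
  f3 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", g$chrom, m$chrom_len),
               paste("rx", 0, g$chrom, g$parts$end[1] - 24, 60,
                     "25M900N25M", "*", 0, 0, "*", "*", sep = "\t")), f3)
  g3 <- discover_novel_junctions(f3, g)
  expect_equal(sum(g3$splices$novel), 0L)
  expect_equal(g3$splices$splice_id, g$splices$splice_id)

  # no split reads at all: identity
  f4 <- tempfile(fileext = ".sam"); write_sam(sim, f4)
  g4 <- discover_novel_junctions(f4, g)
  expect_equal(g4$splices$splice_id, g$splices$splice_id)
})

test_that("alignments sorted by name are rejected with advice to sort", {
  g <- figure_skip_gene()
  sam <- figure_skip_sam()
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  qn <- Rsamtools::sortBam(bam, tempfile(), byQname = TRUE)
  expect_error(count_reads(qn, g), "samtools sort")
})

test_that("per-sample PSI tables cover every catalogued event", {
  m <- generate_gene_model(fixture_spec(events = ALL_TYPES, depth = 60))
  ev <- detect_events(m$graph)
  tab <- sim_psi_table(m, ev, "s1", seed = 21)
  expect_equal(nrow(tab), 7L)
  expect_setequal(tab$event_id, vapply(ev, `[[`, "", "event_id"))
  expect_true(all(tab$psi >= 0 & tab$psi <= 1, na.rm = TRUE))
  expect_true(all(tab$total_reads == tab$include_reads + tab$exclude_reads))
})
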
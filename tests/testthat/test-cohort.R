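# long-format PSI rows for matrix construction without the read pipeline
psi_rows <- function(event_id, sample_id, psi, type = "ES") {
  data.frame(event_id = event_id, symbol = "G", gene_id = "G",
             event_type = type, exons = "x", novel = FALSE,
             sample_id = sample_id, psi = psi,
             include_reads = NA_integer_, exclude_reads = NA_integer_,
             total_reads = NA_integer_, stringsAsFactors = FALSE)
}

sheet_for <- function(samples, groups, classes = "tumor") {
  data.frame(sample_id = samples, group = groups,
             tissue_class = rep(classes, length.out = length(samples)),
             stringsAsFactors = FALSE)
}

test_that("PSI matrix assembly places values and missingness correctly", {
  long <- rbind(psi_rows("E1", c("s1", "s2", "s3"), c(0.1, 0.2, 0.3)),
                psi_rows("E2", c("s1", "s3"), c(0.9, NA)))
  sheet <- sheet_for(paste0("s", 1:3), c("G1", "G1", "G2"))
  pm <- assemble_psi_matrix(long, sheet)
  expect_equal(dim(pm$values), c(2L, 3L))
  expect_equal(pm$values["E1", ], c(s1 = 0.1, s2 = 0.2, s3 = 0.3))
  expect_true(is.na(pm$values["E2", "s2"]))      # sample without the event
  expect_true(is.na(pm$values["E2", "s3"]))      # explicit missing PSI
  expect_error(assemble_psi_matrix(long, sheet[-1, ]), "absent from sample sheet")
  # row means equal an independent recomputation from the long table
  expect_equal(unname(rowMeans(pm$values, na.rm = TRUE)[1]),
               sum(long$psi[long$event_id == "E1"]) / 3)
})

test_that("group means, deltas and cross-group variance are as constructed", {
  samples <- paste0("s", 1:6)
  sheet <- sheet_for(samples, rep(c("G1", "G2"), each = 3),
                     c("tumor", "tumor", "normal"))
  long <- rbind(
    psi_rows("E1", samples, c(0.8, 0.6, 0.5, 0.2, 0.4, 0.9)),
    psi_rows("E2", samples, c(NA, NA, 0.5, 0.3, 0.3, 0.2)))
  pm <- assemble_psi_matrix(long, sheet)
  s <- summarize_groups(pm)
  bg <- s$by_group
  expect_equal(bg$mean_psi[bg$event_id == "E1" & bg$group == "G1"], 0.7)
  expect_equal(bg$delta[bg$event_id == "E1" & bg$group == "G1"], 0.7 - 0.5)
  # all-missing tumor stratum reports NA with n = 0
  e2g1 <- bg[bg$event_id == "E2" & bg$group == "G1", ]
  expect_true(is.na(e2g1$mean_psi))
  expect_equal(e2g1$n, 0)
  # cross-group variance matches the two-pass formula
  v <- s$by_event$var_groups[s$by_event$event_id == "E1"]
  mu <- c(0.7, 0.3)
  expect_equal(v, sum((mu - mean(mu))^2) / 1)
  # E2 has one informative group only: variance undefined
  expect_true(is.na(s$by_event$var_groups[s$by_event$event_id == "E2"]))
})

test_that("tissue-difference ranking matches a brute-force oracle", {
  set.seed(42)
  n_ev <- 50; n_s <- 60
  samples <- sprintf("s%02d", seq_len(n_s))
  groups <- rep(paste0("G", 1:4), each = 15)
  classes <- rep(c(rep("tumor", 10), rep("normal", 5)), 4)
  vals <- matrix(runif(n_ev * n_s), n_ev, n_s)
  vals[sample(length(vals), 300)] <- NA
  ids <- sprintf("EV%02d", seq_len(n_ev))
  long <- do.call(rbind, lapply(seq_len(n_ev), function(i)
    psi_rows(ids[i], samples, vals[i, ])))
  pm <- assemble_psi_matrix(long, sheet_for(samples, groups, classes))
  s <- summarize_groups(pm)
  rk <- rank_tissue_difference(s)

  # oracle: two-pass variance of per-group tumor means, direct sort
  oracle <- vapply(ids, function(id) {
    mus <- vapply(unique(groups), function(g) {
      x <- vals[ids == id, samples %in% samples[groups == g & classes == "tumor"]]
      x <- x[!is.na(x)]
      if (length(x)) sum(x) / length(x) else NA_real_
    }, 0)
    mus <- mus[!is.na(mus)]
    if (length(mus) < 2) return(NA_real_)
    m <- sum(mus) / length(mus)
    sum((mus - m)^2) / (length(mus) - 1)
  }, 0)
  ord <- order(-oracle, ids)
  expect_equal(rk$event_id, ids[ord])
  expect_equal(rk$variance, unname(oracle[ord]), tolerance = 1e-12)

  # tumor-normal ranking against its own oracle
  rk2 <- rank_tumor_normal(s)
  oracle2 <- vapply(ids, function(id) {
    ds <- vapply(unique(groups), function(g) {
      xt <- vals[ids == id, groups == g & classes == "tumor"]
      xn <- vals[ids == id, groups == g & classes == "normal"]
      xt <- xt[!is.na(xt)]; xn <- xn[!is.na(xn)]
      if (!length(xt) || !length(xn)) return(NA_real_)
      abs(sum(xt) / length(xt) - sum(xn) / length(xn))
    }, 0)
    ds <- ds[!is.na(ds)]
    if (!length(ds)) NA_real_ else max(ds)
  }, 0)
  ord2 <- order(-oracle2, ids)
  expect_equal(rk2$event_id, ids[ord2])
  expect_equal(rk2$shift, unname(oracle2[ord2]), tolerance = 1e-12)
})

test_that("ranking honors selections, variance ordering and error contracts", {
  samples <- paste0("s", 1:8)
  sheet <- sheet_for(samples, rep(c("G1", "G2", "G3", "G4"), each = 2))
  long <- rbind(
    psi_rows("Ewide", samples, rep(c(0.1, 0.9, 0.1, 0.9), each = 2)),
    psi_rows("Enarrow", samples, rep(c(0.4, 0.6, 0.4, 0.6), each = 2)),
    psi_rows("Eflat", samples, rep(0.5, 8)))
  s <- summarize_groups(assemble_psi_matrix(long, sheet))
  rk <- rank_tissue_difference(s)
  expect_equal(rk$event_id, c("Ewide", "Enarrow", "Eflat"))
  expect_equal(rk$variance[3], 0)
  rk2 <- rank_tissue_difference(s, groups = c("G1", "G2"))
  expect_equal(rk2$event_id[1], "Ewide")
  expect_error(rank_tissue_difference(s, groups = "G1"), "at least two")
  expect_error(rank_tumor_normal(s), "tumor and adjacent-normal")
})

test_that("novel-splice events need a qualifying share in 10 or more samples", {
  run_scenario <- function(k_qualifying, n = 12) {
    m <- generate_gene_model(fixture_spec(events = character(), depth = 40))
    g <- m$graph
    is0 <- g$parts$end[1]; ie0 <- g$parts$start[3]
    sims <- lapply(seq_len(n), function(i) {
      sim <- simulate_reads(m, sample_id = paste0("s", i), seed = 500 + i)
      if (i <= k_qualifying)
        sim <- plant_novel_junction(sim, g, is0, ie0, n_reads = 6)
      sim
    })
    f1 <- tempfile(fileext = ".sam"); write_sam(sims[[1]], f1)
    ga <- discover_novel_junctions(f1, g)
    ev <- detect_events(ga)
    counts <- lapply(sims, function(sim) {
      f <- tempfile(fileext = ".sam"); write_sam(sim, f)
      on.exit(unlink(f))
      count_reads(f, ga, sample_id = sim$sample_id)
    })
    tabs <- lapply(counts, function(ct) psi_table(ev, ct))
    sheet <- sheet_for(paste0("s", seq_len(n)), rep("G1", n))
    pm <- assemble_psi_matrix(tabs, sheet)
    list(pm = pm, ev = ev, counts = counts)
  }
  sc10 <- run_scenario(10)
  expect_true(any(vapply(sc10$ev, `[[`, TRUE, "novel")))
  kept <- apply_novel_event_filter(sc10$pm, sc10$ev, sc10$counts)
  expect_equal(nrow(kept$values), nrow(sc10$pm$values))   # retained at 10

  sc9 <- run_scenario(9)
  dropped <- apply_novel_event_filter(sc9$pm, sc9$ev, sc9$counts)
  novel_id <- vapply(sc9$ev, `[[`, "", "event_id")[
    vapply(sc9$ev, `[[`, TRUE, "novel")]
  expect_false(novel_id %in% rownames(dropped$values))

  # filter monotonicity: relaxing thresholds never drops a passing event
  for (mf in c(0.01, 0.001)) for (ms in c(10, 5)) {
    res <- apply_novel_event_filter(sc10$pm, sc10$ev, sc10$counts,
                                    min_fraction = mf, min_samples = ms)
    expect_true(all(rownames(kept$values) %in% rownames(res$values)))
  }
  # fully annotated events pass unconditionally
  annotated <- vapply(sc9$ev, function(e) !e$novel, TRUE)
  expect_true(all(vapply(sc9$ev, `[[`, "", "event_id")[annotated] %in%
                    rownames(dropped$values) |
                    !any(annotated)))
})

test_that("the PSI download export filters rows and round-trips losslessly", {
  samples <- paste0("s", 1:4)
  sheet <- sheet_for(samples, rep(c("G1", "G2"), 2),
                     c("tumor", "normal", "tumor", "normal"))
  set.seed(7)
  long <- rbind(
    psi_rows("G_ME_1", samples, runif(4), type = "ME"),
    psi_rows("G_ES_2", samples, c(runif(3), NA), type = "ES"),
    psi_rows("G_ES_3", samples, runif(4), type = "ES"))
  pm <- assemble_psi_matrix(long, sheet)

  f <- tempfile()
  export_psi_download(pm, f)
  back <- read_psi_download(f)
  expect_identical(unname(back$values), unname(pm$values))  # full precision
  expect_equal(back$samples$group, pm$samples$group)
  expect_equal(back$samples$tissue_class, pm$samples$tissue_class)

  me <- export_psi_download(pm, gene = "G", event_type = "ME")
  expect_equal(me$event_id, "G_ME_1")
  g1 <- export_psi_download(pm, groups = "G1")
  expect_equal(ncol(g1), 4 + 2)          # meta columns + two G1 samples
  expect_error(export_psi_download(pm, gene = "GG"), "did you mean")
})
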
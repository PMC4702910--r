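#' @name event-detection
#' @title Alternative-splicing event detection
#'
#' @description
#' Every potential splice event of the seven catalogued types is enumerated
#' from a gene's splice graph, whether or not any sample expresses it.  An
#' event pairs two sets of graph elements (exon parts and splices): reads on
#' `include` elements evidence the presence of the affected transcript
#' element, reads on `exclude` elements evidence its absence.  The two sets
#' are disjoint and non-empty by construction.
#'
#' Types: `ES` exon skip, `AD` alternate (5') donor, `AA` alternate (3')
#' acceptor, `RI` retained intron, `ME` mutually exclusive exons, `AT`
#' alternate first exon, `AL` alternate last exon.
NULL

.txpos <- function(graph, pid) match(pid, graph$parts$part_id)
.region_of <- function(graph, pid) graph$parts$region[.txpos(graph, pid)]

# edge list: splices plus adjacency steps (consecutive same-exon sub-parts
# traversed by some transcript path)
.graph_edges <- function(graph) {
  sp <- graph$splices
  edges <- if (nrow(sp))
    data.frame(from = sp$from, to = sp$to, type = "splice",
               id = sp$splice_id, stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(),
                  type = character(), id = character())
  adj <- list()
  for (p in graph$transcript_paths) {
    if (length(p) < 2) next
    for (i in seq_len(length(p) - 1)) {
      a <- .txpos(graph, p[i]); b <- .txpos(graph, p[i + 1])
      contiguous <- if (graph$strand == "+")
        graph$parts$end[a] == graph$parts$start[b]
      else graph$parts$start[a] == graph$parts$end[b]
      if (contiguous)
        adj[[length(adj) + 1]] <- c(p[i], p[i + 1])
    }
  }
  if (length(adj)) {
    am <- unique(do.call(rbind, adj))
    edges <- rbind(edges, data.frame(from = am[, 1], to = am[, 2],
                                     type = "adj", id = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  edges
}

# all simple paths A -> C confined to parts with transcription positions in
# [ia, ic]; returns list of (part vector, edge-type vector, edge-id vector)
.find_paths <- function(graph, edges, A, C, ia, ic) {
  res <- list()
  walk <- function(node, parts, types, ids) {
    if (node == C) {
      res[[length(res) + 1]] <<- list(parts = parts, types = types, ids = ids)
      return()
    }
    nxt <- which(edges$from == node)
    for (i in nxt) {
      to <- edges$to[i]
      tp <- .txpos(graph, to)
      if (is.na(tp) || tp > ic || tp <= .txpos(graph, node)) next
      if (to %in% parts) next
      walk(to, c(parts, to), c(types, edges$type[i]), c(ids, edges$id[i]))
    }
  }
  walk(A, A, character(), character())
  res
}

.event <- function(graph, type, label, include, exclude, anchor = character()) {
  structure(list(event_id = paste(graph$gene_symbol, type, label, sep = "_"),
                 gene_id = graph$gene_id, gene_symbol = graph$gene_symbol,
                 event_type = type, exons = label,
                 include = unique(include), exclude = unique(exclude),
                 anchor = anchor, novel = FALSE),
            class = "splice_event")
}

# human label for a set of parts: the region ordinal when a full region is
# covered, otherwise the sub-part labels
.label_for_parts <- function(graph, pids) {
  p <- graph$parts
  out <- character()
  for (r in unique(p$region[match(pids, p$part_id)])) {
    in_region <- p$part_id[p$region == r]
    out <- c(out, if (all(in_region %in% pids)) as.character(r)
             else intersect(pids, in_region))
  }
  paste(out, collapse = "/")
}

#' @rdname event-detection
#' @param graph A numbered `splice_graph`.
#' @return Each detector returns a list of `splice_event` objects (possibly
#'   empty); [detect_events()] returns their union with novelty flags set.
#' @export
detect_exon_skip <- function(graph) {
  edges <- .graph_edges(graph)
  events <- list()
  sp <- graph$splices
  for (i in seq_len(nrow(sp))) {
    A <- sp$from[i]; C <- sp$to[i]
    ia <- .txpos(graph, A); ic <- .txpos(graph, C)
    if (ic - ia < 2) next
    paths <- .find_paths(graph, edges, A, C, ia, ic)
    keep <- Filter(function(p) {
      length(p$parts) >= 3 && p$types[1] == "splice" &&
        p$types[length(p$types)] == "splice" &&
        !identical(p$ids, sp$splice_id[i])
    }, paths)
    keep <- Filter(function(p) !(sp$splice_id[i] %in% p$ids), keep)
    if (!length(keep)) next
    mids <- unique(unlist(lapply(keep, function(p)
      p$parts[-c(1, length(p$parts))])))
    jids <- unique(unlist(lapply(keep, function(p) p$ids[p$types == "splice"])))
    events[[length(events) + 1]] <-
      .event(graph, "ES", .label_for_parts(graph, mids),
             include = c(mids, jids), exclude = sp$splice_id[i],
             anchor = c(A, C))
  }
  events
}

# splices leaving (AD) or entering (AA) one exon region at different
# sub-part boundaries; pairwise against the longest (most-included) form
.alt_side <- function(graph, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  sp <- graph$splices
  if (!nrow(sp)) return(list())
  freg <- .region_of(graph, sp$from); treg <- .region_of(graph, sp$to)
  sp <- sp[freg != treg, , drop = FALSE]          # intra-region = retention
  if (!nrow(sp)) return(list())
  key <- if (side == "donor")
    paste(sp$to, .region_of(graph, sp$from))
  else paste(sp$from, .region_of(graph, sp$to))
  events <- list()
  for (k in unique(key)) {
    grp <- sp[key == k, , drop = FALSE]
    vpart <- if (side == "donor") grp$from else grp$to
    if (length(unique(vpart)) < 2) next
    tx <- .txpos(graph, vpart)
    long_i <- if (side == "donor") which.max(tx) else which.min(tx)
    reg <- .region_of(graph, vpart[long_i])
    rparts <- graph$parts$part_id[graph$parts$region == reg]
    rtx <- .txpos(graph, rparts)
    for (j in seq_len(nrow(grp))[-long_i]) {
      ext <- if (side == "donor")
        rparts[rtx > tx[j] & rtx <= tx[long_i]]
      else rparts[rtx >= tx[long_i] & rtx < tx[j]]
      if (!length(ext)) next
      type <- if (side == "donor") "AD" else "AA"
      events[[length(events) + 1]] <-
        .event(graph, type, .label_for_parts(graph, ext),
               include = c(ext, grp$splice_id[long_i]),
               exclude = grp$splice_id[j],
               anchor = if (side == "donor") grp$to[j] else grp$from[j])
    }
  }
  events
}

#' @rdname event-detection
#' @export
detect_alt_donor <- function(graph) .alt_side(graph, "donor")

#' @rdname event-detection
#' @export
detect_alt_acceptor <- function(graph) .alt_side(graph, "acceptor")

#' @rdname event-detection
#' @export
detect_retained_intron <- function(graph) {
  sp <- graph$splices
  events <- list()
  for (i in seq_len(nrow(sp))) {
    if (.region_of(graph, sp$from[i]) != .region_of(graph, sp$to[i])) next
    ia <- .txpos(graph, sp$from[i]); ic <- .txpos(graph, sp$to[i])
    if (ic - ia < 2) next
    mids <- graph$parts$part_id[(ia + 1):(ic - 1)]
    events[[length(events) + 1]] <-
      .event(graph, "RI", .label_for_parts(graph, mids),
             include = mids, exclude = sp$splice_id[i],
             anchor = c(sp$from[i], sp$to[i]))
  }
  events
}

#' @rdname event-detection
#' @export
detect_mutually_exclusive <- function(graph) {
  p <- graph$parts
  sp <- graph$splices
  if (!nrow(sp)) return(list())
  regions <- sort(unique(p$region))
  first_of <- vapply(regions, function(r) p$part_id[p$region == r][1], "")
  last_of <- vapply(regions, function(r) rev(p$part_id[p$region == r])[1], "")
  names(first_of) <- names(last_of) <- regions
  inc <- lapply(regions, function(r)
    sp[sp$to == first_of[as.character(r)] &
         .region_of(graph, sp$from) != r, , drop = FALSE])
  out <- lapply(regions, function(r)
    sp[sp$from == last_of[as.character(r)] &
         .region_of(graph, sp$to) != r, , drop = FALSE])
  names(inc) <- names(out) <- regions
  cand <- regions[vapply(inc, nrow, 0L) > 0 & vapply(out, nrow, 0L) > 0]
  events <- list()
  if (length(cand) < 2) return(events)
  path_regions <- lapply(graph$transcript_paths, function(pp)
    unique(p$region[match(pp, p$part_id)]))
  for (a in seq_len(length(cand) - 1)) for (b in (a + 1):length(cand)) {
    r1 <- cand[a]; r2 <- cand[b]
    As <- intersect(inc[[as.character(r1)]]$from, inc[[as.character(r2)]]$from)
    Cs <- intersect(out[[as.character(r1)]]$to, out[[as.character(r2)]]$to)
    if (!length(As) || !length(Cs)) next
    if (any(vapply(path_regions, function(rr) all(c(r1, r2) %in% rr),
                   logical(1)))) next
    pick <- function(tab, col, vals) tab$splice_id[tab[[col]] %in% vals]
    i1 <- c(p$part_id[p$region == r1],
            pick(inc[[as.character(r1)]], "from", As),
            pick(out[[as.character(r1)]], "to", Cs))
    i2 <- c(p$part_id[p$region == r2],
            pick(inc[[as.character(r2)]], "from", As),
            pick(out[[as.character(r2)]], "to", Cs))
    lab <- paste0(.label_for_parts(graph, p$part_id[p$region == r1]), "|",
                  .label_for_parts(graph, p$part_id[p$region == r2]))
    events[[length(events) + 1]] <-
      .event(graph, "ME", lab, include = i1, exclude = i2,
             anchor = c(As, Cs))
  }
  events
}

# first (or last) splice along a transcript path, i.e. the edge that leaves
# the terminal exon region
.terminal_splice <- function(graph, path, from_start = TRUE) {
  if (length(path) < 2) return(list(splice = NA_character_, prefix = path))
  idx <- seq_len(length(path) - 1)
  if (!from_start) idx <- rev(idx)
  for (i in idx) {
    a <- .txpos(graph, path[i]); b <- .txpos(graph, path[i + 1])
    contiguous <- if (graph$strand == "+")
      graph$parts$end[a] == graph$parts$start[b]
    else graph$parts$start[a] == graph$parts$end[b]
    if (!contiguous) {
      sid <- paste0(path[i], "->", path[i + 1])
      prefix <- if (from_start) path[seq_len(i)] else path[(i + 1):length(path)]
      return(list(splice = sid, prefix = prefix))
    }
  }
  list(splice = NA_character_, prefix = path)
}

# alternate first/last exons, emitted pairwise against the canonical form:
# the transcription-order-first first exon (AT) or transcription-order-last
# last exon (AL); mirrored definitions preserve strand symmetry
.alt_terminal <- function(graph, first = TRUE) {
  paths <- graph$transcript_paths
  if (length(paths) < 2) return(list())
  term <- vapply(paths, function(p) if (first) p[1] else p[length(p)], "")
  treg <- .region_of(graph, term)
  regs <- unique(treg)
  if (length(regs) < 2) return(list())
  common <- Reduce(intersect, paths)
  if (!length(common)) return(list())
  canon <- if (first) min(regs) else max(regs)
  per_region <- function(r) {
    sel <- which(treg == r)
    tinfo <- lapply(paths[sel], .terminal_splice, graph = graph,
                    from_start = first)
    list(splices = unique(stats::na.omit(vapply(tinfo, `[[`, "", "splice"))),
         parts = unique(unlist(lapply(tinfo, `[[`, "prefix"))))
  }
  canon_info <- per_region(canon)
  if (!length(canon_info$splices)) return(list())
  events <- list()
  for (r in setdiff(regs, canon)) {
    info <- per_region(r)
    if (!length(info$splices)) next
    type <- if (first) "AT" else "AL"
    events[[length(events) + 1]] <-
      .event(graph, type, .label_for_parts(graph, info$parts),
             include = c(info$parts, info$splices),
             exclude = canon_info$splices,
             anchor = common[1])
  }
  events
}

#' @rdname event-detection
#' @export
detect_alt_first <- function(graph) .alt_terminal(graph, first = TRUE)

#' @rdname event-detection
#' @export
detect_alt_last <- function(graph) .alt_terminal(graph, first = FALSE)

#' @rdname event-detection
#' @export
detect_events <- function(graph) {
  stopifnot(inherits(graph, "splice_graph"))
  events <- c(detect_exon_skip(graph), detect_alt_donor(graph),
              detect_alt_acceptor(graph), detect_retained_intron(graph),
              detect_mutually_exclusive(graph), detect_alt_first(graph),
              detect_alt_last(graph))
  if (!length(events)) return(structure(list(), class = "splice_event_list"))
  novel_splices <- graph$splices$splice_id[graph$splices$novel]
  events <- lapply(events, function(e) {
    e$novel <- any(c(e$include, e$exclude) %in% novel_splices)
    e
  })
  ids <- vapply(events, `[[`, "", "event_id")
  if (anyDuplicated(ids))
    for (d in unique(ids[duplicated(ids)])) {
      w <- which(ids == d)
      for (k in seq_along(w)) events[[w[k]]]$event_id <- paste0(d, "#", k)
    }
  events <- events[order(vapply(events, `[[`, "", "event_id"))]
  structure(events, class = "splice_event_list")
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("splice_event %s [%s]\n  include: %s\n  exclude: %s\n",
              x$event_id, x$event_type,
              paste(x$include, collapse = ", "),
              paste(x$exclude, collapse = ", ")))
  invisible(x)
}

#' @export
print.splice_event_list <- function(x, ...) {
  cat("splice_event_list with", length(x), "events\n")
  if (length(x))
    print(table(vapply(x, `[[`, "", "event_type")))
  invisible(x)
}

#' @export
as.data.frame.splice_event_list <- function(x, ...) {
  if (!length(x))
    return(data.frame(symbol = character(), event_id = character(),
                      event_type = character(), exons = character(),
                      include = character(), exclude = character(),
                      novel = logical()))
  do.call(rbind, lapply(x, function(e)
    data.frame(symbol = e$gene_symbol, event_id = e$event_id,
               event_type = e$event_type, exons = e$exons,
               include = paste(e$include, collapse = ","),
               exclude = paste(e$exclude, collapse = ","),
               novel = e$novel, stringsAsFactors = FALSE)))
}

#' Export the event catalog as a tab-delimited table
#'
#' @param events A `splice_event_list` from [detect_events()], or a list of
#'   such lists (one per gene).
#' @param file Optional output path.
#' @return The catalog `data.frame`, invisibly when `file` is given.
#' @export
export_event_catalog <- function(events, file = NULL) {
  if (!inherits(events, "splice_event_list") && is.list(events))
    out <- do.call(rbind, lapply(events, as.data.frame))
  else out <- as.data.frame(events)
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
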
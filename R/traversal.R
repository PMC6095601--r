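# State-voting graph traversal: contigs grow from random seeds; a sliding
# window of recently added vertices (the state) votes for candidate
# successors, and fork events interrupt the walk where the graph branches
# for genomic (repeat) reasons.

new_state <- function(vertices, offsets, lens) {
  list(vertices = as.integer(vertices), offsets = as.integer(offsets),
       lens = as.integer(lens))
}

#' Advance the traversal state by one vertex
#'
#' Appends the new vertex at `offset = last offset + arc shift`, then prunes
#' from the old end: while the sequence overlap between the oldest and the
#' newest state member, `len(s1) - (offset(s_r) - offset(s1))`, falls below
#' `min_state_overlap`, the oldest vertex is removed.  A single-entry state
#' is never pruned.  The state thus holds exactly the vertices that can
#' still contribute meaningful votes.
#'
#' @param state `list(vertices, offsets, lens)`.
#' @param new_vertex vertex id to append.
#' @param arc the arc connecting the last state vertex to `new_vertex`
#'   (a list with `shift`).
#' @param min_state_overlap minimum overlap between the state's ends (bp).
#' @param new_len read length of the new vertex.
#' @return The updated state.
#' @export
update_state <- function(state, new_vertex, arc, min_state_overlap,
                         new_len = state$lens[length(state$lens)]) {
  off <- state$offsets[length(state$offsets)] + arc$shift
  st <- new_state(c(state$vertices, new_vertex), c(state$offsets, off),
                  c(state$lens, new_len))
  prune_state(st, min_state_overlap)
}

prune_state <- function(st, min_state_overlap) {
  while (length(st$vertices) > 1L) {
    r <- length(st$offsets)
    ov <- st$lens[1L] - (st$offsets[r] - st$offsets[1L])
    if (ov >= min_state_overlap) break
    st$vertices <- st$vertices[-1L]
    st$offsets <- st$offsets[-1L]
    st$lens <- st$lens[-1L]
  }
  st
}

#' Score candidate successors of a state
#'
#' Candidates are the union of successors of all state members.  The score
#' of a candidate is the sum of the overlap lengths of all supporting arcs
#' from state members, which naturally promotes candidates supported by the
#' newest (largest-overlap) vertices.  The best candidate wins; ties break
#' toward the smallest vertex id.
#'
#' @param state `list(vertices, offsets, lens)`.
#' @param graph an `overlap_graph`.
#' @param exclude_reads integer read indices whose vertices may not be
#'   candidates (reads already on a path or consumed by another contig).
#' @return Data frame with `vertex`, `score` and the implied layout
#'   `offset`, sorted by decreasing score then vertex id.
#' @export
score_candidates <- function(state, graph, exclude_reads = integer()) {
  rows_by <- lapply(state$vertices, function(v) out_arc_rows(graph, v))
  rows <- unlist(rows_by)
  empty <- data.frame(vertex = integer(), score = numeric(),
                      offset = integer())
  if (!length(rows)) return(empty)
  src <- rep(seq_along(state$vertices), lengths(rows_by))
  tgt <- graph$arcs$to[rows]
  keep <- if (is.logical(exclude_reads)) {
    !exclude_reads[vertex_read(tgt)]
  } else {
    !(vertex_read(tgt) %in% exclude_reads)
  }
  if (!any(keep)) return(empty)
  tgt <- tgt[keep]
  ov <- graph$arcs$overlap[rows][keep]
  offc <- state$offsets[src[keep]] + graph$arcs$shift[rows][keep]
  sc <- rowsum(as.numeric(ov), tgt)
  verts <- as.integer(rownames(sc))
  # layout offset of a candidate: the largest offset implied by any
  # supporting arc (consistent for exact overlaps, robust under errors)
  o <- order(tgt, -offc)
  first <- !duplicated(tgt[o])
  off_by <- offc[o][first]
  names(off_by) <- tgt[o][first]
  out <- data.frame(vertex = verts, score = as.numeric(sc[, 1L]),
                    offset = as.integer(off_by[as.character(verts)]))
  out[order(-out$score, out$vertex), , drop = FALSE]
}

# One-directional extension with fork detection.  `blocked` is a logical
# over reads; it is updated in place semantics by returning the final path.
extend_direction <- function(graph, v0, blocked, params) {
  path_v <- v0
  path_off <- 0L
  blocked[vertex_read(v0)] <- TRUE
  state_start <- 1L
  prev_cand <- integer()
  pruned_last <- FALSE
  state_before_prune <- NULL
  reason <- "exhausted"
  forks <- list()
  cut_at <- NA_integer_

  state_of <- function(idx) new_state(path_v[idx], path_off[idx],
                                      graph$vlen[path_v[idx]])
  repeat {
    sidx <- state_start:length(path_v)
    st <- state_of(sidx)
    cand <- score_candidates(st, graph, blocked)
    # forward fork: candidates dropped by the last pruning step
    if (pruned_last) {
      dropped <- setdiff(prev_cand, c(cand$vertex, path_v))
      if (length(dropped)) {
        local_cov <- 1 + mean(graph$deg[st$vertices])
        thr <- drop_threshold(local_cov, graph$deg_median, params)
        ev <- detect_forward_fork(state_before_prune, st, dropped, graph,
                                  thr, params$countercheck_scope)
        if (!is.null(ev)) {
          ev$candidates <- cand$vertex
          cls <- classify_fork(ev, graph, params)
          ev$classification <- cls
          forks[[length(forks) + 1L]] <- ev
          if (cls == "repeat") {
            cut_at <- ev$cut_offset
            reason <- "fork"
            break
          }
        }
      }
    }
    if (nrow(cand) == 0L) { reason <- "dead_end"; break }
    best <- cand[1L, ]
    # backward fork: candidates introduced solely by the incoming vertex
    new_targets <- graph$arcs$to[out_arc_rows(graph, best$vertex)]
    nt_reads <- vertex_read(new_targets)
    new_targets <- new_targets[!blocked[nt_reads] &
                                 !(nt_reads %in% vertex_read(cand$vertex))]
    path_v <- c(path_v, best$vertex)
    path_off <- c(path_off, best$offset)
    blocked[vertex_read(best$vertex)] <- TRUE
    sidx <- state_start:length(path_v)
    st_app <- state_of(sidx)
    if (length(new_targets)) {
      local_cov <- 1 + mean(graph$deg[st_app$vertices])
      thr <- drop_threshold(local_cov, graph$deg_median, params)
      ev <- detect_backward_fork(st_app, new_targets, graph, thr,
                                 known = c(path_v, cand$vertex))
      if (!is.null(ev)) {
        ev$candidates <- setdiff(cand$vertex, best$vertex)
        cls <- classify_fork(ev, graph, params)
        ev$classification <- cls
        forks[[length(forks) + 1L]] <- ev
        if (cls == "repeat") {
          cut_at <- ev$cut_offset
          reason <- "fork"
          break
        }
      }
    }
    # prune the state
    old_start <- state_start
    repeat {
      r <- length(path_v)
      if (state_start >= r) break
      ov <- graph$vlen[path_v[state_start]] -
        (path_off[r] - path_off[state_start])
      if (ov >= params$min_state_overlap) break
      state_start <- state_start + 1L
    }
    pruned_last <- state_start > old_start
    if (pruned_last) state_before_prune <- st_app
    prev_cand <- cand$vertex
  }

  if (!is.na(cut_at)) {
    keep <- path_off < cut_at
    released <- path_v[!keep]
    blocked[vertex_read(released)] <- FALSE
    path_v <- path_v[keep]
    path_off <- path_off[keep]
  }
  list(vertices = path_v, offsets = path_off, reason = reason,
       blocked = blocked, forks = forks)
}

#' Consensus sequence of a path layout
#'
#' Per-column majority vote over all reads covering the column in the layout
#' implied by the offsets; ties break lexicographically (A < C < G < T).
#' Every column must be covered by at least one read -- a zero-coverage
#' column signals inconsistent shifts and raises an error.
#'
#' @param path `list(vertices, offsets)` (offsets are 0-based layout
#'   positions of each read's start).
#' @param reads the [read_set] the vertices refer to.
#' @return The consensus DNA string.
#' @export
consensus <- function(path, reads) {
  vseq <- oriented_sequences(reads)
  consensus_from_seqs(vseq[path$vertices], path$offsets)
}

consensus_from_seqs <- function(seqs, offsets) {
  stopifnot(length(seqs) >= 1L)
  lens <- nchar(seqs)
  L <- max(offsets + lens)
  idx <- unlist(mapply(function(o, l) seq.int(o + 1L, o + l),
                       offsets, lens, SIMPLIFY = FALSE))
  ch <- unlist(strsplit(seqs, "", fixed = TRUE))
  bi <- match(ch, c("A", "C", "G", "T"))
  counts <- matrix(0L, L, 4L)
  for (b in 1:4) {
    counts[, b] <- tabulate(idx[bi == b], nbins = L)
  }
  if (any(rowSums(counts) == 0L)) {
    stop("zero-coverage column in layout: inconsistent shifts", call. = FALSE)
  }
  paste(c("A", "C", "G", "T")[max.col(counts, ties.method = "first")],
        collapse = "")
}

#' Assemble contigs by state-voting traversal
#'
#' Seeds are visited in a random order drawn from `seed`; from each unused
#' seed the path is extended in both directions (rightward from the seed,
#' and rightward from its reverse-complement partner, exploiting the
#' double-vertex symmetry), interrupted where repeat forks are confirmed.
#' Each read is used by at most one contig (both its strands count as one
#' use); vertices released by a fork cut return to the pool.
#'
#' @param graph an `overlap_graph`.
#' @param reads the [read_set].
#' @param params an [assembly_params()] list.
#' @param seed integer seed for the start-point permutation.
#' @return A list of `contig` objects: `id`, `vertices`, `offsets`,
#'   `sequence`, `reason_left`, `reason_right`, `forks`.
#' @export
assemble <- function(graph, reads, params = assembly_params(), seed = 1L) {
  vseq <- oriented_sequences(reads)
  order_seeds <- with_private_seed(seed, sample.int(graph$n_vertices))
  used <- logical(graph$n_reads)
  contigs <- list()
  for (v0 in order_seeds) {
    if (used[vertex_read(v0)]) next
    blocked <- used
    right <- extend_direction(graph, v0, blocked, params)
    blocked <- right$blocked
    # leftward = rightward from the mirror; exclude reads taken by `right`
    left <- extend_direction(graph, partner_vertex(v0), blocked, params)
    # merge: mirror the left path back into forward coordinates
    l0 <- graph$vlen[v0]
    lv <- left$vertices[-1L]
    lo <- left$offsets[-1L]
    if (length(lv)) {
      fv <- partner_vertex(lv)
      fo <- l0 - lo - graph$vlen[fv]
    } else {
      fv <- integer(); fo <- integer()
    }
    verts <- c(fv, right$vertices)
    offs <- c(fo, right$offsets)
    o <- order(offs, verts)
    verts <- verts[o]
    offs <- offs[o] - min(offs)
    used[vertex_read(verts)] <- TRUE
    ctg <- structure(list(
      id = sprintf("contig_%05d", length(contigs) + 1L),
      vertices = verts, offsets = as.integer(offs),
      sequence = consensus_from_seqs(vseq[verts], offs),
      reason_left = left$reason, reason_right = right$reason,
      forks = c(left$forks, right$forks)), class = "contig")
    contigs[[length(contigs) + 1L]] <- ctg
  }
  drop_contained_contigs(contigs)
}

# Contigs assembled from leftover reads of an already-covered region are
# exact (either-strand) substrings of a longer contig; they add duplicated
# sequence only and are dropped.  Ids are reassigned to stay dense.
drop_contained_contigs <- function(contigs) {
  if (length(contigs) < 2L) return(contigs)
  seqs <- vapply(contigs, `[[`, character(1), "sequence")
  o <- order(-nchar(seqs))
  drop <- logical(length(contigs))
  for (ii in seq_along(o)[-1L]) {
    i <- o[ii]
    s <- seqs[i]
    rc <- reverse_complement(s)
    for (jj in seq_len(ii - 1L)) {
      j <- o[jj]
      if (drop[j]) next
      if (grepl(s, seqs[j], fixed = TRUE) ||
          grepl(rc, seqs[j], fixed = TRUE)) {
        drop[i] <- TRUE
        break
      }
    }
  }
  kept <- contigs[!drop]
  for (k in seq_along(kept)) kept[[k]]$id <- sprintf("contig_%05d", k)
  kept
}

#' @export
print.contig <- function(x, ...) {
  cat(x$id, ": ", nchar(x$sequence), " bp, ", length(x$vertices),
      " reads, ends: ", x$reason_left, "/", x$reason_right, "\n", sep = "")
  invisible(x)
}

contig_lengths <- function(contigs) {
  vapply(contigs, function(ct) nchar(ct$sequence), integer(1))
}

#' Write contigs to FASTA and their layout to TSV
#'
#' @param contigs list of contigs from [assemble()].
#' @param reads the [read_set] (for read ids in the layout table).
#' @param fasta_path,layout_path output paths (`NULL` skips the layout).
#' @export
write_contigs <- function(contigs, reads, fasta_path, layout_path = NULL) {
  seqs <- vapply(contigs, `[[`, character(1), "sequence")
  names(seqs) <- vapply(contigs, `[[`, character(1), "id")
  write_fasta(seqs, fasta_path)
  if (!is.null(layout_path)) {
    lay <- do.call(rbind, lapply(contigs, function(ct)
      data.frame(contig_id = ct$id,
                 read_id = reads$id[vertex_read(ct$vertices)],
                 offset = ct$offsets,
                 strand = vertex_strand(ct$vertices))))
    write.table(lay, layout_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fasta_path)
}
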
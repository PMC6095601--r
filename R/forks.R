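# Fork detection: forward forks (one path splits into several) and backward
# forks (several paths merge) discovered during traversal, counterchecked
# against missing-arc artifacts, then classified as repeat (stop and cut),
# sequencing error (ignore) or SNP bubble (ignore).

fork_event <- function(kind, cut_offset, dropped_or_added,
                       state_vertices, candidates = integer()) {
  structure(list(kind = kind, cut_offset = cut_offset,
                 dropped_or_added = dropped_or_added,
                 state_vertices = state_vertices,
                 candidates = candidates,
                 classification = NA_character_),
            class = "fork_event")
}

#' Dynamic candidate-drop threshold
#'
#' The number of simultaneously dropped (or added) candidates needed to
#' confirm a fork scales with the local coverage of the region relative to
#' the typical coverage of the data set:
#' `max(base_drop_threshold, round(coverage_scale * local / median))`.
#' Monotone non-decreasing in the local coverage.
#'
#' @param local_coverage coverage estimate around the current state.
#' @param coverage_distribution vector of per-vertex coverage estimates (its
#'   median is used), or a single precomputed median.
#' @param params an [assembly_params()] list.
#' @return Integer threshold.
#' @export
drop_threshold <- function(local_coverage, coverage_distribution, params) {
  med <- if (length(coverage_distribution) > 1L) {
    stats::median(coverage_distribution[coverage_distribution > 0])
  } else as.numeric(coverage_distribution)
  if (!is.finite(med) || med <= 0) med <- 1
  max(params$base_drop_threshold,
      as.integer(round(params$coverage_scale * local_coverage / med)))
}

# any arc from a vertex in `from_set` to a vertex in `to_set`?
has_arc_between <- function(graph, from_set, to_set) {
  if (!length(from_set) || !length(to_set)) return(FALSE)
  for (v in from_set) {
    rows <- out_arc_rows(graph, v)
    if (any(graph$arcs$to[rows] %in% to_set)) return(TRUE)
  }
  FALSE
}

#' Detect a forward fork
#'
#' A forward fork is confirmed when, after the state has moved entirely onto
#' one branch, a whole group of candidates belonging to the other branch
#' loses support at once: at least `threshold` candidates dropped, and --
#' the countercheck -- no arc leads from any dropped vertex back into the
#' state (such an arc would mean the "fork" is merely a jump over vertices
#' whose transitive arcs were missed during graph construction).  The
#' suggested cut lies directly before the state.
#'
#' @param state_before,state_after state objects (`list(vertices, offsets,
#'   lens)`) before and after the pruning step that dropped the candidates.
#' @param dropped integer vertex ids of the candidates that lost support.
#' @param graph an `overlap_graph`.
#' @param threshold confirmation threshold, usually from [drop_threshold()].
#' @param scope countercheck scope: `"newest"` tests arcs from the dropped
#'   group into the newest state member only, `"any"` into any member.
#' @return A `fork_event` (kind `"forward"`, `cut_offset` = offset of the
#'   first vertex of `state_after`) or `NULL`.
#' @export
detect_forward_fork <- function(state_before, state_after, dropped, graph,
                                threshold, scope = c("newest", "any")) {
  scope <- match.arg(scope)
  if (length(dropped) < threshold) return(NULL)
  targets <- if (scope == "newest") {
    tail(state_after$vertices, 1L)
  } else state_after$vertices
  if (has_arc_between(graph, dropped, targets)) return(NULL)
  fork_event("forward", cut_offset = state_after$offsets[1L],
             dropped_or_added = dropped,
             state_vertices = state_after$vertices)
}

#' Detect a backward fork
#'
#' The mirror situation of a forward fork: as the state enters the vertex
#' common to two merging branches, candidates appear that are supported only
#' by the newest vertex and carry incoming arcs from vertices outside the
#' current path -- the tail of the other branch.  Confirmed when at least
#' `threshold` added candidates have such outside predecessors and no arc
#' runs in the reverse direction from the added group back to the state.
#'
#' @param state the current state (`list(vertices, offsets, lens)`), whose
#'   last entry is the newly added vertex.
#' @param added integer vertex ids of candidates introduced solely by the
#'   newest vertex.
#' @param graph an `overlap_graph`.
#' @param threshold confirmation threshold.
#' @param known integer vertex ids that do not count as "outside" (the rest
#'   of the current path and candidate front, when called from traversal).
#' @return A `fork_event` (kind `"backward"`, `cut_offset` = offset of the
#'   newest state vertex) or `NULL`.
#' @export
detect_backward_fork <- function(state, added, graph, threshold,
                                 known = integer()) {
  if (length(added) < threshold) return(NULL)
  inside <- c(state$vertices, added, known)
  outside_support <- vapply(added, function(v) {
    rows <- in_arc_rows(graph, v)
    any(!(graph$arcs$from[rows] %in% inside))
  }, logical(1))
  if (sum(outside_support) < threshold) return(NULL)
  if (has_arc_between(graph, added, state$vertices)) return(NULL)
  fork_event("backward",
             cut_offset = state$offsets[length(state$offsets)],
             dropped_or_added = added,
             state_vertices = state$vertices)
}

#' Classify a confirmed fork
#'
#' Distinguishes the three sources of forks in a DNA overlap graph:
#' * `"error"` -- the alternative branch dies out within `dead_end_limit`
#'   vertices (a tip of erroneous reads); the fork is ignored.
#' * `"snp"` -- the branches rejoin within `bubble_window` vertices (the
#'   branch reaches the current path or candidate front), or the branch
#'   candidate sets are similar (Jaccard >= `candidate_similarity_tau`);
#'   the fork is discarded and traversal continues on the supported branch.
#' * `"repeat"` -- neither of the above: both branches are real alternative
#'   genomic contexts, traversal must stop and cut.
#'
#' @param event a `fork_event` whose `candidates` field holds the current
#'   branch's candidate front.
#' @param graph an `overlap_graph`.
#' @param params an [assembly_params()] list.
#' @return One of `"error"`, `"snp"`, `"repeat"`.
#' @export
classify_fork <- function(event, graph, params) {
  branch_b <- event$dropped_or_added
  branch_a <- unique(c(event$state_vertices, event$candidates))
  own_reads <- vertex_read(branch_a)
  max_depth <- max(params$dead_end_limit, params$bubble_window)
  step <- function(frontier, seen) {
    nxt <- unique(unlist(lapply(frontier, function(v)
      graph$arcs$to[out_arc_rows(graph, v)])))
    setdiff(nxt, seen)
  }
  # a backward fork with no remaining candidate front has nothing to
  # compare against; without corroboration it is treated as a bubble
  if (event$kind == "backward" && !length(event$candidates)) return("snp")
  # expand both branch fronts in lockstep; reconvergence (by read, either
  # strand) within the bubble window means the fork is a bubble, not a
  # genuine alternative genomic context.  Our own front advances first so
  # a branch running slightly ahead is still caught at the same depth.
  fb <- branch_b; seen_b <- branch_b
  fa <- event$candidates; seen_a <- unique(c(branch_a, event$candidates))
  died_at <- NA_integer_
  for (depth in seq_len(max_depth)) {
    if (depth <= params$bubble_window && length(fa)) {
      na <- step(fa, seen_a)
      seen_a <- c(seen_a, na)
      fa <- na
    }
    nb <- step(fb, seen_b)
    if (depth <= params$bubble_window) {
      if (any(vertex_read(nb) %in% own_reads) ||
          any(vertex_read(nb) %in% vertex_read(seen_a))) {
        return("snp")
      }
    }
    if (!length(nb)) { died_at <- depth; break }
    seen_b <- c(seen_b, nb)
    fb <- nb
  }
  if (!is.na(died_at) && died_at <= params$dead_end_limit) return("error")
  # candidate-set similarity between the two branch fronts
  b_cand <- unique(unlist(lapply(branch_b, function(v)
    graph$arcs$to[out_arc_rows(graph, v)])))
  a_cand <- event$candidates
  if (length(a_cand) || length(b_cand)) {
    jac <- length(intersect(a_cand, b_cand)) /
      length(union(a_cand, b_cand))
    if (jac >= params$candidate_similarity_tau) return("snp")
  }
  "repeat"
}
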
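# Double-vertex bookkeeping: read i is represented by two oriented vertices,
# 2i-1 (as stored, "+") and 2i (reverse complement, "-").

#' Vertex id of a read and strand
#' @param read integer read index.
#' @param strand `"+"` or `"-"`.
#' @export
vertex_id <- function(read, strand = "+") {
  2L * as.integer(read) - as.integer(strand == "+")
}

#' Read index of a vertex
#' @param v integer vertex id.
#' @export
vertex_read <- function(v) (as.integer(v) + 1L) %/% 2L

#' Strand of a vertex
#' @param v integer vertex id.
#' @export
vertex_strand <- function(v) ifelse(v %% 2L == 1L, "+", "-")

#' Reverse-complement partner vertex
#' @param v integer vertex id.
#' @export
partner_vertex <- function(v) {
  v <- as.integer(v)
  v + ifelse(v %% 2L == 1L, 1L, -1L)
}

# Character vector of all 2n oriented read sequences.
oriented_sequences <- function(rs) {
  n <- length(rs)
  if (n == 0L) return(character())
  out <- character(2L * n)
  out[seq(1L, 2L * n, 2L)] <- rs$seq
  out[seq(2L, 2L * n, 2L)] <- reverse_complement(rs$seq)
  out
}

#' Build the overlap graph from verified results
#'
#' Every read contributes a double vertex (itself and its reverse
#' complement).  Each accepted overlap is inserted once in canonical
#' direction -- the arc u -> v means v extends u rightward (positive shift)
#' -- together with its reverse-complement mirror, computed arithmetically
#' via [mirror_revcomp()] without re-alignment.  Containments (the target
#' does not extend past the source) are stored but flagged and excluded
#' from traversal.
#'
#' @param rs the [read_set] the results refer to.
#' @param results data frame of accepted overlaps from [find_overlaps()]
#'   (columns `a`, `b`, `score`, `shift`, `overlap`, `errors`).
#' @return An object of class `overlap_graph`.
#' @export
build_graph <- function(rs, results) {
  n <- length(rs)
  nv <- 2L * n
  vlen <- rep(nchar(rs$seq), each = 2L)
  if (nrow(results)) {
    if (any(results$a > nv | results$b > nv | results$a < 1L | results$b < 1L)) {
      stop("overlap result references an unknown read", call. = FALSE)
    }
    # canonical direction: positive shift from -> to
    pos <- results$shift >= 0L
    from <- ifelse(pos, results$a, results$b)
    to <- ifelse(pos, results$b, results$a)
    shift <- abs(results$shift)
    arc <- data.frame(from = from, to = to, shift = shift,
                      overlap = results$overlap, errors = results$errors,
                      score = results$score)
    # arithmetic mirror onto the reverse complements
    mir <- data.frame(from = partner_vertex(arc$to),
                      to = partner_vertex(arc$from),
                      shift = vlen[arc$to] - arc$overlap,
                      overlap = arc$overlap, errors = arc$errors,
                      score = arc$score)
    arc <- rbind(arc, mir)
    arc <- arc[!duplicated(paste(arc$from, arc$to, arc$shift)), , drop = FALSE]
    arc$contained <- !(arc$shift > 0L &
                         arc$shift + vlen[arc$to] > vlen[arc$from])
  } else {
    arc <- data.frame(from = integer(), to = integer(), shift = integer(),
                      overlap = integer(), errors = integer(),
                      score = integer(), contained = logical())
  }
  o <- order(arc$from, -arc$overlap, arc$to)
  arc <- arc[o, , drop = FALSE]
  rownames(arc) <- NULL
  out_ptr <- cumsum(c(0L, tabulate(arc$from, nbins = nv)))
  oi <- order(arc$to, -arc$overlap, arc$from)
  in_ptr <- cumsum(c(0L, tabulate(arc$to, nbins = nv)))
  usable <- !arc$contained
  deg <- tabulate(arc$from[usable], nbins = nv) +
    tabulate(arc$to[usable], nbins = nv)
  structure(list(n_reads = n, n_vertices = nv, vlen = vlen, arcs = arc,
                 out_ptr = out_ptr, in_idx = oi, in_ptr = in_ptr,
                 deg = deg,
                 deg_median = if (any(deg > 0)) stats::median(deg[deg > 0]) else 1),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat("overlap_graph:", x$n_reads, "reads /", x$n_vertices, "vertices,",
      nrow(x$arcs), "arcs (", sum(x$arcs$contained), "containments )\n")
  invisible(x)
}

# Row indices into g$arcs of the outgoing arcs of v (already sorted by
# decreasing overlap then target id).
out_arc_rows <- function(g, v, include_contained = FALSE) {
  if (g$out_ptr[v] == g$out_ptr[v + 1L]) return(integer())
  rows <- (g$out_ptr[v] + 1L):g$out_ptr[v + 1L]
  if (!include_contained) rows <- rows[!g$arcs$contained[rows]]
  rows
}

in_arc_rows <- function(g, v, include_contained = FALSE) {
  if (g$in_ptr[v] == g$in_ptr[v + 1L]) return(integer())
  rows <- g$in_idx[(g$in_ptr[v] + 1L):g$in_ptr[v + 1L]]
  if (!include_contained) rows <- rows[!g$arcs$contained[rows]]
  rows
}

#' Outgoing arcs of a vertex
#'
#' Arcs are returned sorted by decreasing overlap length, ties broken by
#' target vertex id, so traversal order is deterministic.
#'
#' @param graph an `overlap_graph`.
#' @param v vertex id.
#' @param include_contained also return containment arcs.
#' @return Data frame of arcs (columns as in `graph$arcs`).
#' @export
out_neighbors <- function(graph, v, include_contained = FALSE) {
  if (length(v) != 1L || v < 1L || v > graph$n_vertices) {
    stop("unknown vertex: ", v, call. = FALSE)
  }
  rows <- out_arc_rows(graph, v, include_contained)
  graph$arcs[rows, , drop = FALSE]
}

#' Export the arc table as TSV
#'
#' Columns: source/target read id and strand, shift, overlap length,
#' errors, score.
#'
#' @param graph an `overlap_graph`.
#' @param rs the [read_set] (for read ids).
#' @param path output TSV path.
#' @export
write_arcs_tsv <- function(graph, rs, path) {
  a <- graph$arcs
  df <- data.frame(a_id = rs$id[vertex_read(a$from)],
                   a_strand = vertex_strand(a$from),
                   b_id = rs$id[vertex_read(a$to)],
                   b_strand = vertex_strand(a$to),
                   shift = a$shift, overlap_length = a$overlap,
                   errors = a$errors, score = a$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
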
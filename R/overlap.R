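#' Default assembler parameters
#'
#' One flat list of the tunable parameters shared by the pipeline stages.
#' Alignment scoring is conventional (match +1, mismatch -1, gap -2, end gaps
#' free); "errors" counts mismatches plus gap columns inside the overlapped
#' region.  `k`, `window` and `d` steer overlap preselection; `min_overlap`
#' and `max_error_rate` are the arc acceptance thresholds; the fork and
#' state parameters control traversal.
#'
#' @param ... overrides for any default, by name.
#' @return A named list of parameters.
#' @export
assembly_params <- function(...) {
  p <- list(
    # alignment scoring
    match = 1L, mismatch = -1L, gap = -2L,
    # arc acceptance
    min_overlap = 40L, max_error_rate = 0.03,
    # preselection
    k = 16L, window = 8L, d = 14L, successor_rounds = 3L,
    # traversal state
    min_state_overlap = 40L,
    # fork detection
    base_drop_threshold = 2L, coverage_scale = 3,
    dead_end_limit = 5L, bubble_window = 10L,
    candidate_similarity_tau = 0.5,
    countercheck_scope = "newest",   # or "any"
    # output
    min_contig = 250L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(ov)] <- ov
  p
}

#' Semi-global overlap alignment of two sequences
#'
#' Optimal dovetail/containment alignment with free end gaps (the overlap
#' variant of Needleman-Wunsch).  Returns the alignment score, the signed
#' `shift` of `b`'s start relative to `a`'s start, the number of alignment
#' columns in the overlapped region (`overlap_length`), and the `errors`
#' (mismatches plus gap columns) inside it.  Swapping `a` and `b` negates the
#' shift.  Ties between equally scoring end positions are broken
#' deterministically (last column top-to-bottom, then last row
#' left-to-right; traceback prefers diagonal over vertical over horizontal).
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap alignment scores.
#' @return A list of class `overlap_result` with `score`, `shift`,
#'   `overlap_length`, `errors`.
#' @export
semiglobal_overlap <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  v <- .semiglobal_one_cpp(a, b, match, mismatch, gap)
  structure(list(score = v[["score"]], shift = v[["shift"]],
                 overlap_length = v[["overlap"]], errors = v[["errors"]]),
            class = "overlap_result")
}

#' Arc acceptance rule
#'
#' An overlap becomes an arc when it is long enough and clean enough:
#' `overlap_length >= min_overlap` and
#' `errors <= ceiling(max_error_rate * overlap_length)`.
#'
#' @param result an `overlap_result` (or any list with `overlap_length` and
#'   `errors`).
#' @param min_overlap minimum overlap length in bp.
#' @param max_error_rate maximum fraction of erroneous columns.
#' @return `TRUE` or `FALSE`.
#' @export
accept_arc <- function(result, min_overlap = 40L, max_error_rate = 0.03) {
  stopifnot(min_overlap > 0, max_error_rate > 0)
  result$overlap_length >= min_overlap &&
    result$errors <= ceiling(max_error_rate * result$overlap_length)
}

#' k-mer characteristic of a read region
#'
#' The multiset of k-mers of the chosen region, with duplicate k-mers
#' collapsed into a counter, ordered by decreasing count and then
#' lexicographically -- a sortable fingerprint: reads that overlap over at
#' least half their length have characteristics that land close together
#' once all characteristics are sorted like dictionary words.  Partial
#' characteristics (`begin`/`center`/`end` thirds of the read) catch pairs
#' that overlap over a short terminal segment only.
#'
#' @param sequence DNA string.
#' @param k k-mer length.
#' @param region one of `"full"`, `"begin"`, `"center"`, `"end"` (thirds).
#' @return A list of class `kmer_characteristic` with `kmers`, `counts`,
#'   `region`, `k`.
#' @export
kmer_characteristic <- function(sequence, k,
                                region = c("full", "begin", "center", "end")) {
  region <- match.arg(region)
  n <- nchar(sequence)
  slice <- switch(region,
    full = sequence,
    begin = substr(sequence, 1L, ceiling(n / 3)),
    center = substr(sequence, ceiling(n / 3) + 1L, ceiling(2 * n / 3)),
    end = substring(sequence, ceiling(2 * n / 3) + 1L))
  m <- nchar(slice)
  if (k > m) stop("k exceeds the region length (", m, ")", call. = FALSE)
  km <- substring(slice, 1:(m - k + 1L), k:m)
  km <- sort_c(km)
  r <- rle(km)
  o <- order_c(-r$lengths, r$values)
  structure(list(kmers = r$values[o], counts = r$lengths[o],
                 region = region, k = k),
            class = "kmer_characteristic")
}

# Dictionary-sort key of a characteristic: the entry sequence flattened to
# "kmer:count" tokens; byte-wise lexicographic order over these keys is the
# deterministic total order used for the neighborhood scan.
characteristic_key <- function(ch) {
  paste(ch$kmers, ch$counts, sep = ":", collapse = " ")
}

#' Promising pairs from sorted k-mer characteristics
#'
#' Sorts the characteristics as words of a dictionary and emits every pair of
#' reads whose characteristics lie within `window` positions of each other on
#' the sorted list.
#'
#' @param characteristics list of [kmer_characteristic()] objects, each with
#'   a `$read_ref` field (an integer vertex id); all must share `k` and
#'   region.
#' @param window neighborhood size on the sorted list (>= 1).
#' @return Integer matrix with columns `a`, `b` (`a < b`), one unordered
#'   promising pair per row, duplicates removed.
#' @export
promising_from_characteristics <- function(characteristics, window = 8L) {
  stopifnot(window >= 1L)
  if (length(characteristics) < 2L) {
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b"))))
  }
  ks <- vapply(characteristics, `[[`, integer(1), "k")
  rg <- vapply(characteristics, `[[`, character(1), "region")
  if (length(unique(ks)) != 1L || length(unique(rg)) != 1L) {
    stop("characteristics must share k and region", call. = FALSE)
  }
  refs <- vapply(characteristics, `[[`, integer(1), "read_ref")
  keys <- vapply(characteristics, characteristic_key, character(1))
  neighbor_pairs(refs, keys, window)
}

# Shared neighborhood-scan: sort items by key, pair refs within `window`
# positions, canonicalise a < b, drop self pairs and duplicates.
neighbor_pairs <- function(refs, keys, window) {
  o <- order_c(keys)
  r <- refs[o]
  n <- length(r)
  out <- vector("list", min(window, n - 1L))
  for (w in seq_len(min(window, n - 1L))) {
    out[[w]] <- cbind(r[seq_len(n - w)], r[(w + 1L):n])
  }
  m <- do.call(rbind, out)
  a <- pmin(m[, 1L], m[, 2L])
  b <- pmax(m[, 1L], m[, 2L])
  keep <- a != b
  m <- unique(cbind(a = a[keep], b = b[keep]))
  m
}

#' Smallest lexicographical descriptors of a read
#'
#' For each half of the read, the lexicographically smallest substring of
#' length `d`.  Reads sharing a descriptor value are promising overlap
#' candidates.
#'
#' @param sequence DNA string.
#' @param d descriptor length (each half must be at least `d` long).
#' @return Character vector `c(first = ..., second = ...)`.
#' @export
smallest_lex_descriptor <- function(sequence, d) {
  n <- nchar(sequence)
  h <- n %/% 2L
  if (h < d) stop("read too short for descriptor length d = ", d, call. = FALSE)
  first <- substr(sequence, 1L, h)
  second <- substring(sequence, h + 1L)
  min_sub <- function(s) {
    m <- nchar(s)
    sort_c(substring(s, 1:(m - d + 1L), d:m))[1L]
  }
  c(first = min_sub(first), second = min_sub(second))
}

#' Paired-end promising-pair propagation
#'
#' If reads A and B overlap then their mates A' and B' may overlap as well
#' (on the opposite strand).  For every accepted arc whose two endpoint reads
#' both have mates, the strand-flipped mate vertices are emitted as a
#' promising pair for later verification.
#'
#' @param arcs data frame of accepted overlaps with oriented vertex columns
#'   `a`, `b`.
#' @param mate integer vector mapping read index to mate read index (`NA` if
#'   unpaired), e.g. `rs$mate`.
#' @return Integer matrix of unordered promising pairs (columns `a`, `b`).
#' @export
propagate_paired <- function(arcs, mate) {
  if (nrow(arcs) == 0L) {
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b"))))
  }
  ma <- mate[vertex_read(arcs$a)]
  mb <- mate[vertex_read(arcs$b)]
  keep <- !is.na(ma) & !is.na(mb)
  if (!any(keep)) {
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b"))))
  }
  # mate vertex on the same genomic strand as v: flip the stored orientation
  flip_mate <- function(v, m) 2L * m - as.integer(v %% 2L == 0L)
  pa <- flip_mate(arcs$a[keep], ma[keep])
  pb <- flip_mate(arcs$b[keep], mb[keep])
  a <- pmin(pa, pb); b <- pmax(pa, pb)
  unique(cbind(a = a, b = b)[a != b, , drop = FALSE])
}

#' Successor promising-pair propagation
#'
#' If A overlaps both B and C, then B and C are marked as a promising pair.
#' All unordered pairs of overlap partners of each vertex are emitted; pairs
#' already present as arcs are excluded.
#'
#' @param arcs data frame of accepted overlaps with oriented vertex columns
#'   `a`, `b` (undirected overlap partners).
#' @return Integer matrix of unordered promising pairs (columns `a`, `b`).
#' @export
propagate_successors <- function(arcs) {
  empty <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b")))
  if (nrow(arcs) == 0L) return(empty)
  # undirected partner lists over both endpoints of every overlap
  ep <- c(arcs$a, arcs$b)
  other <- c(arcs$b, arcs$a)
  nb <- split(other, ep)
  out <- vector("list", length(nb))
  for (i in seq_along(nb)) {
    v <- sort(unique(nb[[i]]))
    if (length(v) < 2L) next
    n <- length(v)
    out[[i]] <- cbind(rep(v[-n], times = (n - 1L):1L),
                      v[unlist(lapply(2:n, function(j) j:n))])
  }
  m <- do.call(rbind, out)
  if (is.null(m) || nrow(m) == 0L) return(empty)
  colnames(m) <- c("a", "b")
  m <- unique(m)
  have <- paste(pmin(arcs$a, arcs$b), pmax(arcs$a, arcs$b))
  m[!(paste(m[, 1L], m[, 2L]) %in% have), , drop = FALSE]
}

#' Mirror an accepted overlap onto the reverse complements
#'
#' If A and B overlap, their reverse complements overlap too, with the same
#' overlap length and errors; only the shift changes.  No new alignment is
#' computed: for a dovetail overlap the mirrored shift is
#' `len_b - overlap_length`.
#'
#' @param result an `overlap_result` for the pair (a, b).
#' @param len_a,len_b the sequence lengths.
#' @return The `overlap_result` for the pair (rev-comp b, rev-comp a).
#' @export
mirror_revcomp <- function(result, len_a, len_b) {
  if (result$overlap_length > len_a || result$overlap_length > len_b ||
      abs(result$shift) >= max(len_a, len_b)) {
    stop("overlap result inconsistent with the given lengths", call. = FALSE)
  }
  structure(list(score = result$score,
                 shift = len_b - result$overlap_length,
                 overlap_length = result$overlap_length,
                 errors = result$errors),
            class = "overlap_result")
}

# ---- batch verification engine ------------------------------------------

# Canonicalise an oriented vertex pair modulo the mirror symmetry
# {u,v} ~ {partner(u), partner(v)} and return a single numeric key.
canonical_pairs <- function(a, b, n_vertices) {
  p1a <- pmin(a, b); p1b <- pmax(a, b)
  ma <- partner_vertex(a); mb <- partner_vertex(b)
  p2a <- pmin(ma, mb); p2b <- pmax(ma, mb)
  use2 <- (p2a < p1a) | (p2a == p1a & p2b < p1b)
  cbind(a = ifelse(use2, p2a, p1a), b = ifelse(use2, p2b, p1b))
}

pair_key <- function(a, b, n_vertices) {
  (as.numeric(a) - 1) * n_vertices + as.numeric(b)
}

# Align candidate pairs not seen before, keep those passing accept_arc.
# `state` is an environment carrying the pool, thresholds and the keys of
# every pair tested so far.
verify_promising <- function(pairs, state) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(NULL)
  nv <- length(state$vseq)
  cp <- canonical_pairs(pairs[, 1L], pairs[, 2L], nv)
  key <- pair_key(cp[, 1L], cp[, 2L], nv)
  dup <- duplicated(key)
  cp <- cp[!dup, , drop = FALSE]; key <- key[!dup]
  new <- !(key %in% state$tested)
  if (!any(new)) return(NULL)
  cp <- cp[new, , drop = FALSE]; key <- key[new]
  state$tested <- c(state$tested, key)
  res <- .semiglobal_batch_cpp(state$vseq, cp[, 1L], cp[, 2L],
                               state$params$match, state$params$mismatch,
                               state$params$gap)
  ok <- res[, "overlap"] >= state$params$min_overlap &
    res[, "errors"] <= ceiling(state$params$max_error_rate * res[, "overlap"])
  if (!any(ok)) return(NULL)
  data.frame(a = cp[ok, 1L], b = cp[ok, 2L],
             score = res[ok, "score"], shift = res[ok, "shift"],
             overlap = res[ok, "overlap"], errors = res[ok, "errors"])
}

#' Find verified overlaps among all reads
#'
#' The four-stage preselection pipeline: (1) full k-mer characteristics of
#' every oriented read, sorted as dictionary words and paired within a
#' neighborhood window; (2) partial characteristics of the begin/center/end
#' thirds; (3) smallest lexicographical descriptors of each read half,
#' paired on equal values; then verification of every promising pair by
#' semi-global alignment, followed by (4) paired-end and successor
#' propagation rounds that feed newly implied pairs back into verification
#' until no new arcs appear.
#'
#' @param rs a [read_set].
#' @param params an [assembly_params()] list.
#' @param progress print per-stage pair counts.
#' @return A data frame of accepted overlaps, one per mirror-equivalence
#'   class: oriented vertex columns `a`, `b`, plus `score`, `shift`,
#'   `overlap`, `errors`.
#' @export
find_overlaps <- function(rs, params = assembly_params(), progress = FALSE) {
  vseq <- oriented_sequences(rs)
  nv <- length(vseq)
  st <- new.env(parent = emptyenv())
  st$vseq <- vseq
  st$params <- params
  st$tested <- numeric(0)
  say <- function(...) if (progress) message(...)

  results <- list()
  add <- function(r) if (!is.null(r)) results[[length(results) + 1L]] <<- r
  arcs_so_far <- function() {
    if (!length(results)) {
      data.frame(a = integer(), b = integer(), score = integer(),
                 shift = integer(), overlap = integer(), errors = integer())
    } else do.call(rbind, results)
  }

  # characteristics: full read, then the three partial regions
  for (reg in c("full", "begin", "center", "end")) {
    ch <- lapply(seq_len(nv), function(v) {
      c0 <- kmer_characteristic(vseq[v], params$k, reg)
      c0$read_ref <- v
      c0
    })
    pp <- promising_from_characteristics(ch, params$window)
    say("characteristic [", reg, "]: ", nrow(pp), " promising pairs")
    add(verify_promising(pp, st))
  }

  # smallest lexicographical descriptors, matched across halves
  desc <- vapply(vseq, smallest_lex_descriptor, character(2), d = params$d)
  refs <- rep(seq_len(nv), each = 2L)
  vals <- as.vector(desc)
  grp <- split(refs, vals)
  dp <- do.call(rbind, lapply(grp, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2L) return(NULL)
    n <- length(v)
    cbind(rep(v[-n], times = (n - 1L):1L),
          v[unlist(lapply(2:n, function(j) j:n))])
  }))
  say("descriptors: ", if (is.null(dp)) 0L else nrow(dp), " promising pairs")
  add(verify_promising(dp, st))

  # paired-end propagation
  pp <- propagate_paired(arcs_so_far(), rs$mate)
  say("paired-end propagation: ", nrow(pp), " promising pairs")
  add(verify_promising(pp, st))

  # successor propagation rounds until closure (bounded)
  for (round in seq_len(params$successor_rounds)) {
    sp <- propagate_successors(arcs_so_far())
    say("successor round ", round, ": ", nrow(sp), " promising pairs")
    r <- verify_promising(sp, st)
    if (is.null(r)) break
    add(r)
  }

  out <- arcs_so_far()
  rownames(out) <- NULL
  out
}
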
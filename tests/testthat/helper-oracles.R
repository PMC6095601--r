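# Independent oracles and fixture builders shared across the test files.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Row-vectorised semi-global DP, written independently of the C++ engine but
# following the same documented conventions (end-cell scan order, traceback
# preference, shift/overlap/errors definitions).
nw_oracle <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(av); m <- length(bv)
  H <- matrix(0L, n + 1L, m + 1L)
  for (i in 1:n) {
    s <- ifelse(av[i] == bv, match, mismatch)
    d <- H[i, 1:m] + s
    u <- H[i, 2:(m + 1L)] + gap
    row <- integer(m + 1L)
    for (j in 1:m) row[j + 1L] <- max(d[j], u[j], row[j] + gap)
    H[i + 1L, ] <- row
  }
  bi <- 0L; bj <- m; bs <- H[1L, m + 1L]
  for (i in 1:n) if (H[i + 1L, m + 1L] > bs) { bs <- H[i + 1L, m + 1L]; bi <- i; bj <- m }
  for (j in 0:(m - 1L)) if (H[n + 1L, j + 1L] > bs) { bs <- H[n + 1L, j + 1L]; bi <- n; bj <- j }
  i <- bi; j <- bj; cols <- 0L; errs <- 0L
  while (i > 0L && j > 0L) {
    sc <- if (av[i] == bv[j]) match else mismatch
    if (H[i + 1L, j + 1L] == H[i, j] + sc) {
      if (av[i] != bv[j]) errs <- errs + 1L
      cols <- cols + 1L; i <- i - 1L; j <- j - 1L
    } else if (H[i + 1L, j + 1L] == H[i, j + 1L] + gap) {
      cols <- cols + 1L; errs <- errs + 1L; i <- i - 1L
    } else {
      cols <- cols + 1L; errs <- errs + 1L; j <- j - 1L
    }
  }
  c(score = bs, shift = i - j, overlap = cols, errors = errs)
}

# Exhaustive quality-filter oracle: scan every substring, keep the longest
# whose every full window passes.
quality_filter_oracle <- function(q, min_q, w) {
  n <- length(q)
  best <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (e - s + 1L < w) next
      ok <- all(vapply(s:(e - w + 1L), function(i)
        mean(q[i:(i + w - 1L)]) >= min_q, logical(1)))
      if (ok && (is.null(best) || e - s > best[2L] - best[1L])) best <- c(s, e)
    }
  }
  best
}

# Brute-force NG(X): try every distinct contig length as the cutoff.
ngx_oracle <- function(lens, genome_length, x) {
  lens <- lens[lens > 0]
  need <- genome_length * x / 100
  for (c0 in sort(unique(lens), decreasing = TRUE)) {
    if (sum(as.numeric(lens[lens >= c0])) >= need) return(as.integer(c0))
  }
  NA_integer_
}

# Unpaired read set tiling a template sequence at a fixed step.
tile_reads <- function(template, read_length = 100L, step = 10L,
                       prefix = "t") {
  n <- nchar(template)
  starts <- seq(1L, n - read_length + 1L, by = step)
  seqs <- substring(template, starts, starts + read_length - 1L)
  read_set(paste0(prefix, seq_along(starts)), seqs,
           rep(list(rep(37L, read_length)), length(starts)))
}

# A tiny overlap graph from hand-written arc rows (oriented vertex ids a, b
# with the shift of b relative to a; all reads the same length).
toy_graph <- function(n_reads, arcs, read_length = 100L) {
  rs <- read_set(paste0("r", seq_len(n_reads)),
                 vapply(seq_len(n_reads), function(i) random_dna(read_length),
                        character(1)),
                 rep(list(rep(37L, read_length)), n_reads))
  res <- data.frame(a = arcs$a, b = arcs$b, score = arcs$overlap,
                    shift = arcs$shift, overlap = arcs$overlap,
                    errors = 0L)
  list(reads = rs, graph = build_graph(rs, res))
}

canonical_key <- function(a, b, n_vertices) {
  m <- olcassembler:::canonical_pairs(a, b, n_vertices)
  paste(m[, 1L], m[, 2L])
}

# Strand-canonical form of a contig sequence: a contig legitimately
# assembles on either strand, so comparisons use min(s, revcomp(s)).
canon_seq <- function(s) {
  vapply(s, function(x) {
    rc <- reverse_complement(x)
    if (x <= rc) x else rc
  }, character(1), USE.NAMES = FALSE)
}

# Contig vectors carry bookkeeping attributes (cuts/trims); comparisons of
# the sequences themselves strip everything but names.
drop_attrs <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(names = names(y))
  y
}
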
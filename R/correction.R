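# Paired-end contig correction: reads are mapped back to contigs, two
# low-level anomaly detectors scan the mapping, and a greedy hyper-heuristic
# decides which proposed cut to apply next, learning which detector is more
# useful on the instance at hand.

#' Correction parameters
#'
#' Defaults are derived from the library geometry: the accepted insert range
#' is `insert_mean` plus/minus 3 standard deviations, the minimal continuity
#' break width defaults to the mean insert, and the density window to the
#' read length.  The mismapped-pair count threshold defaults to
#' `max(3, local pair coverage / 4)` computed per contig when left `NULL`.
#'
#' @param insert_mean,insert_sd library insert size distribution (bp).
#' @param read_length read length (bp).
#' @param min_break_width minimal width of a paired-end continuity break to
#'   count as an anomaly (bp).
#' @param window sliding window for the mismapped-density detector (bp).
#' @param mismap_count_threshold pairs-to-different-contigs count threshold
#'   (`NULL` = adaptive).
#' @param insert_min,insert_max accepted insert size range (bp).
#' @param min_piece minimum contig piece kept after a cut (bp).
#' @param max_iter safety bound on hyper-heuristic iterations.
#' @return A named list of parameters.
#' @export
correction_params <- function(insert_mean = 300, insert_sd = 30,
                              read_length = 100L,
                              min_break_width = insert_mean,
                              window = read_length,
                              mismap_count_threshold = NULL,
                              insert_min = insert_mean - 3 * insert_sd,
                              insert_max = insert_mean + 3 * insert_sd,
                              min_piece = 250L, max_iter = 50L) {
  stopifnot(insert_min <= insert_max, min_break_width > 0, window > 0)
  list(insert_mean = insert_mean, insert_sd = insert_sd,
       read_length = read_length, min_break_width = min_break_width,
       window = as.integer(window),
       mismap_count_threshold = mismap_count_threshold,
       insert_min = insert_min, insert_max = insert_max,
       min_piece = as.integer(min_piece), max_iter = as.integer(max_iter))
}

#' Map reads to contigs
#'
#' Reads that belong to a contig's layout are mapped at their layout
#' offsets.  The remaining reads are mapped by exact seed match (a terminal
#' seed of the read, on either strand) followed by full-length verification
#' allowing a small mismatch budget; reads with zero or several equally
#' good positions stay unmapped.  Mates are joined into pair geometry by the
#' anomaly detectors downstream.
#'
#' @param contigs list of contigs (with or without layouts) or named
#'   character vector of contig sequences.
#' @param reads the [read_set].
#' @param seed_length exact seed length for mapping (bp).
#' @param max_mismatch_rate mismatch budget for full-length verification.
#' @return A `read_mapping`: data frame with `read` (index), `contig`
#'   (name), `pos` (1-based start), `strand`, plus attributes
#'   `contig_lengths` and `reads`.
#' @export
map_reads_to_contigs <- function(contigs, reads, seed_length = 31L,
                                 max_mismatch_rate = 0.03) {
  seqs <- contig_seqs(contigs)
  n <- length(reads)
  map <- data.frame(read = integer(), contig = character(),
                    pos = integer(), strand = character())
  placed <- logical(n)
  # layout-based placements
  if (is.list(contigs) && length(contigs) && is.list(contigs[[1L]])) {
    for (ct in contigs) {
      if (is.null(ct$vertices)) next
      r <- vertex_read(ct$vertices)
      map <- rbind(map, data.frame(
        read = r, contig = ct$id, pos = ct$offsets + 1L,
        strand = vertex_strand(ct$vertices)))
      placed[r] <- TRUE
    }
  }
  todo <- which(!placed)
  if (length(todo)) {
    rl <- nchar(reads$seq[todo])
    ok_len <- rl >= seed_length
    todo <- todo[ok_len]
    if (length(todo)) {
      fw <- substr(reads$seq[todo], 1L, seed_length)
      rc_full <- reverse_complement(reads$seq[todo])
      rc <- substr(rc_full, 1L, seed_length)
      pd_f <- Biostrings::PDict(fw)
      pd_r <- Biostrings::PDict(rc)
      cand <- vector("list", length(todo))
      for (ci in seq_along(seqs)) {
        subj <- Biostrings::DNAString(seqs[[ci]])
        mf <- Biostrings::matchPDict(pd_f, subj)
        mr <- Biostrings::matchPDict(pd_r, subj)
        for (i in seq_along(todo)) {
          pf <- IRanges::start(mf[[i]])
          pr <- IRanges::start(mr[[i]])
          if (length(pf)) cand[[i]] <- rbind(cand[[i]],
            cbind(ci = ci, pos = pf, fwd = 1L))
          if (length(pr)) cand[[i]] <- rbind(cand[[i]],
            cbind(ci = ci, pos = pr, fwd = 0L))
        }
      }
      for (i in seq_along(todo)) {
        cc <- cand[[i]]
        if (is.null(cc)) next
        ri <- todo[i]
        len <- nchar(reads$seq[ri])
        budget <- ceiling(max_mismatch_rate * len)
        hits <- list()
        for (j in seq_len(nrow(cc))) {
          ctg <- seqs[[cc[j, "ci"]]]
          p <- cc[j, "pos"]
          if (p + len - 1L > nchar(ctg)) next
          q <- if (cc[j, "fwd"] == 1L) reads$seq[ri] else rc_full[i]
          mm <- count_mismatches(q, substr(ctg, p, p + len - 1L))
          if (mm <= budget) hits[[length(hits) + 1L]] <- c(cc[j, "ci"], p,
                                                           cc[j, "fwd"])
        }
        if (length(hits) == 1L) {
          h <- hits[[1L]]
          map <- rbind(map, data.frame(
            read = ri, contig = names(seqs)[h[1L]], pos = h[2L],
            strand = if (h[3L] == 1L) "+" else "-"))
        }
      }
    }
  }
  rownames(map) <- NULL
  structure(map, contig_lengths = stats::setNames(nchar(seqs), names(seqs)),
            reads = reads, class = c("read_mapping", "data.frame"))
}

count_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# proper (innie, in-range) pairs of one contig: data.frame(left, right,
# start, end) in contig coordinates
proper_pairs <- function(mapping, contig_name, params) {
  reads <- attr(mapping, "reads")
  m <- mapping[mapping$contig == contig_name, , drop = FALSE]
  out <- NULL
  mate <- reads$mate[m$read]
  here <- match(mate, m$read)
  len <- nchar(reads$seq[m$read])
  ok <- !is.na(here) & m$read < ifelse(is.na(mate), 0L, mate)
  for (i in which(ok)) {
    j <- here[i]
    p1 <- m$pos[i]; p2 <- m$pos[j]
    if (p1 <= p2) { li <- i; ri <- j } else { li <- j; ri <- i }
    if (m$strand[li] != "+" || m$strand[ri] != "-") next
    ins <- (m$pos[ri] + len[ri] - 1L) - m$pos[li] + 1L
    if (ins < params$insert_min || ins > params$insert_max) next
    out <- rbind(out, c(start = m$pos[li], end = m$pos[ri] + len[ri] - 1L))
  }
  if (is.null(out)) {
    data.frame(start = integer(), end = integer())
  } else as.data.frame(out)
}

spanning_depth <- function(pairs, L) {
  d <- integer(L + 1L)
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      d[pairs$start[i]] <- d[pairs$start[i]] + 1L
      d[pairs$end[i] + 1L] <- d[pairs$end[i] + 1L] - 1L
    }
  }
  cumsum(d[seq_len(L)])
}

#' Detect paired-end continuity breaks
#'
#' For every contig position, counts the properly oriented read pairs (both
#' mates on the contig, insert within range) whose insert interval spans
#' it.  Maximal zero-coverage runs of width at least `min_break_width`,
#' outside the `insert_max` end margins where no pair can span by
#' construction, become anomalies; severity is the run width.
#'
#' @param mapping a `read_mapping`.
#' @param contig contig name.
#' @param params a [correction_params()] list.
#' @return Data frame of anomalies (`kind`, `contig`, `start`, `end`,
#'   `support`, `severity`).
#' @export
find_continuity_breaks <- function(mapping, contig, params) {
  L <- attr(mapping, "contig_lengths")[[contig]]
  empty <- data.frame(kind = character(), contig = character(),
                      start = integer(), end = integer(),
                      support = integer(), severity = numeric())
  margin <- as.integer(params$insert_max)
  if (L <= 2L * margin) return(empty)
  pp <- proper_pairs(mapping, contig, params)
  depth <- spanning_depth(pp, L)
  interior <- (margin + 1L):(L - margin)
  z <- depth[interior] == 0L
  if (!any(z)) return(empty)
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= params$min_break_width)
  if (!length(runs)) return(empty)
  data.frame(kind = "continuity_break", contig = contig,
             start = interior[starts[runs]], end = interior[ends[runs]],
             support = 1L, severity = as.numeric(r$lengths[runs]))
}

#' Detect mismapped paired-end density
#'
#' Slides a window over the contig and counts reads whose mate maps to a
#' different contig or to a distant (`> insert_max`) part of the same
#' contig.  Windows at least `mismap_count_threshold` high, outside the end
#' margins (mates naturally fall off contig ends), are merged into
#' anomalies; severity is the peak window count.
#'
#' @inheritParams find_continuity_breaks
#' @return Data frame of anomalies as in [find_continuity_breaks()], plus a
#'   `threshold` attribute with the count threshold used.
#' @export
find_mismapped_density <- function(mapping, contig, params) {
  L <- attr(mapping, "contig_lengths")[[contig]]
  reads <- attr(mapping, "reads")
  empty <- data.frame(kind = character(), contig = character(),
                      start = integer(), end = integer(),
                      support = integer(), severity = numeric())
  margin <- as.integer(params$insert_max)
  if (L <= 2L * margin) return(empty)
  m <- mapping[mapping$contig == contig, , drop = FALSE]
  mate <- reads$mate[m$read]
  mrow <- match(mate, mapping$read)
  anom <- !is.na(mrow) &
    (mapping$contig[mrow] != contig |
       abs(mapping$pos[mrow] - m$pos) > params$insert_max)
  thr <- params$mismap_count_threshold
  if (is.null(thr)) {
    pp <- proper_pairs(mapping, contig, params)
    depth <- spanning_depth(pp, L)
    interior <- (margin + 1L):(L - margin)
    thr <- max(3, mean(depth[interior]) / 4)
  }
  pos <- m$pos[anom]
  pos <- pos[pos >= 1L & pos <= L]
  if (!length(pos)) return(structure(empty, threshold = thr))
  cnt <- tabulate(pos, nbins = L)
  w <- params$window
  cs <- cumsum(c(0L, cnt))
  wc <- cs[(w + 1L):(L + 1L)] - cs[seq_len(L - w + 1L)]  # count per window
  wstart <- seq_len(L - w + 1L)
  ok <- wc >= thr & wstart >= margin + 1L & wstart + w - 1L <= L - margin
  if (!any(ok)) return(structure(empty, threshold = thr))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- do.call(rbind, lapply(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    peak <- max(wc[s:e])
    data.frame(kind = "mismapped_density", contig = contig,
               start = wstart[s], end = wstart[e] + w - 1L,
               support = sum(cnt[wstart[s]:(wstart[e] + w - 1L)]),
               severity = as.numeric(peak))
  }))
  structure(out, threshold = thr)
}

# best (highest normalised severity) anomaly of each kind across contigs
best_anomalies <- function(contigs, mapping, params) {
  seqs <- contig_seqs(contigs)
  breaks <- NULL; dens <- NULL; thr_used <- 3
  for (nm in names(seqs)) {
    b <- find_continuity_breaks(mapping, nm, params)
    if (nrow(b)) breaks <- rbind(breaks, b)
    d <- find_mismapped_density(mapping, nm, params)
    if (nrow(d)) { dens <- rbind(dens, d); thr_used <- attr(d, "threshold") }
  }
  list(breaks = breaks, dens = dens, dens_threshold = thr_used)
}

#' Greedy hyper-heuristic contig correction
#'
#' Each iteration both low-level detectors ([find_continuity_breaks()] and
#' [find_mismapped_density()]) propose their most severe anomaly; severities
#' are normalised per kind (break width over `min_break_width`, peak count
#' over the count threshold) and weighted by the detector's current utility.
#' The winning proposal is applied as a cut -- at the anomaly midpoint for
#' breaks, at the peak window center for densities.  The proposing
#' detector's utility is multiplied by 1.2 (capped at 4) when the cut
#' removes at least one anomaly on re-evaluation, by 0.8 (floored at 0.25)
#' otherwise.  The loop ends when no proposal passes the thresholds.
#' Pieces shorter than `min_piece` are discarded.
#'
#' @param contigs list of contigs or named character vector.
#' @param mapping a `read_mapping` for these contigs (recomputed internally
#'   after each cut).
#' @param params a [correction_params()] list.
#' @return Named character vector of corrected contig sequences, with a
#'   `cuts` attribute (data frame: contig, position, kind, severity).
#' @export
hyperheuristic_correct <- function(contigs, mapping, params) {
  seqs <- contig_seqs(contigs)
  reads <- attr(mapping, "reads")
  utility <- c(breaks = 1, dens = 1)
  cuts <- data.frame(contig = character(), position = integer(),
                     kind = character(), severity = numeric())
  cur_map <- mapping
  for (iter in seq_len(params$max_iter)) {
    an <- best_anomalies(seqs, cur_map, params)
    n_before <- NROW(an$breaks) + NROW(an$dens)
    prop <- list()
    if (NROW(an$breaks)) {
      i <- which.max(an$breaks$severity)
      prop$breaks <- list(a = an$breaks[i, ],
                          w = utility[["breaks"]] *
                            an$breaks$severity[i] / params$min_break_width)
    }
    if (NROW(an$dens)) {
      i <- which.max(an$dens$severity)
      prop$dens <- list(a = an$dens[i, ],
                        w = utility[["dens"]] *
                          an$dens$severity[i] / an$dens_threshold)
    }
    if (!length(prop)) break
    kind <- names(prop)[which.max(vapply(prop, `[[`, numeric(1), "w"))]
    a <- prop[[kind]]$a
    cutpos <- as.integer(round((a$start + a$end) / 2))
    cuts <- rbind(cuts, data.frame(contig = a$contig, position = cutpos,
                                   kind = a$kind, severity = a$severity))
    seqs <- apply_cut(seqs, a$contig, cutpos, params$min_piece)
    cur_map <- map_reads_to_contigs(seqs, reads)
    an2 <- best_anomalies(seqs, cur_map, params)
    n_after <- NROW(an2$breaks) + NROW(an2$dens)
    utility[[kind]] <- if (n_after < n_before) {
      min(4, utility[[kind]] * 1.2)
    } else max(0.25, utility[[kind]] * 0.8)
  }
  structure(seqs, cuts = cuts)
}

apply_cut <- function(seqs, contig, pos, min_piece) {
  s <- seqs[[contig]]
  L <- nchar(s)
  pieces <- c(substr(s, 1L, pos), substring(s, pos + 1L))
  names(pieces) <- paste0(contig, c(".1", ".2"))
  pieces <- pieces[nchar(pieces) >= min_piece]
  out <- seqs[names(seqs) != contig]
  c(out, pieces)
}
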
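# Contig trimming: scaffolders expect non-overlapping contigs, but OLC
# contigs carry duplicated sequence very close to their ends (the fork
# position inside a consensus cannot be pinpointed exactly).  End overlaps
# are located by aligning terminal windows and removed from one contig of
# each pair -- unless that would shorten a contig below the keep threshold,
# in which case the other contig is tried, and failing that the pair is
# left untouched to protect short contigs.

#' Find overlapping contig ends
#'
#' Aligns terminal windows of every contig pair (tail-head on the same
#' strand and the strand-crossing combinations) with the semi-global
#' aligner and reports end duplications of at least `min_dup_length` bp
#' within the arc error budget.  Each contig pair is reported once, with
#' its longest end overlap.
#'
#' @param contigs list of contigs or named character vector.
#' @param min_dup_length minimum duplicated length to report (bp).
#' @param max_error_rate error budget, as for arc acceptance.
#' @param end_window how much of each contig end to inspect (bp).
#' @return Data frame: `contig_a`, `contig_b`, `end_a`, `end_b`
#'   (`"head"`/`"tail"`), `length`.
#' @export
find_end_overlaps <- function(contigs, min_dup_length = 40L,
                              max_error_rate = 0.03, end_window = 500L) {
  seqs <- contig_seqs(contigs)
  nms <- names(seqs)
  out <- NULL
  if (length(seqs) < 2L) {
    return(data.frame(contig_a = character(), contig_b = character(),
                      end_a = character(), end_b = character(),
                      length = integer()))
  }
  win <- function(s, side) {
    L <- nchar(s)
    w <- min(L, end_window)
    if (side == "head") substr(s, 1L, w) else substring(s, L - w + 1L)
  }
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in (i + 1L):length(seqs)) {
      a <- seqs[[i]]; b <- seqs[[j]]
      combos <- list(
        list(x = win(a, "tail"), y = win(b, "head"),
             end_a = "tail", end_b = "head"),
        list(x = win(b, "tail"), y = win(a, "head"),
             end_a = "head", end_b = "tail"),
        list(x = win(a, "tail"), y = reverse_complement(win(b, "tail")),
             end_a = "tail", end_b = "tail"),
        list(x = reverse_complement(win(a, "head")), y = win(b, "head"),
             end_a = "head", end_b = "head"))
      best <- NULL
      for (cb in combos) {
        r <- semiglobal_overlap(cb$x, cb$y)
        if (r$overlap_length >= min_dup_length &&
            r$errors <= ceiling(max_error_rate * r$overlap_length) &&
            (is.null(best) || r$overlap_length > best$length)) {
          best <- data.frame(contig_a = nms[i], contig_b = nms[j],
                             end_a = cb$end_a, end_b = cb$end_b,
                             length = r$overlap_length)
        }
      }
      if (!is.null(best)) out <- rbind(out, best)
    }
  }
  if (is.null(out)) {
    data.frame(contig_a = character(), contig_b = character(),
               end_a = character(), end_b = character(), length = integer())
  } else out
}

#' Trim overlapping contig ends
#'
#' For each end overlap, the longer contig of the pair is trimmed first
#' (minimizing relative information loss); if trimming would push it below
#' `min_keep` bp, the other contig is tried; if both would fall below the
#' threshold, the pair is left untouched.
#'
#' @param contigs list of contigs or named character vector.
#' @param overlaps output of [find_end_overlaps()].
#' @param min_keep minimum contig length after trimming (bp).
#' @return Named character vector of trimmed contig sequences, with a
#'   `trims` attribute describing the applied trims.
#' @export
trim_contigs <- function(contigs, overlaps, min_keep = 250L) {
  seqs <- contig_seqs(contigs)
  trims <- data.frame(contig = character(), end = character(),
                      length = integer())
  if (nrow(overlaps)) {
    overlaps <- overlaps[order(-overlaps$length), , drop = FALSE]
    for (i in seq_len(nrow(overlaps))) {
      ov <- overlaps[i, ]
      la <- nchar(seqs[[ov$contig_a]])
      lb <- nchar(seqs[[ov$contig_b]])
      # the longer contig loses its end first
      order_try <- if (la >= lb) c("a", "b") else c("b", "a")
      for (side in order_try) {
        nm <- if (side == "a") ov$contig_a else ov$contig_b
        end <- if (side == "a") ov$end_a else ov$end_b
        L <- nchar(seqs[[nm]])
        if (L - ov$length < min_keep) next
        seqs[[nm]] <- if (end == "tail") {
          substr(seqs[[nm]], 1L, L - ov$length)
        } else {
          substring(seqs[[nm]], ov$length + 1L)
        }
        trims <- rbind(trims, data.frame(contig = nm, end = end,
                                         length = ov$length))
        break
      }
    }
  }
  structure(seqs, trims = trims)
}
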
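# Lightweight assembly evaluation against a known reference: NG(X),
# genome fraction, duplication ratio and misassembly detection via exact
# anchor seeding + extension.  Intended for synthetic references with no or
# low error rates, not as a general-purpose aligner.

#' NG(X) contig length
#'
#' The length `c` of the longest contig such that all contigs of length at
#' least `c` together cover at least `x` percent of the genome length.
#' Undefined (`NA`) when the total contig length is below `x%` of the
#' genome.
#'
#' @param contig_lengths vector of contig lengths in bp.
#' @param genome_length reference genome length in bp.
#' @param x percentage threshold (0 < x <= 100), 50 for the classic NG50.
#' @return The NG(X) length in bp, or `NA` if undefined.
#' @export
ngx <- function(contig_lengths, genome_length, x = 50) {
  stopifnot(genome_length > 0, x > 0, x <= 100)
  contig_lengths <- contig_lengths[contig_lengths > 0]
  if (!length(contig_lengths)) return(NA_integer_)
  s <- sort(contig_lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  need <- genome_length * x / 100
  i <- which(cum >= need)
  if (!length(i)) return(NA_integer_)
  as.integer(s[i[1L]])
}

#' Average depth of coverage of a paired-end library
#'
#' `floor(2 * n_pairs * read_length / genome_length)` -- both mates of every
#' pair contribute `read_length` bases over the genome.
#'
#' @param n_pairs number of read pairs.
#' @param read_length average read length in bp.
#' @param genome_length genome (or effective chromosome) length in bp.
#' @return Integer-valued depth of coverage.
#' @export
depth_of_coverage <- function(n_pairs, read_length, genome_length) {
  stopifnot(n_pairs > 0, read_length > 0, genome_length > 0)
  floor(2 * as.numeric(n_pairs) * as.numeric(read_length) /
          as.numeric(genome_length))
}

# Anchor hits of one contig against the reference on one strand.
# `ref_str` is the forward reference or its reverse complement; positions
# are reported in the coordinates of `ref_str`.
anchor_hits <- function(contig, ref_str, anchor_length, anchor_step) {
  L <- nchar(contig)
  if (L < anchor_length) return(NULL)
  starts <- unique(c(seq.int(1L, L - anchor_length + 1L, by = anchor_step),
                     L - anchor_length + 1L))
  anchors <- substring(contig, starts, starts + anchor_length - 1L)
  pd <- Biostrings::PDict(anchors)
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(ref_str))
  hits <- do.call(rbind, lapply(seq_along(starts), function(i) {
    p <- IRanges::start(m[[i]])
    if (!length(p)) return(NULL)
    cbind(cstart = starts[i], rstart = p)
  }))
  hits
}

# Collinear blocks from anchor hits: group by diagonal, split at big gaps,
# then extend the block ends by exact matching.
anchor_blocks <- function(contig, ref_str, hits, anchor_length, max_gap) {
  if (is.null(hits)) return(NULL)
  diag <- hits[, "rstart"] - hits[, "cstart"]
  out <- list()
  for (d in unique(diag)) {
    h <- hits[diag == d, , drop = FALSE]
    h <- h[order(h[, "cstart"]), , drop = FALSE]
    gaps <- diff(h[, "cstart"])
    grp <- cumsum(c(0L, gaps > max_gap))
    for (g in unique(grp)) {
      hh <- h[grp == g, , drop = FALSE]
      first <- hh[1L, ]
      last <- hh[nrow(hh), ]
      el <- .extend_exact_cpp(contig, ref_str, first[["cstart"]],
                              first[["rstart"]], anchor_length)
      er <- .extend_exact_cpp(contig, ref_str, last[["cstart"]],
                              last[["rstart"]], anchor_length)
      out[[length(out) + 1L]] <- c(cstart = el[1L], cend = er[2L],
                                   rstart = el[3L], rend = er[4L])
    }
  }
  do.call(rbind, out)
}

#' Evaluate contigs against a known reference
#'
#' Contigs shorter than `min_contig` are excluded.  Each remaining contig is
#' aligned to the reference on both strands by exact anchor seeding,
#' diagonal chaining and exact extension; alignment blocks shorter than
#' `min_alignment` are ignored.  A contig is misassembled when its accepted
#' blocks cannot be ordered collinearly on one strand within
#' `misassembly_tolerance` bp.  Genome fraction is the percentage of
#' reference positions covered by at least one block; duplication ratio is
#' total aligned contig bases over covered reference positions.
#'
#' @param contigs list of contigs from [assemble()], or a (named) character
#'   vector of contig sequences.
#' @param reference reference DNA string.
#' @param min_contig minimum contig length considered (default 250 bp).
#' @param misassembly_tolerance breakpoint tolerance in bp (default 1000).
#' @param anchor_length,anchor_step exact seed length and spacing.
#' @param min_alignment minimum alignment block length (default 65 bp).
#' @return A list of class `assembly_report`: `genome_fraction`,
#'   `duplication_ratio`, `ngx` (NG50/NG75), `largest_alignment`,
#'   `total_aligned`, `misassembled` (data frame), `n_contigs`,
#'   `unaligned_contigs`.
#' @export
evaluate <- function(contigs, reference, min_contig = 250L,
                     misassembly_tolerance = 1000L, anchor_length = 31L,
                     anchor_step = 50L, min_alignment = 65L) {
  reference <- as.character(reference)
  if (!nzchar(reference)) stop("empty reference", call. = FALSE)
  seqs <- contig_seqs(contigs)
  seqs <- seqs[nchar(seqs) >= min_contig]
  rlen <- nchar(reference)
  ref_rc <- reverse_complement(reference)
  ref_cov <- list()
  total_aligned <- 0
  largest <- 0L
  mis <- list()
  unaligned <- character()

  for (nm in names(seqs)) {
    ctg <- seqs[[nm]]
    blocks <- list()
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") reference else ref_rc
      h <- anchor_hits(ctg, rs, anchor_length, anchor_step)
      b <- anchor_blocks(ctg, rs, h, anchor_length,
                         max_gap = misassembly_tolerance)
      if (!is.null(b)) {
        blocks[[strand]] <- cbind(b, strand = if (strand == "+") 1L else -1L)
      }
    }
    b <- do.call(rbind, blocks)
    if (is.null(b) || nrow(b) == 0L) { unaligned <- c(unaligned, nm); next }
    b <- b[nchar_block(b) >= min_alignment, , drop = FALSE]
    if (nrow(b) == 0L) { unaligned <- c(unaligned, nm); next }
    # greedy tiling of the contig by decreasing block length
    b <- b[order(-nchar_block(b), b[, "cstart"]), , drop = FALSE]
    acc <- matrix(numeric(), 0L, ncol(b), dimnames = list(NULL, colnames(b)))
    cov_iv <- IRanges::IRanges()
    for (i in seq_len(nrow(b))) {
      iv <- IRanges::IRanges(b[i, "cstart"], b[i, "cend"])
      ovl <- sum(IRanges::width(IRanges::intersect(iv, cov_iv)))
      if (ovl <= 0.5 * IRanges::width(iv)) {
        acc <- rbind(acc, b[i, ])
        cov_iv <- IRanges::reduce(c(cov_iv, iv))
      }
    }
    acc <- acc[order(acc[, "cstart"]), , drop = FALSE]
    # breakpoint scan between consecutive accepted blocks
    bad <- FALSE
    if (nrow(acc) > 1L) {
      for (i in 2:nrow(acc)) {
        same_strand <- acc[i, "strand"] == acc[i - 1L, "strand"]
        dr <- acc[i, "rstart"] - acc[i - 1L, "rstart"]
        dc <- acc[i, "cstart"] - acc[i - 1L, "cstart"]
        if (!same_strand || abs(dr - dc) > misassembly_tolerance || dr < 0) {
          bad <- TRUE
          break
        }
      }
    }
    if (bad) mis[[length(mis) + 1L]] <-
        data.frame(contig_id = nm, length = nchar(ctg))
    aligned_c <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(acc[, "cstart"], acc[, "cend"]))))
    total_aligned <- total_aligned + aligned_c
    largest <- max(largest, max(nchar_block(acc)))
    # forward-reference coverage intervals
    for (i in seq_len(nrow(acc))) {
      if (acc[i, "strand"] == 1L) {
        ref_cov[[length(ref_cov) + 1L]] <- c(acc[i, "rstart"], acc[i, "rend"])
      } else {
        ref_cov[[length(ref_cov) + 1L]] <-
          c(rlen - acc[i, "rend"] + 1L, rlen - acc[i, "rstart"] + 1L)
      }
    }
  }

  covered <- if (length(ref_cov)) {
    m <- do.call(rbind, ref_cov)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(m[, 1L], m[, 2L]))))
  } else 0L
  lens <- nchar(seqs)
  misdf <- if (length(mis)) do.call(rbind, mis) else
    data.frame(contig_id = character(), length = integer())
  structure(list(
    genome_fraction = 100 * covered / rlen,
    duplication_ratio = if (covered > 0) total_aligned / covered else NA_real_,
    ngx = c(NG50 = ngx(lens, rlen, 50), NG75 = ngx(lens, rlen, 75)),
    largest_alignment = largest,
    total_aligned = total_aligned,
    misassembled = misdf,
    n_contigs = length(seqs),
    unaligned_contigs = unaligned), class = "assembly_report")
}

nchar_block <- function(b) b[, "cend"] - b[, "cstart"] + 1L

contig_seqs <- function(contigs) {
  if (is.character(contigs)) {
    if (is.null(names(contigs))) {
      names(contigs) <- sprintf("contig_%05d", seq_along(contigs))
    }
    return(contigs)
  }
  seqs <- vapply(contigs, function(ct)
    if (is.list(ct)) ct$sequence else as.character(ct), character(1))
  names(seqs) <- vapply(seq_along(contigs), function(i) {
    ct <- contigs[[i]]
    if (is.list(ct) && !is.null(ct$id)) ct$id else sprintf("contig_%05d", i)
  }, character(1))
  seqs
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf(paste0(
    "assembly_report: %d contigs\n",
    "  genome fraction    : %.2f %%\n",
    "  duplication ratio  : %.3f\n",
    "  NG50 / NG75        : %s / %s bp\n",
    "  largest alignment  : %d bp\n",
    "  total aligned      : %.0f bp\n",
    "  misassembled       : %d contigs (%.0f bp)\n"),
    x$n_contigs, x$genome_fraction, x$duplication_ratio,
    x$ngx[["NG50"]], x$ngx[["NG75"]], x$largest_alignment,
    x$total_aligned, nrow(x$misassembled), sum(x$misassembled$length)))
  invisible(x)
}
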
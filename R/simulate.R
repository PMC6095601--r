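#' Simulate a genome with planted repeats and optional SNP haplotype
#'
#' Generates a uniform-random DNA sequence and plants exact repeat copies at
#' requested positions, the structures that stress fork detection in an
#' overlap graph.  With `snp_rate > 0` a second haplotype is attached as the
#' `"haplotype2"` attribute, differing from the primary sequence at
#' approximately `snp_rate * length` positions (SNP bubbles).
#'
#' @param length genome length in bp.
#' @param repeats list of repeat specs, each `list(length =, positions =)`
#'   with 1-based start positions; copies are exact duplicates and must fit
#'   inside the genome without overlapping one another.
#' @param snp_rate per-base SNP rate for the optional second haplotype,
#'   in `[0, 1)`.
#' @param seed integer seed; the same seed always yields the same genome.
#' @return A DNA string of exactly `length` bp (with attribute `haplotype2`
#'   when `snp_rate > 0`).
#' @export
simulate_genome <- function(length, repeats = list(), snp_rate = 0,
                            seed = 1L) {
  stopifnot(length >= 1, snp_rate >= 0, snp_rate < 1)
  bases <- c("A", "C", "G", "T")
  with_private_seed(seed, {
    g <- sample(bases, length, replace = TRUE)
    if (base::length(repeats)) {
      iv <- do.call(rbind, lapply(repeats, function(r) {
        stopifnot(is.numeric(r$length), base::length(r$positions) >= 1)
        cbind(start = as.integer(r$positions),
              end = as.integer(r$positions) + as.integer(r$length) - 1L)
      }))
      if (any(iv[, "start"] < 1L) || any(iv[, "end"] > length)) {
        stop("repeat copies do not fit within the genome", call. = FALSE)
      }
      o <- order(iv[, "start"])
      if (any(iv[o, "start"][-1L] <= iv[o, "end"][-nrow(iv)])) {
        stop("repeat copies overlap each other", call. = FALSE)
      }
      for (r in repeats) {
        rep_seq <- sample(bases, r$length, replace = TRUE)
        for (p in r$positions) g[p:(p + r$length - 1L)] <- rep_seq
      }
    }
    out <- paste(g, collapse = "")
    if (snp_rate > 0) {
      n_snp <- rbinom(1L, length, snp_rate)
      pos <- sort(sample.int(length, n_snp))
      h2 <- g
      for (p in pos) h2[p] <- sample(setdiff(bases, g[p]), 1L)
      attr(out, "haplotype2") <- paste(h2, collapse = "")
      attr(out, "snp_positions") <- pos
    }
    out
  })
}

#' Simulate a paired-end read library with ground truth
#'
#' Draws read pairs in the standard Illumina forward-reverse ("innie")
#' orientation: insert sizes come from a Gaussian truncated to
#' `[read_length, genome length]`, the pair start is uniform, the left mate is
#' the forward strand and the right mate the reverse complement of the insert
#' end.  Each whole pair is flipped to the opposite genome strand with
#' probability 1/2.  Substitution errors are i.i.d. per base; no indels are
#' injected (the alignment stage is exercised on indels separately).
#'
#' @param genome DNA string.
#' @param n_pairs number of read pairs.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert size distribution (end-to-end span of
#'   a pair) in bp.
#' @param substitution_rate per-base substitution error rate in `[0, 1)`.
#' @param seed integer seed (mandatory for reproducibility).
#' @param library library name recorded on the read set.
#' @return `list(reads = read_set, truth = data.frame)`; the truth table has
#'   one row per read: `read_id`, `start`, `end` (1-based inclusive interval
#'   on the reference), `strand` (`+`/`-`), `n_errors`.
#' @export
simulate_paired_reads <- function(genome, n_pairs, read_length = 100L,
                                  insert_mean = 300, insert_sd = 30,
                                  substitution_rate = 0, seed = 1L,
                                  library = "sim") {
  g_len <- nchar(genome)
  stopifnot(insert_mean >= read_length, substitution_rate >= 0,
            substitution_rate < 1)
  if (g_len < insert_mean + 4 * insert_sd) {
    stop("genome too short for the requested insert distribution", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  with_private_seed(seed, {
    ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                     read_length), g_len)
    start <- 1L + floor(runif(n_pairs) * (g_len - ins + 1))
    flip <- runif(n_pairs) < 0.5
    left <- substring(genome, start, start + read_length - 1L)
    right_iv_start <- start + ins - read_length
    right <- reverse_complement(
      substring(genome, right_iv_start, start + ins - 1L))
    r1 <- ifelse(flip, right, left)
    r2 <- ifelse(flip, left, right)
    s1 <- ifelse(flip, right_iv_start, start)
    s2 <- ifelse(flip, start, right_iv_start)
    st1 <- ifelse(flip, "-", "+")
    st2 <- ifelse(flip, "+", "-")
    seq <- c(r1, r2)
    n_reads <- 2L * n_pairs
    n_err <- integer(n_reads)
    if (substitution_rate > 0) {
      for (i in seq_len(n_reads)) {
        k <- rbinom(1L, read_length, substitution_rate)
        if (k > 0L) {
          pos <- sample.int(read_length, k)
          ch <- strsplit(seq[i], "")[[1L]]
          for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
          seq[i] <- paste(ch, collapse = "")
          n_err[i] <- k
        }
      }
    }
    id <- c(paste0(library, seq_len(n_pairs), "/1"),
            paste0(library, seq_len(n_pairs), "/2"))
    qual <- rep(list(rep(37L, read_length)), n_reads)
    mate <- c(seq_len(n_pairs) + n_pairs, seq_len(n_pairs))
    rs <- read_set(id, seq, qual, mate, library = library)
    truth <- data.frame(
      read_id = id,
      start = c(s1, s2),
      end = c(s1, s2) + read_length - 1L,
      strand = c(st1, st2),
      n_errors = n_err,
      stringsAsFactors = FALSE)
    list(reads = rs, truth = truth)
  })
}

#' Write a simulated library to disk
#'
#' Emits the standard artifact trio: paired FASTQ, reference FASTA and a
#' tab-separated ground-truth table (`read_id`, `start`, `end`, `strand`,
#' `n_errors`).
#'
#' @param sim result of [simulate_paired_reads()].
#' @param genome the reference the reads were drawn from.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulated_library <- function(sim, genome, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_2.fastq"))
  pr <- file.path(dir, paste0(prefix, "_ref.fasta"))
  pt <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_fastq(sim$reads, p1, p2)
  write_fasta(c(reference = as.character(genome)), pr)
  write.table(sim$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, pr, pt))
}

#' Plant a chimeric junction between two contigs
#'
#' Concatenates the prefix of `contig_a` up to `junction` with a suffix of
#' `contig_b` starting at `b_from` -- the classic misjoin fixture for
#' paired-end contig correction.  The junction position is recorded as the
#' `"junction"` attribute of the result.
#'
#' @param contig_a,contig_b DNA strings.
#' @param junction number of leading bases of `contig_a` to keep (0..len(a)).
#' @param b_from 1-based start of the suffix taken from `contig_b`
#'   (default 1: the whole of `contig_b`).
#' @return The chimeric DNA string.
#' @export
plant_chimera <- function(contig_a, contig_b, junction, b_from = 1L) {
  stopifnot(junction >= 0, junction <= nchar(contig_a),
            b_from >= 1, b_from <= nchar(contig_b) + 1)
  out <- paste0(substr(contig_a, 1L, junction),
                substring(contig_b, b_from))
  attr(out, "junction") <- as.integer(junction)
  out
}
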
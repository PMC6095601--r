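#' Construct a paired-end read set
#'
#' A `read_set` is the container every stage of the assembler works on: a
#' flat collection of reads with Phred qualities and positional mate links.
#' Mate links are symmetric (the mate of a read's mate is the read itself).
#'
#' @param id character vector of unique read identifiers.
#' @param seq character vector of DNA sequences over `{A,C,G,T}`.
#' @param qual list of integer vectors of Phred scores, one per read, each the
#'   same length as its sequence.
#' @param mate integer vector of mate indices into the set (`NA` = unpaired).
#' @param library name of the sequencing library the reads belong to.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq, qual, mate = rep(NA_integer_, length(id)),
                     library = "lib1") {
  stopifnot(length(id) == length(seq), length(qual) == length(seq),
            length(mate) == length(seq))
  if (anyDuplicated(id)) stop("read ids must be unique", call. = FALSE)
  # N is tolerated in the container (reads kept via keep_n); the assembly
  # stages themselves require N-free sequences
  assert_dna(seq, "read sequence", allow_n = TRUE)
  if (!all(lengths(qual) == nchar(seq))) {
    stop("qualities and sequence lengths differ for read(s): ",
         paste(head(id[lengths(qual) != nchar(seq)], 3L), collapse = ", "),
         call. = FALSE)
  }
  mate <- as.integer(mate)
  ok <- is.na(mate) | (mate >= 1L & mate <= length(id) & mate != seq_along(id))
  if (!all(ok)) stop("mate indices out of range", call. = FALSE)
  linked <- which(!is.na(mate))
  if (!all(mate[mate[linked]] == linked)) {
    stop("mate links must be symmetric", call. = FALSE)
  }
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = lapply(qual, as.integer), mate = mate,
                 library = library),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads (",
      sum(!is.na(x$mate)) / 2, "pairs ), library:", x$library, "\n")
  invisible(x)
}

#' Parse a pair of FASTQ mate files
#'
#' Records in the two files must be positionally paired (record i of file 1 is
#' the mate of record i of file 2), the standard layout of split paired-end
#' FASTQ.  Qualities are decoded as Phred+33.  Reads containing `N` are
#' removed by default, mirroring the usual preprocessing of Illumina
#' libraries; the mate of a removed read is kept but loses its pairing.
#'
#' @param path_1,path_2 paths to the two mate FASTQ files.
#' @param keep_n keep reads containing `N` instead of removing them.
#' @param library library name stored on the resulting set.
#' @return A [read_set] with mate links established.
#' @export
parse_fastq <- function(path_1, path_2, keep_n = FALSE, library = "lib1") {
  r1 <- read_one_fastq(path_1)
  r2 <- read_one_fastq(path_2)
  if (length(r1$seq) != length(r2$seq)) {
    stop("mate files have unequal record counts (", length(r1$seq), " vs ",
         length(r2$seq), ")", call. = FALSE)
  }
  n <- length(r1$seq)
  id <- c(paste0(r1$id, "/1"), paste0(r2$id, "/2"))
  seq <- c(r1$seq, r2$seq)
  qual <- c(r1$qual, r2$qual)
  mate <- c(seq_len(n) + n, seq_len(n))
  if (!keep_n) {
    drop <- grepl("N", seq, fixed = TRUE)
    if (any(drop)) {
      keep <- which(!drop)
      remap <- match(seq_along(seq), keep)
      mate <- remap[mate[keep]]
      id <- id[keep]; seq <- seq[keep]; qual <- qual[keep]
    }
  }
  read_set(id, seq, qual, mate, library = library)
}

read_one_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  # structural pre-check for the ubiquitous 4-line record layout, so a
  # corrupt record is reported with its index; anything else is left to the
  # Biostrings parser
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L == 0L && length(lines) > 0L) {
    rec <- matrix(lines, nrow = 4L)
    if (all(startsWith(rec[1L, ], "@")) && all(startsWith(rec[3L, ], "+"))) {
      bad <- which(nchar(rec[2L, ]) != nchar(rec[4L, ]))
      if (length(bad)) {
        stop("malformed FASTQ record ", bad[1L], " in ", path,
             ": sequence and quality lengths differ", call. = FALSE)
      }
    }
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  qraw <- S4Vectors::mcols(x)$qualities
  qual <- as.list(methods::as(Biostrings::PhredQuality(qraw), "IntegerList"))
  id <- sub("\\s.*$", "", names(x))
  list(id = id, seq = as.character(x), qual = qual)
}

#' Write a read set as a pair of FASTQ mate files
#'
#' Reads are emitted in pair order; every read must have its mate present.
#' Identifiers keep their `/1`, `/2` suffixes, so a parse/write cycle on
#' well-formed input is byte-identical.
#'
#' @param rs a [read_set].
#' @param path_1,path_2 output FASTQ paths for the two mates.
#' @export
write_fastq <- function(rs, path_1, path_2) {
  if (anyNA(rs$mate)) stop("write_fastq requires fully paired reads", call. = FALSE)
  first <- which(seq_along(rs$id) < rs$mate)
  emit <- function(idx, path) {
    x <- Biostrings::DNAStringSet(rs$seq[idx])
    names(x) <- sub("/[12]$", "", rs$id[idx])
    q <- Biostrings::PhredQuality(vapply(rs$qual[idx], function(v)
      rawToChar(as.raw(v + 33L)), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  emit(first, path_1)
  emit(rs$mate[first], path_2)
  invisible(rs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Reverse complement of DNA sequences
#'
#' Strict alphabet `{A,C,G,T}`; an involution
#' (`reverse_complement(reverse_complement(s)) == s`).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  assert_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Windowed mean-quality trimming of a read
#'
#' Keeps the longest contiguous substring of the read in which every sliding
#' window of `window` bases has mean Phred quality at least `min_q`.  Reads in
#' which no such substring of length >= `window` exists are rejected
#' (`NULL`); in particular reads shorter than the window are always rejected.
#'
#' @param sequence DNA string.
#' @param qualities integer vector of Phred scores, one per base.
#' @param min_q minimum mean quality within a window (default 30).
#' @param window window length in bases (default 60).
#' @return A list with `sequence`, `qualities`, and the kept `start`/`end`
#'   (1-based, inclusive) on the input read, or `NULL` if rejected.
#' @export
quality_filter <- function(sequence, qualities, min_q = 30, window = 60L) {
  stopifnot(window >= 1L, min_q >= 0)
  n <- nchar(sequence)
  if (length(qualities) != n) stop("qualities length != sequence length", call. = FALSE)
  if (n < window) return(NULL)
  cs <- cumsum(c(0L, qualities))
  wmean <- (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
  pass <- wmean >= min_q
  if (!any(pass)) return(NULL)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  len <- r$lengths[runs] + window - 1L
  best <- runs[which.max(len)]
  s <- starts[best]
  e <- ends[best] + window - 1L
  list(sequence = substr(sequence, s, e), qualities = qualities[s:e],
       start = s, end = e)
}

#' Apply the quality filter to a whole read set
#'
#' @param rs a [read_set].
#' @param min_q,window see [quality_filter()].
#' @param action `"trim"` keeps the surviving substring of each read;
#'   `"discard"` keeps only reads that pass in full length.
#' @return A filtered [read_set]; mates of removed reads become unpaired.
#' @export
filter_read_set <- function(rs, min_q = 30, window = 60L,
                            action = c("trim", "discard")) {
  action <- match.arg(action)
  res <- lapply(seq_along(rs$id), function(i)
    quality_filter(rs$seq[i], rs$qual[[i]], min_q, window))
  keep <- !vapply(res, is.null, logical(1))
  if (action == "discard") {
    keep <- keep & vapply(seq_along(res), function(i)
      keep[i] && nchar(res[[i]]$sequence) == nchar(rs$seq[i]), logical(1))
  }
  idx <- which(keep)
  remap <- match(seq_along(rs$id), idx)
  seq <- rs$seq; qual <- rs$qual
  if (action == "trim") {
    seq[idx] <- vapply(res[idx], `[[`, character(1), "sequence")
    qual[idx] <- lapply(res[idx], `[[`, "qualities")
  }
  read_set(rs$id[idx], seq[idx], qual[idx], remap[rs$mate[idx]],
           library = rs$library)
}
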
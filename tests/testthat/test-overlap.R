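test_that("kmer_characteristic collapses duplicates and orders entries", {
  ch <- kmer_characteristic("AAAA", 2L)
  expect_equal(ch$kmers, "AA")
  expect_equal(ch$counts, 3L)

  ch <- kmer_characteristic("ACGT", 2L)
  expect_equal(ch$kmers, c("AC", "CG", "GT"))  # ties broken lexicographically
  expect_equal(ch$counts, c(1L, 1L, 1L))

  set.seed(20)
  ch <- kmer_characteristic(random_dna(97L), 16L)
  expect_lte(length(ch$kmers), 97L - 16L + 1L)
  expect_true(all(diff(ch$counts) <= 0L))
  expect_error(kmer_characteristic("ACGT", 5L), "exceeds")
})

test_that("promising pairs come from the sorted-characteristic neighborhood", {
  mk <- function(seq, ref) {
    ch <- kmer_characteristic(seq, 3L)
    ch$read_ref <- ref
    ch
  }
  # identical reads sort adjacently: pair emitted for window 1
  p <- promising_from_characteristics(list(mk("ACGTACGTAC", 1L),
                                           mk("ACGTACGTAC", 2L),
                                           mk("TTTTTTTTGG", 3L)), window = 1L)
  expect_true(any(p[, "a"] == 1L & p[, "b"] == 2L))
  # window 1 over n sorted characteristics gives exactly n-1 pairs
  set.seed(21)
  chs <- lapply(1:6, function(i) mk(random_dna(30L), i))
  expect_equal(nrow(promising_from_characteristics(chs, window = 1L)), 5L)
  # a large window yields every unordered pair
  expect_equal(nrow(promising_from_characteristics(chs, window = 10L)),
               choose(6, 2))
})

test_that("reads over disjoint alphabet regions do not pair at small window", {
  # 10 reads: 5 poly-A-ish, 5 poly-T-ish; characteristics sort into two
  # far-apart bands, so window 1 never pairs across the bands
  mk <- function(seq, ref) {
    ch <- kmer_characteristic(seq, 3L)
    ch$read_ref <- ref
    ch
  }
  a <- lapply(1:5, function(i)
    mk(paste0(strrep("A", 20 + i), strrep("C", 5)), i))
  t <- lapply(1:5, function(i)
    mk(paste0(strrep("T", 20 + i), strrep("G", 5)), i + 5L))
  p <- promising_from_characteristics(c(a, t), window = 1L)
  cross <- (p[, "a"] <= 5L & p[, "b"] > 5L)
  expect_equal(sum(cross), 1L)  # only the single boundary pair of the sort
})

test_that("smallest_lex_descriptor takes the minimal substring of each half", {
  expect_equal(unname(smallest_lex_descriptor("AAAA", 2L)), c("AA", "AA"))
  expect_equal(unname(smallest_lex_descriptor("TGCA", 2L)), c("TG", "CA"))
  expect_equal(unname(smallest_lex_descriptor("TTTTGTTT", 3L)),
               c("TTT", "GTT"))
  expect_error(smallest_lex_descriptor("ACGT", 3L), "too short")
  # oracle: enumerate all substrings of a half and take the minimum
  set.seed(22)
  for (i in 1:20) {
    s <- random_dna(24L)
    d <- smallest_lex_descriptor(s, 5L)
    h1 <- substr(s, 1, 12); h2 <- substring(s, 13)
    all1 <- substring(h1, 1:8, 5:12)
    all2 <- substring(h2, 1:8, 5:12)
    expect_equal(unname(d), c(min(all1), min(all2)))
  }
})

test_that("semiglobal_overlap handles identity, dovetail and disjoint pairs", {
  r <- semiglobal_overlap("ACGTACGT", "ACGTACGT")
  expect_equal(r$shift, 0L)
  expect_equal(r$overlap_length, 8L)
  expect_equal(r$errors, 0L)

  r <- semiglobal_overlap("GGGACGT", "ACGTCCC")
  expect_equal(r$shift, 3L)
  expect_equal(r$overlap_length, 4L)
  expect_equal(r$errors, 0L)

  r <- semiglobal_overlap("AAAAAAA", "CCCCCCC")
  expect_equal(r$errors, r$overlap_length)  # no error-free overlap exists
})

test_that("semiglobal_overlap agrees with the independent DP oracle", {
  set.seed(23)
  for (i in 1:200) {
    a <- random_dna(sample(5:30, 1))
    b <- random_dna(sample(5:30, 1))
    r <- semiglobal_overlap(a, b)
    o <- nw_oracle(a, b)
    expect_equal(r$score, unname(o["score"]))
    expect_equal(r$shift, unname(o["shift"]))
    expect_equal(r$overlap_length, unname(o["overlap"]))
    expect_equal(r$errors, unname(o["errors"]))
  }
})

test_that("swapping the sequences negates the shift on clean dovetails", {
  set.seed(24)
  for (i in 1:20) {
    g <- random_dna(150L)
    a <- substr(g, 1, 100)
    b <- substr(g, 31, 130)
    ra <- semiglobal_overlap(a, b)
    rb <- semiglobal_overlap(b, a)
    expect_equal(ra$shift, 30L)
    expect_equal(rb$shift, -30L)
    expect_equal(ra$score, rb$score)
    expect_equal(ra$overlap_length, rb$overlap_length)
  }
})

test_that("accept_arc applies the length and ceiling-error thresholds", {
  mk <- function(ov, err) list(overlap_length = ov, errors = err)
  expect_true(accept_arc(mk(50L, 0L), min_overlap = 40L))
  expect_false(accept_arc(mk(30L, 0L), min_overlap = 40L))
  # overlap 100, rate 0.03 allows ceiling(3) = 3 errors, not 4
  expect_false(accept_arc(mk(100L, 4L), 40L, 0.03))
  expect_true(accept_arc(mk(100L, 3L), 40L, 0.03))
})

test_that("paired-end propagation emits the strand-flipped mate pair", {
  # reads 1..4; 1 paired with 3, 2 paired with 4
  mate <- c(3L, 4L, 1L, 2L)
  arcs <- data.frame(a = vertex_id(1, "+"), b = vertex_id(2, "+"))
  p <- propagate_paired(arcs, mate)
  expect_equal(nrow(p), 1L)
  expect_setequal(as.integer(p[1, ]),
                  c(vertex_id(3, "-"), vertex_id(4, "-")))
  # missing mates: nothing
  expect_equal(nrow(propagate_paired(arcs, rep(NA_integer_, 4L))), 0L)
  # duplicates collapse
  arcs2 <- rbind(arcs, arcs)
  expect_equal(nrow(propagate_paired(arcs2, mate)), 1L)
})

test_that("successor propagation pairs the partners of shared vertices", {
  A <- vertex_id(1); B <- vertex_id(2); C <- vertex_id(3); D <- vertex_id(4)
  arcs <- data.frame(a = c(A, A), b = c(B, C))
  p <- propagate_successors(arcs)
  expect_equal(nrow(p), 1L)
  expect_setequal(as.integer(p[1, ]), c(B, C))
  # a single partner proposes nothing
  expect_equal(nrow(propagate_successors(data.frame(a = A, b = B))), 0L)
  # three partners: 3 choose 2 pairs
  arcs3 <- data.frame(a = c(A, A, A), b = c(B, C, D))
  expect_equal(nrow(propagate_successors(arcs3)), 3L)
  # already-verified pairs are excluded
  arcs4 <- rbind(arcs3, data.frame(a = B, b = C))
  p4 <- propagate_successors(arcs4)
  expect_false(any(p4[, "a"] == min(B, C) & p4[, "b"] == max(B, C)))
})

test_that("mirror_revcomp reproduces direct alignment of the complements", {
  set.seed(25)
  for (i in 1:15) {
    g <- random_dna(170L)
    a <- substr(g, 1, 100)
    b <- substr(g, 31, 130)
    r <- semiglobal_overlap(a, b)
    m <- mirror_revcomp(r, nchar(a), nchar(b))
    direct <- semiglobal_overlap(reverse_complement(b), reverse_complement(a))
    expect_equal(m$shift, direct$shift)
    expect_equal(m$overlap_length, direct$overlap_length)
    expect_equal(m$errors, direct$errors)
    # involution: mirroring the mirror restores the original shift
    back <- mirror_revcomp(m, nchar(b), nchar(a))
    expect_equal(back$shift, r$shift)
  }
  expect_error(mirror_revcomp(list(score = 1, shift = 0,
                                   overlap_length = 50, errors = 0),
                              10L, 10L), "inconsistent")
})

test_that("every accepted arc in find_overlaps satisfies accept_arc", {
  g <- simulate_genome(2500, seed = 26)
  sim <- simulate_paired_reads(g, n_pairs = 60, read_length = 100,
                               insert_mean = 300, insert_sd = 30,
                               substitution_rate = 0.005, seed = 27)
  pr <- assembly_params()
  ov <- find_overlaps(sim$reads, pr)
  expect_gt(nrow(ov), 0L)
  expect_true(all(ov$overlap >= pr$min_overlap))
  expect_true(all(ov$errors <= ceiling(pr$max_error_rate * ov$overlap)))
})
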
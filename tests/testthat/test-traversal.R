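test_that("update_state prunes by the end-to-end overlap rule", {
  st <- olcassembler:::new_state(1L, 0L, 100L)
  # reads of length 100, offsets {0, 70}: overlap 30 < 40, first removed
  st2 <- update_state(st, 3L, list(shift = 70L), min_state_overlap = 40L,
                      new_len = 100L)
  expect_equal(st2$vertices, 3L)
  expect_equal(st2$offsets, 70L)
  # offsets {0, 50}: overlap 50 >= 40, both kept
  st3 <- update_state(st, 3L, list(shift = 50L), min_state_overlap = 40L,
                      new_len = 100L)
  expect_equal(st3$vertices, c(1L, 3L))
  # a single-entry state is never pruned
  st4 <- olcassembler:::prune_state(olcassembler:::new_state(1L, 0L, 10L), 40L)
  expect_equal(st4$vertices, 1L)
})

test_that("score_candidates sums supporting overlaps and breaks ties by id", {
  # v1 and v3 both support v5 with overlaps 80 and 60 -> score 140
  tg <- toy_graph(3L, data.frame(a = c(1L, 3L), b = c(5L, 5L),
                                 shift = c(20L, 40L),
                                 overlap = c(80L, 60L)))
  st <- olcassembler:::new_state(c(1L, 3L), c(0L, 20L), c(100L, 100L))
  sc <- score_candidates(st, tg$graph)
  expect_equal(sc$vertex[1], 5L)
  expect_equal(sc$score[1], 140)
  # a vertex with no arc from any state member is absent
  expect_false(7L %in% sc$vertex)
  # equal scores: the smaller vertex id wins
  tg2 <- toy_graph(3L, data.frame(a = c(1L, 1L), b = c(3L, 5L),
                                  shift = c(30L, 30L),
                                  overlap = c(70L, 70L)))
  sc2 <- score_candidates(olcassembler:::new_state(1L, 0L, 100L), tg2$graph)
  expect_equal(sc2$vertex[1], 3L)
  # excluded reads never become candidates
  sc3 <- score_candidates(st, tg$graph, exclude_reads = 3L)
  expect_false(any(vertex_read(sc3$vertex) == 3L))
})

test_that("consensus majority-votes columns with lexicographic ties", {
  rs <- read_set(c("a", "b", "c"), c("AAC", "ACC", "AAC"),
                 rep(list(rep(37L, 3L)), 3))
  # two identical reads at offset 0 reproduce the read
  expect_equal(consensus(list(vertices = c(1L, 5L), offsets = c(0L, 0L)), rs),
               "AAC")
  # column {A, A, C} -> A by majority; tie {A, C} -> A lexicographically
  expect_equal(consensus(list(vertices = c(1L, 3L, 5L),
                              offsets = c(0L, 0L, 0L)), rs), "AAC")
  expect_equal(consensus(list(vertices = c(1L, 3L), offsets = c(0L, 0L)),
                         rs), "AAC")
  # layout gaps are an error
  expect_error(consensus(list(vertices = c(1L, 3L), offsets = c(0L, 10L)),
                         rs), "zero-coverage")
})

test_that("a linear chain assembles into a single contig with all reads", {
  set.seed(33)
  template <- random_dna(700L)
  rs <- tile_reads(template, read_length = 100L, step = 20L)
  ov <- find_overlaps(rs, assembly_params())
  g <- build_graph(rs, ov)
  ctg <- assemble(g, rs, assembly_params(), seed = 1L)
  big <- ctg[vapply(ctg, function(x) nchar(x$sequence), integer(1)) > 100L]
  expect_equal(length(big), 1L)
  expect_equal(length(big[[1]]$vertices), length(rs))
  expect_equal(canon_seq(big[[1]]$sequence), canon_seq(template))
})

test_that("an empty read set yields no contigs", {
  rs <- read_set(character(), character(), list())
  g <- build_graph(rs, data.frame(a = integer(), b = integer(),
                                  score = integer(), shift = integer(),
                                  overlap = integer(), errors = integer()))
  expect_equal(length(assemble(g, rs)), 0L)
})

test_that("two disconnected chains produce exactly two contigs", {
  set.seed(34)
  t1 <- random_dna(600L)
  t2 <- random_dna(600L)
  rs1 <- tile_reads(t1, step = 20L, prefix = "x")
  rs2 <- tile_reads(t2, step = 20L, prefix = "y")
  rs <- read_set(c(rs1$id, rs2$id), c(rs1$seq, rs2$seq),
                 c(rs1$qual, rs2$qual))
  ov <- find_overlaps(rs, assembly_params())
  g <- build_graph(rs, ov)
  ctg <- assemble(g, rs, assembly_params(), seed = 2L)
  big <- ctg[vapply(ctg, function(x) nchar(x$sequence), integer(1)) > 100L]
  expect_equal(length(big), 2L)
  expect_setequal(canon_seq(vapply(big, `[[`, character(1), "sequence")),
                  canon_seq(c(t1, t2)))
})

test_that("a single over-attractive arc cannot outvote the chain majority", {
  # long chain stepped by 5 bp (each vertex supports the next few); a
  # spurious arc from an early vertex to a decoy with a huge overlap must
  # not divert the path, because the true successor collects more votes and
  # the decoy's lone supporter eventually leaves the state
  set.seed(35)
  template <- random_dna(400L)
  rs <- tile_reads(template, read_length = 100L, step = 5L)  # 61 reads
  n <- length(rs)
  decoy_id <- n + 1L
  all <- read_set(c(rs$id, "decoy"), c(rs$seq, random_dna(100L)),
                  c(rs$qual, list(rep(37L, 100L))))
  ov <- find_overlaps(rs, assembly_params())
  spur <- data.frame(a = vertex_id(3), b = vertex_id(decoy_id), score = 99L,
                     shift = 1L, overlap = 99L, errors = 0L)
  g <- build_graph(all, rbind(ov, spur))
  # walk rightward from the chain start: by the time the spurious arc's
  # source votes, the true successor is backed by three state members and
  # must win; the decoy is quietly dropped later
  walk <- olcassembler:::extend_direction(g, vertex_id(1),
                                          rep(FALSE, n + 1L),
                                          assembly_params())
  expect_equal(vertex_read(walk$vertices), seq_len(n))
  expect_false(decoy_id %in% vertex_read(walk$vertices))
  expect_equal(consensus(list(vertices = walk$vertices,
                              offsets = walk$offsets), all), template)
})

test_that("assembly is deterministic for a fixed seed", {
  g <- simulate_genome(3000, seed = 36)
  sim <- simulate_paired_reads(g, n_pairs = 150, read_length = 100,
                               insert_mean = 300, insert_sd = 30, seed = 37)
  ov <- find_overlaps(sim$reads, assembly_params())
  gr <- build_graph(sim$reads, ov)
  c1 <- assemble(gr, sim$reads, assembly_params(), seed = 5L)
  c2 <- assemble(gr, sim$reads, assembly_params(), seed = 5L)
  expect_identical(c1, c2)
  # different seeds still reconstruct the same sequences on a clean graph
  c3 <- assemble(gr, sim$reads, assembly_params(), seed = 6L)
  seqs <- function(x) sort(canon_seq(vapply(x, `[[`, character(1),
                                            "sequence")[
    vapply(x, function(ct) nchar(ct$sequence), integer(1)) >= 250L]))
  expect_equal(seqs(c1), seqs(c3))
})

test_that("contigs from clean data are exact reference substrings", {
  g <- simulate_genome(3000, seed = 38)
  sim <- simulate_paired_reads(g, n_pairs = 300, read_length = 100,
                               insert_mean = 300, insert_sd = 30, seed = 39)
  res <- assemble_reads(sim$reads, seed = 7L)
  rc <- reverse_complement(as.character(g))
  for (ct in res$contigs) {
    if (nchar(ct$sequence) < 250L) next
    expect_true(grepl(ct$sequence, g, fixed = TRUE) ||
                  grepl(ct$sequence, rc, fixed = TRUE))
    # coverage >= 1 everywhere: total read length covers the contig
    expect_gte(sum(nchar(olcassembler:::oriented_sequences(sim$reads)[
      ct$vertices])), nchar(ct$sequence))
  }
})
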
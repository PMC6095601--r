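# Shared fixture: a 12 kb genome, a chimeric contig joining two loci >= 5 kb
# apart, and the true continuation present as a second contig.
chimera_fixture <- function() {
  g <- simulate_genome(12000, seed = 50)
  sim <- simulate_paired_reads(g, n_pairs = 1800, read_length = 100,
                               insert_mean = 300, insert_sd = 30, seed = 51)
  chim <- plant_chimera(substr(g, 1, 3000), substring(g, 8001, 11000),
                        junction = 3000)
  contigs <- c(chimera = as.character(chim),
               good = substr(g, 3001, 8000))
  params <- correction_params(insert_mean = 300, insert_sd = 30,
                              read_length = 100)
  list(genome = g, sim = sim, contigs = contigs, params = params,
       junction = 3000L)
}

test_that("reads map at layout offsets and unmappable reads stay unmapped", {
  g <- simulate_genome(3000, seed = 52)
  sim <- simulate_paired_reads(g, n_pairs = 200, read_length = 100,
                               insert_mean = 300, insert_sd = 30, seed = 53)
  res <- assemble_reads(sim$reads, seed = 11L)
  big <- res$contigs[vapply(res$contigs, function(x) nchar(x$sequence),
                            integer(1)) >= 250L]
  mp <- map_reads_to_contigs(big, sim$reads)
  ct <- big[[1]]
  lay <- mp[mp$contig == ct$id, ]
  i <- match(vertex_read(ct$vertices), lay$read)
  expect_false(anyNA(i))
  expect_equal(lay$pos[i], ct$offsets + 1L)
  # a read from nowhere stays unmapped
  alien <- read_set("alien", random_dna(100L), list(rep(37L, 100L)))
  both <- read_set(c(sim$reads$id, "alien"), c(sim$reads$seq, alien$seq),
                   c(sim$reads$qual, alien$qual))
  mp2 <- map_reads_to_contigs(contig_seqs <- vapply(big, `[[`,
                                                    character(1), "sequence"),
                              both)
  expect_false(length(both) %in% mp2$read)
})

test_that("mates spanning two contigs are visible as cross-contig pairs", {
  fx <- chimera_fixture()
  mp <- map_reads_to_contigs(fx$contigs, fx$sim$reads)
  rd <- attr(mp, "reads")
  mrow <- match(rd$mate[mp$read], mp$read)
  cross <- !is.na(mrow) & mp$contig[mrow] != mp$contig
  expect_gt(sum(cross), 0L)
})

test_that("continuity breaks fire on unsupported insertions only", {
  g <- simulate_genome(9000, seed = 54)
  sim <- simulate_paired_reads(g, n_pairs = 1400, read_length = 100,
                               insert_mean = 300, insert_sd = 30, seed = 55)
  params <- correction_params(insert_mean = 300, insert_sd = 30,
                              read_length = 100)
  # a correct contig has no breaks
  ok <- c(good = substr(g, 1, 6000))
  mp <- map_reads_to_contigs(ok, sim$reads)
  expect_equal(nrow(find_continuity_breaks(mp, "good", params)), 0L)
  # a contig with 500 bp of foreign sequence spliced in: no pair spans it
  bad <- c(bad = paste0(substr(g, 1, 3000), random_dna(500L),
                        substr(g, 3001, 6000)))
  mpb <- map_reads_to_contigs(bad, sim$reads)
  br <- find_continuity_breaks(mpb, "bad", params)
  expect_gte(nrow(br), 1L)
  expect_true(any(br$start <= 3500 & br$end >= 3000))
  # the same gap is ignored when the minimal width exceeds it
  wide <- correction_params(insert_mean = 300, insert_sd = 30,
                            read_length = 100, min_break_width = 2000)
  expect_equal(nrow(find_continuity_breaks(mpb, "bad", wide)), 0L)
})

test_that("mismapped density flags the junction and tolerates strays", {
  fx <- chimera_fixture()
  mp <- map_reads_to_contigs(fx$contigs, fx$sim$reads)
  d <- find_mismapped_density(mp, "chimera", fx$params)
  expect_gte(nrow(d), 1L)
  peak <- d[which.max(d$severity), ]
  expect_lt(abs((peak$start + peak$end) / 2 - fx$junction),
            fx$params$insert_max)
  # the correct continuation contig shows no anomaly
  expect_equal(nrow(find_mismapped_density(mp, "good", fx$params)), 0L)
  # an isolated stray pair stays below an explicit threshold of 2
  strict <- fx$params
  strict$mismap_count_threshold <- 1e6
  expect_equal(nrow(find_mismapped_density(mp, "chimera", strict)), 0L)
})

test_that("the hyper-heuristic cuts the chimera once and only there", {
  fx <- chimera_fixture()
  mp <- map_reads_to_contigs(fx$contigs, fx$sim$reads)
  out <- hyperheuristic_correct(fx$contigs, mp, fx$params)
  cuts <- attr(out, "cuts")
  expect_equal(nrow(cuts), 1L)
  expect_equal(cuts$contig, "chimera")
  expect_lt(abs(cuts$position - fx$junction), fx$params$insert_max)
  # the cut never makes things worse, and the off-junction residue left on
  # a piece is bounded by the cut placement uncertainty
  before <- evaluate(fx$contigs, fx$genome, min_contig = 250L)
  rep <- evaluate(out, fx$genome, min_contig = 250L)
  expect_lte(nrow(rep$misassembled), nrow(before$misassembled))
  # total length never grows; pieces are substrings of the inputs
  expect_lte(sum(nchar(out)), sum(nchar(fx$contigs)))
  for (nm in names(out)) {
    src <- fx$contigs[[sub("\\..*$", "", nm)]]
    expect_true(grepl(out[[nm]], src, fixed = TRUE))
  }
})

test_that("correct contigs from a clean library are never cut", {
  g <- simulate_genome(9000, seed = 56)
  sim <- simulate_paired_reads(g, n_pairs = 1400, read_length = 100,
                               insert_mean = 300, insert_sd = 30, seed = 57)
  params <- correction_params(insert_mean = 300, insert_sd = 30,
                              read_length = 100)
  contigs <- c(c1 = substr(g, 1, 4500), c2 = substring(g, 4501))
  mp <- map_reads_to_contigs(contigs, sim$reads)
  out <- hyperheuristic_correct(contigs, mp, params)
  expect_equal(nrow(attr(out, "cuts")), 0L)
  expect_identical(unclass(out)[names(contigs)], contigs)
})

test_that("greedy order cuts the more severe of two chimeras first", {
  g <- simulate_genome(16000, seed = 58)
  sim <- simulate_paired_reads(g, n_pairs = 2400, read_length = 100,
                               insert_mean = 300, insert_sd = 30, seed = 59)
  # two chimeric contigs; the true continuations of both junctions exist as
  # further contigs so mismapped mates are observable.  Chimera A has both
  # flanking continuations present (stronger signal) while chimera B has
  # only one (weaker signal).
  chA <- plant_chimera(substr(g, 1, 2500), substring(g, 9001, 12000),
                       junction = 2500)
  chB <- plant_chimera(substr(g, 4001, 6500), substring(g, 13001, 14500),
                       junction = 2500)
  contigs <- c(A = as.character(chA), B = as.character(chB),
               mid = substr(g, 2501, 4000),      # continuation right of A
               pre = substring(g, 8001, 9000),   # continuation left of A'
               m2 = substring(g, 6501, 8000))    # continuation right of B
  params <- correction_params(insert_mean = 300, insert_sd = 30,
                              read_length = 100)
  mp <- map_reads_to_contigs(contigs, sim$reads)
  out <- hyperheuristic_correct(contigs, mp, params)
  cuts <- attr(out, "cuts")
  expect_gte(nrow(cuts), 2L)
  expect_setequal(unique(cuts$contig), c("A", "B"))
  # severities are handled greedily: first cut has the highest severity
  expect_equal(cuts$severity[1], max(cuts$severity))
  expect_equal(cuts$contig[1], "A")
})
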
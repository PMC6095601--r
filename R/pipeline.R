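# End-to-end orchestration.  The exported functions are the primary
# interface; `inst/scripts/olc_pipeline.R` wraps them in a thin command line
# for shell use.

#' Assemble a read set end to end
#'
#' Convenience wrapper chaining overlap discovery, graph construction and
#' traversal: `find_overlaps()` -> `build_graph()` -> `assemble()`.
#'
#' @param rs a [read_set].
#' @param params an [assembly_params()] list.
#' @param seed integer seed controlling traversal start points.
#' @param progress print stage progress.
#' @return `list(graph, contigs)`.
#' @export
assemble_reads <- function(rs, params = assembly_params(), seed = 1L,
                           progress = FALSE) {
  ov <- find_overlaps(rs, params, progress = progress)
  g <- build_graph(rs, ov)
  if (progress) print(g)
  contigs <- assemble(g, rs, params, seed = seed)
  list(graph = g, contigs = contigs)
}

#' Run the full pipeline on a simulated or provided library
#'
#' Stages: simulate (or load) a paired-end library, discover overlaps and
#' build the graph, traverse into contigs, correct contigs with paired-end
#' anomalies, trim overlapping ends, and (when a reference is known)
#' evaluate.  All randomness flows from the single `seed`.  When `out_dir`
#' is given, every stage writes its artifacts (FASTA/TSV) together with the
#' configuration used.
#'
#' @param config a list: either `genome`/`reads` objects or
#'   `fastq_1`/`fastq_2` paths, plus optional overrides `params`
#'   ([assembly_params()]), `correction` ([correction_params()]),
#'   `min_dup_length`, `min_keep`, `reference`.
#' @param seed integer root seed.
#' @param out_dir optional output directory for artifacts.
#' @param progress print stage progress.
#' @return A list with `reads`, `graph`, `contigs`, `corrected`,
#'   `trimmed`, and (when a reference is available) `report`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL,
                         progress = FALSE) {
  params <- config$params %||% assembly_params()
  cpar <- config$correction %||% correction_params()
  rs <- config$reads
  if (is.null(rs)) {
    if (is.null(config$fastq_1) || is.null(config$fastq_2)) {
      stop("config needs either `reads` or `fastq_1`/`fastq_2`",
           call. = FALSE)
    }
    rs <- parse_fastq(config$fastq_1, config$fastq_2)
  }
  res <- assemble_reads(rs, params, seed = seed, progress = progress)
  mapping <- map_reads_to_contigs(res$contigs, rs)
  corrected <- hyperheuristic_correct(res$contigs, mapping, cpar)
  ends <- find_end_overlaps(corrected,
                            min_dup_length = config$min_dup_length %||%
                              params$min_overlap,
                            max_error_rate = params$max_error_rate)
  trimmed <- trim_contigs(corrected, ends,
                          min_keep = config$min_keep %||% 250L)
  out <- list(reads = rs, graph = res$graph, contigs = res$contigs,
              corrected = corrected, trimmed = trimmed)
  if (!is.null(config$reference)) {
    out$report <- evaluate(trimmed, as.character(config$reference),
                           min_contig = params$min_contig)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_contigs(res$contigs, rs, file.path(out_dir, "contigs_raw.fasta"),
                  file.path(out_dir, "layout.tsv"))
    write_fasta(unclass(trimmed), file.path(out_dir, "contigs.fasta"))
    write_arcs_tsv(res$graph, rs, file.path(out_dir, "arcs.tsv"))
    cfg <- list(seed = seed, params = params, correction = cpar,
                min_dup_length = config$min_dup_length %||% params$min_overlap,
                min_keep = config$min_keep %||% 250L)
    writeLines(deparse(cfg), file.path(out_dir, "config.R"))
  }
  out
}
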
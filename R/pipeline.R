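#' Read a mapped mate-pair table
#'
#' Minimal TSV carrying, per mate, its contig, 0-based half-open
#' interval, strand, percent identity, aligned length, read length and
#' the number of places it maps.
#'
#' @param path TSV path with columns `pair_id`, and for each mate `m`
#'   in 1,2: `contig<m>`, `start<m>`, `end<m>`, `strand<m>`,
#'   `identity<m>`, `aligned<m>`, `read_len<m>`, `hit_count<m>`.
#' @return The data.frame.
#' @export
read_mapped_pairs <- function(path) {
  if (!file.exists(path)) stop("mapped-pairs file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id",
            paste0(rep(c("contig", "start", "end", "strand", "identity",
                         "aligned", "read_len", "hit_count"), each = 2), 1:2))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("mapped-pairs table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a mapped mate-pair table
#'
#' @param pairs Data.frame in the [read_mapped_pairs()] layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapped_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pooled-BAC pipeline with the defaults
#' used throughout the package: a 120 kb BAC unit, BES length bounds
#' of (120, 1000) bp, mate-pair thresholds of 100 % identity and
#' >100 bp reads, a link threshold of K = 10 with a 4-9 kb insert
#' range, and the 200x-1000x LOESS analysis window at span 0.75,
#' degree 2.
#'
#' @param r1,r2 Paired FASTQ paths.
#' @param ecoli,vector Contaminant reference FASTA paths.
#' @param bes BES FASTA path (ids must match the BES query table
#'   convention `<clone>_For` / `<clone>_Rev`, or `vectorFOR` /
#'   `vectorREV` for proxies).
#' @param bes_hits BLAST tabular path of BES vs pool contigs.
#' @param mapped_pairs Mapped mate-pair TSV path.
#' @param assembler Assembler callback or command template (see
#'   [saturation_curve()]); must return/write the pooled contigs.
#' @param pool_clones Character vector of clone ids in the pool.
#' @param out_dir Output directory for all reports.
#' @param seed Integer seed.
#' @param unit_length,n_bacs Coverage accounting parameters.
#' @param read_length Read length (bp) of PE and MP libraries.
#' @param bes_min_len,bes_max_len BES length filter bounds (bp).
#' @param min_links Scaffold-link bundle threshold (K).
#' @param insert_range Mate-pair insert range (bp) used for gap
#'   estimation.
#' @param loess_span,loess_degree,fit_window Saturation-fit
#'   parameters.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(r1, r2, ecoli, vector, bes, bes_hits,
                            mapped_pairs, assembler, pool_clones,
                            out_dir, seed = 1L,
                            unit_length = 120000, n_bacs = 4L,
                            read_length = 150L,
                            bes_min_len = 120, bes_max_len = 1000,
                            min_links = 10L, insert_range = c(4000, 9000),
                            loess_span = 0.75, loess_degree = 2,
                            fit_window = c(200, 1000)) {
  cfg <- list(r1 = r1, r2 = r2, ecoli = ecoli, vector = vector, bes = bes,
              bes_hits = bes_hits, mapped_pairs = mapped_pairs,
              assembler = assembler, pool_clones = pool_clones,
              out_dir = out_dir, seed = as.integer(seed),
              unit_length = unit_length, n_bacs = as.integer(n_bacs),
              read_length = as.integer(read_length),
              bes_min_len = bes_min_len, bes_max_len = bes_max_len,
              min_links = as.integer(min_links), insert_range = insert_range,
              loess_span = loess_span, loess_degree = loess_degree,
              fit_window = fit_window)
  structure(cfg, class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' The assembler callback is not serialisable and is dropped with a
#' note; everything else round-trips exactly.
#'
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @return `path` invisibly (write) / the restored config (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (is.function(x$assembler)) x$assembler <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(x[setdiff(names(x), "assembler")],
                             list(assembler = NULL)))
}

stage_fail <- function(stage, ...) {
  stop("pipeline stage '", stage, "' failed: ", ..., call. = FALSE)
}

require_file <- function(stage, path, what) {
  if (is.null(path) || !file.exists(path)) {
    stage_fail(stage, "missing ", what, " file: ",
               if (is.null(path)) "<unset>" else path)
  }
  path
}

#' Run the pooled-BAC pipeline on one pool
#'
#' Executes the stages in pipeline order — read QC (contaminant and
#' clonal filtering), assembly via the pluggable external assembler,
#' BES deconvolution, mate-pair orientation QC, and scaffolding-link
#' construction — writing every report plus a manifest into
#' `config$out_dir`. Re-running with the same configuration and
#' inputs reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `qc_report`,
#'   `deconvolution_report`, orientation summary, bundles, and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- qc ---
  require_file("qc", cfg$r1, "R1 FASTQ")
  require_file("qc", cfg$r2, "R2 FASTQ")
  require_file("qc", cfg$ecoli, "E. coli reference")
  require_file("qc", cfg$vector, "vector reference")
  pairs <- tryCatch(read_paired_fastq(cfg$r1, cfg$r2),
                    error = function(e) stage_fail("qc", conditionMessage(e)))
  qc <- tryCatch(
    run_readqc(pairs,
               ecoli_ref = read_fasta(cfg$ecoli),
               vector_ref = read_fasta(cfg$vector),
               n_bacs = cfg$n_bacs, unit_length = cfg$unit_length),
    error = function(e) stage_fail("qc", conditionMessage(e))
  )
  write_qc_report(qc, file.path(cfg$out_dir, "qc_report.tsv"))

  # --- assemble (external) ---
  if (is.null(cfg$assembler)) stage_fail("assemble", "no assembler configured")
  asm <- tryCatch(resolve_assembler(cfg$assembler)(qc$kept),
                  error = function(e) stage_fail("assemble", conditionMessage(e)))
  if (is.null(names(asm))) names(asm) <- sprintf("contig%03d", seq_along(asm))
  contigs <- as.character(asm)
  names(contigs) <- names(asm)
  write_fasta(contigs, file.path(cfg$out_dir, "contigs.fasta"))
  contig_lengths <- stats::setNames(nchar(contigs), names(contigs))

  # --- deconvolve ---
  require_file("deconvolve", cfg$bes, "BES FASTA")
  require_file("deconvolve", cfg$bes_hits, "BES hits")
  dec <- tryCatch({
    bes_seqs <- read_fasta(cfg$bes)
    bq <- parse_bes_ids(names(bes_seqs), as.character(bes_seqs))
    hits <- read_blast_tabular(cfg$bes_hits)
    assignments <- assign_bes(bq, hits, contig_lengths,
                              min_len = cfg$bes_min_len,
                              max_len = cfg$bes_max_len)
    write_assignments(assignments, file.path(cfg$out_dir, "bes_assignments.tsv"))
    deconvolute_pool(assignments, bq, cfg$pool_clones, names(contig_lengths))
  }, error = function(e) stage_fail("deconvolve", conditionMessage(e)))
  utils::write.table(dec$clone_summary,
                     file.path(cfg$out_dir, "deconvolution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- mpqc ---
  require_file("mpqc", cfg$mapped_pairs, "mapped mate-pair table")
  mp <- tryCatch(read_mapped_pairs(cfg$mapped_pairs),
                 error = function(e) stage_fail("mpqc", conditionMessage(e)))
  valid <- select_validation_pairs(mp)
  if (nrow(valid) == 0) stage_fail("mpqc", "no pairs pass the validation filter")
  calls <- classify_orientation(valid)
  summ <- orientation_summary(calls)
  write_orientation_summary(summ, file.path(cfg$out_dir, "mp_orientation.tsv"))
  utils::write.table(insert_histogram(calls),
                     file.path(cfg$out_dir, "mp_insert_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- links ---
  links <- tryCatch({
    sel <- select_scaffold_pairs(mp, cfg$read_length)
    make_scaffold_links(sel)
  }, error = function(e) stage_fail("links", conditionMessage(e)))
  write_sspace_tab(links, file.path(cfg$out_dir, "links.tab"))
  bundles <- bundle_links(links, contig_lengths,
                          min_links = cfg$min_links,
                          insert_range = cfg$insert_range)
  utils::write.table(bundles, file.path(cfg$out_dir, "bundles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- manifest (no timestamps: reruns must be byte-identical) ---
  manifest <- list(
    package = "bacpool",
    version = as.character(utils::packageVersion("bacpool")),
    seed = cfg$seed,
    inputs = cfg[c("r1", "r2", "ecoli", "vector", "bes", "bes_hits",
                   "mapped_pairs")],
    parameters = cfg[c("unit_length", "n_bacs", "read_length", "bes_min_len",
                       "bes_max_len", "min_links", "insert_range")],
    stages = c("qc", "assemble", "deconvolve", "mpqc", "links")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(qc = qc, deconvolution = dec, orientation = summ,
                 bundles = bundles, out_dir = cfg$out_dir))
}

# BES FASTA ids follow "<clone>_For" / "<clone>_Rev"; "vectorFOR" /
# "vectorREV" denote vector-end proxies.
parse_bes_ids <- function(ids, seqs) {
  is_proxy <- ids %in% c("vectorFOR", "vectorREV")
  end <- ifelse(grepl("(_For|FOR)$", ids), "forward", "reverse")
  clone <- ifelse(is_proxy, NA_character_, sub("_(For|Rev)$", "", ids))
  data.frame(bes_id = ids, clone_id = clone, end = end, sequence = seqs,
             source = ifelse(is_proxy, "vector_end_proxy", "sanger_bes"),
             stringsAsFactors = FALSE)
}
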
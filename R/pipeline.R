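#' Pipeline configuration
#'
#' Bundles every tunable threshold with its published default: k = 19 with
#' an 800-nt maximum gap between matching k-mers, a 5000-nt minimum
#' matching block for the mitochondrial read screen (3000 nt was used for
#' samples with shorter reads), block support filters, the heteroplasmy
#' support threshold, and repeat-finder settings. The configuration is
#' echoed verbatim (with a hash) into every report for provenance.
#'
#' @param k K-mer size (nt).
#' @param gap_threshold Maximum gap (nt) between successive matching
#'   k-mer starts within one block.
#' @param min_block Minimum matching-block span (nt) for the mitochondrial
#'   screen.
#' @param min_kmers,min_query_coverage Block support filters.
#' @param min_anchor_span Fraction of each anchor gene a spanning read's
#'   matching block must extend over.
#' @param min_support Reads per class required for the heteroplasmy
#'   verdict.
#' @param min_period,max_period,min_copies,min_identity Repeat-finder
#'   thresholds.
#' @param seed Seed recorded for provenance.
#' @return An object of class `run_config`.
#' @export
run_config <- function(k = 19, gap_threshold = 800, min_block = 5000,
                       min_kmers = 5, min_query_coverage = 0.1,
                       min_anchor_span = 0.8,
                       min_support = 2, min_period = 10, max_period = 400,
                       min_copies = 1.9, min_identity = 0.8, seed = NA_integer_) {
  cfg <- list(k = k, gap_threshold = gap_threshold, min_block = min_block,
              min_kmers = min_kmers, min_query_coverage = min_query_coverage,
              min_anchor_span = min_anchor_span,
              min_support = min_support, min_period = min_period,
              max_period = max_period, min_copies = min_copies,
              min_identity = min_identity, seed = seed)
  bad <- c("k", "gap_threshold", "min_block", "min_kmers", "min_support",
           "min_period", "max_period")
  for (f in bad) if (cfg[[f]] < 1 && !(f %in% c("min_kmers"))) {
    abort(sprintf("`%s` must be positive", f))
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (f in names(unclass(x))) cat(sprintf("  %s = %s\n", f, format(x[[f]])))
  cat(sprintf("  hash = %s\n", config_hash(x)))
  invisible(x)
}

config_hash <- function(config) rlang::hash(unclass(config))

# Drop copy blocks outside the anchor-enclosed read interval (with k-1 nt
# slack) and recount.
restrict_calls <- function(calls, spans, k) {
  bounds <- spans[match(calls$read_id, spans$read_id), c("between_lo", "between_hi")]
  calls$blocks <- map(seq_len(nrow(calls)), function(i) {
    b <- calls$blocks[[i]]
    lo <- bounds$between_lo[i]
    hi <- bounds$between_hi[i]
    if (is.na(lo) || is.na(hi) || nrow(b) == 0) return(b)
    b[b$start >= lo - (k - 1) & b$end <= hi + (k - 1), , drop = FALSE]
  })
  calls$copy_count <- map_int(calls$blocks, nrow)
  calls$n_blocks <- calls$copy_count
  calls
}

#' Run the full heteroplasmy pipeline
#'
#' Orchestrates screen -> anchor spanning -> copy calling -> spectrum ->
#' heteroplasmy verdict -> read partition on one sample. The anchor genes
#' and the focal copy-counted gene are taken from the reference
#' annotation; a missing label is a hard error naming it.
#'
#' @param reads Data frame with `read_id`/`sequence`, or character
#'   vector, or a FASTA/FASTQ path.
#' @param reference Reference mitogenome sequence (string) or FASTA path.
#' @param annotation Gene annotation tibble (`gene`, `start`, `end`,
#'   `strand`; 1-based inclusive) or TSV path.
#' @param config A [run_config()].
#' @param sample Sample label.
#' @param anchor_genes Labels of the two genes flanking the duplicated
#'   region.
#' @param copy_gene Focal gene whose copies are counted per read.
#' @param out_dir Optional directory; when given, TSV/JSON reports and
#'   per-class FASTA exports are written there.
#' @return An object of class `mito_report`: list with `screen`, `calls`,
#'   `spectrum`, `heteroplasmy`, `partition`, `config`, `config_hash`,
#'   `sample`, `log` (per-stage counts).
#' @export
run_full <- function(reads, reference, annotation, config = run_config(),
                     sample = "sample", anchor_genes = c("12S", "CYTB"),
                     copy_gene = "ND6", out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_seqs(reads)
  }
  reads <- as_reads_tbl(reads)
  if (is.character(reference) && file.exists(reference) &&
      grepl("\\.(fa|fasta|fna)$", reference, ignore.case = TRUE)) {
    reference <- read_seqs(reference)$sequence[1]
  }
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- read_annotation(annotation)
  }

  anchors <- anchor_pair(
    anchor_genes[1], anchor_genes[2],
    gene_sequence(reference, annotation, anchor_genes[1]),
    gene_sequence(reference, annotation, anchor_genes[2]),
    k = config$k
  )
  query <- gene_sequence(reference, annotation, copy_gene)

  screen <- screen_mt_reads(reads, reference, k = config$k,
                            gap_threshold = config$gap_threshold,
                            min_block = config$min_block)
  mt_reads <- filter(reads, .data$read_id %in% screen$read_id[screen$is_mt])

  spans <- screen_anchor_reads(mt_reads, anchors, k = config$k,
                               gap_threshold = config$gap_threshold,
                               min_kmers = config$min_kmers,
                               min_query_coverage = config$min_query_coverage,
                               min_anchor_span = config$min_anchor_span)
  screen <- left_join(screen, spans, by = "read_id") |>
    mutate(spans_anchors = !is.na(.data$spans_anchors) & .data$spans_anchors,
           anchor_orientation = ifelse(is.na(.data$anchor_orientation), "na",
                                       .data$anchor_orientation))

  spanning_ids <- spans$read_id[spans$spans_anchors]
  span_reads <- filter(mt_reads, .data$read_id %in% spanning_ids)
  calls <- count_copies(span_reads, query, k = config$k,
                        gap_threshold = config$gap_threshold,
                        min_kmers = config$min_kmers,
                        min_query_coverage = config$min_query_coverage)
  # only copies enclosed by the anchors are counted: partial copies at the
  # read edges (outside the 12S..CYTB region) do not inform the spectrum
  calls <- restrict_calls(calls, spans, k = config$k)

  spectrum <- build_spectrum(calls, spanning_ids, sample = sample)
  het <- call_heteroplasmy(spectrum, min_support = config$min_support)
  partition <- partition_reads(calls)

  log <- tibble(
    stage = c("input", "mt", "spanning", "called"),
    n_reads = c(nrow(reads), nrow(mt_reads), length(spanning_ids), nrow(calls))
  )

  report <- structure(
    list(screen = screen, calls = calls, spectrum = spectrum,
         heteroplasmy = het, partition = partition, config = config,
         config_hash = config_hash(config), sample = sample, log = log),
    class = "mito_report"
  )
  if (!is.null(out_dir)) write_report(report, span_reads, out_dir)
  report
}

#' @export
print.mito_report <- function(x, ...) {
  cat(sprintf("<mito_report> sample %s (config %s)\n", x$sample, x$config_hash))
  print(x$log)
  print(x$heteroplasmy)
  invisible(x)
}

write_report <- function(report, span_reads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# config_hash=%s %s", report$config_hash,
                    paste(sprintf("%s=%s", names(unclass(report$config)),
                                  unlist(unclass(report$config))), collapse = " "))
  tsv_with_header <- function(tbl, path) {
    writeLines(header, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  }
  tsv_with_header(report$screen, file.path(out_dir, "screen.tsv"))
  calls_flat <- report$calls |>
    mutate(blocks = map_chr(.data$blocks, format_blocks)) |>
    select("read_id", "read_length", "n_blocks", "copy_count", "blocks")
  tsv_with_header(calls_flat, file.path(out_dir, "copy_calls.tsv"))
  tsv_with_header(as_tibble(report$spectrum), file.path(out_dir, "spectrum.tsv"))
  jsonlite::write_json(
    list(sample = report$sample,
         config = unclass(report$config),
         config_hash = report$config_hash,
         is_heteroplasmic = report$heteroplasmy$is_heteroplasmic,
         min_support = report$heteroplasmy$min_support,
         n_spanning = report$heteroplasmy$n_spanning,
         classes = report$heteroplasmy$classes),
    file.path(out_dir, "heteroplasmy.json"),
    auto_unbox = TRUE, digits = NA
  )
  export_partition(report$partition, span_reads, out_dir, sample = report$sample)
  invisible(out_dir)
}
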
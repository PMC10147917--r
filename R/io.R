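#' Read sequences from FASTA or FASTQ
#'
#' Qualities in FASTQ input are ignored; the pipeline works from base calls
#' alone.
#'
#' @param path File path. Format is taken from the extension
#'   (`.fastq`/`.fq` read as FASTQ, anything else as FASTA) unless given.
#' @param format `"fasta"`, `"fastq"`, or `NULL` to guess.
#' @return A tibble with `read_id` and `sequence`.
#' @export
read_seqs <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  set <- Biostrings::readDNAStringSet(path, format = format)
  tibble(
    read_id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set))
  )
}

#' Write sequences to FASTA
#'
#' @param seqs A data frame with `read_id` and `sequence`, or a named
#'   character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_reads_tbl(seqs)
  set <- Biostrings::DNAStringSet(seqs$sequence)
  names(set) <- seqs$read_id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Simulated reads carry no meaningful per-base qualities; a constant
#' quality of `I` (Q40) is emitted.
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(seqs, path) {
  seqs <- as_reads_tbl(seqs)
  lines <- as.vector(rbind(
    paste0("@", seqs$read_id),
    seqs$sequence,
    "+",
    strrep("I", nchar(seqs$sequence))
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED-like gene annotation table
#'
#' Tab-separated with columns `gene`, `start`, `end`, `strand`;
#' coordinates are 1-based inclusive on disk and in memory.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(ann)))
  ann
}

#' Write a gene annotation table
#'
#' @param annotation A tibble with `gene`, `start`, `end`, `strand`.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

# Extract a gene's sequence from a reference using its annotation row;
# minus-strand genes are reverse-complemented so the result reads 5'->3'.
gene_sequence <- function(reference, annotation, gene) {
  rows <- annotation[annotation$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0) abort(sprintf("anchor gene not found: %s", gene))
  r <- rows[1, ]
  s <- substr(reference, r$start, r$end)
  if (identical(r$strand, "-")) s <- revcomp(s)
  s
}
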
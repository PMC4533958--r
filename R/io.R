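# Plain-text I/O: FASTA genome, BED6 annotation tracks, BED6+sequence read
# files (a TSV extension of BED), count matrices and design tables.

#' Write the toy genome as FASTA
#'
#' @param genome a [make_genome()] result.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, file) {
  Biostrings::writeXStringSet(genome$sequences, filepath = file)
  invisible(file)
}

#' Write annotation tracks as BED6 files
#'
#' One 0-based half-open BED6 file per annotation class, with the feature id
#' in the name column.
#'
#' @param genome a [make_genome()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_tracks_bed <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(genome$tracks), function(cl) {
    gr <- genome$tracks[[cl]]
    path <- file.path(dir, paste0(cl, ".bed"))
    names(gr) <- mcols(gr)$feature_id
    mcols(gr)$score <- 0
    rtracklayer::export(gr, path, format = "BED")
    path
  }, character(1))
  invisible(paths)
}

#' Read a BED track
#'
#' @param file BED path.
#' @return GRanges (1-based closed internally) with `feature_id` metadata.
#' @export
read_track_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  mcols(gr)$feature_id <- mcols(gr)$name %||% as.character(seq_along(gr))
  gr
}

#' Write aligned reads as BED6 + sequence
#'
#' Tab-separated BED6 (0-based half-open) with the number of alignment
#' records of the read in the score column and the read sequence in a
#' seventh column.
#'
#' @param alignments GRanges with `read_id`, `seq`, `n_hits` metadata.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_alignments <- function(alignments, file) {
  df <- data.frame(
    chrom = as.character(seqnames(alignments)),
    start = start(alignments) - 1L,
    end = end(alignments),
    name = mcols(alignments)$read_id,
    score = mcols(alignments)$n_hits %||% 1L,
    strand = as.character(strand(alignments)),
    seq = mcols(alignments)$seq,
    stringsAsFactors = FALSE
  )
  write.table(df, file = file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read aligned reads from a BED6 + sequence file
#'
#' @param file path written by [write_alignments()].
#' @return GRanges with `read_id`, `seq`, `n_hits` metadata.
#' @export
read_alignments <- function(file) {
  df <- read.delim(file, header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "seq"),
                   stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand)
  mcols(gr)$read_id <- df$name
  mcols(gr)$seq <- df$seq
  mcols(gr)$n_hits <- df$score
  gr
}

#' Write contigs as BED6 with support in the score column
#'
#' @param contigs a [build_contigs()] result.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_contigs_bed <- function(contigs, file) {
  df <- data.frame(
    chrom = as.character(seqnames(contigs)),
    start = start(contigs) - 1L,
    end = end(contigs),
    name = mcols(contigs)$contig_id,
    score = mcols(contigs)$support,
    strand = as.character(strand(contigs)),
    stringsAsFactors = FALSE
  )
  write.table(df, file = file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write / read a count matrix as TSV (features in rows)
#'
#' @param counts features x samples matrix.
#' @param file path.
#' @return the path (write) or an integer matrix (read).
#' @export
write_count_matrix <- function(counts, file) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, file)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
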
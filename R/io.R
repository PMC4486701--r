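#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings keeping the package's plain
#' named-character-vector representation of sequence sets.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read and write paired FASTQ files
#'
#' Reads are held in a data.frame with columns `pair_id`, `read1_seq`,
#' `read2_seq`, `read1_quals`, `read2_quals` (qualities as Phred+33
#' strings). Files are written/read uncompressed, Phred+33.
#'
#' @param reads A read-pair data.frame as above.
#' @param r1_path,r2_path Paths for the two mate files.
#' @return `read_paired_fastq` returns a read-pair data.frame.
#' @export
write_paired_fastq <- function(reads, r1_path, r2_path) {
  wr <- function(ids, seqs, quals, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals))
    # Biostrings warns that (empty) mcols are dropped on write; cosmetic
    withCallingHandlers(
      Biostrings::writeQualityScaledXStringSet(x, path, compress = FALSE),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  wr(reads$pair_id, reads$read1_seq, reads$read1_quals, r1_path)
  wr(reads$pair_id, reads$read2_seq, reads$read2_quals, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_paired_fastq
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  rd <- function(path) {
    # Biostrings warns about dropping (empty) mcols on read; cosmetic
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(id = sub("\\s.*$", "", names(x)),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  }
  r1 <- rd(r1_path); r2 <- rd(r2_path)
  if (!identical(r1$id, r2$id))
    stop("mate files disagree on read ids or order")
  data.frame(pair_id = r1$id,
             read1_seq = unname(r1$seq), read2_seq = unname(r2$seq),
             read1_quals = unname(r1$qual), read2_quals = unname(r2$qual),
             stringsAsFactors = FALSE)
}

#' Read and write the truth table of a simulated read set
#'
#' TSV with columns `pair_id`, `taxid`, `amplicon_id`.
#'
#' @param truth Data.frame with those columns.
#' @param path File path.
#' @return `read_truth_tsv` returns the data.frame.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth[, c("pair_id", "taxid", "amplicon_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "character"))
}
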
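#' Merge an overlapping read pair into a consensus sequence
#'
#' Scans every overlap of length >= `min_overlap` between read 1 and the
#' reverse complement of read 2 (including full containment, i.e.
#' adapter read-through of short amplicons) and accepts the overlap with
#' the smallest mismatch ratio, ties resolved toward the longest
#' overlap. The pair is rejected when that best ratio exceeds
#' `max_mismatch_ratio`. In the overlap, the consensus base at a
#' disagreement is the base with the higher Phred score (tie: read 1)
#' with quality `|q1 - q2|`; at an agreement the consensus quality is
#' the larger of the two.
#'
#' @param pair List or one-row data.frame with `pair_id`, `read1_seq`,
#'   `read2_seq`, `read1_quals`, `read2_quals` (Phred+33 strings or
#'   integer vectors).
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_ratio Maximum fraction of mismatching columns in
#'   the overlap (default 0.25).
#' @return A list with `pair_id`, `consensus_seq`, `consensus_quals`
#'   (Phred+33 string), `overlap_len`, `mismatches_in_overlap`; or
#'   `NULL` when no acceptable overlap exists.
#' @export
merge_pair <- function(pair, min_overlap = 10L, max_mismatch_ratio = 0.25) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (max_mismatch_ratio < 0 || max_mismatch_ratio > 1)
    stop("max_mismatch_ratio must be in [0, 1]")
  as_q <- function(q) if (is.character(q)) string_to_phred(q) else as.integer(q)
  s1 <- strsplit(toupper(pair$read1_seq[[1L]]), "", fixed = TRUE)[[1L]]
  q1 <- as_q(pair$read1_quals[[1L]])
  r2 <- revcomp(toupper(pair$read2_seq[[1L]]))
  s2 <- strsplit(r2, "", fixed = TRUE)[[1L]]
  q2 <- rev(as_q(pair$read2_quals[[1L]]))
  n1 <- length(s1); n2 <- length(s2)
  if (length(q1) != n1 || length(q2) != n2)
    stop("quality length does not match sequence length")
  max_o <- min(n1, n2)
  if (max_o < min_overlap) return(NULL)

  best_o <- NA_integer_; best_mm <- NA_integer_; best_ratio <- Inf
  for (o in seq.int(min_overlap, max_o)) {
    mm <- sum(s1[(n1 - o + 1L):n1] != s2[seq_len(o)])
    ratio <- mm / o
    if (ratio < best_ratio - 1e-12 ||
        (abs(ratio - best_ratio) <= 1e-12 && o > best_o)) {
      best_o <- o; best_mm <- mm; best_ratio <- ratio
    }
  }
  if (best_ratio > max_mismatch_ratio) return(NULL)

  o <- best_o
  i1 <- (n1 - o + 1L):n1        # overlap columns in read 1
  i2 <- seq_len(o)              # overlap columns in revcomp(read 2)
  a <- s1[i1]; b <- s2[i2]
  qa <- q1[i1]; qb <- q2[i2]
  agree <- a == b
  cons <- ifelse(agree | qa >= qb, a, b)
  qual <- ifelse(agree, pmax(qa, qb), abs(qa - qb))
  consensus <- c(s1[seq_len(n1 - o)], cons, s2[-i2])
  cons_q <- c(q1[seq_len(n1 - o)], qual, q2[-i2])
  list(pair_id = pair$pair_id[[1L]],
       consensus_seq = paste(consensus, collapse = ""),
       consensus_quals = phred_to_string(cons_q),
       overlap_len = o,
       mismatches_in_overlap = best_mm)
}

#' Quality-trim the 3' end of a read
#'
#' Partial-sum trimming in the Trim-Galore/BWA style: the read is cut at
#' the position maximising the suffix sum of `(cutoff - q)`; the suffix
#' is removed whenever that maximum is non-negative, so every trailing
#' base with Phred <= `phred_cutoff` is trimmed. A fully low-quality
#' read trims to the empty sequence.
#'
#' @param seq DNA string.
#' @param quals Phred+33 string or integer vector, same length as `seq`.
#' @param phred_cutoff Quality cutoff (default 25).
#' @return List with `seq` and `quals` (Phred+33 string) after trimming.
#' @export
quality_trim <- function(seq, quals, phred_cutoff = 25L) {
  q <- if (is.character(quals)) string_to_phred(quals) else as.integer(quals)
  n <- nchar(seq)
  if (length(q) != n) stop("quality length does not match sequence length")
  if (n == 0L) return(list(seq = "", quals = ""))
  suffix <- rev(cumsum(rev(phred_cutoff - q)))
  cut <- which.max(suffix)           # earliest position among ties: longest trim
  if (suffix[cut] >= 0) {
    keep <- cut - 1L
  } else {
    keep <- n
  }
  list(seq = substr(seq, 1L, keep),
       quals = phred_to_string(q[seq_len(keep)]))
}

#' Length-filter a trimmed read pair
#'
#' A pair is dropped when either mate is shorter than `min_len`
#' (strictly shorter: 50/50 survives the default).
#'
#' @param pair List or one-row data.frame with `read1_seq`, `read2_seq`.
#' @param min_len Minimum mate length (default 50).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
length_filter <- function(pair, min_len = 50L) {
  nchar(pair$read1_seq[[1L]]) >= min_len &&
    nchar(pair$read2_seq[[1L]]) >= min_len
}

#' Dereplicate sequences
#'
#' Exact full-length, case-insensitive grouping of identical sequences.
#' The representative of each group is the first-seen id; abundance is
#' the group size.
#'
#' @param ids Character vector of sequence ids.
#' @param seqs Character vector of sequences, parallel to `ids`.
#' @return An object of class `"derep_set"`: list with `entries` (a
#'   data.frame `sequence`, `rep_id`, `abundance`), `members` (list of
#'   member ids per entry) and `total_input`.
#' @export
dereplicate <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  key <- toupper(seqs)
  first <- !duplicated(key)
  uk <- key[first]
  grp <- match(key, uk)
  entries <- data.frame(sequence = uk,
                        rep_id = ids[first],
                        abundance = as.integer(tabulate(grp, length(uk))),
                        stringsAsFactors = FALSE)
  structure(list(entries = entries,
                 members = split(ids, factor(grp, seq_along(uk))),
                 total_input = length(ids)),
            class = "derep_set")
}

#' @export
print.derep_set <- function(x, ...) {
  cat("derep_set:", nrow(x$entries), "unique sequences from",
      x$total_input, "inputs\n")
  invisible(x)
}

#' Run the read-preparation stage on a set of read pairs
#'
#' Applies [merge_pair()] to every pair; merged consensus sequences are
#' dereplicated. Non-merging pairs are 3'-quality-trimmed
#' ([quality_trim()], merged reads pass through untrimmed) and
#' length-filtered ([length_filter()]); survivors are kept as unmerged
#' pairs for paired-end mapping. Every input pair lands in exactly one
#' of merged / unmerged-kept / dropped.
#'
#' @param reads Read-pair data.frame (see [read_paired_fastq()]).
#' @param min_overlap,max_mismatch_ratio Passed to [merge_pair()].
#' @param phred_cutoff Passed to [quality_trim()].
#' @param min_len Passed to [length_filter()].
#' @return List with `merged` (data.frame `pair_id`, `consensus_seq`,
#'   `consensus_quals`, `overlap_len`, `mismatches_in_overlap`),
#'   `derep` (a [dereplicate()] set over the merged consensus
#'   sequences), `unmerged` (trimmed read-pair data.frame), and `counts`
#'   (named vector: input, merged, unmerged_kept, dropped).
#' @export
prep_reads <- function(reads, min_overlap = 10L, max_mismatch_ratio = 0.25,
                       phred_cutoff = 25L, min_len = 50L) {
  n <- nrow(reads)
  merged <- vector("list", n)
  unm <- vector("list", n)
  for (i in seq_len(n)) {
    m <- merge_pair(reads[i, ], min_overlap, max_mismatch_ratio)
    if (!is.null(m)) {
      merged[[i]] <- m
    } else {
      t1 <- quality_trim(reads$read1_seq[i], reads$read1_quals[i], phred_cutoff)
      t2 <- quality_trim(reads$read2_seq[i], reads$read2_quals[i], phred_cutoff)
      pr <- data.frame(pair_id = reads$pair_id[i],
                       read1_seq = t1$seq, read2_seq = t2$seq,
                       read1_quals = t1$quals, read2_quals = t2$quals,
                       stringsAsFactors = FALSE)
      if (length_filter(pr, min_len)) unm[[i]] <- pr
    }
  }
  merged <- merged[!vapply(merged, is.null, logical(1))]
  unm <- unm[!vapply(unm, is.null, logical(1))]
  merged_df <- if (length(merged)) {
    data.frame(pair_id = vapply(merged, `[[`, "", "pair_id"),
               consensus_seq = vapply(merged, `[[`, "", "consensus_seq"),
               consensus_quals = vapply(merged, `[[`, "", "consensus_quals"),
               overlap_len = vapply(merged, `[[`, 0L, "overlap_len"),
               mismatches_in_overlap =
                 vapply(merged, `[[`, 0L, "mismatches_in_overlap"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pair_id = character(0), consensus_seq = character(0),
               consensus_quals = character(0), overlap_len = integer(0),
               mismatches_in_overlap = integer(0), stringsAsFactors = FALSE)
  }
  unmerged_df <- if (length(unm)) do.call(rbind, unm) else
    data.frame(pair_id = character(0), read1_seq = character(0),
               read2_seq = character(0), read1_quals = character(0),
               read2_quals = character(0), stringsAsFactors = FALSE)
  counts <- c(input = n, merged = nrow(merged_df),
              unmerged_kept = nrow(unmerged_df),
              dropped = n - nrow(merged_df) - nrow(unmerged_df))
  list(merged = merged_df,
       derep = dereplicate(merged_df$pair_id, merged_df$consensus_seq),
       unmerged = unmerged_df,
       counts = counts)
}
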
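BLAST13 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qlen")

#' Parse BLAST tabular output into hit records
#'
#' Consumes outfmt-6 style tables. The default dialect is the 12
#' standard columns plus `qlen`, from which query coverage is computed
#' as `100 * (qend - qstart + 1) / qlen`; without `qlen` a `qcovs`
#' column must be present.
#'
#' @param path Path to the tabular file.
#' @param columns Column names in file order (default the 13-column
#'   dialect above).
#' @return Data.frame of hit records: `query_id`, `ref_id`,
#'   `identity_pct`, `query_coverage_pct`, `bitscore`, `qstart`, `qend`,
#'   `paired_flag`, plus the raw parsed columns.
#' @export
parse_blast_tabular <- function(path, columns = BLAST13) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(columns))
  if (length(bad))
    stop("ragged row in BLAST tabular input at line ", bad[1L], ": expected ",
         length(columns), " fields, found ", lengths(parts)[bad[1L]])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- columns
  num <- setdiff(columns, c("qseqid", "sseqid"))
  tab[num] <- lapply(tab[num], as.numeric)
  need <- c("qseqid", "sseqid", "pident", "bitscore")
  if (!all(need %in% columns))
    stop("dialect must provide columns: ", paste(need, collapse = ", "))
  if ("qlen" %in% columns) {
    cov <- 100 * (tab$qend - tab$qstart + 1) / tab$qlen
  } else if ("qcovs" %in% columns) {
    cov <- tab$qcovs
  } else {
    stop("cannot compute query coverage: dialect has neither qlen nor qcovs")
  }
  cbind(data.frame(query_id = tab$qseqid, ref_id = tab$sseqid,
                   identity_pct = tab$pident, query_coverage_pct = cov,
                   bitscore = tab$bitscore,
                   qstart = if ("qstart" %in% columns) as.integer(tab$qstart) else NA_integer_,
                   qend = if ("qend" %in% columns) as.integer(tab$qend) else NA_integer_,
                   paired_flag = FALSE, stringsAsFactors = FALSE),
        tab[setdiff(columns, c("qseqid", "sseqid"))])
}

empty_hits <- function() {
  data.frame(query_id = character(0), ref_id = character(0),
             identity_pct = numeric(0), query_coverage_pct = numeric(0),
             bitscore = numeric(0), qstart = integer(0), qend = integer(0),
             paired_flag = logical(0), stringsAsFactors = FALSE)
}

#' Write hit records as 13-column BLAST tabular
#'
#' Canonical formatting (identity to 3 decimals, `%g` scores) so that
#' write / parse / write round-trips bit-identically.
#'
#' @param hits Hit data.frame carrying the 13 dialect columns (as
#'   returned by [parse_blast_tabular()], or synthesized).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_blast_tabular <- function(hits, path) {
  get <- function(col, default) {
    if (col %in% names(hits)) hits[[col]] else rep(default, nrow(hits))
  }
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g\t%d",
                   hits$query_id, hits$ref_id, hits$identity_pct,
                   as.integer(get("length", 0L)), as.integer(get("mismatch", 0L)),
                   as.integer(get("gapopen", 0L)),
                   as.integer(get("qstart", 1L)), as.integer(get("qend", 1L)),
                   as.integer(get("sstart", 1L)), as.integer(get("send", 1L)),
                   get("evalue", 0), hits$bitscore,
                   as.integer(get("qlen", 1L)))
  writeLines(lines, path)
  invisible(path)
}

cigar_counts <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  mapply(function(op, ln) {
    c(alncols = sum(ln[op %in% c("M", "=", "X")]),
      qaln = sum(ln[op %in% c("M", "=", "X", "I")]))
  }, ops, lens)
}

md_mismatches <- function(md) {
  # count substitution letters in an MD tag (letters outside ^-deletions)
  vapply(md, function(x) {
    if (is.na(x)) return(NA_integer_)
    x <- gsub("\\^[A-Z]+", "", x)
    sum(strsplit(gsub("[0-9]", "", x), "", fixed = TRUE)[[1L]] %in%
          c("A", "C", "G", "T", "N"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Parse SAM alignments into hit records
#'
#' Reads a SAM (or BAM) file including secondary alignments. Identity is
#' `100 * (aligned_columns - NM) / aligned_columns` over the CIGAR
#' M/=/X columns (mismatches recovered from the MD tag when NM is
#' absent; records with neither are skipped with a warning). Coverage is
#' `100 * aligned query bases / read length` with soft clips counted in
#' the read length. Records of a properly paired alignment are combined
#' into a single paired hit with identity and coverage averaged over the
#' mates and score the sum of the mates' alignment scores (`AS`, the
#' bitscore analogue for SAM input).
#'
#' @param path Path to a SAM or BAM file.
#' @return Hit data.frame as in [parse_blast_tabular()].
#' @export
parse_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            indexDestination = FALSE, overwrite = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "cigar"),
    tag = c("NM", "MD", "AS"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(x$qname)
  if (n == 0L) return(empty_hits())
  cc <- cigar_counts(x$cigar)
  alncols <- cc["alncols", ]
  qaln <- cc["qaln", ]
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  md_mm <- md_mismatches(if (is.null(x$tag$MD)) rep(NA_character_, n) else x$tag$MD)
  nm[is.na(nm)] <- md_mm[is.na(nm)]
  skip <- is.na(nm)
  if (any(skip))
    warning(sum(skip), " SAM record(s) skipped: neither NM nor MD tag present")
  as_score <- x$tag$AS
  if (is.null(as_score)) as_score <- rep(NA_real_, n)
  score <- ifelse(is.na(as_score), alncols - nm, as_score)

  hits <- data.frame(query_id = x$qname,
                     ref_id = as.character(x$rname),
                     identity_pct = 100 * (alncols - nm) / alncols,
                     query_coverage_pct = 100 * qaln / x$qwidth,
                     bitscore = pmax(score, 0),
                     qstart = 1L, qend = as.integer(qaln),
                     paired_flag = FALSE, stringsAsFactors = FALSE)[!skip, ]
  flag <- x$flag[!skip]
  proper <- bitwAnd(flag, 2L) > 0L
  first <- bitwAnd(flag, 64L) > 0L
  single <- hits[!proper, , drop = FALSE]

  if (any(proper)) {
    ph <- hits[proper, , drop = FALSE]
    pf <- first[proper]
    key <- paste(ph$query_id, ph$ref_id)
    combined <- lapply(split(seq_len(nrow(ph)), key), function(idx) {
      a <- idx[pf[idx]]; b <- idx[!pf[idx]]
      m <- min(length(a), length(b))
      if (m == 0L) return(ph[idx, , drop = FALSE])  # unpaired leftover
      paired <- data.frame(
        query_id = ph$query_id[a[seq_len(m)]],
        ref_id = ph$ref_id[a[seq_len(m)]],
        identity_pct = (ph$identity_pct[a[seq_len(m)]] +
                          ph$identity_pct[b[seq_len(m)]]) / 2,
        query_coverage_pct = (ph$query_coverage_pct[a[seq_len(m)]] +
                                ph$query_coverage_pct[b[seq_len(m)]]) / 2,
        bitscore = ph$bitscore[a[seq_len(m)]] + ph$bitscore[b[seq_len(m)]],
        qstart = 1L,
        qend = ph$qend[a[seq_len(m)]],
        paired_flag = TRUE, stringsAsFactors = FALSE)
      rest <- c(a[-seq_len(m)], b[-seq_len(m)])
      if (length(rest)) rbind(paired, ph[rest, , drop = FALSE]) else paired
    })
    out <- rbind(single, do.call(rbind, combined))
  } else {
    out <- single
  }
  rownames(out) <- NULL
  out
}

#' Filter the alignment hits of one query
#'
#' Three-stage retention: (1) drop hits below the identity or coverage
#' thresholds; (2) among survivors, drop hits whose score falls more
#' than `(1 - bitscore_fraction)` below the best score (the "within 5%
#' of the best match" rule, read fractionally); (3) if any survivor maps
#' to a reference with a complete taxonomic path
#' ([is_complete_path()]), drop survivors mapping to incomplete-path
#' references. Thresholds are inclusive.
#'
#' @param hits Hit data.frame, all rows sharing one `query_id`.
#' @param guide A [build_guide_tree()] object resolving `ref_id` to
#'   taxids.
#' @param min_identity Minimum percent identity (default 97).
#' @param min_coverage Minimum percent query coverage (default 70).
#' @param bitscore_fraction Fraction of the best score to retain
#'   (default 0.95).
#' @param uncultured_patterns Passed to [is_complete_path()].
#' @return The retained subset of `hits` with a `taxid` column appended;
#'   possibly zero rows.
#' @export
filter_hits <- function(hits, guide, min_identity = 97, min_coverage = 70,
                        bitscore_fraction = 0.95,
                        uncultured_patterns = c("uncultured",
                                                "environmental sample",
                                                "unidentified")) {
  if (nrow(hits) == 0L) return(cbind(hits, taxid = integer(0)))
  if (length(unique(hits$query_id)) != 1L)
    stop("filter_hits expects hits of a single query")
  taxid <- guide$ref_to_taxid[hits$ref_id]
  if (anyNA(taxid))
    stop("hit(s) to reference id(s) absent from the guide tree: ",
         paste(unique(hits$ref_id[is.na(taxid)]), collapse = ", "))
  hits$taxid <- unname(taxid)

  s1 <- hits[hits$identity_pct >= min_identity &
               hits$query_coverage_pct >= min_coverage, , drop = FALSE]
  if (nrow(s1) == 0L) return(s1)
  best <- max(s1$bitscore)
  s2 <- s1[s1$bitscore >= bitscore_fraction * best - 1e-9, , drop = FALSE]
  complete <- vapply(s2$taxid, function(t)
    is_complete_path(guide$taxonomy, t, uncultured_patterns), logical(1))
  s3 <- if (any(complete)) s2[complete, , drop = FALSE] else s2
  rownames(s3) <- NULL
  s3
}

#' Build a match file from hits of many queries
#'
#' Applies [filter_hits()] per query and collects the retained
#' candidate taxa. Queries with no surviving hit are omitted (they
#' become unassigned downstream).
#'
#' @param hits Hit data.frame over any number of queries.
#' @param guide A [build_guide_tree()] object.
#' @param ... Passed to [filter_hits()].
#' @return An object of class `"match_file"`: named list, one element
#'   per retained query, each a data.frame with `ref_id`, `taxid`.
#' @export
build_match_file <- function(hits, guide, ...) {
  out <- list()
  for (q in unique(hits$query_id)) {
    kept <- filter_hits(hits[hits$query_id == q, , drop = FALSE], guide, ...)
    if (nrow(kept) > 0L)
      out[[q]] <- data.frame(ref_id = kept$ref_id, taxid = kept$taxid,
                             stringsAsFactors = FALSE)
  }
  structure(out, class = "match_file")
}

#' Write / read a match file
#'
#' TSV dialect: `query_id`, a tab, then the comma-separated retained
#' taxids; rows sorted by query id. Reading inverts writing.
#'
#' @param matches A `"match_file"` object (or named list of data.frames
#'   with a `taxid` column, or of integer vectors).
#' @param path File path.
#' @return `read_match_file` returns a `"match_file"` object whose
#'   elements are data.frames with `ref_id` (`NA` after a round trip)
#'   and `taxid`.
#' @export
write_match_file <- function(matches, path) {
  qs <- sort(names(matches))
  lines <- vapply(qs, function(q) {
    m <- matches[[q]]
    taxids <- if (is.data.frame(m)) m$taxid else m
    paste0(q, "\t", paste(taxids, collapse = ","))
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' @rdname write_match_file
#' @export
read_match_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L) stop("malformed match file line: ", ln)
    taxids <- as.integer(strsplit(f[2L], ",", fixed = TRUE)[[1L]])
    out[[f[1L]]] <- data.frame(ref_id = NA_character_, taxid = taxids,
                               stringsAsFactors = FALSE)
  }
  structure(out, class = "match_file")
}
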
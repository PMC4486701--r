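# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# window-by-window degenerate matcher, 0-based starts
oracle_iupac_match <- function(pattern, sequence, max_mismatches = 0L) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(sequence), "")[[1]]
  k <- length(p); n <- length(s)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    mm <- 0L
    for (j in seq_len(k))
      if (!(s[i + j - 1L] %in% IUPAC_ORACLE[[p[j]]])) mm <- mm + 1L
    if (mm <= max_mismatches) hits <- c(hits, i - 1L)
  }
  hits
}

# same leftmost-first non-nested pairing rule, written independently:
# forward sites ascending, nearest reverse site downstream of the primer,
# scan resumes past an emitted amplicon; both strands
oracle_extract_spans <- function(sequence, fwd, rev_primer, max_len) {
  one_strand <- function(seq) {
    f <- oracle_iupac_match(fwd, seq)
    rsite <- oracle_revcomp(rev_primer)
    r <- oracle_iupac_match(rsite, seq)
    lenF <- nchar(fwd); lenR <- nchar(rev_primer)
    spans <- list(); cur <- 0L
    for (fs in f) {
      if (fs < cur) next
      ok <- r[r >= fs + lenF & r + lenR - fs <= max_len]
      if (!length(ok)) next
      spans[[length(spans) + 1L]] <- c(fs, ok[1] + lenR)
      cur <- ok[1] + lenR
    }
    spans
  }
  L <- nchar(sequence)
  plus <- one_strand(sequence)
  minus <- lapply(one_strand(oracle_revcomp(sequence)),
                  function(sp) c(L - sp[2], L - sp[1]))
  list(plus = plus, minus = minus)
}

oracle_lca <- function(tax, ids) {
  paths <- lapply(ids, function(i) path_to_root(tax, i))
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(i) length(path_to_root(tax, i)), integer(1))
  common[which.max(depth)]
}

oracle_leaves_under <- function(tax, ref_to_taxid, node_id) {
  sum(vapply(unname(ref_to_taxid), function(t)
    node_id %in% path_to_root(tax, t), logical(1)))
}

# exhaustive all-shift overlap alignment of read1 vs revcomp(read2)
oracle_merge <- function(r1, r2, min_overlap, max_mismatch_ratio) {
  s1 <- strsplit(r1, "")[[1]]
  s2 <- strsplit(oracle_revcomp(r2), "")[[1]]
  n1 <- length(s1); n2 <- length(s2)
  best <- NULL
  for (o in seq_len(min(n1, n2))) {
    if (o < min_overlap) next
    mm <- sum(s1[(n1 - o + 1):n1] != s2[1:o])
    ratio <- mm / o
    if (is.null(best) || ratio < best$ratio - 1e-12 ||
        (abs(ratio - best$ratio) <= 1e-12 && o > best$o))
      best <- list(o = o, mm = mm, ratio = ratio)
  }
  if (is.null(best) || best$ratio > max_mismatch_ratio) return(NULL)
  paste(c(s1, s2[-(1:best$o)]), collapse = "")
}

# literal three-pass transcription of the hit retention rules
oracle_filter_hits <- function(hits, complete_by_ref,
                               min_identity = 97, min_coverage = 70,
                               bitscore_fraction = 0.95) {
  s1 <- hits[hits$identity_pct >= min_identity &
               hits$query_coverage_pct >= min_coverage, , drop = FALSE]
  if (nrow(s1) == 0) return(s1)
  s2 <- s1[s1$bitscore >= bitscore_fraction * max(s1$bitscore) - 1e-9, ,
           drop = FALSE]
  comp <- complete_by_ref[s2$ref_id]
  if (any(comp)) s2[comp, , drop = FALSE] else s2
}

# exhaustive minimisation of q*FN + (1-q)*FP over every taxonomy node,
# with subtree membership decided by root paths
oracle_assign <- function(match_taxids, guide, q) {
  tax <- guide$taxonomy
  match_taxids <- unique(as.integer(match_taxids))
  in_subtree <- function(node, taxid) node %in% path_to_root(tax, taxid)
  refs_at <- table(factor(as.character(guide$ref_to_taxid),
                          levels = as.character(tax$nodes$node_id)))
  weight <- function(t) max(1L, as.integer(refs_at[as.character(t)]))
  total <- sum(vapply(match_taxids, weight, integer(1)))
  best <- NULL
  for (n in tax$nodes$node_id) {
    under <- match_taxids[vapply(match_taxids, function(t)
      in_subtree(n, t), logical(1))]
    mu_fn <- sum(vapply(under, weight, integer(1)))
    matched_real <- sum(vapply(under, function(t)
      as.integer(refs_at[as.character(t)]), integer(1)))
    refs_under <- sum(vapply(unname(guide$ref_to_taxid), function(t)
      in_subtree(n, t), logical(1)))
    fn <- total - mu_fn
    fp <- refs_under - matched_real
    score <- q * fn + (1 - q) * fp
    depth <- length(path_to_root(tax, n))
    cand <- list(node = n, score = score, depth = depth)
    if (is.null(best) || score < best$score - 1e-9 ||
        (abs(score - best$score) <= 1e-9 &&
           (depth > best$depth ||
              (depth == best$depth && n < best$node))))
      best <- cand
  }
  best$node
}

# non-empty random subset of a guide tree's reference taxids
resample_taxids <- function(guide) {
  pool <- unname(guide$ref_to_taxid)
  pool[sample.int(length(pool), sample.int(length(pool), 1L))]
}

# random rooted tree on n nodes (node 1 is the root); ranks optional
random_tree_tax <- function(n, ranked = FALSE) {
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  rank <- rep("no rank", n)
  if (ranked) rank <- sample(c(canonical_ranks(), "no rank"), n, replace = TRUE)
  rank[1] <- "kingdom"
  taxonomy(data.frame(node_id = 1:n, parent_id = parent, rank = rank,
                      name = paste0("n", 1:n)))
}

# a single complete 7-rank chain taxonomy, ids 1..7, with optional extras
chain_tax <- function(names = NULL) {
  rk <- canonical_ranks()
  nm <- if (is.null(names)) paste0(rk, "_1") else names
  taxonomy(data.frame(node_id = 1:7, parent_id = c(1L, 1:6),
                      rank = rk, name = nm))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
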
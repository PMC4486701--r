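#' Degenerate primer pairs
#'
#' Constructs a primer pair in PCR convention: both primers written
#' 5'->3', the reverse primer on the opposite strand. IUPAC ambiguity
#' codes are allowed; each primer must be at least 10 nt.
#'
#' @param forward,reverse IUPAC nucleotide strings.
#' @return An object of class `"primer_pair"`.
#' @export
primer_pair <- function(forward, reverse) {
  chk <- function(p, what) {
    p <- toupper(p)
    ch <- strsplit(p, "", fixed = TRUE)[[1L]]
    bad <- setdiff(ch, names(IUPAC_SETS))
    if (length(bad))
      stop("non-IUPAC character(s) in ", what, " primer: ",
           paste(unique(bad), collapse = ", "))
    if (nchar(p) < 10L) stop(what, " primer shorter than 10 nt")
    p
  }
  structure(list(forward = chk(forward, "forward"),
                 reverse = chk(reverse, "reverse")),
            class = "primer_pair")
}

#' Built-in universal primer sets
#'
#' The two universal primer pairs used for bacterial 16S V5-V6 and
#' fungal ITS1 amplification.
#'
#' @param marker `"v5v6"` or `"its1"`.
#' @return A [primer_pair()].
#' @export
primer_set <- function(marker = c("v5v6", "its1")) {
  marker <- match.arg(marker)
  switch(marker,
         v5v6 = primer_pair("TTAGATACCCYGGTAGTCC", "ACGAGCTGACGACARCCATG"),
         its1 = primer_pair("GAACCWGCGGARGGATCA", "GCTGCGTTCTTCATCGATGC"))
}

#' Find degenerate-pattern matches in a DNA sequence
#'
#' All 0-based start positions where an IUPAC pattern matches, allowing
#' up to `max_mismatches` mismatching columns. Ambiguity codes in the
#' pattern match any base of their set; the subject is read literally.
#'
#' @param pattern IUPAC nucleotide string.
#' @param sequence Plain DNA string.
#' @param max_mismatches Non-negative integer (default 0: exact
#'   degenerate matching, the in-silico PCR default).
#' @return Sorted integer vector of 0-based start positions.
#' @export
iupac_match_positions <- function(pattern, sequence, max_mismatches = 0L) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("empty pattern")
  bad <- setdiff(strsplit(pattern, "", fixed = TRUE)[[1L]], names(IUPAC_SETS))
  if (length(bad))
    stop("non-IUPAC character(s) in pattern: ", paste(unique(bad), collapse = ", "))
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(sequence),
                                max.mismatch = max_mismatches,
                                with.indels = FALSE,
                                fixed = c(pattern = FALSE, subject = TRUE))
  s <- BiocGenerics::start(m)
  e <- BiocGenerics::end(m)
  keep <- s >= 1L & e <= nchar(sequence)
  sort(s[keep]) - 1L
}

#' Extract amplicons by in-silico PCR
#'
#' Scans both strands of a source sequence for forward-primer sites and,
#' for each, the nearest downstream reverse-primer site (the reverse
#' complement of the reverse primer on the scanned strand). Pairing is
#' leftmost-first and non-nested: after an amplicon is emitted the scan
#' resumes past its end. Amplicons include both primer sites unless
#' `trim_primers` is set. Minus-strand amplicons are reported
#' reverse-complemented to amplicon plus strand.
#'
#' @param source_id Identifier for the source sequence.
#' @param sequence Plus-strand DNA string.
#' @param taxid Taxon id the source is annotated with.
#' @param primers A [primer_pair()].
#' @param max_amplicon_len Maximum span, primers included (default 2000).
#' @param max_mismatches Mismatches allowed per primer site (default 0).
#' @param trim_primers Drop the primer sequences from the amplicon.
#' @return Data.frame with columns `amplicon_id`, `source_id`, `taxid`,
#'   `start`, `end` (0-based half-open on the source plus strand),
#'   `strand`, `sequence`.
#' @export
extract_amplicons <- function(source_id, sequence, taxid, primers,
                              max_amplicon_len = 2000L,
                              max_mismatches = 0L,
                              trim_primers = FALSE) {
  stopifnot(inherits(primers, "primer_pair"))
  sequence <- toupper(sequence)
  lenF <- nchar(primers$forward)
  lenR <- nchar(primers$reverse)
  rsite <- revcomp(primers$reverse)

  scan_strand <- function(seq) {
    f <- iupac_match_positions(primers$forward, seq, max_mismatches)
    r <- iupac_match_positions(rsite, seq, max_mismatches)
    out <- list()
    cursor <- 0L
    for (fs in f) {
      if (fs < cursor) next
      cand <- r[r >= fs + lenF & (r + lenR - fs) <= max_amplicon_len]
      if (length(cand) == 0L) next
      rs <- cand[1L]
      out[[length(out) + 1L]] <- c(start = fs, end = rs + lenR)
      cursor <- rs + lenR
    }
    out
  }

  L <- nchar(sequence)
  plus <- scan_strand(sequence)
  minus <- scan_strand(revcomp(sequence))
  rows <- list()
  add <- function(s, e, strand) {
    amp <- if (strand == "+") substr(sequence, s + 1L, e)
           else revcomp(substr(sequence, s + 1L, e))
    if (trim_primers) amp <- substr(amp, lenF + 1L, nchar(amp) - lenR)
    rows[[length(rows) + 1L]] <<- data.frame(
      amplicon_id = paste0(source_id, ":", s, "-", e, strand),
      source_id = source_id, taxid = as.integer(taxid),
      start = as.integer(s), end = as.integer(e), strand = strand,
      sequence = amp, stringsAsFactors = FALSE)
  }
  for (h in plus) add(h[["start"]], h[["end"]], "+")
  for (h in minus) add(L - h[["end"]], L - h[["start"]], "-")
  if (length(rows) == 0L)
    return(data.frame(amplicon_id = character(0), source_id = character(0),
                      taxid = integer(0), start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Sample a community with forced co-generic species
#'
#' Draws `n_species` distinct species from a pool while forcing at least
#' `min_cogeneric` of them to belong to genera contributing two or more
#' selected species, emulating benchmark communities built to stress
#' discrimination between closely related taxa.
#'
#' @param species_pool Data.frame with columns `taxid`, `genus_id`.
#' @param n_species Number of species to draw.
#' @param min_cogeneric Minimum number of co-generic species among the
#'   draw (0 for a plain uniform sample).
#' @param seed Optional integer seed; the draw is deterministic under it.
#' @return Integer vector of `n_species` distinct taxids.
#' @export
sample_community <- function(species_pool, n_species, min_cogeneric = 0L,
                             seed = NULL) {
  stopifnot(all(c("taxid", "genus_id") %in% names(species_pool)))
  pool <- species_pool[!duplicated(species_pool$taxid), ]
  if (n_species > nrow(pool))
    stop("n_species exceeds pool size (", nrow(pool), ")")
  if (min_cogeneric > n_species)
    stop("min_cogeneric cannot exceed n_species")
  # feasibility: with k multi-species genera (sizes sorted descending) any
  # co-generic total T with 2k <= T <= min(n_species, sum of the k sizes)
  # is achievable, so the maximum is the best such cap over k
  sizes <- sort(table(pool$genus_id), decreasing = TRUE)
  sizes <- as.integer(sizes[sizes >= 2L])
  max_cog <- 0L
  if (length(sizes)) {
    cum <- cumsum(sizes)
    for (k in seq_along(sizes)) {
      cap <- min(n_species, cum[k])
      if (cap >= 2L * k) max_cog <- max(max_cog, cap)
    }
  }
  if (min_cogeneric > max_cog)
    stop("infeasible co-generic constraint: at most ", max_cog,
         " co-generic species achievable with this pool and n_species")

  multi_sizes <- table(pool$genus_id)
  multi_g <- names(multi_sizes[multi_sizes >= 2L])
  with_seed(seed, {
    chosen <- integer(0)
    if (min_cogeneric > 0L) {
      used <- character(0)
      # first two species per genus, spreading over shuffled genera
      for (g in resample(multi_g)) {
        if (length(chosen) >= min_cogeneric ||
            n_species - length(chosen) < 2L) break
        members <- pool$taxid[pool$genus_id == g]
        chosen <- c(chosen, resample(members, 2L))
        used <- c(used, g)
      }
      # then top up from spare capacity of genera already in the draw
      while (length(chosen) < min_cogeneric &&
             length(chosen) < n_species) {
        spare <- pool$taxid[pool$genus_id %in% used &
                              !(pool$taxid %in% chosen)]
        if (length(spare) == 0L)
          stop("infeasible co-generic constraint under budget")
        chosen <- c(chosen, resample(spare, 1L))
      }
      if (length(chosen) < min_cogeneric)
        stop("infeasible co-generic constraint under budget")
    }
    rest <- setdiff(pool$taxid, chosen)
    fill <- n_species - length(chosen)
    if (fill > 0L) chosen <- c(chosen, resample(rest, fill))
    as.integer(chosen)
  })
}

#' Simulate truth-labeled paired-end reads from one amplicon
#'
#' MiSeq-like 250x2 layout: read 1 is the first `read_len` bases of the
#' amplicon and read 2 the reverse complement of its last `read_len`
#' bases (reads from amplicons shorter than `read_len` are emitted at
#' amplicon length, mirroring adapter read-through after trimming).
#' Errors are i.i.d. substitutions to a uniformly random different base;
#' Phred scores are drawn from a truncated normal clipped to [2, 41].
#'
#' @param amplicon One-row data.frame (or list) with `sequence`,
#'   `amplicon_id`, `taxid`.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (default 250).
#' @param substitution_rate Per-base substitution probability (default
#'   0.001).
#' @param qual_model Numeric `c(mean, sd)` of the Phred distribution.
#' @param seed Optional integer seed.
#' @return Data.frame with `pair_id`, `read1_seq`, `read2_seq`,
#'   `read1_quals`, `read2_quals` (Phred+33 strings), `true_taxid`,
#'   `amplicon_id`.
#' @export
simulate_paired_reads <- function(amplicon, n_pairs, read_len = 250L,
                                  substitution_rate = 0.001,
                                  qual_model = c(35, 4), seed = NULL) {
  if (read_len < 1L) stop("read_len must be >= 1")
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("substitution_rate must be in [0, 1)")
  amp <- toupper(amplicon$sequence[[1L]])
  aid <- amplicon$amplicon_id[[1L]]
  taxid <- as.integer(amplicon$taxid[[1L]])
  L <- nchar(amp)
  rl <- min(read_len, L)
  r1_t <- substr(amp, 1L, rl)
  r2_t <- revcomp(substr(amp, L - rl + 1L, L))
  with_seed(seed, {
    draw_quals <- function() {
      q <- round(rnorm(rl, qual_model[1L], qual_model[2L]))
      phred_to_string(pmin(pmax(q, 2L), 41L))
    }
    r1 <- character(n_pairs); r2 <- character(n_pairs)
    q1 <- character(n_pairs); q2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      r1[i] <- mutate_seq(r1_t, substitution_rate)
      r2[i] <- mutate_seq(r2_t, substitution_rate)
      q1[i] <- draw_quals(); q2[i] <- draw_quals()
    }
    data.frame(pair_id = paste0(aid, "/", seq_len(n_pairs)),
               read1_seq = r1, read2_seq = r2,
               read1_quals = q1, read2_quals = q2,
               true_taxid = taxid, amplicon_id = aid,
               stringsAsFactors = FALSE)
  })
}

#' Plan a multi-species read simulation
#'
#' Per-species pair counts and the implied dataset size, before any
#' sequence is generated. With the benchmark defaults (102 species at
#' 5,000 pairs each) the total is 510,000 pairs.
#'
#' @param n_species Number of community species.
#' @param pairs_per_species Read pairs simulated per species (default
#'   5000).
#' @return Data.frame with `species_index` and `n_pairs`; the total is in
#'   attribute `"total_pairs"`.
#' @export
readset_plan <- function(n_species, pairs_per_species = 5000L) {
  plan <- data.frame(species_index = seq_len(n_species),
                     n_pairs = rep(as.integer(pairs_per_species), n_species))
  attr(plan, "total_pairs") <- as.integer(n_species) * as.integer(pairs_per_species)
  plan
}

#' Simulate a synthetic ranked taxonomy
#'
#' Generates a complete seven-rank taxonomy (one kingdom at the root)
#' with the requested number of taxa per rank; species are spread over
#' genera as evenly as possible so every genus is populated and
#' co-generic species exist whenever `n_species > n_genera`.
#'
#' @param n_species,n_genera,n_families,n_orders,n_classes,n_phyla
#'   Taxon counts per rank.
#' @param kingdom_name Name of the root kingdom.
#' @param seed Optional integer seed (controls the random attachment of
#'   child taxa to parents).
#' @return A [taxonomy()] object.
#' @export
simulate_taxonomy <- function(n_species = 30L, n_genera = 10L,
                              n_families = 5L, n_orders = 3L,
                              n_classes = 2L, n_phyla = 2L,
                              kingdom_name = "Bacteria", seed = NULL) {
  counts <- c(n_phyla, n_classes, n_orders, n_families, n_genera, n_species)
  if (any(diff(c(1L, counts)) < 0L))
    stop("taxon counts must be non-decreasing from kingdom to species")
  with_seed(seed, {
    ranks <- canonical_ranks()
    next_id <- 1L
    rows <- data.frame(node_id = 1L, parent_id = 1L, rank = "kingdom",
                       name = kingdom_name, stringsAsFactors = FALSE)
    parents <- 1L
    for (k in seq_along(counts)) {
      n <- counts[k]
      ids <- next_id + seq_len(n)
      # every parent gets at least one child; leftovers attach at random
      par <- c(parents[seq_len(min(length(parents), n))],
               resample(parents, n - min(length(parents), n), replace = TRUE))
      rows <- rbind(rows, data.frame(
        node_id = ids, parent_id = par, rank = ranks[k + 1L],
        name = sprintf("%s_%02d", tools::toTitleCase(ranks[k + 1L]), seq_len(n)),
        stringsAsFactors = FALSE))
      parents <- ids
      next_id <- max(ids)
    }
    taxonomy(rows)
  })
}

#' Simulate a taxonomically annotated reference database
#'
#' Per species a fixed random seed marker sequence is drawn (length
#' uniform in `marker_len_range`) and each reference copy carries at
#' most `within_divergence` random substitutions, so within-species
#' identity exceeds between-species identity by construction (species
#' seeds are independent, hence ~25% pairwise identity between taxa).
#'
#' @param tax A [taxonomy()] object.
#' @param n_refs_per_species References per species (default 3).
#' @param marker_len_range Length range `c(min, max)` of the marker.
#' @param within_divergence Per-base substitution rate within species
#'   (default 0.005, i.e. at most ~1%).
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   output.
#' @return An object of class `"reference_db"`: list with `sequences`
#'   (named character), `ref_to_taxid` (named integer) and
#'   `species_seed` (named by taxid; the per-species core sequence).
#' @export
simulate_reference_db <- function(tax, n_refs_per_species = 3L,
                                  marker_len_range = c(270L, 310L),
                                  within_divergence = 0.005,
                                  seed = NULL) {
  sp <- tax$nodes$node_id[tax$nodes$rank == "species"]
  if (length(sp) == 0L) stop("taxonomy has no species nodes")
  with_seed(seed, {
    seqs <- character(0); map <- integer(0)
    seed_seq <- character(length(sp)); names(seed_seq) <- sp
    for (s in sp) {
      len <- resample(seq(marker_len_range[1L], marker_len_range[2L]), 1L)
      core <- random_dna(len)
      seed_seq[as.character(s)] <- core
      for (i in seq_len(n_refs_per_species)) {
        rid <- sprintf("ref_%d_%d", s, i)
        seqs[rid] <- if (i == 1L) core else mutate_seq(core, within_divergence)
        map[rid] <- s
      }
    }
    structure(list(sequences = seqs, ref_to_taxid = map,
                   species_seed = seed_seq),
              class = "reference_db")
  })
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db:", length(x$sequences), "sequences,",
      length(unique(x$ref_to_taxid)), "taxa\n")
  invisible(x)
}

#' Write a reference database to FASTA plus mapping TSV
#'
#' @param db A [simulate_reference_db()] object (or any list with
#'   `sequences` and `ref_to_taxid`).
#' @param fasta_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_db <- function(db, fasta_path, map_path) {
  write_fasta(db$sequences, fasta_path)
  utils::write.table(data.frame(ref_id = names(db$ref_to_taxid),
                                taxid = unname(db$ref_to_taxid)),
                     map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, map_path))
}

#' Read a reference-sequence to taxid mapping
#'
#' @param path TSV with columns `ref_id`, `taxid`.
#' @return Named integer vector.
#' @export
read_ref_map <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.integer(m$taxid), m$ref_id)
}
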
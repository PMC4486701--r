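#' Align query sequences against a reference set with BLASTN
#'
#' Convenience wrapper used by the benchmark harness: writes the two
#' FASTA files, builds a nucleotide BLAST database and runs `blastn`
#' with a 13-column tabular output (`std` plus `qlen`), which is then
#' consumed through [parse_blast_tabular()]. Requires the `makeblastdb`
#' and `blastn` executables on the PATH; classification itself only
#' consumes aligner output, it never depends on this helper.
#'
#' @param query_seqs Named character vector of query sequences.
#' @param ref_seqs Named character vector of reference sequences.
#' @param task BLASTN task (default `"megablast"`).
#' @param max_target_seqs Hit list size per query (default 500).
#' @param work_dir Scratch directory (default a fresh tempdir).
#' @return Hit data.frame as returned by [parse_blast_tabular()].
#' @export
blast_align <- function(query_seqs, ref_seqs, task = "megablast",
                        max_target_seqs = 500L, work_dir = tempfile("blast")) {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("blastn/makeblastdb not found on PATH")
  if (length(query_seqs) == 0L) return(empty_hits())
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  qf <- file.path(work_dir, "query.fasta")
  rf <- file.path(work_dir, "ref.fasta")
  out <- file.path(work_dir, "hits.tsv")
  write_fasta(query_seqs, qf)
  write_fasta(ref_seqs, rf)
  st <- system2("makeblastdb", c("-in", rf, "-dbtype", "nucl"),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed")
  st <- system2("blastn",
                c("-task", task, "-query", qf, "-db", rf,
                  "-outfmt", shQuote("6 std qlen"),
                  "-max_target_seqs", max_target_seqs, "-out", out),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastn failed")
  parse_blast_tabular(out)
}

#' Instantiate a degenerate IUPAC pattern
#'
#' Replaces each ambiguity code by a random base from its set; used to
#' plant concrete primer sites in simulated source sequences.
#'
#' @param pattern IUPAC string.
#' @return Plain DNA string of the same length.
#' @export
realize_iupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, names(IUPAC_SETS))
  if (length(bad)) stop("non-IUPAC character(s): ", paste(bad, collapse = ", "))
  paste(vapply(ch, function(c) resample(IUPAC_SETS[[c]], 1L), character(1)),
        collapse = "")
}

#' Build the default synthetic benchmark fixture
#'
#' Emulates the benchmark-construction procedure: a complete seven-rank
#' taxonomy, a reference database with several copies per species, one
#' barcode amplicon per community species recovered by in-silico PCR
#' (the species' core marker flanked by realized universal primer
#' sites), and truth-labeled MiSeq-like paired reads simulated from
#' each amplicon.
#'
#' @param n_species,n_genera Community structure (defaults 30 species
#'   over 10 genera, so co-generic species are abundant).
#' @param pairs_per_species Read pairs per species (default 100).
#' @param substitution_rate Per-base read error rate (default 0,
#'   error-free).
#' @param marker `"v5v6"` (narrow ~300 nt amplicons) or `"its1"` (wide
#'   length distribution).
#' @param n_refs_per_species References per species (default 3).
#' @param read_len Read length (default 250).
#' @param seed Integer seed; the whole fixture is deterministic under
#'   it.
#' @return List with `tax`, `db`, `guide`, `primers`, `amplicons`
#'   (data.frame), `reads` (read-pair data.frame with `true_taxid`,
#'   `amplicon_id`), `truth` (data.frame `pair_id`, `taxid`,
#'   `amplicon_id`).
#' @export
benchmark_fixture <- function(n_species = 30L, n_genera = 10L,
                              pairs_per_species = 100L,
                              substitution_rate = 0,
                              marker = c("v5v6", "its1"),
                              n_refs_per_species = 3L,
                              read_len = 250L, seed = 1L) {
  marker <- match.arg(marker)
  len_range <- switch(marker, v5v6 = c(262L, 302L), its1 = c(120L, 480L))
  primers <- primer_set(marker)
  with_seed(seed, {
    tax <- simulate_taxonomy(n_species = n_species, n_genera = n_genera,
                             n_families = max(2L, n_genera %/% 2L),
                             n_orders = max(2L, n_genera %/% 3L),
                             n_classes = 2L, n_phyla = 2L)
    db <- simulate_reference_db(tax, n_refs_per_species, len_range)
    guide <- build_guide_tree(tax, db$ref_to_taxid)
    species <- as.integer(names(db$species_seed))
    amp <- list(); reads <- list()
    for (s in species) {
      src <- paste0(random_dna(25L), realize_iupac(primers$forward),
                    db$species_seed[as.character(s)],
                    revcomp(realize_iupac(primers$reverse)), random_dna(25L))
      a <- extract_amplicons(paste0("src_", s), src, s, primers)
      if (nrow(a) == 0L) stop("in-silico PCR recovered no amplicon for ", s)
      a <- a[1L, , drop = FALSE]
      amp[[length(amp) + 1L]] <- a
      reads[[length(reads) + 1L]] <-
        simulate_paired_reads(a, pairs_per_species, read_len,
                              substitution_rate)
    }
    amplicons <- do.call(rbind, amp)
    reads <- do.call(rbind, reads)
    truth <- data.frame(pair_id = reads$pair_id, taxid = reads$true_taxid,
                        amplicon_id = reads$amplicon_id,
                        stringsAsFactors = FALSE)
    list(tax = tax, db = db, guide = guide, primers = primers,
         amplicons = amplicons, reads = reads, truth = truth)
  })
}

#' Run the classification pipeline on a read set
#'
#' Read preparation (merge, trim, filter, dereplicate), alignment of
#' the dereplicated consensus sequences against the reference database
#' (BLASTN via [blast_align()]), hit filtering into a match file, and
#' taxonomic assignment. Per-query assignments are expanded back to
#' per-read assignments through the dereplication groups; pairs that
#' were dropped or left unmerged are reported unassigned.
#'
#' @param reads Read-pair data.frame.
#' @param db A reference database (list with `sequences`,
#'   `ref_to_taxid`).
#' @param tax A [taxonomy()] object.
#' @param q Assignment penalty weight (default 0.5).
#' @param min_identity,min_coverage,bitscore_fraction Hit-filter
#'   thresholds.
#' @param prep Optional precomputed [prep_reads()] result (reused
#'   across reference variants, e.g. in the depletion experiment).
#' @param ... Passed to [prep_reads()].
#' @return List with `prep`, `hits`, `matches`, `assignments`
#'   (per dereplicated query), `per_read` (per input pair: `query_id`,
#'   `node_id`, `assigned_rank`, `status`, `abundance` = 1), `profile`.
#' @export
run_classifier <- function(reads, db, tax, q = 0.5,
                           min_identity = 97, min_coverage = 70,
                           bitscore_fraction = 0.95, prep = NULL, ...) {
  guide <- build_guide_tree(tax, db$ref_to_taxid)
  if (is.null(prep)) prep <- prep_reads(reads, ...)
  derep <- prep$derep
  queries <- setNames(derep$entries$sequence, derep$entries$rep_id)
  hits <- blast_align(queries, db$sequences)
  matches <- build_match_file(hits, guide,
                              min_identity = min_identity,
                              min_coverage = min_coverage,
                              bitscore_fraction = bitscore_fraction)
  abund <- setNames(derep$entries$abundance, derep$entries$rep_id)
  assignments <- assign_all(derep$entries$rep_id, matches, guide, q, abund)

  # expand to per-read: members of each dereplication group inherit the
  # representative's call; unmerged/dropped pairs are unassigned
  rep_row <- match(derep$entries$rep_id, assignments$query_id)
  per_read <- list()
  for (i in seq_len(nrow(derep$entries))) {
    ids <- derep$members[[i]]
    a <- assignments[rep_row[i], ]
    per_read[[i]] <- data.frame(query_id = ids, node_id = a$node_id,
                                assigned_rank = a$assigned_rank,
                                status = a$status, abundance = 1L,
                                stringsAsFactors = FALSE)
  }
  covered <- unlist(derep$members, use.names = FALSE)
  missing <- setdiff(reads$pair_id, covered)
  if (length(missing))
    per_read[[length(per_read) + 1L]] <-
      data.frame(query_id = missing, node_id = NA_integer_,
                 assigned_rank = NA_character_, status = "unassigned",
                 abundance = 1L, stringsAsFactors = FALSE)
  per_read <- do.call(rbind, per_read)
  list(prep = prep, hits = hits, matches = matches,
       assignments = assignments, per_read = per_read,
       profile = summarize_profile(assignments, tax))
}

#' Reference-depletion experiment
#'
#' Removes all reference sequences of a randomly drawn fraction of the
#' genera present in the community, re-runs the classifier against the
#' depleted reference, and sorts every read whose true genus was
#' removed into exactly one of three buckets: `wrong` (assigned, call
#' not an ancestor-or-self of the true taxon, or an on-lineage call
#' below family rank, which overclaims a depleted genus),
#' `unassigned`, or `ancestor_family_or_higher` (call is a true
#' ancestor at family rank or above). The buckets partition the
#' removed-genus reads.
#'
#' @param db Reference database (list with `sequences`,
#'   `ref_to_taxid`).
#' @param tax A [taxonomy()] object.
#' @param reads Read-pair data.frame.
#' @param truth Truth table (data.frame `pair_id`, `taxid`).
#' @param fraction Fraction of community genera to remove, in (0, 1)
#'   (default 0.5).
#' @param seed Optional integer seed for the genus draw.
#' @param runner Function `(db_depleted) -> per-read assignment
#'   data.frame`; defaults to [run_classifier()] with `...` options.
#' @param prep Optional precomputed [prep_reads()] result forwarded to
#'   the default runner.
#' @param ... Passed to the default runner.
#' @return An object of class `"depletion_report"`: list with
#'   `removed_genera`, `n_removed_reads`, `counts` and `pct` (named:
#'   wrong, unassigned, ancestor_family_or_higher), and the per-read
#'   `outcomes` data.frame.
#' @export
depletion_experiment <- function(db, tax, reads, truth, fraction = 0.5,
                                 seed = NULL, runner = NULL, prep = NULL,
                                 ...) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be strictly inside (0, 1)")
  tv <- as_truth_vector(truth)
  genera <- unique(project_to_rank(tax, unname(tv), "genus"))
  genera <- genera[!is.na(genera)]
  if (length(genera) < 2L) stop("depletion needs at least 2 community genera")
  removed <- with_seed(seed, sort(resample(genera, round(fraction * length(genera)))))

  ref_genus <- project_to_rank(tax, unname(db$ref_to_taxid), "genus")
  keep_ref <- !(ref_genus %in% removed)
  db_dep <- list(sequences = db$sequences[keep_ref],
                 ref_to_taxid = db$ref_to_taxid[keep_ref])
  if (is.null(runner))
    runner <- function(dbx) run_classifier(reads, dbx, tax, prep = prep,
                                           ...)$per_read
  per_read <- runner(db_dep)

  read_genus <- project_to_rank(tax, unname(tv[per_read$query_id]), "genus")
  sel <- read_genus %in% removed
  pr <- per_read[sel, , drop = FALSE]
  true_tax <- unname(tv[pr$query_id])
  outcome <- character(nrow(pr))
  fam_idx <- match("family", canonical_ranks())
  for (i in seq_len(nrow(pr))) {
    if (pr$status[i] != "assigned") { outcome[i] <- "unassigned"; next }
    lineage <- path_to_root(tax, true_tax[i])
    if (!(pr$node_id[i] %in% lineage)) { outcome[i] <- "wrong"; next }
    rk <- nearest_ranked(tax, pr$node_id[i])
    ri <- match(rk, canonical_ranks())
    outcome[i] <- if (!is.na(ri) && ri <= fam_idx)
      "ancestor_family_or_higher" else "wrong"
  }
  counts <- c(wrong = sum(outcome == "wrong"),
              unassigned = sum(outcome == "unassigned"),
              ancestor_family_or_higher =
                sum(outcome == "ancestor_family_or_higher"))
  structure(list(removed_genera = removed,
                 n_removed_reads = nrow(pr),
                 counts = counts,
                 pct = if (nrow(pr)) 100 * counts / nrow(pr) else counts * NA,
                 outcomes = data.frame(query_id = pr$query_id,
                                       outcome = outcome,
                                       stringsAsFactors = FALSE)),
            class = "depletion_report")
}

#' @export
print.depletion_report <- function(x, ...) {
  cat("depletion_report:", length(x$removed_genera), "genera removed,",
      x$n_removed_reads, "orphaned reads\n")
  for (b in names(x$counts))
    cat(sprintf("  %-26s %6d (%.2f%%)\n", b, x$counts[b], x$pct[b]))
  invisible(x)
}
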
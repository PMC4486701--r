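test_that("degenerate matching follows the IUPAC table", {
  expect_equal(iupac_match_positions("AY", "ACG"), 0L)
  expect_equal(iupac_match_positions("NNN", "ACGT"), c(0L, 1L))
  expect_equal(iupac_match_positions("TTT", "ACGT"), integer(0))
  expect_error(iupac_match_positions("AXZ", "ACGT"), "non-IUPAC")
  # degenerate forward universal primer hits its realized site
  site <- "TTAGATACCCTGGTAGTCC"      # Y -> T
  seq <- paste0("GGGG", site, "AAAA")
  expect_equal(iupac_match_positions("TTAGATACCCYGGTAGTCC", seq), 4L)
})

test_that("degenerate matching equals window-enumeration oracle", {
  set.seed(11)
  pats <- c("ACGT", "RYSW", "NAN", "TTAGATACCCYGGTAGTCC", "GGRAA")
  for (i in 1:60) {
    pat <- sample(pats, 1)
    s <- random_dna_str(sample(30:120, 1))
    for (mm in 0:2)
      expect_equal(iupac_match_positions(pat, s, mm),
                   oracle_iupac_match(pat, s, mm),
                   info = paste(pat, s, mm))
  }
})

test_that("in-silico PCR recovers a constructed amplicon exactly", {
  pr <- primer_pair("ACGTACGTAC", "GGTTCCAAGG")
  insert <- paste(rep("T", 20), collapse = "")
  src <- paste0("AAAA", pr$forward, insert, revcomp(pr$reverse), "CCCC")
  amp <- extract_amplicons("s1", src, 42, pr)
  expect_equal(nrow(amp), 1L)
  plus <- amp[amp$strand == "+", ]
  expect_equal(nchar(plus$sequence), 10 + 20 + 10)
  expect_equal(plus$sequence, substr(src, plus$start + 1, plus$end))
  expect_equal(plus$taxid, 42L)

  # the same construct planted on the minus strand is reported
  # reverse-complemented back to amplicon plus strand
  src_m <- revcomp(src)
  amp_m <- extract_amplicons("s1m", src_m, 42, pr)
  expect_equal(nrow(amp_m), 1L)
  minus <- amp_m[amp_m$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$sequence,
               revcomp(substr(src_m, minus$start + 1, minus$end)))
  expect_equal(minus$sequence, plus$sequence)

  # forward site only: nothing
  none <- extract_amplicons("s2", paste0("AA", pr$forward, "TTTT"), 1, pr)
  expect_equal(nrow(none), 0L)

  # trim_primers drops both primer spans
  trimmed <- extract_amplicons("s1", src, 42, pr, trim_primers = TRUE)
  expect_equal(trimmed$sequence[trimmed$strand == "+"], insert)
})

test_that("amplicon extraction equals exhaustive pairing oracle on random sequences", {
  pr <- primer_pair("ACGTACGTAC", "GGTTCCAAGG")
  set.seed(23)
  for (rep in 1:10) {
    src <- random_dna_str(10000)
    # plant 3 site pairs at random non-overlapping offsets
    at <- sort(sample(seq(100, 9000, by = 400), 3))
    for (a in at) {
      substr(src, a, a + 9) <- pr$forward
      substr(src, a + 150, a + 159) <- revcomp(pr$reverse)
    }
    amp <- extract_amplicons("r", src, 1, pr, max_amplicon_len = 500)
    spans <- oracle_extract_spans(src, pr$forward, pr$reverse, 500)
    got_plus <- amp[amp$strand == "+", c("start", "end")]
    exp_plus <- do.call(rbind, spans$plus)
    expect_equal(nrow(got_plus), NROW(exp_plus))
    if (NROW(exp_plus))
      expect_equal(unname(as.matrix(got_plus)), unname(exp_plus))
    got_minus <- amp[amp$strand == "-", c("start", "end")]
    exp_minus <- do.call(rbind, spans$minus)
    expect_equal(nrow(got_minus), NROW(exp_minus))
    # coordinate/sequence invariant, strand adjusted
    for (k in seq_len(nrow(amp))) {
      sl <- substr(src, amp$start[k] + 1, amp$end[k])
      expect_equal(amp$sequence[k],
                   if (amp$strand[k] == "+") sl else revcomp(sl))
    }
  }
})

test_that("community sampling enforces the co-generic constraint", {
  set.seed(5)
  pool <- data.frame(taxid = 1:300,
                     genus_id = rep(1:75, each = 4))
  com <- sample_community(pool, 102, 58, seed = 9)
  expect_length(com, 102)
  expect_length(unique(com), 102)
  g <- pool$genus_id[match(com, pool$taxid)]
  cog <- sum(table(g)[table(g) >= 2])
  expect_gte(cog, 58)
  expect_identical(com, sample_community(pool, 102, 58, seed = 9))

  # plain uniform draw when the constraint is off
  u <- sample_community(pool, 10, 0, seed = 1)
  expect_length(unique(u), 10)

  # infeasible: 5 singleton genera cannot host co-generic pairs
  singles <- data.frame(taxid = 1:5, genus_id = 1:5)
  expect_error(sample_community(singles, 4, 2, seed = 1), "infeasible")
})

test_that("error-free read pairs are exact amplicon slices", {
  amp <- data.frame(amplicon_id = "a", taxid = 7L,
                    sequence = random_dna_str(300), stringsAsFactors = FALSE)
  rp <- simulate_paired_reads(amp, 3, read_len = 250,
                              substitution_rate = 0, seed = 2)
  expect_equal(nrow(rp), 3)
  expect_true(all(rp$read1_seq == substr(amp$sequence, 1, 250)))
  expect_true(all(rp$read2_seq == revcomp(substr(amp$sequence, 51, 300))))
  expect_true(all(nchar(rp$read1_quals) == 250))
  expect_true(all(rp$true_taxid == 7L))
  # short amplicon: reads at amplicon length, not padded
  short <- data.frame(amplicon_id = "b", taxid = 1L,
                      sequence = random_dna_str(180), stringsAsFactors = FALSE)
  rs <- simulate_paired_reads(short, 1, read_len = 250,
                              substitution_rate = 0, seed = 2)
  expect_equal(nchar(rs$read1_seq), 180)
  expect_equal(rs$read2_seq, revcomp(rs$read1_seq))
})

test_that("substitution rate is recovered within binomial error", {
  amp <- data.frame(amplicon_id = "a", taxid = 1L,
                    sequence = random_dna_str(400), stringsAsFactors = FALSE)
  n <- 2000L; rate <- 0.01
  rp <- simulate_paired_reads(amp, n, read_len = 250,
                              substitution_rate = rate, seed = 3)
  tmpl <- substr(amp$sequence, 1, 250)
  t_ch <- strsplit(tmpl, "")[[1]]
  mm <- vapply(rp$read1_seq, function(s)
    sum(strsplit(s, "")[[1]] != t_ch), integer(1), USE.NAMES = FALSE)
  phat <- sum(mm) / (n * 250)
  se <- sqrt(rate * (1 - rate) / (n * 250))
  expect_lt(abs(phat - rate), 3 * se)
  # Phred scores live in [2, 41]
  q <- string_to_phred(rp$read1_quals[1])
  expect_true(all(q >= 2 & q <= 41))
})

test_that("dataset sizing: benchmark defaults give 510,000 pairs", {
  plan <- readset_plan(102)
  expect_equal(attr(plan, "total_pairs"), 510000L)
  expect_equal(sum(plan$n_pairs), 510000L)
  expect_equal(attr(readset_plan(101), "total_pairs"), 505000L)
})

test_that("simulated taxonomy is complete and evenly populated", {
  tax <- simulate_taxonomy(seed = 4)
  expect_equal(sum(tax$nodes$rank == "species"), 30)
  expect_equal(sum(tax$nodes$rank == "genus"), 10)
  sp <- tax$nodes$node_id[tax$nodes$rank == "species"]
  for (s in sp) expect_true(is_complete_path(tax, s))
  g <- vapply(sp, function(s) rank_ancestor(tax, s, "genus"), integer(1))
  expect_equal(length(unique(g)), 10)   # every genus hosts species
})

test_that("reference db separates species and is reproducible", {
  tax <- simulate_taxonomy(n_species = 10, n_genera = 5, seed = 6)
  db1 <- simulate_reference_db(tax, n_refs_per_species = 2, seed = 8)
  db2 <- simulate_reference_db(tax, n_refs_per_species = 2, seed = 8)
  expect_identical(db1, db2)
  expect_equal(length(db1$sequences), 20)
  expect_equal(length(unique(db1$ref_to_taxid)), 10)

  ident <- function(a, b) {
    if (nchar(a) != nchar(b)) return(0)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  sp <- unique(db1$ref_to_taxid)
  within <- c(); between <- c()
  for (s in sp) {
    rs <- names(db1$ref_to_taxid)[db1$ref_to_taxid == s]
    within <- c(within, ident(db1$sequences[rs[1]], db1$sequences[rs[2]]))
  }
  pairs <- combn(sp, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- names(db1$ref_to_taxid)[db1$ref_to_taxid == pairs[1, k]][1]
    b <- names(db1$ref_to_taxid)[db1$ref_to_taxid == pairs[2, k]][1]
    between <- c(between, ident(db1$sequences[a], db1$sequences[b]))
  }
  expect_gt(min(within), max(between))
})

test_that("its1-like amplicon lengths vary far more than v5v6-like ones", {
  fx_v <- benchmark_fixture(n_species = 15, n_genera = 5,
                            pairs_per_species = 1, marker = "v5v6", seed = 12)
  fx_i <- benchmark_fixture(n_species = 15, n_genera = 5,
                            pairs_per_species = 1, marker = "its1", seed = 12)
  expect_gt(sd(nchar(fx_i$amplicons$sequence)),
            sd(nchar(fx_v$amplicons$sequence)))
})

test_that("fasta/fastq/truth io round-trips", {
  seqs <- setNames(c("ACGT", "GGCC"), c("a", "b"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)

  reads <- data.frame(pair_id = c("p1", "p2"),
                      read1_seq = c("ACGTA", "TTTTT"),
                      read2_seq = c("GGGGG", "CCCCC"),
                      read1_quals = c("IIIII", "!!!!!"),
                      read2_quals = c("ABCDE", "IIIII"),
                      stringsAsFactors = FALSE)
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  write_paired_fastq(reads, r1, r2)
  expect_equal(read_paired_fastq(r1, r2), reads)

  truth <- data.frame(pair_id = c("p1", "p2"), taxid = c(3L, 4L),
                      amplicon_id = c("a", "a"), stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_truth_tsv(truth, tf)
  expect_equal(read_truth_tsv(tf), truth)
})
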
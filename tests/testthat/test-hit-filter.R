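test_that("blast tabular parsing computes coverage and rejects ragged rows", {
  f <- tempfile()
  writeLines(c(paste("q1", "refC", "100.000", "250", "0", "0", "1", "250",
                     "1", "250", "1e-100", "460", "250", sep = "\t")), f)
  h <- parse_blast_tabular(f)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$query_coverage_pct, 100)
  expect_equal(h$bitscore, 460)

  writeLines(character(0), f)
  expect_equal(nrow(parse_blast_tabular(f)), 0)

  writeLines(c(paste(rep("x", 13), collapse = "\t"),
               paste(rep("x", 7), collapse = "\t")), f)
  expect_error(parse_blast_tabular(f), "line 2")
})

test_that("blast tabular write/parse round-trips bit-identically", {
  set.seed(41)
  n <- 50
  hits <- data.frame(query_id = paste0("q", sample(1:9, n, TRUE)),
                     ref_id = paste0("r", sample(1:9, n, TRUE)),
                     identity_pct = round(runif(n, 80, 100), 3),
                     query_coverage_pct = NA_real_,
                     bitscore = round(runif(n, 50, 500), 1),
                     qstart = sample(1:10, n, TRUE),
                     qend = sample(200:250, n, TRUE),
                     paired_flag = FALSE,
                     length = sample(100:250, n, TRUE),
                     mismatch = sample(0:5, n, TRUE),
                     gapopen = 0L,
                     sstart = 1L, send = 250L,
                     evalue = signif(10^-runif(n, 5, 100), 3),
                     qlen = 250L, stringsAsFactors = FALSE)
  f1 <- tempfile(); f2 <- tempfile()
  write_blast_tabular(hits, f1)
  parsed <- parse_blast_tabular(f1)
  write_blast_tabular(parsed, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(parsed$identity_pct, hits$identity_pct)
  expect_equal(parsed$bitscore, hits$bitscore)
})

test_that("sam parsing derives identity and coverage from CIGAR and NM", {
  f <- tempfile(fileext = ".sam")
  write_sam(list(sam_rec("r1", 0, 1, "250M", 250, nm = 0, as = 500),
                 sam_rec("r2", 0, 1, "200M50S", 250, nm = 2, as = 380),
                 sam_rec("r3", 4, 0, "*", 100)), f)  # unmapped
  h <- parse_sam(f)
  h <- h[order(h$query_id), ]
  expect_equal(nrow(h), 2)
  expect_equal(h$identity_pct[h$query_id == "r1"], 100)
  expect_equal(h$query_coverage_pct[h$query_id == "r1"], 100)
  expect_equal(h$identity_pct[h$query_id == "r2"], 99.0)
  expect_equal(h$query_coverage_pct[h$query_id == "r2"], 80.0)
  expect_equal(h$bitscore[h$query_id == "r2"], 380)
})

test_that("sam parsing falls back to MD and skips tagless records", {
  f <- tempfile(fileext = ".sam")
  # MD 95A54 -> one substitution over 150 aligned columns
  write_sam(list(sam_rec("m1", 0, 1, "150M", 150, md = "95A54"),
                 sam_rec("m2", 0, 1, "100M", 100)), f)
  expect_warning(h <- parse_sam(f), "skipped")
  expect_equal(nrow(h), 1)
  expect_equal(h$identity_pct, 100 * 149 / 150)
})

test_that("proper pairs collapse to one averaged record with summed score", {
  f <- tempfile(fileext = ".sam")
  write_sam(list(sam_rec("p1", 99, 1, "250M", 250, nm = 0, as = 500),
                 sam_rec("p1", 147, 300, "200M50S", 250, nm = 2, as = 380)), f)
  h <- parse_sam(f)
  expect_equal(nrow(h), 1)
  expect_true(h$paired_flag)
  expect_equal(h$identity_pct, (100 + 99) / 2)
  expect_equal(h$query_coverage_pct, (100 + 80) / 2)
  expect_equal(h$bitscore, 500 + 380)
})

test_that("staged filtering applies thresholds, 5% rule, then completeness", {
  guide <- make_filter_guide()
  base <- function(ref, id, cov, bs)
    data.frame(query_id = "q", ref_id = ref, identity_pct = id,
               query_coverage_pct = cov, bitscore = bs, qstart = 1L,
               qend = 250L, paired_flag = FALSE, stringsAsFactors = FALSE)

  # identity below 97 dies in stage 1; 97.0 exactly survives
  expect_equal(nrow(filter_hits(base("refC", 96.9, 100, 200), guide)), 0)
  expect_equal(nrow(filter_hits(base("refC", 97, 100, 200), guide)), 1)
  expect_equal(nrow(filter_hits(base("refC", 100, 69.9, 200), guide)), 0)
  expect_equal(nrow(filter_hits(base("refC", 100, 70, 200), guide)), 1)

  # 5% bitscore rule: 190 = 0.95 * 200 stays, 189 goes
  h <- rbind(base("refC", 100, 100, 200), base("refC", 100, 100, 190),
             base("refC", 100, 100, 189))
  kept <- filter_hits(h, guide)
  expect_equal(sort(kept$bitscore), c(190, 200))

  # completeness stage: complete-path ref within 5% of an uncultured best
  h2 <- rbind(base("refU", 100, 100, 300), base("refC", 100, 100, 290))
  kept2 <- filter_hits(h2, guide)
  expect_equal(kept2$ref_id, "refC")
  expect_equal(kept2$taxid, 7L)

  # no complete-path survivor: incomplete ones are kept
  h3 <- rbind(base("refU", 100, 100, 300), base("refI", 100, 100, 295))
  expect_equal(sort(filter_hits(h3, guide)$ref_id), c("refI", "refU"))

  # unknown reference id is a hard error
  expect_error(filter_hits(base("refX", 100, 100, 100), guide), "refX")
})

test_that("filtering equals the three-pass reference on random hit tables", {
  guide <- make_filter_guide()
  comp <- complete_by_ref_for(guide)
  set.seed(43)
  for (i in 1:500) {
    h <- random_hit_table()
    got <- filter_hits(h, guide)
    want <- oracle_filter_hits(h, comp)
    expect_equal(got$ref_id, want$ref_id, info = paste("table", i))
    expect_equal(got$bitscore, want$bitscore)
    # retained hits satisfy all numeric rules
    if (nrow(got)) {
      expect_true(all(got$identity_pct >= 97))
      expect_true(all(got$query_coverage_pct >= 70))
      expect_true(all(got$bitscore >= 0.95 * max(got$bitscore) - 1e-9))
    }
  }
})

test_that("raising min_identity shrinks the threshold-stage survivor pool", {
  # note the *composed* filter is not monotone in min_identity: removing
  # the best-scoring hit lowers the bitscore bar B and can let extra
  # survivors through the 5% rule; monotonicity holds for stage 1, and
  # every final survivor passes its own thresholds
  guide <- make_filter_guide()
  stage1 <- function(h, mi) h[h$identity_pct >= mi &
                                h$query_coverage_pct >= 70, , drop = FALSE]
  set.seed(44)
  for (i in 1:100) {
    h <- random_hit_table()
    expect_lte(nrow(stage1(h, 99)), nrow(stage1(h, 95)))
    for (mi in c(95, 99)) {
      kept <- filter_hits(h, guide, min_identity = mi)
      expect_true(all(kept$ref_id %in% stage1(h, mi)$ref_id) || nrow(kept) == 0)
      expect_true(all(kept$identity_pct >= mi))
    }
  }
})

test_that("match files round-trip through the TSV dialect", {
  m <- structure(list(q1 = data.frame(ref_id = "r1", taxid = 7L),
                      q2 = data.frame(ref_id = c("r2", "r3"),
                                      taxid = c(8L, 10L))),
                 class = "match_file")
  f <- tempfile()
  write_match_file(m, f)
  expect_equal(readLines(f), c("q1\t7", "q2\t8,10"))
  back <- read_match_file(f)
  expect_equal(names(back), c("q1", "q2"))
  expect_equal(back$q2$taxid, c(8L, 10L))

  # empty match file
  write_match_file(structure(list(), class = "match_file"), f)
  expect_equal(length(readLines(f)), 0)
  expect_equal(length(read_match_file(f)), 0)

  set.seed(45)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    mm <- setNames(lapply(seq_len(n), function(j)
      sort(sample(1:1000, sample(1:6, 1)))), paste0("q", sample(1e6, n)))
    write_match_file(mm, f)
    back <- read_match_file(f)
    expect_equal(names(back), sort(names(mm)))
    for (q in names(mm)) expect_equal(back[[q]]$taxid, mm[[q]])
  }
})
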
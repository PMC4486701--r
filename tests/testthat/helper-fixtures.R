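# guide tree with one clean full-lineage species (ref "refC"), one
# "uncultured" species (ref "refU"), and one lineage missing its family
# rank (ref "refI"); used by the hit-filter tests
make_filter_guide <- function() {
  rk <- canonical_ranks()
  rows <- data.frame(node_id = 1:7, parent_id = c(1L, 1:6), rank = rk,
                     name = paste0(rk, "_clean"), stringsAsFactors = FALSE)
  rows <- rbind(rows,
                data.frame(node_id = 8L, parent_id = 6L, rank = "species",
                           name = "uncultured bacterium"),
                # genus 9 hangs straight off the order: family rank absent
                data.frame(node_id = 9L, parent_id = 4L, rank = "genus",
                           name = "orphan genus"),
                data.frame(node_id = 10L, parent_id = 9L, rank = "species",
                           name = "orphan species"))
  tax <- taxonomy(rows)
  build_guide_tree(tax, c(refC = 7L, refU = 8L, refI = 10L))
}

complete_by_ref_for <- function(guide) {
  vapply(guide$ref_to_taxid, function(t)
    is_complete_path(guide$taxonomy, t), logical(1))
}

# random single-query hit table exercising the filter thresholds,
# including exact boundary values
random_hit_table <- function(query = "q", refs = c("refC", "refU", "refI"),
                             n = NULL) {
  if (is.null(n)) n <- sample(1:8, 1)
  data.frame(query_id = query,
             ref_id = sample(refs, n, replace = TRUE),
             identity_pct = sample(c(97, 96.9, 70,
                                     round(runif(4, 90, 100), 2)), n, TRUE),
             query_coverage_pct = sample(c(70, 69.9, 100,
                                           round(runif(4, 40, 100), 1)), n, TRUE),
             bitscore = sample(c(200, 190, 189, round(runif(4, 50, 400), 1)),
                               n, TRUE),
             qstart = 1L, qend = 250L, paired_flag = FALSE,
             stringsAsFactors = FALSE)
}

# two genera under one kingdom; the worked two-taxon evaluation example
# (genus A: 10 reads, 8 called A, 2 called B; genus B: 5 reads, all B)
ab_fixture <- function() {
  tax <- taxonomy(data.frame(node_id = 1:3, parent_id = c(1, 1, 1),
                             rank = c("kingdom", "genus", "genus"),
                             name = c("K", "A", "B")))
  ids <- paste0("r", 1:15)
  truth <- setNames(c(rep(2L, 10), rep(3L, 5)), ids)
  calls <- c(rep(2L, 8), rep(3L, 2), rep(3L, 5))
  a <- data.frame(query_id = ids, node_id = calls,
                  assigned_rank = "genus", status = "assigned",
                  abundance = 1L, stringsAsFactors = FALSE)
  list(tax = tax, truth = truth, assignments = a)
}

# minimal valid SAM text; records are character vectors of fields
write_sam <- function(records, path, ref = "refA", ref_len = 2000L) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", ref, "\tLN:", ref_len),
               vapply(records, paste, "", collapse = "\t")), path)
  path
}

sam_rec <- function(qname, flag, pos, cigar, seqlen, nm = NULL, as = NULL,
                    md = NULL, ref = "refA") {
  f <- c(qname, flag, ref, pos, "60", cigar, "*", "0", "0",
         strrep("A", seqlen), strrep("I", seqlen))
  if (!is.null(nm)) f <- c(f, paste0("NM:i:", nm))
  if (!is.null(md)) f <- c(f, paste0("MD:Z:", md))
  if (!is.null(as)) f <- c(f, paste0("AS:i:", as))
  f
}
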
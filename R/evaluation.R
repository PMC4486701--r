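as_truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    idcol <- intersect(c("query_id", "pair_id"), names(truth))[1L]
    if (is.na(idcol) || !"taxid" %in% names(truth))
      stop("truth table needs a query_id/pair_id column and a taxid column")
    return(setNames(as.integer(truth$taxid), truth[[idcol]]))
  }
  if (is.null(names(truth))) stop("truth vector must be named by query id")
  setNames(as.integer(truth), names(truth))
}

# project truth and calls of every read to `rank`; reads without truth at
# that rank are not evaluable and are dropped
projected_pairs <- function(assignments, truth, tax, rank) {
  tv <- as_truth_vector(truth)
  t_id <- tv[assignments$query_id]
  if (anyNA(t_id))
    stop("truth missing for ", sum(is.na(t_id)), " read(s)")
  t_proj <- project_to_rank(tax, unname(t_id), rank)
  call <- ifelse(assignments$status == "assigned", assignments$node_id,
                 NA_integer_)
  c_proj <- project_to_rank(tax, call, rank)
  keep <- !is.na(t_proj)
  data.frame(truth = t_proj[keep], call = c_proj[keep],
             w = assignments$abundance[keep])
}

#' Per-taxon confusion counts at a rank
#'
#' Each read's true taxon and call are projected to `rank`; calls above
#' the rank (or absent) project to `NA` and count against their true
#' taxon's false negatives. For each taxon `i`: `TP_i` reads with truth
#' and call `i`; `FN_i` reads with truth `i` and call not `i`; `FP_i`
#' reads with truth `j != i` but call `i`; `TN_i` reads with truth
#' `j != i` whose call equals their own truth `j`.
#'
#' @param assignments Per-read data.frame from [assign_all()] (or the
#'   expanded per-read table of the benchmark harness).
#' @param truth Named integer vector (query id -> true taxid) or a
#'   data.frame with `query_id`/`pair_id` and `taxid`.
#' @param tax A [taxonomy()] object.
#' @param rank A canonical rank.
#' @return Data.frame with `taxon`, `TP`, `FN`, `FP`, `TN`, `in_truth`.
#' @export
confusion_at_rank <- function(assignments, truth, tax, rank) {
  pp <- projected_pairs(assignments, truth, tax, rank)
  taxa <- sort(unique(c(pp$truth, pp$call[!is.na(pp$call)])))
  own <- !is.na(pp$call) & pp$call == pp$truth
  out <- lapply(taxa, function(i) {
    is_t <- pp$truth == i
    is_c <- !is.na(pp$call) & pp$call == i
    data.frame(taxon = i,
               TP = sum(pp$w[is_t & is_c]),
               FN = sum(pp$w[is_t & !is_c]),
               FP = sum(pp$w[!is_t & is_c]),
               TN = sum(pp$w[!is_t & own]),
               in_truth = any(is_t))
  })
  do.call(rbind, out)
}

#' Macro-averaged rates from confusion counts
#'
#' Per-taxon rates (in percent): `TPR = 100 TP / (TP + FN)`,
#' `TNR = 100 TN / (TN + FP)`, `FPR = 100 FP / (TN + FP)`,
#' `FNR = 100 FN / (TP + FN)`; the rank-level value is the unweighted
#' mean over the taxa for which the rate's denominator is positive
#' (call-only taxa thus contribute FP but are excluded from the
#' TPR/FNR means). A rate with no evaluable taxon is `NA` (undefined),
#' not zero.
#'
#' @param counts Data.frame from [confusion_at_rank()].
#' @return One-row data.frame with `TPR`, `TNR`, `FPR`, `FNR`,
#'   `n_taxa`.
#' @export
rank_metrics <- function(counts) {
  if (nrow(counts) == 0L || !any(counts$TP + counts$FN > 0))
    stop("no evaluable taxa: every taxon has TP + FN == 0")
  pos <- counts$TP + counts$FN
  neg <- counts$TN + counts$FP
  tpr <- ifelse(pos > 0, 100 * counts$TP / pos, NA_real_)
  fnr <- ifelse(pos > 0, 100 * counts$FN / pos, NA_real_)
  tnr <- ifelse(neg > 0, 100 * counts$TN / neg, NA_real_)
  fpr <- ifelse(neg > 0, 100 * counts$FP / neg, NA_real_)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(TPR = mean_or_na(tpr), TNR = mean_or_na(tnr),
             FPR = mean_or_na(fpr), FNR = mean_or_na(fnr),
             n_taxa = sum(pos > 0))
}

#' Per-rank metrics table over the canonical ranks
#'
#' @inheritParams confusion_at_rank
#' @param ranks Ranks to evaluate (default all seven).
#' @return Data.frame with one row per rank: `rank`, `TPR`, `TNR`,
#'   `FPR`, `FNR`, `n_taxa`.
#' @export
evaluate_ranks <- function(assignments, truth, tax, ranks = canonical_ranks()) {
  do.call(rbind, lapply(ranks, function(r) {
    cbind(rank = r, rank_metrics(confusion_at_rank(assignments, truth, tax, r)))
  }))
}

#' Assigned / correctly assigned read counts at a rank
#'
#' A read counts as assigned at `rank` when its call projects to some
#' taxon at that rank (a genus-level call is assigned at genus and
#' above, not at species); it is correct when the projected call equals
#' the projected truth.
#'
#' @inheritParams confusion_at_rank
#' @return Named numeric vector `c(n_assigned, n_correct)`
#'   (abundance-weighted).
#' @export
assigned_correct_counts <- function(assignments, truth, tax, rank) {
  pp <- projected_pairs(assignments, truth, tax, rank)
  assigned <- !is.na(pp$call)
  c(n_assigned = sum(pp$w[assigned]),
    n_correct = sum(pp$w[assigned & pp$call == pp$truth]))
}

#' Write / read a per-rank benchmark report
#'
#' One row per rank with TPR/TNR/FPR/FNR to two decimals. In
#' compatibility mode undefined rates (e.g. TNR/FPR at a single-taxon
#' kingdom rank, where no negatives exist) are displayed as `0.00`,
#' matching the conventional presentation; otherwise they are left
#' empty.
#'
#' @param metrics Data.frame from [evaluate_ranks()].
#' @param path Output CSV path.
#' @param table1_compat Display undefined rates as 0.00 (default TRUE).
#' @return `read_benchmark_report` returns the parsed data.frame with
#'   numeric rate columns (`NA` for empty cells).
#' @export
write_benchmark_report <- function(metrics, path, table1_compat = TRUE) {
  fmt <- function(x) {
    out <- ifelse(is.na(x),
                  if (table1_compat) "0.00" else "",
                  sprintf("%.2f", x))
    out
  }
  df <- data.frame(rank = metrics$rank,
                   TPR = fmt(metrics$TPR), TNR = fmt(metrics$TNR),
                   FPR = fmt(metrics$FPR), FNR = fmt(metrics$FNR),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_benchmark_report
#' @export
read_benchmark_report <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "character", "character",
                                "character", "character"))
  for (col in c("TPR", "TNR", "FPR", "FNR"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df
}
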
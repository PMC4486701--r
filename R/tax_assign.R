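#' Assign one query to a taxonomy node
#'
#' Places a query on the guide tree by minimising, over every taxonomy
#' node `n`, the penalty `q * FN(n) + (1 - q) * FP(n)`, where `FN(n)`
#' counts matched reference sequences outside the subtree of `n` and
#' `FP(n)` counts guide-tree reference sequences inside the subtree of
#' `n` that were not matched. References mapped at a matched taxid are
#' counted as matched. Ties are broken toward the deepest node, then the
#' smallest node id, making runs reproducible. With `q = 1` the
#' minimiser is exactly the lowest common ancestor of the matched
#' taxids.
#'
#' @param match_taxids Set of matched taxon ids (empty set returns
#'   `NA`).
#' @param guide A [build_guide_tree()] object.
#' @param q False-negative penalty weight in `[0, 1]` (default 0.5,
#'   symmetric; 1 recovers plain LCA).
#' @return The assigned node id, or `NA_integer_` for an empty match
#'   set.
#' @export
assign_query <- function(match_taxids, guide, q = 0.5) {
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  match_taxids <- unique(as.integer(match_taxids))
  if (length(match_taxids) == 0L) return(NA_integer_)
  tax <- guide$taxonomy
  p <- tax_pos(tax, match_taxids)

  # refs mapped directly at each node, restricted to matched taxids
  ref_pos <- tax$.pos[as.character(guide$ref_to_taxid)]
  direct <- tabulate(ref_pos, nbins = n_nodes(tax))
  matched_direct <- integer(n_nodes(tax))
  matched_direct[p] <- direct[p]
  # a matched taxid with no reference mapped exactly there still counts once
  matched_direct[p][matched_direct[p] == 0L] <- 1L
  total <- sum(matched_direct)

  mu <- subtree_sums(tax, matched_direct)      # matched refs under each node
  fn <- total - mu
  fp <- unname(guide$leaves_under[as.character(tax$nodes$node_id)]) -
    subtree_sums(tax, ifelse(seq_len(n_nodes(tax)) %in% p, direct, 0L))
  score <- q * fn + (1 - q) * fp
  best <- which(score <= min(score) + 1e-9)
  best <- best[order(-tax$.depth[best], tax$nodes$node_id[best])][1L]
  tax$nodes$node_id[best]
}

#' Assign all prepped queries from a match file
#'
#' One assignment per query: queries present in the match file get the
#' [assign_query()] node; queries absent from it are recorded as
#' unassigned. Abundances (from dereplication) are joined by query id
#' when provided, defaulting to 1 with a warning on id mismatch.
#'
#' @param query_ids Character vector of all prepped query ids.
#' @param matches A `"match_file"` object.
#' @param guide A [build_guide_tree()] object.
#' @param q Penalty weight, see [assign_query()].
#' @param abundances Optional named integer vector (query id ->
#'   abundance).
#' @return Data.frame with `query_id`, `node_id`, `assigned_rank`,
#'   `status`, `abundance`.
#' @export
assign_all <- function(query_ids, matches, guide, q = 0.5, abundances = NULL) {
  tax <- guide$taxonomy
  node <- rep(NA_integer_, length(query_ids))
  hit <- match(query_ids, names(matches))
  for (i in which(!is.na(hit)))
    node[i] <- assign_query(matches[[hit[i]]]$taxid, guide, q)
  ab <- rep(1L, length(query_ids))
  if (!is.null(abundances)) {
    m <- match(query_ids, names(abundances))
    if (anyNA(m) && any(!is.na(node)))
      warning("abundance missing for ", sum(is.na(m)),
              " query id(s); defaulting to 1")
    ab[!is.na(m)] <- as.integer(abundances[m[!is.na(m)]])
  }
  ar <- rep(NA_character_, length(query_ids))
  ok <- !is.na(node)
  if (any(ok)) {
    ar[ok] <- vapply(node[ok], function(n) nearest_ranked(tax, n), character(1))
  }
  data.frame(query_id = query_ids, node_id = node, assigned_rank = ar,
             status = ifelse(ok, "assigned", "unassigned"),
             abundance = ab, stringsAsFactors = FALSE)
}

# rank of a node; nodes at "no rank" report the nearest ranked ancestor,
# keeping rank-indexed tables well defined
nearest_ranked <- function(tax, node_id) {
  path <- path_to_root(tax, node_id)
  rk <- tax$nodes$rank[tax_pos(tax, path)]
  ranked <- rk[rk != "no rank"]
  if (length(ranked) == 0L) NA_character_ else ranked[1L]
}

#' Summarise assignments into a taxonomic profile
#'
#' Cumulative counting: an assignment of weight `w` (its abundance) at
#' node `n` adds `w` to `n` and to every ancestor of `n`, so counts
#' never increase from the root toward the leaves. Per-rank tables read
#' the counts of the nodes at each canonical rank.
#'
#' @param assignments Data.frame from [assign_all()].
#' @param tax A [taxonomy()] object.
#' @return An object of class `"tax_profile"`: list with `node_counts`
#'   (named by node id), `rank_tables` (per canonical rank a data.frame
#'   `node_id`, `name`, `count`), `n_assigned`, `n_unassigned`.
#' @export
summarize_profile <- function(assignments, tax) {
  w <- numeric(n_nodes(tax))
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (nrow(a)) {
    p <- tax_pos(tax, a$node_id)
    for (i in seq_along(p)) w[p[i]] <- w[p[i]] + a$abundance[i]
  }
  # cumulative: push each node's direct weight onto all its ancestors
  cum <- subtree_sums(tax, w)
  counts <- setNames(cum, tax$nodes$node_id)
  rank_tables <- lapply(setNames(nm = canonical_ranks()), function(r) {
    sel <- tax$nodes$rank == r & cum > 0
    data.frame(node_id = tax$nodes$node_id[sel],
               name = tax$nodes$name[sel],
               count = unname(cum[sel]), stringsAsFactors = FALSE)
  })
  structure(list(node_counts = counts, rank_tables = rank_tables,
                 n_assigned = sum(a$abundance),
                 n_unassigned = sum(assignments$abundance) - sum(a$abundance)),
            class = "tax_profile")
}

#' @export
print.tax_profile <- function(x, ...) {
  cat("tax_profile:", x$n_assigned, "assigned /", x$n_unassigned,
      "unassigned (abundance-weighted)\n")
  for (r in canonical_ranks())
    cat(sprintf("  %-8s %d taxa\n", r, nrow(x$rank_tables[[r]])))
  invisible(x)
}

#' Serialise observed taxonomy nodes as a Newick tree
#'
#' The tree spans every node with non-zero cumulative count; counts are
#' attached as `[&count=N]` comments after each label.
#'
#' @param profile A [summarize_profile()] object.
#' @param tax The matching [taxonomy()] object.
#' @return A single Newick string (empty profile gives `";"`).
#' @export
profile_newick <- function(profile, tax) {
  counts <- profile$node_counts
  keep <- names(counts)[counts > 0]
  if (length(keep) == 0L) return(";")
  keepset <- as.integer(keep)
  kids <- split(tax$nodes$node_id, tax$nodes$parent_id)
  label <- function(id) {
    nm <- gsub("[][ ():;,]", "_", tax$nodes$name[tax_pos(tax, id)])
    sprintf("%s[&count=%d]", nm, as.integer(counts[as.character(id)]))
  }
  emit <- function(id) {
    ch <- setdiff(kids[[as.character(id)]], id)
    ch <- ch[ch %in% keepset]
    if (length(ch) == 0L) return(label(id))
    paste0("(", paste(vapply(sort(ch), emit, character(1)), collapse = ","),
           ")", label(id))
  }
  paste0(emit(tax$root_id), ";")
}

#' Write assignment outputs
#'
#' Emits (a) a per-read CSV (`query_id`, `taxid`, `name`, `rank`,
#' quoted semicolon-separated lineage, `abundance`), (b) a per-rank
#' counts CSV, and (c) a Newick tree of the observed nodes with counts
#' as comments.
#'
#' @param profile A [summarize_profile()] object.
#' @param assignments Data.frame from [assign_all()].
#' @param tax The [taxonomy()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_outputs <- function(profile, assignments, tax, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_read <- file.path(out_dir, "assignments.csv")
  per_rank <- file.path(out_dir, "rank_counts.csv")
  tree <- file.path(out_dir, "profile.nwk")

  a <- assignments
  ok <- a$status == "assigned"
  df <- data.frame(query_id = a$query_id,
                   taxid = a$node_id,
                   name = NA_character_, rank = a$assigned_rank,
                   lineage = NA_character_,
                   abundance = a$abundance, stringsAsFactors = FALSE)
  if (any(ok)) {
    df$name[ok] <- tax$nodes$name[tax_pos(tax, a$node_id[ok])]
    df$lineage[ok] <- vapply(a$node_id[ok], function(n)
      lineage_string(tax, n), character(1))
  }
  write.csv(df, per_read, row.names = FALSE, na = "")

  rk <- do.call(rbind, lapply(canonical_ranks(), function(r) {
    t <- profile$rank_tables[[r]]
    if (nrow(t) == 0L) return(NULL)
    cbind(rank = r, t)
  }))
  if (is.null(rk))
    rk <- data.frame(rank = character(0), node_id = integer(0),
                     name = character(0), count = numeric(0))
  write.csv(rk, per_rank, row.names = FALSE)

  writeLines(profile_newick(profile, tax), tree)
  invisible(c(per_read, per_rank, tree))
}

#' Re-read a per-read assignment CSV
#'
#' Inverse of the per-read file written by [write_outputs()]; suitable
#' for rebuilding a profile from disk.
#'
#' @param path Path to `assignments.csv`.
#' @return Data.frame with the [assign_all()] columns.
#' @export
read_assignments_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(query_id = as.character(df$query_id),
             node_id = as.integer(df$taxid),
             assigned_rank = ifelse(df$rank == "" | is.na(df$rank),
                                    NA_character_, df$rank),
             status = ifelse(is.na(df$taxid), "unassigned", "assigned"),
             abundance = as.integer(df$abundance), stringsAsFactors = FALSE)
}
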
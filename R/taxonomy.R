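#' @importFrom stats rnorm runif setNames aggregate
#' @importFrom utils read.delim write.csv read.csv head tail
NULL

#' Canonical taxonomic ranks
#'
#' The seven ranks used throughout the package, ordered from the most
#' inclusive (kingdom) to the least (species). Reference taxonomies may
#' contain additional intermediate ranks (subclass, tribe, ...); these are
#' loaded as `"no rank"` and are transparent to rank projection.
#'
#' @return Character vector of the seven canonical rank names.
#' @export
canonical_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

norm_rank <- function(rank) {
  r <- gsub("[-_]", " ", tolower(trimws(rank)))
  ifelse(r %in% canonical_ranks(), r, "no rank")
}

#' Construct a taxonomy from a node table
#'
#' Builds and validates a rooted, ranked taxonomy. The root is the unique
#' node whose parent is itself. Ranks outside the canonical seven (see
#' [canonical_ranks()]) are normalised to `"no rank"`.
#'
#' @param nodes A data.frame with columns `node_id`, `parent_id`, `rank`,
#'   `name`. Ids are coerced to integer and must be unique; every
#'   `parent_id` must resolve to a `node_id`.
#' @return An object of class `"taxonomy"`: a list with elements `nodes`
#'   (the validated node table), `root_id`, and precomputed parent/depth
#'   indices used by the query functions.
#' @export
taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  nodes <- data.frame(node_id = as.integer(nodes$node_id),
                      parent_id = as.integer(nodes$parent_id),
                      rank = norm_rank(as.character(nodes$rank)),
                      name = as.character(nodes$name),
                      stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) stop("taxonomy is empty")
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node ids: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  pos <- setNames(seq_len(nrow(nodes)), nodes$node_id)
  parent_pos <- pos[as.character(nodes$parent_id)]
  if (anyNA(parent_pos)) {
    bad <- nodes$node_id[is.na(parent_pos)]
    stop("orphan parent: node(s) ", paste(bad, collapse = ", "),
         " reference a parent_id absent from the table")
  }
  is_root <- nodes$parent_id == nodes$node_id
  if (sum(is_root) == 0L) stop("missing root: no node has parent_id == node_id")
  if (sum(is_root) > 1L)
    stop("multiple roots: ", paste(nodes$node_id[is_root], collapse = ", "))
  root_pos <- which(is_root)

  # depth by iterative relaxation from the root; unresolvable rows lie on a cycle
  depth <- rep(NA_integer_, nrow(nodes))
  depth[root_pos] <- 0L
  repeat {
    reach <- is.na(depth) & !is.na(depth[parent_pos])
    if (!any(reach)) break
    depth[reach] <- depth[parent_pos[reach]] + 1L
  }
  if (anyNA(depth))
    stop("cycle detected involving node ", nodes$node_id[which(is.na(depth))[1L]])

  structure(list(nodes = nodes,
                 root_id = nodes$node_id[root_pos],
                 .pos = pos,
                 .parent_pos = unname(parent_pos),
                 .depth = depth),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy:", nrow(x$nodes), "nodes, root", x$root_id, "\n")
  rk <- table(factor(x$nodes$rank, levels = c(canonical_ranks(), "no rank")))
  print(rk)
  invisible(x)
}

#' Number of nodes in a taxonomy
#' @param tax A [taxonomy()] object.
#' @return Integer node count.
#' @export
n_nodes <- function(tax) nrow(tax$nodes)

tax_pos <- function(tax, node_ids) {
  p <- tax$.pos[as.character(node_ids)]
  if (anyNA(p))
    stop("unknown node id(s): ",
         paste(node_ids[is.na(p)], collapse = ", "))
  unname(p)
}

#' Load a taxonomy from nodes/names tables
#'
#' Reads the NCBI taxonomy dump dialect (fields separated by `"\t|\t"`,
#' records terminated by `"\t|"`; nodes: id, parent, rank; names: id,
#' name, unique name, name class, with only `"scientific name"` rows
#' used) or a plain 3-/2-column TSV fallback (`id, parent, rank` and
#' `id, name`).
#'
#' @param nodes_file Path to the nodes table.
#' @param names_file Path to the names table.
#' @param format `"ncbi_dump"` or `"tsv"`.
#' @return A validated [taxonomy()] object.
#' @export
load_taxonomy <- function(nodes_file, names_file, format = c("ncbi_dump", "tsv")) {
  format <- match.arg(format)
  if (format == "ncbi_dump") {
    parse_dump <- function(path) {
      lines <- readLines(path)
      lines <- sub("\t\\|$", "", lines)
      strsplit(lines, "\t\\|\t")
    }
    nd <- parse_dump(nodes_file)
    if (any(lengths(nd) < 3L)) stop("malformed nodes dump row")
    nodes <- data.frame(node_id = vapply(nd, `[`, "", 1L),
                        parent_id = vapply(nd, `[`, "", 2L),
                        rank = vapply(nd, `[`, "", 3L),
                        stringsAsFactors = FALSE)
    nm <- parse_dump(names_file)
    if (any(lengths(nm) < 4L)) stop("malformed names dump row")
    cls <- vapply(nm, `[`, "", 4L)
    nm <- nm[trimws(cls) == "scientific name"]
    name_map <- setNames(vapply(nm, `[`, "", 2L), vapply(nm, `[`, "", 1L))
  } else {
    nodes <- read.delim(nodes_file, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("node_id", "parent_id", "rank"))
    nmt <- read.delim(names_file, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("node_id", "name"))
    name_map <- setNames(nmt$name, nmt$node_id)
  }
  nodes$name <- unname(name_map[as.character(nodes$node_id)])
  nodes$name[is.na(nodes$name)] <- paste0("node_", nodes$node_id[is.na(nodes$name)])
  taxonomy(nodes)
}

#' Path from a node to the root
#'
#' @param tax A [taxonomy()] object.
#' @param node_id A single node id.
#' @return Integer vector of node ids starting at `node_id` and ending at
#'   the root (inclusive).
#' @export
path_to_root <- function(tax, node_id) {
  p <- tax_pos(tax, node_id)
  out <- integer(tax$.depth[p] + 1L)
  i <- 1L
  repeat {
    out[i] <- tax$nodes$node_id[p]
    pp <- tax$.parent_pos[p]
    if (pp == p) break
    p <- pp
    i <- i + 1L
  }
  out
}

#' Lowest common ancestor of a node set
#'
#' The deepest node that is an ancestor of (or equal to) every node in
#' `node_ids`.
#'
#' @param tax A [taxonomy()] object.
#' @param node_ids Non-empty vector of node ids.
#' @return The LCA node id.
#' @export
lca <- function(tax, node_ids) {
  node_ids <- unique(as.integer(node_ids))
  if (length(node_ids) == 0L) stop("lca of an empty set is undefined")
  p <- tax_pos(tax, node_ids)
  cur <- p[1L]
  for (q in p[-1L]) {
    a <- cur; b <- q
    while (tax$.depth[a] > tax$.depth[b]) a <- tax$.parent_pos[a]
    while (tax$.depth[b] > tax$.depth[a]) b <- tax$.parent_pos[b]
    while (a != b) { a <- tax$.parent_pos[a]; b <- tax$.parent_pos[b] }
    cur <- a
  }
  tax$nodes$node_id[cur]
}

#' Ancestor (or self) at a given canonical rank
#'
#' @param tax A [taxonomy()] object.
#' @param node_id A single node id.
#' @param rank One of the seven canonical ranks.
#' @return The node id of the unique ancestor-or-self at `rank`, or `NA`
#'   if the lineage has no node at that rank.
#' @export
rank_ancestor <- function(tax, node_id, rank) {
  rank <- match.arg(rank, canonical_ranks())
  path <- path_to_root(tax, node_id)
  pr <- tax$nodes$rank[tax_pos(tax, path)]
  hit <- which(pr == rank)
  if (length(hit) == 0L) NA_integer_ else path[hit[1L]]
}

# vectorised rank projection used by profiling/evaluation; NA ids project to NA
project_to_rank <- function(tax, node_ids, rank) {
  rank <- match.arg(rank, canonical_ranks())
  u <- unique(node_ids[!is.na(node_ids)])
  proj <- vapply(u, function(id) rank_ancestor(tax, id, rank), integer(1))
  out <- rep(NA_integer_, length(node_ids))
  ok <- !is.na(node_ids)
  out[ok] <- proj[match(node_ids[ok], u)]
  out
}

#' Does a node have a complete, informative taxonomic path?
#'
#' A lineage is complete when it carries a node at every one of the seven
#' canonical ranks and none of the lineage names matches a placeholder
#' pattern such as "uncultured bacterium" (case-insensitive substring
#' match).
#'
#' @param tax A [taxonomy()] object.
#' @param node_id A single node id.
#' @param uncultured_patterns Character vector of placeholder patterns.
#' @return `TRUE` or `FALSE`.
#' @export
is_complete_path <- function(tax, node_id,
                             uncultured_patterns = c("uncultured",
                                                     "environmental sample",
                                                     "unidentified")) {
  path <- path_to_root(tax, node_id)
  p <- tax_pos(tax, path)
  if (!all(canonical_ranks() %in% tax$nodes$rank[p])) return(FALSE)
  nm <- tolower(tax$nodes$name[p])
  for (pat in tolower(uncultured_patterns))
    if (any(grepl(pat, nm, fixed = TRUE))) return(FALSE)
  TRUE
}

#' Rank-prefixed lineage string for a node
#'
#' Formats the canonical-rank lineage in the conventional
#' `k__...;p__...;...;s__...` dialect, omitting ranks the lineage lacks.
#'
#' @param tax A [taxonomy()] object.
#' @param node_id A single node id.
#' @return A single character string.
#' @export
lineage_string <- function(tax, node_id) {
  ranks <- canonical_ranks()
  prefix <- c("k", "p", "c", "o", "f", "g", "s")
  path <- path_to_root(tax, node_id)
  p <- tax_pos(tax, path)
  keep <- match(ranks, tax$nodes$rank[p])
  parts <- ifelse(is.na(keep), NA_character_,
                  paste0(prefix, "__", tax$nodes$name[p][keep]))
  paste(parts[!is.na(parts)], collapse = ";")
}

#' Build the guide tree for a reference database
#'
#' Annotates the taxonomy with the reference sequences hanging at each
#' node and precomputes, for every node, the number of reference
#' sequences in its subtree (one bottom-up pass). References may map to
#' internal (e.g. genus-level) nodes and are counted there.
#'
#' @param tax A [taxonomy()] object.
#' @param ref_to_taxid Named integer vector: names are reference-sequence
#'   ids, values are taxonomy node ids. Must be non-empty.
#' @return An object of class `"guide_tree"`: list with `taxonomy`,
#'   `ref_to_taxid` and `leaves_under` (named by node id).
#' @export
build_guide_tree <- function(tax, ref_to_taxid) {
  if (length(ref_to_taxid) == 0L)
    stop("guide tree must be non-empty: no reference sequences supplied")
  if (is.null(names(ref_to_taxid)) || any(names(ref_to_taxid) == ""))
    stop("ref_to_taxid must be named by reference-sequence id")
  taxids <- as.integer(ref_to_taxid)
  p <- tax$.pos[as.character(taxids)]
  if (anyNA(p))
    stop("unresolvable taxid for reference(s): ",
         paste(names(ref_to_taxid)[is.na(p)], collapse = ", "))
  direct <- tabulate(p, nbins = n_nodes(tax))
  leaves_under <- subtree_sums(tax, direct)
  structure(list(taxonomy = tax,
                 ref_to_taxid = setNames(taxids, names(ref_to_taxid)),
                 leaves_under = setNames(leaves_under, tax$nodes$node_id)),
            class = "guide_tree")
}

# one bottom-up pass: for per-node weights w (by position), the sum of w
# over each node's subtree, inclusive
subtree_sums <- function(tax, w) {
  acc <- as.numeric(w)
  ord <- order(tax$.depth, decreasing = TRUE)
  for (i in ord) {
    pp <- tax$.parent_pos[i]
    if (pp != i) acc[pp] <- acc[pp] + acc[i]
  }
  acc
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("guide_tree:", length(x$ref_to_taxid), "reference sequences on",
      n_nodes(x$taxonomy), "taxonomy nodes\n")
  invisible(x)
}
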
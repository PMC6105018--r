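#' Read / write phylogenetic trees
#'
#' Thin wrappers over ape's newick and NEXUS readers and writers that add the
#' validation this package relies on: unique leaf labels and non-negative
#' branch lengths. Branch lengths are written with 10 significant digits so a
#' write/read round trip preserves them.
#'
#' @param path file path.
#' @param format \code{"newick"} or \code{"nexus"}.
#' @return \code{read_tree}: a single \code{phylo} (or a \code{multiPhylo} when
#'   the file holds several trees). \code{write_tree}: \code{path}, invisibly.
#' @export
read_tree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(
    if (format == "newick") ape::read.tree(path) else ape::read.nexus(path),
    error = function(e) stop("tree parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("tree parse error in '", path,
                        "': no tree could be read", call. = FALSE)
  check <- function(t) {
    if (anyDuplicated(t$tip.label))
      stop("duplicate leaf label(s): ",
           paste(unique(t$tip.label[duplicated(t$tip.label)]), collapse = ", "),
           call. = FALSE)
    if (!is.null(t$edge.length) && any(t$edge.length < 0))
      stop("negative branch length(s) found", call. = FALSE)
    t
  }
  if (inherits(tr, "multiPhylo")) {
    tr <- structure(lapply(tr, check), class = "multiPhylo")
    if (length(tr) == 1L) tr <- tr[[1L]]
  } else check(tr)
  tr
}

#' @rdname read_tree
#' @param tree a \code{phylo} or \code{multiPhylo}.
#' @export
write_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "newick")
    ape::write.tree(tree, file = path, digits = 12)
  else
    ape::write.nexus(tree, file = path, translate = TRUE)
  invisible(path)
}

# canonical key of one split side: sorted labels, unit-separated
.side_key <- function(labels) paste(sort(labels), collapse = "\x1f")

# Canonical orientation of a split: the side NOT containing the reference
# leaf (default: lexicographically first leaf of the universe), so a split
# and its complement always map to the same key.
.canonical_side <- function(side, universe, ref = sort(universe)[1]) {
  if (ref %in% side) setdiff(universe, side) else side
}

#' Nontrivial splits (bipartitions) of a tree
#'
#' Splits are taken on the unrooted view: every internal edge of the unrooted
#' tree induces one bipartition of the leaves; bipartitions with fewer than
#' two leaves on either side are trivial and dropped. Polytomies simply
#' contribute fewer splits. Each split is stored in canonical orientation
#' (the side not containing the reference leaf).
#'
#' @param tree a \code{phylo}.
#' @param ref reference leaf used for canonical orientation; defaults to the
#'   lexicographically first leaf.
#' @return a list of character vectors (one sorted side per split), with the
#'   leaf universe in attribute \code{"universe"}. Empty for trees with fewer
#'   than four leaves or no internal edges.
#' @export
nontrivial_splits <- function(tree, ref = NULL) {
  labs <- tree$tip.label
  n <- length(labs)
  universe <- sort(labs)
  if (is.null(ref)) ref <- universe[1]
  out <- list()
  if (n >= 4L) {
    tr <- stats::reorder(tree, "postorder")
    nnode <- n + tr$Nnode
    desc <- vector("list", nnode)
    for (i in seq_len(n)) desc[[i]] <- labs[i]
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
      desc[[p]] <- c(desc[[p]], desc[[ch]])
    }
    seen <- character(0)
    for (k in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[k, 2L]
      if (ch <= n) next                       # pendant edge -> trivial
      side <- .canonical_side(desc[[ch]], universe, ref)
      if (length(side) < 2L || length(side) > n - 2L) next
      key <- .side_key(side)
      if (key %in% seen) next                 # root edge duplicates
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- sort(side)
    }
  }
  attr(out, "universe") <- universe
  out
}

.split_keys <- function(tree) {
  vapply(nontrivial_splits(tree), .side_key, character(1))
}

#' Robinson-Foulds distance between two trees
#'
#' Computed on the unrooted view after pruning both trees to their shared
#' leaf set. The normalized distance is the number of bipartitions unique to
#' each tree divided by the total number of bipartitions in both; the raw
#' distance is the plain symmetric difference count.
#'
#' @param t1,t2 \code{phylo} objects.
#' @param normalized logical; divide by the total split count of both trees.
#' @return a single number; 0 for identical split sets, at most 1 when
#'   normalized. Two shared-leaf star trees (no splits at all) have distance 0.
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L)
    stop("RF distance undefined: fewer than 4 shared leaves")
  if (length(shared) < length(t1$tip.label))
    t1 <- ape::keep.tip(t1, shared)
  if (length(shared) < length(t2$tip.label))
    t2 <- ape::keep.tip(t2, shared)
  k1 <- .split_keys(t1)
  k2 <- .split_keys(t2)
  d <- sum(!k1 %in% k2) + sum(!k2 %in% k1)
  if (!normalized) return(d)
  tot <- length(k1) + length(k2)
  if (tot == 0L) 0 else d / tot
}

#' Monophyly of a taxon set
#'
#' On the unrooted view (the default, appropriate for gene trees), a set is
#' monophyletic when it is one side of some bipartition, or trivially so
#' (size 1 or n-1). With \code{rooted = TRUE} the classic clade test is used:
#' some node's descendant leaf set must equal the taxon set exactly.
#'
#' @param tree a \code{phylo}.
#' @param taxa character vector of leaf names.
#' @param rooted logical; use the rooted clade test.
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa, rooted = FALSE) {
  labs <- tree$tip.label
  unknown <- setdiff(taxa, labs)
  if (length(unknown))
    stop("unknown taxon name(s): ", paste(unknown, collapse = ", "))
  taxa <- unique(taxa)
  n <- length(labs)
  if (rooted) {
    cl <- .clade_sets(tree)
    key <- .side_key(taxa)
    return(key %in% vapply(cl, .side_key, character(1)))
  }
  if (length(taxa) <= 1L || length(taxa) >= n - 1L) return(TRUE)
  side <- .canonical_side(taxa, sort(labs))
  .side_key(sort(side)) %in% .split_keys(tree)
}

# all clades (descendant leaf sets of every node, tips included) of a tree
.clade_sets <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  tr <- stats::reorder(tree, "postorder")
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- labs[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Root-to-tip path lengths
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @return named numeric vector, one entry per leaf; on an ultrametric tree
#'   all entries are equal.
#' @export
root_to_tip_distances <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Normalize taxon labels for cross-file matching
#'
#' Leaf-name matching everywhere in the package is exact string match; this
#' optional hook maps spaces to underscores (or back) and squeezes repeated
#' separators, for reconciling files written by tools with different
#' conventions. Apply it explicitly to trees, alignments or clade maps
#' before combining them -- it is never applied implicitly.
#'
#' @param labels character vector (or a \code{phylo}, whose tip labels are
#'   normalized).
#' @param to \code{"underscore"} (default) or \code{"space"}.
#' @return object of the same shape with normalized labels.
#' @export
normalize_labels <- function(labels, to = c("underscore", "space")) {
  to <- match.arg(to)
  fix <- function(x) {
    x <- trimws(gsub("[ _]+", " ", x))
    if (to == "underscore") gsub(" ", "_", x) else x
  }
  if (inherits(labels, "phylo")) {
    labels$tip.label <- fix(labels$tip.label)
    labels
  } else fix(labels)
}

#' Assignment of terminals to backbone clades
#'
#' @param clade_of named character vector: names are terminal labels, values
#'   are clade labels; terminals mapped to \code{outgroup} form the outgroup.
#' @param outgroup the outgroup clade label (must appear in \code{clade_of}).
#' @param clade_order optional ordering of the ingroup clade labels.
#' @return an object of class \code{clade_map} with fields \code{clade_of},
#'   \code{clades} (ingroup labels) and \code{outgroup}.
#' @export
clade_map <- function(clade_of, outgroup, clade_order = NULL) {
  if (is.null(names(clade_of)) || anyDuplicated(names(clade_of)))
    stop("'clade_of' must be named by unique terminal labels")
  labels <- unique(unname(clade_of))
  if (!outgroup %in% labels)
    stop("outgroup label '", outgroup, "' has no terminals")
  ingroup <- setdiff(labels, outgroup)
  if (!is.null(clade_order)) {
    if (!setequal(clade_order, ingroup))
      stop("'clade_order' must be a permutation of the ingroup clade labels")
    ingroup <- clade_order
  }
  structure(list(clade_of = clade_of, clades = ingroup, outgroup = outgroup),
            class = "clade_map")
}

#' @export
print.clade_map <- function(x, ...) {
  cat(sprintf("clade_map: %d terminals, %d ingroup clades + outgroup '%s'\n",
              length(x$clade_of), length(x$clades), x$outgroup))
  invisible(x)
}

#' Terminals belonging to one clade
#' @param map a \code{clade_map}.
#' @param clade clade label.
#' @return character vector of terminal labels.
#' @export
clade_terminals <- function(map, clade) {
  names(map$clade_of)[map$clade_of == clade]
}

#' Read / write a clade-membership table
#'
#' Two-column TSV (terminal, clade) with a header line.
#'
#' @param path file path.
#' @param outgroup outgroup clade label.
#' @return a \code{clade_map}.
#' @export
read_clade_map <- function(path, outgroup) {
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  clade_map(stats::setNames(tb[[2]], tb[[1]]), outgroup = outgroup)
}

#' @rdname read_clade_map
#' @param map a \code{clade_map}.
#' @export
write_clade_map <- function(map, path) {
  utils::write.table(
    data.frame(terminal = names(map$clade_of), clade = unname(map$clade_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
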
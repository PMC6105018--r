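#' Pairwise Robinson-Foulds distance matrix
#'
#' Every pair of trees is pruned to its shared leaf set before comparison.
#' Reference trees (e.g. a concatenated or morphological topology) can be
#' appended and are flagged in the attribute \code{"is_reference"}. Pairs
#' sharing fewer than 4 leaves get \code{NA} with a warning.
#'
#' @param trees list or \code{multiPhylo} of gene trees; names are used as
#'   labels.
#' @param refs optional named list of reference trees.
#' @param normalized passed to [rf_distance()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
rf_matrix <- function(trees, refs = NULL, normalized = TRUE) {
  trees <- c(unclass(trees), unclass(refs))
  n <- length(trees)
  if (n < 2L) stop("need at least 2 trees")
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("tree_", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(names(trees), names(trees)))
  n_missing <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(rf_distance(trees[[i]], trees[[j]], normalized),
                  error = function(e) NA_real_)
    if (is.na(d)) n_missing <- n_missing + 1L
    D[i, j] <- D[j, i] <- d
  }
  if (n_missing)
    warning(n_missing, " pair(s) share fewer than 4 leaves; entries set NA")
  attr(D, "is_reference") <- c(rep(FALSE, n - length(refs)),
                               rep(TRUE, length(refs)))
  D
}

#' Two-dimensional treespace embedding
#'
#' Classical metric multidimensional scaling (double centering of the
#' squared-distance matrix, top two eigenvectors) of an RF distance matrix,
#' with Kruskal stress-1 between the embedded and original distances
#' reported. Missing entries are imputed with the off-diagonal mean (with a
#' warning). Deterministic up to axis sign; a matrix of effective rank 1
#' yields a one-dimensional embedding with a warning.
#'
#' @param D symmetric distance matrix (e.g. from [rf_matrix()]).
#' @return list of class \code{treespace_embedding}: \code{coords} (n x 2),
#'   \code{stress}, \code{eigenvalues}.
#' @export
embed_treespace <- function(D) {
  D <- as.matrix(D)
  if (anyNA(D)) {
    warning("missing distances imputed with the off-diagonal mean")
    off <- D[row(D) != col(D)]
    D[is.na(D)] <- mean(off, na.rm = TRUE)
    diag(D) <- 0
  }
  n <- nrow(D)
  mds <- stats::cmdscale(stats::as.dist(D), k = min(2L, n - 1L), eig = TRUE)
  Y <- mds$points
  if (ncol(Y) < 2L || mds$eig[2] <= 1e-12 * max(mds$eig[1], 1)) {
    if (ncol(Y) < 2L || all(Y[, 2] == 0)) {
      warning("distance matrix has effective rank < 2; ",
              "second axis degenerate")
    }
    if (ncol(Y) < 2L) Y <- cbind(Y, 0)
  }
  rownames(Y) <- rownames(D)
  dhat <- as.matrix(stats::dist(Y))
  num <- sum((D - dhat)[upper.tri(D)]^2)
  den <- sum(D[upper.tri(D)]^2)
  stress <- if (den > 0) sqrt(num / den) else 0
  structure(list(coords = Y, stress = stress, eigenvalues = mds$eig),
            class = "treespace_embedding")
}

#' @export
print.treespace_embedding <- function(x, ...) {
  cat(sprintf("treespace_embedding: %d trees, stress-1 = %.4g\n",
              nrow(x$coords), x$stress))
  invisible(x)
}

#' Split frequencies over a set of gene trees
#'
#' Collects every nontrivial split observed in any tree and computes, for
#' each, the fraction of displaying trees among the trees eligible to show
#' it: a tree is eligible when its leaf set contains all taxa on both sides
#' of the split, and displays the split when the bipartition is present in
#' the tree restricted to those taxa. These frequencies are the supernetwork
#' branch weights.
#'
#' @param trees list or \code{multiPhylo} of gene trees (>= 2).
#' @return data frame of class \code{split_frequency_table}: \code{split_id},
#'   \code{side_a}, \code{side_b} (comma-collapsed taxa), \code{n_eligible},
#'   \code{n_displaying}, \code{frequency}. The leaf universe (union) is in
#'   attribute \code{"universe"}.
#' @export
split_frequencies <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) < 2L) stop("need at least 2 gene trees")
  leafsets <- lapply(trees, `[[`, "tip.label")
  universe <- sort(unique(unlist(leafsets)))
  # candidate splits keyed on both sides (universe-independent orientation:
  # lexicographically smaller side string first)
  canon <- function(a, b) {
    ka <- .side_key(a); kb <- .side_key(b)
    if (ka <= kb) list(a = sort(a), b = sort(b), key = paste(ka, kb, sep = "|"))
    else list(a = sort(b), b = sort(a), key = paste(kb, ka, sep = "|"))
  }
  cand <- list()
  for (tr in trees) {
    for (s in nontrivial_splits(tr)) {
      cs <- canon(s, setdiff(tr$tip.label, s))
      if (is.null(cand[[cs$key]])) cand[[cs$key]] <- cs
    }
  }
  split_cache <- lapply(trees, .split_keys)
  rows <- lapply(cand, function(cs) {
    taxa <- c(cs$a, cs$b)
    elig <- which(vapply(leafsets, function(ls) all(taxa %in% ls), logical(1)))
    disp <- vapply(elig, function(i) {
      tr <- trees[[i]]
      if (length(leafsets[[i]]) > length(taxa))
        tr <- ape::keep.tip(tr, taxa)
      side <- .canonical_side(cs$a, sort(taxa))
      .side_key(sort(side)) %in% .split_keys(tr)
    }, logical(1))
    data.frame(side_a = paste(cs$a, collapse = ","),
               side_b = paste(cs$b, collapse = ","),
               n_eligible = length(elig), n_displaying = sum(disp),
               frequency = sum(disp) / length(elig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(split_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "universe") <- universe
  class(out) <- c("split_frequency_table", "data.frame")
  out
}

#' Write a split-frequency table as a NEXUS splits block
#'
#' Emits a taxa block plus a \code{st_splits} block (weights = frequencies)
#' consumable by network-layout viewers; the network layout itself is
#' delegated to those tools.
#'
#' @param table a [split_frequencies()] result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_splits_nexus <- function(table, path) {
  universe <- attr(table, "universe")
  n <- length(universe)
  idx <- function(side) match(strsplit(side, ",")[[1]], universe)
  lines <- c("#NEXUS", "", "BEGIN Taxa;",
             sprintf("DIMENSIONS ntax=%d;", n), "TAXLABELS",
             sprintf("  [%d] '%s'", seq_len(n), universe), ";", "END;",
             "", "BEGIN st_splits;",
             sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, nrow(table)),
             "FORMAT labels=no weights=yes confidences=no intervals=no;",
             "MATRIX")
  for (i in seq_len(nrow(table))) {
    side <- idx(table$side_a[i])
    lines <- c(lines, sprintf("  [%d] %.6f %s,", i, table$frequency[i],
                              paste(side, collapse = " ")))
  }
  lines <- c(lines, ";", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Write a (distance) matrix as TSV
#'
#' @param D matrix with dimnames.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(cbind(name = rownames(D), as.data.frame(D)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene support frequency for every reference-tree node
#'
#' For each internal node of a rooted reference tree, the fraction of gene
#' trees displaying that node's clade, out of the genes eligible to test it:
#' a gene is eligible when it samples every terminal of the clade plus at
#' least one terminal outside it, and displays the node when the clade is
#' monophyletic in the gene tree (unrooted test). Nodes with no eligible
#' gene get \code{NA}.
#'
#' @param gene_trees list or \code{multiPhylo} of gene trees (missing taxa
#'   allowed).
#' @param reference_tree rooted \code{phylo}.
#' @return data frame: \code{node} (ape node number), \code{clade_size},
#'   \code{clade} (comma-collapsed terminals), \code{n_eligible},
#'   \code{n_displaying}, \code{gsf}.
#' @export
gene_support_frequency <- function(gene_trees, reference_tree) {
  if (!ape::is.rooted(reference_tree))
    stop("reference tree must be rooted")
  gene_trees <- unclass(gene_trees)
  ntip <- length(reference_tree$tip.label)
  clades <- .clade_sets(reference_tree)
  nodes <- (ntip + 1L):(ntip + reference_tree$Nnode)
  leafsets <- lapply(gene_trees, `[[`, "tip.label")
  rows <- lapply(nodes, function(nd) {
    cl <- clades[[nd]]
    if (length(cl) >= ntip)
      return(NULL)                     # root clade: nothing outside it
    elig <- which(vapply(leafsets, function(ls)
      all(cl %in% ls) && length(setdiff(ls, cl)) >= 1L, logical(1)))
    disp <- vapply(elig, function(i)
      is_monophyletic(gene_trees[[i]], cl), logical(1))
    data.frame(node = nd, clade_size = length(cl),
               clade = paste(sort(cl), collapse = ","),
               n_eligible = length(elig), n_displaying = sum(disp),
               gsf = if (length(elig)) sum(disp) / length(elig) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
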
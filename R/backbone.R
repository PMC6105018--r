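#' Enumerate all rooted binary backbone topologies
#'
#' Produces every distinct rooted binary tree whose leaves are the supplied
#' clade labels, by recursive insertion of each successive label along every
#' branch (including above the current root). For n labels there are
#' (2n-3)!! such trees, equivalently the unrooted resolutions on the n clades
#' plus an implied outgroup; for the six-clade squamate backbone this is 945.
#' Output is canonicalized (children sorted lexicographically) so duplicates
#' cannot arise.
#'
#' @param clade_labels character vector of 3 to 9 clade labels.
#' @return character vector of canonical newick strings (no branch lengths),
#'   of length (2n-3)!!.
#' @export
enumerate_backbones <- function(clade_labels) {
  clade_labels <- as.character(clade_labels)
  n <- length(clade_labels)
  if (anyDuplicated(clade_labels)) stop("clade labels must be unique")
  if (n < 3L) stop("need at least 3 clade labels")
  if (n > 9L)
    stop("refusing to enumerate ", n, " clades: (2n-3)!! = ",
         format(prod(seq(2 * n - 3, 1, by = -2)), big.mark = ","),
         " topologies")
  trees <- list(list(clade_labels[1], clade_labels[2]))
  for (k in 3:n) {
    lab <- clade_labels[k]
    trees <- unlist(lapply(trees, .insert_everywhere, lab = lab),
                    recursive = FALSE)
  }
  nw <- vapply(trees, function(t) paste0(.canon_newick(t), ";"), character(1))
  stopifnot(!anyDuplicated(nw))
  nw
}

# attach `lab` as sister to every subtree of `tr` (including `tr` itself,
# i.e. above the root); returns the list of resulting trees
.insert_everywhere <- function(tr, lab) {
  res <- list(list(tr, lab))
  if (is.character(tr)) return(res)
  for (i in 1:2) {
    alt <- .insert_everywhere(tr[[i]], lab)
    other <- tr[[3L - i]]
    res <- c(res, lapply(alt, function(x)
      if (i == 1L) list(x, other) else list(other, x)))
  }
  res
}

.canon_newick <- function(tr) {
  if (is.character(tr)) return(tr)
  ch <- sort(c(.canon_newick(tr[[1]]), .canon_newick(tr[[2]])))
  paste0("(", ch[1], ",", ch[2], ")")
}

#' Number of rooted binary trees on n leaves
#' @param n leaf count (>= 2).
#' @return (2n-3)!! as a double.
#' @export
n_rooted_topologies <- function(n) {
  if (n < 2) stop("n must be >= 2")
  if (n == 2) return(1)
  prod(seq(2 * n - 3, 1, by = -2))
}

#' Default backbone hypotheses for the squamate radiation
#'
#' Scleroglossa: all ingroup clades except Iguania form a clade (the
#' morphological hypothesis). Toxicofera: Iguania + Anguimorpha + Serpentes
#' form a clade (the molecular hypothesis). The two are jointly unsatisfiable
#' on any backbone topology.
#'
#' @param clade_labels the six backbone clade labels.
#' @return named list of character vectors, one monophyly statement each.
#' @export
default_hypotheses <- function(clade_labels = squamate_clades()) {
  list(
    scleroglossa = setdiff(clade_labels, "Iguania"),
    toxicofera = c("Iguania", "Anguimorpha", "Serpentes"))
}

#' The six squamate backbone clade labels
#' @return character vector.
#' @export
squamate_clades <- function() {
  c("Iguania", "Gekkota", "Scincoidea", "Lacertoidea", "Anguimorpha",
    "Serpentes")
}

#' Classify backbone topologies against monophyly hypotheses
#'
#' Each hypothesis is a set of clade labels; a topology matches when that set
#' is a clade of the (rooted) backbone tree. Topologies matching none are
#' labelled \code{"neither"}. If a topology satisfies several configured
#' hypotheses the first in configuration order wins, with a warning (the
#' default pair is mutually exclusive, so this cannot happen there).
#'
#' @param topologies character vector of newick strings (as produced by
#'   [enumerate_backbones()]) or a list of \code{phylo} objects.
#' @param hypotheses named list of clade-label sets; default
#'   [default_hypotheses()].
#' @return factor of length \code{length(topologies)} with levels
#'   \code{c(names(hypotheses), "neither")}.
#' @export
classify_backbone <- function(topologies, hypotheses = default_hypotheses()) {
  if (is.character(topologies))
    topologies <- lapply(topologies, function(s) ape::read.tree(text = s))
  if (inherits(topologies, "phylo")) topologies <- list(topologies)
  hkeys <- lapply(hypotheses, function(h) .side_key(as.character(h)))
  labs0 <- topologies[[1]]$tip.label
  for (nm in names(hypotheses)) {
    h <- hypotheses[[nm]]
    bad <- setdiff(h, labs0)
    if (length(bad))
      stop("hypothesis '", nm, "' references unknown label(s): ",
           paste(bad, collapse = ", "))
    if (length(h) < 2L || length(h) >= length(labs0))
      stop("hypothesis '", nm, "' must be a proper subset of size >= 2")
  }
  lev <- c(names(hypotheses), "neither")
  res <- vapply(topologies, function(tr) {
    ck <- vapply(.clade_sets(tr), .side_key, character(1))
    hit <- names(hypotheses)[vapply(hkeys, function(k) k %in% ck, logical(1))]
    if (length(hit) > 1L) {
      warning("topology satisfies several hypotheses (",
              paste(hit, collapse = ", "), "); keeping the first")
      hit <- hit[1]
    }
    if (length(hit)) hit else "neither"
  }, character(1))
  factor(res, levels = lev)
}

#' Reduce a terminal-level tree to its clade backbone
#'
#' If every ingroup clade of \code{map} is monophyletic in \code{tree} (after
#' rooting on the outgroup), returns the induced rooted tree on the clade
#' labels; otherwise returns \code{NULL} together with the offending clades.
#' Clades with no sampled terminal are excluded and flagged.
#'
#' @param tree a \code{phylo} containing at least one terminal per clade.
#' @param map a [clade_map()].
#' @return list with elements \code{backbone} (a \code{phylo} on clade labels,
#'   or \code{NULL}), \code{newick} (canonical string or \code{NA}),
#'   \code{non_monophyletic} and \code{unsampled} (character vectors).
#' @export
backbone_of <- function(tree, map) {
  labs <- tree$tip.label
  og <- intersect(clade_terminals(map, map$outgroup), labs)
  if (!length(og)) stop("no outgroup terminal present in the tree")
  tree <- tryCatch(
    ape::root(ape::unroot(tree), outgroup = og, resolve.root = TRUE),
    error = function(e) stop("cannot root on the outgroup: ",
                             conditionMessage(e)))
  sampled <- lapply(stats::setNames(map$clades, map$clades),
                    function(cl) intersect(clade_terminals(map, cl), labs))
  unsampled <- names(sampled)[lengths(sampled) == 0L]
  use <- setdiff(map$clades, unsampled)
  mono <- vapply(use, function(cl) is_monophyletic(tree, sampled[[cl]]),
                 logical(1))
  if (!all(mono))
    return(list(backbone = NULL, newick = NA_character_,
                non_monophyletic = use[!mono], unsampled = unsampled))
  reps <- vapply(use, function(cl) sampled[[cl]][1], character(1))
  bb <- ape::keep.tip(tree, c(reps, og[1]))
  bb <- ape::root(ape::unroot(bb), outgroup = og[1], resolve.root = TRUE)
  bb <- ape::drop.tip(bb, og[1])
  bb$tip.label <- names(reps)[match(bb$tip.label, reps)]
  bb$edge.length <- NULL
  nw <- .canon_phylo_newick(bb)
  list(backbone = bb, newick = nw, non_monophyletic = character(0),
       unsampled = unsampled)
}

# canonical newick (sorted children, no lengths) of a phylo object
.canon_phylo_newick <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    ch <- sort(vapply(kids[[as.character(node)]], rec, character(1)))
    paste0("(", paste(ch, collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}
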
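#' Character-matrix alignment container
#'
#' A light container for taxa-by-sites character matrices: DNA alignments
#' (states \code{A C G T} plus IUPAC ambiguities, \code{-} gap, \code{?}/\code{N}
#' missing) or discrete morphological matrices (\code{"standard"} alphabet with
#' states \code{0..k-1}). An optional partition maps every site to a gene.
#'
#' @param x character matrix, rows = taxa (rownames required), columns = sites.
#' @param alphabet \code{"DNA"} or \code{"standard"}.
#' @param partition optional character vector of length \code{ncol(x)} assigning
#'   each site to a named gene; blocks need not be contiguous but usually are.
#' @return an object of class \code{rad_alignment}.
#' @export
rad_alignment <- function(x, alphabet = c("DNA", "standard"), partition = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.matrix(x) || !is.character(x))
    stop("'x' must be a character matrix")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("rows must carry unique taxon names")
  x[] <- toupper(x)
  if (alphabet == "DNA") {
    bad <- setdiff(unique(as.vector(x)), names(.dna_ambiguity))
    if (length(bad))
      stop("unknown DNA state code(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(partition)) {
    if (length(partition) != ncol(x))
      stop("partition length must equal the number of sites")
    partition <- as.character(partition)
  }
  structure(list(matrix = x, alphabet = alphabet, partition = partition),
            class = "rad_alignment")
}

#' @export
print.rad_alignment <- function(x, ...) {
  cat(sprintf("rad_alignment: %d taxa x %d sites (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$alphabet))
  if (!is.null(x$partition))
    cat(sprintf("  partitioned into %d genes\n", length(unique(x$partition))))
  invisible(x)
}

#' @export
dim.rad_alignment <- function(x) dim(x$matrix)

#' Number of taxa / sites in an alignment
#' @param alignment a \code{rad_alignment}.
#' @return integer count.
#' @export
n_taxa <- function(alignment) nrow(alignment$matrix)

#' @rdname n_taxa
#' @export
n_sites <- function(alignment) ncol(alignment$matrix)

#' Subset an alignment by sites or taxa
#'
#' Keeps the partition map in register when sites are dropped.
#'
#' @param alignment a \code{rad_alignment}.
#' @param sites integer or logical site index.
#' @param taxa character vector of taxon names (or integer index).
#' @return a \code{rad_alignment}.
#' @export
subset_alignment <- function(alignment, sites = NULL, taxa = NULL) {
  m <- alignment$matrix
  p <- alignment$partition
  if (!is.null(taxa)) m <- m[taxa, , drop = FALSE]
  if (!is.null(sites)) {
    m <- m[, sites, drop = FALSE]
    if (!is.null(p)) p <- p[sites]
  }
  rad_alignment(m, alphabet = alignment$alphabet, partition = p)
}

#' Extract one gene from a partitioned alignment
#' @param alignment a partitioned \code{rad_alignment}.
#' @param gene gene name present in the partition.
#' @return a \code{rad_alignment} holding that gene's sites.
#' @export
gene_alignment <- function(alignment, gene) {
  if (is.null(alignment$partition)) stop("alignment has no partition")
  if (!gene %in% alignment$partition) stop("unknown gene: ", gene)
  subset_alignment(alignment, sites = alignment$partition == gene)
}

#' Gene names of a partitioned alignment
#' @param alignment a \code{rad_alignment}.
#' @return character vector (order of first appearance), or \code{NULL}.
#' @export
gene_names <- function(alignment) unique(alignment$partition)

# IUPAC ambiguity expansion used by the likelihood engine and composition
# statistics; gap and missing carry no information.
.dna_ambiguity <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
  "?" = c("A", "C", "G", "T"), "X" = c("A", "C", "G", "T"))

# states counted as observed (unambiguous) for composition / OV / TIGER
.is_observed <- function(states, alphabet) {
  if (alphabet == "DNA") states %in% c("A", "C", "G", "T")
  else !states %in% c("-", "?")
}

#' Read an alignment from FASTA, relaxed PHYLIP or NEXUS
#'
#' NEXUS \code{charset} commands (\code{charset name = a-b;}) found in a
#' \code{sets} or \code{assumptions} block are mapped onto the partition.
#'
#' @param path file path.
#' @param format \code{"fasta"}, \code{"phylip"} or \code{"nexus"}.
#' @param alphabet passed to [rad_alignment()].
#' @return a \code{rad_alignment}.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus"),
                           alphabet = "DNA") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  switch(format,
    fasta = .read_fasta(lines, alphabet),
    phylip = .read_phylip(lines, alphabet),
    nexus = .read_nexus_data(lines, alphabet))
}

.seq_to_states <- function(s) strsplit(gsub("\\s", "", s), "")[[1]]

.read_fasta <- function(lines, alphabet) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found")
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- lapply(seq_along(hdr), function(i) {
    .seq_to_states(paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
  })
  len <- lengths(seqs)
  if (length(unique(len)) != 1)
    stop("sequences differ in length")
  m <- do.call(rbind, seqs)
  rownames(m) <- nm
  rad_alignment(m, alphabet = alphabet)
}

.read_phylip <- function(lines, alphabet) {
  lines <- lines[nzchar(trimws(lines))]
  hd <- scan(text = lines[1], what = integer(), n = 2, quiet = TRUE)
  ntax <- hd[1]; nsite <- hd[2]
  if (length(lines) < ntax + 1) stop("truncated PHYLIP file")
  nm <- character(ntax)
  seqs <- vector("list", ntax)
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    nm[i] <- parts[1]
    seqs[[i]] <- .seq_to_states(paste(parts[-1], collapse = ""))
  }
  # interleaved continuation blocks
  k <- ntax + 2L
  while (k <= length(lines) && any(lengths(seqs) < nsite)) {
    for (i in seq_len(ntax)) {
      if (k > length(lines)) break
      seqs[[i]] <- c(seqs[[i]], .seq_to_states(lines[k]))
      k <- k + 1L
    }
  }
  if (any(lengths(seqs) != nsite))
    stop("PHYLIP sequence lengths do not match the header")
  m <- do.call(rbind, seqs)
  rownames(m) <- nm
  rad_alignment(m, alphabet = alphabet)
}

.strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

.read_nexus_data <- function(lines, alphabet) {
  txt <- .strip_nexus_comments(paste(lines, collapse = "\n"))
  mt <- regmatches(txt, regexpr("(?is)matrix.*?;", txt, perl = TRUE))
  if (!length(mt)) stop("no MATRIX command found in NEXUS file")
  body <- sub("(?is)^matrix", "", mt, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  nm <- sub("\\s.*$", "", rows)
  sq <- sub("^\\S+\\s+", "", rows)
  nm <- gsub("^'|'$", "", nm)
  seqs <- tapply(sq, factor(nm, levels = unique(nm)),
                 function(z) .seq_to_states(paste(z, collapse = "")))
  len <- lengths(seqs)
  if (length(unique(len)) != 1) stop("NEXUS rows differ in length")
  m <- do.call(rbind, seqs)
  rownames(m) <- names(seqs)
  part <- NULL
  cs <- regmatches(txt, gregexpr("(?i)charset\\s+[^;]+;", txt, perl = TRUE))[[1]]
  if (length(cs)) {
    part <- rep(NA_character_, ncol(m))
    for (cmd in cs) {
      cmd <- sub(";\\s*$", "", cmd)
      eq <- strsplit(cmd, "=")[[1]]
      gname <- trimws(sub("(?i)charset", "", eq[1], perl = TRUE))
      for (rg in strsplit(trimws(eq[2]), "\\s+")[[1]]) {
        ab <- as.integer(strsplit(rg, "-")[[1]])
        if (length(ab) == 1) ab <- c(ab, ab)
        part[ab[1]:ab[2]] <- gname
      }
    }
    if (anyNA(part)) stop("charsets do not cover every site")
  }
  rad_alignment(m, alphabet = alphabet, partition = part)
}

#' Write an alignment to FASTA, relaxed PHYLIP or NEXUS
#'
#' The NEXUS writer emits \code{charset} commands for a partitioned alignment
#' (blocks are written as explicit site ranges).
#'
#' @param alignment a \code{rad_alignment}.
#' @param path output file path.
#' @param format \code{"fasta"}, \code{"phylip"} or \code{"nexus"}.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(alignment, path,
                            format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  m <- alignment$matrix
  sq <- apply(m, 1, paste, collapse = "")
  out <- switch(format,
    fasta = as.vector(rbind(paste0(">", rownames(m)), sq)),
    phylip = c(sprintf("%d %d", nrow(m), ncol(m)),
               sprintf("%s  %s", rownames(m), sq)),
    nexus = {
      dt <- if (alignment$alphabet == "DNA") "DNA" else "STANDARD"
      x <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
             sprintf("FORMAT DATATYPE=%s MISSING=? GAP=-;", dt),
             "MATRIX", sprintf("%s  %s", rownames(m), sq), ";", "END;")
      if (!is.null(alignment$partition)) {
        p <- alignment$partition
        x <- c(x, "BEGIN SETS;",
               vapply(unique(p), function(g) {
                 idx <- which(p == g)
                 br <- c(0L, which(diff(idx) != 1L), length(idx))
                 rg <- vapply(seq_len(length(br) - 1L), function(i) {
                   a <- idx[br[i] + 1L]; b <- idx[br[i + 1L]]
                   if (a == b) as.character(a) else paste0(a, "-", b)
                 }, character(1))
                 sprintf("CHARSET %s = %s;", g, paste(rg, collapse = " "))
               }, character(1)),
               "END;")
      }
      x
    })
  writeLines(out, path)
  invisible(path)
}
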
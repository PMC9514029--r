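#' Poisson-corrected distance between two aligned peptides
#'
#' `p` is the mismatch fraction over columns where both sequences carry a
#' residue; the distance is `-ln(1 - p)`. `p >= 1` yields `Inf` (flagged
#' saturated).
#'
#' @param aa_a,aa_b aligned amino-acid strings of equal length, gaps as `-`.
#' @return Non-negative distance (possibly `Inf`).
#' @export
poisson_distance <- function(aa_a, aa_b) {
  if (nchar(aa_a) != nchar(aa_b)) stop("aligned lengths differ")
  a <- strsplit(aa_a, "")[[1]]; b <- strsplit(aa_b, "")[[1]]
  shared <- a != "-" & b != "-"
  if (!any(shared)) stop("no shared ungapped columns")
  p <- mean(a[shared] != b[shared])
  if (p >= 1) return(Inf)
  -log(1 - p)
}

#' Drop gap-rich alignment columns
#'
#' Removes columns whose gap fraction exceeds `max_gap_frac` (a simple
#' stand-in for heavier alignment-trimming tools).
#'
#' @param aligned named character vector of equal-length aligned peptides.
#' @param max_gap_frac maximum tolerated gap fraction per column.
#' @return The filtered alignment (same names).
#' @export
filter_gappy_columns <- function(aligned, max_gap_frac = 0.5) {
  chars <- do.call(rbind, strsplit(aligned, ""))
  keep <- colMeans(chars == "-") <= max_gap_frac
  stats::setNames(apply(chars[, keep, drop = FALSE], 1, paste,
                        collapse = ""), names(aligned))
}

#' Pairwise Poisson distance matrix of an alignment
#'
#' @param aligned named character vector of equal-length aligned peptides.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
poisson_dist_matrix <- function(aligned) {
  n <- length(aligned)
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- poisson_distance(aligned[[i]], aligned[[j]])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via `ape::nj`). Negative branch
#' lengths are clamped to zero with the deficit moved onto the sibling
#' branch, preserving path lengths between leaves through their parent.
#'
#' @param dm symmetric distance matrix with labels.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(dm)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- which(tr$edge[, 1L] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sib) > 0)
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Test whether a set of leaves is monophyletic under outgroup rooting
#'
#' @param tree an `ape::phylo` tree.
#' @param taxa leaf labels to test (must not include the outgroup).
#' @param outgroup leaf label used to root the tree.
#' @return `TRUE` iff `taxa` form a clade in the rooted tree.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  labs <- tree$tip.label
  unknown <- setdiff(c(taxa, outgroup), labs)
  if (length(unknown) > 0) stop("unknown label(s): ",
                                paste(unknown, collapse = ", "))
  if (outgroup %in% taxa) stop("outgroup cannot be part of the tested taxa")
  if (length(taxa) <= 1L) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips = taxa)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste(formatC(rownames(dm)[i], width = -10),
                     paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  invisible(path)
}
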
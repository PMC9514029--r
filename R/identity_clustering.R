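#' Pairwise amino-acid identity (CD-HIT convention)
#'
#' Identity is the number of identical residues in the best global alignment
#' with free end gaps (BLOSUM62, gap open 11 / extend 1) divided by the
#' length of the shorter sequence.
#'
#' @param a,b amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, scheme = scoring_scheme()) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "overlap")
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

# identities of one sequence against many representatives, vectorised
.identities_vs <- function(seq, reps, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(reps), Biostrings::AAString(seq),
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "overlap")
  Biostrings::nmatch(pa) / pmin(nchar(reps), nchar(seq))
}

#' Greedy incremental clustering at an identity threshold
#'
#' CD-HIT-style greedy clustering: sequences are sorted longest first (ties
#' by id), each sequence joins the first existing cluster whose
#' representative it matches at `>= threshold` identity, otherwise it founds
#' a new cluster. Membership is tested against the representative only, not
#' all members.
#'
#' @param seqs named character vector of peptides; ids must be unique.
#' @param threshold identity threshold (default 0.5, i.e. 50% amino-acid
#'   identity).
#' @param scheme a [scoring_scheme()].
#' @return List of clusters; each cluster is a list with
#'   `representative_id` (the longest member) and `member_ids`.
#' @export
greedy_cluster <- function(seqs, threshold = 0.5,
                           scheme = scoring_scheme()) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  if (length(seqs) == 0L) return(list())
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    joined <- FALSE
    if (length(reps) > 0L) {
      ident <- .identities_vs(seqs[[i]], reps, scheme)
      hit <- which(ident >= threshold)
      if (length(hit) > 0L) {
        j <- hit[1L]
        members[[j]] <- c(members[[j]], names(seqs)[i])
        joined <- TRUE
      }
    }
    if (!joined) {
      reps <- c(reps, seqs[[i]])
      members[[length(members) + 1L]] <- names(seqs)[i]
    }
  }
  lapply(seq_along(members), function(j)
    list(representative_id = members[[j]][1L], member_ids = members[[j]]))
}

#' Drop members of large clusters
#'
#' Sequences in clusters of more than `max_size` members are removed; the
#' rest survive. With the default `max_size = 10`, a cluster of exactly 10
#' is kept and one of 11 is removed entirely (the young-ERV exclusion rule).
#'
#' @param clusters list of clusters from [greedy_cluster()].
#' @param max_size largest surviving cluster size (default 10).
#' @return Character vector of surviving sequence ids.
#' @export
filter_large_clusters <- function(clusters, max_size = 10L) {
  stopifnot(max_size >= 1L)
  keep <- vapply(clusters, function(cl) length(cl$member_ids) <= max_size,
                 TRUE)
  out <- unlist(lapply(clusters[keep], `[[`, "member_ids"),
                use.names = FALSE)
  if (is.null(out)) character(0) else out
}

#' Cluster table in `.clstr` spirit
#'
#' @param clusters list of clusters from [greedy_cluster()].
#' @param seqs the clustered sequences (for identities to representative).
#' @param scheme a [scoring_scheme()].
#' @return data.frame with `cluster_id`, `representative`, `member`,
#'   `identity`.
#' @export
cluster_table <- function(clusters, seqs, scheme = scoring_scheme()) {
  rows <- lapply(seq_along(clusters), function(j) {
    cl <- clusters[[j]]
    ident <- vapply(cl$member_ids, function(m)
      if (m == cl$representative_id) 1.0
      else pairwise_identity(seqs[[m]], seqs[[cl$representative_id]], scheme),
      numeric(1))
    data.frame(cluster_id = j, representative = cl$representative_id,
               member = cl$member_ids, identity = unname(ident),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
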
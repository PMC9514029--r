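#' Scoring scheme for local protein alignment
#'
#' BLOSUM62 with affine gaps (open 11, extend 1) and the published
#' Karlin-Altschul parameters for that gapped scheme (`lambda` = 0.267 nats
#' per score unit, `K` = 0.041). Exact E-value parity with NCBI BLAST is not
#' a goal; these constants give BLAST-comparable threshold semantics.
#'
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = .blosum62(), gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Optimal local protein alignment (Smith-Waterman)
#'
#' Affine-gap local alignment under the scheme's substitution matrix.
#' Returns `NULL` when no positive-scoring alignment exists.
#'
#' @param query,subject amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id ids carried into the result.
#' @return One-row data.frame (`query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `raw_score`, `n_identical`, `aln_len`) or `NULL`.
#'   `aln_len` is the number of alignment columns (gaps included).
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           query_id = "query", subject_id = "subject") {
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "local")
  if (Biostrings::score(pa) <= 0) return(NULL)
  data.frame(
    query_id = query_id, subject_id = subject_id,
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa)),
    raw_score = Biostrings::score(pa),
    n_identical = Biostrings::nmatch(pa),
    aln_len = nchar(as.character(Biostrings::pattern(pa))),
    stringsAsFactors = FALSE)
}

# vectorised local-alignment raw scores of one query against many subjects
.sw_scores <- function(query, subjects, scheme) {
  if (length(subjects) == 0L) return(numeric(0))
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "local", scoreOnly = TRUE)
}

#' Bitscore and E-value from a raw alignment score
#'
#' `bitscore = (lambda * raw - ln K) / ln 2`;
#' `evalue = K * m * n * exp(-lambda * raw)`.
#'
#' @param raw_score raw score in substitution-matrix units (> 0).
#' @param query_len,db_len effective search-space dimensions (residues).
#' @param scheme a [scoring_scheme()].
#' @return list with `bitscore` and `evalue`.
#' @export
bit_and_evalue <- function(raw_score, query_len, db_len,
                           scheme = scoring_scheme()) {
  stopifnot(all(raw_score > 0))
  bits <- (scheme$lambda * raw_score - log(scheme$K)) / log(2)
  ev <- scheme$K * query_len * db_len * exp(-scheme$lambda * raw_score)
  list(bitscore = bits, evalue = ev)
}

# six-frame stop-split translated segments of a genome: one row per maximal
# stop-free codon run, with enough bookkeeping to map peptide coordinates
# back to the forward strand
.translated_segments <- function(genome, min_codons = 10L) {
  segs <- extract_orfs(genome, min_len_nt = 3L * min_codons,
                       require_both_stops = FALSE)
  segs
}

# genomic span of subject-peptide positions s_start..s_end within a segment
.segment_to_genomic <- function(seg, s_start, s_end) {
  if (seg$strand == "+") {
    gs <- seg$start + 3L * (s_start - 1L)
    ge <- seg$start + 3L * s_end - 1L
  } else {
    ge <- seg$end - 3L * (s_start - 1L)
    gs <- seg$end - 3L * s_end + 1L
  }
  c(gs, ge)
}

#' Translated protein-vs-genome search
#'
#' Aligns a protein query against all six-frame stop-split translated
#' segments of a genome (tBLASTn-style) and maps hits back to genomic
#' coordinates. Only the best hit per (contig, strand, frame) segment is
#' kept, and of overlapping hits the highest-scoring survives. Query cover
#' is the aligned query span divided by the query length.
#'
#' @param protein amino-acid query string.
#' @param genome an [genome()] object or named contig vector.
#' @param scheme a [scoring_scheme()].
#' @param evalue_threshold maximum reported E-value (default `1e-5`).
#' @param query_id id carried into the result.
#' @return data.frame of hits sorted by descending bitscore: alignment
#'   columns plus `contig`, `genomic_start`, `genomic_end`, `strand`,
#'   `query_cover`.
#' @export
translated_search <- function(protein, genome, scheme = scoring_scheme(),
                              evalue_threshold = 1e-5, query_id = "query") {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      raw_score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), n_identical = integer(0),
                      aln_len = integer(0), contig = character(0),
                      genomic_start = integer(0), genomic_end = integer(0),
                      strand = character(0), query_cover = numeric(0),
                      stringsAsFactors = FALSE)
  segs <- .translated_segments(genome)
  if (nrow(segs) == 0L) return(empty)
  m <- nchar(protein)
  n_db <- sum(nchar(segs$aa_seq))
  # minimum raw score implied by the E-value threshold: score the whole
  # segment set cheaply, align fully only what can pass
  smin <- (log(scheme$K * m * n_db) - log(evalue_threshold)) / scheme$lambda
  raw <- .sw_scores(protein, segs$aa_seq, scheme)
  cand <- which(raw >= smin)
  if (length(cand) == 0L) return(empty)
  rows <- lapply(cand, function(i) {
    seg <- segs[i, ]
    al <- smith_waterman(protein, seg$aa_seq, scheme, query_id = query_id,
                         subject_id = seg$orf_id)
    if (is.null(al)) return(NULL)
    be <- bit_and_evalue(al$raw_score, m, n_db, scheme)
    g <- .segment_to_genomic(seg, al$s_start, al$s_end)
    cbind(al[, c("query_id", "subject_id", "q_start", "q_end", "s_start",
                 "s_end", "raw_score")],
          data.frame(bitscore = be$bitscore, evalue = be$evalue,
                     n_identical = al$n_identical, aln_len = al$aln_len,
                     contig = seg$contig, genomic_start = g[1],
                     genomic_end = g[2], strand = seg$strand,
                     query_cover = (al$q_end - al$q_start + 1L) / m,
                     stringsAsFactors = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[out$evalue < evalue_threshold, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out <- out[order(-out$bitscore), , drop = FALSE]
  # cull: drop hits overlapping a better hit on the same contig/strand
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    ov <- out$contig[prior] == out$contig[i] &
      out$strand[prior] == out$strand[i] &
      out$genomic_start[prior] <= out$genomic_end[i] &
      out$genomic_end[prior] >= out$genomic_start[i]
    if (any(ov)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-mer self-dotplot of a nucleotide sequence
#'
#' Reports every pair of positions `(i, j)` with `i < j` whose k-mers are
#' identical on the forward strand (`strand == "+"`) or where the k-mer at
#' `j` is the reverse complement of the one at `i` (`strand == "-"`). The
#' trivial main diagonal is excluded. Tandem repeats appear as off-diagonal
#' bands at offsets equal to the repeat-unit length.
#'
#' @param seq nucleotide string.
#' @param k word size (>= 4; default 12).
#' @return data.frame with columns `i`, `j`, `strand`.
#' @export
self_dotplot <- function(seq, k = 12L) {
  if (k < 4L) stop("k must be >= 4")
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(i = integer(0), j = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (L < k) return(empty)
  starts <- seq_len(L - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  valid <- !grepl("N", words, fixed = TRUE)
  pair_up <- function(groups, strand) {
    res <- lapply(groups, function(g) {
      if (length(g) < 2L) return(NULL)
      cmb <- utils::combn(sort(g), 2L)
      data.frame(i = cmb[1, ], j = cmb[2, ], strand = strand,
                 stringsAsFactors = FALSE)
    })
    res <- res[!vapply(res, is.null, TRUE)]
    if (length(res) == 0L) return(empty)
    do.call(rbind, res)
  }
  fwd <- pair_up(split(starts[valid], words[valid]), "+")
  # reverse-strand matches: position j carries revcomp of the word at i
  rcwords <- vapply(words, function(w)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(w, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
  idx <- split(starts[valid], words[valid])
  rev_rows <- list()
  for (p in starts[valid]) {
    partners <- idx[[rcwords[p]]]
    partners <- partners[partners > p]
    if (length(partners))
      rev_rows[[length(rev_rows) + 1L]] <-
        data.frame(i = p, j = partners, strand = "-",
                   stringsAsFactors = FALSE)
  }
  rev_df <- if (length(rev_rows)) do.call(rbind, rev_rows) else empty
  out <- rbind(fwd, rev_df)
  out <- out[out$i < out$j, , drop = FALSE]
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
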
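#' Extract stop-flanked ORFs from all six frames of a genome
#'
#' An ORF is a maximal run of non-stop codons between two stop codons in one
#' of the six reading frames. The flanking stop codons delimit the ORF but
#' are not part of it: the reported span and length cover the sense codons
#' only. Runs touching a contig end are reported by default (getorf-style
#' stop-to-stop behaviour); set `require_both_stops = TRUE` to demand a stop
#' codon on both sides. Codons containing `N` translate to `X` and do not
#' terminate an ORF, but a run of more than `max_ambig_run` consecutive
#' ambiguous codons (an assembly-gap signature) splits the ORF.
#'
#' @param genome an [genome()] object or named character vector of contigs.
#' @param min_len_nt minimum ORF length in nucleotides (default 240, i.e.
#'   80 codons); must be a positive multiple of 3.
#' @param require_both_stops if `TRUE`, runs touching a contig boundary are
#'   discarded.
#' @param max_ambig_run maximum tolerated run of consecutive all-ambiguous
#'   codons inside an ORF.
#' @return data.frame with one row per ORF: `orf_id`, `contig`, `start`,
#'   `end` (1-based inclusive, forward-strand coordinates), `strand`,
#'   `frame` (0/1/2, offset within the reading strand), `length_nt`,
#'   `nt_seq`, `aa_seq`. Sorted by (contig, start, strand, frame).
#' @export
extract_orfs <- function(genome, min_len_nt = 240L,
                         require_both_stops = FALSE, max_ambig_run = 10L) {
  contigs <- .as_contigs(genome)
  if (min_len_nt <= 0L || min_len_nt %% 3L != 0L)
    stop("min_len_nt must be a positive multiple of 3")
  min_codons <- min_len_nt %/% 3L
  out <- vector("list", length(contigs) * 6L)
  k <- 0L
  for (cid in names(contigs)) {
    fwd <- contigs[[cid]]
    L <- nchar(fwd)
    rev <- revcomp(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      for (frame in 0:2) {
        runs <- .codon_runs(s, frame, min_codons, require_both_stops,
                            max_ambig_run)
        if (nrow(runs) == 0L) next
        # runs carry 1-based nt coords on the reading strand
        if (strand == "+") {
          gstart <- runs$nt_start
          gend <- runs$nt_end
        } else {
          gstart <- L - runs$nt_end + 1L
          gend <- L - runs$nt_start + 1L
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          contig = cid, start = gstart, end = gend, strand = strand,
          frame = frame, length_nt = runs$nt_end - runs$nt_start + 1L,
          nt_seq = runs$nt_seq, aa_seq = runs$aa_seq,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    res <- data.frame(orf_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_nt = integer(0), nt_seq = character(0),
                      aa_seq = character(0), stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$contig, res$start, res$strand, res$frame), ,
             drop = FALSE]
  res <- cbind(orf_id = sprintf("%s:%d-%d(%s)f%d", res$contig, res$start,
                                res$end, res$strand, res$frame),
               res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# maximal non-stop codon runs in one frame of one strand of one contig;
# coordinates are on the given (reading) strand
.codon_runs <- function(seq, frame, min_codons, require_both_stops,
                        max_ambig_run) {
  L <- nchar(seq)
  ncod <- (L - frame) %/% 3L
  empty <- data.frame(nt_start = integer(0), nt_end = integer(0),
                      nt_seq = character(0), aa_seq = character(0))
  if (ncod < min_codons) return(empty)
  starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  ambig <- is.na(aa)
  aa[ambig] <- "X"
  is_stop <- aa == "*"
  # break points: stop codons, plus long ambiguous runs
  brk <- is_stop
  if (any(ambig)) {
    r <- rle(ambig)
    pos <- cumsum(r$lengths)
    long <- which(r$values & r$lengths > max_ambig_run)
    for (i in long) brk[(pos[i] - r$lengths[i] + 1L):pos[i]] <- TRUE
  }
  r <- rle(brk)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- !r$values & r$lengths >= min_codons
  if (require_both_stops) {
    # a run must be preceded and followed by a stop codon (not a gap break
    # or the contig edge)
    ok_left <- begs > 1L & is_stop[pmax(begs - 1L, 1L)]
    ok_right <- ends < ncod & is_stop[pmin(ends + 1L, ncod)]
    keep <- keep & ok_left & ok_right
  }
  if (!any(keep)) return(empty)
  begs <- begs[keep]; ends <- ends[keep]
  nt_start <- starts[begs]
  nt_end <- starts[ends] + 2L
  data.frame(
    nt_start = nt_start, nt_end = nt_end,
    nt_seq = substring(seq, nt_start, nt_end),
    aa_seq = vapply(seq_along(begs), function(i)
      paste(aa[begs[i]:ends[i]], collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}

#' Convert an ORF table to FASTA records
#'
#' Record ids are the `orf_id` column, which encodes contig, coordinates,
#' strand and frame so records stay traceable; [parse_orf_id()] recovers the
#' coordinates.
#'
#' @param orfs ORF table from [extract_orfs()].
#' @param which `"aa"` for peptides, `"nt"` for nucleotide sequences.
#' @return Named character vector suitable for [write_fasta()].
#' @export
orf_to_fasta <- function(orfs, which = c("aa", "nt")) {
  which <- match.arg(which)
  seqs <- if (which == "aa") orfs$aa_seq else orfs$nt_seq
  stats::setNames(as.character(seqs), orfs$orf_id)
}

#' Parse an ORF id back into its coordinates
#'
#' @param orf_id character vector of ids as produced by [extract_orfs()].
#' @return data.frame with `contig`, `start`, `end`, `strand`, `frame`.
#' @export
parse_orf_id <- function(orf_id) {
  m <- regmatches(orf_id,
                  regexec("^(.+):(\\d+)-(\\d+)\\(([+-])\\)f([0-2])$", orf_id))
  bad <- vapply(m, length, 1L) != 6L
  if (any(bad)) stop("unparseable orf_id: ", orf_id[bad][1L])
  data.frame(
    contig = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    frame = as.integer(vapply(m, `[`, "", 6L)),
    stringsAsFactors = FALSE)
}
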
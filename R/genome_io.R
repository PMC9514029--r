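#' Construct a genome object
#'
#' A genome is an ordered set of named contig sequences plus a species label.
#' Sequences are stored as plain uppercase character strings over
#' `{A,C,G,T,N}`.
#'
#' @param contigs named character vector of nucleotide sequences.
#' @param species species label (free text).
#' @return An object of class `erv_genome` with elements `contigs` and
#'   `species`.
#' @export
genome <- function(contigs, species = "unknown") {
  if (length(contigs) == 0L || sum(nchar(contigs)) == 0L)
    stop("genome must contain at least one non-empty contig")
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs))))
    stop("contig ids must be unique and non-empty")
  structure(list(contigs = toupper(contigs), species = species),
            class = "erv_genome")
}

#' @export
print.erv_genome <- function(x, ...) {
  cat(sprintf("<erv_genome> species=%s, %d contig(s), %d bp total\n",
              x$species, length(x$contigs), sum(nchar(x$contigs))))
  invisible(x)
}

# accept either an erv_genome or a bare named character vector
.as_contigs <- function(genome) {
  if (inherits(genome, "erv_genome")) return(genome$contigs)
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  stop("expected an erv_genome or a named character vector of contigs")
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file (nucleotide or amino acid).
#' @return Named character vector of uppercase sequences, one element per
#'   record, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    return(character(0))
  if (!startsWith(first, ">"))
    stop("malformed FASTA (line 1): expected '>' header in ", path)
  set <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(set)
  if (any(w == 0L))
    stop("empty sequence for record '", names(set)[w == 0L][1L], "' in ", path)
  seqs <- toupper(as.character(set))
  # keep only the id token of the header, like most tools do
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) > 0 && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all records need non-empty ids")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read genome features from a GFF3 file
#'
#' Coordinates are kept 1-based inclusive as in GFF3. Output rows are sorted
#' by (contig, start).
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `kind` (the GFF3 type column) and `name` (the `Name` attribute, or the
#'   `ID` when `Name` is absent).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kind = character(0), name = character(0),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  if (!any(!startsWith(lines, "#") & nzchar(lines))) return(empty)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty)
  if (any(GenomicRanges::start(gr) > GenomicRanges::end(gr)))
    stop("feature with start > end in ", path)
  nm <- as.character(gr$Name)
  if (is.null(gr$Name)) nm <- rep(NA_character_, length(gr))
  id <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else as.character(gr$ID)
  nm <- ifelse(is.na(nm) | !nzchar(nm), id, nm)
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
    kind   = as.character(gr$type),
    name   = nm,
    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write features to a GFF3 file
#'
#' @param features data.frame as returned by [read_gff()].
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(features, path, source = "ervscreen") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0) {
    if (any(features$start > features$end)) stop("feature with start > end")
    rows <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                    features$contig, source, features$kind,
                    as.integer(features$start), as.integer(features$end),
                    features$strand,
                    make.unique(features$name, sep = "_"), features$name)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Any codon containing `N` translates to `X`; stop codons translate to `*`.
#'
#' @param nt nucleotide string over `{A,C,G,T,N}`, length divisible by 3.
#' @return Amino-acid string of length `nchar(nt)/3`.
#' @export
translate_nt <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (grepl("[^ACGTN]", nt)) stop("invalid nucleotide character")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement
#'
#' @param nt nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse complement; `revcomp(revcomp(x)) == x`.
#' @export
revcomp <- function(nt) {
  nt <- toupper(nt)
  if (grepl("[^ACGTN]", nt)) stop("invalid nucleotide character")
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}
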
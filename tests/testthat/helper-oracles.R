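# independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals

# six-frame stop-split ORF scanner: split each frame's codon string on stop
# codons and report runs >= min_len_nt/3 codons
brute_orfs <- function(contigs, min_len_nt = 240, both_stops = FALSE) {
  GC <- Biostrings::GENETIC_CODE
  rows <- list()
  for (cn in names(contigs)) {
    for (strand in c("+", "-")) {
      s <- contigs[[cn]]
      if (strand == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      L <- nchar(s)
      for (f in 0:2) {
        ncod <- (L - f) %/% 3
        if (ncod < 1) next
        st <- f + 3 * (seq_len(ncod) - 1) + 1
        cods <- substring(s, st, st + 2)
        aa <- GC[cods]
        aa[is.na(aa)] <- "X"
        bound <- c(0, which(aa == "*"), ncod + 1)
        for (k in seq_len(length(bound) - 1)) {
          beg <- bound[k] + 1
          end <- bound[k + 1] - 1
          if (end < beg || (end - beg + 1) * 3 < min_len_nt) next
          if (both_stops && (bound[k] == 0 || bound[k + 1] == ncod + 1))
            next
          nt_s <- f + 3 * (beg - 1) + 1
          nt_e <- f + 3 * end
          gs <- if (strand == "+") nt_s else L - nt_e + 1
          ge <- if (strand == "+") nt_e else L - nt_s + 1
          rows[[length(rows) + 1]] <- data.frame(
            contig = cn, start = gs, end = ge, strand = strand, frame = f,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand, out$frame), , drop = FALSE]
}

# exhaustive enumeration of all legal local profile-HMM paths; recursion
# explores every move explicitly (no DP)
enum_viterbi <- function(profile, seq) {
  S <- log2(sweep(profile$match_emissions, 2, profile$background, "/"))
  tt <- profile$transitions
  tMI <- log2(tt[["MI"]] / tt[["MM"]]); tIM <- log2(tt[["IM"]] / tt[["MM"]])
  tII <- log2(tt[["II"]] / tt[["MM"]]); tMD <- log2(tt[["MD"]] / tt[["MM"]])
  tDM <- log2(tt[["DM"]] / tt[["MM"]]); tDD <- log2(tt[["DD"]] / tt[["MM"]])
  a <- match(strsplit(seq, "")[[1]], AA20)
  a[is.na(a)] <- 0
  M <- nrow(S); L <- length(a)
  emit <- function(j, i) if (a[i] > 0) S[j, a[i]] else 0
  best <- -Inf
  rec_m <- function(i, j, sc) {
    # in match state j having just emitted position i; any match can exit
    best <<- max(best, sc)
    if (i < L && j < M) rec_m(i + 1, j + 1, sc + emit(j + 1, i + 1))
    if (i < L) rec_i(i + 1, j, sc + tMI)
    if (j < M) rec_d(i, j + 1, sc + tMD)
  }
  rec_i <- function(i, j, sc) {
    if (i < L) rec_i(i + 1, j, sc + tII)
    if (i < L && j < M) rec_m(i + 1, j + 1, sc + tIM + emit(j + 1, i + 1))
  }
  rec_d <- function(i, j, sc) {
    if (j < M) rec_d(i, j + 1, sc + tDD)
    if (i < L && j < M) rec_m(i + 1, j + 1, sc + tDM + emit(j + 1, i + 1))
  }
  for (i0 in seq_len(L)) for (j0 in seq_len(M))
    rec_m(i0, j0, emit(j0, i0))
  best
}

# exhaustive affine-gap local alignment score by recursive path exploration
# (gap of length k costs open + k * extend, matching the package scheme)
enum_local_align <- function(q, s, submat, open = 11, extend = 1) {
  qa <- strsplit(q, "")[[1]]; sa <- strsplit(s, "")[[1]]
  nq <- length(qa); ns <- length(sa)
  best <- 0
  # state: last move ("d" diagonal, "u" gap in subject, "l" gap in query)
  rec <- function(i, j, sc, last) {
    best <<- max(best, sc)
    if (i < nq && j < ns)
      rec(i + 1, j + 1, sc + submat[qa[i + 1], sa[j + 1]], "d")
    if (i < nq)
      rec(i + 1, j, sc - (if (last == "u") extend else open + extend), "u")
    if (j < ns)
      rec(i, j + 1, sc - (if (last == "l") extend else open + extend), "l")
  }
  for (i0 in seq_len(nq)) for (j0 in seq_len(ns))
    rec(i0, j0, submat[qa[i0], sa[j0]], "d")
  best
}

# single-mutant enumeration oracle for Nei-Gojobori site counts
oracle_sites <- function(codon) {
  GC <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      mut <- ch; mut[pos] <- b
      m <- paste(mut, collapse = "")
      if (GC[[m]] == "*") next
      nonstop <- nonstop + 1
      if (GC[[m]] == GC[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

# all-orderings pathway enumeration oracle for substitution counts
oracle_differences <- function(a, b) {
  GC <- Biostrings::GENETIC_CODE
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    pp <- list()
    gen <- function(prefix, rest) {
      if (length(rest) == 0) { pp[[length(pp) + 1]] <<- prefix; return() }
      for (k in seq_along(rest)) gen(c(prefix, rest[k]), rest[-k])
    }
    gen(integer(0), pos)
    pp
  }
  res <- matrix(NA_real_, length(perms), 2)
  valid <- logical(length(perms))
  for (r in seq_along(perms)) {
    cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
    for (p in perms[[r]]) {
      nxt <- cur; nxt[p] <- cb[p]
      if (GC[[paste(nxt, collapse = "")]] == "*") ok <- FALSE
      if (GC[[paste(cur, collapse = "")]] ==
          GC[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[r, ] <- c(sd, nd); valid[r] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, length(perms))
  c(sd = mean(res[use, 1]), nd = mean(res[use, 2]))
}
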
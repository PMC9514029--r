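# --- codon bookkeeping ------------------------------------------------------

.codon_table <- function() {
  if (is.null(.erv_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .erv_cache$codons <- list(all = names(gc), aa = gc,
                              sense = names(gc)[gc != "*"])
  }
  .erv_cache$codons
}

.split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(toupper(nt), seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of a codon
#'
#' For each of the three positions the fraction of synonymous changes among
#' the single-nucleotide changes that do not create a stop codon is
#' accumulated; `s` is the sum of the three fractions and `n = 3 - s`.
#'
#' @param codon a sense codon (3-mer over ACGT).
#' @return Named numeric vector `c(s = , n = )`.
#' @export
count_sites <- function(codon) {
  ct <- .codon_table()
  codon <- toupper(codon)
  if (!codon %in% ct$sense) stop("not a sense codon: ", codon)
  tab <- .sites_table()
  c(s = tab[[codon]], n = 3 - tab[[codon]])
}

.sites_table <- function() {
  if (!is.null(.erv_cache$sites)) return(.erv_cache$sites)
  ct <- .codon_table()
  nts <- c("A", "C", "G", "T")
  s <- vapply(ct$sense, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    total <- 0
    for (pos in 1:3) {
      syn <- 0L; valid <- 0L
      for (b in setdiff(nts, ch[pos])) {
        mut <- ch; mut[pos] <- b
        mcod <- paste(mut, collapse = "")
        if (ct$aa[[mcod]] == "*") next
        valid <- valid + 1L
        if (ct$aa[[mcod]] == ct$aa[[cod]]) syn <- syn + 1L
      }
      if (valid > 0L) total <- total + syn / valid
    }
    total
  }, numeric(1))
  .erv_cache$sites <- s
  s
}

#' Pathway-averaged substitution counts between two codons
#'
#' For `k` differing positions, every one of the `k!` orderings of the
#' single-nucleotide steps is walked; orderings passing through a stop codon
#' are excluded (if all do, the average falls back to all orderings). The
#' synonymous (`sd`) and nonsynonymous (`nd`) step counts are averaged over
#' the retained orderings; `sd + nd` equals the nucleotide Hamming distance.
#'
#' @param codon_a,codon_b sense codons.
#' @return Named numeric vector `c(sd = , nd = )`.
#' @export
count_differences <- function(codon_a, codon_b) {
  ct <- .codon_table()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!codon_a %in% ct$sense) stop("not a sense codon: ", codon_a)
  if (!codon_b %in% ct$sense) stop("not a sense codon: ", codon_b)
  tabs <- .diff_tables()
  c(sd = tabs$sd[codon_a, codon_b], nd = tabs$nd[codon_a, codon_b])
}

.perms <- list(
  `1` = matrix(1L, 1, 1),
  `2` = rbind(c(1L, 2L), c(2L, 1L)),
  `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.pathway_counts <- function(a, b, aa) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diffpos <- which(ca != cb)
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- .perms[[as.character(k)]]
  res <- matrix(NA_real_, nrow(perms), 2L)
  ok <- logical(nrow(perms))
  for (r in seq_len(nrow(perms))) {
    cur <- ca; sd <- 0; nd <- 0; valid <- TRUE
    for (pos in diffpos[perms[r, ]]) {
      nxt <- cur; nxt[pos] <- cb[pos]
      aa_cur <- aa[[paste(cur, collapse = "")]]
      aa_nxt <- aa[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") valid <- FALSE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[r, ] <- c(sd, nd)
    ok[r] <- valid
  }
  use <- if (any(ok)) ok else rep(TRUE, nrow(perms))
  c(sd = mean(res[use, 1L]), nd = mean(res[use, 2L]))
}

.diff_tables <- function() {
  if (!is.null(.erv_cache$diffs)) return(.erv_cache$diffs)
  ct <- .codon_table()
  n <- length(ct$sense)
  sdm <- matrix(0, n, n, dimnames = list(ct$sense, ct$sense))
  ndm <- sdm
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    pc <- .pathway_counts(ct$sense[i], ct$sense[j], ct$aa)
    sdm[i, j] <- pc[["sd"]]; ndm[i, j] <- pc[["nd"]]
  }
  .erv_cache$diffs <- list(sd = sdm, nd = ndm)
  .erv_cache$diffs
}

# --- codon pair alignment ---------------------------------------------------

#' Build a gap-free in-frame codon pair alignment from two coding sequences
#'
#' Translates both sequences, aligns the peptides globally (BLOSUM62, gap
#' open 11 / extend 1), back-threads the codons through the peptide
#' alignment, and drops every column containing a gap, a stop codon or an
#' ambiguous base.
#'
#' @param nt_a,nt_b in-frame coding nucleotide sequences.
#' @param scheme a [scoring_scheme()].
#' @return List of class `codon_alignment` with equal-length character
#'   vectors `codons_a` and `codons_b`.
#' @export
codon_alignment <- function(nt_a, nt_b, scheme = scoring_scheme()) {
  aa_a <- translate_nt(nt_a); aa_b <- translate_nt(nt_b)
  ca <- .split_codons(nt_a); cb <- .split_codons(nt_b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("\\*", "X", aa_a)),
    Biostrings::AAString(gsub("\\*", "X", aa_b)),
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "global")
  pat <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  # the aligned views clip residues aligned to terminal gaps; offset into
  # each sequence accordingly
  ia <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  ib <- Biostrings::start(Biostrings::subject(pa)) - 1L
  keep_a <- integer(0); keep_b <- integer(0)
  for (col in seq_along(pat)) {
    if (pat[col] != "-") ia <- ia + 1L
    if (sub[col] != "-") ib <- ib + 1L
    if (pat[col] != "-" && sub[col] != "-") {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  codons_a <- ca[keep_a]; codons_b <- cb[keep_b]
  sense <- .codon_table()$sense
  ok <- codons_a %in% sense & codons_b %in% sense
  structure(list(codons_a = codons_a[ok], codons_b = codons_b[ok]),
            class = "codon_alignment")
}

.as_codon_alignment <- function(aln) {
  if (inherits(aln, "codon_alignment")) return(aln)
  if (is.list(aln) && !is.null(aln$codons_a) && !is.null(aln$codons_b))
    return(structure(aln[c("codons_a", "codons_b")],
                     class = "codon_alignment"))
  stop("expected a codon_alignment")
}

# per-codon site/difference vectors used by the estimator and the bootstrap
.ng_percodon <- function(aln) {
  aln <- .as_codon_alignment(aln)
  L <- length(aln$codons_a)
  if (L < 1L || length(aln$codons_b) != L)
    stop("codon alignment must have equal positive length")
  stab <- .sites_table()
  dtab <- .diff_tables()
  sA <- stab[aln$codons_a]; sB <- stab[aln$codons_b]
  idx <- cbind(match(aln$codons_a, rownames(dtab$sd)),
               match(aln$codons_b, colnames(dtab$sd)))
  list(L = L,
       s = (sA + sB) / 2, n = 3 - (sA + sB) / 2,
       sd = dtab$sd[idx], nd = dtab$nd[idx])
}

.jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log1p(-4 * p / 3), NA_real_)
}

#' Nei-Gojobori dN/dS estimate for a codon pair alignment
#'
#' Average synonymous (`S`) and nonsynonymous (`N`) site counts over the two
#' sequences, pathway-averaged difference counts, proportions
#' `pS = sum(sd)/S`, `pN = sum(nd)/N`, and Jukes-Cantor-corrected rates
#' `d = -(3/4) ln(1 - (4/3) p)`. A rate is `NA` (flagged undefined) when its
#' proportion reaches 3/4 or its site count is zero.
#'
#' @param aln a [codon_alignment()] (or list with `codons_a`, `codons_b`).
#' @return List of class `selection_result`: `L_codons`, `S_sites`,
#'   `N_sites`, `sd`, `nd`, `pS`, `pN`, `dS`, `dN`, `dnds`,
#'   `percent_identity`.
#' @export
nei_gojobori <- function(aln) {
  pc <- .ng_percodon(aln)
  S <- sum(pc$s); N <- sum(pc$n)
  sd_tot <- sum(pc$sd); nd_tot <- sum(pc$nd)
  pS <- if (S > 0) sd_tot / S else NA_real_
  pN <- if (N > 0) nd_tot / N else NA_real_
  dS <- if (is.na(pS)) NA_real_ else .jc_correct(pS)
  dN <- if (is.na(pN)) NA_real_ else .jc_correct(pN)
  aln <- .as_codon_alignment(aln)
  aa_a <- strsplit(translate_nt(paste(aln$codons_a, collapse = "")), "")[[1]]
  aa_b <- strsplit(translate_nt(paste(aln$codons_b, collapse = "")), "")[[1]]
  structure(list(
    L_codons = pc$L, S_sites = S, N_sites = N, sd = sd_tot, nd = nd_tot,
    pS = pS, pN = pN, dS = dS, dN = dN,
    dnds = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_,
    percent_identity = 100 * mean(aa_a == aa_b)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> L=%d codons, dN=%.4f dS=%.4f dN/dS=%s, %%id=%.1f\n",
    x$L_codons, x$dN, x$dS,
    if (is.na(x$dnds)) "NA" else sprintf("%.3f", x$dnds),
    x$percent_identity))
  invisible(x)
}

#' Codon-based Z-test of neutrality
#'
#' Tests H0: dN = dS with `Z = (dS - dN) / sqrt(Var(dS) + Var(dN))`, the
#' variances estimated by bootstrap over codon columns (resampled with
#' replacement, seeded). The one-sided `purifying` alternative is dN < dS;
#' `positive` is dN > dS.
#'
#' @param aln a [codon_alignment()].
#' @param alternative `"purifying"`, `"positive"` or `"two.sided"`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return List with `Z`, `p_value`, `var_dS`, `var_dN`, `n_boot_used` and
#'   the point estimates `dS`, `dN`.
#' @export
z_test_neutrality <- function(aln, alternative = c("purifying", "positive",
                                                   "two.sided"),
                              n_boot = 1000L, seed = 1L) {
  alternative <- match.arg(alternative)
  pc <- .ng_percodon(aln)
  est <- nei_gojobori(aln)
  if (!is.na(est$dS) && !is.na(est$dN) && est$dS == 0 && est$dN == 0) {
    return(list(Z = 0, p_value = if (alternative == "two.sided") 1 else 1,
                var_dS = 0, var_dN = 0, n_boot_used = 0L,
                dS = est$dS, dN = est$dN))
  }
  set.seed(seed)
  L <- pc$L
  idx <- matrix(sample.int(L, L * n_boot, replace = TRUE), nrow = L)
  Sb <- colSums(matrix(pc$s[idx], nrow = L))
  Nb <- colSums(matrix(pc$n[idx], nrow = L))
  sdb <- colSums(matrix(pc$sd[idx], nrow = L))
  ndb <- colSums(matrix(pc$nd[idx], nrow = L))
  dSb <- .jc_correct(ifelse(Sb > 0, sdb / Sb, NA_real_))
  dNb <- .jc_correct(ifelse(Nb > 0, ndb / Nb, NA_real_))
  ok <- is.finite(dSb) & is.finite(dNb)
  if (sum(ok) < 10L) {
    return(list(Z = NA_real_, p_value = NA_real_, var_dS = NA_real_,
                var_dN = NA_real_, n_boot_used = sum(ok),
                dS = est$dS, dN = est$dN))
  }
  vS <- stats::var(dSb[ok]); vN <- stats::var(dNb[ok])
  se <- sqrt(vS + vN)
  if (!is.finite(se) || se == 0) {
    p <- if (isTRUE(all.equal(est$dS, est$dN))) 1 else NA_real_
    return(list(Z = if (is.na(p)) NA_real_ else 0, p_value = p,
                var_dS = vS, var_dN = vN, n_boot_used = sum(ok),
                dS = est$dS, dN = est$dN))
  }
  Z <- (est$dS - est$dN) / se
  p <- switch(alternative,
              purifying = stats::pnorm(Z, lower.tail = FALSE),
              positive = stats::pnorm(Z),
              two.sided = 2 * stats::pnorm(abs(Z), lower.tail = FALSE))
  list(Z = Z, p_value = p, var_dS = vS, var_dN = vN,
       n_boot_used = sum(ok), dS = est$dS, dN = est$dN)
}

#' Percent identity of two aligned amino-acid sequences
#'
#' Columns gapped in both sequences are removed first; every remaining
#' column (including one-sided gaps) counts in the denominator.
#'
#' @param aa_a,aa_b aligned amino-acid strings of equal length, gaps as `-`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aa_a, aa_b) {
  if (nchar(aa_a) != nchar(aa_b)) stop("aligned lengths differ")
  a <- strsplit(aa_a, "")[[1]]; b <- strsplit(aa_b, "")[[1]]
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) stop("alignment has no non-gap columns")
  100 * sum(a == b & a != "-") / length(a)
}
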
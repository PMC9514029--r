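# Default state-transition probabilities shared by every profile position.
# Rows-of-one constraint: MM+MI+MD = IM+II = DM+DD = 1.
.default_transitions <- c(MM = 0.90, MI = 0.05, MD = 0.05,
                          IM = 0.60, II = 0.40, DM = 0.70, DD = 0.30)

#' Build a protein profile HMM from a seed alignment
#'
#' Columns where at least half the sequences carry a residue become match
#' states; the remaining columns are treated as insertions. Match emissions
#' are column residue frequencies smoothed toward the uniform distribution
#' with total pseudocount mass `pseudocount` (so duplicated sequences leave
#' the profile unchanged); the insert state emits the overall (smoothed)
#' background frequencies.
#' Transition probabilities are position-independent
#' (M->M 0.9, M->I = M->D 0.05, I->M 0.6, D->M 0.7).
#'
#' During scanning ([viterbi_local()]), emissions are scored in bits as
#' `log2(e/background)` and transitions as `log2(t/t_MM)`, so the all-match
#' path carries no transition cost and entry into / exit from any match
#' state is free. A profile's score against its own ungapped consensus is
#' therefore exactly the summed per-position emission log-odds.
#'
#' @param seed named character vector of aligned amino-acid sequences of
#'   equal length; gaps as `-`.
#' @param pseudocount Laplace smoothing constant added per residue.
#' @param name profile name.
#' @return An object of class `erv_profile`.
#' @export
build_profile <- function(seed, pseudocount = 1.0, name = "profile") {
  if (length(seed) < 1L) stop("need at least one seed sequence")
  w <- unique(nchar(seed))
  if (length(w) != 1L) stop("seed sequences must be aligned (equal length)")
  if (w == 0L) stop("alignment has zero columns")
  chars <- do.call(rbind, strsplit(toupper(seed), ""))
  residue <- matrix(chars %in% .AA20, nrow = nrow(chars))
  occupancy <- colMeans(residue)
  match_cols <- which(occupancy >= 0.5)
  if (length(match_cols) == 0L) stop("no column reaches 50% residue occupancy")
  M <- length(match_cols)
  freq <- matrix(0, nrow = M, ncol = 20L,
                 dimnames = list(NULL, .AA20))
  for (k in seq_len(M)) {
    col <- chars[, match_cols[k]]
    tab <- table(factor(col[col %in% .AA20], levels = .AA20))
    freq[k, ] <- as.numeric(tab) / max(sum(tab), 1L)
  }
  em <- (freq + pseudocount / 20) / (1 + pseudocount)
  all_res <- chars[chars %in% .AA20]
  bg_f <- as.numeric(table(factor(all_res, levels = .AA20))) /
    max(length(all_res), 1L)
  bg <- (bg_f + pseudocount / 20) / (1 + pseudocount)
  names(bg) <- .AA20
  structure(list(name = name, M = M, match_emissions = em,
                 insert_emissions = bg, transitions = .default_transitions,
                 background = bg, calibration = NULL,
                 consensus = paste(.AA20[apply(em, 1, which.max)],
                                   collapse = "")),
            class = "erv_profile")
}

#' @export
print.erv_profile <- function(x, ...) {
  cat(sprintf("<erv_profile> %s: M=%d, %s\n", x$name, x$M,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("Gumbel(lambda=%.3f, mu=%.2f)",
                           x$calibration[["lambda"]], x$calibration[["mu"]])))
  invisible(x)
}

# emission bit-score matrix and transition bit scores for the DP kernel
.profile_scores <- function(profile) {
  S <- log2(sweep(profile$match_emissions, 2, profile$background, "/"))
  t <- profile$transitions
  list(M = profile$M, S = S,
       tMI = log2(t[["MI"]] / t[["MM"]]),
       tIM = log2(t[["IM"]] / t[["MM"]]),
       tII = log2(t[["II"]] / t[["MM"]]),
       tMD = log2(t[["MD"]] / t[["MM"]]),
       tDM = log2(t[["DM"]] / t[["MM"]]),
       tDD = log2(t[["DD"]] / t[["MM"]]))
}

.aa_to_int <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], .AA20)
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Best local alignment of a peptide against a profile HMM
#'
#' Maximum-scoring local alignment (any subsequence of `seq` against any
#' subpath of match/insert/delete states) under the scoring model described
#' in [build_profile()]. Residues outside the 20-letter alphabet (e.g. `X`)
#' score 0 bits.
#'
#' @param profile an `erv_profile`.
#' @param seq amino-acid string.
#' @return list with `score` (bits), `seq_start`, `seq_end` (1-based
#'   inclusive peptide span of the best alignment).
#' @export
viterbi_local <- function(profile, seq) {
  if (nchar(seq) < 1L) stop("empty sequence")
  sc <- .profile_scores(profile)
  r <- viterbi_local_cpp(sc$S, .aa_to_int(seq), sc$tMI, sc$tIM, sc$tII,
                         sc$tMD, sc$tDM, sc$tDD)
  list(score = r$score, seq_start = r$seq_start, seq_end = r$seq_end)
}

# method-of-moments Gumbel fit: Var = pi^2/(6 lambda^2), E = mu + gamma/lambda
.fit_gumbel_moments <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate score variance: cannot calibrate")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  c(lambda = lambda, mu = mu)
}

# upper tail P(S >= s) of the fitted Gumbel
.gumbel_upper <- function(s, lambda, mu) {
  -expm1(-exp(-lambda * (s - mu)))
}

#' Calibrate a profile's score null distribution
#'
#' Scores `n_random` peptides sampled i.i.d. from the profile's background
#' composition and fits a Gumbel (type-I extreme value) distribution to the
#' scores by the method of moments. The fitted `(lambda, mu)` are stored in
#' the profile and drive the E-values reported by [scan_profiles()].
#'
#' @param profile an `erv_profile`.
#' @param n_random number of background peptides (>= 100).
#' @param random_len length of each background peptide.
#' @param seed RNG seed for the background sample.
#' @return The profile with `calibration` filled in.
#' @export
calibrate_profile <- function(profile, n_random = 1000L, random_len = 400L,
                              seed = 20260920L) {
  if (n_random < 100L) stop("n_random must be >= 100")
  set.seed(seed)
  bg <- profile$background
  scores <- vapply(seq_len(n_random), function(i) {
    pep <- paste(sample(.AA20, random_len, replace = TRUE, prob = bg),
                 collapse = "")
    viterbi_local(profile, pep)$score
  }, numeric(1))
  profile$calibration <- .fit_gumbel_moments(scores)
  profile
}

#' Scan peptides against a set of calibrated profiles
#'
#' The E-value of a hit with score `s` is `N_seqs * P(S >= s)` under the
#' profile's calibrated Gumbel null; only hits with `E < evalue_threshold`
#' are reported, sorted by E-value.
#'
#' @param profiles list of calibrated `erv_profile` objects.
#' @param seqs named character vector of peptides.
#' @param evalue_threshold report threshold (default `1e-5`).
#' @return data.frame with `profile`, `seq_id`, `seq_start`, `seq_end`,
#'   `bitscore`, `evalue`.
#' @export
scan_profiles <- function(profiles, seqs, evalue_threshold = 1e-5) {
  if (inherits(profiles, "erv_profile")) profiles <- list(profiles)
  for (p in profiles)
    if (is.null(p$calibration))
      stop("profile '", p$name, "' is not calibrated")
  empty <- data.frame(profile = character(0), seq_id = character(0),
                      seq_start = integer(0), seq_end = integer(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  n <- length(seqs)
  rows <- list()
  for (p in profiles) {
    lam <- p$calibration[["lambda"]]; mu <- p$calibration[["mu"]]
    for (i in seq_len(n)) {
      v <- viterbi_local(p, seqs[[i]])
      e <- n * .gumbel_upper(v$score, lam, mu)
      if (e < evalue_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          profile = p$name, seq_id = names(seqs)[i],
          seq_start = v$seq_start, seq_end = v$seq_end,
          bitscore = v$score, evalue = e, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$evalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
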
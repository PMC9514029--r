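test_that("profile construction follows column occupancy and smoothing", {
  p1 <- build_profile(c(s = "ACDEF"))
  expect_equal(p1$M, 5L)
  expect_equal(unname(apply(p1$match_emissions, 1, function(r)
    names(r)[which.max(r)])), c("A", "C", "D", "E", "F"))
  expect_true(all(abs(rowSums(p1$match_emissions) - 1) < 1e-9))
  expect_equal(sum(p1$background), 1, tolerance = 1e-9)

  # two identical sequences give the same profile as one
  p2 <- build_profile(c(a = "ACDEF", b = "ACDEF"))
  expect_equal(p2$match_emissions, p1$match_emissions)

  # a column gapped in 2/3 sequences becomes an insert column
  p3 <- build_profile(c(a = "AC-EF", b = "AC-EF", c = "ACDEF"))
  expect_equal(p3$M, 4L)

  expect_error(build_profile(character(0)), "at least one")
  expect_error(build_profile(c(a = "AC", b = "ACD")), "equal length")
})

test_that("self-hit score equals summed emission log-odds and is maximal", {
  seed <- c(a = "WCHKM", b = "WCHKM", c = "WCHRM")
  p <- build_profile(seed)
  S <- log2(sweep(p$match_emissions, 2, p$background, "/"))
  cons <- "WCHKM"
  self <- viterbi_local(p, cons)
  expected <- sum(S[cbind(1:5, match(strsplit(cons, "")[[1]], AA20))])
  expect_equal(self$score, expected, tolerance = 1e-10)
  expect_equal(c(self$seq_start, self$seq_end), c(1L, 5L))
  # residues absent from the seed never beat the consensus
  expect_lte(viterbi_local(p, "PPPPP")$score, self$score + 1e-12)
  # 'X' residues score background (0 bits)
  expect_equal(viterbi_local(p, "XXXXX")$score, 0, tolerance = 1e-12)
})

test_that("Viterbi equals exhaustive path enumeration (binary alphabet)", {
  set.seed(31)
  seeds <- list(
    build_profile(c(x = "C"), name = "m1"),
    build_profile(c(x = "AC", y = "AA"), name = "m2"),
    build_profile(c(x = "CAC", y = "CCC"), name = "m3"),
    build_profile(c(x = "ACCA", y = "ACAA", z = "CCCA"), name = "m4"))
  peptides <- unlist(lapply(1:6, function(L)
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")))
  for (p in seeds) for (pep in peptides) {
    expect_equal(viterbi_local(p, pep)$score, enum_viterbi(p, pep),
                 tolerance = 1e-9,
                 label = sprintf("M=%d vs '%s'", p$M, pep))
  }
})

test_that("Viterbi equals enumeration on random wider-alphabet peptides", {
  set.seed(77)
  p <- build_profile(c(a = "MKVH", b = "MKIH", c = "MRVH"), name = "m4b")
  for (i in 1:50) {
    pep <- random_peptide(sample(3:6, 1))
    expect_equal(viterbi_local(p, pep)$score, enum_viterbi(p, pep),
                 tolerance = 1e-9, label = pep)
  }
})

test_that("Gumbel moment fit recovers known parameters and shifts correctly", {
  set.seed(13)
  # draws from Gumbel(lambda = 0.7, mu = 5) by inversion
  u <- runif(2000)
  x <- 5 - log(-log(u)) / 0.7
  fit <- ervscreen:::.fit_gumbel_moments(x)
  expect_equal(unname(fit["lambda"]), 0.7, tolerance = 0.1 * 0.7)
  expect_equal(unname(fit["mu"]), 5, tolerance = 0.5)
  # location equivariance: shifting scores shifts mu, lambda unchanged
  fit2 <- ervscreen:::.fit_gumbel_moments(x + 10)
  expect_equal(unname(fit2["lambda"]), unname(fit["lambda"]),
               tolerance = 1e-12)
  expect_equal(unname(fit2["mu"]), unname(fit["mu"]) + 10,
               tolerance = 1e-9)
  expect_error(ervscreen:::.fit_gumbel_moments(rep(3, 200)), "degenerate")
})

test_that("calibration is stable and scanning honours the E-value threshold", {
  set.seed(8)
  cons <- random_peptide(60)
  seed <- vapply(1:6, function(i) mutate_peptide(cons, 0.1), character(1))
  names(seed) <- paste0("s", 1:6)
  p <- build_profile(seed, name = "dom")
  p500 <- calibrate_profile(p, n_random = 500, random_len = 200, seed = 2)
  p1000 <- calibrate_profile(p, n_random = 1000, random_len = 200, seed = 2)
  expect_lt(abs(p500$calibration[["lambda"]] - p1000$calibration[["lambda"]]) /
              p1000$calibration[["lambda"]], 0.2)

  expect_error(scan_profiles(list(p), c(q = cons)), "not calibrated")
  seqs <- c(planted = paste0("GG", cons, "GG"),
            noise = random_peptide(100))
  hits <- scan_profiles(list(p1000), seqs)
  expect_true("planted" %in% hits$seq_id)
  expect_lt(hits$evalue[hits$seq_id == "planted"][1], 1e-5)
  expect_false("noise" %in% hits$seq_id)
  # superset at infinite threshold; E-values monotone in score
  all_hits <- scan_profiles(list(p1000), seqs, evalue_threshold = Inf)
  expect_true(all(hits$seq_id %in% all_hits$seq_id))
  expect_true(all(diff(all_hits$bitscore[order(all_hits$evalue)]) <= 0))
  expect_equal(nrow(scan_profiles(list(p1000), character(0))), 0L)
})

test_that("sequences containing the consensus outscore shuffled versions", {
  set.seed(19)
  cons <- random_peptide(40)
  p <- calibrate_profile(build_profile(
    setNames(vapply(1:5, function(i) mutate_peptide(cons, 0.08),
                    character(1)), paste0("s", 1:5)), name = "sh"),
    n_random = 300, random_len = 120, seed = 3)
  wins <- 0L
  for (i in 1:100) {
    flank1 <- random_peptide(20); flank2 <- random_peptide(20)
    with_cons <- paste0(flank1, cons, flank2)
    shuffled <- paste0(flank1,
                       paste(sample(strsplit(cons, "")[[1]]), collapse = ""),
                       flank2)
    if (viterbi_local(p, with_cons)$score >=
        viterbi_local(p, shuffled)$score) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
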
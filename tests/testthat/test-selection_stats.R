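test_that("site counts match the single-mutant enumeration oracle", {
  expect_equal(count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(count_sites("TGG"), c(s = 0, n = 3))
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (cod in sense)
    expect_equal(count_sites(cod), oracle_sites(cod), tolerance = 1e-12,
                 label = cod)
  expect_error(count_sites("TAA"), "sense")
})

test_that("difference counts match the pathway enumeration oracle", {
  expect_equal(count_differences("GCT", "GCT"), c(sd = 0, nd = 0))
  expect_equal(count_differences("GCT", "GCC"), c(sd = 1, nd = 0))
  expect_equal(count_differences("AAA", "AGA"), c(sd = 0, nd = 1))
  # spot-check two- and three-position pairs against the oracle; the
  # exhaustive 61x61 sweep runs in the acceptance suite
  set.seed(73)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (i in 1:40) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    got <- count_differences(a, b)
    want <- oracle_differences(a, b)
    expect_equal(got, want, tolerance = 1e-12, label = paste(a, b))
    # conservation: sd + nd equals the nucleotide Hamming distance
    expect_equal(unname(sum(got)),
                 sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  }
  expect_error(count_differences("TAA", "AAA"), "sense")
})

test_that("nei_gojobori agrees with direct enumeration on short alignments", {
  set.seed(79)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (i in 1:20) {
    L <- sample(2:5, 1)
    ca <- sample(sense, L, TRUE); cb <- sample(sense, L, TRUE)
    ng <- nei_gojobori(list(codons_a = ca, codons_b = cb))
    S <- sum((vapply(ca, function(x) oracle_sites(x)["s"], 1) +
                vapply(cb, function(x) oracle_sites(x)["s"], 1)) / 2)
    d <- rowSums(vapply(seq_len(L), function(k)
      oracle_differences(ca[k], cb[k]), c(sd = 1, nd = 1)))
    expect_equal(ng$S_sites, S, tolerance = 1e-9)
    expect_equal(ng$N_sites, 3 * L - S, tolerance = 1e-9)
    expect_equal(ng$sd, unname(d["sd"]), tolerance = 1e-9)
    expect_equal(ng$nd, unname(d["nd"]), tolerance = 1e-9)
  }
  # identical sequences: dN = dS = 0
  ca <- sample(sense, 50, TRUE)
  ng0 <- nei_gojobori(list(codons_a = ca, codons_b = ca))
  expect_equal(ng0$dS, 0)
  expect_equal(ng0$dN, 0)
  expect_equal(ng0$percent_identity, 100)
})

test_that("S + N equals 3L and the Jukes-Cantor correction saturates", {
  set.seed(83)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  ca <- sample(sense, 100, TRUE)
  ng <- nei_gojobori(list(codons_a = ca, codons_b = ca))
  expect_lte(ng$S_sites + ng$N_sites, 300 + 1e-6)
  # without stop-neighbour exclusions s + n is exactly 3 per codon
  expect_equal(unname(sum(count_sites("GGG"))), 3)
  # saturated proportions are flagged undefined, not an error
  expect_true(is.na(ervscreen:::.jc_correct(0.8)))
})

test_that("codon alignment back-threads through peptide alignment offsets", {
  set.seed(89)
  core <- random_sense_codons(80)
  # one sequence carries extra codons on both ends (terminal-gap case)
  nt_a <- core
  nt_b <- paste0(random_sense_codons(7), core, random_sense_codons(5))
  aln <- codon_alignment(nt_a, nt_b)
  expect_equal(length(aln$codons_a), 80L)
  expect_equal(mean(aln$codons_a == aln$codons_b), 1.0)
})

test_that("the neutrality Z-test behaves at the boundaries and is seeded", {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  set.seed(97)
  ca <- sample(sense, 60, TRUE)
  same <- list(codons_a = ca, codons_b = ca)
  zt <- z_test_neutrality(same, "purifying")
  expect_equal(zt$p_value, 1)

  anc <- random_sense_codons(200)
  der <- evolve_codon_seq(anc, ds = 0.1, omega = 0.1)
  aln <- codon_alignment(anc, der)
  z1 <- z_test_neutrality(aln, "purifying", n_boot = 500, seed = 7)
  z2 <- z_test_neutrality(aln, "purifying", n_boot = 500, seed = 7)
  expect_identical(z1, z2)
  z3 <- z_test_neutrality(aln, "purifying", n_boot = 500, seed = 8)
  expect_false(identical(z1$p_value, z3$p_value))
  # strong purifying signal is detected
  expect_lt(z1$p_value, 0.05)
  expect_gt(z1$Z, 0)
  # two-sided p is twice the smaller tail
  z2s <- z_test_neutrality(aln, "two.sided", n_boot = 500, seed = 7)
  expect_equal(z2s$p_value, 2 * z1$p_value, tolerance = 1e-12)
})

test_that("percent identity counts one-sided gaps in the denominator", {
  expect_equal(percent_identity("MKVH", "MKVH"), 100)
  expect_equal(percent_identity("AC-D", "ACED"), 75)
  # columns gapped in both sequences are dropped first
  expect_equal(percent_identity("AC--D", "AC-ED"), 75)
  expect_error(percent_identity("AC", "ACD"), "lengths differ")
})
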
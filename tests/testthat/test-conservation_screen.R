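test_that("cross-species pairing takes best hits and is monotone in cutoffs", {
  set.seed(401)
  base1 <- random_sense_codons(150)
  base2 <- random_sense_codons(150)
  mk_orfs <- function(seqs, tag) {
    data.frame(orf_id = sprintf("c%s:%d-%d(+)f0", tag, seq_along(seqs) * 1000,
                                seq_along(seqs) * 1000 + 449),
               contig = paste0("c", tag), start = seq_along(seqs) * 1000,
               end = seq_along(seqs) * 1000 + 449, strand = "+", frame = 0,
               length_nt = 450, nt_seq = seqs,
               aa_seq = vapply(seqs, translate_nt, character(1)),
               stringsAsFactors = FALSE)
  }
  orfs_a <- mk_orfs(c(base1, base2), "A")
  orfs_b <- mk_orfs(c(evolve_codon_seq(base1, 0.1, 0.1),
                      evolve_codon_seq(base2, 0.1, 0.1)), "B")
  pairs <- pair_cross_species(orfs_a, orfs_b, bitscore_min = 100)
  expect_equal(nrow(pairs), 2L)
  # each gene pairs with its own ortholog (first with first etc.)
  expect_equal(sub(".*:(\\d+)-.*", "\\1", pairs$orf_a),
               sub(".*:(\\d+)-.*", "\\1", pairs$orf_b))
  # each B-ORF used at most once
  expect_equal(anyDuplicated(pairs$orf_b), 0L)
  # relaxing bitscore_min never removes pairs
  loose <- pair_cross_species(orfs_a, orfs_b, bitscore_min = 0)
  expect_true(all(pairs$orf_a %in% loose$orf_a))
  # unrelated sequences produce no pairs at the strict E threshold
  none <- pair_cross_species(mk_orfs(base1, "A"),
                             mk_orfs(random_sense_codons(150), "B"))
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(pair_cross_species(orfs_a[0, ], orfs_b)), 0L)
})

test_that("known-gene exclusion removes by annotation and by protein hit", {
  set.seed(409)
  cds <- random_sense_codons(120)
  orfs <- data.frame(
    orf_id = c("c1:100-459(+)f0", "c1:5000-5359(+)f0"),
    contig = "c1", start = c(100L, 5000L), end = c(459L, 5359L),
    strand = "+", frame = 0L, length_nt = 360L,
    nt_seq = c(cds, random_sense_codons(120)),
    aa_seq = c(translate_nt(cds),
               translate_nt(random_sense_codons(120))),
    stringsAsFactors = FALSE)
  orfs$nt_seq[2] <- cds  # same peptide planted at a second locus
  orfs$aa_seq[2] <- translate_nt(cds)
  pairs <- data.frame(orf_a = orfs$orf_id, orf_b = orfs$orf_id,
                      stringsAsFactors = FALSE)
  feats <- data.frame(contig = "c1", start = 50L, end = 500L, strand = "+",
                      kind = "gene", name = "KNOWN1",
                      stringsAsFactors = FALSE)

  # annotation overlap on the exclusion list removes the first pair only
  ex1 <- exclude_annotated(pairs, orfs, orfs, feats, feats,
                           exclusion_list = "KNOWN1")
  expect_equal(nrow(ex1$pairs), 1L)
  expect_equal(ex1$log$reason, "annotated_gene_overlap")
  expect_equal(ex1$log$trigger, "KNOWN1")

  # a gene NOT on the exclusion list does not trigger removal
  ex2 <- exclude_annotated(pairs, orfs, orfs, feats, feats,
                           exclusion_list = "OTHER")
  expect_equal(nrow(ex2$pairs), 2L)

  # known-protein similarity removes both loci carrying the peptide
  db <- setNames(translate_nt(cds), "known_prot")
  ex3 <- exclude_annotated(pairs, orfs, orfs, feats[0, ], feats[0, ],
                           known_protein_db = db)
  expect_equal(nrow(ex3$pairs), 0L)
  expect_true(all(ex3$log$reason == "known_protein_hit"))

  # empty list and db: identity
  ex4 <- exclude_annotated(pairs, orfs, orfs, feats[0, ], feats[0, ])
  expect_equal(ex4$pairs, pairs)
})

test_that("lineage specificity distinguishes ortholog, far copy and absence", {
  set.seed(419)
  cand_cds <- random_sense_codons(150)
  cand <- translate_nt(cand_cds)
  marker_cds <- random_sense_codons(150)
  marker <- translate_nt(marker_cds)
  flank <- function(x) paste0("TAA", x, "TGA")

  # ortholog 2 kb from the marker on the same contig
  og_near <- genome(c(c1 = paste0(
    random_dna(1000), flank(marker_cds), random_dna(2000),
    flank(ervscreen:::.backtranslate(mutate_peptide(cand, 0.1))),
    random_dna(1000))), species = "og1")
  v1 <- lineage_specificity("cand", cand, list(og = list(genome = og_near)),
                            marker, proximity_max = 1e6)
  expect_equal(v1$verdict, "ortholog_found")
  expect_lte(v1$min_marker_distance, 3000)

  # high-identity copy far beyond proximity_max (different contig)
  og_far <- genome(c(c1 = paste0(random_dna(500), flank(marker_cds),
                                 random_dna(500)),
                     c2 = paste0(random_dna(500), flank(cand_cds),
                                 random_dna(500))), species = "og2")
  v2 <- lineage_specificity("cand", cand, list(og = list(genome = og_far)),
                            marker)
  expect_equal(v2$verdict, "lineage_specific")
  expect_gte(v2$n_cover_hits, 1L)

  # marker absent
  og_none <- genome(c(c1 = random_dna(3000)), species = "og3")
  v3 <- lineage_specificity("cand", cand, list(og = list(genome = og_none)),
                            marker)
  expect_equal(v3$verdict, "marker_absent")

  # no outgroups: empty verdicts
  v4 <- lineage_specificity("cand", cand, list(), marker)
  expect_equal(nrow(v4), 0L)

  # query-cover boundary: a hit covering 59% fails, 60% passes
  part60 <- substr(cand_cds, 1, 3 * 90)  # 90 of 150 codons = 0.60
  og_part <- genome(c(c1 = paste0(random_dna(999), flank(marker_cds),
                                  random_dna(999), flank(part60),
                                  random_dna(500))), species = "og4")
  v5 <- lineage_specificity("cand", cand, list(og = list(genome = og_part)),
                            marker, cover_min = 0.6)
  v6 <- lineage_specificity("cand", cand, list(og = list(genome = og_part)),
                            marker, cover_min = 0.61)
  expect_equal(v5$verdict, "ortholog_found")
  expect_equal(v6$verdict, "lineage_specific")
})

test_that("motif check reports presence, positions and wildcard handling", {
  mc <- motif_check("MKYVDDWK", c(rt_catalytic = "YXDD"))
  expect_true(mc$present)
  expect_equal(mc$positions, "3")
  mc2 <- motif_check("MKYVAAWK", c(rt_catalytic = "YXDD", other = "WK"))
  expect_equal(mc2$present, c(FALSE, TRUE))
  expect_equal(mc2$positions[2], "7")
  peptide_no_d <- "MKYVAAWK"
  expect_false(motif_check(peptide_no_d, c(m = "DD"))$present)
  expect_error(motif_check("MK", setNames("DD", "")), "named")
})
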
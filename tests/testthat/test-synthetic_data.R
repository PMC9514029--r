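test_that("the generator is deterministic and keeps its books", {
  cfg <- small_sim_config(seed = 301)
  a1 <- simulate_ancestor(cfg)
  a2 <- simulate_ancestor(cfg)
  expect_identical(a1, a2)
  expect_equal(sum(a1$truth$class == "young_erv"),
               cfg$young_family$copy_number)
  expect_equal(sum(a1$truth$class == "domesticated"),
               cfg$domesticated$n_copies)
  expect_equal(sum(a1$truth$class == "decoy_known"), 1L)

  sp1 <- speciate(a1, cfg)
  sp2 <- speciate(a1, cfg)
  expect_identical(sp1, sp2)
  # every A-side domesticated gene has exactly one linked B-side ortholog
  da <- sp1$truth[sp1$truth$class == "domesticated" &
                    sp1$truth$species == "A", ]
  db <- sp1$truth[sp1$truth$class == "domesticated" &
                    sp1$truth$species == "B", ]
  expect_setequal(da$ortholog, db$name)
})

test_that("planted coordinates index the planted sequences", {
  cfg <- small_sim_config(seed = 303)
  anc <- simulate_ancestor(cfg)
  g <- anc$genome$contigs
  doms <- anc$truth[anc$truth$class == "domesticated", ]
  for (r in seq_len(nrow(doms))) {
    nt <- revcomp(substr(g[[doms$contig[r]]], doms$start[r], doms$end[r]))
    aa <- translate_nt(nt)
    expect_false(grepl("*", aa, fixed = TRUE))
    # flanking stop codons delimit the planted ORF in its frame
    up <- revcomp(substr(g[[doms$contig[r]]], doms$end[r] + 1L,
                         doms$end[r] + 3L))
    dn <- revcomp(substr(g[[doms$contig[r]]], doms$start[r] - 3L,
                         doms$start[r] - 1L))
    expect_true(up %in% c("TAA", "TAG", "TGA"))
    expect_true(dn %in% c("TAA", "TAG", "TGA"))
    # catalytic motif ablated per configuration at the RT-domain site
    rt <- anc$extras$rt_region
    site <- rt[1L] + anc$extras$motif_at - 1L
    expect_false(grepl("Y.DD", substr(aa, site, site + 3L)))
  }
  # young-copy coordinates slice out near-identical copies of the master
  # ORF (copies may carry chance nonsense mutations, as real young ERVs do)
  young <- anc$truth[anc$truth$class == "young_erv", ]
  master <- strsplit(anc$extras$young_master_orf, "")[[1]]
  for (r in seq_len(nrow(young))) {
    slice <- strsplit(substr(g[[young$contig[r]]], young$start[r],
                             young$end[r]), "")[[1]]
    expect_equal(length(slice), length(master))
    expect_gte(mean(slice == master),
               cfg$young_family$intra_identity - 0.01)
  }
  # emitted GFF3 round-trips the feature table
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff(anc$features, tmp)
  back <- read_gff(tmp)
  expect_equal(back[, c("contig", "start", "end", "strand", "kind")],
               anc$features[, c("contig", "start", "end", "strand",
                                "kind")])
})

test_that("young family copies stay near the configured identity", {
  cfg <- small_sim_config(seed = 307)
  anc <- simulate_ancestor(cfg)
  g <- anc$genome$contigs
  young <- anc$truth[anc$truth$class == "young_erv", ]
  seqs <- vapply(seq_len(nrow(young)), function(r)
    substr(g[[young$contig[r]]], young$start[r], young$end[r]), character(1))
  nt_ident <- function(x, y) {
    a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
    mean(a == b)
  }
  for (i in seq_along(seqs)[-1])
    expect_gte(nt_ident(seqs[[1]], seqs[[i]]),
               cfg$young_family$intra_identity - 0.01)
})

test_that("domesticated ORFs score above the scan threshold at generation", {
  fx <- default_fixture()
  anc <- fx$ancestor
  doms <- anc$truth[anc$truth$class == "domesticated", ]
  g <- anc$genome$contigs
  peps <- setNames(vapply(seq_len(nrow(doms)), function(r)
    translate_nt(revcomp(substr(g[[doms$contig[r]]], doms$start[r],
                                doms$end[r]))), character(1)), doms$name)
  hits <- scan_profiles(fx$profiles["rt_like"], peps)
  expect_setequal(hits$seq_id, doms$name)
  expect_true(all(hits$evalue < 1e-5))
})

test_that("speciation limit cases behave as configured", {
  cfg <- small_sim_config(seed = 311)
  anc <- simulate_ancestor(cfg)
  # omega -> 0: descendant peptides identical, nucleotides may differ
  nt0 <- anc$extras$dom_cds[[1]]
  ev <- evolve_codon_seq(nt0, ds = 0.2, omega = 1e-9)
  expect_identical(translate_nt(ev), translate_nt(nt0))
  expect_false(identical(ev, nt0))
  # zero branch length: genomes identical to the ancestor
  cfg0 <- small_sim_config(seed = 311)
  cfg0$divergence$branch_length_syn <- 0
  sp0 <- speciate(anc, cfg0)
  expect_identical(sp0$genome_a$contigs, anc$genome$contigs)
  expect_identical(sp0$genome_b$contigs, anc$genome$contigs)
})

test_that("outgroup construction honours the has_ortholog switch", {
  cfg <- small_sim_config(seed = 313)
  anc <- simulate_ancestor(cfg)
  og0 <- make_outgroup(anc, cfg)  # default: no ortholog
  expect_false(is.null(og0$planted_erv))
  # the planted unrelated copy is not on the marker contig
  expect_false(og0$planted_erv$contig == og0$marker_span$contig)

  cfg1 <- cfg; cfg1$outgroup$has_ortholog <- TRUE
  og1 <- make_outgroup(anc, cfg1)
  expect_null(og1$planted_erv)
  # the tandem array region still carries the (evolved) ortholog: its
  # translation aligns to the ancestral domesticated peptide
  doms <- anc$truth[anc$truth$class == "domesticated", ][1, ]
  nt <- revcomp(substr(og1$genome$contigs[[doms$contig]], doms$start,
                       doms$end))
  al <- smith_waterman(translate_nt(nt),
                       translate_nt(anc$extras$dom_cds[[1]]))
  expect_gt(al$n_identical / nchar(translate_nt(nt)), 0.5)
})
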
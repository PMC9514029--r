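# shared fixtures, built lazily once per test run

.fixture_env <- new.env()

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_peptide <- function(aa, p) {
  ch <- strsplit(aa, "")[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

# the default study-conditions fixture (full-size) and its screen report
default_fixture <- function() {
  if (is.null(.fixture_env$fx))
    .fixture_env$fx <- simulate_screen_fixture(seed = 101)
  .fixture_env$fx
}

default_screen_report <- function() {
  if (is.null(.fixture_env$report))
    .fixture_env$report <- run_screen(fixture_screen_config(default_fixture()))
  .fixture_env$report
}

# reduced-scale configuration: identical biology (divergence, omega, tandem
# triplet, marker), smaller contigs and fewer young copies, for replicated
# simulation experiments
small_sim_config <- function(seed) {
  sim_config(seed = seed,
             contig_lengths = c(chr1 = 30000L, chr2 = 16000L),
             young_family = list(copy_number = 4L, intra_identity = 0.98,
                                 element_length = 2000L, orf_fraction = 0.75))
}

# domesticated ortholog codon pairs straight from a speciated bundle
dom_ortholog_alignments <- function(anc, sp) {
  doms <- anc$truth[anc$truth$class == "domesticated", ]
  lapply(seq_len(nrow(doms)), function(r) {
    nt <- lapply(list(sp$genome_a, sp$genome_b), function(g) {
      x <- substr(g$contigs[[doms$contig[r]]], doms$start[r], doms$end[r])
      if (doms$strand[r] == "-") x <- ervscreen::revcomp(x)
      x
    })
    codon_alignment(nt[[1]], nt[[2]])
  })
}
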
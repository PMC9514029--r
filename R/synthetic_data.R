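# --- low-level sequence generation helpers ---------------------------------

.NTS <- c("A", "C", "G", "T")
# transition partner of each base
.TS <- c(A = "G", G = "A", C = "T", T = "C")

#' Random nucleotide sequence
#' @param n length in bp.
#' @param gc GC content (default 0.5, i.e. uniform over ACGT).
#' @return Nucleotide string.
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(.NTS, n, replace = TRUE, prob = p), collapse = "")
}

#' Random in-frame coding sequence of sense codons
#' @param n_codons number of codons.
#' @return Nucleotide string without stop codons.
#' @export
random_sense_codons <- function(n_codons) {
  sense <- .codon_table()$sense
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# back-translate a peptide choosing synonymous codons uniformly at random
.backtranslate <- function(aa) {
  ct <- .codon_table()
  by_aa <- split(names(ct$aa), unname(ct$aa))
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

# substitute a fraction p of residues with random different amino acids
.mutate_aa <- function(aa, p) {
  chars <- strsplit(aa, "")[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

# per-site neutral substitution with transition/transversion bias
.mutate_neutral <- function(nt, p, kappa = 2.0) {
  if (p <= 0) return(nt)
  v <- strsplit(nt, "")[[1]]
  cand <- which(v %in% .NTS)
  hit <- cand[stats::runif(length(cand)) < p]
  if (length(hit) == 0L) return(nt)
  is_ts <- stats::runif(length(hit)) < kappa / (kappa + 2)
  tv_pick <- stats::runif(length(hit)) < 0.5
  for (k in seq_along(hit)) {
    i <- hit[k]
    if (is_ts[k]) {
      v[i] <- .TS[[v[i]]]
    } else {
      tvs <- setdiff(.NTS, c(v[i], .TS[[v[i]]]))
      v[i] <- if (tv_pick[k]) tvs[1L] else tvs[2L]
    }
  }
  paste(v, collapse = "")
}

# kappa-weighted probability that a random single-nucleotide proposal on a
# codon is synonymous / nonsynonymous (stop-creating proposals are counted
# in the denominator; they are always rejected during evolution)
.proposal_fractions <- function(kappa) {
  key <- sprintf("propfrac_%g", kappa)
  if (!is.null(.erv_cache[[key]])) return(.erv_cache[[key]])
  ct <- .codon_table()
  syn <- stats::setNames(numeric(length(ct$sense)), ct$sense)
  for (cod in ct$sense) {
    ch <- strsplit(cod, "")[[1]]
    tot <- 0
    for (pos in 1:3) for (b in setdiff(.NTS, ch[pos])) {
      w <- if (b == .TS[[ch[pos]]]) kappa else 1
      mut <- ch; mut[pos] <- b
      mcod <- paste(mut, collapse = "")
      if (ct$aa[[mcod]] == ct$aa[[cod]]) tot <- tot + w
    }
    # each site's proposals normalised by (kappa + 2); three sites per codon
    syn[cod] <- tot / (3 * (kappa + 2))
  }
  .erv_cache[[key]] <- syn
  syn
}

#' Evolve an in-frame coding sequence under purifying selection
#'
#' Codon evolution by rejection sampling of single-nucleotide proposals:
#' synonymous proposals are always accepted, nonsynonymous proposals with
#' probability `omega`, stop-creating proposals never. The number of
#' proposals is calibrated from the sequence's codon composition and the
#' ts/tv-weighted synonymous proposal fraction so that `ds` is the expected
#' synonymous divergence of the branch on the Nei-Gojobori scale.
#'
#' @param nt in-frame coding sequence of sense codons.
#' @param ds target synonymous substitutions per synonymous site for this
#'   branch.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS).
#' @param kappa transition/transversion rate ratio.
#' @return The evolved nucleotide string (same length, still stop-free).
#' @export
evolve_codon_seq <- function(nt, ds, omega, kappa = 2.0) {
  if (ds <= 0) return(nt)
  ct <- .codon_table()
  codons <- .split_codons(nt)
  if (!all(codons %in% ct$sense))
    stop("input must consist of sense codons")
  L <- length(codons)
  S <- sum(.sites_table()[codons])
  # expected proportion of synonymous differences for the target ds
  p_target <- 0.75 * (1 - exp(-4 * ds / 3))
  psyn <- mean(.proposal_fractions(kappa)[codons])
  n_prop <- stats::rpois(1L, p_target * S / psyn)
  w_ts <- kappa / (kappa + 2)
  for (k in seq_len(n_prop)) {
    i <- sample.int(L, 1L)
    pos <- sample.int(3L, 1L)
    ch <- strsplit(codons[i], "")[[1]]
    if (stats::runif(1) < w_ts) {
      b <- .TS[[ch[pos]]]
    } else {
      tvs <- setdiff(.NTS, c(ch[pos], .TS[[ch[pos]]]))
      b <- tvs[sample.int(2L, 1L)]
    }
    mut <- ch; mut[pos] <- b
    mcod <- paste(mut, collapse = "")
    if (ct$aa[[mcod]] == "*") next
    if (ct$aa[[mcod]] == ct$aa[[codons[i]]] || stats::runif(1) < omega)
      codons[i] <- mcod
  }
  paste(codons, collapse = "")
}

# a seed alignment: consensus plus n-1 variants at substitution rate p
.make_seed_alignment <- function(consensus, n = 8L, p = 0.1) {
  seqs <- c(consensus,
            vapply(seq_len(n - 1L), function(i) .mutate_aa(consensus, p),
                   character(1)))
  stats::setNames(seqs, sprintf("seed%02d", seq_len(n)))
}

# --- configuration ----------------------------------------------------------

#' Configuration of the synthetic two-species genome pair
#'
#' Defaults are the study conditions every end-to-end test runs under: a
#' 30-copy young ERV family at 98% mutual identity, a tandem triplet of
#' 1800-nt domesticated ERV-derived ORFs (dN/dS 0.1, RT catalytic motif
#' ablated) on the opposite strand of a marker-gene intron, one known-gene
#' decoy, pairwise synonymous divergence 0.15 between the two species with
#' ts/tv ratio 2, and an outgroup without the ortholog.
#'
#' @param seed integer RNG seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @param contig_lengths named vector of contig lengths (bp).
#' @param young_family list: `copy_number`, `intra_identity`,
#'   `element_length`, `orf_fraction`.
#' @param domesticated list: `n_copies`, `orf_length_nt`, `omega`,
#'   `tandem_spacing` (bp between tandem units), `paralog_ds` (pairwise
#'   synonymous divergence between the tandem copies, accrued before
#'   speciation), `rt_region_aa` (length of the embedded RT-like domain),
#'   `motif_ablated` (whether the catalytic YxDD aspartates are replaced).
#' @param marker list: `exon_length` (bp per exon, two exons), `omega`,
#'   `intron_margin` (bp between exon and the tandem array).
#' @param decoy_known_gene plant a conserved ERV-derived decoy that is on
#'   the known-gene list (the ASPRV1 analogue)?
#' @param divergence list: `branch_length_syn` (expected pairwise dS between
#'   the two species), `ts_tv`.
#' @param outgroup list: `present`, `has_ortholog`, `ortholog_distance_bp`
#'   (minimum distance of the unrelated ERV copy from the marker; when it
#'   exceeds what a contig can hold the copy goes to a different contig),
#'   `branch_ds` (synonymous divergence of the outgroup branch).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(
    seed = 101L,
    contig_lengths = c(chr1 = 150000L, chr2 = 100000L),
    young_family = list(copy_number = 30L, intra_identity = 0.98,
                        element_length = 2000L, orf_fraction = 0.75),
    domesticated = list(n_copies = 3L, orf_length_nt = 1800L, omega = 0.1,
                        tandem_spacing = 1200L, paralog_ds = 0.5,
                        rt_region_aa = 180L, motif_ablated = TRUE),
    marker = list(exon_length = 900L, omega = 0.05, intron_margin = 600L),
    decoy_known_gene = TRUE,
    divergence = list(branch_length_syn = 0.15, ts_tv = 2.0),
    outgroup = list(present = TRUE, has_ortholog = FALSE,
                    ortholog_distance_bp = 2e6, branch_ds = 0.5)) {
  cfg <- list(seed = as.integer(seed), contig_lengths = contig_lengths,
              young_family = young_family, domesticated = domesticated,
              marker = marker, decoy_known_gene = decoy_known_gene,
              divergence = divergence, outgroup = outgroup)
  stopifnot(all(contig_lengths > 0),
            young_family$intra_identity > 0,
            young_family$intra_identity <= 1,
            domesticated$omega > 0,
            domesticated$orf_length_nt %% 3 == 0,
            marker$exon_length %% 3 == 0,
            divergence$branch_length_syn >= 0)
  structure(cfg, class = "sim_config")
}

# --- element placement ------------------------------------------------------

# sample a free interval of `len` bp on a contig; `occ` is a two-column
# matrix of occupied (start, end) intervals
.place_element <- function(occ, contig_len, len, margin = 300L,
                           attempts = 1000L) {
  lo <- margin + 1L
  hi <- contig_len - len - margin
  if (hi < lo) stop("contig too short to place a ", len, " bp element")
  for (t in seq_len(attempts)) {
    start <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    end <- start + len - 1L
    if (nrow(occ) == 0L ||
        !any(occ[, 1L] <= end + margin & occ[, 2L] >= start - margin))
      return(c(start, end))
  }
  stop("could not place element without overlap after ", attempts,
       " attempts")
}

# --- ancestor ---------------------------------------------------------------

#' Simulate the ancestral genome with all planted elements
#'
#' Builds a random background genome and plants: a marker gene with two
#' exons whose large intron carries the tandemly repeated domesticated
#' ERV-derived ORFs on the opposite strand; a scattered young ERV family of
#' near-identical elements; optionally a conserved known-gene decoy. Also
#' generates the synthetic retroviral-domain seed alignments (RT-like,
#' gag-like, pro-like) from which the planted coding regions descend.
#'
#' @param cfg a [sim_config()].
#' @return List with `genome` ([genome()]), `features` (data.frame as in
#'   [read_gff()]), `truth` (truth table data.frame), `seeds` (named list of
#'   seed alignments), and `extras` (ancestral coding sequences, coding
#'   layout used by [speciate()], marker protein, known-protein database,
#'   exclusion list).
#' @export
simulate_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  dom <- cfg$domesticated
  yf <- cfg$young_family
  mk <- cfg$marker

  # synthetic retroviral domain seeds
  rt_len <- dom$rt_region_aa
  rt_cons <- paste(sample(.AA20, rt_len, replace = TRUE), collapse = "")
  motif_at <- max(1L, rt_len - 60L)
  substr(rt_cons, motif_at, motif_at + 3L) <- "YVDD"
  gag_cons <- paste(sample(.AA20, 400L, replace = TRUE), collapse = "")
  pro_cons <- paste(sample(.AA20, 200L, replace = TRUE), collapse = "")
  seeds <- list(rt_like = .make_seed_alignment(rt_cons),
                gag_like = .make_seed_alignment(gag_cons),
                pro_like = .make_seed_alignment(pro_cons))

  # ancestral domesticated CDS: random codons with a diverged RT-domain copy
  n_cod <- dom$orf_length_nt %/% 3L
  rt_aa <- .mutate_aa(rt_cons, 0.25)
  substr(rt_aa, motif_at, motif_at + 3L) <-
    if (isTRUE(dom$motif_ablated)) "YVAA" else "YVDD"
  rt_at <- n_cod - rt_len - 20L  # RT domain sits in the C-terminal half
  base_codons <- .split_codons(random_sense_codons(n_cod))
  rt_codons <- .split_codons(.backtranslate(rt_aa))
  base_codons[(rt_at + 1L):(rt_at + rt_len)] <- rt_codons
  dom_base <- paste(base_codons, collapse = "")
  dom_cds <- lapply(seq_len(dom$n_copies), function(i)
    evolve_codon_seq(dom_base, ds = dom$paralog_ds / 2, omega = dom$omega,
                     kappa = cfg$divergence$ts_tv))

  # tandem unit on the minus-strand reading: stop + CDS + stop + spacer
  spacer0 <- random_dna(dom$tandem_spacing)
  spacers <- lapply(seq_len(dom$n_copies), function(i)
    .mutate_neutral(spacer0, p = dom$paralog_ds / 2,
                    kappa = cfg$divergence$ts_tv))
  units <- vapply(seq_len(dom$n_copies), function(i)
    paste0("TAA", dom_cds[[i]], "TGA", spacers[[i]]), character(1))
  triplet_minus <- paste(units, collapse = "")
  unit_len <- dom$orf_length_nt + 6L + dom$tandem_spacing

  # marker gene: exon1 + intron(with tandem array) + exon2
  marker_cds <- random_sense_codons(2L * mk$exon_length %/% 3L)
  exon1 <- substr(marker_cds, 1L, mk$exon_length)
  exon2 <- substr(marker_cds, mk$exon_length + 1L, 2L * mk$exon_length)
  intron_len <- dom$n_copies * unit_len + 2L * mk$intron_margin
  gene_len <- 2L * mk$exon_length + intron_len

  contigs <- lapply(cfg$contig_lengths, random_dna)
  names(contigs) <- names(cfg$contig_lengths)
  occ <- lapply(contigs, function(x) matrix(numeric(0), 0, 2))

  c1 <- names(contigs)[1L]
  span <- .place_element(occ[[c1]], cfg$contig_lengths[[c1]], gene_len,
                         margin = 1000L)
  occ[[c1]] <- rbind(occ[[c1]], span)
  g_start <- span[1L]
  intron_start <- g_start + mk$exon_length
  trip_fwd_start <- intron_start + mk$intron_margin
  trip_len <- nchar(triplet_minus)
  seqpart <- paste0(
    exon1,
    substr(contigs[[c1]], intron_start, trip_fwd_start - 1L),
    revcomp(triplet_minus),
    substr(contigs[[c1]], trip_fwd_start + trip_len,
           intron_start + intron_len - 1L),
    exon2)
  stopifnot(nchar(seqpart) == gene_len)
  substr(contigs[[c1]], g_start, span[2L]) <- seqpart

  # forward-strand span of CDS i (minus-strand gene copies)
  dom_rows <- lapply(seq_len(dom$n_copies), function(i) {
    p <- (i - 1L) * unit_len + 4L               # CDS start within triplet_minus
    q <- p + dom$orf_length_nt - 1L
    data.frame(name = sprintf("dom_erv%d", i), class = "domesticated",
               contig = c1,
               start = trip_fwd_start + trip_len - q - 1L + 1L,
               end = trip_fwd_start + trip_len - p,
               strand = "-", omega = dom$omega,
               catalytic_motif_present = !isTRUE(dom$motif_ablated),
               ortholog = sprintf("dom_erv%d", i), stringsAsFactors = FALSE)
  })

  # young ERV family: master element with one long stop-flanked ORF
  orf_len <- (floor(yf$element_length * yf$orf_fraction) %/% 3L) * 3L
  n_orf_cod <- orf_len %/% 3L
  gag_at <- max(1L, (n_orf_cod - 400L) %/% 2L)
  y_codons <- .split_codons(random_sense_codons(n_orf_cod))
  gag_aa <- .mutate_aa(gag_cons, 0.1)
  y_codons[(gag_at + 1L):(gag_at + 400L)] <- .split_codons(.backtranslate(gag_aa))
  filler <- yf$element_length - orf_len - 6L
  master <- paste0("TAA", paste(y_codons, collapse = ""), "TAG",
                   random_dna(filler))
  p_copy <- (1 - yf$intra_identity) / 2
  young_rows <- vector("list", yf$copy_number)
  for (i in seq_len(yf$copy_number)) {
    copy <- .mutate_neutral(master, p_copy, kappa = cfg$divergence$ts_tv)
    cix <- names(contigs)[1L + (i %% length(contigs))]
    sp <- .place_element(occ[[cix]], cfg$contig_lengths[[cix]],
                         yf$element_length)
    occ[[cix]] <- rbind(occ[[cix]], sp)
    substr(contigs[[cix]], sp[1L], sp[2L]) <- copy
    young_rows[[i]] <- data.frame(
      name = sprintf("young_erv%02d", i), class = "young_erv", contig = cix,
      start = sp[1L] + 3L, end = sp[1L] + 3L + orf_len - 1L, strand = "+",
      omega = NA_real_, catalytic_motif_present = NA,
      ortholog = NA_character_, stringsAsFactors = FALSE)
  }

  # known-gene decoy (conserved ERV-derived protease analogue)
  extras_decoy <- NULL
  decoy_row <- NULL
  if (isTRUE(cfg$decoy_known_gene)) {
    d_codons <- .split_codons(random_sense_codons(300L))
    pro_aa <- .mutate_aa(pro_cons, 0.1)
    d_codons[51L:250L] <- .split_codons(.backtranslate(pro_aa))
    decoy_cds <- paste(d_codons, collapse = "")
    c2 <- names(contigs)[min(2L, length(contigs))]
    sp <- .place_element(occ[[c2]], cfg$contig_lengths[[c2]],
                         nchar(decoy_cds) + 6L)
    occ[[c2]] <- rbind(occ[[c2]], sp)
    substr(contigs[[c2]], sp[1L], sp[2L]) <-
      paste0("TAA", decoy_cds, "TGA")
    decoy_row <- data.frame(
      name = "ASPRV1L", class = "decoy_known", contig = c2,
      start = sp[1L] + 3L, end = sp[1L] + 3L + nchar(decoy_cds) - 1L,
      strand = "+", omega = 0.1, catalytic_motif_present = NA,
      ortholog = "ASPRV1L", stringsAsFactors = FALSE)
    extras_decoy <- decoy_cds
  }

  marker_row <- data.frame(
    name = "MRK1", class = "marker_gene", contig = c1, start = g_start,
    end = span[2L], strand = "+", omega = mk$omega,
    catalytic_motif_present = NA, ortholog = "MRK1",
    stringsAsFactors = FALSE)

  truth <- do.call(rbind, c(dom_rows, young_rows,
                            list(decoy_row, marker_row)))
  rownames(truth) <- NULL

  feat <- data.frame(
    contig = truth$contig, start = truth$start, end = truth$end,
    strand = truth$strand,
    kind = c(domesticated = "ERV", young_erv = "ERV", decoy_known = "gene",
             marker_gene = "gene")[truth$class],
    name = truth$name, stringsAsFactors = FALSE)
  exons <- data.frame(
    contig = c1, start = c(g_start, span[2L] - mk$exon_length + 1L),
    end = c(g_start + mk$exon_length - 1L, span[2L]), strand = "+",
    kind = "exon", name = c("MRK1.e1", "MRK1.e2"), stringsAsFactors = FALSE)
  feat <- rbind(feat, exons)
  feat <- feat[order(feat$contig, feat$start), , drop = FALSE]
  rownames(feat) <- NULL

  # coding layout consumed by speciate()/make_outgroup(): in-frame spans
  coding <- rbind(
    do.call(rbind, dom_rows)[, c("name", "contig", "start", "end", "strand",
                                 "omega")],
    if (!is.null(decoy_row))
      decoy_row[, c("name", "contig", "start", "end", "strand", "omega")],
    data.frame(name = c("MRK1.e1", "MRK1.e2"), contig = c1,
               start = c(g_start, span[2L] - mk$exon_length + 1L),
               end = c(g_start + mk$exon_length - 1L, span[2L]),
               strand = "+", omega = mk$omega, stringsAsFactors = FALSE))

  marker_protein <- translate_nt(marker_cds)
  known_db <- if (!is.null(extras_decoy))
    stats::setNames(translate_nt(extras_decoy), "ASPRV1L_known")
  else stats::setNames(character(0), character(0))

  list(genome = genome(stats::setNames(unlist(contigs), names(contigs)),
                       species = "ancestor"),
       features = feat, truth = truth, seeds = seeds,
       extras = list(coding = coding, dom_cds = dom_cds,
                     dom_base = dom_base,
                     rt_consensus = rt_cons, rt_region = c(rt_at + 1L,
                                                           rt_at + rt_len),
                     motif_at = motif_at,
                     triplet_span = c(trip_fwd_start,
                                      trip_fwd_start + trip_len - 1L),
                     unit_len = unit_len,
                     marker_cds = marker_cds, marker_protein = marker_protein,
                     decoy_cds = extras_decoy, known_protein_db = known_db,
                     exclusion_list = if (is.null(decoy_row)) character(0)
                                      else "ASPRV1L",
                     young_master_orf = paste(y_codons, collapse = "")))
}

# evolve one descendant genome from the ancestor: neutral everywhere, then
# overwrite coding spans with codon-evolved versions of the ancestral CDS
.evolve_descendant <- function(anc, branch_ds, kappa, species) {
  p_neutral <- 0.75 * (1 - exp(-4 * branch_ds / 3))
  contigs <- vapply(anc$genome$contigs, .mutate_neutral, character(1),
                    p = p_neutral, kappa = kappa, USE.NAMES = TRUE)
  cod <- anc$extras$coding
  for (r in seq_len(nrow(cod))) {
    nt <- substr(anc$genome$contigs[[cod$contig[r]]], cod$start[r],
                 cod$end[r])
    if (cod$strand[r] == "-") nt <- revcomp(nt)
    ev <- evolve_codon_seq(nt, ds = branch_ds, omega = cod$omega[r],
                           kappa = kappa)
    if (cod$strand[r] == "-") ev <- revcomp(ev)
    substr(contigs[[cod$contig[r]]], cod$start[r], cod$end[r]) <- ev
  }
  genome(contigs, species = species)
}

#' Split the ancestor into two descendant species
#'
#' Neutral regions (background, young ERV copies, introns, spacers) evolve
#' at the configured per-site rate with ts/tv bias; coding regions
#' (domesticated copies, decoy, marker exons) evolve codon-wise with their
#' dN/dS, rejecting stop-creating changes. Evolution is indel-free, so all
#' coordinates lift over unchanged.
#'
#' @param anc output of [simulate_ancestor()].
#' @param cfg the same [sim_config()].
#' @return List with `genome_a`, `genome_b`, `features` (shared), `truth`
#'   (one row per planted element and species).
#' @export
speciate <- function(anc, cfg) {
  set.seed(cfg$seed + 1L)
  branch <- cfg$divergence$branch_length_syn / 2
  kappa <- cfg$divergence$ts_tv
  ga <- .evolve_descendant(anc, branch, kappa, "speciesA")
  gb <- .evolve_descendant(anc, branch, kappa, "speciesB")
  ta <- cbind(species = "A", anc$truth, stringsAsFactors = FALSE)
  tb <- cbind(species = "B", anc$truth, stringsAsFactors = FALSE)
  list(genome_a = ga, genome_b = gb, features = anc$features,
       truth = rbind(ta, tb))
}

#' Build a deeply diverged outgroup genome
#'
#' The outgroup always contains the (evolved) marker gene. When
#' `cfg$outgroup$has_ortholog` is `TRUE` the domesticated tandem array stays
#' in the marker intron; otherwise it is replaced with fresh background and
#' a single unrelated ERV copy (an independently diverged RT-domain ORF) is
#' planted at least `ortholog_distance_bp` from the marker — on a different
#' contig when no contig is long enough to hold that distance.
#'
#' @param anc output of [simulate_ancestor()].
#' @param cfg the same [sim_config()].
#' @return List with `genome`, `marker_span` (contig, start, end of the
#'   marker gene) and `planted_erv` (span of the unrelated copy, or `NULL`).
#' @export
make_outgroup <- function(anc, cfg) {
  set.seed(cfg$seed + 2L)
  kappa <- cfg$divergence$ts_tv
  g <- .evolve_descendant(anc, cfg$outgroup$branch_ds, kappa, "outgroup")
  contigs <- g$contigs
  truth <- anc$truth
  marker <- truth[truth$class == "marker_gene", ][1L, ]
  planted <- NULL
  if (!isTRUE(cfg$outgroup$has_ortholog)) {
    ts <- anc$extras$triplet_span
    substr(contigs[[marker$contig]], ts[1L], ts[2L]) <-
      random_dna(ts[2L] - ts[1L] + 1L)
    # unrelated RT-carrying element, far from the marker
    rt_aa <- .mutate_aa(anc$extras$rt_consensus, 0.25)
    n_cod <- 500L
    codons <- .split_codons(random_sense_codons(n_cod))
    at <- (n_cod - nchar(rt_aa)) %/% 2L
    codons[(at + 1L):(at + nchar(rt_aa))] <-
      .split_codons(.backtranslate(rt_aa))
    elem <- paste0("TAA", paste(codons, collapse = ""), "TGA")
    far <- names(contigs)[nchar(contigs) == max(nchar(contigs))][1L]
    cand <- setdiff(names(contigs), marker$contig)
    host <- if (length(cand) > 0) cand[1L] else far
    pos <- .place_element(matrix(numeric(0), 0, 2), nchar(contigs[[host]]),
                          nchar(elem))
    substr(contigs[[host]], pos[1L], pos[2L]) <- elem
    planted <- list(contig = host, start = pos[1L], end = pos[2L])
  }
  list(genome = genome(contigs, species = "outgroup"),
       marker_span = list(contig = marker$contig, start = marker$start,
                          end = marker$end),
       planted_erv = planted)
}

#' Build the complete default synthetic screening fixture
#'
#' Runs [simulate_ancestor()], [speciate()] and (when configured)
#' [make_outgroup()], builds and calibrates the domain profiles from the
#' generated seed alignments, and bundles everything a screen run needs.
#'
#' @param seed RNG seed (used as the `sim_config` seed).
#' @param cfg optional [sim_config()]; its `seed` wins over `seed`.
#' @param calibrate_n,calibrate_len profile calibration sample.
#' @return List with `cfg`, `ancestor`, `genome_a`, `genome_b`, `features`,
#'   `truth`, `profiles` (calibrated), `marker_protein`,
#'   `known_protein_db`, `exclusion_list`, `outgroups` (list as accepted by
#'   [lineage_specificity()]).
#' @export
simulate_screen_fixture <- function(seed = 101L, cfg = NULL,
                                    calibrate_n = 1000L,
                                    calibrate_len = 400L) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  anc <- simulate_ancestor(cfg)
  sp <- speciate(anc, cfg)
  og <- if (isTRUE(cfg$outgroup$present)) make_outgroup(anc, cfg) else NULL
  profiles <- lapply(names(anc$seeds), function(nm)
    build_profile(anc$seeds[[nm]], name = nm))
  names(profiles) <- names(anc$seeds)
  profiles <- lapply(seq_along(profiles), function(i)
    calibrate_profile(profiles[[i]], n_random = calibrate_n,
                      random_len = calibrate_len,
                      seed = cfg$seed + 10L + i))
  names(profiles) <- names(anc$seeds)
  list(cfg = cfg, ancestor = anc, genome_a = sp$genome_a,
       genome_b = sp$genome_b, features = sp$features, truth = sp$truth,
       profiles = profiles, marker_protein = anc$extras$marker_protein,
       known_protein_db = anc$extras$known_protein_db,
       exclusion_list = anc$extras$exclusion_list,
       outgroups = if (is.null(og)) list() else list(outgroup1 = og))
}

#' Reverse-transcriptase-region peptides of the planted gene family
#'
#' Extracts the RT-domain peptide of every domesticated gene copy in both
#' species from a fixture, plus the undiverged RT seed consensus as an
#' outgroup sequence. Evolution is indel-free, so the peptides are aligned
#' as extracted.
#'
#' @param fixture output of [simulate_screen_fixture()] (or a list with
#'   `ancestor`, `genome_a`, `genome_b`, `truth`).
#' @return Named character vector: `<gene>_A`, `<gene>_B` for each planted
#'   gene, plus `rt_outgroup`.
#' @export
rt_peptides <- function(fixture) {
  anc <- fixture$ancestor
  rt <- anc$extras$rt_region
  doms <- anc$truth[anc$truth$class == "domesticated", ]
  out <- character(0)
  for (sp in c("A", "B")) {
    gg <- if (sp == "A") fixture$genome_a else fixture$genome_b
    for (r in seq_len(nrow(doms))) {
      nt <- substr(gg$contigs[[doms$contig[r]]], doms$start[r], doms$end[r])
      if (doms$strand[r] == "-") nt <- revcomp(nt)
      aa <- translate_nt(nt)
      out[[paste0(doms$name[r], "_", sp)]] <-
        substr(aa, rt[1L], rt[2L])
    }
  }
  out[["rt_outgroup"]] <- anc$extras$rt_consensus
  out
}
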
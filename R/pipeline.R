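#' Assemble a screen configuration
#'
#' Bundles the inputs and every stage threshold (defaults are the screen's
#' canonical values: 240-nt minimum ORF, domain-scan E `1e-5`, 50% cluster
#' identity with clusters of more than 10 removed, pairing E `1e-50`,
#' outgroup search E `1e-5`, query cover 0.6, marker proximity 1 Mb).
#'
#' @param genome_a,genome_b [genome()] objects (or named contig vectors).
#' @param features_a,features_b annotation tables ([read_gff()] format).
#' @param profiles named list of calibrated [build_profile()] objects.
#' @param marker_protein amino-acid sequence of the conserved marker gene.
#' @param outgroups named list of outgroups (each with `$genome`), possibly
#'   empty.
#' @param known_protein_db named character vector of known ERV-derived
#'   proteins.
#' @param exclusion_list names of annotated genes to exclude.
#' @param min_len_nt,hmm_evalue,cluster_identity,max_cluster_size
#'   stage thresholds (see above).
#' @param pair_evalue,bitscore_min,outgroup_evalue,cover_min,proximity_max
#'   stage thresholds (see above).
#' @param seed seed for the selection-test bootstrap.
#' @param outdir optional directory; when given, every stage intermediate
#'   is written there (FASTA/TSV/newick plus a resolved-config echo).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(genome_a, genome_b, features_a, features_b,
                          profiles, marker_protein, outgroups = list(),
                          known_protein_db = character(0),
                          exclusion_list = character(0),
                          min_len_nt = 240L, hmm_evalue = 1e-5,
                          cluster_identity = 0.5, max_cluster_size = 10L,
                          pair_evalue = 1e-50, bitscore_min = 200,
                          outgroup_evalue = 1e-5, cover_min = 0.6,
                          proximity_max = 1e6, seed = 1L, outdir = NULL) {
  structure(list(
    genome_a = genome_a, genome_b = genome_b, features_a = features_a,
    features_b = features_b, profiles = profiles,
    marker_protein = marker_protein, outgroups = outgroups,
    known_protein_db = known_protein_db, exclusion_list = exclusion_list,
    min_len_nt = min_len_nt, hmm_evalue = hmm_evalue,
    cluster_identity = cluster_identity, max_cluster_size = max_cluster_size,
    pair_evalue = pair_evalue, bitscore_min = bitscore_min,
    outgroup_evalue = outgroup_evalue, cover_min = cover_min,
    proximity_max = proximity_max, seed = seed, outdir = outdir),
    class = "screen_config")
}

#' Screen configuration for a synthetic fixture
#'
#' @param fixture output of [simulate_screen_fixture()].
#' @param ... overrides passed to [screen_config()].
#' @return A `screen_config`.
#' @export
fixture_screen_config <- function(fixture, ...) {
  screen_config(
    genome_a = fixture$genome_a, genome_b = fixture$genome_b,
    features_a = fixture$features, features_b = fixture$features,
    profiles = fixture$profiles, marker_protein = fixture$marker_protein,
    outgroups = fixture$outgroups,
    known_protein_db = fixture$known_protein_db,
    exclusion_list = fixture$exclusion_list, seed = fixture$cfg$seed, ...)
}

# poisson distance of two unaligned peptides via global alignment
.pairwise_poisson <- function(a, b, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "global")
  poisson_distance(as.character(Biostrings::pattern(pa)),
                   as.character(Biostrings::subject(pa)))
}

.write_stage <- function(outdir, name, obj) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, name)
  if (is.data.frame(obj))
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  else if (is.character(obj) && !is.null(names(obj)))
    write_fasta(obj, path)
  invisible(path)
}

#' Run the full conserved-ERV-gene screen
#'
#' Executes, in order: six-frame ORF extraction in both genomes; profile-HMM
#' domain scan; per-species greedy identity clustering with removal of large
#' clusters (the young-ERV filter); cross-species ORF pairing; known-gene
#' exclusion; lineage-specificity tests against the outgroups; Nei-Gojobori
#' selection statistics with the codon Z-test for each surviving pair; a
#' neighbor-joining tree of the candidate peptides; and a k-mer self-dotplot
#' of each candidate locus.
#'
#' @param config a [screen_config()].
#' @return List of class `screen_report`: `stage_counts`, `candidates`
#'   (final table with verdicts and motif check), `selection`, `verdicts`,
#'   `tree` (`phylo` or `NULL`), `dotplots`, `log`, `config`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  scheme <- scoring_scheme()
  counts <- list()
  note <- function(stage, n_a, n_b = NA_integer_)
    counts[[length(counts) + 1L]] <<- data.frame(
      stage = stage, n_a = n_a, n_b = n_b, stringsAsFactors = FALSE)

  orfs_a <- extract_orfs(config$genome_a, config$min_len_nt)
  orfs_b <- extract_orfs(config$genome_b, config$min_len_nt)
  note("orfs", nrow(orfs_a), nrow(orfs_b))
  .write_stage(config$outdir, "orfs_a.tsv",
               orfs_a[, setdiff(names(orfs_a), c("nt_seq", "aa_seq"))])
  .write_stage(config$outdir, "orfs_b.tsv",
               orfs_b[, setdiff(names(orfs_b), c("nt_seq", "aa_seq"))])

  hits_a <- scan_profiles(config$profiles, orf_to_fasta(orfs_a, "aa"),
                          config$hmm_evalue)
  hits_b <- scan_profiles(config$profiles, orf_to_fasta(orfs_b, "aa"),
                          config$hmm_evalue)
  orfs_a <- orfs_a[orfs_a$orf_id %in% hits_a$seq_id, , drop = FALSE]
  orfs_b <- orfs_b[orfs_b$orf_id %in% hits_b$seq_id, , drop = FALSE]
  note("domain_scan", nrow(orfs_a), nrow(orfs_b))
  .write_stage(config$outdir, "domain_hits_a.tsv", hits_a)
  .write_stage(config$outdir, "domain_hits_b.tsv", hits_b)

  surv <- lapply(list(a = orfs_a, b = orfs_b), function(orfs) {
    if (nrow(orfs) == 0L) return(orfs)
    cl <- greedy_cluster(orf_to_fasta(orfs, "aa"), config$cluster_identity,
                         scheme)
    keep <- filter_large_clusters(cl, config$max_cluster_size)
    orfs[orfs$orf_id %in% keep, , drop = FALSE]
  })
  orfs_a <- surv$a; orfs_b <- surv$b
  note("cluster_filter", nrow(orfs_a), nrow(orfs_b))

  pairs <- pair_cross_species(orfs_a, orfs_b, scheme, config$pair_evalue,
                              config$bitscore_min)
  note("pairing", nrow(pairs))
  .write_stage(config$outdir, "pairs.tsv", pairs)

  ex <- exclude_annotated(pairs, orfs_a, orfs_b, config$features_a,
                          config$features_b, config$exclusion_list,
                          config$known_protein_db, scheme,
                          config$outgroup_evalue)
  pairs <- ex$pairs
  note("known_gene_exclusion", nrow(pairs))
  .write_stage(config$outdir, "exclusion_log.tsv", ex$log)

  verdicts <- list()
  lineage_flag <- logical(nrow(pairs))
  if (nrow(pairs) > 0L) for (r in seq_len(nrow(pairs))) {
    pep <- orfs_a$aa_seq[match(pairs$orf_a[r], orfs_a$orf_id)]
    v <- lineage_specificity(pairs$orf_a[r], pep, config$outgroups,
                             config$marker_protein, scheme,
                             config$cover_min, config$proximity_max,
                             config$outgroup_evalue)
    verdicts[[length(verdicts) + 1L]] <- v
    lineage_flag[r] <- nrow(v) == 0L || !any(v$verdict == "ortholog_found")
  }
  verdicts <- if (length(verdicts) > 0L) do.call(rbind, verdicts) else
    data.frame(candidate_id = character(0), outgroup = character(0),
               n_cover_hits = integer(0), min_marker_distance = numeric(0),
               verdict = character(0), stringsAsFactors = FALSE)
  note("final_candidates", nrow(pairs))
  .write_stage(config$outdir, "specificity_verdicts.tsv", verdicts)

  selection <- NULL
  motifs <- NULL
  if (nrow(pairs) > 0L) {
    sel_rows <- list(); motif_rows <- list()
    for (r in seq_len(nrow(pairs))) {
      nt_a <- orfs_a$nt_seq[match(pairs$orf_a[r], orfs_a$orf_id)]
      nt_b <- orfs_b$nt_seq[match(pairs$orf_b[r], orfs_b$orf_id)]
      aln <- codon_alignment(nt_a, nt_b, scheme)
      ng <- nei_gojobori(aln)
      zt <- z_test_neutrality(aln, "purifying", seed = config$seed + r)
      sel_rows[[r]] <- data.frame(
        orf_a = pairs$orf_a[r], orf_b = pairs$orf_b[r],
        L_codons = ng$L_codons, dN = ng$dN, dS = ng$dS, dnds = ng$dnds,
        var_dN = zt$var_dN, var_dS = zt$var_dS, Z = zt$Z,
        p_value = zt$p_value, percent_identity = ng$percent_identity,
        stringsAsFactors = FALSE)
      pep <- orfs_a$aa_seq[match(pairs$orf_a[r], orfs_a$orf_id)]
      mc <- motif_check(pep, c(rt_catalytic = "YXDD"))
      motif_rows[[r]] <- cbind(orf_a = pairs$orf_a[r], mc,
                               stringsAsFactors = FALSE)
    }
    selection <- do.call(rbind, sel_rows)
    motifs <- do.call(rbind, motif_rows)
    .write_stage(config$outdir, "selection_stats.tsv", selection)
  }

  tree <- NULL
  if (nrow(pairs) >= 2L) {
    peps <- c(stats::setNames(
      orfs_a$aa_seq[match(pairs$orf_a, orfs_a$orf_id)],
      paste0(pairs$orf_a, "|A")),
      stats::setNames(
        orfs_b$aa_seq[match(pairs$orf_b, orfs_b$orf_id)],
        paste0(pairs$orf_b, "|B")))
    n <- length(peps)
    if (n >= 3L) {
      d <- matrix(0, n, n, dimnames = list(names(peps), names(peps)))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        d[i, j] <- d[j, i] <- .pairwise_poisson(peps[[i]], peps[[j]], scheme)
      tree <- nj_tree(d)
      if (!is.null(config$outdir))
        ape::write.tree(tree, file.path(config$outdir, "candidates.nwk"))
    }
  }

  dotplots <- list()
  if (nrow(pairs) > 0L) {
    contigs <- .as_contigs(config$genome_a)
    for (r in seq_len(nrow(pairs))) {
      co <- parse_orf_id(pairs$orf_a[r])
      lo <- max(1L, co$start - 5000L)
      hi <- min(nchar(contigs[[co$contig]]), co$end + 5000L)
      dotplots[[pairs$orf_a[r]]] <-
        self_dotplot(substr(contigs[[co$contig]], lo, hi))
    }
  }

  candidates <- pairs
  if (nrow(pairs) > 0L) {
    candidates$lineage_specific <- lineage_flag
    candidates$rt_motif_present <-
      motifs$present[match(candidates$orf_a, motifs$orf_a)]
  }

  stage_counts <- do.call(rbind, counts)
  .write_stage(config$outdir, "stage_counts.tsv", stage_counts)
  .write_stage(config$outdir, "candidates.tsv", candidates)
  if (!is.null(config$outdir)) .write_config_echo(config)

  structure(list(stage_counts = stage_counts, candidates = candidates,
                 selection = selection, verdicts = verdicts, tree = tree,
                 dotplots = dotplots, log = ex$log, config = config),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  print(x$stage_counts, row.names = FALSE)
  cat(sprintf("final candidates: %d (%d lineage-specific)\n",
              nrow(x$candidates),
              if (nrow(x$candidates)) sum(x$candidates$lineage_specific)
              else 0L))
  invisible(x)
}

# resolved-config echo: thresholds only (sequences are written as FASTA)
.write_config_echo <- function(config) {
  keys <- c("min_len_nt", "hmm_evalue", "cluster_identity",
            "max_cluster_size", "pair_evalue", "bitscore_min",
            "outgroup_evalue", "cover_min", "proximity_max", "seed")
  lines <- vapply(keys, function(k)
    sprintf("%s: %s", k, format(config[[k]], scientific = TRUE)),
    character(1))
  writeLines(lines, file.path(config$outdir, "config_echo.yml"))
}

#' Validation mode: recovery of a known truth set
#'
#' Runs the screen and reports, for every truth entry, whether a final
#' candidate ORF overlaps its coordinates in the corresponding species —
#' the recall check used to validate the screen on genomes with known
#' ERV-derived genes.
#'
#' @param config a [screen_config()].
#' @param truth data.frame with `name`, `species` (`"A"`/`"B"`), `contig`,
#'   `start`, `end` and a logical `expected` column: should the screen
#'   recover this entry?
#' @return List with `report` (the [run_screen()] output), `recovery`
#'   (per truth entry: `recovered`), `recall` (fraction of `expected`
#'   entries recovered), `unexpected_hits` (candidates matching entries
#'   with `expected = FALSE`), `extra` (candidates matching no entry).
#' @export
run_validation_mode <- function(config, truth) {
  report <- run_screen(config)
  cand <- report$candidates
  if (nrow(truth) == 0L)
    return(list(report = report,
                recovery = cbind(truth, recovered = logical(0)),
                recall = NA_real_, unexpected_hits = character(0),
                extra = if (nrow(cand)) cand$orf_a else character(0)))
  coords_a <- if (nrow(cand)) parse_orf_id(cand$orf_a) else NULL
  coords_b <- if (nrow(cand)) parse_orf_id(cand$orf_b) else NULL
  expected <- if ("expected" %in% names(truth)) truth$expected else
    rep(TRUE, nrow(truth))
  recovered <- logical(nrow(truth))
  matched_any <- rep(FALSE, max(nrow(cand), 0L))
  unexpected <- character(0)
  for (i in seq_len(nrow(truth))) {
    co <- if (truth$species[i] == "A") coords_a else coords_b
    if (is.null(co)) next
    ov <- co$contig == truth$contig[i] & co$start <= truth$end[i] &
      co$end >= truth$start[i]
    recovered[i] <- any(ov)
    matched_any <- matched_any | ov
    if (any(ov) && !expected[i])
      unexpected <- c(unexpected, cand$orf_a[ov])
  }
  list(report = report,
       recovery = cbind(truth, recovered = recovered),
       recall = if (any(expected)) mean(recovered[expected]) else NA_real_,
       unexpected_hits = unique(unexpected),
       extra = if (nrow(cand)) cand$orf_a[!matched_any] else character(0))
}
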
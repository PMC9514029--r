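#' Pair ORFs across species by local protein alignment
#'
#' For every species-A ORF the best-scoring species-B ORF with
#' `evalue < evalue_max` and `bitscore >= bitscore_min` is taken; each
#' B-ORF is used at most once, assigned greedily by descending bitscore.
#' `bitscore_min = "auto"` places the cut at the largest gap in the sorted
#' bitscore distribution of the passing hits.
#'
#' @param orfs_a,orfs_b ORF tables ([extract_orfs()]) of the two species,
#'   already reduced to domain-positive, cluster-filtered survivors.
#' @param scheme a [scoring_scheme()].
#' @param evalue_max pairing E-value threshold (default `1e-50`).
#' @param bitscore_min minimum bitscore (default 200), or `"auto"`.
#' @return data.frame of candidate pairs: `orf_a`, `orf_b`, aa lengths,
#'   `raw_score`, `bitscore`, `evalue`, `n_identical`, `aln_len`.
#' @export
pair_cross_species <- function(orfs_a, orfs_b, scheme = scoring_scheme(),
                               evalue_max = 1e-50, bitscore_min = 200) {
  empty <- data.frame(orf_a = character(0), orf_b = character(0),
                      len_a = integer(0), len_b = integer(0),
                      raw_score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), n_identical = integer(0),
                      aln_len = integer(0), stringsAsFactors = FALSE)
  if (nrow(orfs_a) == 0L || nrow(orfs_b) == 0L) return(empty)
  db_len <- sum(nchar(orfs_b$aa_seq))
  hits <- list()
  for (i in seq_len(nrow(orfs_a))) {
    raw <- .sw_scores(orfs_a$aa_seq[i], orfs_b$aa_seq, scheme)
    be <- bit_and_evalue(pmax(raw, 1e-9), nchar(orfs_a$aa_seq[i]), db_len,
                         scheme)
    pass <- which(raw > 0 & be$evalue < evalue_max)
    if (length(pass) == 0L) next
    hits[[length(hits) + 1L]] <- data.frame(
      a = i, b = pass, raw_score = raw[pass], bitscore = be$bitscore[pass],
      evalue = be$evalue[pass], stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  hits <- do.call(rbind, hits)
  if (identical(bitscore_min, "auto")) {
    bs <- sort(hits$bitscore)
    bitscore_min <- if (length(bs) < 2L) 0 else {
      gaps <- diff(bs)
      bs[which.max(gaps)] + max(gaps) / 2
    }
  }
  hits <- hits[hits$bitscore >= bitscore_min, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(-hits$bitscore, hits$a, hits$b), , drop = FALSE]
  used_a <- logical(nrow(orfs_a)); used_b <- logical(nrow(orfs_b))
  rows <- list()
  for (r in seq_len(nrow(hits))) {
    a <- hits$a[r]; b <- hits$b[r]
    if (used_a[a] || used_b[b]) next
    used_a[a] <- TRUE; used_b[b] <- TRUE
    al <- smith_waterman(orfs_a$aa_seq[a], orfs_b$aa_seq[b], scheme)
    rows[[length(rows) + 1L]] <- data.frame(
      orf_a = orfs_a$orf_id[a], orf_b = orfs_b$orf_id[b],
      len_a = nchar(orfs_a$aa_seq[a]), len_b = nchar(orfs_b$aa_seq[b]),
      raw_score = hits$raw_score[r], bitscore = hits$bitscore[r],
      evalue = hits$evalue[r], n_identical = al$n_identical,
      aln_len = al$aln_len, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$bitscore), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 1 bp interval overlap of an ORF with features of kind "gene" on a list
.overlapping_gene <- function(orf_coord, features, gene_names) {
  f <- features[features$kind == "gene" & features$name %in% gene_names, ,
                drop = FALSE]
  if (nrow(f) == 0L) return(NA_character_)
  hit <- f$contig == orf_coord$contig & f$start <= orf_coord$end &
    f$end >= orf_coord$start
  if (any(hit)) f$name[which(hit)[1L]] else NA_character_
}

#' Remove candidate pairs that correspond to already-annotated genes
#'
#' A pair is dropped when either ORF overlaps (by at least 1 bp, either
#' strand) an annotated gene whose name is on the exclusion list, or when
#' either peptide hits the known-protein database below `evalue_max`. Both
#' mechanisms run; the trigger is recorded in the returned log.
#'
#' @param pairs output of [pair_cross_species()].
#' @param orfs_a,orfs_b the ORF tables the pairs refer to.
#' @param features_a,features_b annotation tables ([read_gff()] format).
#' @param exclusion_list character vector of known-gene names.
#' @param known_protein_db named character vector of known ERV-derived
#'   proteins.
#' @param scheme a [scoring_scheme()].
#' @param evalue_max protein-similarity threshold (default `1e-5`).
#' @return List with `pairs` (survivors) and `log` (one row per removed
#'   pair: `orf_a`, `orf_b`, `reason`, `trigger`).
#' @export
exclude_annotated <- function(pairs, orfs_a, orfs_b, features_a, features_b,
                              exclusion_list = character(0),
                              known_protein_db = character(0),
                              scheme = scoring_scheme(),
                              evalue_max = 1e-5) {
  log <- data.frame(orf_a = character(0), orf_b = character(0),
                    reason = character(0), trigger = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, log = log))
  db_len <- sum(nchar(known_protein_db))
  keep <- rep(TRUE, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ca <- parse_orf_id(pairs$orf_a[r])
    cb <- parse_orf_id(pairs$orf_b[r])
    ga <- .overlapping_gene(ca, features_a, exclusion_list)
    gb <- .overlapping_gene(cb, features_b, exclusion_list)
    if (!is.na(ga) || !is.na(gb)) {
      keep[r] <- FALSE
      log <- rbind(log, data.frame(
        orf_a = pairs$orf_a[r], orf_b = pairs$orf_b[r],
        reason = "annotated_gene_overlap",
        trigger = if (!is.na(ga)) ga else gb, stringsAsFactors = FALSE))
      next
    }
    if (length(known_protein_db) > 0L) {
      for (side in c("a", "b")) {
        orfs <- if (side == "a") orfs_a else orfs_b
        pep <- orfs$aa_seq[match(pairs[[paste0("orf_", side)]][r],
                                 orfs$orf_id)]
        raw <- .sw_scores(pep, known_protein_db, scheme)
        if (length(raw) == 0L || max(raw) <= 0) next
        ev <- bit_and_evalue(max(raw), nchar(pep), db_len, scheme)$evalue
        if (ev < evalue_max) {
          keep[r] <- FALSE
          log <- rbind(log, data.frame(
            orf_a = pairs$orf_a[r], orf_b = pairs$orf_b[r],
            reason = "known_protein_hit",
            trigger = names(known_protein_db)[which.max(raw)],
            stringsAsFactors = FALSE))
          break
        }
      }
    }
  }
  list(pairs = pairs[keep, , drop = FALSE], log = log)
}

#' Lineage-specificity test against outgroup genomes
#'
#' For each outgroup the candidate peptide is searched with
#' [translated_search()]; hits with query cover at least `cover_min` are
#' kept. The marker locus is located by a translated search of the marker
#' protein, taking the highest-scoring hit as the marker position. The
#' verdict is `ortholog_found` iff a kept hit lies within `proximity_max`
#' bp of the marker on the same contig, `marker_absent` when the marker
#' protein finds no hit, else `lineage_specific`.
#'
#' @param candidate_id candidate label carried into the verdicts.
#' @param peptide candidate amino-acid sequence.
#' @param outgroups named list; each element has at least `genome`.
#' @param marker_protein amino-acid sequence of the conserved neighbour
#'   gene used as the positional anchor.
#' @param scheme a [scoring_scheme()].
#' @param cover_min minimum query cover (default 0.6).
#' @param proximity_max maximum marker distance in bp (default 1e6).
#' @param evalue_threshold search threshold (default `1e-5`).
#' @return data.frame with one row per outgroup: `candidate_id`,
#'   `outgroup`, `n_cover_hits`, `min_marker_distance` (NA when no kept hit
#'   shares a contig with the marker), `verdict`.
#' @export
lineage_specificity <- function(candidate_id, peptide, outgroups,
                                marker_protein, scheme = scoring_scheme(),
                                cover_min = 0.6, proximity_max = 1e6,
                                evalue_threshold = 1e-5) {
  if (nchar(peptide) == 0L) stop("empty candidate peptide")
  out <- list()
  for (og in names(outgroups)) {
    gg <- outgroups[[og]]$genome
    hits <- translated_search(peptide, gg, scheme, evalue_threshold,
                              query_id = candidate_id)
    kept <- hits[hits$query_cover >= cover_min, , drop = FALSE]
    mhits <- translated_search(marker_protein, gg, scheme, evalue_threshold,
                               query_id = "marker")
    if (nrow(mhits) == 0L) {
      out[[og]] <- data.frame(candidate_id = candidate_id, outgroup = og,
                              n_cover_hits = nrow(kept),
                              min_marker_distance = NA_real_,
                              verdict = "marker_absent",
                              stringsAsFactors = FALSE)
      next
    }
    m <- mhits[1L, ]  # highest bitscore
    dist <- NA_real_
    verdict <- "lineage_specific"
    same <- kept[kept$contig == m$contig, , drop = FALSE]
    if (nrow(same) > 0L) {
      gapdist <- pmax(0, pmax(same$genomic_start, m$genomic_start) -
                        pmin(same$genomic_end, m$genomic_end))
      dist <- min(gapdist)
      if (dist <= proximity_max) verdict <- "ortholog_found"
    }
    out[[og]] <- data.frame(candidate_id = candidate_id, outgroup = og,
                            n_cover_hits = nrow(kept),
                            min_marker_distance = dist, verdict = verdict,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(candidate_id = character(0), outgroup = character(0),
                      n_cover_hits = integer(0),
                      min_marker_distance = numeric(0),
                      verdict = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Check a peptide for sequence motifs
#'
#' Patterns are amino-acid strings where `X` matches any residue (e.g.
#' `"YXDD"`, the retroviral RT catalytic motif); other regular-expression
#' syntax over the amino-acid alphabet is passed through.
#'
#' @param peptide amino-acid string.
#' @param motifs named character vector of patterns.
#' @return data.frame with `motif`, `pattern`, `present`, `positions`
#'   (comma-separated match starts).
#' @export
motif_check <- function(peptide, motifs) {
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    stop("motifs must be named")
  rows <- lapply(names(motifs), function(nm) {
    pat <- gsub("X", ".", motifs[[nm]], fixed = TRUE)
    m <- gregexpr(pat, peptide)[[1]]
    ok <- m[1L] != -1L
    data.frame(motif = nm, pattern = motifs[[nm]], present = ok,
               positions = if (ok) paste(as.integer(m), collapse = ",")
                           else "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
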
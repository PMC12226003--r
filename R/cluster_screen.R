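#' Assign each gene its best phn family
#'
#' Filters profile-HMM hits at their per-family trusted cutoffs and keeps,
#' for each gene, the single highest-scoring surviving hit. Ties are broken
#' by the lexicographically smallest family name so results are
#' deterministic.
#'
#' @param hits Domain-hit table (`gene_id`, `family`, `bit_score`,
#'   `e_value`), e.g. from [read_domain_hits()].
#' @param cutoffs Named numeric vector of per-family trusted cutoffs
#'   (bit score); families missing from the vector reject all their hits.
#' @return A data.frame (`gene_id`, `family`, `bit_score`) with at most one
#'   row per gene, every `bit_score` at or above its family's cutoff.
#' @export
assign_families <- function(hits, cutoffs = default_cutoffs()) {
  empty <- data.frame(gene_id = character(), family = character(),
                      bit_score = numeric(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  bad <- setdiff(unique(hits$family), PHN_FAMILIES)
  if (length(bad)) stop("non-phn family in hits: ", paste(bad, collapse = ", "))
  cut <- unname(cutoffs[hits$family])
  keep <- !is.na(cut) & hits$bit_score >= cut
  surv <- hits[keep, c("gene_id", "family", "bit_score")]
  if (nrow(surv) == 0L) return(empty)
  # highest score wins per gene; ties to the alphabetically first family
  surv <- surv[order(surv$gene_id, -surv$bit_score, surv$family), ]
  out <- surv[!duplicated(surv$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Scan one contig for phn gene clusters
#'
#' Implements the windowed co-localization rule: a cluster is valid when at
#' least `k` distinct phn families lie within a `W`-nucleotide window on a
#' single contig (joint span from leftmost gene start to rightmost gene end,
#' inclusive) and the C-P lyase core families (`core`) are all present.
#' Duplicate paralogs of one family count once toward `k`.
#'
#' Candidates are built by anchoring a window at each phn gene's start and
#' collecting every phn gene fully contained in `[start, start + W - 1]`;
#' non-maximal member sets are dropped and calls sharing genes are merged
#' when the merged span still fits in `W`.
#'
#' @param features Gene features for one contig (`contig_id`, `gene_id`,
#'   `start`, `end`).
#' @param assignments Family assignments from [assign_families()].
#' @param W Window width in nucleotides (default 16000).
#' @param k Minimum number of distinct phn families (default 5).
#' @param core Character vector of families that must all be present
#'   (default `phnK`, `phnL`, `phnM`).
#' @param genome_id Optional genome label carried into the calls.
#' @return A data.frame of cluster calls: `genome_id`, `contig_id`,
#'   `members` (comma-joined gene ids in coordinate order), `n_genes`,
#'   `families` (comma-joined, sorted), `n_families`, `span_nt`,
#'   `window_ok`, `core_ok`, `valid`.
#' @export
scan_contig <- function(features, assignments, W = 16000L, k = 5L,
                        core = PHN_CORE, genome_id = NA_character_) {
  if (length(unique(features$contig_id)) > 1L) {
    stop("scan_contig expects features from a single contig")
  }
  unknown <- setdiff(assignments$gene_id, features$gene_id)
  if (length(unknown)) {
    stop("assignment references unknown gene_id: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  contig <- if (nrow(features)) features$contig_id[1] else NA_character_
  g <- merge(features, assignments, by = "gene_id")
  if (nrow(g) == 0L) return(empty_cluster_calls())
  g <- g[order(g$start, g$end, g$gene_id), ]

  member_sets <- lapply(seq_len(nrow(g)), function(i) {
    which(g$start >= g$start[i] & g$end <= g$start[i] + W - 1L)
  })
  member_sets <- Filter(length, member_sets)
  member_sets <- unique(member_sets)
  # keep maximal sets only
  is_sub <- vapply(seq_along(member_sets), function(i) {
    any(vapply(seq_along(member_sets), function(j) {
      i != j && all(member_sets[[i]] %in% member_sets[[j]]) &&
        length(member_sets[[i]]) < length(member_sets[[j]])
    }, logical(1)))
  }, logical(1))
  member_sets <- member_sets[!is_sub]

  # merge overlapping sets whose union still fits the window
  repeat {
    merged <- FALSE
    if (length(member_sets) > 1L) {
      for (i in seq_along(member_sets)) {
        for (j in seq_along(member_sets)) {
          if (i >= j) next
          a <- member_sets[[i]]; b <- member_sets[[j]]
          if (length(intersect(a, b)) == 0L) next
          u <- sort(union(a, b))
          if (max(g$end[u]) - min(g$start[u]) + 1L <= W) {
            member_sets[[i]] <- u
            member_sets[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  calls <- lapply(member_sets, function(idx) {
    fams <- sort(unique(g$family[idx]))
    span <- max(g$end[idx]) - min(g$start[idx]) + 1L
    window_ok <- span <= W
    core_ok <- all(core %in% fams)
    data.frame(
      genome_id = genome_id, contig_id = contig,
      members = paste(g$gene_id[idx], collapse = ","),
      n_genes = length(idx),
      families = paste(fams, collapse = ","),
      n_families = length(fams),
      span_nt = span, window_ok = window_ok, core_ok = core_ok,
      valid = length(fams) >= k && window_ok && core_ok,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  out <- out[order(-out$n_families, out$span_nt, out$members), ]
  rownames(out) <- NULL
  out
}

empty_cluster_calls <- function() {
  data.frame(genome_id = character(), contig_id = character(),
             members = character(), n_genes = integer(),
             families = character(), n_families = integer(),
             span_nt = integer(), window_ok = logical(),
             core_ok = logical(), valid = logical(),
             stringsAsFactors = FALSE)
}

#' Screen a whole genome for valid phn clusters
#'
#' Runs [scan_contig()] on every contig and declares the genome positive
#' when at least one valid cluster exists anywhere. All candidate calls
#' (valid and invalid) are returned for auditability.
#'
#' @param record One-row genome record (needs `genome_id`; if it carries a
#'   `contigs` data.frame in a list column, contig ids are cross-checked).
#' @param features Gene features for the genome (any number of contigs).
#' @param assignments Family assignments from [assign_families()].
#' @inheritParams scan_contig
#' @return A list with `positive` (logical) and `calls` (data.frame).
#' @export
screen_genome <- function(record, features, assignments, W = 16000L, k = 5L,
                          core = PHN_CORE) {
  genome_id <- record$genome_id[1]
  if (!is.null(record$contigs) && length(record$contigs)) {
    known <- record$contigs[[1]]$contig_id
    bad <- setdiff(unique(features$contig_id), known)
    if (length(bad)) {
      stop("features reference contigs absent from genome record: ",
           paste(bad, collapse = ", "))
    }
  }
  calls <- empty_cluster_calls()
  if (nrow(features)) {
    per_contig <- split(features, features$contig_id)
    ass_by_gene <- assignments[assignments$gene_id %in% features$gene_id, ,
                               drop = FALSE]
    calls <- do.call(rbind, lapply(per_contig, function(fc) {
      a <- ass_by_gene[ass_by_gene$gene_id %in% fc$gene_id, , drop = FALSE]
      scan_contig(fc, a, W = W, k = k, core = core, genome_id = genome_id)
    }))
    if (is.null(calls)) calls <- empty_cluster_calls()
    rownames(calls) <- NULL
  }
  list(positive = any(calls$valid), calls = calls)
}

#' Brute-force cluster oracle by exhaustive subset enumeration
#'
#' Test oracle for [scan_contig()]: enumerates every subset of phn-assigned
#' genes on one contig, keeps subsets with joint span at most `W`, at least
#' `k` distinct families, and all core families present, and returns the
#' maximal such subsets. Definitional and deliberately slow; guarded at 25
#' phn genes.
#'
#' @inheritParams scan_contig
#' @return A data.frame of valid maximal cluster calls (same columns as
#'   [scan_contig()], `valid` all `TRUE`); zero rows when no valid subset
#'   exists.
#' @export
brute_force_scan <- function(features, assignments, W = 16000L, k = 5L,
                             core = PHN_CORE, genome_id = NA_character_) {
  g <- merge(features, assignments, by = "gene_id")
  if (nrow(g) > 25L) {
    stop("brute_force_scan refuses contigs with more than 25 phn genes (got ",
         nrow(g), ")")
  }
  if (nrow(g) == 0L) return(empty_cluster_calls())
  g <- g[order(g$start, g$end, g$gene_id), ]
  fam_idx <- match(g$family, PHN_FAMILIES) - 1L
  core_idx <- match(intersect(core, PHN_FAMILIES), PHN_FAMILIES) - 1L
  sets <- bf_enumerate(as.integer(g$start), as.integer(g$end), fam_idx,
                       as.integer(W), as.integer(k), core_idx)
  if (length(sets) == 0L) return(empty_cluster_calls())
  out <- do.call(rbind, lapply(sets, function(idx) {
    fams <- sort(unique(g$family[idx]))
    span <- max(g$end[idx]) - min(g$start[idx]) + 1L
    data.frame(genome_id = genome_id, contig_id = g$contig_id[1],
               members = paste(g$gene_id[idx], collapse = ","),
               n_genes = length(idx),
               families = paste(fams, collapse = ","),
               n_families = length(fams), span_nt = span,
               window_ok = TRUE, core_ok = TRUE, valid = TRUE,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_families, out$span_nt, out$members), ]
  rownames(out) <- NULL
  out
}

#' Summarize a prevalence survey
#'
#' Rolls genome-level positive/negative verdicts up to overall, per-habitat
#' and per-taxon (phylum and order, GTDB lineage prefixes `p__`/`o__`)
#' counts and percentages. Percentages are rounded half-up to one decimal
#' place; habitat totals (including `unknown`) always sum to the number of
#' genomes.
#'
#' @param records Genome metadata (`genome_id`, `habitat`, `lineage`).
#' @param verdicts Named logical vector (`genome_id -> positive`) or a
#'   data.frame with columns `genome_id`, `positive`. Genomes without a
#'   verdict count as negative.
#' @return An object of class `phn_survey_summary`: a list with
#'   `total_genomes`, `positive_genomes`, `prevalence_pct`, `by_habitat`,
#'   `by_rank`.
#' @export
summarize_survey <- function(records, verdicts) {
  if (is.null(records) || nrow(records) == 0L) stop("no genomes to summarize")
  if (is.data.frame(verdicts)) {
    verdicts <- setNames(as.logical(verdicts$positive), verdicts$genome_id)
  }
  unknown <- setdiff(names(verdicts), records$genome_id)
  if (length(unknown)) {
    stop("verdict for genome absent from records: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  pos <- records$genome_id %in% names(verdicts)[verdicts]

  pct <- function(p, t) ifelse(t > 0, round_half_up(100 * p / t, 1), NA_real_)
  roll <- function(key) {
    tot <- table(key)
    ps <- tapply(as.integer(pos), key, sum)
    ps[is.na(ps)] <- 0L
    data.frame(group = names(tot), total = as.integer(tot),
               positive = as.integer(ps[names(tot)]),
               pct = pct(as.integer(ps[names(tot)]), as.integer(tot)),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  hab <- factor(records$habitat, levels = HABITATS)
  by_habitat <- roll(hab)
  names(by_habitat)[1] <- "habitat"

  phylum <- lineage_rank(records$lineage, "p")
  ord <- lineage_rank(records$lineage, "o")
  by_rank <- rbind(
    cbind(rank = "phylum", roll(factor(phylum))),
    cbind(rank = "order", roll(factor(ord)))
  )
  names(by_rank)[2] <- "taxon"

  structure(list(
    total_genomes = nrow(records),
    positive_genomes = sum(pos),
    prevalence_pct = pct(sum(pos), nrow(records)),
    by_habitat = by_habitat,
    by_rank = by_rank
  ), class = "phn_survey_summary")
}

# extract one GTDB rank ("p" -> p__ value) from a lineage string
lineage_rank <- function(lineage, prefix) {
  pat <- paste0("(^|;)\\s*", prefix, "__([^;]*)")
  m <- regmatches(lineage, regexpr(pat, lineage))
  out <- rep("unclassified", length(lineage))
  hit <- grepl(pat, lineage)
  out[hit] <- sub(pat, "\\2", regmatches(lineage, regexpr(pat, lineage)))
  out[out == ""] <- "unclassified"
  out
}

#' Render a percentage as an approximate whole-number label
#'
#' `8.7` becomes `"≈9%"` — the rounded form used when quoting
#' prevalences in running text.
#'
#' @param pct Percentage value(s).
#' @return Character vector like `"≈9%"`.
#' @export
format_approx_pct <- function(pct) {
  paste0("≈", format(round_half_up(pct, 0), trim = TRUE), "%")
}

#' Collapse rare groups of a rollup table for reporting
#'
#' Groups contributing less than `min_pct` percent of the positives are
#' collapsed into a single `other` row. Intended for rendering only; the
#' full counts in the summary object are never collapsed.
#'
#' @param rollup A `by_rank`-style data.frame (`taxon`/`habitat` grouping
#'   column, `total`, `positive`, `pct`).
#' @param min_pct Collapse threshold as percent of total positives
#'   (default 1).
#' @return The rollup with rare rows replaced by an aggregated `other` row.
#' @export
collapse_rare <- function(rollup, min_pct = 1) {
  key <- setdiff(names(rollup), c("rank", "total", "positive", "pct"))[1]
  tot_pos <- sum(rollup$positive)
  if (tot_pos == 0L) return(rollup)
  share <- 100 * rollup$positive / tot_pos
  rare <- share < min_pct
  if (!any(rare)) return(rollup)
  keep <- rollup[!rare, , drop = FALSE]
  oth <- rollup[1, , drop = FALSE]
  oth[[key]] <- "other"
  if ("rank" %in% names(oth)) oth$rank <- rollup$rank[1]
  oth$total <- sum(rollup$total[rare])
  oth$positive <- sum(rollup$positive[rare])
  oth$pct <- round_half_up(100 * oth$positive / max(oth$total, 1L), 1)
  out <- rbind(keep, oth)
  rownames(out) <- NULL
  out
}

#' @export
print.phn_survey_summary <- function(x, ...) {
  cat("phn gene-cluster survey\n")
  cat(sprintf("  %d/%d genomes positive (%.1f%%, %s)\n",
              x$positive_genomes, x$total_genomes, x$prevalence_pct,
              format_approx_pct(x$prevalence_pct)))
  cat("  by habitat:\n")
  hb <- x$by_habitat
  for (i in seq_len(nrow(hb))) {
    cat(sprintf("    %-11s %5d/%5d (%s%%)\n", hb$habitat[i], hb$positive[i],
                hb$total[i],
                ifelse(is.na(hb$pct[i]), "-", format(hb$pct[i]))))
  }
  invisible(x)
}

#' Write cluster calls as TSV
#' @param calls Cluster-call table from [scan_contig()]/[screen_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a survey summary as JSON
#' @param summary A `phn_survey_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
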
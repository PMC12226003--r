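#' Read gene features from a GFF3 file
#'
#' Parses `gene`/`CDS` records into a flat table of genomic intervals used by
#' the cluster screen. Coordinates are kept 1-based inclusive exactly as in
#' GFF3; downstream window logic uses the full `[start, end]` extent of each
#' gene, never a midpoint.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types GFF3 `type` values to keep (default `gene` and `CDS`;
#'   when a file carries both for the same locus, supply one of them).
#' @return A data.frame with columns `contig_id`, `gene_id`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `unknown`), one row per kept record.
#' @details Records whose attributes carry no `ID`, `gene_id` or `locus_tag`
#'   get a synthesized id `<contig>.<n>`. Malformed lines raise a parse error
#'   naming the offending line number; `end < start` raises a validation
#'   error. An empty file returns an empty table with a warning.
#' @export
read_gene_features <- function(path, feature_types = c("gene", "CDS")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0L) {
    warning("GFF3 file has no feature lines: ", path)
    return(empty_gene_features())
  }
  # structural pre-check so errors can name the line number
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("GFF3 parse error at line ", i, ": expected >= 8 tab-separated fields")
    }
    st <- suppressWarnings(as.integer(f[4])); en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en)) {
      stop("GFF3 parse error at line ", i, ": non-numeric coordinates")
    }
    if (en < st) {
      stop_validation("GFF3 validation error at line ", i, ": end (", en,
                      ") < start (", st, ")")
    }
    if (st < 1L) {
      stop_validation("GFF3 validation error at line ", i, ": start < 1")
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) {
    warning("GFF3 file has no ", paste(feature_types, collapse = "/"),
            " records: ", path)
    return(empty_gene_features())
  }
  md <- S4Vectors::mcols(gr)
  id <- rep(NA_character_, length(gr))
  for (col in c("ID", "gene_id", "locus_tag")) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      id[is.na(id) & !is.na(v)] <- v[is.na(id) & !is.na(v)]
    }
  }
  contig <- as.character(GenomicRanges::seqnames(gr))
  miss <- is.na(id)
  if (any(miss)) id[miss] <- paste0(contig[miss], ".", which(miss))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "unknown"
  out <- data.frame(
    contig_id = contig,
    gene_id = id,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    dup <- unique(out$gene_id[duplicated(out$gene_id)])
    stop_validation("duplicate gene_id in GFF3: ", paste(head(dup, 5), collapse = ", "))
  }
  out
}

empty_gene_features <- function() {
  data.frame(contig_id = character(), gene_id = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Write gene features as GFF3
#'
#' Inverse of [read_gene_features()]; used by the simulator and for
#' round-trip tests.
#'
#' @param features Gene-feature table (`contig_id`, `gene_id`, `start`,
#'   `end`, `strand`).
#' @param path Output file path.
#' @param type Feature type to write (default `CDS`).
#' @return `path`, invisibly.
#' @export
write_gene_features <- function(features, path, type = "CDS") {
  strand <- features$strand
  strand[!strand %in% c("+", "-")] <- "."
  lines <- c("##gff-version 3",
             sprintf("%s\tphnomp\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                     features$contig_id, type, features$start, features$end,
                     strand, features$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read profile-HMM domain hits
#'
#' Reads a whitespace-delimited HMMER-style hit table and keeps hits whose
#' query model is one of the 14 phn families. Two layouts are accepted:
#' HMMER3 `--domtblout` (>= 22 columns; target in column 1, query model in
#' column 4, full-sequence E-value and bit score in columns 7-8) and a
#' minimal 4-column layout `gene_id family bit_score e_value`.
#'
#' @param path Path to the hit table. `#`-prefixed lines are comments.
#' @return A data.frame with columns `gene_id`, `family`, `bit_score`,
#'   `e_value`; the number of rows dropped for carrying a non-phn query
#'   model is attached as attribute `n_dropped` and reported via message.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE, fill = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop("hit table format error: ", conditionMessage(e))
    })
  if (is.null(tab) || nrow(tab) == 0L) {
    out <- data.frame(gene_id = character(), family = character(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (ncol(tab) >= 22L) {         # HMMER3 domtblout
    hits <- data.frame(gene_id = as.character(tab[[1]]),
                       family = as.character(tab[[4]]),
                       bit_score = as.numeric(tab[[8]]),
                       e_value = as.numeric(tab[[7]]),
                       stringsAsFactors = FALSE)
  } else if (ncol(tab) == 4L) {   # minimal layout
    hits <- data.frame(gene_id = as.character(tab[[1]]),
                       family = as.character(tab[[2]]),
                       bit_score = as.numeric(tab[[3]]),
                       e_value = as.numeric(tab[[4]]),
                       stringsAsFactors = FALSE)
  } else {
    stop("hit table format error: expected HMMER domtblout (>= 22 columns) ",
         "or 4-column layout, got ", ncol(tab), " columns")
  }
  if (anyNA(hits$bit_score) || anyNA(hits$e_value)) {
    stop("hit table format error: non-numeric score/E-value fields")
  }
  if (any(hits$e_value < 0)) {
    stop_validation("negative E-value in hit table")
  }
  keep <- hits$family %in% PHN_FAMILIES
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " hit(s) with non-phn query model dropped")
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a minimal 4-column domain-hit table
#' @param hits Hit table (`gene_id`, `family`, `bit_score`, `e_value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  write.table(hits[, c("gene_id", "family", "bit_score", "e_value")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genome metadata
#'
#' Reads a TSV with columns `genome_id`, `habitat`, `lineage` (GTDB-style
#' `d__...;p__...;...` string). Habitat is normalized case-insensitively to
#' the closed vocabulary `freshwater`, `aquatic`, `soil`, `sediment`;
#' anything else becomes `unknown` with a warning, so prevalence
#' denominators stay unambiguous.
#'
#' @param path Path to the metadata TSV (header required).
#' @return A data.frame with columns `genome_id`, `habitat`, `lineage`.
#' @export
read_genome_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  need <- c("genome_id", "habitat", "lineage")
  if (!all(need %in% names(tab))) {
    stop("metadata format error: need columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$genome_id)) {
    dup <- unique(tab$genome_id[duplicated(tab$genome_id)])
    stop_validation("duplicate genome_id in metadata: ",
                    paste(head(dup, 10), collapse = ", "))
  }
  hab <- tolower(trimws(tab$habitat))
  bad <- !hab %in% setdiff(HABITATS, "unknown")
  if (any(bad)) {
    warning(sum(bad), " genome(s) with habitat outside {",
            paste(setdiff(HABITATS, "unknown"), collapse = ", "),
            "} mapped to 'unknown'")
    hab[bad] <- "unknown"
  }
  data.frame(genome_id = as.character(tab$genome_id), habitat = hab,
             lineage = as.character(tab$lineage), stringsAsFactors = FALSE)
}

#' Write genome metadata TSV
#' @param records Metadata table (`genome_id`, `habitat`, `lineage`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_metadata <- function(records, path) {
  write.table(records[, c("genome_id", "habitat", "lineage")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an incubation measurement table
#'
#' Reads a CSV/TSV of timestamped bottle observations. Recognized columns:
#' `treatment`, `replicate`, `time` (hours) plus any of `headspace_ppm`,
#' `peak_area`, `TDP`, `DIP`, `cells`, `Pi_initial` (micromolar / counts
#' per mL). Time must be non-negative and strictly increasing within each
#' (treatment, replicate) series.
#'
#' @param path Path to the table; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @return A validated data.frame of measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_measurements(tab)
}

#' Validate an in-memory measurement table
#' @param tab Measurement data.frame (see [read_measurements()]).
#' @return `tab`, with `treatment`/`replicate` defaulted when absent.
#' @export
validate_measurements <- function(tab) {
  if (!"time" %in% names(tab)) stop("measurement table needs a 'time' column")
  if (!"treatment" %in% names(tab)) tab$treatment <- "default"
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  if (any(tab$time < 0)) stop_validation("negative time in measurement table")
  key <- interaction(tab$treatment, tab$replicate, drop = TRUE)
  for (g in split(tab$time, key)) {
    if (length(g) > 1L && any(diff(g) <= 0)) {
      stop_validation("time not strictly increasing within a ",
                      "(treatment, replicate) series")
    }
  }
  num <- intersect(c("headspace_ppm", "peak_area", "TDP", "DIP", "cells"),
                   names(tab))
  for (col in num) {
    if (any(tab[[col]] < 0, na.rm = TRUE)) {
      stop_validation("negative values in column ", col)
    }
  }
  tab
}

#' Write a measurement table
#' @param tab Measurement data.frame.
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(tab, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-family trusted-cutoff table
#'
#' Two columns, `family` and `trusted_cutoff` (TSV with header, or a YAML
#' map `family: cutoff`). Per-model trusted cutoffs are the bit-score
#' thresholds above which a profile-HMM hit is accepted without further
#' filtering.
#'
#' @param path TSV or YAML file.
#' @return Named numeric vector, one cutoff per phn family present.
#' @export
read_cutoffs <- function(path) {
  if (!file.exists(path)) stop("cutoff table not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    out <- unlist(lst)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("family", "trusted_cutoff") %in% names(tab))) {
      stop("cutoff table needs columns family, trusted_cutoff")
    }
    out <- setNames(as.numeric(tab$trusted_cutoff), tab$family)
  }
  bad <- setdiff(names(out), PHN_FAMILIES)
  if (length(bad)) stop("unknown phn family in cutoff table: ",
                        paste(bad, collapse = ", "))
  out
}

#' Default trusted cutoffs shipped for simulation
#'
#' Convenience accessor for `inst/extdata/phn_trusted_cutoffs.tsv`: synthetic
#' default bit-score cutoffs used by the simulator and tests. Real screens
#' should supply the trusted cutoffs of their own curated HMM models via
#' [read_cutoffs()].
#'
#' @return Named numeric vector of per-family cutoffs.
#' @export
default_cutoffs <- function() {
  read_cutoffs(system.file("extdata", "phn_trusted_cutoffs.tsv",
                           package = "phnomp", mustWork = TRUE))
}
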
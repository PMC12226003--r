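# Shared fixture builders: everything is generated in code, nothing on disk.

# a contig's feature table from family names and (start, end) pairs
contig_features <- function(families, starts, ends, contig = "c1") {
  data.frame(contig_id = contig,
             gene_id = paste0(contig, ".", families, ".", seq_along(families)),
             start = as.integer(starts), end = as.integer(ends),
             strand = "+", stringsAsFactors = FALSE)
}

# matching assignments (all above cutoff by construction)
contig_assignments <- function(features, families) {
  data.frame(gene_id = features$gene_id, family = families,
             bit_score = 200, stringsAsFactors = FALSE)
}

# lay out n genes left to right with given lengths and gaps
tandem_layout <- function(lengths, gaps, at = 1000L) {
  starts <- at + cumsum(c(0L, head(lengths + gaps, -1L)))
  list(starts = starts, ends = starts + lengths - 1L)
}

# a random contig of n phn genes for oracle-equivalence checks
random_phn_contig <- function(n, max_pos = 60000L) {
  starts <- sort(sample.int(max_pos, n))
  lens <- sample(300:1500, n, replace = TRUE)
  fams <- sample(PHN_FAMILIES, n, replace = TRUE)
  feats <- contig_features(fams, starts, starts + lens)
  list(features = feats, assignments = contig_assignments(feats, fams))
}

# a compact contig guaranteed to carry the core plus extra families,
# usually (but not always) a valid cluster at the default window
dense_phn_contig <- function(n_extra = 4, width = 14000L) {
  n <- 3L + n_extra
  starts <- sort(sample.int(width, n))
  lens <- sample(300:900, n, replace = TRUE)
  fams <- c(PHN_CORE, sample(PHN_FAMILIES, n_extra, replace = TRUE))
  feats <- contig_features(fams, starts, starts + lens)
  list(features = feats, assignments = contig_assignments(feats, fams))
}

# write a FASTA string to a temp file
temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.character(unlist(lapply(names(records), function(nm) {
    c(paste0(">", nm), records[[nm]])
  }))), path)
  path
}

# closed-form planted CH4 trajectory (umol/L): lag slope then production slope
planted_true_ch4 <- function(t, rate = 92, lag_rate = 4, lag_hours = 24) {
  (lag_rate * pmin(t, lag_hours) + rate * pmax(t - lag_hours, 0)) / 1000
}
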
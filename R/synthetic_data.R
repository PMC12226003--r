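#' Specification for a synthetic genome survey
#'
#' Describes a simulated genome collection with planted phn clusters and
#' decoys, emulating the inputs of a database-wide cluster screen. Decoy
#' types enumerate the screening rules: `four_gene` (fewer than five
#' distinct families), `missing_core` (no phnK/L/M), `overspread` (families
#' spaced so no 16 kb window holds five), `split_contig` (cluster split
#' across contigs so neither part validates), `subthreshold_scores` (intact
#' architecture but bit scores below the trusted cutoffs). Decoy rates are
#' proportions of the negative genomes; the remainder carry background
#' genes only.
#'
#' @param n_genomes Number of genomes.
#' @param prevalence Fraction of genomes with a planted valid cluster; the
#'   planted positive count is `round(n_genomes * prevalence)`.
#' @param habitat_mix Named proportions over freshwater/aquatic/soil/
#'   sediment (must sum to 1).
#' @param gene_length_range Planted gene length range, nt.
#' @param gap_range Planted intergenic gap range, nt.
#' @param decoy_rates Named proportions over the five decoy types.
#' @param background_gene_density Background genes per 10 kb of contig.
#' @param contig_length Contig length in nt.
#' @param seed Integer RNG seed (reproducibility contract).
#' @return A list of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_genomes = 200, prevalence = 0.1,
                            habitat_mix = c(freshwater = 0.07,
                                            aquatic = 0.35,
                                            soil = 0.40, sediment = 0.18),
                            gene_length_range = c(600, 900),
                            gap_range = c(50, 250),
                            decoy_rates = c(four_gene = 0.15,
                                            missing_core = 0.15,
                                            overspread = 0.15,
                                            split_contig = 0.15,
                                            subthreshold_scores = 0.15),
                            background_gene_density = 2,
                            contig_length = 50000L, seed = 1L) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            all(habitat_mix >= 0), all(decoy_rates >= 0),
            sum(decoy_rates) <= 1)
  if (abs(sum(habitat_mix) - 1) > 1e-8) stop("habitat_mix must sum to 1")
  # a full 14-gene cluster must be plantable inside the 16 kb window
  max_span <- 14 * gene_length_range[2] + 13 * gap_range[2]
  if (max_span > 16000) {
    stop("impossible spec: cluster architecture can exceed the 16 kb window (",
         max_span, " nt)")
  }
  structure(list(n_genomes = n_genomes, prevalence = prevalence,
                 habitat_mix = habitat_mix,
                 gene_length_range = gene_length_range,
                 gap_range = gap_range, decoy_rates = decoy_rates,
                 background_gene_density = background_gene_density,
                 contig_length = as.integer(contig_length),
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

# GTDB-style lineages used for rollup realism; positives are drawn mostly
# from Pseudomonadota (the phylum dominating phn-positive genomes).
.SIM_LINEAGES <- c(
  pseudo_burk = "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Burkholderiales;f__Comamonadaceae;g__Variovorax;s__",
  pseudo_entero = "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__Escherichia;s__",
  pseudo_rhizo = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Rhizobiales;f__Rhizobiaceae;g__Mesorhizobium;s__",
  actino = "d__Bacteria;p__Actinomycetota;c__Actinomycetes;o__Mycobacteriales;f__Mycobacteriaceae;g__Mycobacterium;s__",
  bacillota = "d__Bacteria;p__Bacillota;c__Bacilli;o__Bacillales;f__Bacillaceae;g__Bacillus;s__",
  bacteroidota = "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Flavobacteriales;f__Flavobacteriaceae;g__Flavobacterium;s__"
)

#' Simulate a genome survey with planted phn clusters and decoys
#'
#' Generates genome metadata, gene features, domain hits and a truth table.
#' Every planted positive satisfies the cluster validity rule by
#' construction; every decoy violates exactly its designated condition.
#' Reproducible bit-for-bit given the spec's seed.
#'
#' @param spec A [genome_sim_spec()].
#' @param cutoffs Per-family trusted cutoffs used to place planted scores
#'   above (or, for `subthreshold_scores` decoys, below) threshold.
#' @return A list with `records` (metadata), `features`, `hits`, `truth`
#'   (`genome_id`, `positive`, `decoy_type`), and `cutoffs`.
#' @export
simulate_survey <- function(spec, cutoffs = default_cutoffs()) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genomes
    ids <- sprintf("G%04d", seq_len(n))
    n_pos <- round(n * spec$prevalence)
    pos_ids <- sort(sample(ids, n_pos))
    neg_ids <- setdiff(ids, pos_ids)

    # decoy allocation among negatives
    decoy <- rep("background", length(neg_ids))
    if (length(neg_ids)) {
      p <- c(spec$decoy_rates, background = 1 - sum(spec$decoy_rates))
      decoy <- sample(names(p), length(neg_ids), replace = TRUE, prob = p)
    }
    decoy_type <- setNames(rep("none", n), ids)
    decoy_type[neg_ids] <- decoy

    habitat <- sample(names(spec$habitat_mix), n, replace = TRUE,
                      prob = spec$habitat_mix)
    lineage_pool <- function(is_pos) {
      if (is_pos && runif(1) < 0.9) sample(.SIM_LINEAGES[1:3], 1)
      else sample(.SIM_LINEAGES, 1)
    }
    lineage <- vapply(ids %in% pos_ids, lineage_pool, character(1))

    records <- data.frame(genome_id = ids, habitat = habitat,
                          lineage = unname(lineage),
                          stringsAsFactors = FALSE)

    feats <- list(); hits <- list()
    for (gid in ids) {
      sim <- simulate_genome(gid, decoy_type[[gid]] == "none",
                             decoy_type[[gid]], spec, cutoffs)
      feats[[gid]] <- sim$features
      hits[[gid]] <- sim$hits
    }
    features <- do.call(rbind, feats); rownames(features) <- NULL
    hits <- do.call(rbind, hits); rownames(hits) <- NULL

    truth <- data.frame(genome_id = ids,
                        positive = ids %in% pos_ids,
                        decoy_type = unname(decoy_type[ids]),
                        stringsAsFactors = FALSE)
    list(records = records, features = features, hits = hits, truth = truth,
         cutoffs = cutoffs)
  })
}

# lay out genes left-to-right from `at`, returning start/end matrix
lay_genes <- function(n_genes, at, len_range, gap_range) {
  lens <- round(runif(n_genes, len_range[1], len_range[2]))
  gaps <- round(runif(n_genes, gap_range[1], gap_range[2]))
  starts <- at + cumsum(c(0, (lens + gaps)[-n_genes]))
  cbind(start = starts, end = starts + lens - 1)
}

simulate_genome <- function(gid, positive, decoy, spec, cutoffs) {
  clen <- spec$contig_length
  contigs <- paste0(gid, ".c", 1:2)
  feats <- list(); hits <- list()

  plant <- function(contig, families, at, gap_range = spec$gap_range,
                    above = TRUE) {
    xy <- lay_genes(length(families), at, spec$gene_length_range, gap_range)
    gene_ids <- paste0(contig, ".", families)
    f <- data.frame(genome_id = gid, contig_id = contig, gene_id = gene_ids,
                    start = as.integer(xy[, "start"]),
                    end = as.integer(xy[, "end"]),
                    strand = "+", stringsAsFactors = FALSE)
    score <- if (above) cutoffs[families] + runif(length(families), 5, 50)
             else cutoffs[families] - runif(length(families), 1, 10)
    h <- data.frame(gene_id = gene_ids, family = families,
                    bit_score = round(unname(score), 1),
                    e_value = 10^-runif(length(families), 10, 50),
                    stringsAsFactors = FALSE)
    list(f = f, h = h)
  }

  at0 <- sample(1000:5000, 1)
  if (positive) {
    p <- plant(contigs[1], PHN_FAMILIES, at0)
    feats <- c(feats, list(p$f)); hits <- c(hits, list(p$h))
  } else if (decoy == "four_gene") {
    p <- plant(contigs[1], c("phnJ", "phnK", "phnL", "phnM"), at0)
    feats <- c(feats, list(p$f)); hits <- c(hits, list(p$h))
  } else if (decoy == "missing_core") {
    p <- plant(contigs[1], paste0("phn", LETTERS[3:10]), at0)  # phnC..phnJ
    feats <- c(feats, list(p$f)); hits <- c(hits, list(p$h))
  } else if (decoy == "overspread") {
    # gaps so wide that no 16 kb window holds five genes
    p <- plant(contigs[1], PHN_FAMILIES, at0, gap_range = c(4500, 5000))
    feats <- c(feats, list(p$f)); hits <- c(hits, list(p$h))
  } else if (decoy == "split_contig") {
    p1 <- plant(contigs[1], paste0("phn", LETTERS[3:10]), at0)  # no core
    p2 <- plant(contigs[2], PHN_CORE, at0)                      # core only
    feats <- c(feats, list(p1$f, p2$f)); hits <- c(hits, list(p1$h, p2$h))
  } else if (decoy == "subthreshold_scores") {
    p <- plant(contigs[1], PHN_FAMILIES, at0, above = FALSE)
    feats <- c(feats, list(p$f)); hits <- c(hits, list(p$h))
  }

  # background genes without phn hits
  n_bg <- round(spec$background_gene_density * clen / 1e4)
  if (n_bg > 0) {
    bs <- sort(sample(seq(25000L, clen - 2000L), n_bg))
    feats <- c(feats, list(data.frame(
      genome_id = gid, contig_id = contigs[1],
      gene_id = paste0(contigs[1], ".bg", seq_len(n_bg)),
      start = bs, end = bs + 999L, strand = "-",
      stringsAsFactors = FALSE
    )))
  }
  list(features = do.call(rbind, feats),
       hits = if (length(hits)) do.call(rbind, hits) else
         data.frame(gene_id = character(), family = character(),
                    bit_score = numeric(), e_value = numeric()))
}

#' Write a simulated survey in the on-disk dialects the readers consume
#'
#' Emits `features.gff3`, `hits.tsv` (4-column layout), `metadata.tsv`,
#' `truth.tsv` and `contig_map.tsv` (genome to contig assignment) under
#' `dir`. The overspread decoys need contigs longer than the default, so
#' contig lengths in the map are taken from the realized features.
#'
#' @param sim Output of [simulate_survey()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_survey_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_features(sim$features, file.path(dir, "features.gff3"))
  write_domain_hits(sim$hits, file.path(dir, "hits.tsv"))
  write_genome_metadata(sim$records, file.path(dir, "metadata.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cmap <- unique(sim$features[, c("genome_id", "contig_id")])
  write.table(cmap, file.path(dir, "contig_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Specification for a synthetic MPn incubation experiment
#'
#' Plants the kinetics the quantitation chain must recover: a lag phase
#' with a low methane production rate and a low CH4-to-DOP stoichiometric
#' ratio, a post-lag linear production phase, a ratio ramp to its
#' asymptote, logistic cell growth, and monotone phosphate inhibition
#' across initial Pi levels.
#'
#' @param duration Total incubation length, hours (default 288 = 12 days).
#' @param times Sampling times in hours; default: every 6 h for the first
#'   24 h, then every 48 h (the dense-then-sparse bottle-sacrifice
#'   schedule).
#' @param planted_rate Post-lag CH4 production rate, nmol L^-1 h^-1.
#' @param lag_rate Lag-phase CH4 production rate, nmol L^-1 h^-1.
#' @param lag_hours Lag length, hours.
#' @param lag_ratio ΔCH4/ΔDOP during the lag (dimensionless).
#' @param asymptotic_ratio ΔCH4/ΔDOP at stationary phase; must be >=
#'   `lag_ratio`.
#' @param ramp_end Hour at which the ratio reaches its asymptote.
#' @param dop0 Initial DOP (the MPn phosphorus pool), umol/L.
#' @param dip0 Initial residual DIP, umol/L.
#' @param pi_levels Initial Pi amendments, umol/L, one treatment each.
#' @param inhibition_K Half-inhibition Pi concentration of the monotone
#'   hyperbolic inhibition factor `1 / (1 + Pi / K)`, umol/L.
#' @param noise_sd List of Gaussian measurement noise parameters:
#'   `ppm_rel` (relative SD of the headspace mixing ratio, FID-style
#'   proportional noise), `ppm_floor` (absolute SD floor in ppm, the
#'   detection-limit scale), `phosphorus` (absolute SD of TDP and DIP,
#'   umol/L), `cells` (absolute SD, counts/mL). Scalar 0 switches all
#'   noise off.
#' @param n_replicates Replicate bottles per treatment and timepoint.
#' @param geometry A [bottle_geometry()].
#' @param seed Integer RNG seed.
#' @return A list of class `incubation_sim_spec`.
#' @export
incubation_sim_spec <- function(duration = 288, times = NULL,
                                planted_rate = 92, lag_rate = 4.0,
                                lag_hours = 24, lag_ratio = 0.4,
                                asymptotic_ratio = 1.0, ramp_end = 240,
                                dop0 = 200, dip0 = 0.1,
                                pi_levels = c(0, 5, 10, 20, 30, 40),
                                inhibition_K = 10,
                                noise_sd = list(ppm_rel = 0.02,
                                                ppm_floor = 0.05,
                                                phosphorus = 0.3,
                                                cells = 5e4),
                                n_replicates = 3,
                                geometry = bottle_geometry(), seed = 1L) {
  if (is.null(times)) {
    times <- unique(c(seq(0, min(24, duration), by = 6),
                      seq(72, duration, by = 48), duration))
  }
  if (is.numeric(noise_sd) && length(noise_sd) == 1L) {
    noise_sd <- list(ppm_rel = noise_sd, ppm_floor = noise_sd,
                     phosphorus = noise_sd, cells = noise_sd)
  }
  stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE),
            planted_rate >= 0, lag_rate >= 0, lag_hours >= 0,
            lag_ratio <= asymptotic_ratio, dop0 >= 0,
            all(pi_levels >= 0), inhibition_K > 0, n_replicates >= 1)
  structure(list(duration = duration, times = times,
                 planted_rate = planted_rate, lag_rate = lag_rate,
                 lag_hours = lag_hours, lag_ratio = lag_ratio,
                 asymptotic_ratio = asymptotic_ratio, ramp_end = ramp_end,
                 dop0 = dop0, dip0 = dip0, pi_levels = pi_levels,
                 inhibition_K = inhibition_K, noise_sd = noise_sd,
                 n_replicates = n_replicates, geometry = geometry,
                 seed = as.integer(seed)),
            class = "incubation_sim_spec")
}

# planted true CH4 (umol/L, total per liquid) and ratio trajectory
planted_ch4 <- function(t, spec, inhibit = 1) {
  (spec$lag_rate * pmin(t, spec$lag_hours) +
     spec$planted_rate * pmax(t - spec$lag_hours, 0)) * inhibit / 1000
}

planted_ratio <- function(t, spec) {
  lo <- spec$lag_ratio; hi <- spec$asymptotic_ratio
  frac <- (t - spec$lag_hours) / max(spec$ramp_end - spec$lag_hours, 1e-9)
  lo + (hi - lo) * pmin(pmax(frac, 0), 1)
}

#' Simulate an MPn incubation measurement table
#'
#' One treatment per initial Pi level (named `Pi_<level>`), `n_replicates`
#' bottle series each. CH4 accrues piecewise-linearly (lag then production
#' phase), scaled per treatment by the hyperbolic Pi inhibition factor;
#' DOP declines as cumulative CH4 divided by the planted ratio trajectory,
#' so the asymptotic ΔCH4/ΔDOP equals the spec's `asymptotic_ratio`.
#' Headspace mixing ratios are back-computed through the same bottle
#' partition model the quantitation chain inverts, so noise-free tables
#' round-trip exactly. Gaussian noise is added per observable; draws that
#' would go negative are resampled (count attached as attribute
#' `n_resampled`), never clamped.
#'
#' @param spec An [incubation_sim_spec()].
#' @return A measurement data.frame (`treatment`, `replicate`, `time`,
#'   `headspace_ppm`, `TDP`, `DIP`, `cells`, `Pi_initial`) with the spec
#'   attached as attribute `truth`.
#' @export
simulate_incubation <- function(spec) {
  stopifnot(inherits(spec, "incubation_sim_spec"))
  with_seed(spec$seed, {
    n_res <- 0L
    noisy <- function(x, sd) {
      sd <- rep_len(sd, length(x))
      if (all(sd == 0)) return(x)
      out <- rnorm(length(x), x, sd)
      for (i in seq_along(out)) {
        tries <- 0L
        while (out[i] < 0 && tries < 1000L) {
          out[i] <- rnorm(1, x[i], sd[i])
          tries <- tries + 1L
          n_res <<- n_res + 1L
        }
        if (out[i] < 0) out[i] <- 0   # pathological sd >> mean; logged
      }
      out
    }
    rows <- list()
    for (pi0 in spec$pi_levels) {
      inhibit <- 1 / (1 + pi0 / spec$inhibition_K)
      for (r in seq_len(spec$n_replicates)) {
        t <- spec$times
        ch4 <- planted_ch4(t, spec, inhibit)
        ratio <- planted_ratio(t, spec)
        dop <- spec$dop0 - ch4 / ratio
        if (any(dop < 0)) {
          stop("impossible spec: planted DOP drawdown exceeds dop0")
        }
        dip <- rep(spec$dip0, length(t))
        total_nmol <- ch4 * 1000 * spec$geometry$V_liq
        ppm <- mixing_ratio_from_total(total_nmol, spec$geometry)
        cells <- 1e5 + (1e8 - 1e5) / (1 + exp(-0.05 * (t - 140)))
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = paste0("Pi_", pi0), replicate = r, time = t,
          headspace_ppm = noisy(ppm, spec$noise_sd$ppm_rel * ppm +
                                  spec$noise_sd$ppm_floor),
          TDP = noisy(dop + dip, spec$noise_sd$phosphorus),
          DIP = noisy(dip, spec$noise_sd$phosphorus),
          cells = noisy(cells, spec$noise_sd$cells),
          Pi_initial = pi0, stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- spec
    attr(out, "n_resampled") <- n_res
    if (n_res > 0) message(n_res, " negative noise draw(s) resampled")
    out
  })
}
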
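# Reproducible benchmark experiments on synthetic data. Each function
# generates its inputs from a seed, runs the relevant pipeline stages,
# and measures performance against the planted ground truth. These are
# the package's figure-analog validation experiments; the test suite and
# the acceptance script are thin wrappers around them.

#' Null calibration of the modification caller
#'
#' Simulates kinetics with no planted modifications (IPD multiplier acts
#' on nothing) and measures the fraction of candidate sites reaching the
#' primary score threshold (mQv >= 22). Under a calibrated caller this
#' rate cannot exceed the nominal per-site level 10^-2.2.
#'
#' @param seed RNG seed.
#' @param n_sites number of null sites (one per genome bp).
#' @param min_score score threshold whose exceedance rate is measured.
#' @return list: rate, n, threshold_rate (10^(-min_score/10)), and the
#'   3-SE binomial bound on the null rate.
#' @export
benchmark_null_calibration <- function(seed = 1L, n_sites = 12000L,
                                       min_score = 22) {
  cfg <- sim_config(seed = seed,
                    genome = list(length = as.integer(n_sites), n_contigs = 1L),
                    genes = list(n = 0L), te_families = empty_te_families(),
                    tandem_repeats = list(n = 0L),
                    meth_4mC = list(prob = 0), meth_6mA = list(prob = 0))
  genome <- simulate_genome(cfg)
  kin <- simulate_kinetics(genome, empty_methylome(), cfg)
  calls <- call_modifications(kin, genome, call_filter())
  rate <- sum(calls$score >= min_score) / nrow(kin)
  p0 <- 10^(-min_score / 10)
  list(rate = rate, n = nrow(kin), threshold_rate = p0,
       bound = p0 + 3 * sqrt(p0 * (1 - p0) / nrow(kin)))
}

empty_te_families <- function() {
  new_df(name = character(), consensus_length = integer(), n_full = integer(),
         n_medium = integer(), n_short = integer())
}

#' Caller recovery on a fully methylated planted methylome
#'
#' Default 200-kb genome, IPD multiplier 3, sigma 0.4, 25x coverage,
#' all planted fractions 1.0. Recall and precision of primary calls are
#' measured against the true methylome by (contig, position, strand).
#'
#' @param seed RNG seed.
#' @return list: recall, precision, n_truth, n_primary.
#' @export
benchmark_caller_recovery <- function(seed = 1L) {
  cfg <- sim_config(seed = seed,
                    meth_4mC = list(frac_full = 1),
                    meth_6mA = list(frac_full = 1))
  genome <- simulate_genome(cfg)
  truth <- plant_methylome(genome, cfg)
  kin <- simulate_kinetics(genome, truth, cfg)
  calls <- call_modifications(kin, genome, call_filter())
  primary <- calls[calls$primary, , drop = FALSE]
  key <- function(d) paste(d$contig, d$pos, d$strand)
  tp <- sum(key(primary) %in% key(truth))
  list(recall = tp / nrow(truth), precision = tp / nrow(primary),
       n_truth = nrow(truth), n_primary = nrow(primary))
}

#' Fraction-estimator recovery across planted levels
#'
#' Plants sites at fractions 0.25 / 0.5 / 0.75 / 1.0, simulates 50x
#' kinetics, estimates per-site fractions and measures mean absolute
#' error per level plus the agreement of estimated level classes with
#' the truth classes.
#'
#' @param seed RNG seed.
#' @param n_per_level planted sites per fraction level.
#' @param levels planted fraction levels.
#' @return list: per_level (data.frame fraction/n/mae/class_accuracy),
#'   max_mae, class_accuracy (overall).
#' @export
benchmark_fraction_recovery <- function(seed = 1L, n_per_level = 2000L,
                                        levels = c(0.25, 0.5, 0.75, 1.0)) {
  n_tot <- n_per_level * length(levels)
  cfg <- sim_config(seed = seed,
                    genome = list(length = as.integer(5L * n_tot), n_contigs = 1L),
                    genes = list(n = 0L), te_families = empty_te_families(),
                    tandem_repeats = list(n = 0L),
                    meth_4mC = list(prob = 0), meth_6mA = list(prob = 0),
                    kinetics = list(passes = 50))
  genome <- simulate_genome(cfg)
  ch <- seq_chars(genome$contigs[[1]])
  set.seed(stage_seed(seed, 11L))
  pos <- sample(length(ch), n_tot) - 1L
  strand <- unname(c(A = "+", C = "+", G = "-", T = "-")[ch[pos + 1L]])
  mark <- unname(ifelse(c(A = "A", C = "C", G = "C", T = "A")[ch[pos + 1L]] == "C",
                        "4mC", "6mA"))
  truth <- new_df(contig = "contig_01", pos = pos, strand = strand, mark = mark,
                  fraction = rep(levels, each = n_per_level))
  kin <- simulate_kinetics(genome, truth, cfg, positions = truth)
  mult <- attr(kin, "multiplier")
  est <- vapply(kin$native, estimate_fraction, 0,
                unmod_meanlog = 0, mod_meanlog = log(mult))
  est_cls <- classify_fraction(est)
  true_cls <- classify_fraction(kin$true_fraction)
  per <- do.call(rbind, lapply(levels, function(f) {
    i <- kin$true_fraction == f
    new_df(fraction = f, n = sum(i), mae = mean(abs(est[i] - f)),
           class_accuracy = mean(est_cls[i] == true_cls[i]))
  }))
  list(per_level = per, max_mae = max(per$mae),
       class_accuracy = mean(est_cls == true_cls))
}

#' DIP-seq peak recovery on planted methylated clusters
#'
#' A genome carrying 60 compact fully methylated clusters (250-bp TE
#' copies) is sequenced by simulated DIP with 10x capture enrichment;
#' peaks are called at p < 1e-5 against the global Poisson background.
#' Measures cluster recall, the fraction of summits within 100 bp of the
#' planted cluster centre (mean position of the planted marks), and the
#' significant-bin count of a matched no-enrichment (null) simulation.
#'
#' @param seed RNG seed.
#' @param n_clusters number of planted clusters.
#' @param library_size DIP library size.
#' @return list: cluster_recall, summit_within_100bp, n_clusters,
#'   null_sig_bins, null_bins, null_bound.
#' @export
benchmark_peak_recovery <- function(seed = 1L, n_clusters = 60L,
                                    library_size = 500000L) {
  mkcfg <- function(odds) {
    sim_config(seed = seed,
               genome = list(length = 300000L, n_contigs = 3L),
               genes = list(n = 0L),
               te_families = new_df(name = "cluster", consensus_length = 250L,
                                    n_full = as.integer(n_clusters),
                                    n_medium = 0L, n_short = 0L),
               tandem_repeats = list(n = 0L),
               meth_4mC = list(prob = 1, copy_prob = 1, tr_prob = 0,
                               context_weights = c(CG = 1, CA = 1, CC = 1, CT = 1),
                               frac_full = 1, te5p_floor = 1),
               meth_6mA = list(prob = 0),
               dip = list(library_size = as.integer(library_size),
                          capture_odds = odds))
  }
  cfg <- mkcfg(10)
  genome <- simulate_genome(cfg)
  truth <- plant_methylome(genome, cfg)
  dip <- simulate_dipseq(genome, truth, cfg)
  track <- bin_coverage(dip$dip4mC, genome, 10L, cfg$dip$read_len)
  peaks <- call_peaks(track)
  te <- genome$te_copies
  centre <- vapply(seq_len(nrow(te)), function(i) {
    p <- truth$pos[truth$contig == te$contig[i] &
                     truth$pos >= te$start[i] & truth$pos < te$end[i]]
    if (length(p) < 3L) NA_real_ else round(mean(p))
  }, 0)
  keep <- which(!is.na(centre))
  hit <- logical(length(keep)); dist <- rep(NA_real_, length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    pp <- peaks[peaks$contig == te$contig[i] &
                  peaks$end > te$start[i] - 200L &
                  peaks$start < te$end[i] + 200L, , drop = FALSE]
    if (nrow(pp)) {
      hit[j] <- TRUE
      dist[j] <- min(abs(pp$summit - centre[i]))
    }
  }
  # matched null: no capture enrichment
  cfg0 <- mkcfg(0)
  dip0 <- simulate_dipseq(genome, truth, cfg0)
  track0 <- bin_coverage(dip0$dip4mC, genome, 10L, cfg$dip$read_len)
  v0 <- unlist(track0$values, use.names = FALSE)
  p0 <- ppois(ceiling(v0) - 1, mean(v0), lower.tail = FALSE)
  thr <- 1e-5
  list(cluster_recall = mean(hit),
       summit_within_100bp = mean(dist[hit] <= 100),
       n_clusters = length(keep),
       null_sig_bins = sum(p0 < thr), null_bins = length(v0),
       null_bound = thr * length(v0) + 3 * sqrt(thr * length(v0)))
}

#' Spatial-correlation power and calibration
#'
#' Power: the planted 4mC sites of a default genome are tested against
#' the TE copies they were planted in (Jaccard statistic, 999
#' permutations). Calibration: uniformly placed query intervals are
#' tested against the same reference across `n_calib` seeded runs (199
#' permutations each), recording how often p > 0.05.
#'
#' @param seed RNG seed.
#' @param n_calib number of calibration runs.
#' @return list: p_planted, jaccard_planted, calib_frac_nonsig,
#'   calib_p (vector).
#' @export
benchmark_spatial <- function(seed = 1L, n_calib = 50L) {
  cfg <- sim_config(seed = seed)
  genome <- simulate_genome(cfg)
  truth <- plant_methylome(genome, cfg)
  m4 <- truth[truth$mark == "4mC", , drop = FALSE]
  query <- new_df(contig = m4$contig, start = m4$pos, end = m4$pos + 1L)
  ref <- genome$te_copies[c("contig", "start", "end")]
  planted <- permutation_spatial_test(query, ref, genome, "jaccard",
                                      n_perm = 999L, seed = seed)
  set.seed(stage_seed(seed, 13L))
  calib_p <- vapply(seq_len(n_calib), function(i) {
    n <- 150L
    cl <- genome$contig_len
    contig <- sample(names(cl), n, replace = TRUE, prob = cl / sum(cl))
    w <- 100L
    start <- as.integer(floor(runif(n) * (cl[contig] - w)))
    q <- new_df(contig = contig, start = start, end = start + w)
    permutation_spatial_test(q, ref, genome, "jaccard", n_perm = 199L,
                             seed = seed + i)$p_value
  }, 0)
  list(p_planted = planted$p_value, jaccard_planted = planted$observed,
       calib_frac_nonsig = mean(calib_p > 0.05), calib_p = calib_p)
}

#' Feature-direction reproduction on default synthetic data
#'
#' Runs the density, TE-integrity, chromatin co-localization and
#' sequence-context analyses on a default-configuration genome and
#' reports the directional quantities: normalized 4mC density for
#' genes / TE / TR, mean per-copy 4mC counts by integrity class, the
#' central log2(IP/input) of H3K4me3 / H3K9me3 / H3K27me3 around 4mC
#' DIP peak summits, the top modified doublets, and the CG k-mer
#' enrichment q-value.
#'
#' @param seed RNG seed.
#' @return list of the quantities above.
#' @export
benchmark_feature_directions <- function(seed = 1L) {
  cfg <- sim_config(seed = seed)
  genome <- simulate_genome(cfg)
  truth <- plant_methylome(genome, cfg)
  m4 <- truth[truth$mark == "4mC", , drop = FALSE]
  gl <- sum(genome$contig_len)
  genes_nt <- genome$genes[!genome$genes$te_gene, , drop = FALSE]
  dens <- rbind(
    normalized_density(m4, genes_nt, interval_bp(genes_nt) / gl, "genes"),
    normalized_density(m4, genome$te_copies,
                       interval_bp(genome$te_copies) / gl, "TE"),
    normalized_density(m4, genome$tandem_repeats,
                       interval_bp(genome$tandem_repeats) / gl, "TR"))
  integ <- density_by_integrity(m4, genome$te_copies)

  dip <- simulate_dipseq(genome, truth, cfg)
  chip <- simulate_chipseq(genome, cfg)
  dtrack <- bin_coverage(dip$dip4mC, genome, 10L, cfg$dip$read_len)
  dip_peaks <- call_peaks(dtrack)
  input_rpgc <- normalize_rpgc(bin_coverage(chip$chip_input, genome, 10L,
                                            cfg$chip$read_len))
  summit_centre <- list()
  for (nm in c("H3K4me3", "H3K9me3", "H3K27me3")) {
    l2r <- log2_ratio(normalize_rpgc(bin_coverage(chip[[nm]], genome, 10L,
                                                  cfg$chip$read_len)),
                      input_rpgc)
    prof <- summit_signal_profile(dip_peaks, l2r, flank = 3000L)
    v <- profile_values(prof)
    summit_centre[[nm]] <- mean(v[abs(prof$bins) <= 250])
  }

  # the +/-5 bp window concentrates the centre-doublet signal
  win <- extract_context(m4, genome, flank = 5L)
  dt <- doublet_triplet_stats(win)
  bg <- sample_context_background(genome, "C", n = 5L * nrow(win),
                                  flank = 5L, seed = seed + 17L)
  enr <- kmer_enrichment(win, bg)
  cg_q <- enr$q_value[enr$kmer == "CG"][1]

  list(density = dens, integrity = integ,
       summit_log2ratio_centre = summit_centre,
       top_doublets = names(dt$doublet)[1:2],
       doublet_props = dt$doublet,
       cg_q = cg_q, n_dip_peaks = nrow(dip_peaks))
}

#' Expression-direction reproduction
#'
#' A larger genome (~2.2 Mb, ~1180 gene models including 480 TE-derived
#' genes) is simulated so that each contrast has at least 200 genes per
#' group: TE genes with vs without 4mC within +/-500 bp, and non-TE
#' genes with vs without 6mA. Two-tailed Welch t-tests on log2 RPKM.
#'
#' @param seed RNG seed.
#' @return list: t4 (estimate = with-4mC minus without, p), t6, group
#'   sizes.
#' @export
benchmark_expression <- function(seed = 1L) {
  cfg <- sim_config(seed = seed,
                    genome = list(length = 2200000L, n_contigs = 8L),
                    genes = list(n = 700L),
                    te_families = new_df(name = "Vesta", consensus_length = 1500L,
                                         n_full = 480L, n_medium = 0L,
                                         n_short = 100L),
                    te_gene_prob = 1.0,
                    tandem_repeats = list(n = 4L),
                    meth_4mC = list(prob = 0.05, copy_prob = 0.5),
                    meth_6mA = list(prob = 0.0028),
                    rnaseq = list(library_size = 2e6))
  genome <- simulate_genome(cfg)
  truth <- plant_methylome(genome, cfg)
  rna <- simulate_rnaseq(genome, truth, cfg)
  e <- rna$expression
  t4 <- expression_group_tests(e[e$te_gene, , drop = FALSE],
                               e$has_4mC[e$te_gene])
  t6 <- expression_group_tests(e[!e$te_gene, , drop = FALSE],
                               e$has_6mA[!e$te_gene])
  list(t4 = list(estimate = t4$estimate, p = t4$p_value),
       t6 = list(estimate = t6$estimate, p = t6$p_value),
       n_te_with = sum(e$te_gene & e$has_4mC),
       n_te_without = sum(e$te_gene & !e$has_4mC),
       n_gene_with = sum(!e$te_gene & e$has_6mA),
       n_gene_without = sum(!e$te_gene & !e$has_6mA))
}
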
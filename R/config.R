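#' Simulation configuration
#'
#' Builds the configuration object that controls every stage of the
#' synthetic data generator: genome composition, gene and transposable
#' element (TE) structure, methylome planting, polymerase-kinetics
#' simulation, and DIP-seq / ChIP-seq / RNA-seq read simulation. The same
#' seed always yields bit-identical simulated data.
#'
#' Defaults encode the study conditions the package's analyses are
#' benchmarked under: asymmetric single-strand 4mC concentrated at CpG/CpA
#' positions of full-length and nearly full-length TE copies and of tandem
#' repeats, with a point mass of fully methylated sites; 6mA at GA-context
#' adenines genome-wide with a broad Beta fraction distribution (mean 0.74);
#' 200-400 bp DIP fragments sequenced as 50-bp single-end reads; 75-bp
#' ChIP reads with bimodal H3K4me3 at the TSS of expressed genes and
#' H3K9me3/H3K27me3 across TE bodies with flanking spread; and expression
#' multiplicatively repressed (0.25x) for 4mC-marked TE genes and elevated
#' (2x) for 6mA-associated genes.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param ... named blocks overriding defaults; each of `genome`, `genes`,
#'   `tandem_repeats`, `meth_4mC`, `meth_6mA`, `kinetics`, `dip`, `chip`,
#'   `rnaseq` may be a partial list (merged over the defaults), and
#'   `te_families` a data.frame with columns name, consensus_length,
#'   n_full, n_medium, n_short. `symmetric_fraction` is a scalar.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(length = 200000L, n_contigs = 4L, gc = 0.32),
    genes = list(
      n = 60L, mean_exons = 3, exon_meanlen = 250, intron_meanlen = 150,
      utr5 = c(60L, 140L), utr3 = c(80L, 200L), promoter_span = 2000L,
      expressed_prob = 0.7
    ),
    te_families = new_df(
      name = c("Vesta", "Athena"),
      consensus_length = c(3000L, 2000L),
      n_full = c(4L, 3L), n_medium = c(4L, 3L), n_short = c(18L, 14L)
    ),
    te_gene_prob = 0.6,
    tandem_repeats = list(n = 6L, unit_len = 25L, units_min = 12L, units_max = 28L),
    meth_4mC = list(
      prob = 0.6, copy_prob = 0.8, tr_prob = 0.8,
      context_weights = c(CG = 1.6, CA = 0.85, CC = 0.32, CT = 0.32),
      frac_full = 0.58, frac_beta = c(2, 1.2),
      te5p_decay = 800, te5p_floor = 0.4,
      target = c("te_full", "te_medium", "tr")
    ),
    meth_6mA = list(
      prob = 0.03, triplet_bonus = 2.5, frac_full = 0, frac_beta = c(3, 1.054)
    ),
    symmetric_fraction = 0.1,
    kinetics = list(passes = 25, sigma = 0.4, multiplier = 3, coverage_cv = 0.1),
    dip = list(
      frag_min = 200L, frag_max = 400L, read_len = 50L,
      capture_odds = 10, background = 1, library_size = 150000L,
      oversample = 4
    ),
    chip = list(
      read_len = 75L, spread = 500L, background = 0.7,
      library_size = 150000L, tss_offset = 200, tss_sd = 120
    ),
    rnaseq = list(
      library_size = 1e6, read_len = 50L,
      baseline_meanlog = log(10), baseline_sdlog = 1,
      silent_factor = 0.05, repression_4mC = 0.25, activation_6mA = 2,
      assoc_window = 500L
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config blocks: ", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && !is.data.frame(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' Checks probabilities and fractions lie in [0,1], lengths are positive,
#' and the configured features can fit the genome.
#'
#' @param config a `sim_config`.
#' @return the config, invisibly, or an error.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  if (g$length <= 0 || g$n_contigs <= 0) stop("genome length and n_contigs must be > 0")
  if (g$gc < 0 || g$gc > 1) stop("gc content must be in [0,1]")
  probs <- c(
    config$meth_4mC$prob, config$meth_4mC$copy_prob, config$meth_4mC$tr_prob,
    config$meth_6mA$prob, config$symmetric_fraction,
    config$genes$expressed_prob, config$te_gene_prob,
    config$chip$background, config$meth_4mC$frac_full
  )
  if (any(probs < 0 | probs > 1)) stop("all probabilities/fractions must lie in [0,1]")
  if (any(config$meth_4mC$context_weights < 0)) stop("context weights must be >= 0")
  te <- config$te_families
  if (nrow(te) && any(te$consensus_length <= 0)) stop("TE consensus lengths must be > 0")
  k <- config$kinetics
  if (k$passes < 0 || k$sigma <= 0 || k$multiplier <= 0) {
    stop("kinetics: passes >= 0, sigma > 0, multiplier > 0 required")
  }
  d <- config$dip
  if (d$frag_min <= 0 || d$frag_max < d$frag_min) stop("dip fragment range invalid")
  if (d$read_len > d$frag_min) stop("dip read length exceeds minimum fragment length")
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "| genome", x$genome$length, "bp in",
      x$genome$n_contigs, "contigs | genes", x$genes$n, "| TE families",
      nrow(x$te_families), "| TRs", x$tandem_repeats$n, "\n")
  invisible(x)
}

# total feature length demanded by a config (used for sizing errors)
config_feature_bp <- function(config) {
  te <- config$te_families
  te_bp <- if (nrow(te)) {
    sum(te$n_full * te$consensus_length * 0.95 +
          te$n_medium * te$consensus_length * 0.7 +
          te$n_short * te$consensus_length * 0.3)
  } else 0
  tr <- config$tandem_repeats
  tr_bp <- tr$n * tr$unit_len * (tr$units_min + tr$units_max) / 2
  gn <- config$genes
  gene_bp <- gn$n * (mean(gn$utr5) + mean(gn$utr3) +
                       gn$mean_exons * gn$exon_meanlen +
                       (gn$mean_exons - 1) * gn$intron_meanlen)
  te_bp + tr_bp + gene_bp
}
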
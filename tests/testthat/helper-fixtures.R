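# Shared fixtures: compact configs and a hand-built toy genome.

small_config <- function(seed = 9L, ...) {
  base <- list(genome = list(length = 60000L, n_contigs = 2L),
               genes = list(n = 18L),
               te_families = data.frame(name = "Vesta", consensus_length = 2000L,
                                        n_full = 3L, n_medium = 2L, n_short = 6L),
               tandem_repeats = list(n = 3L),
               dip = list(library_size = 30000L),
               chip = list(library_size = 30000L),
               rnaseq = list(library_size = 200000))
  for (nm in names(list(...))) {
    v <- list(...)[[nm]]
    base[[nm]] <- if (!is.null(base[[nm]]) && is.list(base[[nm]]) &&
                      !is.data.frame(base[[nm]]) && is.list(v)) {
      utils::modifyList(base[[nm]], v)
    } else v
  }
  do.call(sim_config, c(list(seed = seed), base))
}

no_feature_families <- function() {
  data.frame(name = character(), consensus_length = integer(),
             n_full = integer(), n_medium = integer(), n_short = integer())
}

# minimal annotated_genome built by hand (no simulation)
toy_genome <- function(contigs) {
  empty_genes <- data.frame(gene_id = character(), contig = character(),
                            start = integer(), end = integer(),
                            strand = character(), te_gene = logical(),
                            expressed = logical(), exon_bp = integer(),
                            stringsAsFactors = FALSE)
  structure(list(
    contigs = contigs,
    contig_len = vapply(contigs, nchar, 0L),
    genes = empty_genes,
    subfeatures = data.frame(),
    promoters = data.frame(),
    te_copies = data.frame(),
    tandem_repeats = data.frame(),
    config = sim_config()
  ), class = "annotated_genome")
}

# kinetic_table built by hand from lists of per-pass IPDs
toy_kinetics <- function(contig, pos, strand, native, control,
                         control_mean = exp(0.08), multiplier = 3) {
  df <- data.frame(contig = contig, pos = pos, strand = strand,
                   stringsAsFactors = FALSE)
  df$coverage <- lengths(native)
  df$true_fraction <- 0
  df$native <- native
  df$control <- control
  attr(df, "control_mean") <- control_mean
  attr(df, "multiplier") <- multiplier
  class(df) <- c("kinetic_table", "data.frame")
  df
}

rand_intervals <- function(n, L, max_w = 300L, contigs = "c1") {
  s <- sample.int(L - max_w, n, replace = TRUE) - 1L
  data.frame(contig = sample(contigs, n, replace = TRUE),
             start = s, end = s + sample.int(max_w, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
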
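# Synthetic genome, methylome and read-set generator.

test_that("empty feature configuration yields empty annotation sets", {
  cfg <- sim_config(seed = 1, genome = list(length = 5000L, n_contigs = 1L),
                    genes = list(n = 0L), te_families = no_feature_families(),
                    tandem_repeats = list(n = 0L))
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 0L)
  expect_equal(nrow(g$te_copies), 0L)
  expect_equal(nrow(g$tandem_repeats), 0L)
  expect_equal(sum(g$contig_len), 5000L)
})

test_that("TE copy counts and integrity classes follow the family config", {
  cfg <- sim_config(seed = 2, genome = list(length = 40000L, n_contigs = 1L),
                    genes = list(n = 0L), tandem_repeats = list(n = 0L),
                    te_families = data.frame(name = "fam", consensus_length = 3000L,
                                             n_full = 2L, n_medium = 0L, n_short = 5L))
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$te_copies), 7L)
  expect_equal(sum(g$te_copies$integrity < 0.5), 5L)
  expect_equal(sum(g$te_copies$class == "full"), 2L)
  expect_true(all(g$te_copies$end <= g$contig_len[g$te_copies$contig]))
})

test_that("oversized feature configurations raise a sizing error", {
  cfg <- sim_config(seed = 1, genome = list(length = 20000L, n_contigs = 1L))
  expect_error(simulate_genome(cfg), "sizing error")
})

test_that("same seed reproduces byte-identical FASTA and GFF3", {
  cfg <- small_config(seed = 4)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  write_genome(g1, file.path(d, "a.fa"), file.path(d, "a.gff3"))
  write_genome(g2, file.path(d, "b.fa"), file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.fa")), readLines(file.path(d, "b.fa")))
  expect_identical(readLines(file.path(d, "a.gff3")), readLines(file.path(d, "b.gff3")))
  m1 <- plant_methylome(g1, cfg)
  m2 <- plant_methylome(g2, cfg)
  expect_identical(m1, m2)
})

test_that("gene subfeatures nest within gene spans", {
  g <- simulate_genome(small_config(seed = 5))
  s <- merge(g$subfeatures, g$genes, by = "gene_id", suffixes = c("", ".g"))
  expect_true(all(s$start >= s$start.g & s$end <= s$end.g))
  # per-gene subfeature widths tile the gene span
  widths <- tapply(s$end - s$start, s$gene_id, sum)
  spans <- setNames(g$genes$end - g$genes$start, g$genes$gene_id)
  expect_equal(as.numeric(widths[names(spans)]), as.numeric(spans))
})

test_that("planted marks respect base identity, contexts, and targets", {
  cfg <- small_config(seed = 6)
  g <- simulate_genome(cfg)
  m <- plant_methylome(g, cfg)
  expect_gt(nrow(m), 50)
  expect_equal(methylome_base_violations(m, g), 0L)
  expect_true(all(m$fraction > 0 & m$fraction <= 1))
  # 4mC only inside the targeted feature classes
  m4 <- m[m$mark == "4mC", ]
  targets <- rbind(g$te_copies[g$te_copies$class %in% c("full", "medium"),
                               c("contig", "start", "end")],
                   g$tandem_repeats[c("contig", "start", "end")])
  # symmetric partners may sit 1 bp outside a span boundary
  targets$start <- targets$start - 1L
  targets$end <- targets$end + 1L
  inside <- window_intersect(m4, targets, window = 0L)$item_associated
  expect_true(all(inside))
})

test_that("planting probability zero yields an empty methylome", {
  cfg <- small_config(seed = 7, meth_4mC = list(prob = 0),
                      meth_6mA = list(prob = 0))
  g <- simulate_genome(cfg)
  expect_equal(nrow(plant_methylome(g, cfg)), 0L)
})

test_that("degenerate fraction distribution plants fraction 1 everywhere", {
  cfg <- small_config(seed = 8, meth_4mC = list(frac_full = 1),
                      meth_6mA = list(frac_full = 1))
  g <- simulate_genome(cfg)
  m <- plant_methylome(g, cfg)
  expect_true(all(m$fraction == 1))
})

test_that("4mC planting errors when the genome lacks targeted classes", {
  cfg <- sim_config(seed = 1, genome = list(length = 5000L, n_contigs = 1L),
                    genes = list(n = 0L), te_families = no_feature_families(),
                    tandem_repeats = list(n = 0L))
  g <- simulate_genome(cfg)
  expect_error(plant_methylome(g, cfg), "no eligible")
})

test_that("kinetics reproduce the configured IPD ratio at full methylation", {
  cfg <- sim_config(seed = 10, genome = list(length = 2000L, n_contigs = 1L),
                    genes = list(n = 0L), te_families = no_feature_families(),
                    tandem_repeats = list(n = 0L),
                    kinetics = list(passes = 50))
  g <- simulate_genome(cfg)
  ch <- strsplit(g$contigs[[1]], "")[[1]]
  pos <- which(ch == "C")[1:50] - 1L
  m <- data.frame(contig = "contig_01", pos = pos, strand = "+", mark = "4mC",
                  fraction = 1, stringsAsFactors = FALSE)
  k <- simulate_kinetics(g, m, cfg, positions = m)
  ratios <- vapply(seq_len(nrow(k)), function(i) {
    compute_ipd_ratio(k$native[[i]], k$control[[i]])
  }, 0)
  expect_true(mean(ratios) > 2.5 && mean(ratios) < 3.5)
})

test_that("zero passes produce an empty kinetic table", {
  cfg <- small_config(seed = 11, kinetics = list(passes = 0))
  g <- simulate_genome(cfg)
  k <- simulate_kinetics(g, plant_methylome(g, cfg), cfg)
  expect_equal(nrow(k), 0L)
})

test_that("read sets conserve configured library sizes exactly", {
  cfg <- small_config(seed = 12)
  g <- simulate_genome(cfg)
  m <- plant_methylome(g, cfg)
  dip <- simulate_dipseq(g, m, cfg)
  for (rs in dip) expect_equal(rs$total_reads, 30000L)
  chip <- simulate_chipseq(g, cfg)
  for (rs in chip) expect_equal(rs$total_reads, 30000L)
  rna <- simulate_rnaseq(g, m, cfg)
  expect_equal(sum(rna$expression$count), 200000L)
  # all read spans inside contigs
  all_reads <- rbind(dip$dip4mC$reads, chip$H3K9me3$reads, rna$reads$reads)
  expect_true(all(all_reads$start >= 0))
  expect_true(all(all_reads$end <= g$contig_len[all_reads$contig]))
})

test_that("null DIP capture matches the input library", {
  cfg <- small_config(seed = 13, dip = list(capture_odds = 0))
  g <- simulate_genome(cfg)
  m <- plant_methylome(g, cfg)
  dip <- simulate_dipseq(g, m, cfg)
  ip <- bin_coverage(dip$dip4mC, g, 100L, 50L)
  input <- bin_coverage(dip$input, g, 100L, 50L)
  # coverage at planted marks shows no enrichment over the input track
  m4 <- m[m$mark == "4mC", ]
  at_marks <- function(tr) {
    mean(vapply(seq_len(nrow(m4)), function(i) {
      tr$values[[m4$contig[i]]][m4$pos[i] %/% 100L + 1L]
    }, 0))
  }
  expect_lt(abs(at_marks(ip) / at_marks(input) - 1), 0.2)
})

test_that("DIP library size zero yields empty read sets", {
  cfg <- small_config(seed = 14, dip = list(library_size = 0L))
  g <- simulate_genome(cfg)
  dip <- simulate_dipseq(g, plant_methylome(g, cfg), cfg)
  expect_equal(dip$dip4mC$total_reads, 0L)
})

test_that("H3K4me3 coverage concentrates around the TSS of expressed genes", {
  cfg <- small_config(seed = 15, chip = list(background = 0.2))
  g <- simulate_genome(cfg)
  chip <- simulate_chipseq(g, cfg)
  tr <- bin_coverage(chip$H3K4me3, g, 100L, 75L)
  genes <- g$genes[!g$genes$te_gene & g$genes$expressed, ]
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  near <- mean(vapply(seq_len(nrow(genes)), function(i) {
    v <- tr$values[[genes$contig[i]]]
    b <- tss[i] %/% 100L + 1L
    mean(v[max(1, b - 10):min(length(v), b + 10)])
  }, 0))
  genome_mean <- mean(unlist(tr$values))
  expect_gt(near, 2 * genome_mean)
})

test_that("repressive ChIP signal stays inside TE spans when spread is zero", {
  cfg <- small_config(seed = 16, chip = list(spread = 0L, background = 0))
  g <- simulate_genome(cfg)
  chip <- simulate_chipseq(g, cfg)
  reads <- chip$H3K9me3$reads
  te <- rbind(g$te_copies[c("contig", "start", "end")],
              g$tandem_repeats[c("contig", "start", "end")])
  # read centres within the target spans (blur limited to half a read)
  centres <- data.frame(contig = reads$contig,
                        pos = (reads$start + reads$end) %/% 2L)
  hit <- window_intersect(centres, te, window = 40L)$item_associated
  expect_gt(mean(hit), 0.99)
})

test_that("null expression coupling gives equal group means", {
  # sparse 6mA so both groups are populated; factors at 1 remove coupling
  cfg <- small_config(seed = 17,
                      meth_6mA = list(prob = 0.0015),
                      rnaseq = list(repression_4mC = 1, activation_6mA = 1))
  g <- simulate_genome(cfg)
  m <- plant_methylome(g, cfg)
  rna <- simulate_rnaseq(g, m, cfg)
  e <- rna$expression[!rna$expression$te_gene, ]
  tt <- expression_group_tests(e, e$has_6mA)
  expect_gt(tt$p_value, 0.01)
})

test_that("zero-length genes are rejected by the RNA-seq simulator", {
  cfg <- small_config(seed = 18)
  g <- simulate_genome(cfg)
  g$genes$exon_bp[1] <- 0L
  expect_error(simulate_rnaseq(g, plant_methylome(g, cfg), cfg),
               "length 0")
})

test_that("config serialization round-trips through YAML", {
  cfg <- small_config(seed = 19)
  d <- withr::local_tempdir()
  write_config_yaml(cfg, file.path(d, "cfg.yaml"))
  cfg2 <- read_config_yaml(file.path(d, "cfg.yaml"))
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$meth_4mC$context_weights, cfg$meth_4mC$context_weights)
  expect_equal(cfg2$te_families$consensus_length, cfg$te_families$consensus_length)
  # a re-simulated genome is identical
  expect_identical(simulate_genome(cfg)$contigs, simulate_genome(cfg2)$contigs)
})
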
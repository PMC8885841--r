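# Feature-association statistics.

test_that("occupancy profiles match hand-tabulated counts", {
  feats <- data.frame(contig = "c1", start = c(100L, 300L, 500L),
                      end = c(150L, 350L, 550L), strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  sites <- data.frame(contig = "c1",
                      pos = c(90L, 95L, 110L, 310L, 340L, 495L, 505L),
                      stringsAsFactors = FALSE)
  prof <- occupancy_profile(sites, feats, flank = 50L, bin = 10L)
  expect_equal(dim(prof$matrix), c(3L, 10L))
  orc <- oracle_occupancy(sites, feats, 50L, 10L)
  expect_equal(prof$matrix, orc)
  # conservation: total profile mass equals items landing in windows
  expect_equal(sum(profile_values(prof)) * nrow(feats), sum(orc))
  expect_error(occupancy_profile(sites, feats, flank = 55L, bin = 10L),
               "divisible")
  expect_error(occupancy_profile(sites, feats[0, ]), "at least one feature")
})

test_that("no items yield an all-zero profile", {
  feats <- data.frame(contig = "c1", start = 100L, end = 200L, strand = "+")
  prof <- occupancy_profile(data.frame(contig = character(), pos = integer()),
                            feats, flank = 50L, bin = 10L)
  expect_true(all(prof$matrix == 0))
})

test_that("metaprofiles rescale feature bodies to common coordinates", {
  feats <- data.frame(contig = "c1", start = c(1000L, 3000L),
                      end = c(1100L, 3200L), strand = c("+", "+"),
                      stringsAsFactors = FALSE)
  # one site at 25% of each body, lengths 100 and 200
  sites <- data.frame(contig = "c1", pos = c(1025L, 3050L))
  prof <- metaprofile(sites, feats, flank = 100L, bin = 10L, n_body_bins = 20L)
  hits1 <- which(prof$matrix[1, ] > 0)
  hits2 <- which(prof$matrix[2, ] > 0)
  expect_equal(hits1, hits2)          # same body bin despite length difference
  expect_equal(hits1, 10L + 5L + 1L)  # 25% of 20 body bins, after 10 flank bins
  # midpoint site lands in the central body bin
  mid <- metaprofile(data.frame(contig = "c1", pos = 1050L), feats[1, ],
                     flank = 100L, bin = 10L, n_body_bins = 20L)
  expect_equal(which(mid$matrix[1, ] > 0), 10L + 10L + 1L)
  # zero-length features are skipped with a warning
  z <- rbind(feats, data.frame(contig = "c1", start = 5000L, end = 5000L,
                               strand = "+"))
  expect_warning(metaprofile(sites, z, flank = 100L, bin = 10L), "skipped")
})

test_that("uniformly placed items give a flat metaprofile", {
  set.seed(51)
  feats <- data.frame(contig = "c1", start = seq(0L, 45000L, by = 5000L),
                      end = seq(2000L, 47000L, by = 5000L), strand = "+",
                      stringsAsFactors = FALSE)
  sites <- data.frame(contig = "c1", pos = sample.int(50000L, 20000L, TRUE) - 1L)
  prof <- metaprofile(sites, feats, flank = 500L, bin = 50L, n_body_bins = 20L)
  v <- profile_values(prof)
  body <- v[11:30] / 100 * 50   # body bin width is feature_len/20 = 100 bp
  flank <- v[1:10]
  expect_lt(sd(c(body, flank)) / mean(c(body, flank)), 0.15)
})

test_that("fraction profiles average call fractions per bin", {
  anchors <- data.frame(contig = "c1", pos = 1000L, strand = "+")
  calls <- data.frame(contig = "c1", pos = c(1001L, 1003L, 1100L),
                      fraction = c(1, 0.5, 1), stringsAsFactors = FALSE)
  prof <- fraction_profile(calls, anchors, flank = 200L, bin = 25L)
  v <- profile_values(prof)
  bin_of <- function(p) (p - 800L) %/% 25L + 1L
  expect_equal(v[bin_of(1001L)], 0.75)   # {1.0, 0.5} share a bin
  expect_equal(v[bin_of(1100L)], 1)
  expect_equal(sum(prof$mask), 2L)       # only two covered bins
  expect_true(all(v[!prof$mask[1, ]] == 0))
})

test_that("normalized density follows the published formula", {
  # 2000 annotations, the first 1000 carrying one site each, fraction 0.533
  ann <- data.frame(contig = "c1", start = seq(0L, by = 100L, length.out = 2000L),
                    end = seq(50L, by = 100L, length.out = 2000L))
  sites <- data.frame(contig = "c1", pos = ann$start[1:1000] + 10L)
  row <- normalized_density(sites, ann, 0.533, "genes")
  expect_equal(row$normalized_density, (1000 / 2000) / 0.533, tolerance = 1e-12)
  expect_equal(round(row$normalized_density, 3), 0.938)
  # zero sites
  expect_equal(normalized_density(sites[0, ], ann, 0.5)$normalized_density, 0)
  # zero annotations: flagged undefined
  r0 <- normalized_density(sites, ann[0, ], 0.5)
  expect_false(r0$defined)
  expect_true(is.na(r0$normalized_density))
  expect_error(normalized_density(sites, ann, 0), "genome_fraction")
})

test_that("windowed association respects the base-distance boundary", {
  feat <- data.frame(contig = "c1", start = 1000L, end = 1100L)
  at <- function(p) data.frame(contig = "c1", pos = p)
  expect_true(window_intersect(at(1050L), feat, 0L)$item_associated)   # inside
  expect_true(window_intersect(at(1599L), feat, 500L)$item_associated) # 500 bp
  expect_false(window_intersect(at(1600L), feat, 500L)$item_associated) # 501 bp
  expect_false(window_intersect(at(1100L), feat, 0L)$item_associated)  # just past
  expect_error(window_intersect(at(1L), feat, -1L), "window")
})

test_that("windowed association equals the all-pairs oracle", {
  set.seed(52)
  for (rep in 1:5) {
    items <- rand_intervals(60L, 20000L, 50L, c("c1", "c2"))
    feats <- rand_intervals(25L, 20000L, 400L, c("c1", "c2"))
    got <- window_intersect(items, feats, window = 300L)
    orc <- oracle_window_intersect(items, feats, 300L)
    expect_equal(got$item_associated, orc$item_associated)
    expect_equal(got$feature_hit, orc$feature_hit)
  }
})

test_that("bp Jaccard has its set-theoretic properties", {
  a <- data.frame(contig = "c1", start = 0L, end = 100L)
  b <- data.frame(contig = "c1", start = 50L, end = 150L)
  expect_equal(jaccard_bp(a, a), 1)
  expect_equal(jaccard_bp(a, b), 50 / 150)
  expect_equal(jaccard_bp(a, b), jaccard_bp(b, a))
  disj <- data.frame(contig = "c1", start = 500L, end = 600L)
  expect_equal(jaccard_bp(a, disj), 0)
  expect_true(is.na(jaccard_bp(a[0, ], a[0, ])))
  # self-merge first: overlapping fragments of a equal a
  afrag <- data.frame(contig = "c1", start = c(0L, 40L), end = c(60L, 100L))
  expect_equal(jaccard_bp(afrag, a), 1)
})

test_that("fast spatial statistics agree with reference implementations", {
  set.seed(53)
  for (rep in 1:20) {
    q <- rand_intervals(40L, 10000L, 200L, c("c1", "c2"))
    r <- rand_intervals(15L, 10000L, 400L, c("c1", "c2"))
    expect_equal(unname(bdellometh:::fast_jaccard(q, r)), jaccard_bp(q, r))
    expect_equal(bdellometh:::fast_mnd(q, r),
                 bdellometh:::mean_nearest_distance(q, r))
    expect_equal(jaccard_bp(q, r), oracle_jaccard(q, r, 11000L, c("c1", "c2")))
  }
})

test_that("permutation p-values honor the add-one floor and the seed", {
  g <- toy_genome(c(c1 = strrep("A", 20000)))
  ref <- data.frame(contig = "c1", start = c(1000L, 5000L, 9000L),
                    end = c(2000L, 6000L, 10000L), stringsAsFactors = FALSE)
  res <- permutation_spatial_test(ref, ref, g, "jaccard", n_perm = 99L, seed = 5)
  expect_equal(res$p_value, 1 / 100)    # identical sets: maximal statistic
  expect_equal(res$observed, 1)
  res2 <- permutation_spatial_test(ref, ref, g, "jaccard", n_perm = 99L, seed = 5)
  expect_identical(res$null, res2$null)  # reproducible under the seed
  # distance statistic: clustered-inside query below all null draws
  q <- data.frame(contig = "c1",
                  start = c(1100L, 1500L, 1800L, 5100L, 5500L, 5800L,
                            9100L, 9500L, 9800L, 1300L),
                  end = c(1200L, 1600L, 1900L, 5200L, 5600L, 5900L,
                          9200L, 9600L, 9900L, 1400L))
  resd <- permutation_spatial_test(q, ref, g, "mean_nearest_distance",
                                   n_perm = 99L, seed = 6)
  expect_equal(resd$observed, 0)
  expect_equal(resd$p_value, 0.01)
  too_long <- data.frame(contig = "c1", start = 0L, end = 30000L)
  expect_error(permutation_spatial_test(too_long, ref, g), "longer than")
  expect_error(permutation_spatial_test(q, ref, g, n_perm = 10L), "n_perm")
})

test_that("TE integrity classes follow the consensus-length rule", {
  expect_equal(classify_te_integrity(400, 1000), "short")
  expect_equal(classify_te_integrity(700, 1000), "medium")
  expect_equal(classify_te_integrity(1000, 1000), "full")
  expect_equal(classify_te_integrity(c(499, 500, 899, 900), 1000),
               c("short", "medium", "medium", "full"))
  expect_warning(cls <- classify_te_integrity(1300, 1000), "suspect")
  expect_equal(cls, "full")
  expect_error(classify_te_integrity(100, 0), "consensus_length")
})

test_that("integrity-stratified densities match hand-computed summaries", {
  te <- data.frame(contig = "c1", start = c(0L, 100L, 200L, 300L, 400L),
                   end = c(90L, 190L, 290L, 350L, 440L),
                   class = c("full", "full", "medium", "short", "short"),
                   stringsAsFactors = FALSE)
  calls <- data.frame(contig = "c1", pos = c(10L, 20L, 110L, 210L, 211L, 212L))
  d <- density_by_integrity(calls, te)
  expect_equal(d$mean_count[d$class == "full"], 1.5)      # (2 + 1) / 2
  expect_equal(d$sd_count[d$class == "full"], sd(c(2, 1)))
  expect_equal(d$mean_count[d$class == "medium"], 3)
  expect_equal(d$mean_count[d$class == "short"], 0)
  # no calls at all
  d0 <- density_by_integrity(calls[0, ], te)
  expect_true(all(d0$mean_count == 0))
  # empty class flagged, not NaN
  d1 <- density_by_integrity(calls, te[te$class != "medium", ])
  expect_false(d1$defined[d1$class == "medium"])
})

test_that("co-localization percentages equal brute-force overlap counts", {
  set.seed(54)
  dip <- rand_intervals(30L, 10000L, 200L)
  chipsets <- list(A = rand_intervals(10L, 10000L, 500L),
                   B = rand_intervals(10L, 10000L, 500L))
  out <- colocalization_fractions(dip, chipsets,
                                  combine = list(AB = c("A", "B")))
  for (nm in c("A", "B")) {
    orc <- oracle_window_intersect(dip, chipsets[[nm]], 0L)$item_associated
    expect_equal(out$pct[out$class == nm], 100 * mean(orc))
  }
  orc_ab <- oracle_window_intersect(dip, rbind(chipsets$A, chipsets$B),
                                    0L)$item_associated
  expect_equal(out$pct[out$class == "AB"], 100 * mean(orc_ab))
  # whole-genome class: 100%; disjoint class: 0%
  whole <- list(all = data.frame(contig = "c1", start = 0L, end = 10000L))
  expect_equal(colocalization_fractions(dip, whole)$pct, 100)
  far <- list(none = data.frame(contig = "c9", start = 0L, end = 100L))
  expect_equal(colocalization_fractions(dip, far)$pct, 0)
  e <- colocalization_fractions(dip[0, ], chipsets)
  expect_false(any(e$defined))
})

test_that("summit profiles slice the signal track", {
  g <- toy_genome(c(c1 = strrep("A", 10000)))
  tr <- bin_coverage(data.frame(contig = "c1", start = 0L, end = 50L,
                                strand = "+"), g, 10L, 50L)
  tr$values$c1 <- seq_along(tr$values$c1)   # ramp
  summits <- data.frame(contig = "c1", summit = 5000L)
  prof <- summit_signal_profile(summits, tr, flank = 200L)
  expect_equal(unname(profile_values(prof)), tr$values$c1[481:520])
  # flat zero track: zero profile
  tr0 <- tr; tr0$values$c1[] <- 0
  expect_true(all(profile_values(summit_signal_profile(summits, tr0, 200L)) == 0))
  # summit too close to the edge is skipped and counted
  both <- data.frame(contig = "c1", summit = c(5000L, 30L))
  p2 <- summit_signal_profile(both, tr, flank = 200L)
  expect_equal(p2$skipped, 1L)
  expect_equal(nrow(p2$matrix), 1L)
})

test_that("strand symmetry counts doublet-paired complementary calls", {
  expect_equal(strand_symmetry(data.frame(contig = character(), pos = integer(),
                                          strand = character(),
                                          mark = character()))$n_pairs, 0L)
  # one CpG methylated on both strands: symmetry fraction 1
  calls <- data.frame(contig = "c1", pos = c(10L, 11L), strand = c("+", "-"),
                      mark = "4mC", stringsAsFactors = FALSE)
  s <- strand_symmetry(calls)
  expect_equal(s$symmetric_fraction, 1)
  expect_equal(s$n_positions, 1L)
  # unpaired calls are asymmetric
  lone <- data.frame(contig = "c1", pos = c(10L, 50L), strand = c("+", "+"),
                     mark = "4mC")
  expect_equal(strand_symmetry(lone)$symmetric_fraction, 0)
  # genome validation rejects pairs without a CpG doublet
  g <- toy_genome(c(c1 = paste0(strrep("A", 10), "CGAT", strrep("A", 10))))
  ok <- data.frame(contig = "c1", pos = c(10L, 11L), strand = c("+", "-"),
                   mark = "4mC")
  expect_equal(strand_symmetry(ok, g)$n_pairs, 1L)
  notcg <- data.frame(contig = "c1", pos = c(12L, 13L), strand = c("+", "-"),
                      mark = "4mC")
  expect_equal(strand_symmetry(notcg, g)$n_pairs, 0L)
})

test_that("planted symmetric fraction is recovered from the methylome", {
  cfg <- small_config(seed = 55, symmetric_fraction = 0.1)
  g <- simulate_genome(cfg)
  m <- plant_methylome(g, cfg)
  m4 <- m[m$mark == "4mC", ]
  # symmetry is only possible at CpG-context sites; restrict to them
  nxt <- ifelse(m4$strand == "+",
                bdellometh:::base_at(g, m4$contig, m4$pos + 1L, "+"),
                bdellometh:::base_at(g, m4$contig, m4$pos - 1L, "-"))
  cg <- m4[nxt == "G", ]
  s <- strand_symmetry(cg, g)
  est <- s$n_pairs / s$n_positions
  se <- sqrt(0.1 * 0.9 / s$n_positions)
  expect_lt(abs(est - 0.1), 3 * se + 0.02)
})

test_that("CpG observed/expected behaves on known sequences", {
  r <- cpg_obs_exp("CGCG")
  expect_equal(r$n_cpg, 2L)
  expect_equal(r$obs_exp, 2)
  expect_true(is.na(cpg_obs_exp("AATTAA")$obs_exp))
  set.seed(56)
  long <- paste(sample(c("A", "C", "G", "T"), 200000, TRUE), collapse = "")
  expect_equal(mean(cpg_obs_exp(long, 10000L)$obs_exp), 1, tolerance = 0.05)
  expect_error(cpg_obs_exp("ACGT", 0L), "window")
})

test_that("RPKM follows its definition", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  counts <- c(10, 250, 33, 0, 7)
  len <- c(500, 2000, 1500, 800, 1200)
  expect_equal(rpkm(counts, len, 2e6),
               counts / (len / 1000) / 2)
  expect_error(rpkm(1, 0, 1e6), "exon_length")
  expect_error(rpkm(1, 100, 0), "total_mapped")
})

test_that("expression grouping tests match closed-form statistics", {
  # textbook two-sample case on log2 scale
  e <- data.frame(rpkm = 2^c(1, 2, 3, 4, 5, 6) - 0.1)
  grp <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  out <- expression_group_tests(e, grp, pseudocount = 0.1)
  ref <- t.test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(out$p_value, ref$p.value)
  expect_equal(out$estimate, 3)
  # identical groups: p ~= 1
  e2 <- data.frame(rpkm = rep(c(1, 2, 4), 2))
  out2 <- expression_group_tests(e2, rep(c(TRUE, FALSE), each = 3))
  expect_gt(out2$p_value, 0.99)
  # ANOVA path with Tukey post hoc
  set.seed(57)
  e3 <- data.frame(rpkm = 2^rnorm(60, rep(c(2, 5, 5), each = 20), 0.5))
  out3 <- expression_group_tests(e3, rep(c("a", "b", "c"), each = 20))
  expect_equal(out3$test, "anova")
  expect_lt(out3$p_value, 1e-6)
  expect_true(!is.null(out3$tukey))
  expect_true("b-a" %in% rownames(out3$tukey))
  # undersized groups are skipped with a flag
  out4 <- expression_group_tests(rbind(e3, data.frame(rpkm = 1)),
                                 c(rep(c("a", "b", "c"), each = 20), "d"))
  expect_equal(out4$skipped_groups, "d")
})
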
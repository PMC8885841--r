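# Simulated sequencing read sets. Reads are emitted as alignment
# intervals (BED-like), not sequences: alignment itself is outside the
# scope of this package, and intervals are the minimal sufficient input
# for coverage, peak and profile analyses.

read_set <- function(assay, reads) {
  structure(list(assay = assay,
                 reads = reads,
                 total_reads = nrow(reads)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", x$assay, "-", x$total_reads, "alignments\n")
  invisible(x)
}

empty_reads <- function() {
  new_df(contig = character(), start = integer(), end = integer(),
         strand = character())
}

# uniform random fragments over the genome: data.frame + lengths
draw_fragments <- function(genome, n, len_min, len_max) {
  if (n == 0L) return(cbind(empty_reads()))
  cl <- genome$contig_len
  contig <- sample(names(cl), n, replace = TRUE, prob = cl / sum(cl))
  len <- sample(seq.int(len_min, len_max), n, replace = TRUE)
  len <- pmin(len, cl[contig])
  start <- as.integer(floor(runif(n) * (cl[contig] - len + 1)))
  new_df(contig = contig, start = start, end = as.integer(start + len))
}

# 5' prefix reads from fragments with random strand
fragment_reads <- function(frags, read_len) {
  n <- nrow(frags)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  w <- pmin(read_len, frags$end - frags$start)
  new_df(contig = frags$contig,
         start = as.integer(ifelse(strand == "+", frags$start, frags$end - w)),
         end = as.integer(ifelse(strand == "+", frags$start + w, frags$end)),
         strand = strand)
}

# sum of mark fractions covered by each fragment
fragment_mark_load <- function(frags, marks) {
  load <- numeric(nrow(frags))
  if (!nrow(marks) || !nrow(frags)) return(load)
  for (cn in unique(frags$contig)) {
    fi <- which(frags$contig == cn)
    mi <- which(marks$contig == cn)
    if (!length(mi)) next
    hits <- IRanges::findOverlaps(
      as_ir0(frags$start[fi], frags$end[fi]),
      IRanges::IRanges(start = marks$pos[mi] + 1L, width = 1L))
    if (length(hits)) {
      agg <- rowsum(marks$fraction[mi][S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
      load[fi[as.integer(rownames(agg))]] <- agg[, 1]
    }
  }
  load
}

#' Simulate DIP-seq (MeDIP-seq) read sets
#'
#' Fragments are drawn uniformly with lengths in the configured range
#' (200-400 bp by default); antibody capture weight grows linearly with
#' the summed fraction of matching methyl marks a fragment covers, on top
#' of a background capture rate that also retains unmethylated fragments
#' (residual IgG binding). Reads are 5'-end prefixes of the configured
#' read length (50 bp single-read by default). The input assay skips
#' capture. Library sizes are met exactly.
#'
#' @param genome an `annotated_genome`.
#' @param methylome the true methylome providing capture targets.
#' @param config a [sim_config()]; `config$dip` holds fragment range,
#'   read length, `capture_odds` (0 disables enrichment), `background`,
#'   and `library_size`.
#' @return named list of `read_set`s: dip4mC, dip6mA, input.
#' @export
simulate_dipseq <- function(genome, methylome, config) {
  validate_sim_config(config)
  d <- config$dip
  set.seed(stage_seed(config$seed, 3L))
  out <- list()
  for (assay in c("dip4mC", "dip6mA", "input")) {
    if (d$library_size == 0L) { out[[assay]] <- read_set(assay, empty_reads()); next }
    pool <- draw_fragments(genome, as.integer(d$oversample * d$library_size),
                           d$frag_min, d$frag_max)
    if (assay == "input") {
      idx <- sample.int(nrow(pool), d$library_size, replace = TRUE)
    } else {
      mk <- methylome[methylome$mark == sub("dip", "", assay), , drop = FALSE]
      wt <- d$background + d$capture_odds * fragment_mark_load(pool, mk)
      idx <- sample.int(nrow(pool), d$library_size, replace = TRUE, prob = wt)
    }
    out[[assay]] <- read_set(assay, fragment_reads(pool[idx, , drop = FALSE],
                                                   d$read_len))
  }
  out
}

clip_reads <- function(reads, genome) {
  cl <- genome$contig_len[reads$contig]
  reads$start <- pmax(0L, reads$start)
  reads$end <- pmin(as.integer(cl), reads$end)
  reads[reads$start < reads$end, , drop = FALSE]
}

#' Simulate ChIP-seq read sets for histone marks
#'
#' H3K4me3 read density is bimodal around the TSS of expressed (non
#' TE-derived) genes; H3K9me3 and H3K27me3 densities are uniform over TE
#' bodies plus a configurable flanking spread; the remainder of each
#' library (the `background` fraction) and the chip_input library are
#' uniform over the genome. Reads are 75 bp by default, centred on the
#' sampled position.
#'
#' @param genome an `annotated_genome`.
#' @param config a [sim_config()].
#' @return named list of `read_set`s: H3K4me3, H3K9me3, H3K27me3,
#'   chip_input.
#' @export
simulate_chipseq <- function(genome, config) {
  validate_sim_config(config)
  ch <- config$chip
  set.seed(stage_seed(config$seed, 4L))
  cl <- genome$contig_len
  genes <- genome$genes[!genome$genes$te_gene & genome$genes$expressed, , drop = FALSE]
  # repressive marks cover TE bodies and heterochromatic tandem-repeat arrays
  te <- rbind(genome$te_copies[c("contig", "start", "end")],
              genome$tandem_repeats[c("contig", "start", "end")])
  half <- ch$read_len %/% 2L

  centre_reads <- function(contig, centre) {
    n <- length(centre)
    clip_reads(new_df(contig = contig,
                      start = as.integer(round(centre)) - half,
                      end = as.integer(round(centre)) - half + ch$read_len,
                      strand = sample(c("+", "-"), n, replace = TRUE)),
               genome)
  }
  uniform_reads <- function(n) {
    contig <- sample(names(cl), n, replace = TRUE, prob = cl / sum(cl))
    centre_reads(contig, floor(runif(n) * cl[contig]))
  }

  out <- list()
  for (assay in c("H3K4me3", "H3K9me3", "H3K27me3", "chip_input")) {
    lib <- as.integer(ch$library_size)
    if (lib == 0L) { out[[assay]] <- read_set(assay, empty_reads()); next }
    if (assay == "chip_input") {
      reads <- uniform_reads(lib)
    } else {
      n_bg <- as.integer(round(ch$background * lib))
      n_sig <- lib - n_bg
      sig <- NULL
      if (assay == "H3K4me3" && nrow(genes) && n_sig > 0L) {
        gi <- sample.int(nrow(genes), n_sig, replace = TRUE)
        tss <- ifelse(genes$strand[gi] == "+", genes$start[gi], genes$end[gi] - 1L)
        side <- sample(c(-1, 1), n_sig, replace = TRUE)
        centre <- tss + side * rnorm(n_sig, ch$tss_offset, ch$tss_sd)
        sig <- centre_reads(genes$contig[gi], centre)
      } else if (assay != "H3K4me3" && nrow(te) && n_sig > 0L) {
        w <- (te$end - te$start) + 2 * ch$spread
        ti <- sample.int(nrow(te), n_sig, replace = TRUE, prob = w)
        centre <- te$start[ti] - ch$spread +
          floor(runif(n_sig) * ((te$end[ti] - te$start[ti]) + 2 * ch$spread))
        sig <- centre_reads(te$contig[ti], centre)
      } else {
        n_bg <- lib
      }
      reads <- rbind(sig, uniform_reads(n_bg))
      # clipping can drop a few reads; top up from the uniform background
      while (nrow(reads) < lib) {
        reads <- rbind(reads, uniform_reads(lib - nrow(reads)))
      }
      reads <- reads[seq_len(lib), , drop = FALSE]
    }
    rownames(reads) <- NULL
    out[[assay]] <- read_set(assay, reads)
  }
  out
}

#' Simulate RNA-seq counts and reads
#'
#' Per-gene expected rates are a log-normal baseline, multiplied by a
#' silencing factor for non-expressed genes, a repression factor for
#' TE-derived genes carrying 4mC within the association window (default
#' 0.25x), and an activation factor for genes with 6mA within the window
#' (default 2x). Counts are multinomial at the configured library size
#' with probabilities proportional to rate x transcript length, and reads
#' are placed uniformly within exonic intervals.
#'
#' @param genome an `annotated_genome`.
#' @param methylome the true methylome (drives the 4mC/6mA coupling).
#' @param config a [sim_config()].
#' @return list(reads = `read_set`, expression = data.frame with gene_id,
#'   exon_bp, count, rpkm, baseline, has_4mC, has_6mA, te_gene,
#'   expressed).
#' @export
simulate_rnaseq <- function(genome, methylome, config) {
  validate_sim_config(config)
  r <- config$rnaseq
  set.seed(stage_seed(config$seed, 5L))
  genes <- genome$genes
  if (!nrow(genes)) stop("sizing error: no genes to express")
  if (any(genes$exon_bp <= 0)) stop("sizing error: gene of length 0 disallowed")
  w <- r$assoc_window
  m4 <- methylome[methylome$mark == "4mC", , drop = FALSE]
  m6 <- methylome[methylome$mark == "6mA", , drop = FALSE]
  g4 <- window_intersect(m4, genes, window = w)$feature_hit
  g6 <- window_intersect(m6, genes, window = w)$feature_hit

  baseline <- rlnorm(nrow(genes), r$baseline_meanlog, r$baseline_sdlog)
  rate <- baseline *
    ifelse(genes$expressed, 1, r$silent_factor) *
    ifelse(genes$te_gene & g4, r$repression_4mC, 1) *
    ifelse(g6, r$activation_6mA, 1)
  p <- rate * genes$exon_bp
  counts <- as.integer(rmultinom(1L, as.integer(r$library_size), p))

  # place reads uniformly within exonic intervals
  ex <- genome$subfeatures[genome$subfeatures$type %in%
                             c("CDS", "five_prime_UTR", "three_prime_UTR"), ,
                           drop = FALSE]
  ex <- ex[ex$gene_id %in% genes$gene_id, , drop = FALSE]
  exw <- ex$end - ex$start
  gene_of <- match(ex$gene_id, genes$gene_id)
  reads <- NULL
  tot <- sum(counts)
  if (tot > 0L) {
    gidx <- rep.int(seq_len(nrow(genes)), counts)
    # choose an exon row for each read, weighted by width within its gene
    exon_rows <- split(seq_len(nrow(ex)), gene_of)
    pick <- integer(tot)
    for (gi in unique(gidx)) {
      rows <- exon_rows[[as.character(gi)]]
      ri <- which(gidx == gi)
      pick[ri] <- if (length(rows) == 1L) rows else
        sample(rows, length(ri), replace = TRUE, prob = exw[rows])
    }
    start <- ex$start[pick] +
      floor(runif(tot) * pmax(1L, exw[pick] - r$read_len + 1L))
    reads <- clip_reads(new_df(contig = ex$contig[pick],
                               start = as.integer(start),
                               end = as.integer(start + r$read_len),
                               strand = ex$strand[pick]), genome)
  } else {
    reads <- empty_reads()
  }
  expr <- new_df(gene_id = genes$gene_id, exon_bp = genes$exon_bp,
                 count = counts,
                 rpkm = rpkm(counts, genes$exon_bp, max(1, sum(counts))),
                 baseline = baseline, has_4mC = g4, has_6mA = g6,
                 te_gene = genes$te_gene, expressed = genes$expressed)
  list(reads = read_set("rnaseq", reads), expression = expr)
}
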
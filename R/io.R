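# Serialization of pipeline artifacts. Internal coordinates are 0-based
# half-open everywhere; GFF3 is emitted 1-based inclusive, BED/bedGraph
# 0-based half-open. All writers are deterministic (same object, same
# bytes).

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 8))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genome FASTA and GFF3 annotation
#'
#' @param genome an `annotated_genome`.
#' @param fasta,gff3 output paths.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta, gff3) {
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, fasta, width = 80L)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$contig_len),
                     genome$contig_len))
  gff_row <- function(contig, type, start, end, strand, attrs) {
    sprintf("%s\tbdellometh\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, type, start + 1L, end, strand, attrs)
  }
  g <- genome$genes
  if (nrow(g)) {
    lines <- c(lines,
               gff_row(g$contig, "gene", g$start, g$end, g$strand,
                       sprintf("ID=%s;te_gene=%s;expressed=%s", g$gene_id,
                               tolower(g$te_gene), tolower(g$expressed))),
               gff_row(g$contig, "mRNA", g$start, g$end, g$strand,
                       sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id)))
    s <- genome$subfeatures
    lines <- c(lines, gff_row(s$contig, s$type, s$start, s$end, s$strand,
                              sprintf("Parent=%s.t1", s$gene_id)))
  }
  te <- genome$te_copies
  if (nrow(te)) {
    lines <- c(lines, gff_row(te$contig, "transposable_element", te$start,
                              te$end, te$strand,
                              sprintf("ID=%s;family=%s;integrity=%.3f;class=%s",
                                      te$te_id, te$family, te$integrity, te$class)))
  }
  tr <- genome$tandem_repeats
  if (nrow(tr)) {
    lines <- c(lines, gff_row(tr$contig, "tandem_repeat", tr$start, tr$end, "+",
                              sprintf("ID=%s;unit_len=%d", tr$tr_id, tr$unit_len)))
  }
  writeLines(lines, gff3)
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Write a methylome (or call set) as BED-like TSV
#'
#' Six columns: contig, start (0-based), end, name (mark), score
#' (fraction), strand.
#'
#' @param methylome methylome/call rows with contig, pos, strand, mark,
#'   fraction.
#' @param path output path.
#' @export
write_methylome_bed <- function(methylome, path) {
  frac <- methylome$fraction
  frac[is.na(frac)] <- 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4f\t%s", methylome$contig, methylome$pos,
                   methylome$pos + 1L, methylome$mark, frac, methylome$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write modification calls as GFF3
#'
#' Mirrors the layout of single-molecule modification reports: one
#' feature per called site with coverage, IPD ratio, score and fraction
#' attributes.
#'
#' @param calls a `mod_calls` data.frame.
#' @param path output path.
#' @export
write_calls_gff3 <- function(calls, path) {
  attrs <- sprintf("coverage=%d;IPDRatio=%.3f;frac=%s;class=%s;primary=%s",
                   calls$coverage, calls$ipd_ratio,
                   ifelse(is.na(calls$fraction), ".", sprintf("%.3f", calls$fraction)),
                   ifelse(is.na(calls$class), ".", calls$class),
                   tolower(calls$primary))
  lines <- c("##gff-version 3",
             sprintf("%s\tbdellometh\tmodified_DNA_base\t%d\t%d\t%.1f\t%s\t.\t%s;mark=%s",
                     calls$contig, calls$pos + 1L, calls$pos + 1L, calls$score,
                     calls$strand, attrs, calls$mark))
  writeLines(lines, path)
  invisible(path)
}

#' Write calls as TSV
#' @param calls a `mod_calls` data.frame.
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) write_tsv(calls, path)

#' Write a read set as BED6
#' @param reads a `read_set` or reads data.frame.
#' @param path output path.
#' @export
write_reads_bed <- function(reads, path) {
  assay <- "reads"
  if (inherits(reads, "read_set")) { assay <- reads$assay; reads <- reads$reads }
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$contig, reads$start,
                   reads$end, assay, reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  lines <- unlist(lapply(names(track$values), function(cn) {
    v <- track$values[[cn]]
    start <- (seq_along(v) - 1L) * track$bin_size
    end <- pmin(start + track$bin_size, track$contig_len[[cn]])
    sprintf("%s\t%d\t%d\t%s", cn, start, end, formatC(v, format = "g", digits = 6))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write peaks in narrowPeak-style BED
#'
#' Columns: chrom, start, end, name, score, ".", signal (max bin count),
#' -log10 p, -1, summit offset from start.
#'
#' @param peaks a `peaks` data.frame.
#' @param path output path.
#' @param name_prefix peak name prefix.
#' @export
write_peaks_narrowpeak <- function(peaks, path, name_prefix = "peak") {
  lines <- sprintf("%s\t%d\t%d\t%s_%d\t%d\t.\t%.3f\t%.3f\t-1\t%d",
                   peaks$contig, peaks$start, peaks$end, name_prefix,
                   seq_len(nrow(peaks)), pmin(1000L, as.integer(round(peaks$score))),
                   peaks$max_count, peaks$score / 10, peaks$summit - peaks$start)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file as intervals
#' @param path BED path (3+ columns).
#' @return data.frame: contig, start, end (0-based half-open), and
#'   name/score/strand when present.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  df
}

#' Write a sim_config as YAML
#' @param config a `sim_config`.
#' @param path output path.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$te_families <- as.list(as.data.frame(x$te_families))
  x$meth_4mC$context_weights <- as.list(x$meth_4mC$context_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a sim_config from YAML
#' @param path YAML path.
#' @return a `sim_config`.
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  te <- as.data.frame(x$te_families, stringsAsFactors = FALSE)
  x$te_families <- NULL
  cfg <- do.call(sim_config, c(list(seed = x$seed), x[setdiff(names(x), "seed")]))
  cfg$te_families <- te
  cfg$meth_4mC$context_weights <- unlist(cfg$meth_4mC$context_weights)
  cfg
}
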
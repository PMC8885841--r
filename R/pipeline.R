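#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> call modifications -> enrichment peaks ->
#' association statistics -> motif statistics from one configuration,
#' writing all artifacts and a machine-readable JSON run report. Stages
#' execute in dependency order; disabling an upstream stage while
#' requesting a downstream one raises a dependency error naming the
#' stage. The report (and every artifact) is byte-identical across runs
#' with the same configuration.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param stages character subset of c("simulate", "callmods", "peaks",
#'   "associate", "motifs").
#' @return the run report (list), invisibly; written to
#'   `outdir/report.json`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "callmods", "peaks",
                                    "associate", "motifs")) {
  validate_sim_config(config)
  all_stages <- c("simulate", "callmods", "peaks", "associate", "motifs")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(up, down) {
    if (down %in% stages && !(up %in% stages)) {
      stop("dependency error: stage '", down, "' requires stage '", up, "'")
    }
  }
  need("simulate", "callmods"); need("simulate", "peaks")
  need("callmods", "associate"); need("peaks", "associate")
  need("callmods", "motifs")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  report <- list(package_version = as.character(packageVersion("bdellometh")),
                 seed = config$seed, stages = stages)
  artifacts <- character(0)

  log_stage <- function(name, ...) message("[", name, "] ", ...)

  ## ---- simulate ----
  log_stage("simulate", "genome ", config$genome$length, " bp, seed ", config$seed)
  genome <- simulate_genome(config)
  methylome <- plant_methylome(genome, config)
  kinetics <- simulate_kinetics(genome, methylome, config)
  dip <- simulate_dipseq(genome, methylome, config)
  chip <- simulate_chipseq(genome, config)
  rna <- simulate_rnaseq(genome, methylome, config)
  write_genome(genome, pth("genome.fasta"), pth("annotation.gff3"))
  write_methylome_bed(methylome, pth("methylome_truth.bed"))
  write_config_yaml(config, pth("config.yaml"))
  for (rs in c(dip, chip, list(rna$reads))) {
    write_reads_bed(rs, pth(paste0("reads_", rs$assay, ".bed")))
  }
  write_tsv(rna$expression, pth("expression_truth.tsv"))
  artifacts <- c(artifacts, "genome.fasta", "annotation.gff3",
                 "methylome_truth.bed", "config.yaml", "expression_truth.tsv",
                 paste0("reads_", vapply(c(dip, chip, list(rna$reads)),
                                         `[[`, "", "assay"), ".bed"))
  report$simulate <- list(
    contigs = length(genome$contigs), genome_bp = sum(genome$contig_len),
    n_genes = nrow(genome$genes), n_te_copies = nrow(genome$te_copies),
    n_tandem_repeats = nrow(genome$tandem_repeats),
    n_4mC_true = sum(methylome$mark == "4mC"),
    n_6mA_true = sum(methylome$mark == "6mA"))

  ## ---- callmods ----
  calls <- primary <- NULL
  if ("callmods" %in% stages) {
    log_stage("callmods", "calling modifications at ", nrow(kinetics), " sites")
    filter <- call_filter()
    calls <- call_modifications(kinetics, genome, filter)
    primary <- calls[calls$primary, , drop = FALSE]
    write_calls_tsv(calls, pth("calls.tsv"))
    write_calls_gff3(calls, pth("calls.gff3"))
    artifacts <- c(artifacts, "calls.tsv", "calls.gff3")
    fs <- fraction_summary(primary)
    fs$high_low_ratio[!is.finite(fs$high_low_ratio)] <- NA_real_
    report$callmods <- list(
      n_retained = nrow(calls), n_primary = nrow(primary),
      n_primary_4mC = sum(primary$mark == "4mC"),
      n_primary_6mA = sum(primary$mark == "6mA"),
      fraction_summary = fs,
      strand_symmetry = strand_symmetry(primary, genome)$symmetric_fraction)
  }

  ## ---- peaks ----
  peaks <- l2r <- NULL
  if ("peaks" %in% stages) {
    log_stage("peaks", "tracks and peak calling")
    d <- config$dip
    tracks <- list()
    for (nm in names(dip)) {
      tracks[[nm]] <- bin_coverage(dip[[nm]], genome, 10L, d$read_len)
    }
    for (nm in names(chip)) {
      tracks[[nm]] <- bin_coverage(chip[[nm]], genome, 10L, config$chip$read_len)
    }
    peaks <- list()
    for (nm in c("dip4mC", "dip6mA", "H3K4me3", "H3K9me3", "H3K27me3")) {
      peaks[[nm]] <- call_peaks(tracks[[nm]])
      write_peaks_narrowpeak(peaks[[nm]], pth(paste0("peaks_", nm, ".bed")), nm)
    }
    rpgc <- lapply(tracks, normalize_rpgc)
    l2r <- list()
    for (nm in c("H3K4me3", "H3K9me3", "H3K27me3")) {
      l2r[[nm]] <- log2_ratio(rpgc[[nm]], rpgc$chip_input)
      write_track_bedgraph(l2r[[nm]], pth(paste0("log2ratio_", nm, ".bedgraph")))
    }
    write_track_bedgraph(rpgc$dip4mC, pth("rpgc_dip4mC.bedgraph"))
    artifacts <- c(artifacts,
                   paste0("peaks_", c("dip4mC", "dip6mA", "H3K4me3", "H3K9me3",
                                      "H3K27me3"), ".bed"),
                   paste0("log2ratio_", c("H3K4me3", "H3K9me3", "H3K27me3"),
                          ".bedgraph"), "rpgc_dip4mC.bedgraph")
    report$peaks <- lapply(peaks, nrow)
  }

  if (!("associate" %in% stages)) {
    if (!("motifs" %in% stages)) return(finish_report(report, artifacts, outdir))
  }

  ## ---- associate ----
  if ("associate" %in% stages) {
  log_stage("associate", "feature association statistics")
  gl <- sum(genome$contig_len)
  genes_nt <- genome$genes[!genome$genes$te_gene, , drop = FALSE]
  m4 <- methylome[methylome$mark == "4mC", , drop = FALSE]
  sites4 <- primary[primary$mark == "4mC", , drop = FALSE]
  sites <- if (nrow(sites4)) sites4 else m4
  dens <- rbind(
    normalized_density(sites, genes_nt, interval_bp(genes_nt) / gl, "genes"),
    normalized_density(sites, genome$te_copies,
                       interval_bp(genome$te_copies) / gl, "TE"),
    normalized_density(sites, genome$tandem_repeats,
                       interval_bp(genome$tandem_repeats) / gl, "TR"))
  write_tsv(dens, pth("density_table.tsv"))
  integ <- density_by_integrity(sites, genome$te_copies)
  write_tsv(integ, pth("integrity_table.tsv"))
  coloc <- colocalization_fractions(
    peaks$dip4mC, peaks[c("H3K4me3", "H3K9me3", "H3K27me3")],
    combine = list(heterochromatin = c("H3K9me3", "H3K27me3")))
  write_tsv(coloc, pth("colocalization.tsv"))
  summit_centre <- list()
  if (nrow(peaks$dip4mC)) {
    for (nm in names(l2r)) {
      prof <- summit_signal_profile(peaks$dip4mC, l2r[[nm]], flank = 3000L)
      v <- profile_values(prof)
      summit_centre[[nm]] <- mean(v[abs(prof$bins) <= 250])
    }
  }
  expr <- rna$expression
  t4 <- expression_group_tests(expr[expr$te_gene, , drop = FALSE],
                               expr$has_4mC[expr$te_gene])
  t6 <- expression_group_tests(expr[!expr$te_gene, , drop = FALSE],
                               expr$has_6mA[!expr$te_gene])
  hist_cls <- assign_histone_class(genes_nt,
                                   peaks[c("H3K4me3", "H3K9me3", "H3K27me3")])
  ta <- expression_group_tests(expr[match(genes_nt$gene_id, expr$gene_id), ,
                                    drop = FALSE], hist_cls)
  # fraction histogram analog
  frac_hist <- table(cut(primary$fraction[!is.na(primary$fraction)],
                         c(0, 0.1, 0.5, 0.8, 1), include.lowest = TRUE))
  report$associate <- list(
    density = dens, integrity = integ, colocalization = coloc,
    summit_log2ratio_centre = summit_centre,
    ttest_4mC_te_genes = list(p = t4$p_value, estimate = t4$estimate),
    ttest_6mA_genes = list(p = t6$p_value, estimate = t6$estimate),
    anova_histone_p = ta$p_value,
    fraction_histogram = as.list(frac_hist),
    cpg_obs_exp_genome = mean(
      cpg_obs_exp(paste(genome$contigs, collapse = ""), 10000L)$obs_exp,
      na.rm = TRUE))
  artifacts <- c(artifacts, "density_table.tsv", "integrity_table.tsv",
                 "colocalization.tsv")
  }

  if (!("motifs" %in% stages)) return(finish_report(report, artifacts, outdir))

  ## ---- motifs ----
  log_stage("motifs", "sequence-context statistics")
  motif_report <- list()
  for (mk in c("4mC", "6mA")) {
    sub <- primary[primary$mark == mk, , drop = FALSE]
    if (!nrow(sub)) next
    win <- extract_context(sub, genome, flank = 10L)
    if (!nrow(win)) next
    dt <- doublet_triplet_stats(win)
    bg <- sample_context_background(genome, if (mk == "4mC") "C" else "A",
                                    n = 5L * nrow(win), flank = 10L,
                                    seed = config$seed + 7L)
    enr <- kmer_enrichment(win, bg)
    write_tsv(enr, pth(paste0("kmer_enrichment_", mk, ".tsv")))
    artifacts <- c(artifacts, paste0("kmer_enrichment_", mk, ".tsv"))
    motif_report[[mk]] <- list(
      top_doublets = as.list(head(dt$doublet, 4)),
      top_kmers = head(enr$kmer, 5),
      top_q = enr$q_value[1])
  }
  report$motifs <- motif_report
  finish_report(report, artifacts, outdir)
}

finish_report <- function(report, artifacts, outdir) {
  files <- file.path(outdir, sort(unique(artifacts)))
  sums <- md5sum(files)
  names(sums) <- basename(names(sums))
  report$checksums <- as.list(sums)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  invisible(report)
}

#' Validate pipeline input files
#'
#' Checks FASTA, GFF3, BED and TSV inputs for well-formedness: readable
#' sequences with unique names, coordinates within contig bounds, valid
#' strand symbols, start < end. Returns structured diagnostics; rows with
#' level "fatal" indicate unusable inputs.
#'
#' @param paths named list with any of `fasta`, `gff3`, `bed` (character
#'   vector of BED paths), `tsv`.
#' @return data.frame of diagnostics: level, file, line, message (zero
#'   rows when everything is valid).
#' @export
validate_inputs <- function(paths) {
  diag <- list()
  note <- function(level, file, line, msg) {
    diag[[length(diag) + 1L]] <<- new_df(level = level, file = file,
                                         line = line, message = msg)
  }
  contig_len <- NULL
  if (!is.null(paths$fasta)) {
    if (!file.exists(paths$fasta)) {
      note("fatal", paths$fasta, NA_integer_, "file not found")
    } else {
      dna <- tryCatch(Biostrings::readDNAStringSet(paths$fasta),
                      error = function(e) NULL)
      if (is.null(dna)) {
        note("fatal", paths$fasta, NA_integer_, "unreadable FASTA")
      } else {
        nm <- sub("\\s.*", "", names(dna))
        if (anyDuplicated(nm)) note("fatal", paths$fasta, NA_integer_,
                                    "duplicate contig names")
        contig_len <- setNames(Biostrings::width(dna), nm)
      }
    }
  }
  if (!is.null(paths$gff3) && file.exists(paths$gff3)) {
    lines <- readLines(paths$gff3)
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    for (i in body) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 9L) { note("fatal", paths$gff3, i, "fewer than 9 columns"); next }
      s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
      if (is.na(s) || is.na(e) || s < 1L || e < s) {
        note("fatal", paths$gff3, i, sprintf("invalid coordinates %s..%s", f[4], f[5]))
      } else if (!is.null(contig_len)) {
        if (!f[1] %in% names(contig_len)) {
          note("fatal", paths$gff3, i, paste("unknown contig", f[1]))
        } else if (e > contig_len[[f[1]]]) {
          note("fatal", paths$gff3, i,
               sprintf("feature end %d beyond contig %s end %d", e, f[1],
                       contig_len[[f[1]]]))
        }
      }
      if (!f[7] %in% c("+", "-", ".")) note("fatal", paths$gff3, i,
                                            paste("invalid strand", f[7]))
    }
  } else if (!is.null(paths$gff3)) {
    note("fatal", paths$gff3, NA_integer_, "file not found")
  }
  for (bed in paths$bed %||% character(0)) {
    if (!file.exists(bed)) { note("fatal", bed, NA_integer_, "file not found"); next }
    lines <- readLines(bed)
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) { note("fatal", bed, i, "fewer than 3 columns"); next }
      s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e) || s < 0L || s >= e) {
        note("fatal", bed, i, sprintf("invalid interval %s..%s", f[2], f[3]))
      } else if (!is.null(contig_len) && f[1] %in% names(contig_len) &&
                 e > contig_len[[f[1]]]) {
        note("fatal", bed, i, "interval beyond contig end")
      }
      if (length(f) >= 6L && !f[6] %in% c("+", "-", "."))
        note("fatal", bed, i, paste("invalid strand", f[6]))
    }
  }
  if (!is.null(paths$tsv)) {
    for (tsv in paths$tsv) {
      if (!file.exists(tsv)) { note("fatal", tsv, NA_integer_, "file not found"); next }
      ok <- tryCatch({ read.delim(tsv, nrows = 5); TRUE },
                     error = function(e) FALSE)
      if (!ok) note("fatal", tsv, NA_integer_, "unreadable TSV")
    }
  }
  out <- if (length(diag)) do.call(rbind, diag) else
    new_df(level = character(), file = character(), line = integer(),
           message = character())
  rownames(out) <- NULL
  out
}
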
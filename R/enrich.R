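#' Binned coverage track from a read set
#'
#' Each read is extended to `read_extension` bp from its 5' end in read
#' orientation (emulating fragment-length read extension) and per-bin
#' values are the overlapping extended-read base pairs divided by the bin
#' size. The bin grid is anchored at contig position 0; the last partial
#' bin is kept.
#'
#' @param reads a `read_set` or a reads data.frame (contig, start, end,
#'   strand).
#' @param genome an `annotated_genome` (supplies contig lengths).
#' @param bin_size bin width in bp (default 10).
#' @param read_extension extension length in bp; must be at least the
#'   read length.
#' @return a `coverage_track`: list with per-contig numeric bin vectors,
#'   `bin_size`, `normalization` ("raw"), `read_extension`, `contig_len`.
#' @export
bin_coverage <- function(reads, genome, bin_size = 10L, read_extension = 50L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  cl <- genome$contig_len
  if (nrow(reads)) {
    w <- reads$end - reads$start
    if (read_extension < max(w)) {
      stop("read_extension (", read_extension, ") is shorter than the longest read (",
           max(w), ")")
    }
  }
  values <- lapply(names(cl), function(cn) {
    L <- cl[[cn]]
    nb <- as.integer(ceiling(L / bin_size))
    r <- reads[reads$contig == cn, , drop = FALSE]
    if (!nrow(r)) return(numeric(nb))
    s <- ifelse(r$strand == "-", pmax(0L, r$end - read_extension), r$start)
    e <- ifelse(r$strand == "-", r$end, pmin(L, r$start + read_extension))
    # per-bp pileup via difference array, then aggregate to bins
    d <- numeric(L + 1L)
    ds <- rowsum(rep(1, length(s)), s + 1L)
    d[as.integer(rownames(ds))] <- ds[, 1]
    de <- rowsum(rep(1, length(e)), e + 1L)
    ei <- as.integer(rownames(de))
    keep <- ei <= L
    d[ei[keep]] <- d[ei[keep]] - de[keep, 1]
    covbp <- cumsum(d[seq_len(L)])
    bin_of <- rep(seq_len(nb), each = bin_size, length.out = L)
    as.numeric(rowsum(covbp, bin_of)[, 1] / bin_size)
  })
  names(values) <- names(cl)
  structure(list(values = values, bin_size = as.integer(bin_size),
                 normalization = "raw", read_extension = as.integer(read_extension),
                 contig_len = cl),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", sum(lengths(x$values)), "bins of", x$bin_size,
      "bp;", x$normalization, "normalization\n")
  invisible(x)
}

track_total_bp <- function(track) {
  sum(vapply(track$values, sum, 0)) * track$bin_size
}

#' RPGC (1x genome coverage) normalization
#'
#' Scales a raw track so that mean coverage over the effective genome is
#' 1 ("reads per genomic content").
#'
#' @param track a raw `coverage_track`.
#' @param effective_genome_size effective genome size in bp (defaults to
#'   the track's total contig length).
#' @return the normalized `coverage_track`.
#' @export
normalize_rpgc <- function(track, effective_genome_size = sum(track$contig_len)) {
  tot <- track_total_bp(track)
  if (tot <= 0) stop("cannot RPGC-normalize a track with zero total coverage")
  scale <- effective_genome_size / tot
  track$values <- lapply(track$values, function(v) v * scale)
  track$normalization <- "RPGC"
  track
}

#' log2 IP/input ratio track
#'
#' Per-bin log2((ip + pseudocount) / (input + pseudocount)) between two
#' RPGC-normalized tracks on the same bin grid.
#'
#' @param ip_track,input_track RPGC-normalized `coverage_track`s.
#' @param pseudocount stabilizer on the RPGC scale (default 1).
#' @return a `coverage_track` with normalization "log2ratio".
#' @export
log2_ratio <- function(ip_track, input_track, pseudocount = 1) {
  if (!identical(lengths(ip_track$values), lengths(input_track$values)) ||
      ip_track$bin_size != input_track$bin_size) {
    stop("ip and input tracks are on different bin grids")
  }
  ip_track$values <- Map(function(a, b) log2((a + pseudocount) / (b + pseudocount)),
                         ip_track$values, input_track$values)
  ip_track$normalization <- "log2ratio"
  ip_track
}

#' Call enrichment peaks against a global Poisson background
#'
#' Reproduces a "no model, no local lambda" peak-calling mode: each bin's
#' count is tested against the genome-wide mean bin count with a
#' one-sided Poisson upper-tail p-value; significant bins (p below the
#' threshold) are merged when separated by at most `min_gap` bp, peaks
#' shorter than `min_width` are dropped, and the summit is the midpoint
#' of the (leftmost) maximal bin.
#'
#' @param track a raw `coverage_track` (counts).
#' @param p_threshold per-bin significance threshold (default 1e-5).
#' @param min_gap merge gap in bp (default 300, about one fragment).
#' @param min_width minimum peak width in bp (default 150).
#' @return a `peaks` data.frame: contig, start, end, summit, max_count,
#'   p_value, score (-10*log10 p).
#' @export
call_peaks <- function(track, p_threshold = 1e-5, min_gap = 300L,
                       min_width = 150L) {
  lambda <- mean(unlist(track$values, use.names = FALSE))
  if (!is.finite(lambda) || lambda <= 0) {
    stop("zero background rate: cannot call peaks on an empty track")
  }
  bs <- track$bin_size
  out <- lapply(names(track$values), function(cn) {
    v <- track$values[[cn]]
    p <- ppois(ceiling(v) - 1, lambda, lower.tail = FALSE)
    sig <- which(p < p_threshold)
    if (!length(sig)) return(NULL)
    # merge significant bins whose gaps are <= min_gap bp
    gap_bins <- max(0L, as.integer(floor(min_gap / bs)))
    brk <- c(0L, which(diff(sig) > gap_bins + 1L), length(sig))
    peaks <- lapply(seq_len(length(brk) - 1L), function(i) {
      bins <- sig[(brk[i] + 1L):brk[i + 1L]]
      start <- (bins[1] - 1L) * bs
      end <- min(bins[length(bins)] * bs, track$contig_len[[cn]])
      if (end - start < min_width) return(NULL)
      inside <- seq.int(bins[1], bins[length(bins)])
      top <- inside[which.max(v[inside])]
      new_df(contig = cn, start = as.integer(start), end = as.integer(end),
             summit = as.integer(min((top - 1L) * bs + bs %/% 2L,
                                     track$contig_len[[cn]] - 1L)),
             max_count = max(v[inside]), p_value = min(p[bins]))
    })
    do.call(rbind, peaks)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- new_df(contig = character(), start = integer(), end = integer(),
                  summit = integer(), max_count = numeric(), p_value = numeric())
  }
  out$score <- -10 * log10(pmax(out$p_value, 1e-300))
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

#' @export
print.peaks <- function(x, ...) {
  cat("peaks:", nrow(x), "enriched intervals\n")
  invisible(x)
}
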
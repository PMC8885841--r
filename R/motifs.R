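# Sequence-context statistics around modification sites: strand-aware
# window extraction, doublet/triplet composition, and exhaustive k-mer
# enrichment by Fisher's exact test (a deterministic stand-in for
# position-specific motif discovery).

#' Extract strand-aware context windows around modification sites
#'
#' Returns the +/- flank sequence around each site, read on the modified
#' strand (minus-strand sites yield reverse-complemented windows), so the
#' centre base is always C for 4mC and A for 6mA. Windows truncated at
#' contig edges, and records whose centre base does not match the mark,
#' are dropped and counted.
#'
#' @param calls call/methylome rows: contig, pos, strand, mark.
#' @param genome an `annotated_genome`.
#' @param flank window half-width in bp (5, 10 or 20 are the usual
#'   choices).
#' @return a `context_windows` data.frame (contig, pos, strand, mark,
#'   window) with attributes `n_edge_dropped` and `n_base_mismatch`.
#' @export
extract_context <- function(calls, genome, flank = 10L) {
  L <- genome$contig_len[calls$contig]
  keep <- calls$pos - flank >= 0L & calls$pos + flank < L
  n_edge <- sum(!keep)
  calls <- calls[keep, , drop = FALSE]
  win <- substring(genome$contigs[calls$contig],
                   calls$pos - flank + 1L, calls$pos + flank + 1L)
  minus <- calls$strand == "-"
  if (any(minus)) win[minus] <- revcomp(win[minus])
  centre <- substring(win, flank + 1L, flank + 1L)
  expected <- ifelse(calls$mark == "4mC", "C", "A")
  ok <- centre == expected
  n_mismatch <- sum(!ok)
  out <- new_df(contig = calls$contig[ok], pos = calls$pos[ok],
                strand = calls$strand[ok], mark = calls$mark[ok],
                window = win[ok])
  attr(out, "n_edge_dropped") <- n_edge
  attr(out, "n_base_mismatch") <- n_mismatch
  attr(out, "flank") <- as.integer(flank)
  class(out) <- c("context_windows", "data.frame")
  out
}

#' Random background context windows
#'
#' Samples genome positions with the requested centre base (on a random
#' strand) and extracts matched windows — the background set for k-mer
#' enrichment.
#'
#' @param genome an `annotated_genome`.
#' @param centre_base "C" (4mC-matched) or "A" (6mA-matched).
#' @param n number of windows.
#' @param flank window half-width in bp.
#' @param seed RNG seed.
#' @return a `context_windows` data.frame.
#' @export
sample_context_background <- function(genome, centre_base = c("C", "A"),
                                      n = 1000L, flank = 10L, seed = 1L) {
  centre_base <- match.arg(centre_base)
  set.seed(stage_seed(seed, 0L))
  picks <- lapply(names(genome$contigs), function(cn) {
    ch <- seq_chars(genome$contigs[[cn]])
    plus <- which(ch == centre_base) - 1L
    minus <- which(ch == comp_base(centre_base)) - 1L
    new_df(contig = cn, pos = c(plus, minus),
           strand = rep(c("+", "-"), c(length(plus), length(minus))))
  })
  sites <- do.call(rbind, picks)
  if (!nrow(sites)) stop("no genome positions with centre base ", centre_base)
  sites <- sites[sample.int(nrow(sites), min(n, nrow(sites))), , drop = FALSE]
  sites$mark <- if (centre_base == "C") "4mC" else "6mA"
  extract_context(sites, genome, flank)
}

#' Doublet and triplet composition at modification sites
#'
#' Tabulates the dinucleotide at (centre, centre+1) and the trinucleotides
#' at (centre-1 .. centre+1) and (centre .. centre+2) of each context
#' window, as proportions (each table sums to 1).
#'
#' @param windows a `context_windows` object (flank >= 2).
#' @return list of named proportion vectors: `doublet`, `triplet_m1`,
#'   `triplet_p2`, each sorted decreasing.
#' @export
doublet_triplet_stats <- function(windows) {
  if (!nrow(windows)) {
    return(list(doublet = numeric(0), triplet_m1 = numeric(0),
                triplet_p2 = numeric(0)))
  }
  flank <- attr(windows, "flank") %||%
    ((nchar(windows$window[1]) - 1L) %/% 2L)
  if (flank < 2L) stop("doublet/triplet statistics need flank >= 2")
  c1 <- flank + 1L
  prop <- function(x) sort(table(x) / length(x), decreasing = TRUE)
  list(doublet = prop(substring(windows$window, c1, c1 + 1L)),
       triplet_m1 = prop(substring(windows$window, c1 - 1L, c1 + 1L)),
       triplet_p2 = prop(substring(windows$window, c1, c1 + 2L)))
}

window_kmer_presence <- function(windows, k) {
  # windows: character vector; returns table kmer -> number of windows
  # containing it at least once
  L <- nchar(windows[1])
  subs <- do.call(cbind, lapply(seq_len(L - k + 1L),
                                function(i) substring(windows, i, i + k - 1L)))
  per_window <- lapply(seq_len(nrow(subs)), function(r) unique(subs[r, ]))
  tab <- table(unlist(per_window, use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' k-mer enrichment by Fisher's exact test
#'
#' For every k-mer observed in either window set, builds the 2x2 table of
#' windows containing vs lacking the k-mer (foreground vs background) and
#' tests one-sided enrichment with Fisher's exact test;
#' Benjamini-Hochberg adjustment is applied across all tested k-mers.
#' K-mers absent from both sets never enter the output.
#'
#' @param foreground,background `context_windows` objects (or data.frames
#'   with a `window` column).
#' @param k_range k-mer sizes to test (default 2:6).
#' @return data.frame sorted by (q_value, -odds_ratio): kmer, k, fg_with,
#'   fg_total, bg_with, bg_total, odds_ratio, p_value, q_value.
#' @export
kmer_enrichment <- function(foreground, background, k_range = 2:6) {
  nf <- nrow(foreground); nb <- nrow(background)
  if (!nf || !nb) stop("foreground and background must be non-empty")
  if (nb < nf) warning("background smaller than foreground; proceeding")
  rows <- list()
  for (k in k_range) {
    fg <- window_kmer_presence(foreground$window, k)
    bg <- window_kmer_presence(background$window, k)
    kmers <- union(names(fg), names(bg))
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    if (!length(kmers)) next
    a <- unname(ifelse(is.na(fg[kmers]), 0L, fg[kmers]))
    b <- unname(ifelse(is.na(bg[kmers]), 0L, bg[kmers]))
    p <- vapply(seq_along(kmers), function(i) {
      fisher.test(matrix(c(a[i], nf - a[i], b[i], nb - b[i]), 2L),
                  alternative = "greater")$p.value
    }, 0)
    or <- (a + 0.5) / (nf - a + 0.5) / ((b + 0.5) / (nb - b + 0.5))
    rows[[length(rows) + 1L]] <- new_df(kmer = kmers, k = k, fg_with = a,
                                        fg_total = nf, bg_with = b,
                                        bg_total = nb, odds_ratio = or,
                                        p_value = p)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no valid k-mers found")
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, -out$odds_ratio), , drop = FALSE]
  rownames(out) <- NULL
  out
}
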
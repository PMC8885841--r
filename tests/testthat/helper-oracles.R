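# Brute-force oracles, written independently of the implementations they
# check: per-bp pileups, bp-set operations on logical vectors, all-pairs
# distance scans, and manual window binning.

oracle_bin_coverage <- function(reads, contig_len, bin_size, ext) {
  out <- lapply(names(contig_len), function(cn) {
    L <- contig_len[[cn]]
    bp <- numeric(L)
    r <- reads[reads$contig == cn, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      if (r$strand[i] == "+") {
        s <- r$start[i]; e <- min(L, r$start[i] + ext)
      } else {
        s <- max(0L, r$end[i] - ext); e <- r$end[i]
      }
      if (s < e) for (p in (s + 1L):e) bp[p] <- bp[p] + 1
    }
    nb <- ceiling(L / bin_size)
    v <- numeric(nb)
    for (b in seq_len(nb)) {
      lo <- (b - 1L) * bin_size + 1L
      hi <- min(L, b * bin_size)
      v[b] <- sum(bp[lo:hi]) / bin_size
    }
    v
  })
  names(out) <- names(contig_len)
  out
}

oracle_jaccard <- function(a, b, L, contigs) {
  inter <- 0L; uni <- 0L
  for (cn in contigs) {
    va <- logical(L); vb <- logical(L)
    aa <- a[a$contig == cn, , drop = FALSE]
    bb <- b[b$contig == cn, , drop = FALSE]
    for (i in seq_len(nrow(aa))) va[(aa$start[i] + 1L):aa$end[i]] <- TRUE
    for (i in seq_len(nrow(bb))) vb[(bb$start[i] + 1L):bb$end[i]] <- TRUE
    inter <- inter + sum(va & vb)
    uni <- uni + sum(va | vb)
  }
  if (uni == 0L) NA_real_ else inter / uni
}

oracle_window_intersect <- function(items, features, window) {
  assoc <- logical(nrow(items))
  hit <- logical(nrow(features))
  for (i in seq_len(nrow(items))) {
    for (j in seq_len(nrow(features))) {
      if (items$contig[i] != features$contig[j]) next
      # closest-base distance: 0 when overlapping, else bases between the
      # nearest covered positions
      d <- max(0L, features$start[j] - items$end[i] + 1L,
               items$start[i] - features$end[j] + 1L)
      if (d <= window) { assoc[i] <- TRUE; hit[j] <- TRUE }
    }
  }
  list(item_associated = assoc, feature_hit = hit)
}

oracle_occupancy <- function(items, features, flank, bin) {
  nb <- 2L * flank / bin
  mat <- matrix(0, nrow(features), nb)
  for (j in seq_len(nrow(features))) {
    anchor <- if (features$strand[j] == "+") features$start[j] else features$end[j] - 1L
    for (i in seq_len(nrow(items))) {
      if (items$contig[i] != features$contig[j]) next
      rel <- items$pos[i] - (anchor - flank)
      if (rel < 0 || rel >= 2L * flank) next
      b <- rel %/% bin + 1L
      if (features$strand[j] == "-") b <- nb + 1L - b
      mat[j, b] <- mat[j, b] + 1
    }
  }
  mat
}
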
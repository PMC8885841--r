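# Feature-association statistics: profiles, densities, windowed
# intersections, spatial correlation, integrity stratification,
# co-localization, strand symmetry, CpG observed/expected, and
# expression grouping.

new_profile <- function(mat, bins_bp, bin_size, flank, anchor, n_body_bins = 0L,
                        mask = NULL, skipped = 0L) {
  structure(list(matrix = mat, bins = bins_bp, bin_size = bin_size,
                 flank = flank, anchor = anchor, n_body_bins = n_body_bins,
                 mask = mask, skipped = skipped),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$matrix), "features x", ncol(x$matrix),
      "bins (anchor:", x$anchor, ")\n")
  invisible(x)
}

#' Aggregate profile of a profile matrix
#'
#' Column sums divided by the number of features (occupancy), or column
#' means over the coverage mask for fraction profiles.
#'
#' @param x a `profile_matrix`.
#' @return numeric vector, one value per bin.
#' @export
profile_values <- function(x) {
  if (is.null(x$mask)) {
    colSums(x$matrix) / max(1L, nrow(x$matrix))
  } else {
    n <- colSums(x$mask)
    ifelse(n > 0, colSums(x$matrix * x$mask) / pmax(n, 1L), 0)
  }
}

#' @export
plot.profile_matrix <- function(x, ...) {
  v <- profile_values(x)
  graphics::plot(x$bins, v, type = "l", xlab = "position (bp)",
                 ylab = "mean signal", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Occupancy profile around anchored features
#'
#' Counts items (modification sites, or reads by midpoint) in fixed-width
#' bins within +/- flank of each feature's anchor point, divided by the
#' number of features ("IP occupancy"). Feature strand flips the axis so
#' upstream is always to the left.
#'
#' @param items sites (data.frame with `pos`) or reads/intervals
#'   (counted at their midpoints).
#' @param features stranded feature data.frame (contig, start, end,
#'   strand, or a `summit` column for `anchor = "summit"`).
#' @param flank window half-width in bp (default 2500).
#' @param bin bin width in bp, must divide flank (default 25).
#' @param anchor which feature point to align on.
#' @return a `profile_matrix` (rows = features, columns = bins from
#'   -flank to +flank).
#' @export
occupancy_profile <- function(items, features, flank = 2500L, bin = 25L,
                              anchor = c("5prime", "TSS", "TTS", "summit")) {
  anchor <- match.arg(anchor)
  if (!nrow(features)) stop("occupancy_profile needs at least one feature")
  if (flank %% bin != 0L) stop("flank must be divisible by bin")
  an <- anchor_points(features, anchor)
  pts <- item_points(items)
  nb <- as.integer(2L * flank / bin)
  mat <- matrix(0, nrow(features), nb)
  for (cn in unique(an$contig)) {
    fi <- which(an$contig == cn)
    pp <- sort(pts$pos[pts$contig == cn])
    if (!length(pp)) next
    for (j in fi) {
      lo <- an$pos[j] - flank
      rel <- pp[pp >= lo & pp < an$pos[j] + flank] - lo
      if (!length(rel)) next
      idx <- rel %/% bin + 1L
      if (an$strand[j] == "-") idx <- nb + 1L - idx
      tb <- tabulate(idx, nb)
      mat[j, ] <- mat[j, ] + tb
    }
  }
  centres <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  new_profile(mat, centres, bin, flank, anchor)
}

#' Metaprofile with a length-normalized body
#'
#' Feature bodies are rescaled to a fixed number of body bins (0-100% of
#' feature length) with absolute-bp flanks on both sides; items falling
#' in the flanks use fixed-width bins. Zero-length features are skipped
#' (counted in the result's `skipped` field).
#'
#' @param items sites or intervals (midpoints).
#' @param features feature intervals with strand.
#' @param flank flank width in bp.
#' @param bin flank bin width in bp.
#' @param n_body_bins number of scaled body bins (default 100).
#' @return a `profile_matrix`; columns are upstream flank bins, body
#'   bins, downstream flank bins.
#' @export
metaprofile <- function(items, features, flank = 2500L, bin = 25L,
                        n_body_bins = 100L) {
  if (flank %% bin != 0L) stop("flank must be divisible by bin")
  keep <- features$end > features$start
  skipped <- sum(!keep)
  if (skipped) warning(skipped, " zero-length features skipped")
  features <- features[keep, , drop = FALSE]
  if (!nrow(features)) stop("metaprofile needs at least one non-empty feature")
  nf <- as.integer(flank / bin)
  nb <- 2L * nf + n_body_bins
  strand <- if ("strand" %in% names(features)) features$strand else rep("+", nrow(features))
  pts <- item_points(items)
  mat <- matrix(0, nrow(features), nb)
  for (cn in unique(features$contig)) {
    fi <- which(features$contig == cn)
    pp <- sort(pts$pos[pts$contig == cn])
    if (!length(pp)) next
    for (j in fi) {
      s <- features$start[j]; e <- features$end[j]
      sel <- pp[pp >= s - flank & pp < e + flank]
      if (!length(sel)) next
      idx <- integer(length(sel))
      up <- sel < s; dn <- sel >= e; body <- !up & !dn
      idx[up] <- (sel[up] - (s - flank)) %/% bin + 1L
      idx[body] <- nf + pmin(n_body_bins - 1L,
                             ((sel[body] - s) * n_body_bins) %/% (e - s)) + 1L
      idx[dn] <- nf + n_body_bins + (sel[dn] - e) %/% bin + 1L
      if (strand[j] == "-") idx <- nb + 1L - idx
      mat[j, ] <- mat[j, ] + tabulate(idx, nb)
    }
  }
  centres <- c(seq(-flank + bin / 2, -bin / 2, by = bin),
               seq_len(n_body_bins),
               seq(bin / 2, flank - bin / 2, by = bin))
  out <- new_profile(mat, centres, bin, flank, "body", n_body_bins)
  out$skipped <- skipped
  out
}

#' Mean-fraction profile around anchors
#'
#' Per bin, the mean methylation fraction of calls falling in the bin
#' ("mean normalized fraction"); bins without calls are masked.
#'
#' @param calls `mod_calls` (or methylome) rows carrying fractions.
#' @param anchors anchor data.frame (contig, pos, optional strand).
#' @param flank,bin window half-width and bin width in bp.
#' @return a `profile_matrix` with a coverage mask; `profile_values()`
#'   averages over covered bins.
#' @export
fraction_profile <- function(calls, anchors, flank = 2500L, bin = 25L) {
  if (flank %% bin != 0L) stop("flank must be divisible by bin")
  calls <- calls[!is.na(calls$fraction), , drop = FALSE]
  nb <- as.integer(2L * flank / bin)
  na <- nrow(anchors)
  sums <- matrix(0, na, nb)
  cnts <- matrix(0, na, nb)
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep("+", na)
  for (cn in unique(anchors$contig)) {
    ai <- which(anchors$contig == cn)
    cc <- calls[calls$contig == cn, , drop = FALSE]
    if (!nrow(cc)) next
    o <- order(cc$pos)
    cp <- cc$pos[o]; cf <- cc$fraction[o]
    for (j in ai) {
      lo <- anchors$pos[j] - flank
      in_w <- cp >= lo & cp < anchors$pos[j] + flank
      if (!any(in_w)) next
      idx <- (cp[in_w] - lo) %/% bin + 1L
      if (strand[j] == "-") idx <- nb + 1L - idx
      sums[j, ] <- sums[j, ] + rowsum_vec(cf[in_w], idx, nb)
      cnts[j, ] <- cnts[j, ] + tabulate(idx, nb)
    }
  }
  mat <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  centres <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  new_profile(mat, centres, bin, flank, "anchor", mask = cnts > 0)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  r <- rowsum(x, idx)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

#' Feature-class density normalized by genome fraction
#'
#' The published density measure: total modified sites overlapping a
#' feature class, divided by the number of annotations in the class,
#' divided by the genome fraction the class covers.
#'
#' @param calls sites (data.frame with contig, pos).
#' @param annotations feature intervals of one class.
#' @param genome_fraction fraction of the genome covered by the class
#'   (must be > 0).
#' @param class_name label for the output row.
#' @return one-row data.frame: class, n_sites, n_annotations,
#'   genome_fraction, normalized_density, defined.
#' @export
normalized_density <- function(calls, annotations, genome_fraction,
                               class_name = "class") {
  if (!is.null(annotations) && nrow(annotations)) {
    if (genome_fraction <= 0 || genome_fraction > 1) {
      stop("genome_fraction must lie in (0, 1]")
    }
    n_ann <- nrow(annotations)
    n_sites <- sum(window_intersect(calls, annotations, window = 0L)$item_associated)
    new_df(class = class_name, n_sites = n_sites, n_annotations = n_ann,
           genome_fraction = genome_fraction,
           normalized_density = (n_sites / n_ann) / genome_fraction,
           defined = TRUE)
  } else {
    new_df(class = class_name, n_sites = 0L, n_annotations = 0L,
           genome_fraction = genome_fraction, normalized_density = NA_real_,
           defined = FALSE)
  }
}

#' Windowed intersection of items and features
#'
#' An item is associated with a feature class when it overlaps a feature
#' or lies within `window` bp of one (base distance; an item whose
#' nearest feature base is `window + 1` bp away is not associated). Each
#' item counts once per class (union semantics).
#'
#' @param items points (data.frame with `pos`) or intervals.
#' @param features feature intervals.
#' @param window association distance in bp (default 500).
#' @return list: `item_associated` (logical per item), `feature_hit`
#'   (logical per feature), `n_with`, `n_without`.
#' @export
window_intersect <- function(items, features, window = 500L) {
  if (window < 0L) stop("window must be >= 0")
  if ("pos" %in% names(items)) {
    items <- new_df(contig = items$contig, start = items$pos,
                    end = items$pos + 1L)
  }
  item_assoc <- logical(nrow(items))
  feat_hit <- logical(nrow(features))
  if (nrow(items) && nrow(features)) {
    for (cn in unique(items$contig)) {
      ii <- which(items$contig == cn)
      fi <- which(features$contig == cn)
      if (!length(fi)) next
      hits <- IRanges::findOverlaps(
        as_ir0(items$start[ii], items$end[ii]),
        as_ir0(pmax(0L, features$start[fi] - window), features$end[fi] + window))
      item_assoc[ii[unique(S4Vectors::queryHits(hits))]] <- TRUE
      feat_hit[fi[unique(S4Vectors::subjectHits(hits))]] <- TRUE
    }
  }
  list(item_associated = item_assoc, feature_hit = feat_hit,
       n_with = sum(item_assoc), n_without = sum(!item_assoc))
}

#' Base-pair Jaccard index of two interval sets
#'
#' Intersection over union in base pairs after self-merging each set.
#' Undefined (NA) when both sets are empty.
#'
#' @param setA,setB interval data.frames (contig, start, end).
#' @return numeric in [0, 1], or NA when undefined.
#' @export
jaccard_bp <- function(setA, setB) {
  a <- merge_intervals(setA)
  b <- merge_intervals(setB)
  if (!nrow(a) && !nrow(b)) return(NA_real_)
  inter <- 0L
  for (cn in intersect(unique(a$contig), unique(b$contig))) {
    ra <- as_ir0(a$start[a$contig == cn], a$end[a$contig == cn])
    rb <- as_ir0(b$start[b$contig == cn], b$end[b$contig == cn])
    inter <- inter + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  uni <- sum(a$end - a$start) + sum(b$end - b$start) - inter
  inter / uni
}

# fast event-sweep intersection/union in bp for one contig's intervals
sweep_inter_union <- function(sa, ea, sb, eb) {
  pos <- c(sa, ea, sb, eb)
  typ <- rep(c(1L, -1L, 2L, -2L), c(length(sa), length(ea), length(sb), length(eb)))
  o <- order(pos)
  pos <- pos[o]; typ <- typ[o]
  covA <- cumsum((typ == 1L) - (typ == -1L))
  covB <- cumsum((typ == 2L) - (typ == -2L))
  if (length(pos) < 2L) return(c(0, 0))
  seg <- diff(pos)
  a <- covA[-length(covA)] > 0L
  b <- covB[-length(covB)] > 0L
  c(inter = sum(seg[a & b]), union = sum(seg[a | b]))
}

# fast per-contig Jaccard over data.frames (same result as jaccard_bp)
fast_jaccard <- function(query, reference, ref_split = NULL) {
  inter <- 0; uni <- 0
  qs <- split(seq_len(nrow(query)), query$contig)
  if (is.null(ref_split)) ref_split <- split(seq_len(nrow(reference)), reference$contig)
  for (cn in union(names(qs), names(ref_split))) {
    qi <- qs[[cn]]; ri <- ref_split[[cn]]
    iu <- sweep_inter_union(query$start[qi] %||% integer(0), query$end[qi] %||% integer(0),
                            reference$start[ri] %||% integer(0),
                            reference$end[ri] %||% integer(0))
    inter <- inter + iu[[1]]; uni <- uni + iu[[2]]
  }
  if (uni == 0) NA_real_ else inter / uni
}

# fast mean nearest distance: sorted reference + findInterval
fast_mnd <- function(query, reference) {
  if (!nrow(query) || !nrow(reference)) return(NA_real_)
  total <- 0
  rs <- split(seq_len(nrow(reference)), reference$contig)
  qs <- split(seq_len(nrow(query)), query$contig)
  for (cn in names(qs)) {
    qi <- qs[[cn]]; ri <- rs[[cn]]
    if (is.null(ri)) { total <- total + Inf * length(qi); next }
    o <- order(reference$start[ri])
    s <- reference$start[ri][o]; e <- cummax(reference$end[ri][o])
    # nearest gap: reference starting after query end, or ending before query
    # start; references starting inside the query span mean distance 0
    n_end <- findInterval(query$end[qi], s)
    n_start <- findInterval(query$start[qi], s)
    idx_next <- n_end + 1L
    d_next <- ifelse(idx_next <= length(s), s[pmin(idx_next, length(s))] - query$end[qi], Inf)
    d_prev <- ifelse(n_start >= 1L, query$start[qi] - e[pmax(n_start, 1L)], Inf)
    gap <- pmax(0, pmin(d_next, d_prev))
    gap[n_end > n_start] <- 0
    total <- total + sum(gap)
  }
  total / nrow(query)
}

mean_nearest_distance <- function(query, reference) {
  if (!nrow(query) || !nrow(reference)) return(NA_real_)
  total <- 0
  for (i in seq_len(nrow(query))) {
    ri <- reference[reference$contig == query$contig[i], , drop = FALSE]
    if (!nrow(ri)) { total <- total + Inf; next }
    gap <- pmax(0L, pmax(ri$start - query$end[i], query$start[i] - ri$end))
    total <- total + min(gap)
  }
  total / nrow(query)
}

#' Spatial correlation of interval sets by permutation
#'
#' Measures the genometric association of a query interval set with
#' reference features (base-pair Jaccard, or mean nearest distance) and
#' builds a null by randomly relocating query intervals within their
#' contigs, preserving lengths and contig assignment. The permutation
#' p-value uses the add-one rule, so p >= 1/(n_perm + 1).
#'
#' @param query,reference interval data.frames.
#' @param genome an `annotated_genome` (contig lengths bound the
#'   relocation).
#' @param statistic "jaccard" (enrichment: null >= observed) or
#'   "mean_nearest_distance" (closeness: null <= observed).
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return a `spatial_corr` list: observed, p_value, n_perm, statistic,
#'   direction, null (the permuted statistics).
#' @export
permutation_spatial_test <- function(query, reference, genome,
                                     statistic = c("jaccard", "mean_nearest_distance"),
                                     n_perm = 999L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (n_perm < 99L) stop("n_perm must be >= 99")
  check_intervals(query, "query"); check_intervals(reference, "reference")
  cl <- genome$contig_len
  w <- query$end - query$start
  if (any(w > cl[query$contig])) stop("query intervals longer than their contig")
  ref_split <- split(seq_len(nrow(reference)), reference$contig)
  stat_fun <- if (statistic == "jaccard") {
    function(q) fast_jaccard(q, reference, ref_split)
  } else {
    function(q) fast_mnd(q, reference)
  }
  observed <- stat_fun(query)
  set.seed(stage_seed(seed, 0L))
  null <- vapply(seq_len(n_perm), function(i) {
    q <- query
    q$start <- as.integer(floor(runif(nrow(q)) * (cl[q$contig] - w + 1)))
    q$end <- q$start + w
    stat_fun(q)
  }, 0)
  extreme <- if (statistic == "jaccard") sum(null >= observed) else sum(null <= observed)
  structure(list(observed = observed,
                 p_value = (1 + extreme) / (n_perm + 1),
                 n_perm = as.integer(n_perm), statistic = statistic,
                 direction = if (statistic == "jaccard") "greater" else "less",
                 null = null),
            class = "spatial_corr")
}

#' @export
print.spatial_corr <- function(x, ...) {
  cat("spatial_corr:", x$statistic, "=", fmt_num(x$observed),
      "; permutation p =", fmt_num(x$p_value), "(", x$n_perm, "perms )\n")
  invisible(x)
}

#' Classify TE copy integrity
#'
#' Copies spanning less than one-half of the family consensus length are
#' "short"; at least 0.9 of the consensus is "full"; in between is
#' "medium". Ratios above 1.2 trigger a warning (suspect annotation) and
#' classify as full.
#'
#' @param copy_length span length(s) of the copies in bp.
#' @param consensus_length family consensus length(s) in bp (> 0).
#' @return character vector: "short", "medium", "full".
#' @export
classify_te_integrity <- function(copy_length, consensus_length) {
  if (any(consensus_length <= 0)) stop("consensus_length must be > 0")
  r <- copy_length / consensus_length
  if (any(r > 1.2)) warning("TE copies longer than 1.2x consensus: annotation suspect")
  ifelse(r < 0.5, "short", ifelse(r < 0.9, "medium", "full"))
}

#' Modification density stratified by TE copy integrity
#'
#' Mean and standard deviation of per-copy modification-site counts for
#' full, medium and short TE copies.
#'
#' @param calls sites (contig, pos).
#' @param te_copies TE copy intervals with `class` (or `length` and
#'   `consensus_length` from which classes are derived).
#' @return data.frame: class, n_copies, mean_count, sd_count, defined.
#' @export
density_by_integrity <- function(calls, te_copies) {
  if (!"class" %in% names(te_copies)) {
    te_copies$class <- classify_te_integrity(te_copies$end - te_copies$start,
                                             te_copies$consensus_length)
  }
  counts <- integer(nrow(te_copies))
  if (nrow(calls) && nrow(te_copies)) {
    for (cn in unique(te_copies$contig)) {
      ti <- which(te_copies$contig == cn)
      cp <- calls$pos[calls$contig == cn]
      if (!length(cp)) next
      counts[ti] <- vapply(ti, function(j) {
        sum(cp >= te_copies$start[j] & cp < te_copies$end[j])
      }, 0L)
    }
  }
  out <- lapply(c("full", "medium", "short"), function(cls) {
    i <- te_copies$class == cls
    if (!any(i)) {
      new_df(class = cls, n_copies = 0L, mean_count = NA_real_,
             sd_count = NA_real_, defined = FALSE)
    } else {
      new_df(class = cls, n_copies = sum(i), mean_count = mean(counts[i]),
             sd_count = if (sum(i) > 1) sd(counts[i]) else 0, defined = TRUE)
    }
  })
  do.call(rbind, out)
}

#' Co-localization of DIP peaks with chromatin peak classes
#'
#' Percentage of DIP-seq peaks intersecting at least one peak of each
#' chromatin class; combined classes use the union of their peak sets.
#'
#' @param dip_peaks DIP peak intervals.
#' @param chip_peak_sets named list of chromatin peak interval sets.
#' @param combine named list of character vectors defining combined
#'   classes, e.g. list(heterochromatin = c("H3K9me3", "H3K27me3")).
#' @return data.frame: class, n_overlap, pct (NA/flagged when the DIP
#'   set is empty).
#' @export
colocalization_fractions <- function(dip_peaks, chip_peak_sets,
                                     combine = list()) {
  sets <- chip_peak_sets
  for (nm in names(combine)) {
    sets[[nm]] <- do.call(rbind, lapply(chip_peak_sets[combine[[nm]]],
                                        function(d) d[c("contig", "start", "end")]))
  }
  n <- nrow(dip_peaks)
  out <- lapply(names(sets), function(nm) {
    if (n == 0L) {
      return(new_df(class = nm, n_overlap = 0L, pct = NA_real_, defined = FALSE))
    }
    hit <- window_intersect(dip_peaks, sets[[nm]], window = 0L)$item_associated
    new_df(class = nm, n_overlap = sum(hit), pct = 100 * sum(hit) / n,
           defined = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean signal profile around peak summits
#'
#' Slices a (log2-ratio) coverage track in a +/- flank window around each
#' summit and averages across summits. Summits whose window leaves the
#' track are skipped and counted.
#'
#' @param summits data.frame with contig and summit (or pos) columns.
#' @param track a `coverage_track` (typically log2ratio-normalized).
#' @param flank half-window in bp (default 3000).
#' @return a `profile_matrix` (rows = summits kept).
#' @export
summit_signal_profile <- function(summits, track, flank = 3000L) {
  bs <- track$bin_size
  nb <- as.integer(2L * floor(flank / bs))
  pos <- if ("summit" %in% names(summits)) summits$summit else summits$pos
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(summits))) {
    v <- track$values[[summits$contig[i]]]
    cbin <- pos[i] %/% bs + 1L
    lo <- cbin - nb %/% 2L
    hi <- lo + nb - 1L
    if (lo < 1L || hi > length(v)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- v[lo:hi]
  }
  if (!length(rows)) stop("no summits with a complete window on the track")
  mat <- do.call(rbind, rows)
  centres <- seq(-(nb / 2) * bs + bs / 2, (nb / 2) * bs - bs / 2, by = bs)
  out <- new_profile(mat, centres, bs, flank, "summit")
  out$skipped <- skipped
  out
}

#' Strand symmetry of modification calls
#'
#' Fraction of modified positions carrying calls on both strands.
#' Complementary calls pair at offset +1 within the doublet (a plus-strand
#' call at p pairs with a minus-strand call at p+1 of the same mark:
#' CpG-style pairing for 4mC, ApT-style for 6mA); identical-coordinate
#' opposite-strand calls of the same mark also pair. When a genome is
#' supplied, offset pairs must sit in a valid complementary doublet.
#'
#' @param calls a call (or methylome) data.frame: contig, pos, strand,
#'   mark.
#' @param genome optional `annotated_genome` for doublet validation.
#' @return list: symmetric_fraction, n_pairs, n_positions.
#' @export
strand_symmetry <- function(calls, genome = NULL) {
  if (!nrow(calls)) {
    return(list(symmetric_fraction = 0, n_pairs = 0L, n_positions = 0L))
  }
  key <- paste(calls$contig, calls$pos, calls$strand, calls$mark)
  plus <- calls[calls$strand == "+", , drop = FALSE]
  partner_off <- paste(plus$contig, plus$pos + 1L, "-", plus$mark)
  ok <- partner_off %in% key
  if (!is.null(genome) && any(ok)) {
    b1 <- base_at(genome, plus$contig[ok], plus$pos[ok], "+")
    b2 <- base_at(genome, plus$contig[ok], plus$pos[ok] + 1L, "+")
    valid <- ifelse(plus$mark[ok] == "4mC", b1 == "C" & b2 == "G",
                    b1 == "A" & b2 == "T")
    ok[ok] <- valid
  }
  partner_same <- paste(plus$contig, plus$pos, "-", plus$mark)
  same <- partner_same %in% key
  n_pairs <- sum(ok | same)
  n_pos <- nrow(calls) - n_pairs
  list(symmetric_fraction = if (n_pos > 0) n_pairs / n_pos else 0,
       n_pairs = as.integer(n_pairs), n_positions = as.integer(n_pos))
}

#' Observed/expected CpG ratio in sequence windows
#'
#' The standard depletion diagnostic (N_CpG x L) / (N_C x N_G) per
#' non-overlapping window; historical 5mC deamination depresses the
#' ratio, while genomes without 5mC stay near 1. Undefined (NA) where a
#' window has no C or no G.
#'
#' @param sequence a DNA sequence (character scalar).
#' @param window window length in bp (> 0); default covers the whole
#'   sequence.
#' @return data.frame: start, end, n_cpg, n_c, n_g, obs_exp.
#' @export
cpg_obs_exp <- function(sequence, window = nchar(sequence)) {
  if (window <= 0) stop("window length must be > 0")
  L <- nchar(sequence)
  starts <- seq.int(1L, L, by = window)
  dna <- Biostrings::DNAStringSet(substring(sequence, starts,
                                            pmin(L, starts + window - 1L)))
  n_cpg <- Biostrings::vcountPattern("CG", dna)
  lf <- Biostrings::letterFrequency(dna, c("C", "G"))
  wlen <- Biostrings::width(dna)
  obs_exp <- ifelse(lf[, "C"] * lf[, "G"] > 0,
                    n_cpg * wlen / (lf[, "C"] * lf[, "G"]), NA_real_)
  new_df(start = starts - 1L, end = starts - 1L + wlen,
         n_cpg = n_cpg, n_c = lf[, "C"], n_g = lf[, "G"], obs_exp = obs_exp)
}

#' RPKM: reads per kilobase per million mapped reads
#'
#' @param counts read counts per gene.
#' @param exon_length_bp summed exonic length per gene (> 0).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return numeric RPKM values.
#' @export
rpkm <- function(counts, exon_length_bp, total_mapped) {
  if (any(exon_length_bp <= 0)) stop("exon_length_bp must be > 0")
  if (length(total_mapped) != 1L || total_mapped <= 0) {
    stop("total_mapped must be a single value > 0")
  }
  counts / (exon_length_bp / 1000) / (total_mapped / 1e6)
}

#' Expression grouping tests
#'
#' Two-group mark-presence comparisons use a two-tailed Welch t-test on
#' log2(RPKM + pseudocount); multi-level (histone-class) groupings use a
#' one-way ANOVA with Tukey's post-hoc. Groups with fewer than 2 members
#' are skipped with a flag.
#'
#' @param expr expression data.frame with an `rpkm` column.
#' @param group vector (logical or factor) of group labels, one per gene.
#' @param pseudocount added to RPKM before log2 (default 0.1).
#' @return list: `summaries` (per-group n / mean / sd of log2 RPKM),
#'   `test` ("ttest"/"anova"), `p_value`, `estimate` (group-mean
#'   difference for two groups), `tukey` (for ANOVA), `skipped_groups`.
#' @export
expression_group_tests <- function(expr, group, pseudocount = 0.1) {
  y <- log2(expr$rpkm + pseudocount)
  g <- if (is.logical(group)) factor(group, levels = c(FALSE, TRUE)) else factor(group)
  tab <- table(g)
  skipped <- names(tab)[tab < 2L]
  keep <- !(g %in% skipped)
  y <- y[keep]; g <- droplevels(g[keep])
  summaries <- do.call(rbind, lapply(levels(g), function(l) {
    new_df(group = l, n = sum(g == l), mean_log2_rpkm = mean(y[g == l]),
           sd_log2_rpkm = sd(y[g == l]))
  }))
  if (nlevels(g) < 2L) {
    return(list(summaries = summaries, test = "none", p_value = NA_real_,
                estimate = NA_real_, tukey = NULL, skipped_groups = skipped))
  }
  if (nlevels(g) == 2L) {
    tt <- t.test(y ~ g, alternative = "two.sided", var.equal = FALSE)
    # estimate: mean of the second group minus mean of the first
    # (for a logical grouping: with-mark minus without-mark)
    list(summaries = summaries, test = "ttest", p_value = tt$p.value,
         estimate = unname(diff(tt$estimate)),
         tukey = NULL, skipped_groups = skipped)
  } else {
    fit <- aov(y ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    list(summaries = summaries, test = "anova", p_value = p,
         estimate = NA_real_, tukey = tk, skipped_groups = skipped)
  }
}

#' Assign histone chromatin classes to genes
#'
#' Genes are classed by the chromatin peaks within the association
#' window: both H3K9me3 and H3K27me3 gives "H3K9-27me3"; otherwise a
#' single repressive mark wins over H3K4me3; genes near none are "none".
#'
#' @param genes gene intervals.
#' @param chip_peaks named list with H3K4me3 / H3K9me3 / H3K27me3 peak
#'   sets.
#' @param window association window in bp (default 500).
#' @return factor of classes, one per gene.
#' @export
assign_histone_class <- function(genes, chip_peaks, window = 500L) {
  near <- function(nm) {
    if (is.null(chip_peaks[[nm]]) || !nrow(chip_peaks[[nm]])) {
      return(logical(nrow(genes)))
    }
    window_intersect(chip_peaks[[nm]], genes, window = window)$feature_hit
  }
  k4 <- near("H3K4me3"); k9 <- near("H3K9me3"); k27 <- near("H3K27me3")
  cls <- rep("none", nrow(genes))
  cls[k4] <- "H3K4me3"
  cls[k27] <- "H3K27me3"
  cls[k9] <- "H3K9me3"
  cls[k9 & k27] <- "H3K9-27me3"
  factor(cls, levels = c("H3K4me3", "H3K9me3", "H3K27me3", "H3K9-27me3", "none"))
}
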
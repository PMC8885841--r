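# Shared internal helpers. All genomic coordinates inside the package are
# 0-based half-open; converters to 1-based formats (GFF3, IRanges) live here.

`%||%` <- function(a, b) if (is.null(a)) b else a

new_df <- function(...) data.frame(..., stringsAsFactors = FALSE)

#' @noRd
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# intervals: data.frame(contig, start, end) with 0-based half-open spans
as_ir0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

check_intervals <- function(df, what = "intervals") {
  stopifnot(is.data.frame(df))
  need <- c("contig", "start", "end")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s must have columns contig, start, end", what))
  }
  if (nrow(df) && any(df$start >= df$end)) {
    stop(sprintf("%s contain spans with start >= end", what))
  }
  invisible(df)
}

# merge (self-union) per contig; returns data.frame(contig, start, end)
merge_intervals <- function(df) {
  check_intervals(df)
  if (!nrow(df)) return(new_df(contig = character(), start = integer(), end = integer()))
  out <- lapply(split(df, df$contig), function(d) {
    r <- IRanges::reduce(as_ir0(d$start, d$end))
    new_df(contig = d$contig[1], start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Total base pairs covered by an interval set
#'
#' Width of the self-merged union; divide by genome length to get the
#' genome fraction a feature class covers (the denominator of
#' [normalized_density()]).
#'
#' @param df interval data.frame (contig, start, end; 0-based half-open).
#' @return total covered bp.
#' @export
interval_bp <- function(df) {
  m <- merge_intervals(df)
  if (!nrow(m)) 0L else sum(m$end - m$start)
}

# points (or interval midpoints) as data.frame(contig, pos)
item_points <- function(items) {
  if ("pos" %in% names(items)) {
    new_df(contig = items$contig, pos = as.integer(items$pos))
  } else {
    check_intervals(items, "items")
    new_df(contig = items$contig,
           pos = as.integer(floor((items$start + items$end - 1L) / 2)))
  }
}

# random non-negative integer composition of `total` into `k` parts
random_composition <- function(total, k) {
  if (k == 1L) return(total)
  if (total == 0L) return(rep(0L, k))
  as.integer(rmultinom(1L, total, rep(1, k)))
}

fmt_num <- function(x, digits = 6) formatC(x, format = "g", digits = digits)
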
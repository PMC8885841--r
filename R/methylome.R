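#' Plant a ground-truth methylome on an annotated genome
#'
#' 4mC records are drawn from cytosines (either strand) inside the targeted
#' feature classes (full/medium TE copies and tandem repeats by default),
#' with dinucleotide context weights favouring CpG and CpA and an
#' exponential positional bias toward TE 5' ends. 6mA records are drawn
#' genome-wide from GA-context adenines, with a bonus for AGG/GAA
#' triplets. Methylation is asymmetric: only a configurable small fraction
#' of sites receives a complementary-strand partner record (offset +1,
#' CpG for 4mC and ApT-compatible contexts for 6mA). Per-site true
#' fractions follow the configured distributions (4mC: point mass at 1.0
#' mixed with a Beta; 6mA: Beta with mean 0.74).
#'
#' @param genome an `annotated_genome`.
#' @param config the [sim_config()] used to generate it.
#' @return a `methylome` data.frame: contig, pos (0-based), strand,
#'   mark ("4mC"/"6mA"), fraction in (0,1].
#' @export
plant_methylome <- function(genome, config) {
  stopifnot(inherits(genome, "annotated_genome"))
  validate_sim_config(config)
  chars <- lapply(genome$contigs, seq_chars)

  # independent streams so each mark's draw is unaffected by the other's
  # parameters
  set.seed(stage_seed(config$seed, 1L))
  rec4 <- plant_4mC(genome, config, chars)
  set.seed(stage_seed(config$seed, 21L))
  rec6 <- plant_6mA(genome, config, chars)
  out <- rbind(rec4, rec6)
  if (nrow(out)) {
    out <- out[order(out$contig, out$pos, out$strand), ]
    out <- out[!duplicated(out[c("contig", "pos", "strand")]), ]
    rownames(out) <- NULL
  }
  class(out) <- c("methylome", "data.frame")
  out
}

empty_methylome <- function() {
  new_df(contig = character(), pos = integer(), strand = character(),
         mark = character(), fraction = numeric())
}

# candidate cytosines in a span: position, strand, next base on that strand
span_c_sites <- function(ch, start, end) {
  idx <- (start + 1L):end              # 1-based indices into ch
  b <- ch[idx]
  plus <- idx[b == "C"]
  minus <- idx[b == "G"]
  nxt_p <- ifelse(plus < length(ch), ch[plus + 1L], "N")
  nxt_m <- ifelse(minus > 1L, comp_base(ch[minus - 1L]), "N")
  new_df(pos = c(plus, minus) - 1L,
         strand = rep(c("+", "-"), c(length(plus), length(minus))),
         nxt = c(nxt_p, nxt_m))
}

draw_frac_4mC <- function(n, m4) {
  f <- ifelse(runif(n) < m4$frac_full, 1,
              0.1 + 0.9 * rbeta(n, m4$frac_beta[1], m4$frac_beta[2]))
  pmin(1, pmax(1e-6, f))
}

plant_4mC <- function(genome, config, chars) {
  m4 <- config$meth_4mC
  if (m4$prob == 0) return(empty_methylome())
  regions <- NULL
  te <- genome$te_copies
  if (any(c("te_full", "te_medium") %in% m4$target) && nrow(te)) {
    keep <- te$class %in% sub("^te_", "", grep("^te_", m4$target, value = TRUE))
    tek <- te[keep, , drop = FALSE]
    if (nrow(tek)) {
      tek <- tek[runif(nrow(tek)) < m4$copy_prob, , drop = FALSE]
      if (nrow(tek)) {
        regions <- new_df(contig = tek$contig, start = tek$start, end = tek$end,
                          strand = tek$strand, kind = "te", prob = m4$prob)
      }
    }
  }
  if ("tr" %in% m4$target && nrow(genome$tandem_repeats)) {
    tr <- genome$tandem_repeats
    regions <- rbind(regions,
                     new_df(contig = tr$contig, start = tr$start, end = tr$end,
                            strand = "+", kind = "tr", prob = m4$tr_prob))
  }
  if (is.null(regions) || !nrow(regions)) {
    if (length(m4$target)) {
      # only error when targets were requested but genome has none eligible
      has_target <- (any(grepl("^te_", m4$target)) && nrow(te)) ||
        ("tr" %in% m4$target && nrow(genome$tandem_repeats))
      if (!has_target) {
        stop("no eligible 4mC context positions: genome has no annotations of class ",
             paste(m4$target, collapse = "/"))
      }
    }
    return(empty_methylome())
  }
  wmax <- max(m4$context_weights)
  recs <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    cs <- span_c_sites(chars[[r$contig]], r$start, r$end)
    if (!nrow(cs)) next
    w <- m4$context_weights[paste0("C", cs$nxt)]
    w[is.na(w)] <- 0
    wpos <- 1
    if (r$kind == "te") {
      d5 <- if (r$strand == "+") cs$pos - r$start else (r$end - 1L) - cs$pos
      wpos <- m4$te5p_floor + (1 - m4$te5p_floor) * exp(-d5 / m4$te5p_decay)
    }
    keep <- runif(nrow(cs)) < r$prob * (w / wmax) * wpos
    if (!any(keep)) next
    k <- cs[keep, , drop = FALSE]
    recs[[i]] <- new_df(contig = r$contig, pos = k$pos, strand = k$strand,
                        mark = "4mC", fraction = draw_frac_4mC(sum(keep), m4),
                        nxt = k$nxt)
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs) || !nrow(recs)) return(empty_methylome())
  # keep methylation asymmetric: when both cytosines of one CpG were drawn
  # independently, drop the minus-strand record (explicit symmetric
  # partners are added below at the configured rate)
  minus_cg <- recs$strand == "-" & recs$nxt == "G"
  partner_key <- paste(recs$contig, recs$pos - 1L, "+")
  own_key <- paste(recs$contig, recs$pos, recs$strand)
  accidental <- minus_cg & (partner_key %in% own_key[recs$strand == "+" & recs$nxt == "G"])
  recs <- recs[!accidental, , drop = FALSE]
  # symmetric partners at CpG doublets: (+, p) pairs with (-, p+1)
  cg <- recs$nxt == "G"
  sym <- cg & runif(nrow(recs)) < config$symmetric_fraction
  partners <- NULL
  if (any(sym)) {
    s <- recs[sym, , drop = FALSE]
    partners <- new_df(
      contig = s$contig,
      pos = ifelse(s$strand == "+", s$pos + 1L, s$pos - 1L),
      strand = ifelse(s$strand == "+", "-", "+"),
      mark = "4mC", fraction = s$fraction
    )
  }
  rbind(recs[, names(empty_methylome())], partners)
}

plant_6mA <- function(genome, config, chars) {
  m6 <- config$meth_6mA
  if (m6$prob == 0) return(empty_methylome())
  recs <- lapply(names(chars), function(cn) {
    ch <- chars[[cn]]
    L <- length(ch)
    if (L < 3L) return(NULL)
    j <- 2:(L - 1L)
    plus <- j[ch[j] == "A" & ch[j - 1L] == "G"]          # GA on + strand
    minus <- j[ch[j] == "T" & ch[j + 1L] == "C"]         # GA on - strand
    pos <- c(plus, minus) - 1L
    strand <- rep(c("+", "-"), c(length(plus), length(minus)))
    if (!length(pos)) return(NULL)
    # triplet contexts on the modified strand: (c-1..c+1) and (c..c+2)
    at <- function(i) ifelse(i >= 1L & i <= L, ch[pmax(pmin(i, L), 1L)], "N")
    t1p <- paste0(at(plus - 1L), ch[plus], at(plus + 1L))
    t2p <- paste0(ch[plus], at(plus + 1L), at(plus + 2L))
    t1m <- paste0(comp_base(at(minus + 1L)), comp_base(ch[minus]), comp_base(at(minus - 1L)))
    t2m <- paste0(comp_base(ch[minus]), comp_base(at(minus - 1L)), comp_base(at(minus - 2L)))
    w <- rep(1, length(pos))
    bonus <- c(t1p, t1m) == "GAA" | c(t2p, t2m) == "AGG"
    w[bonus] <- m6$triplet_bonus
    keep <- runif(length(pos)) < m6$prob * w / max(m6$triplet_bonus, 1)
    if (!any(keep)) return(NULL)
    n <- sum(keep)
    f <- ifelse(runif(n) < (m6$frac_full %||% 0), 1,
                pmin(1, pmax(1e-6, rbeta(n, m6$frac_beta[1], m6$frac_beta[2]))))
    new_df(contig = cn, pos = pos[keep], strand = strand[keep], mark = "6mA",
           fraction = f)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || !nrow(recs)) return(empty_methylome())
  # symmetric partners where the opposite strand carries a GA-context A at +1
  valid <- logical(nrow(recs))
  for (cn in unique(recs$contig)) {
    ch <- chars[[cn]]
    L <- length(ch)
    at <- function(i) ifelse(i >= 1L & i <= L, ch[pmax(pmin(i, L), 1L)], "N")
    rows <- which(recs$contig == cn)
    i1 <- recs$pos[rows] + 1L + ifelse(recs$strand[rows] == "+", 1L, -1L)
    valid[rows] <- ifelse(recs$strand[rows] == "+",
                          at(i1) == "T" & at(i1 + 1L) == "C",
                          at(i1) == "A" & at(i1 - 1L) == "G")
  }
  sym <- valid & runif(nrow(recs)) < config$symmetric_fraction
  partners <- NULL
  if (any(sym)) {
    s <- recs[sym, , drop = FALSE]
    partners <- new_df(contig = s$contig,
                       pos = ifelse(s$strand == "+", s$pos + 1L, s$pos - 1L),
                       strand = ifelse(s$strand == "+", "-", "+"),
                       mark = "6mA", fraction = s$fraction)
  }
  rbind(recs, partners)
}

#' Verify that methylome records sit on the correct base
#'
#' Every 4mC record must fall on a cytosine of its strand and every 6mA
#' record on an adenine. Used as a generator invariant and as an input
#' sanity check for externally supplied methylomes.
#'
#' @param methylome a methylome data.frame.
#' @param genome an `annotated_genome`.
#' @return number of violating records (0 for a valid methylome).
#' @export
methylome_base_violations <- function(methylome, genome) {
  if (!nrow(methylome)) return(0L)
  b <- base_at(genome, methylome$contig, methylome$pos, methylome$strand)
  expected <- ifelse(methylome$mark == "4mC", "C", "A")
  sum(b != expected)
}

# base on a given strand at 0-based positions
base_at <- function(genome, contig, pos, strand) {
  strand <- rep(strand, length.out = length(pos))
  out <- character(length(pos))
  for (cn in unique(contig)) {
    i <- contig == cn
    if (any(pos[i] < 0L | pos[i] >= genome$contig_len[[cn]])) {
      stop("coordinate error: position outside contig ", cn)
    }
    b <- substring(genome$contigs[[cn]], pos[i] + 1L, pos[i] + 1L)
    out[i] <- ifelse(strand[i] == "+", b, comp_base(b))
  }
  out
}
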
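#' Simulate an annotated genome
#'
#' Generates a small multi-contig genome with non-overlapping gene models
#' (5' UTR, CDS exons, introns, 3' UTR, plus derived promoters), TE copies
#' of configurable families partitioned into full / medium / short
#' integrity classes, and tandem-repeat arrays. TE copies carry the 5'
#' portion of a per-family consensus sequence so copies of one family are
#' homologous; a configurable fraction of full/medium copies contains an
#' internal TE-derived gene (flagged `te_gene`). All coordinates are
#' 0-based half-open; `write_genome()` serializes to FASTA + GFF3.
#'
#' @param config a [sim_config()].
#' @return an object of class `annotated_genome`: a list with `contigs`
#'   (named character vector of sequences), `contig_len`, `genes`,
#'   `subfeatures`, `promoters`, `te_copies`, `tandem_repeats`
#'   data.frames, and the `config` used.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 0L))
  g <- config$genome
  nc <- g$n_contigs
  clen <- rep(g$length %/% nc, nc)
  clen[1] <- clen[1] + g$length %% nc
  cname <- sprintf("contig_%02d", seq_len(nc))

  if (config_feature_bp(config) > 0.9 * g$length) {
    stop("sizing error: configured features (",
         round(config_feature_bp(config)), " bp) cannot fit a ",
         g$length, " bp genome")
  }

  te <- draw_te_copies(config)
  tr <- draw_tandem_repeats(config)
  gn <- draw_gene_models(config)

  feats <- rbind(
    if (nrow(te)) new_df(kind = "te", idx = seq_len(nrow(te)), len = te$length),
    if (nrow(tr)) new_df(kind = "tr", idx = seq_len(nrow(tr)), len = tr$length),
    if (length(gn)) new_df(kind = "gene", idx = seq_along(gn),
                           len = vapply(gn, `[[`, 0, "length"))
  )
  placed <- place_features(feats, clen, cname)

  # background sequence, then overwrite feature spans
  p <- c(A = (1 - g$gc) / 2, C = g$gc / 2, G = g$gc / 2, T = (1 - g$gc) / 2)
  contigs <- vapply(clen, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, "")
  names(contigs) <- cname

  fam_cons <- character(0)
  if (nrow(config$te_families)) {
    fam_cons <- vapply(config$te_families$consensus_length, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, "")
    names(fam_cons) <- config$te_families$name
  }

  te_out <- tr_out <- NULL
  genes <- sub <- NULL

  if (!is.null(placed)) {
    pl_te <- placed[placed$kind == "te", , drop = FALSE]
    if (nrow(pl_te)) {
      te_out <- te[pl_te$idx, , drop = FALSE]
      te_out$contig <- pl_te$contig
      te_out$start <- pl_te$start
      te_out$end <- pl_te$start + te_out$length
      te_out$strand <- sample(c("+", "-"), nrow(te_out), replace = TRUE)
      te_out$te_id <- sprintf("TE%04d", seq_len(nrow(te_out)))
      for (i in seq_len(nrow(te_out))) {
        s <- substr(fam_cons[[te_out$family[i]]], 1L, te_out$length[i])
        if (te_out$strand[i] == "-") s <- revcomp(s)
        substr(contigs[[te_out$contig[i]]], te_out$start[i] + 1L, te_out$end[i]) <- s
      }
    }
    pl_tr <- placed[placed$kind == "tr", , drop = FALSE]
    if (nrow(pl_tr)) {
      tr_out <- tr[pl_tr$idx, , drop = FALSE]
      tr_out$contig <- pl_tr$contig
      tr_out$start <- pl_tr$start
      tr_out$end <- pl_tr$start + tr_out$length
      tr_out$tr_id <- sprintf("TR%03d", seq_len(nrow(tr_out)))
      for (i in seq_len(nrow(tr_out))) {
        unit <- paste(sample(names(p), tr_out$unit_len[i], replace = TRUE, prob = p),
                      collapse = "")
        arr <- strrep(unit, ceiling(tr_out$length[i] / tr_out$unit_len[i]))
        substr(contigs[[tr_out$contig[i]]], tr_out$start[i] + 1L, tr_out$end[i]) <-
          substr(arr, 1L, tr_out$length[i])
      }
    }
    pl_gn <- placed[placed$kind == "gene", , drop = FALSE]
    if (nrow(pl_gn)) {
      built <- build_gene_features(gn, pl_gn, config)
      genes <- built$genes
      sub <- built$subfeatures
    }
  }

  # TE-derived genes carved inside full/medium copies
  if (!is.null(te_out)) {
    host <- te_out[te_out$class %in% c("full", "medium"), , drop = FALSE]
    if (nrow(host)) {
      pick <- runif(nrow(host)) < config$te_gene_prob
      host <- host[pick, , drop = FALSE]
      if (nrow(host)) {
        gs <- host$start + as.integer(round(0.2 * host$length))
        ge <- gs + as.integer(round(0.6 * host$length))
        teg <- new_df(
          gene_id = sprintf("TEG%04d", seq_len(nrow(host))),
          contig = host$contig, start = gs, end = ge, strand = host$strand,
          te_gene = TRUE,
          expressed = runif(nrow(host)) < config$genes$expressed_prob,
          exon_bp = ge - gs
        )
        teg_sub <- new_df(
          gene_id = teg$gene_id, type = "CDS", contig = teg$contig,
          start = teg$start, end = teg$end, strand = teg$strand
        )
        genes <- rbind(genes, teg)
        sub <- rbind(sub, teg_sub)
      }
    }
  }

  if (is.null(genes)) {
    genes <- new_df(gene_id = character(), contig = character(), start = integer(),
                    end = integer(), strand = character(), te_gene = logical(),
                    expressed = logical(), exon_bp = integer())
    sub <- new_df(gene_id = character(), type = character(), contig = character(),
                  start = integer(), end = integer(), strand = character())
  }
  if (is.null(te_out)) {
    te_out <- new_df(te_id = character(), family = character(), contig = character(),
                     start = integer(), end = integer(), strand = character(),
                     consensus_length = integer(), length = integer(),
                     integrity = numeric(), class = character())
  } else {
    te_out <- te_out[, c("te_id", "family", "contig", "start", "end", "strand",
                         "consensus_length", "length", "integrity", "class")]
  }
  if (is.null(tr_out)) {
    tr_out <- new_df(tr_id = character(), contig = character(), start = integer(),
                     end = integer(), unit_len = integer(), length = integer())
  } else {
    tr_out <- tr_out[, c("tr_id", "contig", "start", "end", "unit_len", "length")]
  }

  promoters <- derive_promoters(genes, clen, cname, config$genes$promoter_span)

  structure(list(
    contigs = contigs,
    contig_len = setNames(as.integer(clen), cname),
    genes = genes, subfeatures = sub, promoters = promoters,
    te_copies = te_out, tandem_repeats = tr_out,
    config = config
  ), class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", sum(x$contig_len), "bp in", length(x$contigs),
      "contigs;", nrow(x$genes), "genes (", sum(x$genes$te_gene), "TE-derived );",
      nrow(x$te_copies), "TE copies;", nrow(x$tandem_repeats), "tandem repeats\n")
  invisible(x)
}

draw_te_copies <- function(config) {
  te <- config$te_families
  if (!nrow(te)) {
    return(new_df(family = character(), consensus_length = integer(),
                  integrity = numeric(), length = integer(), class = character()))
  }
  out <- lapply(seq_len(nrow(te)), function(i) {
    f <- te[i, ]
    integ <- c(runif(f$n_full, 0.92, 1.0),
               runif(f$n_medium, 0.5, 0.9),
               runif(f$n_short, 0.08, 0.5))
    cls <- rep(c("full", "medium", "short"), c(f$n_full, f$n_medium, f$n_short))
    new_df(family = f$name, consensus_length = f$consensus_length,
           integrity = integ,
           length = pmax(50L, as.integer(round(integ * f$consensus_length))),
           class = cls)
  })
  do.call(rbind, out)
}

draw_tandem_repeats <- function(config) {
  tr <- config$tandem_repeats
  if (!tr$n) {
    return(new_df(unit_len = integer(), n_units = integer(), length = integer()))
  }
  n_units <- sample(tr$units_min:tr$units_max, tr$n, replace = TRUE)
  new_df(unit_len = as.integer(tr$unit_len), n_units = n_units,
         length = as.integer(tr$unit_len * n_units))
}

draw_gene_models <- function(config) {
  gn <- config$genes
  if (!gn$n) return(list())
  lapply(seq_len(gn$n), function(i) {
    ne <- 1L + rpois(1L, max(0, gn$mean_exons - 1))
    ex <- pmax(30L, as.integer(round(rlnorm(ne, log(gn$exon_meanlen), 0.45))))
    it <- if (ne > 1L) {
      pmax(40L, as.integer(round(rlnorm(ne - 1L, log(gn$intron_meanlen), 0.45))))
    } else integer(0)
    u5 <- as.integer(round(runif(1, gn$utr5[1], gn$utr5[2])))
    u3 <- as.integer(round(runif(1, gn$utr3[1], gn$utr3[2])))
    list(exons = ex, introns = it, utr5 = u5, utr3 = u3,
         length = u5 + u3 + sum(ex) + sum(it))
  })
}

# assign features to contigs (greedy by free space) and draw random gaps
place_features <- function(feats, clen, cname) {
  if (is.null(feats) || !nrow(feats)) return(NULL)
  feats <- feats[sample.int(nrow(feats)), , drop = FALSE]
  free <- clen
  assign <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    j <- which.max(free)
    if (free[j] < feats$len[i] + 2L) {
      stop("sizing error: feature of ", feats$len[i],
           " bp does not fit in remaining contig space")
    }
    assign[i] <- j
    free[j] <- free[j] - feats$len[i] - 2L
  }
  out <- vector("list", length(clen))
  for (j in seq_along(clen)) {
    rows <- which(assign == j)
    if (!length(rows)) next
    d <- feats[rows, , drop = FALSE]
    slack <- clen[j] - sum(d$len)
    gaps <- random_composition(as.integer(slack), nrow(d) + 1L)
    starts <- cumsum(c(0L, d$len)) + cumsum(gaps)[seq_len(nrow(d) + 1L)]
    d$contig <- cname[j]
    d$start <- as.integer(starts[seq_len(nrow(d))])
    out[[j]] <- d
  }
  do.call(rbind, out)
}

build_gene_features <- function(gn, placed, config) {
  genes <- vector("list", nrow(placed))
  subs <- vector("list", nrow(placed))
  for (k in seq_len(nrow(placed))) {
    m <- gn[[placed$idx[k]]]
    s <- placed$start[k]
    strand <- sample(c("+", "-"), 1L)
    # forward layout: 5'UTR, exon1, intron1, ..., exonN, 3'UTR
    widths <- c(m$utr5, as.vector(rbind(m$exons, c(m$introns, NA)))[
      seq_len(2L * length(m$exons) - 1L)], m$utr3)
    types <- c("five_prime_UTR",
               rep(c("CDS", "intron"), length.out = 2L * length(m$exons) - 1L),
               "three_prime_UTR")
    if (strand == "-") { widths <- rev(widths); types <- rev(types) }
    ends <- s + cumsum(widths)
    starts <- c(s, head(ends, -1L))
    gid <- sprintf("G%04d", placed$idx[k])
    genes[[k]] <- new_df(
      gene_id = gid, contig = placed$contig[k],
      start = s, end = s + m$length, strand = strand, te_gene = FALSE,
      expressed = runif(1) < config$genes$expressed_prob,
      exon_bp = as.integer(m$utr5 + m$utr3 + sum(m$exons))
    )
    subs[[k]] <- new_df(gene_id = gid, type = types, contig = placed$contig[k],
                        start = as.integer(starts), end = as.integer(ends),
                        strand = strand)
  }
  list(genes = do.call(rbind, genes), subfeatures = do.call(rbind, subs))
}

derive_promoters <- function(genes, clen, cname, span) {
  if (!nrow(genes)) {
    return(new_df(gene_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  L <- setNames(clen, cname)[genes$contig]
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - span), genes$end)
  end <- ifelse(plus, genes$start, pmin(L, genes$end + span))
  keep <- start < end
  new_df(gene_id = genes$gene_id[keep], contig = genes$contig[keep],
         start = as.integer(start[keep]), end = as.integer(end[keep]),
         strand = genes$strand[keep])
}

# anchoring coordinate of a stranded feature (5' end by default)
anchor_points <- function(features, anchor = c("5prime", "TSS", "TTS", "summit")) {
  anchor <- match.arg(anchor)
  if (anchor == "summit") {
    stopifnot("summit" %in% names(features))
    return(new_df(contig = features$contig, pos = as.integer(features$summit),
                  strand = if ("strand" %in% names(features)) features$strand else "+"))
  }
  strand <- if ("strand" %in% names(features)) features$strand else rep("+", nrow(features))
  five <- anchor %in% c("5prime", "TSS")
  pos <- ifelse((strand == "+") == five, features$start, features$end - 1L)
  new_df(contig = features$contig, pos = as.integer(pos), strand = strand)
}
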
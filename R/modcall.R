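#' Call filter for kinetic modification calling
#'
#' Thresholds reproducing the published filtering rules: sites below 10x
#' coverage are removed outright; primary calls require 20x coverage and a
#' Phred-scaled modification quality (mQv) of at least 22. An additional
#' minimum IPD-ratio floor rejects retained sites whose kinetic effect
#' size is too small to be a credible modification.
#'
#' @param min_coverage_retain sites below this coverage are dropped (10).
#' @param primary_min_coverage coverage needed for a primary call (20).
#' @param min_score minimum mQv for a primary call (22).
#' @param min_ratio minimum IPD ratio for a primary call (1.5).
#' @param alpha per-site test level implied by `min_score`
#'   (10^(-min_score/10)); stored for reporting.
#' @return object of class `call_filter`.
#' @export
call_filter <- function(min_coverage_retain = 10L, primary_min_coverage = 20L,
                        min_score = 22, min_ratio = 1.5,
                        alpha = 10^(-min_score / 10)) {
  if (primary_min_coverage < min_coverage_retain) {
    stop("primary_min_coverage must be >= min_coverage_retain")
  }
  structure(list(min_coverage_retain = as.integer(min_coverage_retain),
                 primary_min_coverage = as.integer(primary_min_coverage),
                 min_score = min_score, min_ratio = min_ratio, alpha = alpha),
            class = "call_filter")
}

#' IPD ratio at a site
#'
#' The native-to-control ratio of mean inter-pulse durations, the basic
#' kinetic signal of base modification.
#'
#' @param native_ipds positive per-pass IPDs at the site.
#' @param control control per-pass IPDs, or a single in-silico control
#'   mean IPD.
#' @return mean(native) / mean(control).
#' @export
compute_ipd_ratio <- function(native_ipds, control) {
  if (!length(native_ipds)) stop("undefined site: no native IPD observations")
  cm <- if (length(control) > 1L) mean(control) else control
  if (!length(cm) || cm <= 0) stop("control mean must be > 0")
  mean(native_ipds) / cm
}

# Welch one-sided score on summary statistics (vectorized)
welch_score <- function(m1, v1, n1, m2, v2, n2, max_score = 1000) {
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), ifelse(m1 > m2, Inf, -Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v2 / n2)^2 / pmax(n2 - 1, 1)),
               1)
  p <- pt(tt, df, lower.tail = FALSE)
  p[m1 == m2 & se2 == 0] <- 1       # exact tie handling
  score <- -10 * log10(pmax(p, 10^(-max_score / 10)))
  pmin(pmax(score, 0), max_score)
}

#' Phred-scaled modification score (mQv) at a site
#'
#' A one-sided two-sample Welch test on log-IPDs (native greater than
#' control), reported as -10*log10(p) and capped. Degenerate zero-variance
#' input is resolved by exact tie handling (never NaN). When the control
#' is given as a single in-silico model mean, a one-sample test against
#' the implied log-scale mean is used.
#'
#' @param native_ipds per-pass native IPDs (>= 2 values).
#' @param control control per-pass IPDs (>= 2 values) or a scalar control
#'   mean IPD.
#' @param max_score score cap (default 1000).
#' @return the score (>= 0).
#' @export
score_site <- function(native_ipds, control, max_score = 1000) {
  if (length(native_ipds) < 2L) stop("score_site needs >= 2 native observations")
  ln <- log(native_ipds)
  if (length(control) > 1L) {
    lc <- log(control)
    welch_score(mean(ln), var(ln), length(ln), mean(lc), var(lc), length(lc),
                max_score)
  } else {
    # model mean of IPDs -> implied log-scale mean via the plug-in variance
    mu0 <- log(control) - var(ln) / 2
    welch_score(mean(ln), var(ln), length(ln), mu0, 0, 1e9, max_score)
  }
}

#' Call base modifications from a kinetic table
#'
#' Applies the published decision rule: sites under the retain threshold
#' (10x) are removed; the mark is assigned from the reference base on the
#' tested strand (C gives 4mC, A gives 6mA; other bases are discarded);
#' primary calls require 20x coverage, mQv >= 22, and an IPD ratio above
#' the filter's floor. Per-site methylation fractions are estimated (for
#' sites at or above the primary coverage threshold) by classifying each
#' pass to the nearer kinetic component.
#'
#' @param kinetics a `kinetic_table`.
#' @param genome the `annotated_genome` the positions refer to.
#' @param filter a [call_filter()].
#' @param models list(unmod_meanlog, mod_meanlog): log-scale means of the
#'   unmodified and modified IPD components used for fraction estimation;
#'   defaults are taken from the kinetic table's simulation attributes
#'   when present.
#' @return a `mod_calls` data.frame sorted by (contig, pos, strand) with
#'   columns contig, pos, strand, mark, coverage, ipd_ratio, score,
#'   fraction, class, primary.
#' @export
call_modifications <- function(kinetics, genome, filter = call_filter(),
                               models = NULL) {
  stopifnot(inherits(filter, "call_filter"))
  if (is.null(models)) {
    mult <- attr(kinetics, "multiplier") %||% 3
    models <- list(unmod_meanlog = 0, mod_meanlog = log(mult))
  }
  kinetics <- kinetics[lengths(kinetics$native) > 0L, , drop = FALSE]
  if (!nrow(kinetics)) return(empty_calls())
  base <- base_at(genome, kinetics$contig, kinetics$pos, kinetics$strand)
  cov <- lengths(kinetics$native)

  ul <- unlist(kinetics$native, use.names = FALSE)
  grp <- rep.int(seq_len(nrow(kinetics)), cov)
  s1 <- rowsum(ul, grp)[, 1]
  lg <- log(ul)
  ls1 <- rowsum(lg, grp)[, 1]
  ls2 <- rowsum(lg * lg, grp)[, 1]
  m_nat <- s1 / cov
  lm_nat <- ls1 / cov
  lv_nat <- pmax(0, (ls2 - cov * lm_nat^2) / pmax(cov - 1, 1))

  ctrl_n <- lengths(kinetics$control)
  if (all(ctrl_n > 1L)) {
    uc <- unlist(kinetics$control, use.names = FALSE)
    grc <- rep.int(seq_len(nrow(kinetics)), ctrl_n)
    cs1 <- rowsum(uc, grc)[, 1]
    lgc <- log(uc)
    cls1 <- rowsum(lgc, grc)[, 1]
    cls2 <- rowsum(lgc * lgc, grc)[, 1]
    m_ctl <- cs1 / ctrl_n
    lm_ctl <- cls1 / ctrl_n
    lv_ctl <- pmax(0, (cls2 - ctrl_n * lm_ctl^2) / pmax(ctrl_n - 1, 1))
  } else {
    cm <- attr(kinetics, "control_mean") %||% 1
    m_ctl <- rep(cm, nrow(kinetics))
    lm_ctl <- log(cm) - lv_nat / 2
    lv_ctl <- rep(0, nrow(kinetics))
    ctrl_n <- rep(1e9, nrow(kinetics))
  }

  ratio <- m_nat / m_ctl
  score <- welch_score(lm_nat, lv_nat, cov, lm_ctl, lv_ctl, ctrl_n)

  # per-pass nearest-component classification for fraction estimation
  tau <- (models$unmod_meanlog + models$mod_meanlog) / 2
  kmod <- rowsum((lg > tau) + 0, grp)[, 1]
  fraction <- kmod / cov

  mark <- ifelse(base == "C", "4mC", ifelse(base == "A", "6mA", NA))
  calls <- new_df(contig = kinetics$contig, pos = kinetics$pos,
                  strand = kinetics$strand, mark = mark,
                  coverage = as.integer(cov), ipd_ratio = ratio,
                  score = score, fraction = fraction)
  calls <- calls[!is.na(calls$mark), , drop = FALSE]
  filter_calls(calls, filter)
}

empty_calls <- function() {
  out <- new_df(contig = character(), pos = integer(), strand = character(),
                mark = character(), coverage = integer(), ipd_ratio = numeric(),
                score = numeric(), fraction = numeric(), class = character(),
                primary = logical())
  class(out) <- c("mod_calls", "data.frame")
  out
}

#' Apply (or re-apply) a call filter
#'
#' Idempotent: filtering an already-filtered call set changes nothing.
#' Drops sub-retain coverage and non-positive kinetic effects, flags
#' primary calls, withholds fractions below the fraction-calling coverage
#' threshold, and sorts by (contig, pos, strand).
#'
#' @param calls a `mod_calls`-like data.frame.
#' @param filter a [call_filter()].
#' @return a `mod_calls` data.frame.
#' @export
filter_calls <- function(calls, filter = call_filter()) {
  keep <- calls$coverage >= filter$min_coverage_retain & calls$ipd_ratio > 1
  calls <- calls[keep, , drop = FALSE]
  calls$fraction[calls$coverage < filter$primary_min_coverage] <- NA_real_
  calls$class <- ifelse(is.na(calls$fraction), NA_character_,
                        classify_fraction(ifelse(is.na(calls$fraction), 0, calls$fraction)))
  calls$primary <- calls$coverage >= filter$primary_min_coverage &
    calls$score >= filter$min_score & calls$ipd_ratio >= filter$min_ratio
  calls <- calls[order(calls$contig, calls$pos, calls$strand), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("mod_calls", "data.frame")
  calls
}

#' @export
print.mod_calls <- function(x, ...) {
  cat("mod_calls:", nrow(x), "retained sites (", sum(x$primary), "primary;",
      sum(x$mark == "4mC"), "4mC /", sum(x$mark == "6mA"), "6mA )\n")
  invisible(x)
}

#' Estimate per-site methylation fraction
#'
#' Each sequencing pass is classified to the nearer of the unmodified and
#' modified log-IPD components by likelihood (equal component spread, so
#' the decision boundary is the component midpoint); the fraction is the
#' proportion of passes classified modified — the methylated portion of
#' passes at the site, 1 meaning full methylation.
#'
#' @param native_ipds per-pass native IPDs at the site.
#' @param unmod_meanlog log-scale mean of the unmodified component.
#' @param mod_meanlog log-scale mean of the modified component.
#' @return fraction in [0, 1].
#' @export
estimate_fraction <- function(native_ipds, unmod_meanlog = 0,
                              mod_meanlog = log(3)) {
  if (!length(native_ipds)) stop("zero coverage: fraction undefined")
  if (mod_meanlog <= unmod_meanlog) stop("mod_meanlog must exceed unmod_meanlog")
  tau <- (unmod_meanlog + mod_meanlog) / 2
  mean(log(native_ipds) > tau)
}

#' Classify a methylation fraction
#'
#' Published level bins: low-fraction sites (0.1-0.5), moderately
#' methylated (0.5-0.8), highly methylated (0.8-1). Fractions below 0.1
#' fall outside the three classes ("sub_threshold").
#'
#' @param fraction numeric vector in [0, 1].
#' @return character vector: "sub_threshold", "low", "moderate", "high".
#' @export
classify_fraction <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("fraction must lie in [0, 1]")
  }
  out <- character(length(fraction))
  out[fraction < 0.1] <- "sub_threshold"
  out[fraction >= 0.1 & fraction < 0.5] <- "low"
  out[fraction >= 0.5 & fraction < 0.8] <- "moderate"
  out[fraction >= 0.8] <- "high"
  out
}

#' Summarize methylation fractions of a call set
#'
#' Per-mark mean fraction, counts per level class, high:low ratio (Inf
#' when there are no low-fraction sites), and the percentage of fully
#' methylated sites (fraction exactly 1).
#'
#' @param calls a `mod_calls` data.frame (rows without fractions are
#'   ignored).
#' @return data.frame with one row per mark; zero rows for empty input.
#' @export
fraction_summary <- function(calls) {
  calls <- calls[!is.na(calls$fraction), , drop = FALSE]
  if (!nrow(calls)) {
    return(new_df(mark = character(), n = integer(), mean_fraction = numeric(),
                  n_low = integer(), n_moderate = integer(), n_high = integer(),
                  high_low_ratio = numeric(), pct_fully_methylated = numeric()))
  }
  cls <- classify_fraction(calls$fraction)
  out <- lapply(split(seq_len(nrow(calls)), calls$mark), function(i) {
    ci <- cls[i]
    n_low <- sum(ci == "low"); n_high <- sum(ci == "high")
    new_df(mark = calls$mark[i[1]], n = length(i),
           mean_fraction = mean(calls$fraction[i]),
           n_low = n_low, n_moderate = sum(ci == "moderate"), n_high = n_high,
           high_low_ratio = if (n_low == 0) Inf else n_high / n_low,
           pct_fully_methylated = 100 * mean(calls$fraction[i] == 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
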
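#' Simulate per-site polymerase kinetics
#'
#' Emulates single-molecule sequencing kinetics at single-base resolution.
#' Every genomic position contributes exactly one candidate strand-site:
#' the strand on which the reference base is C (a 4mC candidate) or A (a
#' 6mA candidate). Per-pass inter-pulse durations (IPDs) are log-normal;
#' at a site methylated with true fraction f, each pass is modified with
#' probability f and modified passes have their median IPD multiplied by
#' the configured multiplier. A matched control sample of unmodified
#' passes is drawn per site (emulating an unmethylated control library);
#' the analytic unmodified mean IPD is carried as `control_mean` for use
#' as an in-silico control.
#'
#' @param genome an `annotated_genome`.
#' @param methylome a methylome data.frame (may be empty).
#' @param config the [sim_config()]; `config$kinetics` holds mean passes
#'   per strand, log-IPD sigma, the modified-site IPD multiplier, and the
#'   coverage coefficient of variation.
#' @param positions optional data.frame(contig, pos, strand) restricting
#'   the table to specific sites (defaults to all candidate sites).
#' @return a `kinetic_table` data.frame with columns contig, pos, strand,
#'   base, coverage, true_fraction, and list-columns `native` and
#'   `control` of per-pass IPDs; attribute `control_mean` and `sigma`.
#' @export
simulate_kinetics <- function(genome, methylome, config, positions = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  validate_sim_config(config)
  k <- config$kinetics
  set.seed(stage_seed(config$seed, 2L))
  if (k$passes == 0) {
    out <- new_df(contig = character(), pos = integer(), strand = character(),
                  base = character(), coverage = integer(), true_fraction = numeric())
    out$native <- list(); out$control <- list()
    class(out) <- c("kinetic_table", "data.frame")
    return(out)
  }
  if (is.null(positions)) {
    sites <- do.call(rbind, lapply(names(genome$contigs), function(cn) {
      ch <- seq_chars(genome$contigs[[cn]])
      strand <- c(A = "+", C = "+", G = "-", T = "-")[ch]
      base <- c(A = "A", C = "C", G = "C", T = "A")[ch]
      new_df(contig = cn, pos = seq_along(ch) - 1L, strand = unname(strand),
             base = unname(base))
    }))
  } else {
    sites <- new_df(contig = positions$contig, pos = as.integer(positions$pos),
                    strand = positions$strand)
    sites$base <- base_at(genome, sites$contig, sites$pos, sites$strand)
  }
  if (nrow(methylome)) {
    key <- function(d) paste(d$contig, d$pos, d$strand)
    f <- methylome$fraction[match(key(sites), key(methylome))]
    sites$true_fraction <- ifelse(is.na(f), 0, f)
  } else {
    sites$true_fraction <- 0
  }
  n <- nrow(sites)
  cov <- pmax(2L, as.integer(round(k$passes * (1 + k$coverage_cv * rnorm(n)))))
  kmod <- rbinom(n, cov, sites$true_fraction)
  grp <- rep.int(seq_len(n), cov)
  is_mod <- sequence(cov) <= rep.int(kmod, cov)
  native <- exp(rnorm(length(grp), mean = ifelse(is_mod, log(k$multiplier), 0),
                      sd = k$sigma))
  control <- exp(rnorm(length(grp), mean = 0, sd = k$sigma))
  sites$coverage <- cov
  sites$native <- split(native, grp)
  sites$control <- split(control, grp)
  attr(sites, "control_mean") <- exp(k$sigma^2 / 2)
  attr(sites, "sigma") <- k$sigma
  attr(sites, "multiplier") <- k$multiplier
  class(sites) <- c("kinetic_table", "data.frame")
  sites
}

#' @export
print.kinetic_table <- function(x, ...) {
  cat("kinetic_table:", nrow(x), "sites; mean coverage",
      round(mean(x$coverage), 1), "\n")
  invisible(x)
}
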
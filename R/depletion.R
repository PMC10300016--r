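# Depletion-of-homozygotes test. For a haplotype with n_carriers
# heterozygous animals among N genotyped and zero homozygotes observed:
#   simple method  E[hom] = N * C^2 / 4 = N * f^2         (random mating)
#   mating method  E[hom] = (carrier sire x carrier MGS progeny) / 4
# with zero-homozygote probabilities (1 - x^2/4)^N and 0.75^n_matings.
# All probabilities are evaluated in log space so that deeply depleted
# haplotypes (Phh down to ~1e-130) do not underflow.

#' Expected homozygotes under random mating
#'
#' N * (n_carriers/N)^2 / 4, identically N * f^2 with the haplotype
#' frequency f = n_carriers / (2N).
#'
#' @param n_carriers carrier (heterozygote) count
#' @param N number of genotyped animals
#' @return expected homozygote count
#' @export
expected_hom_simple <- function(n_carriers, N) {
  if (any(N <= 0)) stop("N must be positive")
  if (any(n_carriers < 0 | n_carriers > N)) stop("n_carriers must be in [0, N]")
  n_carriers^2 / (4 * N)
}

#' Probability of observing zero homozygotes (random mating)
#'
#' (1 - freq^2 / 4)^N evaluated in log space. The `convention` flag
#' records which frequency the caller supplies: with `"haplotype"` the
#' haplotype frequency f = carriers/(2N) is inserted (the default, which
#' reproduces published candidate tables), with `"carrier"` the carrier
#' frequency C = carriers/N = 2f (the formula's textual reading). Both
#' apply the same functional form to the supplied value.
#'
#' @param freq frequency in `[0, 1]` (see `convention`)
#' @param N number of genotyped animals
#' @param convention `"haplotype"` or `"carrier"`, recorded on the result
#' @return probability in `(0, 1]`
#' @export
phh_simple <- function(freq, N, convention = c("haplotype", "carrier")) {
  convention <- match.arg(convention)
  stopifnot(all(freq >= 0 & freq <= 1), all(N >= 0))
  p <- exp(N * log1p(-freq^2 / 4))
  attr(p, "convention") <- convention
  p
}

#' Count carrier-sire x carrier-maternal-grandsire progeny
#'
#' The mating-method exposure: genotyped animals whose sire and maternal
#' grandsire are both carriers of the haplotype. Animals with an unknown
#' sire, unknown dam or unknown dam's sire are not counted (the dam's
#' haplotype cannot be tracked). Maternal-granddam and maternal-grandsire
#' allele frequencies are taken as equal, so each such progeny is one
#' Bernoulli trial with homozygote probability 1/4.
#'
#' @param ped a [as_pedigree()] object
#' @param carriers character vector of carrier animal ids
#' @param genotyped character vector of genotyped animal ids
#' @return count of carrier-mating progeny
#' @export
count_carrier_matings <- function(ped, carriers, genotyped) {
  if (!length(carriers) || !length(genotyped)) return(0L)
  g <- intersect(as.character(genotyped), ped$id)
  i <- match(g, ped$id)
  sire <- ped$sire[i]
  mgs <- rep(NA_character_, length(i))
  known_dam <- !is.na(ped$dam[i])
  mgs[known_dam] <- ped$sire[match(ped$dam[i][known_dam], ped$id)]
  sum(!is.na(sire) & !is.na(mgs) & sire %in% carriers & mgs %in% carriers)
}

#' Probability of observing zero homozygotes (mating method)
#'
#' 0.75 raised to the number of carrier-sire x carrier-MGS progeny,
#' evaluated in log space (0.75^1028 ~ 3.7e-129 without underflow).
#'
#' @param n_matings nonnegative count
#' @return probability in `(0, 1]`
#' @export
phh_mating <- function(n_matings) {
  stopifnot(all(n_matings >= 0))
  exp(n_matings * log(0.75))
}

#' Candidate filter for putative lethal haplotypes
#'
#' Keeps records with zero observed homozygotes whose haplotype percentage
#' (100 f) exceeds `min_hap_pct`, whose simple-method expected homozygote
#' count exceeds `min_exp_hom`, and whose zero-homozygote probabilities
#' (both methods) fall below `max_phh`. Output sorted by chromosome and
#' start position.
#'
#' @param records data.frame of depletion records (see [depletion_report()])
#' @param min_hap_pct haplotype percentage floor (default 2)
#' @param min_exp_hom expected-homozygote floor, simple method (default 1)
#' @param max_phh probability ceiling applied to both methods (default 0.6)
#' @return the retained records, with `passes_filter` set to `TRUE`
#' @export
filter_candidates <- function(records, min_hap_pct = 2, min_exp_hom = 1,
                              max_phh = 0.6) {
  keep <- records$n_homozygotes == 0 &
    records$hap_pct > min_hap_pct &
    records$exp_hom_simple > min_exp_hom &
    records$phh_simple < max_phh &
    records$phh_mating < max_phh
  out <- records[keep, , drop = FALSE]
  out$passes_filter <- rep(TRUE, nrow(out))
  ord <- order(suppressWarnings(as.numeric(out$chrom)), out$chrom, out$start_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Depletion report over a haplotype catalog
#'
#' Builds one depletion record per zero-homozygote haplotype above the
#' frequency floor, populating both expectation methods and both
#' zero-homozygote probabilities, and flags the candidates that pass the
#' filter conditions.
#'
#' @param catalog an [enumerate_haplotypes()] result
#' @param ped a [as_pedigree()] object (the reported pedigree; used for
#'   the carrier-mating count)
#' @param genotyped ids of genotyped animals; defaults to the ids stored
#'   with the catalog's carrier/homozygote sets' panel via
#'   `attr(catalog, "n_genotyped")` only for N, so pass explicitly when
#'   the mating method is wanted
#' @param min_hap_pct,min_exp_hom,max_phh filter thresholds, see
#'   [filter_candidates()]
#' @param convention frequency convention for [phh_simple()]
#' @return data.frame of depletion records sorted by chrom/start, with
#'   `passes_filter` logical
#' @export
depletion_report <- function(catalog, ped, genotyped,
                             min_hap_pct = 2, min_exp_hom = 1,
                             max_phh = 0.6,
                             convention = c("haplotype", "carrier")) {
  convention <- match.arg(convention)
  N <- attr(catalog, "n_genotyped")
  if (is.null(N)) N <- length(genotyped)
  stopifnot(N > 0)
  cand <- catalog[catalog$n_homozygotes == 0 &
                    100 * catalog$n_carriers / (2 * N) > min_hap_pct, ,
                  drop = FALSE]
  if (!nrow(cand)) {
    out <- cand[, c("hap_id", "segment", "hap_no", "chrom", "start_bp",
                    "end_bp", "n_markers", "n_carriers", "n_homozygotes")]
    out$n_genotyped <- integer(0); out$hap_freq <- numeric(0)
    out$carrier_freq <- numeric(0); out$hap_pct <- numeric(0)
    out$exp_hom_simple <- numeric(0); out$phh_simple <- numeric(0)
    out$n_carrier_matings <- integer(0); out$exp_hom_mating <- numeric(0)
    out$phh_mating <- numeric(0); out$passes_filter <- logical(0)
    return(out)
  }
  missing_ct <- 0L
  n_mat <- vapply(cand$carriers, function(cids) {
    miss <- setdiff(cids, ped$id)
    if (length(miss)) missing_ct <<- missing_ct + length(miss)
    count_carrier_matings(ped, intersect(cids, ped$id), genotyped)
  }, integer(1))
  if (missing_ct > 0L)
    message("mating method: skipped ", missing_ct,
            " carrier ids absent from the pedigree")
  f <- cand$n_carriers / (2 * N)
  C <- cand$n_carriers / N
  out <- data.frame(
    hap_id = cand$hap_id, segment = cand$segment, hap_no = cand$hap_no,
    chrom = cand$chrom, start_bp = cand$start_bp, end_bp = cand$end_bp,
    n_markers = cand$n_markers, n_genotyped = N,
    n_carriers = cand$n_carriers, n_homozygotes = cand$n_homozygotes,
    hap_freq = f, carrier_freq = C, hap_pct = 100 * f,
    exp_hom_simple = expected_hom_simple(cand$n_carriers, N),
    phh_simple = as.numeric(phh_simple(if (convention == "haplotype") f else C,
                                       N, convention)),
    n_carrier_matings = n_mat,
    exp_hom_mating = n_mat / 4,
    phh_mating = phh_mating(n_mat),
    stringsAsFactors = FALSE)
  out$passes_filter <- out$hap_pct > min_hap_pct &
    out$exp_hom_simple > min_exp_hom &
    out$phh_simple < max_phh & out$phh_mating < max_phh
  ord <- order(suppressWarnings(as.numeric(out$chrom)), out$chrom, out$start_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "carriers") <- cand$carriers[ord]
  out
}

#' Write a candidate table as TSV
#'
#' Columns mirror a published candidate-haplotype report: id, chromosome,
#' span, length in Mb, carrier count, haplotype percentage, simple
#' expectation and probability, mating-pair count and probability, filter
#' verdict. Expectations are rounded for display; callers needing full
#' precision use the report data.frame itself.
#'
#' @param report a [depletion_report()] result
#' @param path output path
#' @export
write_candidate_table <- function(report, path) {
  df <- data.frame(
    hap_id = report$hap_id, chrom = report$chrom,
    start_bp = report$start_bp, end_bp = report$end_bp,
    length_mb = round((report$end_bp - report$start_bp) / 1e6, 3),
    n_carriers = report$n_carriers,
    hap_pct = round(report$hap_pct, 2),
    exp_hom_simple = round(report$exp_hom_simple),
    phh_simple = sprintf("%.3g", report$phh_simple),
    n_carrier_matings = report$n_carrier_matings,
    phh_mating = sprintf("%.3g", report$phh_mating),
    passes_filter = report$passes_filter)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
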
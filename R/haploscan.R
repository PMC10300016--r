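# Sliding-window haplotype enumeration over a fully phased biallelic panel.
# Chromosomes are partitioned into contiguous segments of at most max_len
# markers (as equal as possible), and within each segment every distinct
# allele string contributed by the 2N haplotype copies is catalogued with
# its copy count, carriers (one copy) and homozygotes (two copies).

#' Phased haplotype panel
#'
#' @param H integer matrix of 0/1 alleles, one row per haplotype copy:
#'   rows 2i-1 and 2i are the two haplotypes of animal i
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `id`;
#'   markers sorted by position within chromosome
#' @param ids character vector of animal ids (length `nrow(H) / 2`)
#' @return object of class `phased_panel`
#' @export
phased_panel <- function(H, map, ids) {
  stopifnot(is.matrix(H), nrow(H) == 2L * length(ids),
            ncol(H) == nrow(map),
            all(c("chrom", "pos", "id") %in% names(map)))
  if (anyNA(H))
    stop("panel is not fully phased: missing alleles present; this pipeline requires complete phased input")
  if (!all(H %in% c(0L, 1L))) stop("alleles must be 0/1")
  map$chrom <- as.character(map$chrom)
  bad <- unlist(lapply(split(map$pos, map$chrom), is.unsorted))
  if (any(bad))
    stop("marker map must be sorted by position within chromosome")
  structure(list(H = H, map = map, ids = as.character(ids)),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("Phased panel: %d animals x %d markers on %d chromosome(s)\n",
              length(x$ids), nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

#' Plan chromosome segmentation
#'
#' Partitions each chromosome's markers into `ceiling(M / max_len)`
#' contiguous blocks whose sizes differ by at most one, longer blocks
#' first. Segments are numbered consecutively across chromosomes in map
#' order.
#'
#' @param map marker map (`chrom`, `pos`, `id`), sorted within chromosome
#' @param max_len maximum markers per segment (default 200)
#' @return data.frame with columns `segment`, `chrom`, `start`, `end`
#'   (half-open 0-based marker indices within chromosome), `start_col`,
#'   `end_col` (half-open 0-based columns in the full panel), `start_bp`,
#'   `end_bp`, `n_markers`
#' @export
plan_segments <- function(map, max_len = 200L) {
  stopifnot(max_len >= 1L)
  map$chrom <- as.character(map$chrom)
  chroms <- unique(map$chrom)
  out <- list()
  seg_no <- 0L
  offset <- 0L
  for (ch in chroms) {
    rows <- which(map$chrom == ch)
    m <- length(rows)
    if (m == 0L) {
      warning("chromosome ", ch, " has no markers; skipped")
      next
    }
    n_seg <- ceiling(m / max_len)
    base <- m %/% n_seg
    extra <- m %% n_seg
    sizes <- c(rep(base + 1L, extra), rep(base, n_seg - extra))
    ends <- cumsum(sizes)
    starts <- ends - sizes
    out[[ch]] <- data.frame(
      segment = seg_no + seq_len(n_seg),
      chrom = ch,
      start = starts, end = ends,
      start_col = offset + starts, end_col = offset + ends,
      start_bp = map$pos[rows[starts + 1L]],
      end_bp = map$pos[rows[ends]],
      n_markers = sizes,
      stringsAsFactors = FALSE)
    seg_no <- seg_no + n_seg
    offset <- offset + m
  }
  plan <- do.call(rbind, out)
  rownames(plan) <- NULL
  plan
}

#' Enumerate segment haplotypes with carrier and homozygote sets
#'
#' Exact string identity over the segment's markers defines a haplotype.
#' Within each segment haplotypes are numbered by descending copy count,
#' ties broken lexicographically by allele string, giving the stable
#' `<segment>.<haplotype>` ids used throughout the screen.
#'
#' @param panel a [phased_panel()]
#' @param plan a [plan_segments()] plan for the panel's map
#' @return data.frame (one row per segment haplotype) with columns
#'   `hap_id`, `segment`, `hap_no`, `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, `allele_string`, `copies`, `n_carriers`,
#'   `n_homozygotes`, plus list-columns `carriers` and `homozygotes`
#'   holding animal ids; attribute `n_genotyped` records N
#' @export
enumerate_haplotypes <- function(panel, plan) {
  stopifnot(inherits(panel, "phased_panel"))
  n <- length(panel$ids)
  odd <- seq(1L, 2L * n, by = 2L)
  even <- odd + 1L
  res <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    cols <- (plan$start_col[k] + 1L):plan$end_col[k]
    hs <- do.call(paste0, as.data.frame(panel$H[, cols, drop = FALSE]))
    a1 <- hs[odd]; a2 <- hs[even]
    copies <- table(hs)
    hom <- a1 == a2
    hom_ids <- split(panel$ids[hom], a1[hom])
    het <- !hom
    carrier_ids <- split(rep(panel$ids[het], 2L), c(a1[het], a2[het]))
    strs <- names(copies)
    n_hom <- lengths(hom_ids)[strs]; n_hom[is.na(n_hom)] <- 0L
    n_car <- lengths(carrier_ids)[strs]; n_car[is.na(n_car)] <- 0L
    ord <- order(-as.integer(copies), strs)
    strs <- strs[ord]
    df <- data.frame(
      hap_id = sprintf("%d.%d", plan$segment[k], seq_along(strs)),
      segment = plan$segment[k],
      hap_no = seq_along(strs),
      chrom = plan$chrom[k],
      start_bp = plan$start_bp[k], end_bp = plan$end_bp[k],
      n_markers = plan$n_markers[k],
      allele_string = strs,
      copies = as.integer(copies)[ord],
      n_carriers = as.integer(n_car[ord]),
      n_homozygotes = as.integer(n_hom[ord]),
      stringsAsFactors = FALSE)
    df$carriers <- unname(lapply(strs, function(s) {
      v <- carrier_ids[[s]]; if (is.null(v)) character(0) else v
    }))
    df$homozygotes <- unname(lapply(strs, function(s) {
      v <- hom_ids[[s]]; if (is.null(v)) character(0) else v
    }))
    res[[k]] <- df
  }
  cat_df <- do.call(rbind, res)
  rownames(cat_df) <- NULL
  attr(cat_df, "n_genotyped") <- n
  cat_df
}

#' Write a haplotype catalog as TSV
#'
#' @param catalog an [enumerate_haplotypes()] result
#' @param path output path
#' @export
write_catalog <- function(catalog, path) {
  df <- catalog[, c("segment", "hap_no", "chrom", "start_bp", "end_bp",
                    "n_markers", "copies", "n_carriers", "n_homozygotes",
                    "allele_string")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
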
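# Pedigree container and relationship algebra.
#
# A pedigree is held as a data.frame (id, sire, dam, plus metadata columns)
# topologically sorted so parents precede offspring. Unknown parents are NA
# internally; "0", 0 and "" on input are normalised to NA and treated as
# unrelated base-population founders.

.norm_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", "0", "NA")] <- NA_character_
  x
}

#' Build a validated pedigree
#'
#' Normalises unknown-parent codes, inserts founder stubs for parents that
#' have no record of their own, topologically sorts the records (parents
#' before offspring) and checks for cycles and duplicate ids. Metadata
#' columns beyond `id`, `sire`, `dam` are carried along.
#'
#' @param df data.frame with columns `id`, `sire`, `dam` (any further
#'   columns are kept as metadata). `0`, `""` or `NA` mark unknown parents.
#' @return An object of class `pedigree`: the sorted data.frame with
#'   integer parent indices stored in attributes `sire_idx` / `dam_idx`
#'   (0 = unknown).
#' @export
as_pedigree <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "sire", "dam") %in% names(df)))
  df$id <- as.character(df$id)
  df$sire <- .norm_parent(df$sire)
  df$dam <- .norm_parent(df$dam)
  if (anyNA(df$id) || any(df$id == ""))
    stop("pedigree ids must be non-missing")
  if (anyDuplicated(df$id))
    stop("duplicate pedigree ids: ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))

  # founder stubs for named parents without their own record
  parents <- setdiff(stats::na.omit(unique(c(df$sire, df$dam))), df$id)
  if (length(parents)) {
    stub <- df[0, , drop = FALSE][seq_along(parents), , drop = FALSE]
    stub$id <- parents
    stub$sire <- NA_character_
    stub$dam <- NA_character_
    df <- rbind(stub, df)
    rownames(df) <- NULL
  }

  # stable topological sort (Kahn)
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$id
  si <- ifelse(is.na(df$sire), 0L, idx[df$sire])
  di <- ifelse(is.na(df$dam), 0L, idx[df$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  order_out <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(order_out) != n)
    stop("invalid pedigree: cycle detected among ids ",
         paste(df$id[indeg > 0L], collapse = ", "))
  df <- df[order_out, , drop = FALSE]
  rownames(df) <- NULL

  idx <- seq_len(n)
  names(idx) <- df$id
  attr(df, "sire_idx") <- unname(ifelse(is.na(df$sire), 0L, idx[df$sire]))
  attr(df, "dam_idx") <- unname(ifelse(is.na(df$dam), 0L, idx[df$dam]))
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree with %d animals (%d founders, %.1f%% unknown sires, %.1f%% unknown dams)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam)),
              100 * mean(is.na(x$sire)), 100 * mean(is.na(x$dam))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

.ped_lookup <- function(ped, ids) {
  m <- match(ids, ped$id)
  if (anyNA(m))
    stop("animals not in pedigree: ", paste(ids[is.na(m)], collapse = ", "))
  m
}

#' Maternal grandsire of an animal
#'
#' Returns the sire of the animal's dam, the pedigree link through which an
#' ungenotyped dam's haplotype is tracked in the mating-based depletion
#' test. Unknown dam, or dam with unknown sire, yields `NA`.
#'
#' @param ped a [as_pedigree()] object
#' @param animal character vector of animal ids
#' @return character vector of maternal grandsire ids (`NA` where unknown)
#' @export
maternal_grandsire <- function(ped, animal) {
  stopifnot(inherits(ped, "pedigree"))
  i <- .ped_lookup(ped, as.character(animal))
  dam <- ped$dam[i]
  out <- rep(NA_character_, length(i))
  known <- !is.na(dam)
  if (any(known)) out[known] <- ped$sire[match(dam[known], ped$id)]
  out
}

#' Inbreeding coefficients
#'
#' Recursive (Meuwissen & Luo) inbreeding coefficients for every animal in
#' the pedigree. Unknown parents are treated as unrelated base-population
#' founders, so founders have F = 0.
#'
#' @param ped a [as_pedigree()] object
#' @return named numeric vector of F, in pedigree order
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  F <- ml_inbreeding_cpp(attr(ped, "sire_idx"), attr(ped, "dam_idx"))
  names(F) <- ped$id
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, with
#' the Quaas adjustment for parental inbreeding when `use_inbreeding` is
#' `TRUE`. The Mendelian sampling variance d for animal i is
#' 0.5 - 0.25 (F_s + F_d) with both parents known, 0.75 - 0.25 F_p with
#' one, and 1 for founders (without the adjustment: 0.5, 0.75, 1).
#'
#' @param ped a [as_pedigree()] object
#' @param use_inbreeding adjust d for parental inbreeding (default `TRUE`)
#' @return list with `Ainv` (symmetric `dgCMatrix`, dimnames = ids),
#'   `F` (inbreeding coefficients) and `d` (Mendelian sampling variances)
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  s <- attr(ped, "sire_idx")
  d <- attr(ped, "dam_idx")
  F <- inbreeding(ped)
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], if (use_inbreeding) -1 else 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], if (use_inbreeding) -1 else 0)
  if (use_inbreeding) {
    dv <- 0.5 - 0.25 * (Fs + Fd)
  } else {
    dv <- ifelse(s > 0L & d > 0L, 0.5, ifelse(s > 0L | d > 0L, 0.75, 1))
  }
  al <- 1 / dv

  i <- seq_len(n)
  ks <- s > 0L
  kd <- d > 0L
  kb <- ks & kd
  ti <- c(i,
          i[ks], s[ks], s[ks],
          i[kd], d[kd], d[kd],
          s[kb], d[kb])
  tj <- c(i,
          s[ks], i[ks], s[ks],
          d[kd], i[kd], d[kd],
          d[kb], s[kb])
  tx <- c(al,
          -al[ks] / 2, -al[ks] / 2, al[ks] / 4,
          -al[kd] / 2, -al[kd] / 2, al[kd] / 4,
          al[kb] / 4, al[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- methods::as(Ainv, "generalMatrix")
  list(Ainv = Ainv, F = F, d = stats::setNames(dv, ped$id))
}

#' Export A-inverse as triplet table
#'
#' @param fac result of [a_inverse()]
#' @param path output TSV path (columns id_i, id_j, value; upper triangle)
#' @export
write_a_inverse <- function(fac, path) {
  T3 <- methods::as(Matrix::triu(fac$Ainv), "TsparseMatrix")
  ids <- rownames(fac$Ainv)
  df <- data.frame(id_i = ids[T3@i + 1L], id_j = ids[T3@j + 1L], value = T3@x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
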
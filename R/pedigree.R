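#' Pedigree construction and validation
#'
#' A pedigree is a set of (individual, sire, dam) triples. Unknown parents are
#' coded `NA` (or `"0"` / `""` in files). Validation topologically sorts the
#' records so that every parent precedes its offspring, and checks that the
#' pedigree is acyclic and that every named parent is itself a record.
#'
#' @param id character vector of individual ids (opaque strings).
#' @param sire,dam character vectors of parent ids; `NA`, `"0"` or `""` mean
#'   unknown. Every non-unknown parent must appear in `id`.
#' @param external optional logical vector flagging individuals that are
#'   external (contaminant) pollen donors rather than orchard members.
#'
#' @return An object of class `pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam`, `founder`, `external`, ordered so parents precede
#'   offspring.
#' @examples
#' ped <- validate_pedigree(id = c("O", "S", "D"),
#'                          sire = c("S", NA, NA),
#'                          dam  = c("D", NA, NA))
#' ped$id  # "S" "D" "O" -- parents first
#' @export
validate_pedigree <- function(id, sire, dam, external = NULL) {
  id   <- as.character(id)
  sire <- .norm_parent(sire)
  dam  <- .norm_parent(dam)
  if (length(id) == 0L) stop("pedigree is empty")
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  if (anyDuplicated(id))
    stop("duplicated individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (is.null(external)) external <- rep(FALSE, length(id))

  parents <- c(sire, dam)
  orphan <- setdiff(parents[!is.na(parents)], id)
  if (length(orphan))
    stop("unknown parent ", paste(sort(orphan), collapse = ", "))

  ord <- .topo_sort(id, sire, dam)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  ped$founder  <- is.na(ped$sire) & is.na(ped$dam)
  ped$external <- as.logical(external)[ord]
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.norm_parent <- function(p) {
  p <- as.character(p)
  p[!is.na(p) & (p == "0" | p == "")] <- NA_character_
  p
}

# Kahn's algorithm; reports a cycle by naming its members.
.topo_sort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  parent_idx <- cbind(ifelse(is.na(sire), NA_integer_, idx[sire]),
                      ifelse(is.na(dam),  NA_integer_, idx[dam]))
  indeg <- rowSums(!is.na(parent_idx))
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parent_idx[i, ]) if (!is.na(p))
    children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    stop("pedigree cycle detected involving: ",
         paste(id[left], collapse = ", "))
  }
  out
}

#' Read / write the 3-column pedigree CSV
#'
#' File dialect: header `id,sire,dam`, with `0` or an empty field meaning an
#' unknown parent. An optional `external` column (0/1) flags contaminant
#' pollen donors.
#'
#' @param path file path.
#' @return `read_pedigree` returns a validated [validate_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id,sire,dam")
  ext <- if ("external" %in% names(df)) df$external == "1" else NULL
  validate_pedigree(df$id, df$sire, df$dam, external = ext)
}

#' @param ped a `pedigree` object.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam  = ifelse(is.na(ped$dam),  "0", ped$dam),
                    external = as.integer(ped$external))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average numerator relationship matrix (tabular method)
#'
#' Computes the additive relationship matrix A implied by a pedigree:
#' `a_ii = 1 + 0.5 * a(sire_i, dam_i)` (the parental term is 0 when either
#' parent is unknown) and `a_ij = 0.5 * (a(j, sire_i) + a(j, dam_i))` for
#' `j` earlier in the pedigree order, unknown-parent terms contributing 0.
#' Unknown parents are treated as unique, unrelated, non-inbred founders, so
#' each contaminant father simply contributes nothing to relationships.
#'
#' @param ped a validated `pedigree`.
#' @return A dense symmetric matrix with dimnames equal to `ped$id`. Entries
#'   are twice the kinship coefficients; diagonals are `1 + F_i`.
#' @export
numerator_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0L) A[j, s] else 0) +
                    (if (d > 0L) A[j, d] else 0))
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  A
}

#' Half-sib and full-sib family structure
#'
#' Offspring of the founder (parental) generation are grouped into half-sib
#' families by each known parent, and into full-sib families by the unordered
#' (sire, dam) pair. An offspring with one unknown parent belongs to the known
#' parent's half-sib family only; its full-sib family key carries the unknown
#' side as `NA` so such offspring never merge with a fully-pedigreed family.
#'
#' @param ped a validated `pedigree`.
#' @return A list of class `family_structure` with elements
#'   `halfsib` (named list: parent id -> offspring ids), `halfsib_n` (the
#'   per-family counts, Table-style N_b), `fullsib` (named list keyed by
#'   `"p1|p2"` with the pair sorted), and `n_fullsib_families` (count of
#'   distinct full-sib families with both parents known).
#' @export
assemble_families <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  off <- ped[!(is.na(ped$sire) & is.na(ped$dam)), , drop = FALSE]
  halfsib <- list()
  for (col in c("sire", "dam")) {
    known <- !is.na(off[[col]])
    sp <- split(off$id[known], off[[col]][known])
    for (p in names(sp)) halfsib[[p]] <- c(halfsib[[p]], sp[[p]])
  }
  keys <- character(nrow(off))
  for (k in seq_len(nrow(off))) {
    s <- off$sire[k]; d <- off$dam[k]
    keys[k] <- if (is.na(s) || is.na(d))
      # half-pedigreed offspring form singleton "families"; never merged
      paste0("half:", off$id[k])
    else paste(sort(c(s, d)), collapse = "|")
  }
  fullsib <- split(off$id, keys)
  complete <- !startsWith(names(fullsib), "half:")
  structure(list(
    halfsib = halfsib,
    halfsib_n = vapply(halfsib, length, integer(1)),
    fullsib = fullsib,
    n_fullsib_families = sum(complete)
  ), class = "family_structure")
}

#' Coverage of the half-diallel mating scheme
#'
#' Fraction of the possible unordered parent pairs (selfs excluded, so
#' `n (n - 1) / 2` pairs) realised as full-sib families. With 53 parents and
#' 491 families this is 491/1378 = 0.356.
#'
#' @param n_parents number of orchard parents (>= 2).
#' @param n_fullsib_families number of distinct full-sib families observed.
#' @return the coverage proportion.
#' @export
diallel_coverage <- function(n_parents, n_fullsib_families) {
  stopifnot(n_parents >= 2, n_fullsib_families >= 0)
  possible <- n_parents * (n_parents - 1) / 2
  if (n_fullsib_families > possible)
    stop("n_fullsib_families (", n_fullsib_families,
         ") exceeds the possible half-diallel count (", possible, ")")
  n_fullsib_families / possible
}

#' Export a relationship matrix
#'
#' `write_relationship_matrix` writes either a dense CSV (ids as the first
#' column and as the header) or a sparse triplet CSV `i,j,value` keeping the
#' upper triangle of non-zero entries.
#'
#' @param A relationship matrix with dimnames.
#' @param path output file.
#' @param format `"dense"` or `"triplet"`.
#' @export
write_relationship_matrix <- function(A, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- data.frame(id = rownames(A), A, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    keep <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
    df <- data.frame(i = rownames(A)[keep[, 1]],
                     j = colnames(A)[keep[, 2]],
                     value = A[keep])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
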
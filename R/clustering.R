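# Torsion-bin-string construction, cyclic canonicalization, and
# equivalence-class clustering with lowest-energy representatives.

#' Torsion bin string of a conformation
#'
#' One label per residue, the bin assignment of its (phi, psi) point.
#'
#' @param conf a [torsion_conformation()].
#' @param scheme a [torsion_bins()] scheme.
#' @return character string of length-n over "1".."6".
#' @export
bin_string <- function(conf, scheme = torsion_bins()) {
  paste(assign_bin(conf$phi, conf$psi, scheme), collapse = "")
}

#' Canonical rotation of a cyclic bin string
#'
#' The unique representative of the rotation-equivalence class: the
#' cyclic permutation that brings the smallest label to position 1,
#' breaking ties by the label at position 2, and so on - i.e. the
#' lexicographically smallest rotation. Idempotent.
#'
#' @param s character string (nonempty).
#' @return canonical string.
#' @export
canonicalize <- function(s) {
  if (!is.character(s) || length(s) != 1 || nchar(s) < 1)
    stop("s must be a nonempty string")
  n <- nchar(s)
  rots <- vapply(seq_len(n) - 1L, function(k)
    paste0(substr(s, k + 1, n), substr(s, 1, k)), character(1))
  min(rots)
}

#' Cluster backbone candidates by canonical bin string
#'
#' Groups candidates into rotation-equivalence classes of their torsion bin
#' strings and selects the lowest-total-energy member of each class as its
#' representative (ties: first seen).
#'
#' @param candidates list of candidates from [run_annealing()] (each with
#'   `conformation`, `breakdown`, and optionally `bin_string`).
#' @param scheme a [torsion_bins()] scheme, used when a candidate lacks a
#'   precomputed bin string.
#' @return data.frame with one row per class: `canonical`, `size`,
#'   `energy`, `rep_index`; attribute `representatives` holds the
#'   representative candidates keyed by canonical string.
#' @export
cluster_candidates <- function(candidates, scheme = torsion_bins()) {
  if (length(candidates) == 0)
    return(structure(data.frame(canonical = character(0), size = integer(0),
                                energy = numeric(0), rep_index = integer(0)),
                     representatives = list()))
  strs <- vapply(candidates, function(cd)
    canonicalize(cd$bin_string %||% bin_string(cd$conformation, scheme)),
    character(1))
  energies <- vapply(candidates, function(cd) cd$breakdown$total, numeric(1))
  classes <- split(seq_along(candidates), strs)
  rep_idx <- vapply(classes, function(ix) ix[which.min(energies[ix])],
                    integer(1))
  out <- data.frame(canonical = names(classes),
                    size = lengths(classes),
                    energy = energies[rep_idx],
                    rep_index = rep_idx,
                    row.names = NULL)
  out <- out[order(out$energy), ]
  rownames(out) <- NULL
  attr(out, "representatives") <-
    stats::setNames(candidates[out$rep_index], out$canonical)
  out
}
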
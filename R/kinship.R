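# Malecot kinship coefficients on a pedigree forest.

#' Kinship matrix of a cohort
#'
#' Computes the matrix of Malecot kinship coefficients phi(i, j): the
#' probability that an allele drawn at random from i and one drawn at
#' random from j are identical by descent. The standard pedigree recursion
#' is used, filling individuals in an order where parents precede their
#' children:
#' phi(i, i) = (1 + phi(father_i, mother_i)) / 2 and, for j already
#' placed, phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2, with
#' founders pairwise unrelated.
#'
#' Canonical values in non-inbred pedigrees: self 0.5, parent-offspring
#' and full siblings 0.25, first cousins 0.0625, unrelated founders 0.
#'
#' @param x An `ech_cohort`.
#' @return A symmetric numeric matrix with individual ids as dimnames.
#' @export
kinship_matrix <- function(x) {
  stopifnot(inherits(x, "ech_cohort"))
  ind <- x$individuals
  n <- nrow(ind)
  idx <- stats::setNames(seq_len(n), ind$id)
  fa <- unname(idx[ind$father_id])
  mo <- unname(idx[ind$mother_id])
  ord <- attr(x, "pedigree_order")
  phi <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  for (i in ord) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
      row_i <- 0.5 * (phi[fa[i], ] + phi[mo[i], ])
      row_i[i] <- phi[i, i]
      phi[i, ] <- row_i
      phi[, i] <- row_i
    }
  }
  phi
}
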
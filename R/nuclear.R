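# Nuclear-family decomposition of a pedigree forest.

#' Decompose a cohort into nuclear families
#'
#' Polygamous family structures and multi-generation pedigrees are split
#' into nuclear families, each with a dedicated father and mother and their
#' shared offspring. Every individual with recorded parents belongs to
#' exactly one nuclear family as offspring; a father with several wives
#' heads one nuclear family per wife. The sibship size of a nuclear family
#' counts its living offspring only.
#'
#' @param x An `ech_cohort`.
#' @return A data.frame with one row per nuclear family: `nf_id`,
#'   `family_id`, `father_id`, `mother_id`, `sibship_size` (living
#'   offspring) and a list-column `offspring_ids` (all offspring, in input
#'   order).
#' @export
split_nuclear <- function(x) {
  ind <- if (inherits(x, "ech_cohort")) x$individuals else x
  child <- !is.na(ind$father_id)  # both-parent rule enforced at validation
  if (!any(child)) {
    return(data.frame(nf_id = character(0), family_id = character(0),
                      father_id = character(0), mother_id = character(0),
                      sibship_size = integer(0),
                      offspring_ids = I(list()),
                      stringsAsFactors = FALSE))
  }
  key <- paste(ind$father_id[child], ind$mother_id[child], sep = "\r")
  key <- factor(key, levels = unique(key))
  off <- split(ind$id[child], key)
  liv <- split(ind$alive[child], key)
  fam <- vapply(split(ind$family_id[child], key), `[`, "", 1L)
  parents <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  data.frame(
    nf_id = sprintf("NF%03d", seq_along(off)),
    family_id = unname(fam),
    father_id = parents[, 1L],
    mother_id = parents[, 2L],
    sibship_size = vapply(liv, function(a) sum(a), 0L, USE.NAMES = FALSE),
    offspring_ids = I(unname(off)),
    stringsAsFactors = FALSE
  )
}
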
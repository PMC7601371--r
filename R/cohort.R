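# Cohort container: a validated pedigree forest with phenotype annotation.

#' Phenotype vocabulary
#'
#' Recognised phenotype subtypes for cohort members. `unknown` marks subjects
#' that were never phenotyped; `ech_unspecified` marks subjects reported as
#' affected by some form of endemic congenital hypothyroidism (CH) without a
#' recorded subtype (in the historical survey these are deceased subjects
#' reported by villagers).
#'
#' @format Character vector of valid phenotype codes.
#' @export
PHENOTYPE_LEVELS <- c(
  "unaffected",
  "myxedematous_severe", "myxedematous_moderate", "myxedematous_unknown_grade",
  "mixed",
  "neurological", "deaf_mute",
  "ech_unspecified",
  "unknown"
)

GOITRE_LEVELS <- c("absent", "palpable_not_visible", "visible")
SEX_LEVELS <- c("male", "female", "unknown")

#' Construct a cohort from an individual table
#'
#' Builds and validates a pedigree cohort. The pedigree must form a forest:
#' parent references must resolve within the cohort (or be `NA` for
#' founders), both parents are recorded or neither, parent sexes must be
#' compatible, and no individual may be its own ancestor.
#'
#' @param individuals A data.frame with columns `id`, `family_id`,
#'   `father_id`, `mother_id` (`NA` for founders), `sex` (`"male"`,
#'   `"female"`, `"unknown"`), `alive` (logical), `age_years` (non-negative
#'   numeric, `NA` allowed), `phenotype` (see [PHENOTYPE_LEVELS]) and
#'   `goitre` (`"absent"`, `"palpable_not_visible"`, `"visible"` or `NA`).
#' @return An object of class `ech_cohort`: a list with elements
#'   `individuals` (the validated table), `nuclear` (the nuclear-family
#'   decomposition, see [split_nuclear()]) and `phenotyped_count` (alive
#'   subjects with a known phenotype).
#' @seealso [read_pedigree()], [phenotype_mask()], [kinship_matrix()]
#' @export
cohort <- function(individuals) {
  required <- c("id", "family_id", "father_id", "mother_id", "sex", "alive",
                "age_years", "phenotype", "goitre")
  missing_cols <- setdiff(required, names(individuals))
  if (length(missing_cols) > 0L) {
    stop("individual table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ind <- as.data.frame(individuals)[required]
  ind$id <- as.character(ind$id)
  ind$family_id <- as.character(ind$family_id)
  ind$father_id <- as.character(ind$father_id)
  ind$mother_id <- as.character(ind$mother_id)
  ind$sex <- as.character(ind$sex)
  ind$alive <- as.logical(ind$alive)
  ind$age_years <- as.numeric(ind$age_years)
  ind$phenotype <- as.character(ind$phenotype)
  ind$goitre <- as.character(ind$goitre)
  rownames(ind) <- NULL

  if (anyNA(ind$id) || any(!nzchar(ind$id))) stop("empty or missing individual id")
  dup <- unique(ind$id[duplicated(ind$id)])
  if (length(dup) > 0L) {
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(ind$sex %in% SEX_LEVELS)) {
    stop("invalid sex value(s): ",
         paste(unique(setdiff(ind$sex, SEX_LEVELS)), collapse = ", "))
  }
  if (!all(ind$phenotype %in% PHENOTYPE_LEVELS)) {
    stop("invalid phenotype value(s): ",
         paste(unique(setdiff(ind$phenotype, PHENOTYPE_LEVELS)), collapse = ", "))
  }
  bad_goitre <- !is.na(ind$goitre) & !(ind$goitre %in% GOITRE_LEVELS)
  if (any(bad_goitre)) {
    stop("invalid goitre value(s): ",
         paste(unique(ind$goitre[bad_goitre]), collapse = ", "))
  }
  if (anyNA(ind$alive)) stop("alive flag must be TRUE or FALSE for every individual")
  if (any(!is.na(ind$age_years) & ind$age_years < 0)) {
    stop("negative age_years")
  }

  one_parent <- xor(is.na(ind$father_id), is.na(ind$mother_id))
  if (any(one_parent)) {
    stop("individual(s) with exactly one recorded parent: ",
         paste(ind$id[one_parent], collapse = ", "))
  }
  for (col in c("father_id", "mother_id")) {
    refs <- ind[[col]]
    unresolved <- !is.na(refs) & !(refs %in% ind$id)
    if (any(unresolved)) {
      stop("unresolved ", sub("_id", "", col), " reference for individual(s): ",
           paste(ind$id[unresolved], collapse = ", "),
           " (missing: ", paste(unique(refs[unresolved]), collapse = ", "), ")")
    }
  }
  sex_of <- stats::setNames(ind$sex, ind$id)
  fathers <- stats::na.omit(unique(ind$father_id))
  bad_f <- fathers[sex_of[fathers] == "female"]
  mothers <- stats::na.omit(unique(ind$mother_id))
  bad_m <- mothers[sex_of[mothers] == "male"]
  if (length(bad_f) > 0L || length(bad_m) > 0L) {
    stop("parent(s) of incompatible sex: ",
         paste(c(bad_f, bad_m), collapse = ", "))
  }

  ord <- pedigree_order(ind)  # errors on cycles

  obj <- structure(
    list(individuals = ind, nuclear = NULL,
         phenotyped_count = sum(ind$alive & ind$phenotype != "unknown")),
    class = "ech_cohort",
    pedigree_order = ord
  )
  obj$nuclear <- split_nuclear(obj)
  obj
}

# Topological order of the pedigree (parents before children).
# Errors with the offending ids when the parent graph contains a cycle.
pedigree_order <- function(ind) {
  n <- nrow(ind)
  idx <- stats::setNames(seq_len(n), ind$id)
  fa <- idx[ind$father_id]
  mo <- idx[ind$mother_id]
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop("cyclic pedigree involving individual(s): ",
         paste(ind$id[!placed], collapse = ", "))
  }
  ord
}

#' @export
print.ech_cohort <- function(x, ...) {
  ind <- x$individuals
  cat(sprintf("<ech_cohort> %d individuals in %d families\n",
              nrow(ind), length(unique(ind$family_id))))
  cat(sprintf("  phenotyped alive: %d; nuclear families: %d\n",
              x$phenotyped_count, nrow(x$nuclear)))
  invisible(x)
}

#' @export
summary.ech_cohort <- function(object, ...) {
  ind <- object$individuals
  mask <- phenotype_mask(object, "combined")
  out <- list(
    n = nrow(ind),
    n_families = length(unique(ind$family_id)),
    n_nuclear = nrow(object$nuclear),
    phenotyped = object$phenotyped_count,
    deceased = sum(!ind$alive),
    affected_combined = sum(mask == "affected"),
    phenotypes = table(factor(ind$phenotype, levels = PHENOTYPE_LEVELS))
  )
  class(out) <- "summary.ech_cohort"
  out
}

#' @export
print.summary.ech_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d individuals (%d deceased) in %d families (%d nuclear)\n",
              x$n, x$deceased, x$n_families, x$n_nuclear))
  cat(sprintf("Phenotyped alive: %d; affected (combined phenotype): %d\n",
              x$phenotyped, x$affected_combined))
  print(x$phenotypes)
  invisible(x)
}

#' Affection status of every cohort member under a phenotype category
#'
#' Familial aggregation is assessed for three phenotype categories:
#' `"myxedematous"` (severe, moderate or unknown-grade myxedematous forms,
#' plus the mixed form), `"neurological"` (neurological and deaf-mute
#' forms), and `"combined"` (either of the two). Under each category every
#' individual is classed `affected`, `control` or `unphenotyped`. Deceased
#' subjects and subjects with phenotype `unknown` are `unphenotyped` in
#' every category; all other alive subjects that do not carry the
#' category's phenotype are controls (so, e.g., a neurological subject is a
#' control under the myxedematous category).
#'
#' @param x An `ech_cohort`.
#' @param category One of `"myxedematous"`, `"neurological"`, `"combined"`.
#' @return A named character vector (one element per individual, named by
#'   id) with values `"affected"`, `"control"`, `"unphenotyped"`.
#' @export
phenotype_mask <- function(x, category = c("combined", "myxedematous", "neurological")) {
  stopifnot(inherits(x, "ech_cohort"))
  category <- match.arg(category)
  myx <- c("myxedematous_severe", "myxedematous_moderate",
           "myxedematous_unknown_grade", "mixed")
  neu <- c("neurological", "deaf_mute")
  affected_set <- switch(category,
    myxedematous = myx,
    neurological = neu,
    combined = c(myx, neu)
  )
  ind <- x$individuals
  out <- rep("control", nrow(ind))
  out[ind$phenotype %in% affected_set] <- "affected"
  out[!ind$alive | ind$phenotype == "unknown"] <- "unphenotyped"
  stats::setNames(out, ind$id)
}

#' Per-family phenotyped and affected counts
#'
#' Tabulates, for each recorded family unit (parents included), the number
#' of phenotyped members and the number of affected members under a
#' phenotype category. These counts feed the per-family binomial
#' probability test and the cohort-level clustering test.
#'
#' @inheritParams phenotype_mask
#' @return A data.frame with columns `family_id`, `n_phenotyped`,
#'   `k_affected`, one row per family, in order of first appearance.
#' @export
family_counts <- function(x, category = c("combined", "myxedematous", "neurological")) {
  category <- match.arg(category)
  mask <- phenotype_mask(x, category)
  ind <- x$individuals
  fam <- factor(ind$family_id, levels = unique(ind$family_id))
  data.frame(
    family_id = levels(fam),
    n_phenotyped = as.integer(tapply(mask != "unphenotyped", fam, sum)),
    k_affected = as.integer(tapply(mask == "affected", fam, sum)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
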
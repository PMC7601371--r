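# Synthetic cohort generators.
#
# The defaults emulate the structure of the surveyed cohort: 62 family
# units (45 monogamous, 12 bigamous, 5 polygamous), sibship sizes 1..9
# drawn with the empirical frequencies of the 89 observed sibships, and a
# case prevalence of 46/468 (~10%). Parents are always unaffected
# controls with unrecorded ages.

# Empirical sibship-size distribution of the surveyed cohort (sizes 1..9).
REFERENCE_SIBSHIP_COUNTS <- c(19L, 15L, 19L, 11L, 10L, 4L, 6L, 3L, 2L)

#' Configuration for the synthetic cohort generator
#'
#' @param n_families Number of family units.
#' @param sibship_size_distribution Named numeric vector of probabilities
#'   over sibship sizes (names are the sizes); defaults to the empirical
#'   distribution of the surveyed cohort's 89 sibships.
#' @param prevalence Case prevalence among offspring, in (0, 1).
#' @param mechanism Affection mechanism: `"null_iid"` (independent
#'   Bernoulli(prevalence) per offspring), `"beta_binomial"` (per-sibship
#'   affection probability drawn from a Beta distribution with mean
#'   `prevalence` and intra-class correlation `rho`, offspring
#'   conditionally independent), or `"recessive"` (parental genotypes
#'   drawn at allele frequency `q`, offspring affected iff homozygous for
#'   the recessive allele; parents never express the phenotype).
#' @param rho Intra-family correlation for `beta_binomial`, in (0, 1).
#' @param q Recessive allele frequency for `recessive`, in (0, 1).
#' @param family_structure Probabilities of a family unit being
#'   monogamous (1 wife), bigamous (2 wives) or polygamous (4 wives);
#'   defaults to the surveyed 45/12/5 split.
#' @param seed Optional integer seed.
#' @return A list of class `ech_generator_config`.
#' @export
generator_config <- function(n_families = 62L,
                             sibship_size_distribution =
                               stats::setNames(REFERENCE_SIBSHIP_COUNTS / 89,
                                               1:9),
                             prevalence = 46 / 468,
                             mechanism = c("null_iid", "beta_binomial", "recessive"),
                             rho = 0.2,
                             q = 0.15,
                             family_structure = c(monogamous = 45 / 62,
                                                  bigamous = 12 / 62,
                                                  polygamous = 5 / 62),
                             seed = NULL) {
  mechanism <- match.arg(mechanism)
  sdist <- sibship_size_distribution
  if (is.null(names(sdist)) || anyNA(as.integer(names(sdist)))) {
    stop("sibship_size_distribution must be named by integer sizes")
  }
  if (any(sdist < 0) || abs(sum(sdist) - 1) > 1e-8) {
    stop("sibship size probabilities must be non-negative and sum to 1")
  }
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (any(family_structure < 0) || abs(sum(family_structure) - 1) > 1e-8) {
    stop("family structure probabilities must be non-negative and sum to 1")
  }
  structure(list(n_families = as.integer(n_families),
                 sibship_size_distribution = sdist,
                 prevalence = prevalence, mechanism = mechanism,
                 rho = rho, q = q,
                 family_structure = family_structure, seed = seed),
            class = "ech_generator_config")
}

#' Generate a synthetic cohort
#'
#' Draws family units (with 1, 2 or 4 wives according to the structure
#' probabilities), one sibship per wife with size from the configured
#' distribution, and offspring affection according to the configured
#' mechanism. Affected offspring are recorded with phenotype
#' `myxedematous_severe`; everyone is alive, ages and goitre are missing,
#' offspring sexes alternate deterministically.
#'
#' @param config An [generator_config()] object.
#' @return A validated [cohort()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ech_generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sizes <- as.integer(names(config$sibship_size_distribution))
  wives_per_type <- c(monogamous = 1L, bigamous = 2L, polygamous = 4L)
  nf <- config$n_families
  fam_ids <- sprintf("F%04d", seq_len(nf))
  n_wives <- wives_per_type[sample.int(3L, nf, replace = TRUE,
                                       prob = config$family_structure)]
  shape <- (1 - config$rho) / config$rho

  id <- fam <- fa <- mo <- sex <- pheno <- vector("list", nf)
  gt_id <- gt_val <- vector("list", nf)
  for (f in seq_len(nf)) {
    fam_id <- fam_ids[f]
    w <- n_wives[f]
    father <- paste0(fam_id, "_P0")
    mothers <- sprintf("%s_P%d", fam_id, seq_len(w))
    s <- sizes[sample.int(length(sizes), w, replace = TRUE,
                          prob = config$sibship_size_distribution)]
    kid_mother <- rep(mothers, s)
    kid_wife <- rep(seq_len(w), s)
    kid_rank <- sequence(s)
    kids <- sprintf("%s_W%d_C%d", fam_id, kid_wife, kid_rank)
    n_kids <- length(kids)
    affected <- switch(config$mechanism,
      null_iid = stats::rbinom(n_kids, 1L, config$prevalence) == 1L,
      beta_binomial = {
        pfam <- stats::rbeta(w, config$prevalence * shape,
                             (1 - config$prevalence) * shape)
        stats::rbinom(n_kids, 1L, rep(pfam, s)) == 1L
      },
      recessive = {
        father_gt <- stats::rbinom(1L, 2L, config$q)  # recessive allele count
        mother_gt <- stats::rbinom(w, 2L, config$q)
        gt_id[[f]] <- c(father, mothers)
        gt_val[[f]] <- c(father_gt, mother_gt)
        stats::rbinom(n_kids, 1L, father_gt / 2) +
          stats::rbinom(n_kids, 1L, rep(mother_gt, s) / 2) == 2L
      })
    id[[f]] <- c(father, mothers, kids)
    fam[[f]] <- rep.int(fam_id, 1L + w + n_kids)
    fa[[f]] <- c(rep(NA_character_, 1L + w), rep.int(father, n_kids))
    mo[[f]] <- c(rep(NA_character_, 1L + w), kid_mother)
    sex[[f]] <- c("male", rep.int("female", w),
                  ifelse(kid_rank %% 2L == 1L, "male", "female"))
    pheno[[f]] <- c(rep.int("unaffected", 1L + w),
                    ifelse(affected, "myxedematous_severe", "unaffected"))
  }
  ind <- data.frame(
    id = unlist(id), family_id = unlist(fam),
    father_id = unlist(fa), mother_id = unlist(mo),
    sex = unlist(sex), alive = TRUE, age_years = NA_real_,
    phenotype = unlist(pheno), goitre = NA_character_,
    stringsAsFactors = FALSE)
  out <- cohort(ind)
  if (config$mechanism == "recessive") {
    attr(out, "parent_genotypes") <-
      stats::setNames(unlist(gt_val), unlist(gt_id))
  }
  out
}

individual_row <- function(id, family_id, sex,
                           father_id = NA_character_,
                           mother_id = NA_character_,
                           phenotype = "unaffected",
                           alive = TRUE, age_years = NA_real_,
                           goitre = NA_character_) {
  data.frame(id = id, family_id = family_id, father_id = father_id,
             mother_id = mother_id, sex = sex, alive = alive,
             age_years = age_years, phenotype = phenotype, goitre = goitre,
             stringsAsFactors = FALSE)
}
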
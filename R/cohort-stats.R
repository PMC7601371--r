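# Sibship-level case distribution, recessive-model probabilities and
# descriptive comparisons.

#' Observed versus expected cases by sibship size
#'
#' Tabulates, for every sibship size present among the nuclear families:
#' the number of nuclear families of that size (`n_families`), how many of
#' them contain at least one affected living offspring
#' (`n_affected_families`), the observed number of affected living
#' offspring (`observed`), and the number expected under random,
#' independent affection at the given prevalence
#' (`expected = n_families * size * prevalence`).
#'
#' @param nuclear Nuclear-family table from [split_nuclear()].
#' @param mask Affection vector from [phenotype_mask()].
#' @param prevalence Disease prevalence in (0, 1).
#' @return A data.frame with columns `sibship_size`, `n_families`,
#'   `n_affected_families`, `observed`, `expected`, one row per size,
#'   increasing; class `ech_sibship_table`.
#' @export
sibship_table <- function(nuclear, mask, prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be a single number in (0, 1)")
  }
  keep <- nuclear$sibship_size >= 1L
  nuc <- nuclear[keep, , drop = FALSE]
  if (nrow(nuc) == 0L) stop("no nuclear family with living offspring")
  n_aff <- vapply(nuc$offspring_ids, function(ids) {
    sum(mask[ids] == "affected")
  }, 0L)
  size <- factor(nuc$sibship_size, levels = sort(unique(nuc$sibship_size)))
  out <- data.frame(
    sibship_size = as.integer(levels(size)),
    n_families = as.integer(table(size)),
    n_affected_families = as.integer(tapply(n_aff > 0L, size, sum)),
    observed = as.integer(tapply(n_aff, size, sum)),
    row.names = NULL
  )
  out$expected <- out$n_families * out$sibship_size * prevalence
  class(out) <- c("ech_sibship_table", "data.frame")
  out
}

#' Chi-squared test of the observed case distribution against random
#' allocation
#'
#' Pearson statistic over the sibship-size cells of a [sibship_table()]:
#' chi2 = sum (O_s - E_s)^2 / E_s, with S - 1 degrees of freedom for S
#' cells and an upper-tail chi-squared p-value.
#'
#' @param tab A sibship table from [sibship_table()].
#' @return A list with elements `chi2`, `df`, `p`.
#' @export
chi2_random_distribution <- function(tab) {
  O <- tab$observed
  E <- tab$expected
  if (any(E <= 0)) stop("all expected counts must be positive")
  chi2 <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Upper-tail probability under a Mendelian recessive model
#'
#' For a mating of two carrier parents each offspring is affected with
#' probability 1/4 independently; this returns the exact probability of
#' observing at least `k_min_affected` affected among `n_offspring`,
#' summing binomial terms directly (each term is an exact dyadic multiple
#' of a power of 3, so the sum is exact for small sibships).
#'
#' @param n_offspring Number of offspring.
#' @param k_min_affected Minimum number of affected offspring.
#' @return P(X >= k) with X ~ Binomial(n, 1/4).
#' @export
recessive_model_prob <- function(n_offspring, k_min_affected) {
  n <- n_offspring
  k <- k_min_affected
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 0, k >= 0)
  if (k > n) stop("k_min_affected cannot exceed n_offspring")
  if (k == 0L) return(1)
  j <- k:n
  sum(choose(n, j) * 0.25^j * 0.75^(n - j))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation of all hypergeometric table
#' probabilities not exceeding that of the observed table (the usual
#' mass-summation convention).
#'
#' @param a,b,c,d Cell counts, row-wise: matrix(c(a, c, b, d), 2).
#' @return The two-sided p-value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("empty table")
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L))$p.value
}

#' Descriptive comparison of affected and unaffected cohort members
#'
#' Compares cases and controls (combined phenotype, alive and phenotyped
#' subjects only) on sex, age and goitre: counts of males/females with a
#' Fisher exact p; counts of missing ages with a Fisher exact p; median
#' and interquartile range of age with a two-sided Mann-Whitney p; age
#' strata (<5, 5-18, >=18 years, the boundary 18 belonging to the upper
#' stratum) with a Fisher p for the >=18 split; missing goitre, any-form
#' and visible-form goitre proportions with Fisher p-values.
#'
#' @param x An `ech_cohort`.
#' @return A list of class `ech_cohort_summary` with components `sex`,
#'   `age_missing`, `age`, `age_strata`, `goitre_missing`, `goitre_any`,
#'   `goitre_visible`; count components carry a 2x2 `table`
#'   (rows affected/control) and `p`.
#' @export
cohort_summary <- function(x) {
  mask <- phenotype_mask(x, "combined")
  ind <- x$individuals
  grp <- list(affected = ind[mask == "affected", , drop = FALSE],
              control = ind[mask == "control", , drop = FALSE])

  tab2 <- function(f) {
    m <- t(vapply(grp, f, c(yes = 0, no = 0)))
    p <- if (sum(m) == 0) NA_real_ else fisher_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    list(table = m, p = p)
  }

  sex <- tab2(function(g) c(sum(g$sex == "male"), sum(g$sex == "female")))
  age_missing <- tab2(function(g) c(sum(is.na(g$age_years)), sum(!is.na(g$age_years))))

  ages <- lapply(grp, function(g) g$age_years[!is.na(g$age_years)])
  age <- list(
    median = vapply(ages, stats::median, 0),
    iqr = vapply(ages, function(a) {
      unname(diff(stats::quantile(a, c(0.25, 0.75))))
    }, 0),
    n = vapply(ages, length, 0L),
    p = if (all(lengths(ages) > 0L)) {
      suppressWarnings(stats::wilcox.test(ages$affected, ages$control)$p.value)
    } else NA_real_
  )
  strata <- t(vapply(ages, function(a) {
    c(under5 = sum(a < 5), mid = sum(a >= 5 & a < 18), over18 = sum(a >= 18))
  }, c(under5 = 0, mid = 0, over18 = 0)))
  age_strata <- list(
    table = strata,
    p_over18 = if (sum(strata) == 0) NA_real_ else {
      fisher_2x2(strata[1, 3], sum(strata[1, 1:2]),
                 strata[2, 3], sum(strata[2, 1:2]))
    }
  )

  goitre_missing <- tab2(function(g) c(sum(is.na(g$goitre)), sum(!is.na(g$goitre))))
  goitre_any <- tab2(function(g) {
    obs <- g$goitre[!is.na(g$goitre)]
    c(sum(obs != "absent"), sum(obs == "absent"))
  })
  goitre_visible <- tab2(function(g) {
    obs <- g$goitre[!is.na(g$goitre)]
    c(sum(obs == "visible"), sum(obs != "visible"))
  })

  structure(list(sex = sex, age_missing = age_missing, age = age,
                 age_strata = age_strata, goitre_missing = goitre_missing,
                 goitre_any = goitre_any, goitre_visible = goitre_visible),
            class = "ech_cohort_summary")
}

#' @export
print.ech_cohort_summary <- function(x, ...) {
  cat("Affected vs control comparison (combined phenotype)\n")
  show <- function(name, comp) {
    cat(sprintf("  %-16s M/yes: %d/%d  Fisher p = %.3g\n", name,
                comp$table[1, 1], comp$table[2, 1], comp$p))
  }
  show("sex (male)", x$sex)
  show("age missing", x$age_missing)
  cat(sprintf("  %-16s median %.1f vs %.1f  Mann-Whitney p = %.3g\n",
              "age", x$age$median[1], x$age$median[2], x$age$p))
  show("goitre missing", x$goitre_missing)
  show("goitre any", x$goitre_any)
  show("goitre visible", x$goitre_visible)
  invisible(x)
}
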
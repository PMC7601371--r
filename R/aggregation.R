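# Familial aggregation tests with Monte-Carlo null distributions.
#
# All Monte-Carlo p-values use the add-one estimator (k + 1) / (B + 1)
# (pooled variants: (k + 1) / (B * n + 1)); ties with the observed
# statistic count as exceedances. When no null draw reaches the observed
# statistic the estimate is flagged as an upper bound (`p_is_bound`), so
# that "p < 1/B"-style results are representable without claiming p = 0.

new_test_result <- function(unit_id, statistic, p, n_sims, exceedances,
                            p_is_bound = FALSE, degenerate = FALSE) {
  out <- data.frame(
    unit_id = as.character(unit_id),
    statistic = as.numeric(statistic),
    p = as.numeric(p),
    p_is_bound = as.logical(p_is_bound),
    p_adj = NA_real_,
    n_sims = as.integer(n_sims),
    exceedances = as.integer(exceedances),
    degenerate = as.logical(degenerate),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ech_test", "data.frame")
  out
}

#' @export
print.ech_test <- function(x, digits = 4, ...) {
  cat(sprintf("<ech_test> %d unit(s)\n", nrow(x)))
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, digits)
  df$p <- signif(df$p, digits)
  df$p_adj <- signif(df$p_adj, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-family binomial probability test
#'
#' For each family unit with `n` phenotyped members of whom `k` are
#' affected, computes the exact upper-tail binomial probability
#' P(X >= k) with X ~ Binomial(n, prevalence): the probability of
#' observing at least as many cases under random, independent affection at
#' the population prevalence. Deterministic (no simulation).
#'
#' @param counts A data.frame as returned by [family_counts()]
#'   (`family_id`, `n_phenotyped`, `k_affected`).
#' @param prevalence Disease prevalence in (0, 1); typically the number of
#'   affected over the number of phenotyped subjects in the cohort.
#' @return An `ech_test` data.frame, one row per family; `statistic` is the
#'   affected count.
#' @export
binomial_family_test <- function(counts, prevalence) {
  stopifnot(is.data.frame(counts),
            all(c("family_id", "n_phenotyped", "k_affected") %in% names(counts)))
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be a single number in (0, 1)")
  }
  n <- counts$n_phenotyped
  k <- counts$k_affected
  if (any(k < 0) || any(k > n)) stop("k_affected must lie in [0, n_phenotyped]")
  p <- stats::pbinom(k - 1, n, prevalence, lower.tail = FALSE)
  new_test_result(counts$family_id, statistic = k, p = p,
                  n_sims = 0L, exceedances = NA_integer_)
}

# Kinship sums of a set of individuals: for each member of `ids`, the sum
# of kinship with the other members.
kinship_sums <- function(phi, ids) {
  sub <- phi[ids, ids, drop = FALSE]
  rowSums(sub) - diag(sub)
}

# Scaled mean kinship over all unordered pairs of `ids`.
gif_statistic <- function(phi, ids) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 individuals for a mean pairwise kinship")
  sub <- phi[ids, ids, drop = FALSE]
  1e5 * (sum(sub) - sum(diag(sub))) / (n * (n - 1))
}

#' Kinship sum test
#'
#' Per-affected-individual test: the statistic for case i is the sum of
#' kinship coefficients between i and all other affected individuals, so
#' cases with affected close relatives score high. The null distribution is
#' built by resampling, `B` times, the observed number of cases uniformly
#' (without replacement) from all phenotyped individuals and recording the
#' resampled individuals' kinship sums. With `null = "pooled"` (default)
#' all B * n_affected resampled sums form one pooled null and
#' p_i = (1 + #\{pooled sums >= s_i\}) / (1 + B * n_affected); with
#' `null = "per_draw_max"` only each draw's maximum sum is kept and
#' p_i = (1 + #\{max sums >= s_i\}) / (B + 1).
#'
#' @param phi Kinship matrix from [kinship_matrix()].
#' @param mask Affection vector from [phenotype_mask()].
#' @param B Number of Monte-Carlo draws (default 1e6; reduce for desk-scale
#'   runs).
#' @param seed Optional integer seed for reproducibility.
#' @param null Null summarisation convention, see above.
#' @return An `ech_test` data.frame, one row per affected individual.
#' @export
kinship_sum_test <- function(phi, mask, B = 1e6, seed = NULL,
                             null = c("pooled", "per_draw_max")) {
  null <- match.arg(null)
  B <- check_B(B)
  aff <- names(mask)[mask == "affected"]
  phen <- names(mask)[mask != "unphenotyped"]
  if (length(aff) < 2L) stop("kinship sum test needs at least 2 affected individuals")
  if (!is.null(seed)) set.seed(seed)
  s_obs <- kinship_sums(phi, aff)
  n_aff <- length(aff)
  n_phen <- length(phen)
  pool <- if (null == "pooled") numeric(B * n_aff) else numeric(B)
  for (b in seq_len(B)) {
    draw <- phen[sample.int(n_phen, n_aff)]
    s <- kinship_sums(phi, draw)
    if (null == "pooled") {
      pool[((b - 1L) * n_aff + 1L):(b * n_aff)] <- s
    } else {
      pool[b] <- max(s)
    }
  }
  srt <- sort(pool)
  m <- length(srt)
  # exceedances: null values >= observed (ties conservative)
  exc <- m - findInterval(s_obs - 1e-12, srt)
  p <- (1 + exc) / (1 + m)
  new_test_result(aff, statistic = s_obs, p = p, n_sims = B,
                  exceedances = exc, p_is_bound = exc == 0L)
}

#' Genealogical index of familiality (cohort level)
#'
#' The statistic is 1e5 times the mean kinship coefficient over all
#' unordered pairs of affected individuals; large values indicate that
#' cases are more closely related than expected. The Monte-Carlo null
#' resamples the observed number of cases from all phenotyped individuals.
#'
#' @inheritParams kinship_sum_test
#' @return An `ech_test` data.frame with a single row (`unit_id`
#'   `"cohort"`).
#' @export
genealogical_index_test <- function(phi, mask, B = 1e6, seed = NULL) {
  B <- check_B(B)
  aff <- names(mask)[mask == "affected"]
  phen <- names(mask)[mask != "unphenotyped"]
  if (length(aff) < 2L) stop("genealogical index needs at least 2 affected individuals")
  if (!is.null(seed)) set.seed(seed)
  obs <- gif_statistic(phi, aff)
  n_aff <- length(aff)
  n_phen <- length(phen)
  exc <- 0L
  for (b in seq_len(B)) {
    g <- gif_statistic(phi, phen[sample.int(n_phen, n_aff)])
    if (g >= obs - 1e-12) exc <- exc + 1L
  }
  new_test_result("cohort", statistic = obs, p = (1 + exc) / (B + 1),
                  n_sims = B, exceedances = exc, p_is_bound = exc == 0L)
}

#' Genealogical index of familiality for a single family
#'
#' Same statistic as [genealogical_index_test()], restricted to one
#' family's affected members, with the null resampling the same number of
#' individuals from that family's phenotyped members only. In small
#' families the family-restricted null can collapse to a point mass (e.g.
#' when all phenotyped members are affected); the result is then flagged
#' `degenerate` and no p-value is reported.
#'
#' @inheritParams kinship_sum_test
#' @param families Named character vector mapping individual id to family
#'   id (e.g. `setNames(ind$family_id, ind$id)`).
#' @param family_id The family to test.
#' @return An `ech_test` data.frame with a single row.
#' @export
family_genealogical_index_test <- function(phi, mask, families, family_id,
                                           B = 1e6, seed = NULL) {
  B <- check_B(B)
  members <- names(families)[families == family_id]
  fmask <- mask[intersect(names(mask), members)]
  aff <- names(fmask)[fmask == "affected"]
  phen <- names(fmask)[fmask != "unphenotyped"]
  if (length(aff) < 2L) {
    stop("family ", family_id, " has fewer than 2 affected phenotyped members")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- gif_statistic(phi, aff)
  n_aff <- length(aff)
  n_phen <- length(phen)
  nulls <- numeric(B)
  for (b in seq_len(B)) {
    nulls[b] <- gif_statistic(phi, phen[sample.int(n_phen, n_aff)])
  }
  if (max(nulls) - min(nulls) < 1e-9) {
    return(new_test_result(family_id, statistic = obs, p = NA_real_,
                           n_sims = B, exceedances = NA_integer_,
                           degenerate = TRUE))
  }
  exc <- sum(nulls >= obs - 1e-12)
  new_test_result(family_id, statistic = obs, p = (1 + exc) / (B + 1),
                  n_sims = B, exceedances = exc, p_is_bound = exc == 0L)
}

#' Probability of familial clustering test
#'
#' Cohort-level test of whether cases concentrate in families more than
#' random allocation predicts. Under the null, the A case labels are
#' allocated uniformly at random among the N phenotyped individuals, so
#' the per-family case counts follow a multivariate hypergeometric law.
#' The statistic is the probability mass of the observed per-family
#' configuration under that law; the p-value is the (Monte-Carlo estimate
#' of the) total mass of configurations no more probable than the observed
#' one.
#'
#' @param counts A data.frame from [family_counts()].
#' @inheritParams kinship_sum_test
#' @return An `ech_test` data.frame with a single row (`unit_id`
#'   `"cohort"`); `statistic` is the log10 of the observed configuration
#'   mass.
#' @export
familial_clustering_test <- function(counts, B = 1e6, seed = NULL) {
  B <- check_B(B)
  n <- counts$n_phenotyped
  k <- counts$k_affected
  N <- sum(n)
  A <- sum(k)
  if (A < 1L) stop("clustering test needs at least 1 affected individual")
  if (A > N) stop("more affected than phenotyped individuals")
  if (!is.null(seed)) set.seed(seed)
  log_denom <- lchoose(N, A)
  obs_logmass <- sum(lchoose(n, k)) - log_denom
  # Draw per-family counts under the multivariate hypergeometric law by
  # sequential conditioning; vectorised across the B draws.
  a_rem <- rep.int(A, B)
  n_rem <- N
  logmass <- rep.int(-log_denom, B)
  for (f in seq_along(n)) {
    kf <- if (n_rem == n[f]) a_rem else stats::rhyper(B, n[f], n_rem - n[f], a_rem)
    logmass <- logmass + lchoose(n[f], kf)
    a_rem <- a_rem - kf
    n_rem <- n_rem - n[f]
  }
  exc <- sum(logmass <= obs_logmass + 1e-9)
  new_test_result("cohort", statistic = obs_logmass / log(10),
                  p = (1 + exc) / (B + 1),
                  n_sims = B, exceedances = exc, p_is_bound = exc == 0L)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the m p-values sorted
#' increasingly, p_adj(i) = min over j >= i of min(1, p(j) * m / j),
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Prevalence scenario sweep for the binomial family test
#'
#' Runs the per-family binomial probability test at each prevalence in
#' `prevalences`, adjusts across families by Benjamini-Hochberg, and
#' reports how many (and which) families remain significant at `alpha`.
#' Lower assumed prevalences make the same observed case counts more
#' surprising, so the count of significant families is non-increasing in
#' the prevalence.
#'
#' @param x An `ech_cohort`.
#' @param category Phenotype category, see [phenotype_mask()].
#' @param prevalences Numeric vector of prevalences in (0, 1).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return A data.frame with columns `prevalence`, `category`,
#'   `n_significant` and `family_ids` (comma-separated significant family
#'   ids).
#' @export
prevalence_scenarios <- function(x, category = "combined", prevalences,
                                 alpha = 0.05) {
  if (length(prevalences) == 0L) stop("empty prevalence list")
  if (any(prevalences <= 0 | prevalences >= 1)) {
    stop("prevalences must lie in (0, 1)")
  }
  counts <- family_counts(x, category)
  rows <- lapply(prevalences, function(pi) {
    res <- binomial_family_test(counts, pi)
    res$p_adj <- bh_adjust(res$p)
    sig <- res$unit_id[res$p_adj < alpha]
    data.frame(prevalence = pi, category = category,
               n_significant = length(sig),
               family_ids = paste(sig, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_B <- function(B) {
  if (!is.numeric(B) || length(B) != 1L || is.na(B) || B < 1) {
    stop("B must be a positive integer")
  }
  as.integer(B)
}
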
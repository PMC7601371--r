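# Shared fixtures and independent oracles for the test suite.

ind_row <- function(id, family_id = "F1", father_id = NA, mother_id = NA,
                    sex = "unknown", alive = TRUE, age_years = NA,
                    phenotype = "unaffected", goitre = NA) {
  if (length(id) == 0L) {
    return(ind_row("placeholder")[0L, , drop = FALSE])
  }
  data.frame(id = id, family_id = family_id,
             father_id = as.character(father_id),
             mother_id = as.character(mother_id),
             sex = sex, alive = alive, age_years = as.numeric(age_years),
             phenotype = phenotype, goitre = as.character(goitre),
             stringsAsFactors = FALSE)
}

# A monogamous nuclear family: parents fam_P0/fam_P1 plus n offspring
# fam_C1..fam_Cn, the first k affected (myxedematous_severe).
nuclear_family_rows <- function(fam, n, k = 0L) {
  rows <- rbind(ind_row(paste0(fam, "_P0"), fam, sex = "male"),
                ind_row(paste0(fam, "_P1"), fam, sex = "female"))
  for (j in seq_len(n)) {
    rows <- rbind(rows, ind_row(
      sprintf("%s_C%d", fam, j), fam,
      father_id = paste0(fam, "_P0"), mother_id = paste0(fam, "_P1"),
      phenotype = if (j <= k) "myxedematous_severe" else "unaffected"))
  }
  rows
}

# A cohort of monogamous family units given a matrix/list of (n, k) specs.
build_unit_cohort <- function(specs) {
  rows <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    nuclear_family_rows(sprintf("U%02d", i), specs[i, 1], specs[i, 2])
  }))
  cohort(rows)
}

# Three generations: grandparents GF/GM -> father FA (married-in mother MO)
# -> children C1, C2.
three_generation_rows <- function(fam = "T1") {
  rbind(ind_row("GF", fam, sex = "male"), ind_row("GM", fam, sex = "female"),
        ind_row("FA", fam, "GF", "GM", sex = "male"),
        ind_row("MO", fam, sex = "female"),
        ind_row("C1", fam, "FA", "MO"), ind_row("C2", fam, "FA", "MO"))
}

# First cousins: two sibs FA1/FA2 marry founders, one child each.
first_cousin_rows <- function() {
  rbind(ind_row("GF", sex = "male"), ind_row("GM", sex = "female"),
        ind_row("FA1", father_id = "GF", mother_id = "GM", sex = "male"),
        ind_row("FA2", father_id = "GF", mother_id = "GM", sex = "male"),
        ind_row("MO1", sex = "female"), ind_row("MO2", sex = "female"),
        ind_row("K1", father_id = "FA1", mother_id = "MO1"),
        ind_row("K2", father_id = "FA2", mother_id = "MO2"))
}

# Gene-dropping estimate of the kinship coefficient: founders carry unique
# allele labels, every child inherits one random allele from each parent,
# and phi(i, j) is estimated as the mean identity over the four possible
# cross-individual allele draws. Independent of the pedigree recursion.
gene_drop_phi <- function(ind, ndrops, seed = 1) {
  set.seed(seed)
  n <- nrow(ind)
  idx <- setNames(seq_len(n), ind$id)
  fa <- unname(idx[ind$father_id])
  mo <- unname(idx[ind$mother_id])
  A1 <- matrix(0L, n, ndrops)
  A2 <- matrix(0L, n, ndrops)
  placed <- logical(n)
  while (!all(placed)) {
    for (i in which(!placed)) {
      if (is.na(fa[i])) {
        A1[i, ] <- 2L * i - 1L
        A2[i, ] <- 2L * i
        placed[i] <- TRUE
      } else if (placed[fa[i]] && placed[mo[i]]) {
        pickf <- runif(ndrops) < 0.5
        A1[i, ] <- ifelse(pickf, A1[fa[i], ], A2[fa[i], ])
        pickm <- runif(ndrops) < 0.5
        A2[i, ] <- ifelse(pickm, A1[mo[i], ], A2[mo[i], ])
        placed[i] <- TRUE
      }
    }
  }
  phi_pair <- function(i, j) {
    x <- (A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
         (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])
    x / 4
  }
  list(estimate = function(i, j) {
    v <- phi_pair(idx[[i]], idx[[j]])
    c(mean = mean(v), se = stats::sd(v) / sqrt(ndrops))
  })
}

# Literal step-up Benjamini-Hochberg reference: sort, walk from the
# largest rank down taking running minima of p_(j) * m / j.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- 1
  for (j in m:1) {
    running <- min(running, sorted[j] * m / j)
    adj[j] <- running
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive enumeration oracles for the Monte-Carlo nulls: probability
# that a statistic of a uniformly drawn affected set reaches the observed
# value.
enumerate_subsets <- function(ids, k) {
  utils::combn(ids, k, simplify = FALSE)
}

# Pooled kinship-sum tail: fraction, over all subsets and subset members,
# of member kinship sums >= s.
oracle_kinship_sum_tail <- function(phi, phen_ids, n_aff, s) {
  subsets <- enumerate_subsets(phen_ids, n_aff)
  vals <- unlist(lapply(subsets, function(ids) {
    sub <- phi[ids, ids, drop = FALSE]
    rowSums(sub) - diag(sub)
  }))
  mean(vals >= s - 1e-12)
}

oracle_gif_tail <- function(phi, phen_ids, n_aff, obs) {
  subsets <- enumerate_subsets(phen_ids, n_aff)
  vals <- vapply(subsets, function(ids) {
    sub <- phi[ids, ids, drop = FALSE]
    1e5 * (sum(sub) - sum(diag(sub))) / (length(ids) * (length(ids) - 1))
  }, 0)
  mean(vals >= obs - 1e-12)
}

# Exact clustering-test p: enumerate every allocation of A case labels to
# the N phenotyped individuals and sum the (uniform) probability of the
# allocations whose per-family configuration mass does not exceed the
# observed one.
oracle_clustering_p <- function(fam_sizes, k_obs) {
  N <- sum(fam_sizes)
  A <- sum(k_obs)
  fam_label <- rep(seq_along(fam_sizes), fam_sizes)
  log_denom <- lchoose(N, A)
  logmass <- function(kk) sum(lchoose(fam_sizes, kk)) - log_denom
  obs <- logmass(k_obs)
  allocations <- utils::combn(N, A, simplify = FALSE)
  hits <- vapply(allocations, function(sel) {
    kk <- tabulate(fam_label[sel], nbins = length(fam_sizes))
    logmass(kk) <= obs + 1e-9
  }, TRUE)
  mean(hits)
}

# 99% CI half-width for comparing a Monte-Carlo tail estimate against its
# enumerated limit q, at B draws (plus the add-one estimator offset).
mc_ci <- function(q, B) 2.576 * sqrt(q * (1 - q) / B) + 2 / B
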
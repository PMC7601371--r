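# End-to-end analysis driver: runs every aggregation test on a cohort,
# applies BH correction per test and category, sweeps prevalence
# scenarios, and (optionally) re-runs after excluding families.

#' Analysis run configuration
#'
#' @param ped_path,phenotype_path Input pedigree files; ignored when
#'   `use_reference = TRUE`.
#' @param use_reference Use the deterministic [reference_cohort()] instead
#'   of reading files.
#' @param categories Phenotype categories to analyse.
#' @param B Monte-Carlo draws for the resampling tests. The default 1e5 is
#'   a desk-scale profile; set 1e6 for a full-scale run.
#' @param seed Integer seed used for all resampling.
#' @param alpha BH-adjusted significance threshold.
#' @param prevalence Prevalence override; default (`NULL`) uses
#'   affected / phenotyped per category.
#' @param scenario_prevalences Prevalences for the binomial-test scenario
#'   sweep (in addition to the observed one).
#' @param exclude_families Family ids to drop in a sensitivity re-run.
#' @param out_dir Output directory for TSV tables and the log (`NULL` for
#'   no file output).
#' @return A list of class `ech_run_config`.
#' @export
run_config <- function(ped_path = NULL, phenotype_path = NULL,
                       use_reference = is.null(ped_path),
                       categories = c("combined", "myxedematous", "neurological"),
                       B = 1e5, seed = 1L, alpha = 0.05,
                       prevalence = NULL,
                       scenario_prevalences = c(0.02, 0.05, 0.07),
                       exclude_families = character(0),
                       out_dir = NULL) {
  stopifnot(B >= 1, alpha > 0, alpha < 1)
  categories <- match.arg(categories, several.ok = TRUE)
  structure(list(ped_path = ped_path, phenotype_path = phenotype_path,
                 use_reference = use_reference, categories = categories,
                 B = as.integer(B), seed = as.integer(seed), alpha = alpha,
                 prevalence = prevalence,
                 scenario_prevalences = scenario_prevalences,
                 exclude_families = as.character(exclude_families),
                 out_dir = out_dir),
            class = "ech_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Accepts the fields of [run_config()] as top-level YAML keys.
#'
#' @param path Path to a YAML file.
#' @return An `ech_run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full familial-aggregation analysis
#'
#' For each requested phenotype category: the sibship table with its
#' chi-squared test against random case allocation, the per-family
#' binomial probability test, the kinship sum test, the cohort and
#' per-family genealogical index tests, the familial clustering test
#' (BH adjustment applied per test across its units), the prevalence
#' scenario sweep, and a per-nuclear-family size-versus-cases table. A
#' descriptive affected/control summary is computed for the combined
#' category. When `exclude_families` is set the binomial and kinship sum
#' tests are re-run on the reduced cohort. Identical configurations
#' (including `seed`) give identical results.
#'
#' @param config An [run_config()] object.
#' @return A list of class `ech_report` with one element per category plus
#'   `cohort`, `summary`, `log`, and (if requested) `sensitivity`.
#' @export
run_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "ech_run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- c(
    sprintf("echagg %s | R %s.%s", as.character(utils::packageVersion("echagg")),
            R.version$major, R.version$minor),
    sprintf("seed=%d B=%d alpha=%g", config$seed, config$B, config$alpha))
  if (length(config$categories) == 0L) {
    message("no phenotype categories requested; nothing to do")
    return(invisible(structure(list(log = log_lines), class = "ech_report")))
  }
  coh <- if (isTRUE(config$use_reference)) {
    reference_cohort()
  } else {
    read_pedigree(config$ped_path, config$phenotype_path)
  }
  phi <- kinship_matrix(coh)
  fam_of <- stats::setNames(coh$individuals$family_id, coh$individuals$id)

  bundle <- list(cohort = coh)
  for (cat_i in seq_along(config$categories)) {
    category <- config$categories[cat_i]
    bundle[[category]] <- analyse_category(coh, phi, fam_of, category, config)
  }
  bundle$summary <- cohort_summary(coh)

  if (length(config$exclude_families) > 0L) {
    keep <- !(coh$individuals$family_id %in% config$exclude_families)
    sub <- cohort(coh$individuals[keep, , drop = FALSE])
    sub_phi <- kinship_matrix(sub)
    sens <- list()
    for (category in config$categories) {
      mask <- phenotype_mask(sub, category)
      if (sum(mask == "affected") < 2L) next
      pi_hat <- prevalence_of(mask, config$prevalence)
      counts <- family_counts(sub, category)
      bt <- binomial_family_test(counts, pi_hat)
      bt$p_adj <- bh_adjust(bt$p)
      ks <- kinship_sum_test(sub_phi, mask, B = config$B,
                             seed = config$seed + 1000L)
      ks$p_adj <- bh_adjust(ks$p)
      sens[[category]] <- list(
        binomial = bt, kinship_sum = ks,
        significant_families = bt$unit_id[bt$p_adj < config$alpha],
        significant_individuals = ks$unit_id[ks$p_adj < config$alpha])
    }
    bundle$sensitivity <- sens
  }

  log_lines <- c(log_lines,
                 sprintf("elapsed=%.1fs", proc.time()[["elapsed"]] - t0))
  bundle$log <- log_lines
  class(bundle) <- "ech_report"
  if (!is.null(config$out_dir)) write_report(bundle, config)
  invisible(bundle)
}

prevalence_of <- function(mask, override = NULL) {
  if (!is.null(override)) return(override)
  sum(mask == "affected") / sum(mask != "unphenotyped")
}

analyse_category <- function(coh, phi, fam_of, category, config) {
  mask <- phenotype_mask(coh, category)
  n_aff <- sum(mask == "affected")
  pi_hat <- prevalence_of(mask, config$prevalence)
  counts <- family_counts(coh, category)

  sib <- sibship_table(coh$nuclear, mask, pi_hat)
  chi2 <- chi2_random_distribution(sib)

  bt <- binomial_family_test(counts, pi_hat)
  bt$p_adj <- bh_adjust(bt$p)

  fig_data <- data.frame(nf_id = coh$nuclear$nf_id,
                         family_id = coh$nuclear$family_id,
                         sibship_size = coh$nuclear$sibship_size,
                         n_affected = vapply(coh$nuclear$offspring_ids,
                                             function(ids) sum(mask[ids] == "affected"),
                                             0L))

  out <- list(category = category, prevalence = pi_hat,
              n_affected = n_aff, sibship_table = sib, chi2 = chi2,
              binomial = bt, family_scatter = fig_data)

  if (n_aff >= 2L) {
    ks <- kinship_sum_test(phi, mask, B = config$B, seed = config$seed)
    ks$p_adj <- bh_adjust(ks$p)
    out$kinship_sum <- ks
    out$genealogical_index <-
      genealogical_index_test(phi, mask, B = config$B, seed = config$seed)
    fam_aff <- counts$family_id[counts$k_affected >= 2L]
    if (length(fam_aff) > 0L) {
      out$family_genealogical_index <- do.call(rbind, lapply(fam_aff, function(f) {
        family_genealogical_index_test(phi, mask, fam_of, f,
                                       B = config$B, seed = config$seed)
      }))
    }
  }
  if (sum(counts$k_affected) >= 1L) {
    out$clustering <- familial_clustering_test(counts, B = config$B,
                                               seed = config$seed)
  }
  out$scenarios <- prevalence_scenarios(
    coh, category, unique(c(pi_hat, config$scenario_prevalences)),
    alpha = config$alpha)
  out$significant_families <- bt$unit_id[bt$p_adj < config$alpha]
  out
}

write_report <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  for (category in config$categories) {
    res <- bundle[[category]]
    if (is.null(res)) next
    tsv(res$sibship_table, sprintf("sibship_table_%s.tsv", category))
    tsv(res$family_scatter, sprintf("family_scatter_%s.tsv", category))
    tsv(res$scenarios, sprintf("scenarios_%s.tsv", category))
    tests <- list(binomial = res$binomial, kinship_sum = res$kinship_sum,
                  genealogical_index = res$genealogical_index,
                  family_genealogical_index = res$family_genealogical_index,
                  clustering = res$clustering)
    rows <- lapply(names(tests), function(nm) {
      tt <- tests[[nm]]
      if (is.null(tt)) return(NULL)
      data.frame(unit_id = tt$unit_id, category = category, test = nm,
                 statistic = tt$statistic, p = tt$p,
                 p_is_bound = tt$p_is_bound, p_adj = tt$p_adj,
                 B = tt$n_sims, exceedances = tt$exceedances,
                 degenerate = tt$degenerate, seed = config$seed)
    })
    tsv(do.call(rbind, rows), sprintf("test_results_%s.tsv", category))
  }
  writeLines(bundle$log, file.path(config$out_dir, "run.log"))
  invisible(NULL)
}

#' @export
print.ech_report <- function(x, ...) {
  cat("<ech_report>\n")
  for (nm in intersect(c("combined", "myxedematous", "neurological"), names(x))) {
    res <- x[[nm]]
    cat(sprintf("  %s: %d affected, prevalence %.4f, chi2 %.2f (df %d, p %.3g)\n",
                nm, res$n_affected, res$prevalence, res$chi2$chi2,
                res$chi2$df, res$chi2$p))
    cat(sprintf("    binomial-significant families: %s\n",
                if (length(res$significant_families) > 0L)
                  paste(res$significant_families, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Scatter of affected versus living offspring per nuclear family
#'
#' Cosmetic companion plot to the sibship analysis: one jittered point per
#' nuclear family, with reference lines for the expected case count under
#' random affection at the given prevalence and under a Mendelian
#' recessive model (25% per offspring).
#'
#' @param x An `ech_cohort`.
#' @param category Phenotype category.
#' @param prevalence Prevalence for the random-affection reference line.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data.frame.
#' @export
plot_family_scatter <- function(x, category = "combined",
                                prevalence = NULL, ...) {
  mask <- phenotype_mask(x, category)
  prevalence <- prevalence_of(mask, prevalence)
  nuc <- x$nuclear[x$nuclear$sibship_size >= 1L, , drop = FALSE]
  n_aff <- vapply(nuc$offspring_ids, function(ids) sum(mask[ids] == "affected"), 0L)
  set.seed(0)
  graphics::plot(jitter(nuc$sibship_size, 0.3), jitter(n_aff, 0.3),
                 xlab = "living offspring", ylab = "affected offspring", ...)
  graphics::abline(0, prevalence, lty = 2)
  graphics::abline(0, 0.25, lty = 1)
  invisible(data.frame(sibship_size = nuc$sibship_size, n_affected = n_aff))
}
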
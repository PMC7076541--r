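#' Run the full diallel analysis pipeline and write a report bundle
#'
#' Orchestrates every stage on one data set: distributional QC,
#' per-environment ANOVA with Griffing effects and rankings, the combined
#' ANOVA, variance components and heritabilities, heterosis tables and
#' the hybrids-vs-parents contrast (when selfed parents are present), GGE
#' biplot coordinates per environment, and — when a genetic-distance
#' matrix is supplied — Euclidean/cross-statistic matrices with Mantel
#' tests. One CSV per result table is written to `out_dir`; the bundle is
#' a pure function of the inputs and the seed, so a rerun reproduces it
#' byte for byte.
#'
#' @param records Long phenotype records, or a path to a phenotype CSV.
#' @param design A [diallel_design()].
#' @param out_dir Output directory (created if needed).
#' @param genetic_distance Optional `diallel_dist` matrix (or CSV path)
#'   of parental genetic distances for the Mantel stage.
#' @param traits Traits to analyse; defaults to all present.
#' @param n_perm Mantel permutations.
#' @param seed Seed recorded in the run log and used for the Mantel stage.
#' @param f GGE singular-value partition exponent.
#' @return Invisibly, a named list with every computed object.
#' @export
run_diallel_pipeline <- function(records, design, out_dir,
                                 genetic_distance = NULL,
                                 traits = NULL, n_perm = 10000,
                                 seed = 1, f = 0.5) {
  if (is.character(records)) {
    records <- read_phenotype(records, design)
  }
  if (is.character(genetic_distance)) {
    genetic_distance <- read_distance_matrix(genetic_distance)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traits <- traits %||% unique(records$trait)
  envs <- intersect(design$environments, unique(records$env))
  results <- list()
  emit <- function(tbl, name) {
    readr::write_csv(tibble::as_tibble(tbl), file.path(out_dir,
                                                       paste0(name, ".csv")),
                     progress = FALSE)
  }

  qc <- qc_normality(records)
  results$qc <- qc
  emit(dplyr::select(qc, -"qq"), "qc_normality")

  has_selfs <- any(records$parent_a == records$parent_b)

  for (trait in traits) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(paste0("Stage '", what, "' failed for trait '", trait,
                     "': ", conditionMessage(e)))
      })
    }
    tr_envs <- intersect(envs,
                         unique(records$env[records$trait == trait]))
    direction <- trait_direction(design, trait)
    per_env <- list()
    for (e in tr_envs) {
      an <- stage("anova", anova_single_env(records, design, trait, e))
      m <- entry_means(records, design, trait, e)
      eff <- griffing_effects(m, anova = an)
      rk <- rank_effects(eff, direction)
      vc <- variance_components(an)
      per_env[[e]] <- list(anova = an, means = m, effects = eff,
                           ranks = rk, varcomp = vc)
      emit(tidy(an), paste0("anova_", trait, "_", e))
      emit(tidy(eff), paste0("effects_", trait, "_", e))
      emit(rk$gca, paste0("gca_ranking_", trait, "_", e))
      emit(tidy(vc), paste0("varcomp_", trait, "_", e))
      if (has_selfs) {
        het <- stage("heterosis",
                     heterosis_table(records, design, trait, e,
                                     direction = direction))
        con <- stage("contrast",
                     parents_vs_hybrids(records, design, trait, e))
        gge <- stage("gge", gge_biplot(
          entry_means(records, method2_view(design), trait, e), f = f))
        per_env[[e]]$heterosis <- het
        per_env[[e]]$contrast <- con
        per_env[[e]]$gge <- gge
        emit(het, paste0("heterosis_", trait, "_", e))
        emit(con, paste0("contrast_", trait, "_", e))
        emit(tidy(gge), paste0("gge_scores_", trait, "_", e))
        emit(gge$projections, paste0("gge_atc_", trait, "_", e))
      }
    }
    combined <- NULL
    if (length(tr_envs) >= 2) {
      an_c <- stage("combined anova", anova_combined(records, design, trait))
      vc_c <- variance_components(an_c)
      combined <- list(anova = an_c, varcomp = vc_c)
      emit(tidy(an_c), paste0("anova_combined_", trait))
      emit(tidy(vc_c), paste0("varcomp_combined_", trait))
    }
    results[[trait]] <- list(per_env = per_env, combined = combined)
  }

  if (!is.null(genetic_distance) && has_selfs) {
    mantel_rows <- list()
    for (trait in traits) {
      for (e in intersect(envs,
                          unique(records$env[records$trait == trait]))) {
        m <- entry_means(records, method2_view(design), trait, e)
        lsm <- tidy(m)
        lsm <- lsm[lsm$parent_a != lsm$parent_b, ]
        cmat <- cross_statistic_matrix(lsm, design, value = "mean")
        mt <- mantel_test(cmat, align_labels(genetic_distance, design),
                          n_perm = n_perm, seed = seed)
        mantel_rows[[paste(trait, e)]] <-
          dplyr::mutate(glance(mt), trait = trait, env = e,
                        statistic = "LsM", .before = 1)
      }
    }
    mantel_tbl <- dplyr::bind_rows(mantel_rows)
    results$mantel <- mantel_tbl
    emit(mantel_tbl, "mantel_tests")
  }

  run_info <- tibble::tibble(
    seed = seed, n_perm = n_perm, f = f,
    traits = paste(traits, collapse = ";"),
    environments = paste(envs, collapse = ";"),
    package_version = as.character(utils::packageVersion("diallelr"))
  )
  emit(run_info, "run_info")
  invisible(results)
}

method2_view <- function(design) {
  design$method <- "method2"
  design
}

align_labels <- function(m, design) {
  keep <- intersect(design$parents, rownames(m))
  if (length(keep) != length(design$parents)) {
    abort("Genetic-distance matrix does not cover all parents.")
  }
  unclass(m)[design$parents, design$parents]
}
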
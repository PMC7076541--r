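#' Single-environment diallel analysis of variance
#'
#' Fits the fixed-genotype RCBD ANOVA for one trait in one environment and
#' partitions the entry sum of squares into its GCA and SCA components
#' with Griffing's sums of squares computed from entry means scaled by the
#' replicate count. All F ratios are taken against the plot-error mean
#' square (genotypes fixed, replicates random).
#'
#' @param records Long phenotype records.
#' @param design A [diallel_design()].
#' @param trait Trait to analyse.
#' @param environment Environment to analyse.
#' @return A `diallel_anova` tibble with columns `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value` and rows Blocks, Entries, GCA, SCA,
#'   Error, Total. Attributes record `p`, `r`, `n_env`, `method`, `scope`.
#' @export
anova_single_env <- function(records, design, trait, environment) {
  sub <- records[records$trait == trait & records$env == environment, ]
  if (nrow(sub) == 0) {
    abort(paste0("No records for '", trait, "' in '", environment, "'."))
  }
  require_balanced(sub, design, trait, environment)
  pieces <- rcbd_pieces(sub, design, trait, environment)
  p <- length(design$parents)
  r <- design$n_blocks
  n <- n_entries(design)
  df <- c(Blocks = r - 1, Entries = n - 1, GCA = p - 1,
          SCA = sca_df(design), Error = (n - 1) * (r - 1),
          Total = n * r - 1)
  ss <- c(Blocks = pieces$ss_blocks, Entries = pieces$ss_entries,
          GCA = pieces$ss_gca, SCA = pieces$ss_sca,
          Error = pieces$ss_error, Total = pieces$ss_total)
  finish_anova(df, ss, p = p, r = r, n_env = 1L, method = design$method,
               scope = "single", trait = trait, environment = environment)
}

#' Combined multi-environment diallel analysis of variance
#'
#' Pools the balanced single-environment RCBD analyses across
#' environments: main-effect entry, GCA and SCA sums of squares come from
#' the Griffing partition of the across-environment entry means (scaled by
#' `r x E`), and each interaction sum of squares is the sum of the
#' within-environment partitions minus the corresponding main effect.
#' Every F ratio uses the pooled plot-error mean square, reproducing the
#' fixed-genotype layout of multi-environment diallel reports.
#'
#' @inheritParams anova_single_env
#' @return A `diallel_anova` tibble with rows Environments, Blocks(Env),
#'   Entries, GCA, SCA, Env x Entries, Env x GCA, Env x SCA, Error, Total.
#' @export
anova_combined <- function(records, design, trait) {
  sub <- records[records$trait == trait, ]
  envs <- intersect(design$environments, unique(sub$env))
  E <- length(envs)
  if (E < 2) abort("The combined ANOVA needs at least 2 environments.")
  require_balanced(sub, design, trait, envs)
  p <- length(design$parents)
  r <- design$n_blocks
  n <- n_entries(design)

  per_env <- purrr::map(envs, function(e) {
    rcbd_pieces(sub[sub$env == e, ], design, trait, e)
  })
  grand <- mean(sub$value)
  env_means <- purrr::map_dbl(per_env, "env_mean")
  ss_env <- n * r * sum((env_means - grand)^2)
  ss_blocks <- sum(purrr::map_dbl(per_env, "ss_blocks"))
  ss_error <- sum(purrr::map_dbl(per_env, "ss_error"))
  ss_total <- sum((sub$value - grand)^2)

  pooled_means <- entry_means(sub, design, trait, environment = NULL,
                              check_balance = FALSE)
  main <- griffing_ss(pooled_means, design, scale = r * E)
  ss_entries_w <- sum(purrr::map_dbl(per_env, "ss_entries"))
  ss_gca_w <- sum(purrr::map_dbl(per_env, "ss_gca"))
  ss_sca_w <- sum(purrr::map_dbl(per_env, "ss_sca"))

  df_sca <- sca_df(design)
  df <- c(Environments = E - 1, `Blocks(Env)` = E * (r - 1),
          Entries = n - 1, GCA = p - 1, SCA = df_sca,
          `Env x Entries` = (E - 1) * (n - 1),
          `Env x GCA` = (E - 1) * (p - 1),
          `Env x SCA` = (E - 1) * df_sca,
          Error = E * (n - 1) * (r - 1),
          Total = E * n * r - 1)
  ss <- c(Environments = ss_env, `Blocks(Env)` = ss_blocks,
          Entries = main$entries, GCA = main$gca, SCA = main$sca,
          `Env x Entries` = ss_entries_w - main$entries,
          `Env x GCA` = ss_gca_w - main$gca,
          `Env x SCA` = ss_sca_w - main$sca,
          Error = ss_error, Total = ss_total)
  finish_anova(df, ss, p = p, r = r, n_env = E, method = design$method,
               scope = "combined", trait = trait, environment = envs)
}

# Per-environment RCBD sums of squares plus the Griffing partition of the
# entry SS. Interaction-friendly: entry/GCA/SCA SS are computed about the
# environment's own mean.
rcbd_pieces <- function(sub, design, trait, environment) {
  r <- design$n_blocks
  n <- n_entries(design)
  env_mean <- mean(sub$value)
  block_means <- tapply(sub$value, sub$block, mean)
  ss_blocks <- n * sum((block_means - env_mean)^2)
  m <- entry_means(sub, design, trait, environment, check_balance = FALSE)
  gp <- griffing_ss(m, design, scale = r)
  ss_total <- sum((sub$value - env_mean)^2)
  # the residual is a difference of sums of squares; guard the tiny
  # negative values floating point can produce on noise-free data
  ss_error <- max(ss_total - ss_blocks - gp$entries, 0)
  list(env_mean = env_mean, ss_blocks = ss_blocks,
       ss_entries = gp$entries, ss_gca = gp$gca, ss_sca = gp$sca,
       ss_error = ss_error, ss_total = ss_total)
}

# Griffing sums of squares on the entry-mean basis, times `scale`
# (r for one environment, r*E for the across-environment means).
griffing_ss <- function(m, design, scale) {
  p <- nrow(m)
  m0 <- unclass(m)
  if (design$method == "method4") {
    xi <- cross_row_totals(m)
    xx <- sum(xi) / 2
    vals <- m0[upper.tri(m0)]
    gca <- scale * (sum(xi^2) / (p - 2) - 4 * xx^2 / (p * (p - 2)))
    sca <- scale * (sum(vals^2) - sum(xi^2) / (p - 2) +
                      2 * xx^2 / ((p - 1) * (p - 2)))
    entries <- scale * (sum(vals^2) - xx^2 / (p * (p - 1) / 2))
  } else {
    yi <- rowSums(m0)
    yy <- (sum(m0) + sum(diag(m0))) / 2
    row_stat <- yi + diag(m0)
    vals <- m0[upper.tri(m0, diag = TRUE)]
    gca <- scale * (sum(row_stat^2) - 4 * yy^2 / p) / (p + 2)
    sca <- scale * (sum(vals^2) - sum(row_stat^2) / (p + 2) +
                      2 * yy^2 / ((p + 1) * (p + 2)))
    entries <- scale * (sum(vals^2) - yy^2 / (p * (p + 1) / 2))
  }
  list(entries = entries, gca = gca, sca = sca)
}

sca_df <- function(design) {
  p <- length(design$parents)
  if (design$method == "method4") p * (p - 3) / 2 else p * (p - 1) / 2
}

finish_anova <- function(df, ss, p, r, n_env, method, scope,
                         trait = NULL, environment = NULL) {
  ms <- ss / df
  me <- ms[["Error"]]
  dfe <- df[["Error"]]
  terms <- names(df)
  f <- ifelse(terms %in% c("Error", "Total"), NA_real_, ms / me)
  pv <- ifelse(is.na(f), NA_real_, pf(f, df, dfe, lower.tail = FALSE))
  out <- tibble::tibble(term = terms, df = unname(df), sumsq = unname(ss),
                        meansq = unname(ms), statistic = unname(f),
                        p.value = unname(pv))
  new_diallel_anova(out, p = p, r = r, n_env = n_env, method = method,
                    scope = scope, trait = trait, environment = environment)
}

new_diallel_anova <- function(tbl, p, r, n_env, method, scope,
                              trait = NULL, environment = NULL) {
  structure(tbl,
            class = c("diallel_anova", class(tibble::tibble())),
            p = p, r = r, n_env = n_env, method = method, scope = scope,
            trait = trait, environment = environment)
}

#' Assemble a diallel ANOVA table from published mean squares
#'
#' Builds a `diallel_anova` object from a data frame of source names and
#' mean squares (for example, the numbers printed in a trial report), so
#' that downstream stages — variance components, heritabilities, standard
#' errors for effects and heterosis — can be computed without the raw plot
#' data. Degrees of freedom are filled in from the design structure unless
#' a `df` column is supplied.
#'
#' @param data Data frame with columns `term` and `meansq`, optionally
#'   `df`. Recognised terms: Environments, Entries, GCA, SCA,
#'   Env x Entries, Env x GCA, Env x SCA, Error.
#' @param p Number of parents.
#' @param r Replicates.
#' @param n_env Number of environments (1 for a single-environment table).
#' @param method `"method4"` or `"method2"`.
#' @return A `diallel_anova` tibble.
#' @examples
#' # a yield ANOVA known only through its printed mean squares
#' ms <- data.frame(term = c("GCA", "SCA", "Error"),
#'                  meansq = c(32.12, 3.52, 2.83))
#' as_diallel_anova(ms, p = 8, r = 3)
#' @export
as_diallel_anova <- function(data, p, r, n_env = 1,
                             method = c("method4", "method2")) {
  method <- match.arg(method)
  if (!all(c("term", "meansq") %in% names(data))) {
    abort("`data` needs columns `term` and `meansq`.")
  }
  design_stub <- list(parents = paste0("P", seq_len(p)), method = method)
  n <- if (method == "method4") p * (p - 1) / 2 else p * (p + 1) / 2
  df_sca <- if (method == "method4") p * (p - 3) / 2 else p * (p - 1) / 2
  E <- n_env
  df_map <- c(Environments = E - 1, `Blocks(Env)` = E * (r - 1),
              Blocks = r - 1, Entries = n - 1, GCA = p - 1, SCA = df_sca,
              `Env x Entries` = (E - 1) * (n - 1),
              `Env x GCA` = (E - 1) * (p - 1),
              `Env x SCA` = (E - 1) * df_sca,
              Error = E * (n - 1) * (r - 1))
  unknown <- setdiff(data$term, names(df_map))
  if (length(unknown) > 0) {
    abort(paste0("Unknown ANOVA term(s): ", paste(unknown, collapse = ", ")))
  }
  df <- if ("df" %in% names(data)) data$df else unname(df_map[data$term])
  ms <- data$meansq
  me <- ms[data$term == "Error"]
  dfe <- df[data$term == "Error"]
  f <- pv <- rep(NA_real_, nrow(data))
  if (length(me) == 1) {
    f <- ifelse(data$term == "Error", NA_real_, ms / me)
    pv <- ifelse(is.na(f), NA_real_, pf(f, df, dfe, lower.tail = FALSE))
  }
  out <- tibble::tibble(term = data$term, df = df,
                        sumsq = ms * df, meansq = ms,
                        statistic = f, p.value = pv)
  new_diallel_anova(out, p = p, r = r, n_env = n_env, method = method,
                    scope = if (n_env > 1) "combined" else "single")
}

error_mean_square <- function(anova) {
  me <- anova$meansq[anova$term == "Error"]
  if (length(me) != 1) abort("ANOVA table has no Error row.")
  me
}

error_df <- function(anova) {
  anova$df[anova$term == "Error"]
}

ms_of <- function(anova, term) {
  v <- anova$meansq[anova$term == term]
  if (length(v) != 1) {
    abort(paste0("ANOVA table is missing the '", term, "' row."))
  }
  v
}

#' @method tidy diallel_anova
#' @export
tidy.diallel_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance diallel_anova
#' @export
glance.diallel_anova <- function(x, ...) {
  me <- error_mean_square(x)
  r <- attr(x, "r")
  tibble::tibble(
    scope = attr(x, "scope"), method = attr(x, "method"),
    p = attr(x, "p"), r = r, n_env = attr(x, "n_env"),
    error_ms = me, error_df = error_df(x),
    # nominal standard error of an entry mean under the RCBD model
    se_entry_mean = sqrt(me / r)
  )
}

#' Orthogonal contrast of hybrids versus parents
#'
#' Tests whether the pool of F1 hybrids differs from the pool of selfed
#' parents in one environment: the estimate is the difference of the two
#' pool means of entry means, its standard error
#' `sqrt(Me (1/n_h + 1/n_p) / r)` uses the RCBD error mean square over all
#' entries, and a significant difference indicates average heterosis
#' (negative for traits where hybrids ripen or mature earlier).
#'
#' @param records Long phenotype records including selfed parents.
#' @param design A [diallel_design()]; its parent set defines the pools.
#' @param trait,environment Trait and environment to test.
#' @param anova Optional `diallel_anova` supplying the error mean square;
#'   by default the method-2 RCBD ANOVA of the same data is used.
#' @return A one-row tibble: `estimate`, `std.error`, `statistic`, `df`,
#'   `p.value`, `n_hybrids`, `n_parents`.
#' @export
parents_vs_hybrids <- function(records, design, trait, environment,
                               anova = NULL) {
  sub <- records[records$trait == trait & records$env == environment, ]
  if (!any(sub$parent_a == sub$parent_b)) {
    abort("No selfed-parent records; the contrast needs both pools.")
  }
  design2 <- design
  design2$method <- "method2"
  m <- entry_means(sub, design2, trait, environment)
  if (is.null(anova)) {
    anova <- anova_single_env(sub, design2, trait, environment)
  }
  me <- error_mean_square(anova)
  dfe <- error_df(anova)
  r <- design$n_blocks
  hyb <- m[upper.tri(m)]
  par <- diag(m)
  est <- mean(hyb) - mean(par)
  se <- sqrt(me * (1 / length(hyb) + 1 / length(par)) / r)
  t <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  tibble::tibble(
    estimate = est, std.error = se, statistic = t, df = dfe,
    p.value = 2 * pt(abs(t), dfe, lower.tail = FALSE),
    n_hybrids = length(hyb), n_parents = length(par)
  )
}
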
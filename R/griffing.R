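#' Griffing combining-ability effects from a diallel table
#'
#' Decomposes a table of entry means into the grand mean, general
#' combining-ability (GCA) effects `g_i` and specific combining-ability
#' (SCA) effects `s_ij`, using Griffing's fixed-genotype estimators.
#'
#' For method 4 (crosses only), with `X_i.` the row total of parent `i`
#' over its crosses and `X..` the grand total over all crosses:
#' \deqn{g_i = [p X_{i.} - 2 X_{..}] / [p(p-2)]}
#' \deqn{s_{ij} = x_{ij} - (X_{i.} + X_{j.})/(p-2) + 2X_{..}/[(p-1)(p-2)]}
#' \deqn{m = 2X_{..}/[p(p-1)]}
#' The decomposition is saturated: `m + g_i + g_j + s_ij` reproduces every
#' cell exactly, `sum(g) = 0`, and each SCA row sums to zero over mates.
#'
#' For method 2 (crosses plus selfs), with `Y_i.` the row total of the
#' symmetric table including the self once and `Y..` the total over the
#' `p(p+1)/2` distinct cells:
#' \deqn{g_i = [Y_{i.} + y_{ii} - 2Y_{..}/p] / (p+2)}
#' \deqn{s_{ij} = y_{ij} - (Y_{i.} + y_{ii} + Y_{j.} + y_{jj})/(p+2) +
#'   2Y_{..}/[(p+1)(p+2)]}
#' under the constraints `sum(g) = 0` and `sum_j s_ij + s_ii = 0` for every
#' parent.
#'
#' When an ANOVA table is supplied, standard errors are attached from its
#' error mean square `Me` and replicate count: for method 4,
#' `se(g_i) = sqrt((p-1) Me / (p(p-2) r))` and
#' `se(s_ij) = sqrt((p-3) Me / ((p-1) r))`.
#'
#' @param x A `cross_means` table (see [entry_means()], [as_cross_means()]).
#' @param anova Optional `diallel_anova` table supplying the error mean
#'   square for standard errors.
#' @param r Replicates per entry mean for the SE formulas; defaults to the
#'   `n_rep` attribute of `x`, then to the ANOVA's replicate count.
#' @return A `griffing_effects` object: grand mean, named GCA vector, SCA
#'   matrix, method, and (when available) standard errors `se_g`, `se_s`,
#'   `se_g_diff` (and `se_s_self` for method 2).
#' @examples
#' d <- diallel_design(paste0("P", 1:6))
#' crosses <- t(combn(paste0("P", 1:6), 2))
#' tbl <- data.frame(parent_a = crosses[, 1], parent_b = crosses[, 2],
#'                   value = rnorm(15, 10))
#' fit <- griffing_effects(as_cross_means(tbl, d))
#' sum(tidy(fit, effects = "gca")$estimate)  # 0
#' @export
griffing_effects <- function(x, anova = NULL, r = NULL) {
  method <- attr(x, "method")
  p <- nrow(x)
  if (method == "method4") {
    if (p < 4) abort("Method 4 needs p >= 4 (SCA df would be nonpositive).")
    fit <- griffing4_fit(x)
  } else {
    if (anyNA(diag(x))) {
      abort("Method 2 needs the selfed-parent diagonal; it is absent.")
    }
    fit <- griffing2_fit(x)
  }
  se <- NULL
  if (!is.null(anova)) {
    me <- error_mean_square(anova)
    r <- r %||% attr(x, "n_rep") %||% attr(anova, "r")
    if (is.null(r)) abort("Supply `r` to compute standard errors.")
    se <- effect_se(method, p, me, r)
    se$error_df <- error_df(anova)
  }
  new_griffing_effects(
    mean = fit$m, gca = fit$g, sca = fit$s, method = method,
    trait = attr(x, "trait"), environment = attr(x, "environment"),
    se = se
  )
}

griffing4_fit <- function(x) {
  p <- nrow(x)
  xi <- cross_row_totals(x)
  xx <- sum(xi) / 2
  g <- (p * xi - 2 * xx) / (p * (p - 2))
  s <- unclass(x) - outer(xi, xi, function(a, b) (a + b) / (p - 2)) +
    2 * xx / ((p - 1) * (p - 2))
  diag(s) <- NA_real_
  list(m = 2 * xx / (p * (p - 1)), g = g, s = s)
}

griffing2_fit <- function(x) {
  p <- nrow(x)
  m0 <- unclass(x)
  yi <- rowSums(m0)                       # self counted once
  yy <- (sum(m0) + sum(diag(m0))) / 2     # total over distinct cells
  g <- (yi + diag(m0) - 2 * yy / p) / (p + 2)
  row_stat <- yi + diag(m0)
  s <- m0 - outer(row_stat, row_stat, "+") / (p + 2) +
    2 * yy / ((p + 1) * (p + 2))
  list(m = 2 * yy / (p * (p + 1)), g = g, s = s)
}

effect_se <- function(method, p, me, r) {
  if (method == "method4") {
    list(
      se_g = sqrt((p - 1) * me / (p * (p - 2) * r)),
      se_s = sqrt((p - 3) * me / ((p - 1) * r)),
      se_g_diff = sqrt(2 * me / ((p - 2) * r)),
      me = me, r = r
    )
  } else {
    list(
      se_g = sqrt((p - 1) * me / (p * (p + 2) * r)),
      se_s = sqrt((p^2 + p + 2) * me / ((p + 1) * (p + 2) * r)),
      se_s_self = sqrt(p * (p - 1) * me / ((p + 1) * (p + 2) * r)),
      se_g_diff = sqrt(2 * me / ((p + 2) * r)),
      me = me, r = r
    )
  }
}

new_griffing_effects <- function(mean, gca, sca, method,
                                 trait = NULL, environment = NULL,
                                 se = NULL) {
  structure(
    list(mean = mean, gca = gca, sca = sca, method = method,
         trait = trait, environment = environment, se = se),
    class = "griffing_effects"
  )
}

#' @export
print.griffing_effects <- function(x, digits = 3, ...) {
  cat("<griffing_effects>", x$method,
      if (!is.null(x$trait)) paste0("trait = ", x$trait), "\n")
  cat("grand mean:", round(x$mean, digits), "\n")
  cat("GCA:\n")
  print(round(x$gca, digits))
  cat("SCA:\n")
  print(round(x$sca, digits))
  invisible(x)
}

#' Tidy Griffing effects into one row per effect
#'
#' @param x A `griffing_effects` object.
#' @param effects `"gca"`, `"sca"` or `"all"` (default).
#' @param ... Unused.
#' @return A tibble with columns `effect`, `parent_a`, `parent_b` (equal to
#'   `parent_a` for GCA rows and selfs), `estimate`, and `std.error` when
#'   standard errors are available.
#' @method tidy griffing_effects
#' @export
tidy.griffing_effects <- function(x, effects = c("all", "gca", "sca"), ...) {
  effects <- match.arg(effects)
  parents <- names(x$gca)
  g_tbl <- tibble::tibble(
    effect = "gca", parent_a = parents, parent_b = parents,
    estimate = unname(x$gca),
    std.error = if (!is.null(x$se)) x$se$se_g else NA_real_
  )
  idx <- which(upper.tri(x$sca, diag = x$method == "method2"), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  self <- idx[, 1] == idx[, 2]
  s_tbl <- tibble::tibble(
    effect = "sca",
    parent_a = parents[idx[, 1]],
    parent_b = parents[idx[, 2]],
    estimate = x$sca[idx],
    std.error = if (is.null(x$se)) NA_real_ else
      ifelse(self, x$se$se_s_self %||% NA_real_, x$se$se_s)
  )
  out <- switch(effects, gca = g_tbl, sca = s_tbl,
                all = dplyr::bind_rows(g_tbl, s_tbl))
  if (all(is.na(out$std.error))) out$std.error <- NULL
  out
}

#' @method glance griffing_effects
#' @export
glance.griffing_effects <- function(x, ...) {
  tibble::tibble(
    grand_mean = x$mean,
    method = x$method,
    n_parents = length(x$gca),
    se_gca = if (!is.null(x$se)) x$se$se_g else NA_real_,
    se_sca = if (!is.null(x$se)) x$se$se_s else NA_real_
  )
}

#' Rank GCA and SCA effects by trait direction
#'
#' Rank 1 is the most favourable effect: the largest for a
#' higher-is-better trait, the smallest (most negative) for a
#' lower-is-better trait such as days to ripening. Ties are broken by
#' parent order and flagged.
#'
#' @param effects A `griffing_effects` object.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return A list of tibbles `gca` and `sca`, each with `estimate`,
#'   `rank`, and a `tied` flag.
#' @export
rank_effects <- function(effects,
                         direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  rank_one <- function(tbl) {
    v <- if (direction == "higher_better") -tbl$estimate else tbl$estimate
    tbl$rank <- rank(v, ties.method = "first")
    tbl$tied <- duplicated(tbl$estimate) | duplicated(tbl$estimate,
                                                      fromLast = TRUE)
    dplyr::arrange(tbl, .data$rank)
  }
  list(
    gca = rank_one(tidy(effects, effects = "gca")),
    sca = rank_one(tidy(effects, effects = "sca"))
  )
}

#' Predicted entry means from a Griffing decomposition
#'
#' Reconstructs `m + g_i + g_j + s_ij` (with `m + 2 g_i + s_ii` on the
#' method-2 diagonal); for a saturated fit this reproduces the input table
#' exactly.
#'
#' @param object A `griffing_effects` object.
#' @param ... Unused.
#' @return A symmetric matrix of fitted entry means.
#' @export
fitted.griffing_effects <- function(object, ...) {
  g <- object$gca
  fit <- object$mean + outer(g, g, "+") + object$sca
  if (object$method == "method2") {
    diag(fit) <- object$mean + 2 * g + diag(object$sca)
  }
  fit
}

#' @method autoplot griffing_effects
#' @export
autoplot.griffing_effects <- function(object, ...) {
  tbl <- tidy(object, effects = "gca")
  tbl$parent_a <- factor(tbl$parent_a, levels = names(object$gca))
  pl <- ggplot2::ggplot(tbl, ggplot2::aes(.data$parent_a, .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "GCA effect",
                  title = paste("General combining ability",
                                object$trait %||% ""))
  if (!is.null(object$se)) {
    pl <- pl + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      width = 0.2
    )
  }
  pl
}
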
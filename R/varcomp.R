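#' Variance components, heritabilities and the GCA/SCA ratio
#'
#' Solves the expected-mean-squares equations of the all-random model for
#' a diallel ANOVA table, truncating negative solutions at zero, and
#' derives the additive, dominance and phenotypic variances with
#' narrow- and broad-sense heritabilities.
#'
#' For a single environment (method 4):
#' `E[MS_SCA] = s2_e + r s2_s` and
#' `E[MS_GCA] = s2_e + r s2_s + r (p-2) s2_g`, so
#' `s2_s = (MS_SCA - Me)/r` and `s2_g = (MS_GCA - MS_SCA)/(r (p-2))`.
#' Across `E` environments the chain extends with
#' `E[MS_ExSCA] = s2_e + r s2_sE`,
#' `E[MS_ExGCA] = s2_e + r s2_sE + r (p-2) s2_gE`,
#' `E[MS_SCA] = s2_e + r s2_sE + r E s2_s`,
#' `E[MS_GCA] = s2_e + r s2_sE + r (p-2) s2_gE + r E s2_s + r E (p-2) s2_g`,
#' back-solved in the order `s2_sE, s2_gE, s2_s, s2_g`. Note that the
#' difference `MS_GCA - MS_SCA` is used for `s2_g` even when `s2_s`
#' truncates to zero.
#'
#' Derived quantities: `s2_A = 2 s2_g`, `s2_D = s2_s`,
#' `s2_P = s2_A + s2_D + s2_e`, `h2_N = s2_A / s2_P`,
#' `h2_B = (s2_A + s2_D) / s2_P`, and the ratio `s2_g / s2_s`
#' (undefined when `s2_s = 0`).
#'
#' Per-component significance is the F-test of the component's defining
#' numerator mean square against the next mean square in the back-solve
#' order (`s2_g`: GCA vs SCA; `s2_s`: SCA vs Env x SCA, or vs error for a
#' single environment; `s2_gE`: Env x GCA vs Env x SCA; `s2_sE`:
#' Env x SCA vs error).
#'
#' The same template is applied to method-2 tables; the method-2 random
#' model is less standard and those components should be read as
#' indicative only (see the methods vignette).
#'
#' @param anova A `diallel_anova` table, from [anova_single_env()],
#'   [anova_combined()] or [as_diallel_anova()].
#' @return A `diallel_varcomp` tibble with one row per component
#'   (`sigma2_g`, `sigma2_s`, `sigma2_gE`, `sigma2_sE`, `sigma2_e`,
#'   `sigma2_A`, `sigma2_D`, `sigma2_P`, `gca_sca_ratio`, `h2_N`, `h2_B`),
#'   its `estimate`, whether truncation fired, and for the random
#'   components the F `statistic`, df and `p.value` with significance
#'   stars.
#' @examples
#' ms <- data.frame(term = c("GCA", "SCA", "Error"),
#'                  meansq = c(32.12, 3.52, 2.83))
#' variance_components(as_diallel_anova(ms, p = 8, r = 3))
#' @export
variance_components <- function(anova) {
  p <- attr(anova, "p")
  r <- attr(anova, "r")
  E <- attr(anova, "n_env")
  scope <- attr(anova, "scope")
  if (is.null(p) || is.null(r)) {
    abort(paste0("The ANOVA table must carry `p` and `r` attributes; ",
                 "build it with as_diallel_anova() or the anova_* functions."))
  }
  me <- error_mean_square(anova)
  ms_gca <- ms_of(anova, "GCA")
  ms_sca <- ms_of(anova, "SCA")
  coef_g <- p - 2  # method-4 EMS template (see Details for method 2)

  if (scope == "combined") {
    ms_gE <- ms_of(anova, "Env x GCA")
    ms_sE <- ms_of(anova, "Env x SCA")
    raw <- c(
      sigma2_sE = (ms_sE - me) / r,
      sigma2_gE = (ms_gE - ms_sE) / (r * coef_g),
      sigma2_s = (ms_sca - ms_sE) / (r * E),
      sigma2_g = (ms_gca - ms_sca - (ms_gE - ms_sE)) / (r * E * coef_g)
    )
    tests <- list(
      sigma2_g = c("GCA", "SCA"),
      sigma2_s = c("SCA", "Env x SCA"),
      sigma2_gE = c("Env x GCA", "Env x SCA"),
      sigma2_sE = c("Env x SCA", "Error")
    )
  } else {
    raw <- c(
      sigma2_s = (ms_sca - me) / r,
      sigma2_g = (ms_gca - ms_sca) / (r * coef_g)
    )
    tests <- list(
      sigma2_g = c("GCA", "SCA"),
      sigma2_s = c("SCA", "Error")
    )
  }
  est <- pmax(raw, 0)
  s2_g <- est[["sigma2_g"]]
  s2_s <- est[["sigma2_s"]]
  s2_A <- 2 * s2_g
  s2_D <- s2_s
  s2_P <- s2_A + s2_D + me
  derived <- c(
    sigma2_e = me,
    sigma2_A = s2_A,
    sigma2_D = s2_D,
    sigma2_P = s2_P,
    gca_sca_ratio = if (s2_s > 0) s2_g / s2_s else NA_real_,
    h2_N = s2_A / s2_P,
    h2_B = (s2_A + s2_D) / s2_P
  )

  comp_order <- c("sigma2_g", "sigma2_s",
                  if (scope == "combined") c("sigma2_gE", "sigma2_sE"),
                  "sigma2_e", "sigma2_A", "sigma2_D", "sigma2_P",
                  "gca_sca_ratio", "h2_N", "h2_B")
  all_est <- c(est, derived)[comp_order]
  truncated <- setNames(rep(FALSE, length(comp_order)), comp_order)
  truncated[names(raw)] <- raw < 0

  test_tbl <- purrr::map_dfr(comp_order, function(cmp) {
    pair <- tests[[cmp]]
    if (is.null(pair)) {
      return(tibble::tibble(statistic = NA_real_, df1 = NA_real_,
                            df2 = NA_real_, p.value = NA_real_))
    }
    num <- pair[1]
    den <- pair[2]
    f <- ms_of(anova, num) / ms_of(anova, den)
    d1 <- anova$df[anova$term == num]
    d2 <- anova$df[anova$term == den]
    tibble::tibble(statistic = f, df1 = d1, df2 = d2,
                   p.value = pf(f, d1, d2, lower.tail = FALSE))
  })

  out <- tibble::tibble(
    component = comp_order,
    estimate = unname(all_est),
    truncated = unname(truncated)
  )
  out <- dplyr::bind_cols(out, test_tbl)
  out$signif <- significance_stars(out$p.value)
  structure(out,
            class = c("diallel_varcomp", class(tibble::tibble())),
            p = p, r = r, n_env = E, scope = scope,
            method = attr(anova, "method"),
            trait = attr(anova, "trait"))
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @method tidy diallel_varcomp
#' @export
tidy.diallel_varcomp <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance diallel_varcomp
#' @export
glance.diallel_varcomp <- function(x, ...) {
  wide <- setNames(as.list(x$estimate), x$component)
  tibble::as_tibble(wide)
}

#' @method autoplot diallel_varcomp
#' @export
autoplot.diallel_varcomp <- function(object, ...) {
  keep <- object$component %in% c("sigma2_g", "sigma2_s", "sigma2_gE",
                                  "sigma2_sE", "sigma2_e")
  tbl <- tibble::as_tibble(object)[keep, ]
  tbl$component <- factor(tbl$component, levels = tbl$component)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$component, .data$estimate)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "Variance estimate",
                  title = "Variance components (random model)")
}
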
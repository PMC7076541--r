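#' Mid-parent heterosis
#'
#' Percent superiority of the F1 over the mid-parent value:
#' `MPH = 100 (F1 - MP) / MP` with `MP = (P1 + P2)/2`. Vectorized.
#'
#' @param f1 F1 entry mean(s).
#' @param p1,p2 Selfed-parent entry means.
#' @return Percent mid-parent heterosis; `NA` (with a warning) where the
#'   mid-parent value is zero.
#' @export
mph <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  bad <- mp == 0
  if (any(bad, na.rm = TRUE)) {
    warn("Mid-parent value is zero for some crosses; MPH undefined there.")
  }
  ifelse(bad, NA_real_, 100 * (f1 - mp) / mp)
}

#' Best-parent heterosis
#'
#' Percent superiority of the F1 over the better parent, where "better"
#' honours the trait direction: the larger parent mean for
#' higher-is-better traits, the smaller (e.g. earlier-ripening) parent for
#' lower-is-better traits. `BPH = 100 (F1 - Ph) / Ph`.
#'
#' @inheritParams mph
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return Percent best-parent heterosis; `NA` where the better-parent
#'   mean is zero.
#' @export
bph <- function(f1, p1, p2, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  ph <- if (direction == "higher_better") pmax(p1, p2) else pmin(p1, p2)
  bad <- ph == 0
  if (any(bad, na.rm = TRUE)) {
    warn("Better-parent value is zero for some crosses; BPH undefined there.")
  }
  ifelse(bad, NA_real_, 100 * (f1 - ph) / ph)
}

#' Standard errors for heterosis tests
#'
#' `SE_MPH = sqrt(3 Me / (2 r))` and `SE_BPH = sqrt(2 Me / r)`, in trait
#' units, from the ANOVA error mean square `Me` and the number of
#' replicate observations `r` behind each entry mean.
#'
#' @param me Error mean square.
#' @param r Replicates per entry mean.
#' @return A one-row tibble with `se_mph` and `se_bph`.
#' @export
heterosis_se <- function(me, r) {
  if (any(me < -1e-8)) abort("`me` must be nonnegative.")
  me <- pmax(me, 0)
  if (any(r < 1)) abort("`r` must be at least 1.")
  tibble::tibble(se_mph = sqrt(3 * me / (2 * r)),
                 se_bph = sqrt(2 * me / r))
}

#' Per-cross heterosis table
#'
#' Computes, for every cross of one trait in one environment, the F1 entry
#' mean, the parental means, mid-parent and best-parent heterosis with
#' their standard errors and t-tests. Testing is on the trait-unit scale
#' (`t = (F1 - MP)/SE_MPH`, `t = (F1 - Ph)/SE_BPH`) against the ANOVA
#' error df. The replicate count entering the SE formulas is taken from
#' the data (records per entry mean), so fruit-level traits with many
#' observations per plot are handled consistently.
#'
#' @param records Long phenotype records including selfed parents.
#' @param design A [diallel_design()].
#' @param trait,environment Trait and environment to analyse.
#' @param anova Optional `diallel_anova` for `Me` and the error df; by
#'   default the method-2 RCBD ANOVA of the same data is used.
#' @param direction Trait direction; defaults to
#'   [trait_direction()]`(design, trait)`.
#' @return A `heterosis_tbl` tibble with one row per cross: `parent_a`,
#'   `parent_b`, `f1`, `p1`, `p2`, `mp`, `ph`, `mph`, `bph`, standard
#'   errors, t statistics, p-values and significance stars. Crosses whose
#'   parents lack selfed records are kept with `NA` heterosis and flagged.
#' @export
heterosis_table <- function(records, design, trait, environment,
                            anova = NULL, direction = NULL) {
  direction <- direction %||% trait_direction(design, trait)
  sub <- records[records$trait == trait & records$env == environment, ]
  if (!any(sub$parent_a == sub$parent_b)) {
    abort("No selfed-parent records; heterosis needs parental means.")
  }
  sub <- canonicalize_pairs(sub, design)
  means <- dplyr::summarise(
    dplyr::group_by(sub, .data$parent_a, .data$parent_b),
    value = mean(.data$value), n = dplyr::n(), .groups = "drop"
  )
  selfs <- means[means$parent_a == means$parent_b, ]
  parent_mean <- setNames(selfs$value, selfs$parent_a)
  crosses <- means[means$parent_a != means$parent_b, ]

  if (is.null(anova)) {
    design2 <- design
    design2$method <- "method2"
    bal <- validate_design(sub, design2)
    anova <- if (all(bal$balanced)) {
      anova_single_env(sub, design2, trait, environment)
    } else {
      NULL
    }
  }
  r_eff <- mean(crosses$n)
  if (!is.null(anova)) {
    me <- error_mean_square(anova)
    dfe <- error_df(anova)
    se <- heterosis_se(me, r_eff)
  } else {
    se <- tibble::tibble(se_mph = NA_real_, se_bph = NA_real_)
    dfe <- NA_real_
  }

  p1 <- unname(parent_mean[crosses$parent_a])
  p2 <- unname(parent_mean[crosses$parent_b])
  flagged <- is.na(p1) | is.na(p2)
  if (any(flagged)) {
    warn(paste0(sum(flagged), " cross(es) have a parent without selfed ",
                "records; their heterosis is NA."))
  }
  mp <- (p1 + p2) / 2
  ph <- if (direction == "higher_better") pmax(p1, p2) else pmin(p1, p2)
  out <- tibble::tibble(
    parent_a = crosses$parent_a,
    parent_b = crosses$parent_b,
    f1 = crosses$value,
    p1 = p1, p2 = p2, mp = mp, ph = ph,
    mph = mph(crosses$value, p1, p2),
    bph = bph(crosses$value, p1, p2, direction),
    se_mph = se$se_mph, se_bph = se$se_bph,
    statistic_mph = (crosses$value - mp) / se$se_mph,
    statistic_bph = (crosses$value - ph) / se$se_bph,
    missing_parent = flagged
  )
  out$p.value_mph <- 2 * pt(abs(out$statistic_mph), dfe, lower.tail = FALSE)
  out$p.value_bph <- 2 * pt(abs(out$statistic_bph), dfe, lower.tail = FALSE)
  out$signif_mph <- significance_stars(out$p.value_mph)
  out$signif_bph <- significance_stars(out$p.value_bph)
  out <- dplyr::arrange(out,
                        match(out$parent_a, design$parents),
                        match(out$parent_b, design$parents))
  structure(out,
            class = c("heterosis_tbl", class(tibble::tibble())),
            trait = trait, environment = environment,
            direction = direction, r = r_eff, error_df = dfe)
}

#' @method autoplot heterosis_tbl
#' @export
autoplot.heterosis_tbl <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  tbl$cross <- entry_label(tbl$parent_a, tbl$parent_b)
  long <- tidyr::pivot_longer(tbl[, c("cross", "mph", "bph")],
                              c("mph", "bph"),
                              names_to = "type", values_to = "percent")
  long$type <- toupper(long$type)
  ggplot2::ggplot(long, ggplot2::aes(.data$cross, .data$percent,
                                     fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Heterosis (%)", fill = NULL,
                  title = paste("Mid- and best-parent heterosis,",
                                attr(object, "trait") %||% ""))
}
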
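#' Distributional quality control per trait and environment
#'
#' Computes sample skewness and excess kurtosis as moment ratios
#' (`g1 = m3 / m2^1.5`, `g2 = m4 / m2^2 - 3`) together with the sorted
#' normal-quantile pairs needed for an external Q-Q plot, for every
#' trait-by-environment combination present in the records.
#'
#' @param records Long phenotype records.
#' @param trait Optional trait filter.
#' @param environment Optional environment filter.
#' @return A `diallel_qc` tibble with one row per trait x environment:
#'   `n`, `mean`, `sd`, `skewness`, `kurtosis`, `zero_variance` flag and a
#'   `qq` list-column of (theoretical, sample) quantile pairs.
#' @export
qc_normality <- function(records, trait = NULL, environment = NULL) {
  sub <- records
  if (!is.null(trait)) sub <- sub[sub$trait %in% trait, ]
  if (!is.null(environment)) sub <- sub[sub$env %in% environment, ]
  if (nrow(sub) == 0) abort("No records match the requested trait/environment.")
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$trait, .data$env),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = sd(.data$value),
    skewness = moment_skewness(.data$value),
    kurtosis = moment_kurtosis(.data$value),
    qq = list(qq_pairs(.data$value)),
    .groups = "drop"
  )
  out$zero_variance <- !is.finite(out$skewness)
  class(out) <- c("diallel_qc", class(out))
  out
}

# g1 = m3 / m2^(3/2) with central moments m_k = mean((x - xbar)^k).
moment_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

# g2 = m4 / m2^2 - 3 (excess kurtosis).
moment_kurtosis <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^4) / m2^2 - 3
}

qq_pairs <- function(x) {
  n <- length(x)
  tibble::tibble(
    theoretical = qnorm(stats::ppoints(n)),
    sample = sort(x)
  )
}

#' @method autoplot diallel_qc
#' @export
autoplot.diallel_qc <- function(object, ...) {
  qq <- tidyr::unnest(
    dplyr::select(object, "trait", "env", "qq"), "qq"
  )
  ggplot2::ggplot(qq, ggplot2::aes(.data$theoretical, .data$sample)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         se = FALSE, linewidth = 0.4, colour = "red") +
    ggplot2::facet_grid(trait ~ env, scales = "free_y") +
    ggplot2::labs(x = "Theoretical normal quantiles", y = "Sample quantiles",
                  title = "Q-Q normality check by trait and environment")
}
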
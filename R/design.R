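#' Describe a half-diallel mating design
#'
#' A design object records everything the estimators need to know about the
#' trial: the parents, whether selfed parents are included (Griffing's
#' method 2) or only the F1 crosses (method 4), the number of complete
#' blocks per environment, the environments, and the direction of
#' improvement for each trait.
#'
#' @param parents Character vector of at least three parent identifiers,
#'   in display order. Order is used for canonicalizing cross labels and
#'   for tie-breaking in rankings.
#' @param method `"method4"` (crosses only, the default) or `"method2"`
#'   (crosses plus selfed parents). Reciprocal crosses are never part of a
#'   half diallel.
#' @param n_blocks Number of complete blocks (replicates) per environment.
#'   At least 2 is required for any analysis of variance.
#' @param environments Character vector of environment identifiers.
#' @param trait_directions Named character vector mapping trait names to
#'   `"higher_better"` or `"lower_better"`. Traits not named here default to
#'   `"higher_better"`, except traits named `"DTR"` (days to ripening),
#'   which default to `"lower_better"`.
#'
#' @return An object of class `diallel_design`.
#' @examples
#' d <- diallel_design(paste0("P", 1:8), method = "method4",
#'                     n_blocks = 3, environments = c("E1", "E2"))
#' n_entries(d)
#' @export
diallel_design <- function(parents,
                           method = c("method4", "method2"),
                           n_blocks = 3,
                           environments = "env1",
                           trait_directions = NULL) {
  method <- match.arg(method)
  parents <- as.character(parents)
  if (anyDuplicated(parents)) {
    abort("`parents` must be unique.")
  }
  if (length(parents) < 3) {
    abort("A diallel needs at least 3 parents.")
  }
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1) {
    abort("`n_blocks` must be a positive integer.")
  }
  environments <- as.character(environments)
  if (anyDuplicated(environments)) {
    abort("`environments` must be unique.")
  }
  if (!is.null(trait_directions)) {
    bad <- setdiff(unique(trait_directions),
                   c("higher_better", "lower_better"))
    if (length(bad) > 0) {
      abort(paste0("Unknown trait direction(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      parents = parents,
      method = method,
      n_blocks = n_blocks,
      environments = environments,
      trait_directions = trait_directions
    ),
    class = "diallel_design"
  )
}

#' @export
print.diallel_design <- function(x, ...) {
  cat("<diallel_design>\n")
  cat("  parents     :", length(x$parents), "(",
      paste(head(x$parents, 8), collapse = ", "),
      if (length(x$parents) > 8) "..." else "", ")\n")
  cat("  method      :", x$method,
      if (x$method == "method2") "(crosses + selfs)" else "(crosses only)", "\n")
  cat("  entries     :", n_entries(x), "\n")
  cat("  blocks      :", x$n_blocks, "\n")
  cat("  environments:", paste(x$environments, collapse = ", "), "\n")
  invisible(x)
}

#' Number of entries implied by a design
#'
#' `p(p-1)/2` crosses for method 4, plus the `p` selfed parents
#' (`p(p+1)/2` entries in total) for method 2.
#'
#' @param design A [diallel_design()].
#' @return Integer entry count.
#' @export
n_entries <- function(design) {
  p <- length(design$parents)
  if (design$method == "method2") p * (p + 1L) / 2L else p * (p - 1L) / 2L
}

#' Direction of improvement for a trait
#'
#' Looks the trait up in the design's `trait_directions`; unknown traits
#' default to `"higher_better"` unless named `"DTR"`, for which earlier
#' ripening (a smaller value) is better.
#'
#' @param design A [diallel_design()].
#' @param trait Trait name.
#' @return `"higher_better"` or `"lower_better"`.
#' @export
trait_direction <- function(design, trait) {
  td <- design$trait_directions
  if (!is.null(td) && trait %in% names(td)) {
    return(unname(td[[trait]]))
  }
  if (trait %in% c("DTR", "dtr")) "lower_better" else "higher_better"
}

# Canonical unordered-pair ordering: parent_a precedes parent_b in the
# design's parent order. (a, b) and (b, a) denote the same entry.
canonicalize_pairs <- function(data, design) {
  ia <- match(data$parent_a, design$parents)
  ib <- match(data$parent_b, design$parents)
  swap <- !is.na(ia) & !is.na(ib) & ia > ib
  if (any(swap)) {
    tmp <- data$parent_a[swap]
    data$parent_a[swap] <- data$parent_b[swap]
    data$parent_b[swap] <- tmp
  }
  data
}

# Entry label helper, e.g. "P1 x P3" or "P2 x P2" for a self.
entry_label <- function(parent_a, parent_b) paste(parent_a, "x", parent_b)

# All entries of a design as a canonical tibble (parent_a, parent_b).
design_entries <- function(design) {
  p <- length(design$parents)
  cross <- t(combn(design$parents, 2))
  out <- tibble::tibble(parent_a = cross[, 1], parent_b = cross[, 2])
  if (design$method == "method2") {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(parent_a = design$parents, parent_b = design$parents)
    )
  }
  dplyr::arrange(out,
                 match(.data$parent_a, design$parents),
                 match(.data$parent_b, design$parents))
}
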
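#' Entry means of a diallel table
#'
#' Averages every entry (cross or selfed parent) over the blocks of one
#' environment, producing the symmetric parent-by-parent table of entry
#' means that all combining-ability formulas consume. In a balanced RCBD
#' the arithmetic entry mean equals the least-squares mean of the entry.
#'
#' @param records Long phenotype records (see [read_phenotype()]).
#' @param design A [diallel_design()].
#' @param trait Trait to average.
#' @param environment Environment to use, or `NULL` to average each entry
#'   across all environments present (used for the combined analysis).
#' @param check_balance Refuse unbalanced layouts (default `TRUE`).
#' @return A `cross_means` object: a symmetric `p x p` matrix with parent
#'   dimnames, diagonal present only when the design includes selfs, and
#'   attributes `trait`, `environment`, `method`, `n_rep` (records averaged
#'   per entry mean).
#' @export
entry_means <- function(records, design, trait,
                        environment = NULL, check_balance = TRUE) {
  sub <- records[records$trait == trait, ]
  if (!is.null(environment)) {
    sub <- sub[sub$env %in% environment, ]
  }
  if (nrow(sub) == 0) {
    abort(paste0("No records for trait '", trait, "'",
                 if (!is.null(environment))
                   paste0(" in ", paste(environment, collapse = ", "))))
  }
  if (check_balance) {
    require_balanced(sub, design, trait, unique(sub$env))
  }
  sub <- canonicalize_pairs(sub, design)
  means <- dplyr::summarise(
    dplyr::group_by(sub, .data$parent_a, .data$parent_b),
    value = mean(.data$value), n = dplyr::n(), .groups = "drop"
  )
  p <- length(design$parents)
  m <- matrix(NA_real_, p, p, dimnames = list(design$parents, design$parents))
  ia <- match(means$parent_a, design$parents)
  ib <- match(means$parent_b, design$parents)
  m[cbind(ia, ib)] <- means$value
  m[cbind(ib, ia)] <- means$value
  if (design$method == "method4") {
    diag(m) <- NA_real_
  }
  new_cross_means(m,
                  method = design$method,
                  trait = trait,
                  environment = environment,
                  n_rep = mean(means$n))
}

new_cross_means <- function(m, method, trait = NULL, environment = NULL,
                            n_rep = NULL) {
  off <- m[upper.tri(m)]
  if (anyNA(off)) {
    abort("Every cross must have a mean; some off-diagonal cells are NA.")
  }
  structure(m,
            class = c("cross_means", "matrix", "array"),
            method = method, trait = trait,
            environment = environment, n_rep = n_rep)
}

#' Build a cross-means table from a long data frame
#'
#' Constructs the symmetric entry-means matrix directly from one value per
#' unordered cross (and per self for method 2), e.g. published least-square
#' means.
#'
#' @param data Data frame with columns `parent_a`, `parent_b` and a value
#'   column.
#' @param design A [diallel_design()].
#' @param value Name of the value column (default `"value"`).
#' @return A `cross_means` matrix.
#' @export
as_cross_means <- function(data, design, value = "value") {
  data <- canonicalize_pairs(data, design)
  p <- length(design$parents)
  m <- matrix(NA_real_, p, p, dimnames = list(design$parents, design$parents))
  ia <- match(data$parent_a, design$parents)
  ib <- match(data$parent_b, design$parents)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(data$parent_a[is.na(ia)], data$parent_b[is.na(ib)]))
    abort(paste0("Unknown parent(s): ", paste(bad, collapse = ", ")))
  }
  m[cbind(ia, ib)] <- data[[value]]
  m[cbind(ib, ia)] <- data[[value]]
  new_cross_means(m, method = design$method)
}

#' @export
print.cross_means <- function(x, digits = 3, ...) {
  cat("<cross_means> method =", attr(x, "method"),
      if (!is.null(attr(x, "trait"))) paste0("trait = ", attr(x, "trait")),
      "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @describeIn entry_means Tidy a cross-means matrix into one row per entry.
#' @param x A `cross_means` object.
#' @param ... Unused.
#' @method tidy cross_means
#' @export
tidy.cross_means <- function(x, ...) {
  parents <- rownames(x)
  idx <- which(upper.tri(x, diag = attr(x, "method") == "method2"),
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    parent_a = parents[idx[, 1]],
    parent_b = parents[idx[, 2]],
    mean = x[idx]
  )
}

# Row totals over crosses only (diagonal excluded): Griffing's X_i.
cross_row_totals <- function(m) {
  m2 <- unclass(m)
  diag(m2) <- 0
  rowSums(m2)
}

# Grand total over the p(p-1)/2 crosses.
cross_grand_total <- function(m) {
  sum(cross_row_totals(m)) / 2
}
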
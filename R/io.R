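#' Read a long-format phenotype table
#'
#' Reads a plot/fruit phenotype CSV with header columns `env`, `block`,
#' `parent_a`, `parent_b` and one column per trait, and returns one record
#' per observation in long format. Cross labels are canonicalized so that
#' `(a, b)` and `(b, a)` denote the same entry; `parent_a == parent_b`
#' denotes a selfed parent. Missing trait cells are tolerated and dropped
#' with a count in the completeness attribute.
#'
#' @param path Path to a CSV file (comma separated, UTF-8, header row).
#' @param design A [diallel_design()]; parent names in the file must match.
#' @return A tibble with columns `env`, `block`, `parent_a`, `parent_b`,
#'   `trait`, `value`, carrying a `completeness` attribute (records read,
#'   records kept, missing cells dropped).
#' @seealso [validate_design()] for the balance report,
#'   [write_phenotype()] for the inverse operation.
#' @export
read_phenotype <- function(path, design) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("env", "block", "parent_a", "parent_b")
  missing_cols <- setdiff(required, names(wide))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  traits <- setdiff(names(wide), required)
  # strtod parsing is correctly rounded, so a write -> read cycle
  # reproduces each stored double bit-exactly
  wide[traits] <- lapply(wide[traits], as.numeric)
  if (length(traits) == 0) {
    abort("No trait columns found after env, block, parent_a, parent_b.")
  }
  unknown <- setdiff(unique(c(wide$parent_a, wide$parent_b)), design$parents)
  if (length(unknown) > 0) {
    rows <- which(wide$parent_a %in% unknown | wide$parent_b %in% unknown)
    abort(paste0("Unknown parent(s) ", paste(unknown, collapse = ", "),
                 " in data row(s) ", paste(head(rows, 5), collapse = ", "),
                 if (length(rows) > 5) " ..." else ""))
  }
  wide <- canonicalize_pairs(wide, design)
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(traits),
                              names_to = "trait", values_to = "value")
  n_read <- nrow(long)
  dup <- dplyr::count(long, .data$env, .data$block, .data$parent_a,
                      .data$parent_b, .data$trait)
  dup <- dplyr::filter(dup, .data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate observation(s) for the same (env, block, entry, ",
                 "trait), e.g. ", dup$env[1], "/", dup$block[1], "/",
                 entry_label(dup$parent_a[1], dup$parent_b[1]), "/",
                 dup$trait[1]))
  }
  kept <- dplyr::filter(long, is.finite(.data$value))
  attr(kept, "completeness") <- tibble::tibble(
    records_read = n_read,
    records_kept = nrow(kept),
    missing_dropped = n_read - nrow(kept)
  )
  kept
}

#' Write phenotype records back to the wide CSV layout
#'
#' Inverse of [read_phenotype()]: pivots the long records to one column per
#' trait and writes a plain CSV. A read-write-read round trip preserves
#' every record.
#'
#' @param records Long records as returned by [read_phenotype()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(records, path) {
  wide <- tidyr::pivot_wider(records, names_from = "trait",
                             values_from = "value")
  # serialize trait values at full double precision so that a
  # read -> write -> read cycle is bit-exact
  num <- vapply(wide, is.numeric, logical(1))
  wide[num] <- lapply(wide[num], function(x) sprintf("%.17g", x))
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a symmetric parent-by-parent distance matrix
#'
#' Reads a CSV whose first column and header hold parent names, checks
#' symmetry and the zero diagonal, and returns a labelled matrix.
#'
#' @param path Path to the CSV file.
#' @param kind Distance kind label, e.g. `"genetic"`.
#' @param tol Symmetry tolerance.
#' @return A numeric matrix of class `diallel_dist` with parent dimnames.
#' @export
read_distance_matrix <- function(path, kind = "genetic", tol = 1e-8) {
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  labels <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  mode(m) <- "double"
  if (!identical(colnames(m), labels)) {
    abort("Row and column parent names differ or are out of order.")
  }
  dimnames(m) <- list(labels, labels)
  new_distance_matrix(m, kind = kind, tol = tol)
}

new_distance_matrix <- function(m, kind, tol = 1e-8) {
  if (max(abs(m - t(m))) > tol) {
    abort("Distance matrix is not symmetric.")
  }
  if (max(abs(diag(m))) > tol) {
    abort("Distance matrix diagonal is not zero.")
  }
  if (kind != "cross_statistic" && min(m) < -tol) {
    abort("Distances must be nonnegative.")
  }
  structure(m, class = c("diallel_dist", "matrix", "array"), kind = kind)
}

#' Check the balance of a diallel RCBD layout
#'
#' For every environment-by-trait combination, reports whether each design
#' entry appears exactly once in every block. The ANOVA stages require
#' balance and refuse to run otherwise; this report says what is missing.
#'
#' @param records Long phenotype records.
#' @param design A [diallel_design()].
#' @return A tibble with one row per `env` x `trait`: `balanced` (logical),
#'   `diagonal_absent` (method-2 designs with no selfed records),
#'   `n_missing`, and a `missing` list-column of the absent
#'   (block, entry) combinations.
#' @export
validate_design <- function(records, design) {
  if (nrow(records) == 0) {
    abort("`records` is empty.")
  }
  entries <- design_entries(design)
  combos <- dplyr::distinct(records, .data$env, .data$trait)
  out <- purrr::pmap_dfr(combos, function(env, trait) {
    sub <- records[records$env == env & records$trait == trait, ]
    blocks <- sort(unique(sub$block))
    expected <- tidyr::crossing(block = blocks, entries)
    got <- dplyr::count(sub, .data$block, .data$parent_a, .data$parent_b)
    chk <- dplyr::left_join(expected, got,
                            by = c("block", "parent_a", "parent_b"))
    miss <- dplyr::filter(chk, is.na(.data$n) | .data$n != 1L)
    selfs <- sub$parent_a == sub$parent_b
    diagonal_absent <- design$method == "method2" && !any(selfs)
    tibble::tibble(
      env = env, trait = trait,
      n_blocks = length(blocks),
      balanced = nrow(miss) == 0 && length(blocks) == design$n_blocks &&
        !diagonal_absent,
      diagonal_absent = diagonal_absent,
      n_missing = nrow(miss),
      missing = list(dplyr::select(miss, "block", "parent_a", "parent_b"))
    )
  })
  out
}

# Internal guard used by the ANOVA stages.
require_balanced <- function(records, design, trait, env) {
  sub <- records[records$trait == trait & records$env %in% env, ]
  rep <- validate_design(sub, design)
  if (!all(rep$balanced)) {
    abort(paste0("Unbalanced layout for trait '", trait, "' in ",
                 paste(rep$env[!rep$balanced], collapse = ", "),
                 "; run validate_design() for the missing plots."))
  }
  invisible(TRUE)
}
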
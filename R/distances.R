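#' Euclidean distance between parent trait profiles
#'
#' Standardizes every trait to zero mean and unit variance across parents
#' (so kilogram-scale traits cannot dominate degree-Brix-scale ones) and
#' returns the Euclidean distance matrix in that multivariate space.
#'
#' @param profiles Data frame with a `parent` column and one numeric
#'   column per trait.
#' @param standardize Scale traits before distancing (default `TRUE`).
#' @return A `diallel_dist` matrix (symmetric, zero diagonal). Parents
#'   with any missing trait value are excluded with a warning.
#' @export
dist_euclidean <- function(profiles, standardize = TRUE) {
  traits <- setdiff(names(profiles), "parent")
  m <- as.matrix(profiles[, traits, drop = FALSE])
  rownames(m) <- profiles$parent
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    warn(paste0("Excluding parent(s) with missing trait values: ",
                paste(rownames(m)[!keep], collapse = ", ")))
    m <- m[keep, , drop = FALSE]
  }
  if (standardize) m <- scale(m)
  d <- as.matrix(dist(m))
  new_distance_matrix(d, kind = "euclidean")
}

#' Mahalanobis distances between entries via canonical analysis
#'
#' Computes the squared generalized distance
#' `D2_ab = (xbar_a - xbar_b)' W^-1 (xbar_a - xbar_b)` between the
#' multivariate trait means of selfed parents (or all entries), with `W`
#' the pooled within-entry covariance of the replicate observations.
#' Internally the replicates are whitened by the canonical transform
#' `W^(-1/2)` so the distance is the squared Euclidean distance in
#' canonical-variate space; both routes coincide and the equivalence is
#' exercised by the package tests.
#'
#' @param records Long phenotype records containing all `traits` for the
#'   same plots.
#' @param design A [diallel_design()].
#' @param traits Character vector of traits to span the space.
#' @param environment Environment to use.
#' @param parents_only Restrict to selfed parents (default `TRUE`),
#'   matching the use of parental distances against a genetic-distance
#'   matrix; `FALSE` uses every entry.
#' @return A `diallel_dist` matrix of squared Mahalanobis distances.
#' @export
dist_mahalanobis <- function(records, design, traits, environment,
                             parents_only = TRUE) {
  sub <- records[records$trait %in% traits & records$env == environment, ]
  if (parents_only) {
    sub <- sub[sub$parent_a == sub$parent_b, ]
    if (nrow(sub) == 0) abort("No selfed-parent records in this environment.")
  }
  wide <- tidyr::pivot_wider(sub, names_from = "trait",
                             values_from = "value")
  wide$entry <- entry_label(wide$parent_a, wide$parent_b)
  if (parents_only) wide$entry <- wide$parent_a
  y <- as.matrix(wide[, traits, drop = FALSE])
  if (anyNA(y)) abort("Replicate records are incomplete for some traits.")
  groups <- split(seq_len(nrow(y)), wide$entry)
  if (any(lengths(groups) < 2)) {
    abort("Every entry needs at least 2 replicates for the pooled covariance.")
  }
  centered <- y
  for (g in groups) {
    centered[g, ] <- sweep(y[g, , drop = FALSE], 2,
                           colMeans(y[g, , drop = FALSE]))
  }
  w <- crossprod(centered) / (nrow(y) - length(groups))
  ev <- eigen(w, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values)) {
    abort(paste0("Pooled within-entry covariance is singular; drop ",
                 "redundant traits before computing Mahalanobis distances."))
  }
  means <- do.call(rbind, lapply(groups, function(g) {
    colMeans(y[g, , drop = FALSE])
  }))
  # canonical transform: whiten by W^(-1/2), then squared Euclidean
  whitener <- ev$vectors %*% diag(1 / sqrt(ev$values),
                                  length(ev$values)) %*% t(ev$vectors)
  canon <- means %*% whitener
  d2 <- as.matrix(dist(canon))^2
  dimnames(d2) <- list(rownames(means), rownames(means))
  new_distance_matrix(d2, kind = "mahalanobis")
}

#' Arrange a per-cross statistic as a parent-by-parent matrix
#'
#' Mantel comparisons need every per-cross quantity (entry mean, SCA,
#' MPH, BPH, ...) in the same square symmetric layout as a distance
#' matrix: value at `(i, j)` and `(j, i)`, zero diagonal.
#'
#' @param data Data frame with `parent_a`, `parent_b` and a value column,
#'   one row per unordered cross.
#' @param design A [diallel_design()] providing the parent order.
#' @param value Name of the value column.
#' @return A `diallel_dist` matrix of kind `"cross_statistic"` (values may
#'   be signed).
#' @export
cross_statistic_matrix <- function(data, design, value = "value") {
  data <- canonicalize_pairs(data, design)
  p <- length(design$parents)
  need <- p * (p - 1) / 2
  crosses <- data[data$parent_a != data$parent_b, ]
  if (nrow(crosses) != need) {
    abort(paste0("Expected one value for each of the ", need,
                 " crosses, got ", nrow(crosses), "."))
  }
  m <- matrix(0, p, p, dimnames = list(design$parents, design$parents))
  ia <- match(crosses$parent_a, design$parents)
  ib <- match(crosses$parent_b, design$parents)
  m[cbind(ia, ib)] <- crosses[[value]]
  m[cbind(ib, ia)] <- crosses[[value]]
  new_distance_matrix(m, kind = "cross_statistic")
}

#' Mantel permutation test between two parent-by-parent matrices
#'
#' Pearson correlation of the `p(p-1)/2` off-diagonal pairs, with a null
#' distribution built by jointly permuting the rows and columns of the
#' second matrix. The p-value is `(hits + 1) / (n_perm + 1)`; the default
#' alternative is upper-tailed (greater similarity than expected).
#'
#' @param a,b Square symmetric matrices with identical parent labels
#'   (class `diallel_dist` or plain matrices).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducible permutations.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exhaustive Enumerate all `n!` relabelings instead of sampling
#'   (only sensible for small matrices, `n <= 8`); the p-value is then the
#'   exact proportion of relabelings at least as extreme as the observed
#'   one.
#' @return A `mantel_test` object; `glance()` gives `r`, `p.value`,
#'   `n_perm`, `alternative`, `seed`.
#' @examples
#' m1 <- as.matrix(dist(matrix(rnorm(16), 8)))
#' m2 <- as.matrix(dist(matrix(rnorm(16), 8)))
#' dimnames(m2) <- dimnames(m1)
#' mantel_test(m1, m2, n_perm = 199, seed = 7)
#' @export
mantel_test <- function(a, b, n_perm = 10000, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  a <- unclass(a); b <- unclass(b)
  if (!identical(dim(a), dim(b))) abort("Matrices have different sizes.")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("Matrix labels differ; align the parents first.")
  }
  lt <- lower.tri(a)
  va <- a[lt]
  r_obs <- cor(va, b[lt])
  n <- nrow(a)
  if (exhaustive) {
    if (n > 8) abort("Exhaustive enumeration is limited to n <= 8.")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(pp) cor(va, b[pp, pp][lt]), numeric(1))
    p <- if (alternative == "greater") {
      mean(r_perm >= r_obs - 1e-12)
    } else {
      mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    }
    return(structure(
      list(r = r_obs, p.value = p, n_perm = length(perms), seed = seed,
           alternative = alternative, r_perm = r_perm, exhaustive = TRUE),
      class = "mantel_test"
    ))
  }
  if (n_perm < 99) abort("Use at least 99 permutations.")
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    pp <- sample.int(n)
    cor(va, b[pp, pp][lt])
  }, numeric(1))
  p <- if (alternative == "greater") {
    (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  } else {
    (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  }
  structure(
    list(r = r_obs, p.value = p, n_perm = n_perm, seed = seed,
         alternative = alternative, r_perm = r_perm, exhaustive = FALSE),
    class = "mantel_test"
  )
}

# All n! permutations of 1..n: insert n at every position of every
# permutation of 1..(n-1).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  shorter <- all_permutations(n - 1L)
  out <- vector("list", n * length(shorter))
  k <- 0L
  for (perm in shorter) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(perm, n, after = pos)
    }
  }
  out
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel test: r =", round(x$r, 4),
      " p =", signif(x$p.value, 3),
      "(", x$n_perm, "permutations,", x$alternative, ")\n")
  invisible(x)
}

#' @method glance mantel_test
#' @export
glance.mantel_test <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p.value, n_perm = x$n_perm,
                 alternative = x$alternative,
                 seed = x$seed %||% NA_integer_)
}

#' @method tidy mantel_test
#' @export
tidy.mantel_test <- function(x, ...) glance(x)
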
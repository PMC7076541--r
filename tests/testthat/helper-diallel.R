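# Shared fixtures and independent oracles for the diallel test suite.

make_design <- function(p = 8, method = "method4", r = 3, E = 1) {
  diallel_design(paste0("P", seq_len(p)), method = method, n_blocks = r,
                 environments = paste0("E", seq_len(E)))
}

random_cross_means <- function(p, method = "method4", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- rnorm(p * (p - 1) / 2, 10, 2)
  m <- m + t(m)
  diag(m) <- if (method == "method2") rnorm(p, 10, 2) else NA_real_
  dimnames(m) <- list(paste0("P", 1:p), paste0("P", 1:p))
  design <- make_design(p, method)
  diallelr::as_cross_means(
    tibble::tibble(
      parent_a = rownames(m)[row(m)[upper.tri(m, diag = method == "method2")]],
      parent_b = colnames(m)[col(m)[upper.tri(m, diag = method == "method2")]],
      value = m[upper.tri(m, diag = method == "method2")]
    ),
    design
  )
}

# Independent oracle: saturated constrained least squares for the Griffing
# decomposition, solved through the QR of the stacked (model, constraint)
# system rather than the closed-form estimators.
ls_oracle <- function(x, method) {
  p <- nrow(x)
  cells <- which(upper.tri(x, diag = method == "method2"), arr.ind = TRUE)
  n <- nrow(cells)
  np <- 1 + p + n
  X <- matrix(0, n, np)
  for (k in seq_len(n)) {
    i <- cells[k, 1]; j <- cells[k, 2]
    X[k, 1] <- 1
    X[k, 1 + i] <- X[k, 1 + i] + 1
    X[k, 1 + j] <- X[k, 1 + j] + 1
    X[k, 1 + p + k] <- 1
  }
  if (method == "method4") {
    C <- matrix(0, p + 1, np)
    C[1, 2:(p + 1)] <- 1
    for (i in seq_len(p)) {
      hit <- cells[, 1] == i | cells[, 2] == i
      C[1 + i, 1 + p + which(hit)] <- 1
    }
  } else {
    # sum g = 0; per parent: sum_j s_ij + s_ii = 0 (self counted twice)
    C <- matrix(0, p + 1, np)
    C[1, 2:(p + 1)] <- 1
    for (i in seq_len(p)) {
      w <- (cells[, 1] == i) + (cells[, 2] == i)
      C[1 + i, 1 + p + seq_len(n)] <- w
    }
  }
  theta <- qr.solve(rbind(X, C), c(x[cells], rep(0, p + 1)))
  g <- theta[2:(p + 1)]
  s <- matrix(NA_real_, p, p)
  s[cells] <- theta[-(1:(p + 1))]
  s[cells[, c(2, 1)]] <- theta[-(1:(p + 1))]
  if (method == "method4") diag(s) <- NA_real_
  list(m = theta[1], g = unname(g), s = s)
}

# Load the published melon trial summaries shipped with the package.
melon_parents <- function() {
  c("Vedrantais", "Ita1", "Ogen", "Top Mark", "Magyar Kincs",
    "Hale's Best Jumbo", "PI414723", "PI161375")
}

melon_lsm_lt2015 <- function() {
  path <- system.file("extdata", "melon_yield_lsm_latina2015.csv",
                      package = "diallelr")
  readr::read_csv(path, show_col_types = FALSE)
}

melon_single_ms <- function(trait, env) {
  path <- system.file("extdata", "melon_mean_squares_single_env.csv",
                      package = "diallelr")
  ms <- readr::read_csv(path, show_col_types = FALSE)
  ms[ms$trait == trait & ms$env == env, c("term", "df", "meansq")]
}

melon_combined_ms <- function(trait = "yield", method = "method4") {
  path <- system.file("extdata", "melon_mean_squares_combined.csv",
                      package = "diallelr")
  ms <- readr::read_csv(path, show_col_types = FALSE)
  ms[ms$trait == trait & ms$method == method, ]
}

# Records with every entry observed once per block, built from a known
# entry-mean matrix plus optional block offsets (no error).
records_from_matrix <- function(m, design, block_offsets = NULL, env = NULL) {
  env <- env %||% design$environments[1]
  r <- design$n_blocks
  block_offsets <- block_offsets %||% rep(0, r)
  entries <- which(upper.tri(m, diag = design$method == "method2"),
                   arr.ind = TRUE)
  purrr::map_dfr(seq_len(r), function(k) {
    tibble::tibble(
      env = env, block = paste0("B", k),
      parent_a = rownames(m)[entries[, 1]],
      parent_b = colnames(m)[entries[, 2]],
      trait = "trait",
      value = m[entries] + block_offsets[k]
    )
  })
}

`%||%` <- rlang::`%||%`

# Agreement with a published value at its printed precision.
expect_printed <- function(actual, printed) {
  digits <- nchar(sub("^[^.]*\\.?", "", printed))
  testthat::expect_lt(abs(actual - as.numeric(printed)),
                      0.51 * 10^(-digits))
}

# Crosses of a design as a tibble (no selfs).
design_entries_for_test <- function(design) {
  cross <- t(combn(design$parents, 2))
  tibble::tibble(parent_a = cross[, 1], parent_b = cross[, 2])
}

# Independent enumeration of all permutations of 1..n: filter the n^n
# grid down to bijections (fine for tiny n; deliberately not the
# package's recursive construction).
gtools_perms_for_test <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  keep <- apply(grid, 1, function(x) length(unique(x)) == n)
  lapply(seq_len(sum(keep)), function(i) unname(grid[keep, ][i, ]))
}

# Minimal effects object for ranking tests.
new_effects_for_test <- function(g) {
  p <- length(g)
  s <- matrix(0, p, p, dimnames = list(names(g), names(g)))
  diag(s) <- NA_real_
  diallelr:::new_griffing_effects(mean = 0, gca = g, sca = s,
                                  method = "method4")
}
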
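#' Specify a synthetic half-diallel trial
#'
#' Bundles a design with the generative parameters of a multi-environment
#' half-diallel RCBD: a grand mean per trait, environment effects (fixed
#' offsets by default, optionally random), block, additive (GCA),
#' non-additive (SCA), genotype-by-environment and plot-error variance
#' components, and an optional self-penalty mimicking inbreeding
#' depression so that hybrids exceed their parents.
#'
#' @param design A [diallel_design()].
#' @param mu Grand mean, optionally a named vector with one element per
#'   trait; traits are simulated independently with the same variance
#'   structure.
#' @param env_effects Optional numeric vector of fixed environment offsets
#'   (length = number of environments). When `NULL`, offsets are drawn from
#'   `N(0, sigma2_env)` and centered.
#' @param sigma2_env,sigma2_block,sigma2_g,sigma2_s,sigma2_gE,sigma2_sE,sigma2_e
#'   Nonnegative variance components: environment, block-within-environment,
#'   GCA, SCA, GCA-by-environment, SCA-by-environment, and plot error.
#' @param delta_self Offset added to every selfed entry (method-2 designs).
#'   A negative value on a higher-is-better trait produces positive
#'   mid-parent heterosis.
#' @param random_env If `TRUE`, environment effects are treated as random
#'   draws (relevant only for how downstream heritability simulations are
#'   interpreted; the generated records are the same given a seed).
#' @return A `diallel_sim_spec` list.
#' @seealso [simulate_diallel()]
#' @export
diallel_sim_spec <- function(design,
                             mu = 10,
                             env_effects = NULL,
                             sigma2_env = 1,
                             sigma2_block = 0.1,
                             sigma2_g = 1,
                             sigma2_s = 0.25,
                             sigma2_gE = 0.1,
                             sigma2_sE = 0.1,
                             sigma2_e = 1,
                             delta_self = 0,
                             random_env = FALSE) {
  vars <- c(sigma2_env = sigma2_env, sigma2_block = sigma2_block,
            sigma2_g = sigma2_g, sigma2_s = sigma2_s,
            sigma2_gE = sigma2_gE, sigma2_sE = sigma2_sE,
            sigma2_e = sigma2_e)
  if (any(vars < 0)) abort("Variance components must be nonnegative.")
  if (!is.null(env_effects) &&
      length(env_effects) != length(design$environments)) {
    abort("`env_effects` must have one value per design environment.")
  }
  if (is.null(names(mu))) {
    names(mu) <- if (length(mu) == 1) "trait" else paste0("trait", seq_along(mu))
  }
  structure(
    list(design = design, mu = mu, env_effects = env_effects,
         sigma2_env = sigma2_env, sigma2_block = sigma2_block,
         sigma2_g = sigma2_g, sigma2_s = sigma2_s,
         sigma2_gE = sigma2_gE, sigma2_sE = sigma2_sE,
         sigma2_e = sigma2_e, delta_self = delta_self,
         random_env = random_env),
    class = "diallel_sim_spec"
  )
}

#' Simulate a half-diallel RCBD trial with known effects
#'
#' Generates plot records according to
#' `y = mu + e_l + b_lk + g_i + g_j + s_ij + gE_il + gE_jl + sE_ijl + eps`,
#' with selfed entries (method 2) receiving `2 g_i + s_ii + delta_self` and
#' the corresponding doubled GxE deviation. Random effect draws are
#' centered within their stratum (`sum(g) = 0`, GCA-by-environment
#' deviations sum to zero over parents within each environment, cross
#' deviations are mean-centered), and the cross deviations are otherwise
#' unconstrained exchangeable effects, exactly as the random model behind
#' the expected mean squares assumes. The reported truth uses the
#' identifiable Griffing parametrization: the GCA-like leak of the raw
#' cross deviations is moved into `g`, so `sum(g) = 0` and every SCA row
#' sums to zero over mates, and the estimators reproduce the reported
#' effects exactly on noise-free data.
#'
#' @param spec A [diallel_sim_spec()].
#' @param seed Integer seed; identical seeds give identical trials.
#' @return A list of class `diallel_sim` with `records` (long tibble as
#'   from [read_phenotype()]) and `truth`, a per-trait list of the drawn
#'   `g`, `s`, `gE`, `sE`, block and environment effects.
#' @examples
#' d <- diallel_design(paste0("P", 1:6), environments = c("A", "B"))
#' sim <- simulate_diallel(diallel_sim_spec(d), seed = 1)
#' head(sim$records)
#' @export
simulate_diallel <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- spec$design
  parents <- design$parents
  p <- length(parents)
  E <- length(design$environments)
  r <- design$n_blocks
  entries <- design_entries(design)
  ia <- match(entries$parent_a, parents)
  ib <- match(entries$parent_b, parents)
  is_self <- ia == ib

  env_eff <- spec$env_effects
  if (is.null(env_eff)) {
    env_eff <- center(rnorm(E, 0, sqrt(spec$sigma2_env)))
  }
  names(env_eff) <- design$environments

  records <- NULL
  truth <- list()
  for (trait in names(spec$mu)) {
    mu <- spec$mu[[trait]]
    g <- center(rnorm(p, 0, sqrt(spec$sigma2_g)))
    names(g) <- parents
    s <- sym_draw(p, spec$sigma2_s, diag_too = design$method == "method2")
    dimnames(s) <- list(parents, parents)
    # identifiable parametrization: the unconstrained cross deviations
    # leak a GCA-like component, which belongs to g under the Griffing
    # constraints; report the truth accordingly
    leak <- gca_leak(s)
    g_true <- g + leak$g
    s_true <- sca_project(s)
    diag(s_true) <- diag(s)
    dimnames(s_true) <- dimnames(s)
    gE <- matrix(0, p, E, dimnames = list(parents, design$environments))
    sE <- array(0, c(p, p, E),
                dimnames = list(parents, parents, design$environments))
    for (l in seq_len(E)) {
      gE[, l] <- center(rnorm(p, 0, sqrt(spec$sigma2_gE)))
      sE[, , l] <- sym_draw(p, spec$sigma2_sE,
                            diag_too = design$method == "method2")
    }
    blocks <- matrix(0, E, r,
                     dimnames = list(design$environments, paste0("B", 1:r)))
    for (l in seq_len(E)) {
      blocks[l, ] <- center(rnorm(r, 0, sqrt(spec$sigma2_block)))
    }

    entry_gen <- ifelse(is_self,
                        2 * g[ia] + diag(s)[ia] + spec$delta_self,
                        g[ia] + g[ib] + s[cbind(ia, ib)])
    per_env <- purrr::map_dfr(seq_len(E), function(l) {
      ge_term <- ifelse(is_self,
                        2 * gE[ia, l] + diag(sE[, , l])[ia],
                        gE[ia, l] + gE[ib, l] + sE[, , l][cbind(ia, ib)])
      purrr::map_dfr(seq_len(r), function(k) {
        tibble::tibble(
          env = design$environments[l],
          block = paste0("B", k),
          parent_a = entries$parent_a,
          parent_b = entries$parent_b,
          trait = trait,
          value = mu + env_eff[l] + blocks[l, k] + entry_gen + ge_term +
            rnorm(length(entry_gen), 0, sqrt(spec$sigma2_e))
        )
      })
    })
    records <- dplyr::bind_rows(records, per_env)
    truth[[trait]] <- list(mu = mu + leak$m, g = g_true, s = s_true,
                           gE = gE, sE = sE,
                           blocks = blocks, env_effects = env_eff,
                           delta_self = spec$delta_self)
  }
  structure(list(records = records, truth = truth, spec = spec, seed = seed),
            class = "diallel_sim")
}

center <- function(x) if (length(x) > 1) x - mean(x) else x * 0

# Cross deviations are drawn as exchangeable symmetric effects (the
# textbook random model): iid draws, mean-centered. Their GCA-like leak
# stays in the data — that is what gives the expected mean squares their
# published coefficients — while the reported truth moves the leak into
# g via gca_leak()/sca_project().
sym_draw <- function(p, sigma2, diag_too = FALSE) {
  s <- matrix(0, p, p)
  vals <- rnorm(p * (p - 1) / 2, 0, sqrt(sigma2))
  s[upper.tri(s)] <- vals - mean(vals)
  s <- s + t(s)
  if (diag_too) diag(s) <- center(rnorm(p, 0, sqrt(sigma2)))
  s
}

# Griffing method-4 decomposition of a pure cross-deviation table:
# the GCA-like component and grand-mean shift of a symmetric matrix.
gca_leak <- function(s) {
  p <- nrow(s)
  s0 <- s
  diag(s0) <- 0
  rt <- rowSums(s0)
  tot <- sum(rt) / 2
  list(g = (p * rt - 2 * tot) / (p * (p - 2)),
       m = 2 * tot / (p * (p - 1)))
}

sca_project <- function(s) {
  p <- nrow(s)
  diag(s) <- 0
  rt <- rowSums(s)
  tot <- sum(rt) / 2
  out <- s - outer(rt, rt, function(a, b) (a + b) / (p - 2)) +
    2 * tot / ((p - 1) * (p - 2))
  diag(out) <- 0
  out
}

#' Package the true simulated effects in estimator shape
#'
#' Returns the drawn GCA/SCA effects of one simulated trait as a
#' `griffing_effects` object so they can be compared directly with the
#' output of [griffing_effects()].
#'
#' @param sim A `diallel_sim` from [simulate_diallel()].
#' @param trait Trait name (defaults to the first simulated trait).
#' @return A `griffing_effects` object holding the true effects.
#' @export
true_effect_summary <- function(sim, trait = NULL) {
  trait <- trait %||% names(sim$truth)[1]
  tr <- sim$truth[[trait]]
  mean_env <- mean(tr$env_effects[sim$spec$design$environments])
  new_griffing_effects(
    mean = tr$mu + mean_env,
    gca = tr$g,
    sca = tr$s,
    method = sim$spec$design$method,
    trait = trait
  )
}
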
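#' Probability of genealogical incongruence under strict isolation
#'
#' For a sample of two lineages from each of two populations that split `t`
#' generations ago with no subsequent gene flow, a genealogy is incongruent
#' (first coalescence joins lineages from different populations) only if both
#' sampled pairs fail to coalesce before the split. The probability is
#' `(2/3) * exp(-t/(2*N_a)) * exp(-t/(2*N_b))` and does not depend on the
#' ancestral population size.
#'
#' @param t Split time in generations (`>= 0`).
#' @param N_a,N_b Diploid effective sizes of the two sampled populations.
#' @return The incongruence probability, in `(0, 2/3]`.
#' @examples
#' p_incongruence_isolation(t = 200000, N_a = 1e5, N_b = 1e5)  # (2/3) e^-2
#' @export
p_incongruence_isolation <- function(t, N_a, N_b) {
  stopifnot(is.finite(t), is.finite(N_a), is.finite(N_b))
  if (t < 0) stop("split time t must be >= 0")
  if (N_a <= 0 || N_b <= 0) stop("population sizes must be > 0")
  (2 / 3) * exp(-t / (2 * N_a)) * exp(-t / (2 * N_b))
}

#' Probability of genealogical incongruence under the IM model
#'
#' Closed form for the equal-Ne unidirectional IM model:
#' `(2*exp(-2*T*(1+M)) + 2*M) / (3 + 3*M)`. At `M = 0` this reduces to the
#' strict-isolation result; at `T = 0` or `M -> Inf` it approaches the
#' panmictic value 2/3. It equals the summed probability of the 33 incongruent
#' event paths (see [im_paths()]).
#'
#' @param params A [scaled_im_params()] object.
#' @return The incongruence probability, in `(0, 2/3]`.
#' @examples
#' p_incongruence(scaled_im_params(T = 10, M = 1e-4))  # ~ 6.7e-5
#' @export
p_incongruence <- function(params) {
  stopifnot(inherits(params, "scaled_im_params"))
  T <- params$T; M <- params$M
  (2 * exp(-2 * T * (1 + M)) + 2 * M) / (3 + 3 * M)
}

#' Expected external branch lengths of incongruent genealogies without gene flow
#'
#' Conditional on incongruence and `me = 0`, all four lineages reach the
#' ancestral population, where the coalescence order is exchangeable. Both
#' total external branch lengths then have expectation `2*t + (8/3)*N_ab`
#' generations, independent of `N_a` and `N_b` -- the symmetry whose breakage
#' by gene flow the Ai/Am statistics detect.
#'
#' @param t Split time in generations.
#' @param N_ab Diploid effective size of the ancestral population.
#' @return A list with `tau_a_bar`, `tau_b_bar` (equal, in generations) and
#'   `units = "generations"`.
#' @examples
#' expected_tau_incongruent_isolation(t = 2e5, N_ab = 1e5)
#' @export
expected_tau_incongruent_isolation <- function(t, N_ab) {
  stopifnot(is.finite(t), is.finite(N_ab))
  if (t < 0) stop("split time t must be >= 0")
  if (N_ab <= 0) stop("N_ab must be > 0")
  v <- 2 * t + (8 / 3) * N_ab
  list(tau_a_bar = v, tau_b_bar = v, units = "generations")
}

#' Enumerate the event paths of the equal-Ne unidirectional IM model
#'
#' Enumerates every ordered sequence of events -- pairwise coalescence,
#' migration of a lineage from A to B (backwards in time), and the population
#' split -- that takes a 2+2 sample from its initial configuration to the MRCA.
#' There are 95 such paths, of which 33 produce an incongruent topology (their
#' genealogy contains an `ab` internal branch). Among the incongruent paths,
#' 10 are symmetric (equal conditional expectations of the external branch
#' lengths), 20 form 10 equiprobable pairs whose combined a and b lengths are
#' equal, and 3 are asymmetric: those begin with a migration followed by an
#' a+b coalescence while one a-lineage is still isolated in population A, have
#' zero probability when `M = 0`, and are the sole source of external-branch
#' asymmetry on incongruent genealogies.
#'
#' @param params Optional [scaled_im_params()]. When supplied, per-path
#'   probabilities and conditional expected total external branch lengths
#'   (units of `2*Ne` generations) are evaluated at `(T, M)` and returned as
#'   extra columns. Path probabilities sum to 1.
#' @return A data frame with one row per path: `path_id`, `events`
#'   (`" > "`-separated event sequence), `n_events`, `topology_class`
#'   (`congruent`/`incongruent`), `symmetry_class` (`symmetric`/`paired`/
#'   `asymmetric`, `NA` for congruent paths), `pair_id` (partner path for
#'   paired paths) and, if `params` is given, `probability`, `exp_tau_a`,
#'   `exp_tau_b`.
#' @examples
#' paths <- im_paths()
#' nrow(paths)                                   # 95
#' sum(paths$topology_class == "incongruent")    # 33
#' @export
im_paths <- function(params = NULL) {
  gp <- gf_paths()
  n <- length(gp$paths)
  out <- data.frame(
    path_id = seq_len(n),
    events = vapply(gp$paths, function(p) paste(p$labels, collapse = " > "), ""),
    n_events = vapply(gp$paths, function(p) length(p$labels), 0L),
    topology_class = ifelse(gp$incongruent, "incongruent", "congruent"),
    symmetry_class = gp$symmetry,
    pair_id = gp$pair_of,
    stringsAsFactors = FALSE)
  if (!is.null(params)) {
    stopifnot(inherits(params, "scaled_im_params"))
    ev <- eval_all_paths(gp$paths, params$T, params$M)
    out$probability <- vapply(ev, function(e) e$G, 0)
    out$exp_tau_a <- vapply(ev, function(e) e$Ea, 0) / out$probability
    out$exp_tau_b <- vapply(ev, function(e) e$Eb, 0) / out$probability
    zero <- out$probability <= 0
    out$exp_tau_a[zero] <- NA_real_
    out$exp_tau_b[zero] <- NA_real_
  }
  out
}

# degenerate-regime guard threshold for conditional ratios
.tt_prob_floor <- 1e-30

# summed E[tau_x * 1(path)] over incongruent paths at a given load
incongruent_moments <- function(T, M, omega = c(a = 0, b = 0, ab = 0, aa = 0)) {
  gp <- gf_paths()
  ev <- eval_all_paths(gp$paths[gp$incongruent], T, M, omega)
  list(P = sum(vapply(ev, function(e) e$G, 0)),
       Ea = sum(vapply(ev, function(e) e$Ea, 0)),
       Eb = sum(vapply(ev, function(e) e$Eb, 0)))
}

#' Expected external branch lengths conditional on incongruence
#'
#' Probability-weighted conditional expectations of the total a and b external
#' branch lengths over the 33 incongruent event paths, normalized by the
#' incongruence probability. With `M = 0` both equal `2*T + 4/3` (the
#' strict-isolation result in scaled units); with `M > 0` the recipient
#' population A has the longer external branches (`tau_a_bar >= tau_b_bar`).
#'
#' @param params A [scaled_im_params()] object.
#' @return A list with `tau_a_bar`, `tau_b_bar` in units of `2*Ne` generations
#'   and `units = "2Ne generations"`.
#' @examples
#' expected_tau_incongruent(scaled_im_params(T = 1, M = 0))  # both 2 + 4/3
#' @export
expected_tau_incongruent <- function(params) {
  stopifnot(inherits(params, "scaled_im_params"))
  mom <- incongruent_moments(params$T, params$M)
  if (!is.finite(mom$P) || mom$P < .tt_prob_floor)
    stop("incongruence probability is numerically degenerate (< 1e-30); ",
         "conditional branch lengths are undefined at these parameters")
  list(tau_a_bar = mom$Ea / mom$P, tau_b_bar = mom$Eb / mom$P,
       units = "2Ne generations")
}

#' Analytic Ai: scaled external-branch asymmetry of incongruent genealogies
#'
#' `Ai = (tau_a_bar - tau_b_bar) / (tau_a_bar + tau_b_bar)` with the
#' expectations conditional on an incongruent topology. `Ai = 0` exactly when
#' `M = 0` or `T = 0`; `Ai > 0` whenever `M > 0` and `T > 0`, the sign
#' indicating that population A receives gene flow forwards in time.
#'
#' @param params A [scaled_im_params()] object.
#' @return The Ai value in `[-1, 1]`.
#' @examples
#' ai_expected(scaled_im_params(T = 1, M = 1))   # 0.12016
#' @export
ai_expected <- function(params) {
  tb <- expected_tau_incongruent(params)
  (tb$tau_a_bar - tb$tau_b_bar) / (tb$tau_a_bar + tb$tau_b_bar)
}

#' Analytic Am: asymmetry conditional on observing a shared heterozygous site
#'
#' The empirically accessible version of [ai_expected()]: expectations of the
#' external branch lengths restricted to incongruent genealogies that carry at
#' least one mutation on the `ab` internal branch (a `hetAB` polymorphism in a
#' block of `block_len` sites). The conditioning reweights genealogies towards
#' long `ab` branches, so Am differs from Ai in scale though not in sign.
#'
#' Computation: with mutations falling on the `ab` branches as a Poisson
#' process of rate `theta = 2*Ne*mu*block_len` per unit of scaled branch
#' length, the transform of each incongruent path evaluated with the `ab`
#' dummy variable loaded by `theta` gives the joint weight of "path and zero
#' `hetAB` mutations". Subtracting the loaded moments from the marginal ones
#' leaves `E[tau_x * 1(>=1 hetAB mutation)]`, whose normalized difference is Am.
#'
#' @param params A [scaled_im_params()] object.
#' @param model A [block_model()] (mutation rate, block length, Ne).
#' @return The Am value in `[-1, 1]`; 0 when `M = 0`.
#' @examples
#' am_expected(scaled_im_params(T = 1, M = 1),
#'             block_model(mu = 1e-8, block_len = 200, Ne = 1e5))  # 0.04394
#' @export
am_expected <- function(params, model) {
  stopifnot(inherits(params, "scaled_im_params"), inherits(model, "block_model"))
  theta <- block_theta(model)
  m0 <- incongruent_moments(params$T, params$M)
  mL <- incongruent_moments(params$T, params$M,
                            omega = c(a = 0, b = 0, ab = theta, aa = 0))
  p_mut <- m0$P - mL$P  # P(incongruent and >= 1 hetAB mutation)
  if (!is.finite(p_mut) || p_mut < .tt_prob_floor)
    stop("probability of observing a hetAB mutation is numerically degenerate ",
         "(< 1e-30); Am is undefined at these parameters")
  num_a <- m0$Ea - mL$Ea
  num_b <- m0$Eb - mL$Eb
  (num_a - num_b) / (num_a + num_b)
}

#' Mutation-count asymmetry under strict isolation with population-specific
#' mutation rates
#'
#' Ai estimated from mutation counts is biased away from zero when the two
#' sampled populations mutate at different rates, even with no gene flow.
#' Under strict isolation the bias has the closed form
#' `Ai = 3*t*(mu_a - mu_b) / (3*t*(mu_a + mu_b) + 8*N_ab*mu_ab)`:
#' external branches spend `t` generations in their own population (rate
#' `mu_a` or `mu_b`) and the remaining `(4/3)*N_ab` expected generations per
#' branch in the ancestral population (rate `mu_ab`).
#'
#' @param t Split time in generations.
#' @param N_ab Ancestral diploid effective size.
#' @param mu_a,mu_b,mu_ab Per-site per-generation mutation rates in population
#'   A, population B and the ancestral population (all `> 0`).
#' @return The mutation-count Ai; 0 when `mu_a == mu_b`.
#' @examples
#' ai_mutation_bias(t = 2e5, N_ab = 1e5, mu_a = 2e-8, mu_b = 1e-8,
#'                  mu_ab = 1e-8)  # 0.231
#' @export
ai_mutation_bias <- function(t, N_ab, mu_a, mu_b, mu_ab) {
  stopifnot(is.finite(t), is.finite(N_ab), is.finite(mu_a), is.finite(mu_b),
            is.finite(mu_ab))
  if (t < 0) stop("split time t must be >= 0")
  if (N_ab <= 0) stop("N_ab must be > 0")
  if (mu_a <= 0 || mu_b <= 0 || mu_ab <= 0)
    stop("mutation rates must be > 0")
  3 * t * (mu_a - mu_b) / (3 * t * (mu_a + mu_b) + 8 * N_ab * mu_ab)
}
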
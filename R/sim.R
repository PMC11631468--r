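#' Simulate genealogies of a 2+2 sample under the IM model
#'
#' Exact draws from the structured coalescent for two lineages sampled in each
#' population (one diploid each), under the full five-parameter IM model with
#' optional bidirectional migration. This is the package's Monte-Carlo oracle:
#' independent, non-recombining genealogies with total branch lengths recorded
#' by branch type on the unrooted tree.
#'
#' External (a/b) branch time is additionally split by the population the
#' lineage occupied (`a_in_A`, `a_in_B`, `a_in_AB`, likewise for b), which
#' supports experiments with population-specific mutation rates.
#'
#' @param params An [im_params()] object (natural units).
#' @param n Number of independent replicates.
#' @param seed Integer seed; the same seed reproduces the output bit-for-bit.
#' @return A data frame with one row per replicate: `incongruent` (0/1),
#'   `tau_a`, `tau_b`, `tau_aa`, `tau_ab` (generations) and the six occupancy
#'   columns.
#' @examples
#' g <- sim_genealogies(im_params(1e5, 1e5, 1e5, t = 0), n = 100, seed = 1)
#' mean(g$incongruent)  # ~ 2/3 in the panmictic limit
#' @export
sim_genealogies <- function(params, n, seed) {
  stopifnot(inherits(params, "im_params"), n >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is required for simulation")
  set.seed(as.integer(seed))
  m <- .sample_genealogies_cpp(as.integer(n), params$N_a, params$N_b,
                               params$N_ab, params$t, params$m_a, params$m_b)
  as.data.frame(m)
}

#' Drop Poisson mutations on simulated genealogies
#'
#' Infinite-sites mutation counts for a block of sequence: independent Poisson
#' draws with mean `mu * block_len * tau` for each branch type, mapped to the
#' four polymorphism classes observable from two unphased diploids. Mutations
#' on external a/b branches give `hetA`/`hetB` sites, on the `ab` internal
#' branch `hetAB` sites (possible only for incongruent genealogies), and on
#' the `aa`/`bb` internal branch fixed differences.
#'
#' @param genealogies A data frame from [sim_genealogies()] (branch lengths in
#'   generations).
#' @param model A [block_model()]; its `Ne` is not used here because branch
#'   lengths are already in generations.
#' @param seed Integer seed.
#' @return A data frame with columns `k_hetA`, `k_hetB`, `k_hetAB`, `k_fixed`.
#' @export
drop_mutations <- function(genealogies, model, seed) {
  stopifnot(is.data.frame(genealogies), inherits(model, "block_model"))
  if (missing(seed) || is.null(seed)) stop("a seed is required for simulation")
  set.seed(as.integer(seed))
  rate <- model$mu * model$block_len
  n <- nrow(genealogies)
  data.frame(
    k_hetA  = rpois(n, rate * genealogies$tau_a),
    k_hetB  = rpois(n, rate * genealogies$tau_b),
    k_hetAB = rpois(n, rate * genealogies$tau_ab),
    k_fixed = rpois(n, rate * genealogies$tau_aa))
}

# delete-one-group block jackknife for a pooled ratio (sum(x)-sum(y))/(sum(x)+sum(y));
# `group` assigns each observation to one of g groups
jackknife_pooled_ratio <- function(x, y, group) {
  sx <- tapply(x, group, sum)
  sy <- tapply(y, group, sum)
  keep <- !is.na(sx)
  sx <- sx[keep]; sy <- sy[keep]
  g <- length(sx)
  if (g < 2) stop("block jackknife needs at least 2 nonempty groups")
  tx <- sum(sx); ty <- sum(sy)
  point <- (tx - ty) / (tx + ty)
  loo <- ((tx - sx) - (ty - sy)) / ((tx - sx) + (ty - sy))
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(point = point, se = se,
       ci_low = point - 1.96 * se, ci_high = point + 1.96 * se,
       n_groups = g)
}

# contiguous group assignment: indices 1..n into g groups of near-equal size
contiguous_groups <- function(n, g) {
  if (g > n) g <- n
  as.integer(ceiling(seq_len(n) / (n / g)))
}

#' Monte-Carlo estimate of Ai with block-jackknife confidence interval
#'
#' Simulates `n_reps` independent genealogies, restricts to those with an
#' incongruent topology, and computes the pooled external-branch asymmetry
#' `Ai = (sum tau_a - sum tau_b) / (sum tau_a + sum tau_b)`. The standard
#' error comes from a delete-one-group jackknife over `n_groups` contiguous
#' replicate groups; the 95% interval is `point +/- 1.96 * SE`.
#'
#' @param params An [im_params()] object.
#' @param n_reps Number of replicates (`>= n_groups`).
#' @param n_groups Number of jackknife groups (minimum 25).
#' @param seed Integer seed.
#' @return A list of class `sim_estimate`: `statistic`, `point`, `se`,
#'   `ci_low`, `ci_high`, `n_replicates`, `n_used`, `n_groups`.
#' @examples
#' \donttest{
#' p <- im_params(1e5, 1e5, 1e5, t = 2e5, m_a = 5e-6)  # T = 1, M = 1
#' mc_ai(p, n_reps = 20000, seed = 7)
#' }
#' @export
mc_ai <- function(params, n_reps, n_groups = 25, seed) {
  stopifnot(n_groups >= 25, n_reps >= n_groups)
  g <- sim_genealogies(params, n_reps, seed)
  grp <- contiguous_groups(n_reps, n_groups)
  inc <- g$incongruent == 1
  if (!any(inc)) stop("no incongruent replicates; cannot estimate Ai")
  jk <- jackknife_pooled_ratio(g$tau_a[inc], g$tau_b[inc], grp[inc])
  structure(c(list(statistic = "Ai"), jk,
              list(n_replicates = n_reps, n_used = sum(inc))),
            class = "sim_estimate")
}

#' Monte-Carlo estimate of Am with block-jackknife confidence interval
#'
#' As [mc_ai()], but conditioning on genealogies whose block carries at least
#' one `hetAB` mutation (Poisson with mean `mu * block_len * tau_ab`), the
#' observable subset the empirical Am statistic is built on. The estimate uses
#' the branch lengths of the qualifying replicates.
#'
#' @inheritParams mc_ai
#' @param model A [block_model()].
#' @return A list of class `sim_estimate` (see [mc_ai()]).
#' @export
mc_am <- function(params, model, n_reps, n_groups = 25, seed) {
  stopifnot(n_groups >= 25, n_reps >= n_groups)
  g <- sim_genealogies(params, n_reps, seed)
  k_ab <- rpois(n_reps, model$mu * model$block_len * g$tau_ab)
  grp <- contiguous_groups(n_reps, n_groups)
  cond <- k_ab >= 1
  if (!any(cond)) stop("no replicates with a hetAB mutation; cannot estimate Am")
  jk <- jackknife_pooled_ratio(g$tau_a[cond], g$tau_b[cond], grp[cond])
  structure(c(list(statistic = "Am"), jk,
              list(n_replicates = n_reps, n_used = sum(cond))),
            class = "sim_estimate")
}

#' @exportS3Method print sim_estimate
print.sim_estimate <- function(x, ...) {
  cat(sprintf("%s = %.5f (95%% CI %.5f, %.5f); SE %.5f; %d/%d replicates, %d jackknife groups\n",
              x$statistic, x$point, x$ci_low, x$ci_high, x$se,
              x$n_used, x$n_replicates, x$n_groups))
  invisible(x)
}
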
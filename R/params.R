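#' Scaled isolation-with-migration parameters
#'
#' Parameters of the equal-Ne, unidirectional IM model in coalescent units, the
#' setting in which all closed-form results of the package are derived. Time is
#' measured in units of `2*Ne` generations and the pairwise coalescence rate is 1.
#'
#' @param T Split time in units of `2*Ne` generations (`T = t / (2*Ne)`).
#' @param M Scaled migration rate `M = 2*Ne*me`. Lineages move from population A
#'   to population B backwards in time, i.e. population A *receives* migrants
#'   forwards in time. Positive `Ai`/`Am` therefore indicates gene flow into A.
#'
#' @return An object of class `scaled_im_params`.
#' @examples
#' scaled_im_params(T = 1, M = 1)
#' @export
scaled_im_params <- function(T, M) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T),
            is.numeric(M), length(M) == 1L, is.finite(M))
  if (T < 0) stop("split time T must be >= 0")
  if (M < 0) stop("scaled migration rate M must be >= 0")
  structure(list(T = as.numeric(T), M = as.numeric(M)),
            class = "scaled_im_params")
}

#' @exportS3Method print scaled_im_params
print.scaled_im_params <- function(x, ...) {
  cat(sprintf("Scaled IM parameters: T = %g (2Ne gens), M = %g (= 2Ne me, A <- B forwards)\n",
              x$T, x$M))
  invisible(x)
}

#' Full isolation-with-migration parameters in natural units
#'
#' The five-parameter IM model used by the Monte-Carlo simulator: two sampled
#' populations of diploid effective size `N_a` and `N_b` that split from an
#' ancestral population of size `N_ab` a number `t` of generations ago, with
#' (possibly bidirectional) migration after the split.
#'
#' @param N_a,N_b,N_ab Diploid effective population sizes (A, B, ancestral).
#' @param t Split time in generations.
#' @param m_a Backwards-in-time per-generation migration rate of lineages from
#'   A to B (population A receives migrants forwards in time).
#' @param m_b Backwards-in-time per-generation migration rate from B to A.
#'
#' @return An object of class `im_params`.
#' @examples
#' # Equal-Ne history with scaled migration M = 2*Ne*m_a = 1:
#' im_params(N_a = 1e5, N_b = 1e5, N_ab = 1e5, t = 2e5, m_a = 5e-6)
#' @export
im_params <- function(N_a, N_b, N_ab, t, m_a = 0, m_b = 0) {
  vals <- c(N_a = N_a, N_b = N_b, N_ab = N_ab, t = t, m_a = m_a, m_b = m_b)
  stopifnot(all(is.finite(vals)))
  if (N_a <= 0 || N_b <= 0 || N_ab <= 0) stop("population sizes must be > 0")
  if (t < 0) stop("split time t must be >= 0")
  if (m_a < 0 || m_b < 0) stop("migration rates must be >= 0")
  structure(list(N_a = as.numeric(N_a), N_b = as.numeric(N_b),
                 N_ab = as.numeric(N_ab), t = as.numeric(t),
                 m_a = as.numeric(m_a), m_b = as.numeric(m_b)),
            class = "im_params")
}

#' @exportS3Method print im_params
print.im_params <- function(x, ...) {
  cat(sprintf("IM parameters: N_a=%g N_b=%g N_ab=%g t=%g m_a=%g m_b=%g\n",
              x$N_a, x$N_b, x$N_ab, x$t, x$m_a, x$m_b))
  invisible(x)
}

#' Convert natural-unit IM parameters to coalescent-scaled parameters
#'
#' Only defined for the regime the closed-form results cover: equal effective
#' sizes in all three populations and unidirectional migration (`m_b = 0`).
#'
#' @param params An [im_params()] object with `N_a == N_b == N_ab` and `m_b == 0`.
#' @return A [scaled_im_params()] object with `T = t/(2Ne)` and `M = 2*Ne*m_a`.
#' @export
as_scaled_im_params <- function(params) {
  stopifnot(inherits(params, "im_params"))
  if (params$N_a != params$N_b || params$N_a != params$N_ab)
    stop("scaled parameters require equal Ne in all three populations")
  if (params$m_b != 0)
    stop("scaled parameters require unidirectional migration (m_b = 0)")
  Ne <- params$N_a
  scaled_im_params(T = params$t / (2 * Ne), M = 2 * Ne * params$m_a)
}

#' Convert scaled IM parameters to natural units
#'
#' @param params A [scaled_im_params()] object.
#' @param Ne Diploid effective size applied to all three populations.
#' @return An [im_params()] object.
#' @export
as_im_params <- function(params, Ne) {
  stopifnot(inherits(params, "scaled_im_params"), Ne > 0)
  im_params(N_a = Ne, N_b = Ne, N_ab = Ne,
            t = params$T * 2 * Ne, m_a = params$M / (2 * Ne), m_b = 0)
}

#' Block mutation model
#'
#' Mutation model for a block of sequence: a per-site per-generation rate `mu`,
#' a block length in bases, and the diploid `Ne` used to convert scaled branch
#' lengths to generations. The total mutation rate on a branch of scaled length
#' `tau` (units of `2*Ne` generations) is `2 * Ne * mu * block_len * tau`.
#'
#' @param mu Per-site per-generation mutation rate.
#' @param block_len Block size in bases. The empirical estimator uses odd block
#'   sizes `2l+1` centred on a focal site; the analytic operations accept any
#'   positive length (the reference default is 200 bp).
#' @param Ne Diploid effective size used for the scaled-to-generations conversion.
#' @return An object of class `block_model`.
#' @examples
#' block_model(mu = 1e-8, block_len = 200, Ne = 1e5)
#' @export
block_model <- function(mu, block_len, Ne) {
  stopifnot(is.finite(mu), is.finite(block_len), is.finite(Ne))
  if (mu <= 0) stop("mutation rate mu must be > 0")
  if (block_len < 1) stop("block_len must be >= 1")
  if (Ne <= 0) stop("Ne must be > 0")
  structure(list(mu = as.numeric(mu), block_len = as.numeric(block_len),
                 Ne = as.numeric(Ne)),
            class = "block_model")
}

# scaled per-branch mutation load: Poisson rate per unit of scaled branch length
block_theta <- function(model) 2 * model$Ne * model$mu * model$block_len
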
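# Thin adapter around an established coalescent simulator (msprime, driven
# through the system `python`) for recombining sequences. The adapter's
# contract: for each replicate sequence it returns either (mode "branch")
# per-block integrated branch lengths by branch type together with a Poisson
# hetAB presence indicator, aggregated per block size, or (mode "genotypes")
# the derived-allele counts of every biallelic site. Everything downstream
# (pooling, jackknife, VCF writing) stays in R.

find_adapter_python <- function() {
  py <- Sys.getenv("TWOTAXON_PYTHON", Sys.which("python"))
  if (!nzchar(py)) return(NULL)
  ok <- tryCatch(
    system2(py, c("-c", shQuote("import msprime")),
            stdout = FALSE, stderr = FALSE) == 0,
    error = function(e) FALSE, warning = function(w) FALSE)
  if (isTRUE(ok)) py else NULL
}

run_recomb_adapter <- function(params, model, r, seq_len, n_reps,
                               block_sizes, seed, mode) {
  py <- find_adapter_python()
  if (is.null(py))
    stop("recombination-enabled simulation needs a python interpreter with ",
         "msprime on the PATH (or TWOTAXON_PYTHON); for r = 0 use the ",
         "built-in sampler via sim_genealogies()/mc_am() instead")
  script <- system.file("python", "recomb_sim.py", package = "twotaxon")
  if (script == "") stop("bundled adapter script not found")
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  args <- c(script, "--mode", mode,
            "--na", params$N_a, "--nb", params$N_b, "--nab", params$N_ab,
            "--t", params$t, "--ma", params$m_a, "--mb", params$m_b,
            "--mu", model$mu, "--r", r, "--seq-len", seq_len,
            "--n-reps", n_reps, "--seed", seed, "--out", out)
  if (!is.null(block_sizes))
    args <- c(args, "--block-sizes", paste(block_sizes, collapse = ","))
  status <- system2(py, args, stdout = FALSE, stderr = "")
  if (status != 0) stop("msprime adapter failed with exit status ", status)
  utils::read.delim(out, stringsAsFactors = FALSE)
}

#' Am across block sizes from recombining simulated sequences
#'
#' Simulates `n_reps` recombining sequences of `seq_len` bases under the full
#' IM model with the msprime coalescent simulator (through a bundled adapter
#' script run with the system `python`), then estimates Am per block size from
#' the marginal genealogies: each block's integrated a/b branch lengths enter
#' the pooled ratio if the block carries at least one `hetAB` mutation
#' (Poisson on the block's integrated `ab` branch length). Jackknife groups
#' are contiguous groups of whole replicates, so blocks from the same
#' recombining sequence are never split across groups.
#'
#' With `r = 0` every block size gives the same expectation as [mc_am()]; with
#' `r > 0` small blocks track the non-recombining analytic value
#' ([am_expected()]) while large blocks approach the unconditional asymmetry
#' of a random sample of genealogies.
#'
#' @param params An [im_params()] object.
#' @param model A [block_model()] (only `mu` is used; block sizes come from
#'   `block_sizes`).
#' @param r Per-base per-generation recombination rate (`>= 0`).
#' @param seq_len Sequence length per replicate, in bases.
#' @param n_reps Number of replicate sequences.
#' @param block_sizes Integer block sizes in bases.
#' @param seed Integer seed (passed to msprime and to the Poisson thinning).
#' @param n_groups Number of jackknife replicate groups (minimum 25).
#' @return A data frame with one row per block size: `block_size`, `am`,
#'   `se`, `ci_low`, `ci_high`, `n_blocks_used`, `n_reps`.
#' @export
sim_recomb_profile <- function(params, model, r, seq_len, n_reps,
                               block_sizes, seed, n_groups = 25) {
  stopifnot(inherits(params, "im_params"), inherits(model, "block_model"),
            r >= 0, seq_len >= 1, n_reps >= n_groups, n_groups >= 25,
            all(block_sizes >= 1))
  if (missing(seed)) stop("a seed is required for simulation")
  raw <- run_recomb_adapter(params, model, r, seq_len, n_reps,
                            block_sizes, seed, mode = "branch")
  grp_of_rep <- contiguous_groups(n_reps, n_groups)
  rows <- lapply(sort(unique(raw$block_size)), function(bs) {
    d <- raw[raw$block_size == bs, , drop = FALSE]
    if (sum(d$sum_tau_a + d$sum_tau_b) == 0)
      return(data.frame(block_size = bs, am = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_blocks_used = 0L, n_reps = n_reps))
    jk <- jackknife_pooled_ratio(d$sum_tau_a, d$sum_tau_b,
                                 grp_of_rep[d$rep + 1L])
    data.frame(block_size = bs, am = jk$point, se = jk$se,
               ci_low = jk$ci_low, ci_high = jk$ci_high,
               n_blocks_used = sum(d$n_cond), n_reps = n_reps)
  })
  do.call(rbind, rows)
}
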
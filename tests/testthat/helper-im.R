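# shared fixtures: the equal-Ne unidirectional history with Ne = 100,000,
# t = 200,000 generations (T = 1) used throughout as the reference condition
table1_params <- function(M = 1) {
  Ne <- 1e5
  im_params(N_a = Ne, N_b = Ne, N_ab = Ne, t = 2e5, m_a = M / (2 * Ne))
}

table1_model <- function(block_len = 200) block_model(1e-8, block_len, 1e5)

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

# standard error of a conditional mean from simulated values
mean_se <- function(x) stats::sd(x) / sqrt(length(x))

adapter_available <- function() !is.null(twotaxon:::find_adapter_python())
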
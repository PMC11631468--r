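#' Specify a synthetic VCF fixture
#'
#' Bundles a demographic scenario, mutation model, recombination rate and seed
#' into a reproducible recipe for [make_fixture()]. Named scenarios provide
#' reference defaults (Ne = 100,000, t = 200,000 generations, mu = 1e-8,
#' 200 bp blocks); pass `params` to override.
#'
#' Scenarios: `SI-equal-Ne` (strict isolation, equal sizes), `SI-unequal-Ne`
#' (strict isolation, N_a doubled), `IM-unidirectional` (M = 1 into A),
#' `IM-bidirectional` (M_a = 1, M_b = 0.25), `continent-island` (N_b doubled,
#' gene flow into the smaller population A at M = 1).
#'
#' @param scenario Scenario name (see above).
#' @param params Optional [im_params()] overriding the scenario preset.
#' @param model A [block_model()]; `block_len` is the per-locus sequence
#'   length for non-recombining fixtures.
#' @param r Per-base per-generation recombination rate. `r = 0` (default)
#'   simulates independent loci with the built-in sampler; `r > 0` simulates
#'   recombining sequences through the msprime adapter (see
#'   [sim_recomb_profile()] for requirements).
#' @param n_loci Number of independent loci (`r = 0`) or replicate sequences
#'   (`r > 0`).
#' @param seq_len Sequence length per replicate when `r > 0` (default 66 kb).
#' @param seed Integer seed; fixtures are deterministic given the seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(scenario = c("SI-equal-Ne", "SI-unequal-Ne",
                                      "IM-unidirectional", "IM-bidirectional",
                                      "continent-island"),
                         params = NULL,
                         model = block_model(mu = 1e-8, block_len = 200, Ne = 1e5),
                         r = 0, n_loci = 1000, seq_len = 66000, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("a seed is required for fixture generation")
  if (is.null(params)) {
    Ne <- 1e5; t <- 2e5; m1 <- 1 / (2 * Ne)  # M = 1
    params <- switch(scenario,
      "SI-equal-Ne"       = im_params(Ne, Ne, Ne, t),
      "SI-unequal-Ne"     = im_params(2 * Ne, Ne, Ne, t),
      "IM-unidirectional" = im_params(Ne, Ne, Ne, t, m_a = m1),
      "IM-bidirectional"  = im_params(Ne, Ne, Ne, t, m_a = m1, m_b = m1 / 4),
      "continent-island"  = im_params(Ne, 2 * Ne, Ne, t, m_a = m1))
  }
  stopifnot(inherits(params, "im_params"), inherits(model, "block_model"),
            r >= 0, n_loci >= 1)
  structure(list(scenario = scenario, params = params, model = model,
                 r = r, n_loci = as.integer(n_loci),
                 seq_len = as.integer(seq_len), seed = as.integer(seed)),
            class = "fixture_spec")
}

# genotype strings for a site class with random REF/ALT polarity
# (flip = TRUE means the REF allele is the derived one)
class_genotypes <- function(class, flip) {
  hom_anc <- ifelse(flip, "1/1", "0/0")
  hom_der <- ifelse(flip, "0/0", "1/1")
  ga <- ifelse(class == "hetA" | class == "hetAB", "0/1",
        ifelse(class == "fixed", hom_der, hom_anc))
  gb <- ifelse(class == "hetB" | class == "hetAB", "0/1",
        ifelse(class == "fixed", hom_anc, hom_der))
  # for fixed sites A carries the derived allele on the aa branch by
  # convention; polarity is randomized by `flip`, so the estimator cannot
  # exploit the choice
  list(a = ga, b = gb)
}

vcf_header <- function(contigs, lengths) {
  c("##fileformat=VCFv4.2",
    "##source=twotaxon synthetic fixture",
    sprintf("##contig=<ID=%s,length=%d>", contigs, lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA0\tB0")
}

#' Write a synthetic VCF fixture and parameter sidecar
#'
#' Generates biallelic SNP records for two diploid samples (`A0`, `B0`) from
#' simulated genealogies. For `r = 0` each locus is an independent
#' non-recombining block written as its own contig (`L000001`, ...), with
#' per-class site counts drawn by [drop_mutations()] and positions placed
#' uniformly without collision; for `r > 0` replicate recombining sequences
#' are simulated through the msprime adapter and written one contig per
#' replicate. REF/ALT polarity is randomized per site. A plain-text sidecar
#' (`<out>.sidecar.txt`) records the generating parameters and, for equal-Ne
#' unidirectional non-recombining scenarios, the analytic expected Am.
#'
#' @param spec A [fixture_spec()].
#' @param out_path Output VCF path (plain text).
#' @return Invisibly, the sidecar values as a named character vector.
#' @export
make_fixture <- function(spec, out_path) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$params
  L <- spec$model$block_len
  if (spec$r == 0) {
    g <- sim_genealogies(p, spec$n_loci, seed = spec$seed)
    k <- drop_mutations(g, spec$model, seed = spec$seed + 1L)
    set.seed(spec$seed + 2L)
    n_sites <- k$k_hetA + k$k_hetB + k$k_hetAB + k$k_fixed
    if (any(n_sites > L))
      stop("some loci received more mutations than sites; increase block_len")
    contigs <- sprintf("L%06d", seq_len(spec$n_loci))
    occ <- which(n_sites > 0)
    # positions uniform without collision within each locus; classes
    # interleaved along the locus
    pos <- unlist(lapply(occ, function(i) sort(sample.int(L, n_sites[i]))))
    cls <- unlist(lapply(occ, function(i)
      sample(rep(c("hetA", "hetB", "hetAB", "fixed"),
                 times = c(k$k_hetA[i], k$k_hetB[i], k$k_hetAB[i],
                           k$k_fixed[i])))))
    sites <- if (length(occ))
      data.frame(contig = rep(contigs[occ], n_sites[occ]), pos = pos,
                 class = cls, stringsAsFactors = FALSE) else NULL
    lens <- rep(L, spec$n_loci)
  } else {
    raw <- run_recomb_adapter(p, spec$model, spec$r, spec$seq_len,
                              spec$n_loci, block_sizes = NULL,
                              seed = spec$seed, mode = "genotypes")
    # stacked/back mutations can leave a biallelic record with no observed
    # segregation; only segregating genotype configurations are written
    raw <- raw[(raw$g_a + raw$g_b) %in% 1:3, , drop = FALSE]
    contigs <- sprintf("R%05d", seq_len(spec$n_loci))
    set.seed(spec$seed + 2L)
    sites <- NULL
    if (nrow(raw)) {
      sites <- data.frame(contig = contigs[raw$rep + 1L], pos = raw$pos,
                          g_a = raw$g_a, g_b = raw$g_b,
                          stringsAsFactors = FALSE)
    }
    lens <- rep(spec$seq_len, spec$n_loci)
  }

  if (is.null(sites) || nrow(sites) == 0) {
    writeLines(vcf_header(contigs, lens), out_path)
  } else {
    n <- nrow(sites)
    flip <- runif(n) < 0.5
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    if (spec$r == 0) {
      gts <- class_genotypes(sites$class, flip)
    } else {
      # derived allele count -> genotype; `flip` makes REF the derived allele
      gt_of <- function(cnt, flp) {
        ifelse(cnt == 1L, "0/1", ifelse((cnt == 2L) != flp, "1/1", "0/0"))
      }
      gts <- list(a = gt_of(sites$g_a, flip), b = gt_of(sites$g_b, flip))
    }
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s\t%s",
                    sites$contig, sites$pos, ref, alt, gts$a, gts$b)
    writeLines(c(vcf_header(contigs, lens), body), out_path)
  }

  side <- c(scenario = spec$scenario,
            N_a = p$N_a, N_b = p$N_b, N_ab = p$N_ab, t = p$t,
            m_a = p$m_a, m_b = p$m_b,
            mu = spec$model$mu, block_len = spec$model$block_len,
            Ne = spec$model$Ne, r = spec$r, n_loci = spec$n_loci,
            seq_len = if (spec$r > 0) spec$seq_len else NA,
            seed = spec$seed, samples = "A0,B0")
  scaled_ok <- p$N_a == p$N_b && p$N_a == p$N_ab && p$m_b == 0 && spec$r == 0
  if (scaled_ok) {
    sp <- as_scaled_im_params(p)
    side <- c(side,
              expected_am = if (sp$M > 0)
                format(am_expected(sp, spec$model), digits = 10) else "0")
  }
  writeLines(paste(names(side), unname(side), sep = "="),
             paste0(out_path, ".sidecar.txt"))
  invisible(side)
}
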
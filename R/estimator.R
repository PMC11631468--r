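#' Classify biallelic genotype pairs into polymorphism classes
#'
#' Total classification of a biallelic SNP from the unphased diploid genotypes
#' of one sample per population: both heterozygous for the same alleles ->
#' `hetAB`; heterozygous only in A -> `hetA`; only in B -> `hetB`; opposite
#' homozygotes -> `fixed`; identical homozygotes -> `invariant`; anything with
#' missing or non-biallelic alleles -> `excluded`. The classification uses
#' only heterozygosity and allele identity, so it is invariant to phase
#' (`0/1` vs `0|1` vs `1|0`) and to swapping REF and ALT.
#'
#' @param gt_a,gt_b Character vectors of VCF GT fields (e.g. `"0/1"`, `"0|1"`,
#'   `"./."`); recycled to a common length.
#' @return A character vector with values in
#'   `c("hetA", "hetB", "hetAB", "fixed", "invariant", "excluded")`.
#' @examples
#' classify_site(c("0/1", "0/0", "0/1"), c("0/1", "1/1", "./."))
#' @export
classify_site <- function(gt_a, gt_b) {
  n <- max(length(gt_a), length(gt_b))
  gt_a <- rep_len(as.character(gt_a), n)
  gt_b <- rep_len(as.character(gt_b), n)
  ok <- function(g) !is.na(g) & grepl("^[01][/|][01]$", g)
  va <- ok(gt_a); vb <- ok(gt_b)
  a1 <- substr(gt_a, 1, 1); a2 <- substr(gt_a, 3, 3)
  b1 <- substr(gt_b, 1, 1); b2 <- substr(gt_b, 3, 3)
  het_a <- a1 != a2
  het_b <- b1 != b2
  out <- rep("excluded", n)
  valid <- va & vb
  out[valid & het_a & het_b] <- "hetAB"
  out[valid & het_a & !het_b] <- "hetA"
  out[valid & !het_a & het_b] <- "hetB"
  hom <- valid & !het_a & !het_b
  out[hom & a1 != b1] <- "fixed"
  out[hom & a1 == b1] <- "invariant"
  out
}

#' Read and classify biallelic SNPs from a VCF file
#'
#' Parses a VCF (plain or bgzipped) with `vcfR`, restricts to biallelic SNP
#' records (single-base REF and ALT), and classifies each site from the GT
#' fields of the two named samples. Indels, multiallelic records and sites
#' with missing or malformed genotypes are classified `excluded`; counts of
#' excluded records are reported to standard error.
#'
#' @param vcf_path Path to the VCF file.
#' @param sample_a,sample_b Sample names (population A and B respectively).
#' @param verbose Report per-class counts to standard error.
#' @return A data frame sorted by (contig, pos) with columns `contig`, `pos`
#'   (1-based) and `class`.
#' @export
read_site_classes <- function(vcf_path, sample_a, sample_b, verbose = TRUE) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("no variant records in ", vcf_path)
  samples <- colnames(v@gt)[-1]
  for (s in c(sample_a, sample_b)) {
    if (!s %in% samples)
      stop("sample '", s, "' not in VCF; available samples: ",
           paste(samples, collapse = ", "))
  }
  fix <- v@fix
  gt <- vcfR::extract.gt(v, element = "GT")
  bases <- c("A", "C", "G", "T")
  snp <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  cls <- classify_site(gt[, sample_a], gt[, sample_b])
  cls[!snp] <- "excluded"
  out <- data.frame(contig = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (verbose) {
    tb <- table(factor(out$class, levels = c("hetA", "hetB", "hetAB", "fixed",
                                             "invariant", "excluded")))
    message("classified ", nrow(out), " records on ",
            length(unique(out$contig)), " contig(s): ",
            paste(names(tb), tb, sep = "=", collapse = " "))
  }
  out
}

#' Collect per-hetAB windows of flanking polymorphism counts
#'
#' For every `hetAB` site, counts the `hetA` and `hetB` sites within `l` bases
#' on the same contig (closed window `[pos - l, pos + l]`, block size
#' `2l + 1`). Every `hetAB` site yields a window, including windows containing
#' other `hetAB` sites (those contribute nothing to the counts; flanking
#' `hetA`/`hetB` sites shared by overlapping windows are counted in each).
#'
#' @param sites A data frame from [read_site_classes()] (must be sorted by
#'   contig and position; an unsorted input is an error).
#' @param l Half-window in bases (`>= 1`).
#' @return A data frame with one row per `hetAB` site: `contig`, `pos`,
#'   `k_hetA_prime`, `k_hetB_prime`.
#' @examples
#' s <- data.frame(contig = "c1", pos = c(450, 490, 500, 520),
#'                 class = c("hetA", "hetB", "hetAB", "hetA"))
#' collect_windows(s, l = 100)  # k'A = 2, k'B = 1
#' @export
collect_windows <- function(sites, l) {
  stopifnot(is.data.frame(sites), all(c("contig", "pos", "class") %in% names(sites)),
            is.finite(l), l >= 1)
  l <- as.integer(l)
  pieces <- lapply(split(seq_len(nrow(sites)), sites$contig), function(ix) {
    pos <- sites$pos[ix]
    if (is.unsorted(pos, strictly = FALSE))
      stop("sites are not sorted by position within contig '",
           sites$contig[ix[1]], "'")
    cls <- sites$class[ix]
    focal <- pos[cls == "hetAB"]
    if (!length(focal)) return(NULL)
    pa <- pos[cls == "hetA"]
    pb <- pos[cls == "hetB"]
    ka <- findInterval(focal + l, pa) - findInterval(focal - l - 1L, pa)
    kb <- findInterval(focal + l, pb) - findInterval(focal - l - 1L, pb)
    data.frame(contig = sites$contig[ix[1]], pos = focal,
               k_hetA_prime = ka, k_hetB_prime = kb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(contig = character(0), pos = integer(0),
                      k_hetA_prime = integer(0), k_hetB_prime = integer(0))
  rownames(out) <- NULL
  out
}

#' Pooled Am from a set of windows
#'
#' `Am = (sum k'A - sum k'B) / (sum k'A + sum k'B)`: the ratio of summed
#' counts over all windows (not a mean of per-window ratios, which would be
#' undefined for the many empty windows).
#'
#' @param windows A data frame from [collect_windows()].
#' @return The pooled Am value.
#' @export
am_from_windows <- function(windows) {
  stopifnot(is.data.frame(windows))
  ka <- sum(windows$k_hetA_prime)
  kb <- sum(windows$k_hetB_prime)
  if (ka + kb == 0)
    stop("no informative windows: all hetA'/hetB' counts are zero")
  (ka - kb) / (ka + kb)
}

# resolve a grouping spec to a per-window group vector
window_groups <- function(windows, grouping = "auto", min_groups = 25) {
  n <- nrow(windows)
  if (length(grouping) == n && n > 1) return(grouping)  # explicit assignment
  if (identical(grouping, "auto")) {
    grouping <- if (length(unique(windows$contig)) >= min_groups) "contig" else "snps"
  }
  if (identical(grouping, "contig")) return(windows$contig)
  if (identical(grouping, "snps")) {
    g <- min(min_groups, n)
    return(contiguous_groups(n, g))
  }
  if (is.numeric(grouping) && length(grouping) == 1) {
    # N consecutive windows per group
    return(as.integer((seq_len(n) - 1) %/% grouping))
  }
  stop("invalid grouping: use 'auto', 'contig', 'snps', a group size, ",
       "or a per-window vector")
}

#' Block-jackknife standard error and CI for pooled Am
#'
#' Delete-one-group jackknife on the pooled ratio: for `g` groups the SE is
#' `sqrt((g-1)/g * sum((theta_i - mean(theta))^2))` over the leave-one-out
#' estimates, and the 95% CI is `point +/- 1.96 * SE`.
#'
#' @param windows A data frame from [collect_windows()].
#' @param grouping `"contig"` (one group per contig), `"snps"` (consecutive
#'   windows split into 25 groups), `"auto"` (per-contig when there are at
#'   least 25 contigs, else `"snps"`), a single number (consecutive windows
#'   per group), or a vector assigning each window to a group.
#' @return A list: `point`, `se`, `ci_low`, `ci_high`, `n_groups`.
#' @export
block_jackknife <- function(windows, grouping = "auto") {
  grp <- window_groups(windows, grouping)
  jackknife_pooled_ratio(windows$k_hetA_prime, windows$k_hetB_prime, grp)
}

# default block-size ladder: powers of two as 2l+1 (3, 5, 9, ..., 65537)
default_block_sizes <- function(max_exp = 16) 2L^(1:max_exp) + 1L

#' Am across a ladder of block sizes from a VCF
#'
#' The package's end-to-end estimator: classify sites once, then for each
#' block size `2l + 1` collect per-`hetAB` windows, compute pooled Am and a
#' block-jackknife CI. Reading Am across block sizes is the recommended use:
#' values that are stable and nonzero across small block sizes indicate gene
#' flow, while values that grow with block size can reflect recombination
#' combined with unequal effective sizes.
#'
#' @param vcf_path Path to a VCF with both samples.
#' @param sample_a,sample_b Sample names; positive Am means gene flow into the
#'   population of `sample_a` (forwards in time).
#' @param block_sizes Odd block sizes `2l + 1` (default `2^k + 1` for
#'   `k = 1..16`, i.e. 3 to 65537).
#' @param grouping Jackknife grouping (see [block_jackknife()]).
#' @param verbose Report progress to standard error.
#' @return A data frame with one row per block size: `block_size`,
#'   `n_windows`, `k_hetA_prime`, `k_hetB_prime`, `am`, `se`, `ci_low`,
#'   `ci_high`, `n_groups`.
#' @export
am_profile <- function(vcf_path, sample_a, sample_b,
                       block_sizes = default_block_sizes(),
                       grouping = "auto", verbose = TRUE) {
  stopifnot(all(block_sizes >= 3), all(block_sizes %% 2 == 1))
  sites <- read_site_classes(vcf_path, sample_a, sample_b, verbose = verbose)
  rows <- lapply(block_sizes, function(bs) {
    w <- collect_windows(sites, l = (bs - 1) / 2)
    if (nrow(w) == 0 || sum(w$k_hetA_prime + w$k_hetB_prime) == 0) {
      return(data.frame(block_size = bs, n_windows = nrow(w),
                        k_hetA_prime = sum(w$k_hetA_prime),
                        k_hetB_prime = sum(w$k_hetB_prime),
                        am = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_groups = NA_integer_))
    }
    jk <- block_jackknife(w, grouping)
    data.frame(block_size = bs, n_windows = nrow(w),
               k_hetA_prime = sum(w$k_hetA_prime),
               k_hetB_prime = sum(w$k_hetB_prime),
               am = jk$point, se = jk$se, ci_low = jk$ci_low,
               ci_high = jk$ci_high, n_groups = jk$n_groups)
  })
  do.call(rbind, rows)
}
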
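test_that("site classification is total, phase-free and polarization-free", {
  expect_equal(classify_site("0/1", "0/1"), "hetAB")
  expect_equal(classify_site("0/1", "0/0"), "hetA")
  expect_equal(classify_site("1/1", "0/1"), "hetB")
  expect_equal(classify_site("0/0", "1/1"), "fixed")
  expect_equal(classify_site("1/1", "1/1"), "invariant")
  expect_equal(classify_site("0/1", "./."), "excluded")
  expect_equal(classify_site(NA, "0/1"), "excluded")
  expect_equal(classify_site("0/2", "0/1"), "excluded")   # multiallelic call
  expect_equal(classify_site("garbage", "0/1"), "excluded")
  # phase separators and haplotype order never matter
  expect_equal(classify_site("0|1", "1|0"), "hetAB")
  expect_equal(classify_site("1|0", "0/0"), "hetA")
  # swapping REF and ALT (0 <-> 1 in every call) never changes the class
  gts <- c("0/0", "0/1", "1/1", "1|0", "./.")
  flip <- function(g) chartr("01", "10", g)
  for (a in gts) for (b in gts) {
    expect_equal(classify_site(flip(a), flip(b)), classify_site(a, b),
                 info = paste(a, b))
  }
})

test_that("window collection counts flanking sites in closed intervals", {
  s <- data.frame(contig = "c1",
                  pos = c(450, 490, 500, 520),
                  class = c("hetA", "hetB", "hetAB", "hetA"))
  w <- collect_windows(s, l = 100)
  expect_equal(nrow(w), 1)
  expect_equal(w$k_hetA_prime, 2)
  expect_equal(w$k_hetB_prime, 1)
  # boundary: a site exactly l away is inside, l + 1 away is outside
  s2 <- data.frame(contig = "c1", pos = c(500, 600, 601),
                   class = c("hetAB", "hetA", "hetA"))
  expect_equal(collect_windows(s2, l = 100)$k_hetA_prime, 1)
  # two nearby hetAB sites each get a window; flanks count in both
  s3 <- data.frame(contig = "c1", pos = c(495, 500, 510),
                   class = c("hetA", "hetAB", "hetAB"))
  w3 <- collect_windows(s3, l = 100)
  expect_equal(nrow(w3), 2)
  expect_equal(w3$k_hetA_prime, c(1, 1))
  # windows never span contigs
  s4 <- data.frame(contig = c("c1", "c2"), pos = c(500, 510),
                   class = c("hetAB", "hetA"))
  expect_equal(collect_windows(s4, l = 100)$k_hetA_prime, 0)
  # unsorted input is an error, not a silent miscount
  s5 <- data.frame(contig = "c1", pos = c(500, 450),
                   class = c("hetAB", "hetA"))
  expect_error(collect_windows(s5, l = 10), "not sorted")
})

test_that("pooled Am is a ratio of summed counts with exact antisymmetry", {
  w <- data.frame(contig = "c1", pos = c(1, 2),
                  k_hetA_prime = c(60, 50), k_hetB_prime = c(40, 50))
  expect_equal(am_from_windows(w), 0.1)
  w_sw <- w
  w_sw[c("k_hetA_prime", "k_hetB_prime")] <- w[c("k_hetB_prime", "k_hetA_prime")]
  expect_equal(am_from_windows(w_sw), -0.1)
  w0 <- data.frame(contig = "c1", pos = 1, k_hetA_prime = 0, k_hetB_prime = 0)
  expect_error(am_from_windows(w0), "no informative windows")
})

test_that("block jackknife has the expected structural behaviour", {
  # identical groups: zero variance
  w <- data.frame(contig = rep(sprintf("c%02d", 1:25), each = 2),
                  pos = 1, k_hetA_prime = 6, k_hetB_prime = 4)
  jk <- block_jackknife(w, grouping = "contig")
  expect_equal(jk$n_groups, 25)
  expect_equal(jk$se, 0)
  expect_equal(jk$point, 0.2)
  # per-contig grouping on 20 contigs: 20 leave-one-out evaluations
  set.seed(1)
  w20 <- data.frame(contig = rep(sprintf("c%02d", 1:20), each = 3), pos = 1,
                    k_hetA_prime = rpois(60, 5), k_hetB_prime = rpois(60, 5))
  expect_equal(block_jackknife(w20, grouping = "contig")$n_groups, 20)
  expect_error(block_jackknife(w20[1:3, ], grouping = "contig"), "at least 2")
})

test_that("am_profile is antisymmetric under sample swap and order-invariant", {
  spec <- fixture_spec("IM-unidirectional", model = table1_model(201),
                       n_loci = 3000, seed = 91)
  vcf <- file.path(tempdir(), "prof.vcf")
  make_fixture(spec, vcf)
  sizes <- c(51, 201)
  pr <- am_profile(vcf, "A0", "B0", block_sizes = sizes, verbose = FALSE)
  pr_sw <- am_profile(vcf, "B0", "A0", block_sizes = sizes, verbose = FALSE)
  expect_equal(pr_sw$am, -pr$am)
  expect_equal(pr_sw$se, pr$se)
  # rewriting the records with contigs in reverse order changes nothing
  lines <- readLines(vcf)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr]
  key <- sub("\t.*", "", body)
  shuffled <- body[order(factor(key, levels = rev(unique(key))))]
  vcf2 <- file.path(tempdir(), "prof_rev.vcf")
  writeLines(c(lines[hdr], shuffled), vcf2)
  pr2 <- am_profile(vcf2, "A0", "B0", block_sizes = sizes, verbose = FALSE)
  expect_equal(pr2$am, pr$am)
  # asking for an absent sample names the available ones
  expect_error(am_profile(vcf, "A0", "Zz", block_sizes = 201, verbose = FALSE),
               "available samples: A0, B0")
})

test_that("am_profile on independent loci reproduces the analytic Am", {
  spec <- fixture_spec("IM-unidirectional", model = table1_model(201),
                       n_loci = 50000, seed = 92)
  vcf <- file.path(tempdir(), "im50k.vcf")
  make_fixture(spec, vcf)
  pr <- am_profile(vcf, "A0", "B0", block_sizes = 201, verbose = FALSE)
  pred <- am_expected(scaled_im_params(1, 1), table1_model(201))
  expect_lt(abs(pr$am - pred), 3 * pr$se)
  expect_gt(pr$am, 0)
})
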
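test_that("self-comparison is 100% over every record", {
  ds <- small_dataset(seed = 51)
  vs <- ds$family$variant_set
  res <- compare_vcfs(vs, vs, "PROBAND", "PROBAND")
  expect_equal(res$positions_in_common, n_variants(vs))
  expect_equal(res$concordance_percent, 100)
  expect_equal(res$private_a, 0L)
  expect_equal(res$private_b, 0L)
})

test_that("disjoint loci share nothing and concordance is undefined", {
  a <- variant_set(chrom = "1", pos = 10L, ref = "A", alt = "G",
                   samples = "S", gt = matrix("0/1"))
  b <- variant_set(chrom = "2", pos = 10L, ref = "A", alt = "G",
                   samples = "S", gt = matrix("0/1"))
  res <- compare_vcfs(a, b)
  expect_equal(res$positions_in_common, 0L)
  expect_true(is.na(res$concordance_percent))
})

test_that("genotypes are compared as allele multisets, not index strings", {
  # same site, different ALT encodings: A>G called 0/1 in a, and in b the
  # record is A>T,G with GT 0/2 — the same heterozygous A/G genotype
  a <- variant_set(chrom = "1", pos = 100L, ref = "A", alt = "G",
                   samples = "S", gt = matrix("0/1"))
  b <- variant_set(chrom = "1", pos = 100L, ref = "A", alt = "T,G",
                   samples = "S", gt = matrix("0/2"))
  res <- compare_vcfs(a, b)
  expect_equal(res$concordant_genotypes, 1L)
  # phase is ignored
  b2 <- variant_set(chrom = "1", pos = 100L, ref = "A", alt = "G",
                    samples = "S", gt = matrix("1|0"))
  expect_equal(compare_vcfs(a, b2)$concordance_percent, 100)
})

test_that("planted genotype flips are recovered at the planted rate", {
  set.seed(61)
  n <- 800
  vs <- random_variant_set(n = n, samples = "S", seed = 61)
  vs <- sanity_check(vs)
  flipped <- vs
  n_kept <- n_variants(vs)
  callable <- which(zygosity_class(vs$gt[, 1]) != "missing")
  flip <- sample(callable, floor(length(callable) * 0.1))
  for (i in flip) {
    flipped$gt[i, 1] <- if (vs$gt[i, 1] == "1/1") "0/1" else "1/1"
  }
  res <- compare_vcfs(vs, flipped)
  expect_equal(res$positions_in_common, length(callable))
  expect_equal(res$concordant_genotypes, length(callable) - length(flip))
  expect_equal(res$concordance_percent,
               100 * (1 - length(flip) / length(callable)))
  expect_equal(nrow(res$discordant), length(flip))
})

test_that("comparison is symmetric", {
  a <- sanity_check(random_variant_set(150, samples = "S", seed = 62))
  b <- sanity_check(random_variant_set(150, samples = "S", seed = 63))
  ab <- compare_vcfs(a, b)
  ba <- compare_vcfs(b, a)
  expect_equal(ab$positions_in_common, ba$positions_in_common)
  expect_equal(ab$concordance_percent, ba$concordance_percent)
  expect_equal(ab$private_a, ba$private_b)
})

test_that("private variants are the alt-carrying set differences", {
  base <- sanity_check(random_variant_set(100, samples = "S", seed = 64))
  extra <- variant_set(chrom = rep("21", 3), pos = c(11L, 22L, 33L),
                       ref = rep("A", 3), alt = rep("G", 3), samples = "S",
                       gt = matrix(c("0/1", "1/1", "0/1"), 3, 1))
  a <- variant_set(
    chrom = c(base$fix$chrom, extra$fix$chrom),
    pos = c(base$fix$pos, extra$fix$pos),
    id = c(base$fix$id, extra$fix$id),
    ref = c(base$fix$ref, extra$fix$ref),
    alt = c(base$fix$alt, extra$fix$alt),
    qual = c(base$fix$qual, extra$fix$qual),
    filter = c(base$fix$filter, extra$fix$filter),
    info = c(base$info, extra$info), samples = "S",
    gt = rbind(base$gt, extra$gt), dp = rbind(base$dp, extra$dp),
    gq = rbind(base$gq, extra$gq), meta = base$meta)
  priv <- private_variants(a, base)
  expect_equal(priv$a$fix$pos, c(11L, 22L, 33L))
  expect_equal(n_variants(priv$b), 0L)
  same <- private_variants(base, base)
  expect_equal(n_variants(same$a), 0L)
  # set-difference oracle on position keys for a random pair
  b <- sanity_check(random_variant_set(100, samples = "S", seed = 65))
  pv <- private_variants(a, b)
  keys <- function(vs) paste(vs$fix$chrom, vs$fix$pos)
  carries <- function(vs) zygosity_class(vs$gt[, 1]) %in% c("het", "hom_alt", "hemi")
  expect_setequal(keys(pv$a), setdiff(keys(a)[carries(a)], keys(b)))
  expect_setequal(keys(pv$b), setdiff(keys(b)[carries(b)], keys(a)))
})
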
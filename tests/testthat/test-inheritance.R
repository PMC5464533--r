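# Textbook segregation cases per inheritance model; the exhaustive
# genotype-combination sweep lives in the acceptance suite.

trio_set <- function(gt_p, gt_m, gt_f, chrom = "1", gene = NULL) {
  n <- length(gt_p)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (is.null(gene)) gene <- sprintf("G%03d", seq_len(n))
  variant_set(
    chrom = chrom, pos = seq_len(n) * 100L, ref = rep("A", n),
    alt = rep("G", n),
    info = lapply(gene, function(g) list(gene = g)),
    samples = c("P", "M", "F"),
    gt = cbind(gt_p, gt_m, gt_f),
    dp = matrix(50L, n, 3), gq = matrix(90L, n, 3))
}

trio_ped <- pedigree("P", mother = "M", father = "F", sex_proband = "male")

test_that("AR_HOM keeps textbook recessive segregation and rejects violations", {
  vs <- trio_set(gt_p = c("1/1", "1/1", "1/1", "0/1"),
                 gt_m = c("0/1", "0/0", "1/1", "0/1"),
                 gt_f = c("0/1", "0/1", "0/1", "0/1"))
  rep <- filter_inheritance(vs, trio_ped, "AR_HOM")
  expect_equal(rep$variants$fix$pos, 100L)  # only the carrier-parent trio
})

test_that("AR_HOM degrades gracefully when parents are absent or uncalled", {
  solo <- pedigree("P", sex_proband = "male")
  vs <- trio_set(gt_p = c("1/1", "0/1"), gt_m = c("0/0", "0/0"),
                 gt_f = c("0/0", "0/0"))
  rep <- filter_inheritance(vs, solo, "AR_HOM")
  expect_equal(rep$variants$fix$pos, 100L)
  # missing parental calls are skipped, not treated as violations
  vs2 <- trio_set(gt_p = "1/1", gt_m = ".", gt_f = "./.")
  expect_equal(filter_inheritance(vs2, trio_ped, "AR_HOM")$n_output, 1L)
})

test_that("compound heterozygotes require one variant from each parent", {
  # gene CG1: trans (one from mother, one from father) -> kept
  # gene CG2: both from the mother (cis) -> dropped
  vs <- trio_set(
    gt_p = c("0/1", "0/1", "0/1", "0/1"),
    gt_m = c("0/1", "0/0", "0/1", "0/1"),
    gt_f = c("0/0", "0/1", "0/0", "0/0"),
    gene = c("CG1", "CG1", "CG2", "CG2"))
  rep <- filter_inheritance(vs, trio_ped, "AR_COMPHET")
  expect_setequal(unique(rep$gene), "CG1")
  expect_equal(rep$n_output, 2L)
})

test_that("compound het without parents qualifies but is flagged unverified", {
  solo <- pedigree("P", sex_proband = "male")
  vs <- trio_set(gt_p = c("0/1", "0/1"), gt_m = c("0/1", "0/1"),
                 gt_f = c("0/0", "0/0"), gene = c("CG1", "CG1"))
  vs$samples <- "P"
  vs$gt <- vs$gt[, 1, drop = FALSE]
  vs$dp <- vs$dp[, 1, drop = FALSE]
  vs$gq <- vs$gq[, 1, drop = FALSE]
  rep <- filter_inheritance(vs, solo, "AR_COMPHET")
  expect_equal(rep$n_output, 2L)
  expect_true(all(vapply(rep$provenance, function(p) "phase_unverified" %in% p,
                         logical(1))))
  # a single het in a gene never qualifies
  one <- subset_variants(vs, 1)
  expect_equal(filter_inheritance(one, solo, "AR_COMPHET")$n_output, 0L)
})

test_that("de novo requires het proband and verifiably clean parents", {
  vs <- trio_set(gt_p = c("0/1", "0/1", "0/1", "1/1"),
                 gt_m = c("0/0", "0/0", "./.", "0/0"),
                 gt_f = c("0/0", "0/1", "0/0", "0/0"))
  rep <- filter_inheritance(vs, trio_ped, "DE_NOVO")
  expect_equal(rep$variants$fix$pos, 100L)
  no_father <- pedigree("P", mother = "M", sex_proband = "male")
  expect_error(filter_inheritance(vs, no_father, "DE_NOVO"), "both parents")
})

test_that("dominant het candidates must segregate with affection status", {
  ped <- pedigree("P", mother = "M", father = "F", affected = "SIB_A",
                  unaffected = "SIB_U", sex_proband = "male")
  n <- 3
  vs <- variant_set(
    chrom = rep("5", n), pos = 1:3 * 10L, ref = rep("A", n), alt = rep("G", n),
    info = lapply(1:n, function(i) list(gene = "D1")),
    samples = c("P", "M", "F", "SIB_A", "SIB_U"),
    gt = rbind(c("0/1", "0/0", "0/0", "0/1", "0/0"),   # segregates
               c("0/1", "0/0", "0/0", "0/0", "0/0"),   # affected sib lacks it
               c("0/1", "0/0", "0/0", "0/1", "0/1")))  # unaffected carries it
  rep <- filter_inheritance(vs, ped, "AD_HET")
  expect_equal(rep$variants$fix$pos, 10L)
})

test_that("X-linked hemizygous requires X, a male proband and a carrier mother", {
  vs <- trio_set(gt_p = c("1", "1", "1/1", "1", "0"),
                 gt_m = c("0/1", "1/1", "0/1", "0/0", "0/1"),
                 gt_f = c("0", "0", "0", "0", "0"),
                 chrom = c("X", "X", "X", "X", "X"))
  rep <- filter_inheritance(vs, trio_ped, "XL_HEMI")
  expect_setequal(rep$variants$fix$pos, c(100L, 300L))
  # autosomal site never qualifies
  auto <- trio_set("1", "0/1", "0", chrom = "7")
  expect_equal(filter_inheritance(auto, trio_ped, "XL_HEMI")$n_output, 0L)
  # unknown sex is an error
  ped_u <- pedigree("P", mother = "M", father = "F")
  expect_error(filter_inheritance(vs, ped_u, "XL_HEMI"), "sex")
})
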
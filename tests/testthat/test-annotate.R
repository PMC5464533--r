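# Panel annotation joins and the coordinate index.

make_panel_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##INFO=<ID=AF,Number=A,Type=Float,Description="freq">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO"), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

target_at <- function(chrom, pos, ref, alt) {
  variant_set(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
              samples = "S1", gt = matrix("0/1", length(chrom), 1))
}

test_that("an exact allele match copies the panel field under its prefix", {
  p <- make_panel_vcf("1\t1000\t.\tA\tG\t.\t.\tAF=0.25")
  panel <- reference_panel("1000g", "vcf", p, "AF")
  out <- annotate_with_panel(target_at("1", 1000, "A", "G"), panel)
  expect_equal(out$info[[1]][["1000g_AF"]], 0.25)
})

test_that("an allele mismatch at the same position adds nothing", {
  p <- make_panel_vcf("1\t1000\t.\tA\tG\t.\t.\tAF=0.25")
  panel <- reference_panel("1000g", "vcf", p, "AF")
  out <- annotate_with_panel(target_at("1", 1000, "A", "T"), panel)
  expect_null(out$info[[1]][["1000g_AF"]])
})

test_that("multi-allelic targets are annotated per alt in ALT order", {
  p <- make_panel_vcf(c("1\t1000\t.\tA\tG\t.\t.\tAF=0.1",
                        "1\t1000\t.\tA\tT\t.\t.\tAF=0.01"))
  panel <- reference_panel("1000g", "vcf", p, "AF")
  out <- annotate_with_panel(target_at("1", 1000, "A", "G,T"), panel)
  expect_equal(out$info[[1]][["1000g_AF"]], "0.1,0.01")
  # partial match: unmatched alt becomes "."
  out2 <- annotate_with_panel(target_at("1", 1000, "A", "G,C"), panel)
  expect_equal(out2$info[[1]][["1000g_AF"]], "0.1,.")
})

test_that("id_fill unions panel identifiers into the target ids", {
  p <- make_panel_vcf("1\t1000\trs77\tA\tG\t.\t.\tAF=0.2")
  panel <- reference_panel("dbsnp", "vcf", p, "AF", id_fill = TRUE)
  out <- annotate_with_panel(target_at("1", 1000, "A", "G"), panel)
  expect_equal(out$fix$id[1], "rs77")
})

test_that("a prefix collision is a hard error, never a silent overwrite", {
  p <- make_panel_vcf("1\t1000\t.\tA\tG\t.\t.\tAF=0.25")
  panel <- reference_panel("1000g", "vcf", p, "AF")
  tgt <- target_at("1", 1000, "A", "G")
  tgt$info[[1]][["1000g_AF"]] <- 0.9
  expect_error(annotate_with_panel(tgt, panel), "collision")
})

test_that("score tables annotate on exact alleles and omit absent scores", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tsift_score\tpolyphen2_score",
               "1\t500\tA\tG\t0.02\tNA",
               "2\t900\tC\tT\t0.80\t0.99"), tsv)
  panel <- reference_panel("dbnsfp", "scores", tsv,
                           c("sift_score", "polyphen2_score"))
  tgt <- target_at(c("1", "2", "3"), c(500, 900, 100),
                   c("A", "C", "G"), c("G", "T", "A"))
  out <- annotate_scores(tgt, panel)
  expect_equal(out$info[[1]]$dbnsfp_sift_score, 0.02)
  expect_null(out$info[[1]]$dbnsfp_polyphen2_score)  # absent, not zero
  expect_equal(out$info[[2]]$dbnsfp_polyphen2_score, 0.99)
  expect_length(out$info[[3]], 0)
})

test_that("indexed interval queries equal a linear scan on a synthetic panel", {
  ds <- small_dataset(seed = 21)
  idx <- build_index(ds$panels$panels[[1]])
  rows <- idx$rows
  set.seed(77)
  for (q in 1:200) {
    chrom <- sample(c(as.character(1:22), "X", "ZZ"), 1)
    start <- sample.int(7e5, 1)
    end <- start + sample.int(5e4, 1)
    expect_equal(panel_query(idx, chrom, start, end),
                 oracle_linear_query(rows, chrom, start, end))
  }
})

test_that("an unsorted panel is rejected naming the offending row", {
  p <- make_panel_vcf(c("2\t1000\t.\tA\tG\t.\t.\tAF=0.1",
                        "1\t500\t.\tC\tT\t.\t.\tAF=0.2"))
  expect_error(build_index(reference_panel("1000g", "vcf", p, "AF")),
               "row 2")
})

test_that("annotate_all equals sequential composition and is order-invariant", {
  ds <- small_dataset(seed = 31)
  panels <- ds$panels$panels
  vs <- ds$family$variant_set
  full <- annotate_all(vs, annotation_config(panels))
  # sequential composition by hand (key order canonicalized for comparison)
  seq_out <- sanity_check(vs)
  for (p in panels) seq_out <- annotate_with_panel(seq_out, p)
  sort_keys <- function(info) lapply(info, function(ii) ii[order(names(ii))])
  expect_equal(sort_keys(full$info), sort_keys(seq_out$info))
  expect_equal(full$fix, seq_out$fix)
  # reversed panel order
  rev_out <- annotate_all(vs, annotation_config(rev(panels)))
  expect_same_records(full, rev_out)
  # chunk-and-concatenate invariance
  n <- n_variants(vs)
  half <- floor(n / 2)
  a <- annotate_all(subset_variants(vs, seq_len(half)), annotation_config(panels))
  b <- annotate_all(subset_variants(vs, (half + 1):n), annotation_config(panels))
  expect_equal(c(a$info, b$info), full$info)
  # annotation never touches loci or calls
  expect_equal(full$fix[, c("chrom", "pos", "ref", "alt")],
               sanity_check(vs)$fix[, c("chrom", "pos", "ref", "alt")])
  expect_equal(full$gt, sanity_check(vs)$gt)
})

test_that("dbsnp_build_of reads the copied build field", {
  vs <- target_at(c("1", "1"), c(10, 20), c("A", "C"), c("G", "T"))
  vs$info[[1]]$dbsnp_build <- 129L
  expect_equal(dbsnp_build_of(vs), c(129L, NA))
  vs$info[[2]]$dbsnp_build <- "not_a_build"
  expect_error(dbsnp_build_of(vs), "non-integer")
})
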
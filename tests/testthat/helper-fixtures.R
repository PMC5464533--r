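# Fixture builders shared across tests. Everything is generated in code at
# test time; files go under tempdir().

write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# a minimal single-sample VCF with an arbitrary body
tiny_vcf <- function(body, samples = "S1",
                     extra_meta = character(0)) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##INFO=<ID=gene,Number=1,Type=String,Description="Gene">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    extra_meta,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  write_vcf_text(c(header, body))
}

# a random VariantSet built directly in memory (for round-trip and
# sanity-check property tests)
random_variant_set <- function(n = 50, samples = c("S1", "S2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- sample(c(as.character(1:22), "X", "chr3", "Chr7", "MT"), n, replace = TRUE)
  pos <- sample.int(1e6, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  n_alt <- sample(1:2, n, replace = TRUE, prob = c(0.85, 0.15))
  alt <- vapply(seq_len(n), function(i) {
    paste(sample(setdiff(bases, ref[i]), n_alt[i]), collapse = ",")
  }, character(1))
  gts <- c("0/0", "0/1", "1/1", "./.", ".", "0|1", "1")
  gt <- matrix(sample(gts, n * length(samples), replace = TRUE), n)
  # keep allele indices legal for biallelic records
  info <- lapply(seq_len(n), function(i) {
    out <- list()
    if (runif(1) < 0.5) out$DP <- sample.int(200, 1)
    if (runif(1) < 0.3) out$EFF <- "upstream"
    if (runif(1) < 0.2) out$ANN <- "x"
    if (runif(1) < 0.5) out$gene <- sprintf("GN%03d", sample.int(40, 1))
    out
  })
  variant_set(
    chrom = chroms, pos = pos,
    id = ifelse(runif(n) < 0.3, sprintf("rs%d", seq_len(n)), ""),
    ref = ref, alt = alt,
    qual = ifelse(runif(n) < 0.9, round(runif(n, 10, 3000), 1), NA),
    filter = sample(c("PASS", "."), n, replace = TRUE),
    info = info, samples = samples, gt = gt,
    dp = matrix(ifelse(runif(n * length(samples)) < 0.9,
                       sample.int(120, n * length(samples), replace = TRUE),
                       NA), n),
    gq = matrix(sample.int(99, n * length(samples), replace = TRUE), n),
    meta = c("##fileformat=VCFv4.2",
             '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
             '##INFO=<ID=EFF,Number=1,Type=String,Description="old annotation">',
             '##INFO=<ID=ANN,Number=1,Type=String,Description="old annotation">',
             '##INFO=<ID=gene,Number=1,Type=String,Description="Gene">'))
}

# compare two variant sets on the data model (ignoring header meta)
expect_same_records <- function(a, b) {
  expect_equal(a$samples, b$samples)
  expect_equal(a$fix, b$fix)
  expect_equal(a$info, b$info)
  expect_equal(unname(a$gt), unname(b$gt))
  expect_equal(unname(a$dp), unname(b$dp))
  expect_equal(unname(a$gq), unname(b$gq))
}

# small synthetic dataset used by several module tests
small_cfg <- function(seed = 11, model = "AR_HOM", ...) {
  synth_config(seed = seed, model = model, n_background = 600, n_genes = 60,
               n_diseases = 25, ...)
}

small_dataset <- function(seed = 11, model = "AR_HOM", ...) {
  cfg <- small_cfg(seed, model, ...)
  dir <- file.path(tempdir(), sprintf("synth_%s_%d", model, seed))
  list(cfg = cfg, panels = make_panels(cfg, dir),
       family = make_family(cfg, dir), dir = dir)
}

# record keys for membership checks
vs_keys <- function(vs) {
  paste(vs$fix$chrom, vs$fix$pos, vs$fix$ref, vs$fix$alt)
}

truth_keys <- function(truth) {
  paste(truth$variants$chrom, truth$variants$pos,
        truth$variants$ref, truth$variants$alt)
}

# random annotated records for filter-engine property tests: carries the
# fields the filter criteria reference (impact, func_class, gene,
# dbsnp_build, panel AFs, scores), with missing values and occasional
# multi-allelic sites
random_annotated_set <- function(n = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chrom <- sample(c(as.character(1:22), "X"), n, replace = TRUE)
  pos <- sample.int(1e6, n)
  ref <- sample(bases, n, replace = TRUE)
  n_alt <- sample(1:2, n, replace = TRUE, prob = c(0.8, 0.2))
  alt <- vapply(seq_len(n), function(i) {
    paste(sample(setdiff(bases, ref[i]), n_alt[i]), collapse = ",")
  }, character(1))
  info <- lapply(seq_len(n), function(i) {
    out <- list(gene = sprintf("GN%04d", sample.int(60, 1)))
    out$impact <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), 1)
    if (runif(1) < 0.8) out$func_class <- sample(c("missense", "stop_gained",
                                                   "synonymous", "intron"), 1)
    if (runif(1) < 0.5) out$dbsnp_build <- sample(c(100:150), 1)
    if (runif(1) < 0.7) {
      af <- round(runif(n_alt[i], 0, 0.4), 4)
      out[["1000g_AF"]] <- if (n_alt[i] > 1) paste(af, collapse = ",") else af
    }
    if (runif(1) < 0.5) {
      out$dbnsfp_sift_score <- round(runif(1), 3)
    }
    out
  })
  gts1 <- c("0/0", "0/1", "1/1", ".", "1", "0")
  gts2 <- c("0/0", "0/1", "1/1", "1/2", "2/2", ".", "1", "0/2")
  gt <- vapply(seq_len(n), function(i) {
    sample(if (n_alt[i] == 1) gts1 else gts2, 1)
  }, character(1))
  variant_set(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = ifelse(runif(n) < 0.85, round(runif(n, 1, 2000), 1), NA),
    info = info, samples = "S1", gt = matrix(gt, n, 1),
    dp = matrix(ifelse(runif(n) < 0.85, sample.int(80, n, replace = TRUE), NA), n, 1),
    gq = matrix(sample.int(99, n, replace = TRUE), n, 1))
}
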
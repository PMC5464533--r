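test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 71)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  make_panels(cfg, d1); make_panels(cfg, d2)
  make_family(cfg, d1); make_family(cfg, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  make_panels(small_cfg(seed = 72), d3)
  expect_false(tools::md5sum(file.path(d1, "1000g.vcf")) ==
                 tools::md5sum(file.path(d3, "1000g.vcf")))
})

test_that("the planted causal variant is absent from every panel", {
  ds <- small_dataset(seed = 73, model = "AR_COMPHET")
  tk <- truth_keys(ds$family$truth)
  for (p in ds$panels$panels) {
    idx <- build_index(p)
    panel_keys <- paste(idx$rows$chrom, idx$rows$pos, idx$rows$ref, idx$rows$alt)
    expect_false(any(tk %in% panel_keys), info = p$name)
  }
})

test_that("planted genotypes segregate exactly as the model dictates", {
  for (m in c("AR_HOM", "AR_COMPHET", "AD_HET", "DE_NOVO", "XL_HEMI")) {
    fam <- small_dataset(seed = 74, model = m)$family
    vs <- fam$variant_set
    tr <- fam$truth$variants
    i <- match(truth_keys(fam$truth), vs_keys(vs))
    expect_false(anyNA(i), info = m)
    expect_equal(unname(vs$gt[i, "PROBAND"]), tr$gt_proband, info = m)
    expect_equal(unname(vs$gt[i, "MOTHER"]), tr$gt_mother, info = m)
    expect_equal(unname(vs$gt[i, "FATHER"]), tr$gt_father, info = m)
    expect_true(all(vs$dp[i, ] >= 10), info = m)
    expect_true(all(info_field_chr(vs, "impact")[i] == "HIGH"), info = m)
    # the causal gene is in the disease catalog under the right label
    dcat <- small_dataset(seed = 74, model = m)$panels$disease_catalog
    hit <- search_diseases(dcat, fam$truth$gene)
    expect_gt(nrow(hit), 0)
    lab <- switch(m, AR_HOM = "AR", AR_COMPHET = "AR", AD_HET = "AD",
                  DE_NOVO = "AD", XL_HEMI = "XL")
    expect_true(lab %in% hit$inheritance, info = m)
  }
})

test_that("background sites are Mendelian-consistent in the trio", {
  fam <- small_dataset(seed = 75)$family
  vs <- fam$variant_set
  bad <- 0
  for (i in seq_len(n_variants(vs))) {
    alts <- strsplit(vs$fix$alt[i], ",")[[1]]
    p <- oracle_alleles(vs$gt[i, "PROBAND"], vs$fix$ref[i], alts)
    m <- oracle_alleles(vs$gt[i, "MOTHER"], vs$fix$ref[i], alts)
    f <- oracle_alleles(vs$gt[i, "FATHER"], vs$fix$ref[i], alts)
    if (vs$fix$chrom[i] == "X") {
      # male proband: single maternal allele
      if (!(length(p) == 1 && p %in% m)) bad <- bad + 1
    } else {
      ok <- any(vapply(seq_along(p), function(k) {
        p[k] %in% m && all(p[-k] %in% f)
      }, logical(1)))
      if (!ok) bad <- bad + 1
    }
  }
  expect_equal(bad, 0)
})

test_that("panel allele-frequency composition matches the configured mixture", {
  cfg <- synth_config(seed = 76, n_background = 4000, n_genes = 120,
                      common_frac = 0.3)
  p <- make_panels(cfg, file.path(tempdir(), "afmix"))
  idx <- build_index(p$panels[[1]])  # 1000g-like panel
  af <- vapply(idx$fields$AF, function(v) as.numeric(v), numeric(1))
  frac_common <- mean(af >= 0.05)
  # binomial tolerance: 4 sd of p(1-p)/n around 0.30
  expect_lt(abs(frac_common - 0.30), 4 * sqrt(0.3 * 0.7 / length(af)))
  expect_true(all(af > 0 & af <= 0.5))
})

test_that("generated datasets validate cleanly end to end", {
  for (m in c("AR_HOM", "XL_HEMI")) {
    ds <- small_dataset(seed = 77, model = m)
    expect_equal(nrow(validate_vcf(ds$family$variant_set)), 0L)
    expect_equal(nrow(validate_vcf(parse_vcf(ds$panels$files[["g1000"]]))), 0L)
    expect_equal(nrow(validate_vcf(parse_vcf(ds$panels$files[["dbsnp"]]))), 0L)
  }
})

test_that("dbSNP-like build numbers follow the common/rare split", {
  cfg <- synth_config(seed = 78, n_background = 4000, n_genes = 120)
  p <- make_panels(cfg, file.path(tempdir(), "builds"))
  dbsnp <- parse_vcf(p$files[["dbsnp"]])
  build <- vapply(dbsnp$info, function(ii) as.integer(ii$build), integer(1))
  af <- vapply(dbsnp$info, function(ii) as.numeric(ii$AF), numeric(1))
  common <- af >= 0.05
  # common panel members are overwhelmingly old builds (<=129)
  expect_gt(mean(build[common] <= 129), 0.9)
  # rare members, when present at all, are post-129 discoveries
  expect_true(all(build[!common] > 129))
})
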
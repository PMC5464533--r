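test_that("an empty specification passes every record through", {
  vs <- random_annotated_set(50, seed = 1)
  rep <- apply_filters(vs, filter_spec(), "S1")
  expect_equal(rep$n_output, 50L)
  expect_same_records(rep$variants, vs)
})

test_that("the dbSNP-build boundary excludes at and below the cutoff", {
  vs <- random_annotated_set(2, seed = 2)
  vs$info[[1]]$dbsnp_build <- 129L
  vs$info[[2]]$dbsnp_build <- 130L
  rep <- apply_filters(vs, filter_spec(max_dbsnp_build = 129), "S1")
  expect_equal(rep$n_output, 1L)
  expect_equal(rep$variants$info[[1]]$dbsnp_build, 130L)
})

test_that("the depth cutoff is exclusive below and missing DP passes by default", {
  vs <- random_annotated_set(3, seed = 3)
  vs$dp[, 1] <- c(9L, 10L, NA)
  rep <- apply_filters(vs, filter_spec(min_depth = 10), "S1")
  expect_equal(vs$dp[vs_keys(vs) %in% vs_keys(rep$variants), 1], c(10L, NA))
  strict <- apply_filters(vs, filter_spec(min_depth = 10, strict_depth = TRUE), "S1")
  expect_equal(strict$n_output, 1L)
})

test_that("criteria referencing fields absent everywhere raise a naming error", {
  vs <- random_annotated_set(10, seed = 4)
  vs$info <- lapply(vs$info, function(ii) ii[setdiff(names(ii), "impact")])
  expect_error(apply_filters(vs, filter_spec(impacts = "HIGH"), "S1"), "impact")
  expect_error(
    apply_filters(random_annotated_set(10, seed = 4),
                  filter_spec(max_panel_frequency = c(esp = 0.01)), "S1"),
    "esp_AF")
})

test_that("random specs match the brute-force per-record evaluator", {
  vs <- random_annotated_set(300, seed = 5)
  set.seed(6)
  for (k in 1:25) {
    spec <- random_spec(panel_names = "1000g",
                        score_fields = "dbnsfp_sift_score")
    got <- vs_keys(apply_filters(vs, spec, "S1")$variants)
    want <- vs_keys(vs)[oracle_apply_filters(vs, spec, "S1")]
    expect_equal(got, want, info = sprintf("spec %d", k))
  }
})

test_that("tightening any single criterion never grows the survivor set", {
  vs <- random_annotated_set(300, seed = 7)
  base <- filter_spec(min_depth = 5, max_panel_frequency = c("1000g" = 0.2),
                      impacts = c("HIGH", "MODERATE", "LOW"))
  loose <- vs_keys(apply_filters(vs, base, "S1")$variants)
  tighter <- list(
    merge_filter_spec(base, list(min_depth = 30)),
    merge_filter_spec(base, list(max_panel_frequency = c("1000g" = 0.01))),
    merge_filter_spec(base, list(impacts = "HIGH")),
    merge_filter_spec(base, list(max_dbsnp_build = 140)),
    merge_filter_spec(base, list(min_qual = 500)))
  for (spec in tighter) {
    expect_true(all(vs_keys(apply_filters(vs, spec, "S1")$variants) %in% loose))
  }
})

test_that("survivors carry provenance and counts never grow", {
  vs <- random_annotated_set(100, seed = 8)
  spec <- filter_spec(impacts = c("HIGH", "MODERATE"), min_depth = 10)
  rep <- apply_filters(vs, spec, "S1")
  expect_lte(rep$n_output, rep$n_input)
  if (rep$n_output > 0) {
    expect_true(all(vapply(rep$provenance, function(p) {
      all(c("impact", "min_depth") %in% p)
    }, logical(1))))
  }
})

test_that("genes in common intersect across individuals", {
  mk <- function(genes) {
    vs <- random_annotated_set(length(genes), seed = 9)
    for (i in seq_along(genes)) vs$info[[i]]$gene <- genes[i]
    candidate_report(vs)
  }
  r1 <- mk(c("A", "B"))
  r2 <- mk(c("B", "C"))
  expect_equal(genes_in_common(list(r1, r2))$symbols, "B")
  expect_setequal(genes_in_common(list(r1))$symbols, c("A", "B"))
  expect_error(genes_in_common(list()), "at least one")
  # five-individual brute force
  set.seed(10)
  gene_sets <- replicate(5, sample(LETTERS[1:8], sample(3:6, 1)), simplify = FALSE)
  reports <- lapply(gene_sets, mk)
  expect_setequal(genes_in_common(reports)$symbols,
                  Reduce(intersect, gene_sets))
})

test_that("filter specifications survive a config-file round trip", {
  spec <- filter_spec(zygosity = c("het", "hom_alt"),
                      impacts = c("HIGH", "MODERATE"), min_depth = 10,
                      max_dbsnp_build = 129,
                      max_panel_frequency = c("1000g" = 0.01, esp = 0.01),
                      gene_panel = gene_panel(c("AAA", "BBB"), "demo"),
                      score_thresholds = list(
                        dbnsfp_sift_score = list(direction = "le", cutoff = 0.05)))
  path <- tempfile(fileext = ".json")
  write_filter_spec(spec, path)
  expect_equal(read_filter_spec(path), spec)
})
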
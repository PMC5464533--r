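# Deterministic synthetic-data generator: reference panels, score tables,
# gene/disease catalogs and trio VCFs with a planted causal variant, so the
# whole annotate -> filter -> prioritize pipeline can run hermetically.

.SYNTH_MODELS <- c("AR_HOM", "AR_COMPHET", "AD_HET", "DE_NOVO", "XL_HEMI")

#' Configure the synthetic-data generator
#'
#' The defaults emulate an exome-scale family study: a pool of background
#' variant sites spread over ~1,000 genes, a 30%/70% mixture of common
#' (allele frequency uniform on 0.05–0.5) and rare (uniform on 0.0001–0.01)
#' sites, frequency panels covering most of the pool, a dbSNP-like panel in
#' which ~95% of common variants carry a first-build number of 129 or lower
#' while rare variants are mostly unassigned, Poisson read depth around 60x
#' with a 5% low-depth fraction, and consequence impact drawn as 5% HIGH,
#' 15% MODERATE, 40% LOW, 40% MODIFIER. All randomness is fixed by `seed`.
#'
#' @param seed integer seed fixing every random draw.
#' @param model inheritance model of the planted causal variant(s): one of
#'   `"AR_HOM"`, `"AR_COMPHET"`, `"AD_HET"`, `"DE_NOVO"`, `"XL_HEMI"`.
#' @param n_background number of background variant sites in the pool (the
#'   family VCF contains the subset at which the trio carries an alternate
#'   allele).
#' @param n_genes number of genes, laid out round-robin over `chroms`.
#' @param chroms chromosome labels used (must include `"X"` for `XL_HEMI`).
#' @param common_frac fraction of pool sites that are common.
#' @param mean_depth mean of the Poisson read-depth distribution.
#' @param low_depth_frac fraction of family records forced below depth 10.
#' @param impact_probs named probabilities for the four impact classes.
#' @param panel_coverage named fractions of pool sites present in the
#'   1000 Genomes-like and ESP-like frequency panels.
#' @param dbsnp_common_frac fraction of common sites with a dbSNP-like entry
#'   of build <= 129.
#' @param score_coverage fraction of pool sites present in the score table.
#' @param n_diseases number of synthetic catalog diseases.
#' @return An object of class `SynthConfig`.
#' @export
synth_config <- function(seed = 1L, model = "AR_HOM", n_background = 20000L,
                         n_genes = 1000L, chroms = c(as.character(1:22), "X"),
                         common_frac = 0.3, mean_depth = 60,
                         low_depth_frac = 0.05,
                         impact_probs = c(HIGH = 0.05, MODERATE = 0.15,
                                          LOW = 0.40, MODIFIER = 0.40),
                         panel_coverage = c("1000g" = 0.98, esp = 0.90),
                         dbsnp_common_frac = 0.95, score_coverage = 0.4,
                         n_diseases = 150L) {
  model <- match.arg(model, .SYNTH_MODELS)
  stopifnot(n_background > 0L, n_genes > 0L, n_diseases > 0L,
            common_frac >= 0, common_frac <= 1, mean_depth > 0)
  if (model == "XL_HEMI" && !"X" %in% chroms) {
    stop("XL_HEMI requires 'X' among the configured chromosomes")
  }
  if (abs(sum(impact_probs) - 1) > 1e-8) stop("impact_probs must sum to 1")
  structure(list(seed = as.integer(seed), model = model,
                 n_background = as.integer(n_background),
                 n_genes = as.integer(n_genes), chroms = as.character(chroms),
                 common_frac = common_frac, mean_depth = mean_depth,
                 low_depth_frac = low_depth_frac, impact_probs = impact_probs,
                 panel_coverage = panel_coverage,
                 dbsnp_common_frac = dbsnp_common_frac,
                 score_coverage = score_coverage,
                 n_diseases = as.integer(n_diseases)),
            class = "SynthConfig")
}

.set_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

.FUNC_CLASS_BY_IMPACT <- list(
  HIGH = c("stop_gained", "frameshift"),
  MODERATE = c("missense", "inframe_indel"),
  LOW = c("synonymous", "splice_region"),
  MODIFIER = c("intron", "intergenic")
)

# Deterministic universe shared by make_panels() and make_family():
# gene layout, background site pool with frequencies/panel membership/
# annotations, causal site selection and the disease catalog.
.synth_universe <- function(cfg) {
  .set_seed(cfg$seed)
  n_genes <- cfg$n_genes
  gene_chrom <- rep(cfg$chroms, length.out = n_genes)
  rank_in_chrom <- stats::ave(seq_len(n_genes), gene_chrom, FUN = seq_along)
  gene_width <- 10000L
  gene_start <- (rank_in_chrom - 1L) * 15000L + 1000L
  genes <- data.frame(
    symbol = sprintf("GN%04d", seq_len(n_genes)),
    name = sprintf("synthetic gene %04d", seq_len(n_genes)),
    chrom = gene_chrom, start = gene_start, end = gene_start + gene_width - 1L,
    stringsAsFactors = FALSE)

  # background site pool with unique (chrom, pos)
  n <- cfg$n_background
  g_idx <- integer(0); pos <- integer(0)
  while (length(g_idx) < n) {
    need <- n - length(g_idx)
    gi <- sample.int(n_genes, ceiling(need * 1.3), replace = TRUE)
    pp <- genes$start[gi] + sample.int(gene_width, length(gi), replace = TRUE) - 1L
    g_idx <- c(g_idx, gi); pos <- c(pos, pp)
    keep <- !duplicated(paste(genes$chrom[g_idx], pos))
    g_idx <- g_idx[keep]; pos <- pos[keep]
  }
  g_idx <- g_idx[seq_len(n)]; pos <- pos[seq_len(n)]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                USE.NAMES = FALSE)
  common <- stats::runif(n) < cfg$common_frac
  af <- round(ifelse(common, stats::runif(n, 0.05, 0.5),
                     stats::runif(n, 1e-4, 0.01)), 6)
  in_1000g <- stats::runif(n) < cfg$panel_coverage[["1000g"]]
  in_esp <- stats::runif(n) < cfg$panel_coverage[["esp"]]
  af_esp <- round(pmin(pmax(af * stats::runif(n, 0.8, 1.2), 1e-5), 0.999), 6)

  # dbSNP-like membership with first-build numbers
  in_dbsnp <- logical(n); build <- rep(NA_integer_, n)
  u <- stats::runif(n)
  old_common <- common & u < cfg$dbsnp_common_frac
  new_common <- common & !old_common & u < cfg$dbsnp_common_frac + 0.025
  new_rare <- !common & u < 0.10
  in_dbsnp <- old_common | new_common | new_rare
  build[old_common] <- sample(80:129, sum(old_common), replace = TRUE)
  build[new_common | new_rare] <- sample(130:150, sum(new_common | new_rare),
                                         replace = TRUE)
  rsid <- ifelse(in_dbsnp, sprintf("rs%07d", seq_len(n)), "")

  has_scores <- stats::runif(n) < cfg$score_coverage
  sift <- round(stats::runif(n), 4)
  polyphen <- round(stats::runif(n), 4)
  cadd <- round(stats::runif(n, 0, 40), 2)
  impact <- sample(names(cfg$impact_probs), n, replace = TRUE,
                   prob = cfg$impact_probs)
  func_class <- vapply(impact, function(im) {
    sample(.FUNC_CLASS_BY_IMPACT[[im]], 1L)
  }, character(1), USE.NAMES = FALSE)

  sites <- data.frame(
    chrom = genes$chrom[g_idx], pos = pos, gene = genes$symbol[g_idx],
    ref = ref, alt = alt, af = af, common = common,
    in_1000g = in_1000g, in_esp = in_esp, af_esp = af_esp,
    in_dbsnp = in_dbsnp, build = build, rsid = rsid,
    has_scores = has_scores, sift = sift, polyphen = polyphen, cadd = cadd,
    impact = impact, func_class = func_class, stringsAsFactors = FALSE)
  ord <- order(chrom_rank(sites$chrom), sites$chrom, sites$pos, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL

  # causal gene and site(s): on X for the X-linked model, autosomal otherwise
  on_x <- genes$chrom == "X"
  causal_gene <- if (cfg$model == "XL_HEMI") {
    genes[on_x, ][sample(sum(on_x), 1L), ]
  } else {
    genes[!on_x, ][sample(sum(!on_x), 1L), ]
  }
  n_causal <- if (cfg$model == "AR_COMPHET") 2L else 1L
  taken <- sites$pos[sites$chrom == causal_gene$chrom]
  free <- setdiff(seq(causal_gene$start, causal_gene$end), taken)
  cpos <- sort(sample(free, n_causal))
  cref <- sample(bases, n_causal, replace = TRUE)
  calt <- vapply(cref, function(r) sample(setdiff(bases, r), 1L), character(1),
                 USE.NAMES = FALSE)
  causal <- data.frame(
    chrom = causal_gene$chrom, pos = cpos, gene = causal_gene$symbol,
    ref = cref, alt = calt, impact = "HIGH",
    func_class = "stop_gained", stringsAsFactors = FALSE)

  # disease catalog: random gene bundles plus one disease for the causal gene
  inh_label <- switch(cfg$model, AR_HOM = "AR", AR_COMPHET = "AR",
                      AD_HET = "AD", DE_NOVO = "AD", XL_HEMI = "XL")
  nd <- cfg$n_diseases
  disease_genes <- lapply(seq_len(nd - 1L), function(d) {
    sample(genes$symbol, sample(1:5, 1L))
  })
  diseases <- data.frame(
    disease_name = c(sprintf("Synthetic disorder %03d", seq_len(nd - 1L)),
                     sprintf("Synthetic disorder of %s", causal_gene$symbol)),
    source = sample(c("omim", "cgd"), nd, replace = TRUE),
    inheritance = c(sample(c("AD", "AR", "XL", "other"), nd - 1L, replace = TRUE),
                    inh_label),
    genes = I(c(disease_genes, list(causal_gene$symbol))),
    stringsAsFactors = FALSE)

  list(genes = genes, sites = sites, causal = causal,
       causal_disease = diseases$disease_name[nd], diseases = diseases)
}

# serialize a sites subset as a sorted panel VCF
.write_panel_vcf <- function(rows, info_fun, path, extra_meta = character(0)) {
  vs <- variant_set(
    chrom = rows$chrom, pos = rows$pos,
    id = if (is.null(rows$rsid)) rep("", nrow(rows)) else rows$rsid,
    ref = rows$ref, alt = rows$alt,
    qual = rep(NA_real_, nrow(rows)), filter = rep(".", nrow(rows)),
    info = info_fun(rows),
    meta = c("##fileformat=VCFv4.2", extra_meta))
  write_vcf(vs, path)
}

#' Generate the synthetic reference panels and catalogs
#'
#' Writes, under `dir`: `1000g.vcf` and `esp.vcf` (frequency panels with an
#' `AF` INFO field), `dbsnp.vcf` (rs identifiers, `AF` and first-`build`
#' INFO fields), `dbnsfp.tsv` (per-allele SIFT/PolyPhen-2/CADD score table),
#' `genes.tsv` and `diseases.tsv` (catalogs), and `panels.cfg` (annotation
#' configuration referencing the panels). The planted causal variant is, by
#' construction, absent from every panel; the disease catalog contains the
#' causal gene under the configured inheritance label. Output is
#' byte-identical across runs with the same configuration.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return A list with elements `panels` (list of [reference_panel()]),
#'   `files` (named paths), `gene_catalog`, `disease_catalog`.
#' @export
make_panels <- function(cfg, dir) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- .synth_universe(cfg)
  s <- u$sites
  files <- c(g1000 = file.path(dir, "1000g.vcf"),
             esp = file.path(dir, "esp.vcf"),
             dbsnp = file.path(dir, "dbsnp.vcf"),
             dbnsfp = file.path(dir, "dbnsfp.tsv"),
             genes = file.path(dir, "genes.tsv"),
             diseases = file.path(dir, "diseases.tsv"),
             config = file.path(dir, "panels.cfg"))

  af_meta <- '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">'
  r1 <- s[s$in_1000g, , drop = FALSE]
  .write_panel_vcf(r1, function(r) lapply(r$af, function(a) list(AF = a)),
                   files[["g1000"]], af_meta)
  r2 <- s[s$in_esp, , drop = FALSE]
  r2$af <- r2$af_esp
  .write_panel_vcf(r2, function(r) lapply(r$af, function(a) list(AF = a)),
                   files[["esp"]], af_meta)
  r3 <- s[s$in_dbsnp, , drop = FALSE]
  .write_panel_vcf(r3, function(r) {
    lapply(seq_len(nrow(r)), function(i) list(AF = r$af[i], build = r$build[i]))
  }, files[["dbsnp"]],
  c(af_meta, '##INFO=<ID=build,Number=1,Type=Integer,Description="First dbSNP build">'))

  sc <- s[s$has_scores, c("chrom", "pos", "ref", "alt", "sift", "polyphen", "cadd")]
  names(sc) <- c("chrom", "pos", "ref", "alt", "sift_score", "polyphen2_score",
                 "cadd_phred")
  utils::write.table(sc, files[["dbnsfp"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(u$genes[, c("symbol", "name")], files[["genes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dtab <- data.frame(disease_name = u$diseases$disease_name,
                     source = u$diseases$source,
                     inheritance = u$diseases$inheritance,
                     genes = vapply(u$diseases$genes, paste, character(1),
                                    collapse = ";"),
                     stringsAsFactors = FALSE)
  utils::write.table(dtab, files[["diseases"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  panels <- list(
    reference_panel("1000g", "vcf", files[["g1000"]], "AF"),
    reference_panel("esp", "vcf", files[["esp"]], "AF"),
    reference_panel("dbsnp", "vcf", files[["dbsnp"]], c("AF", "build"),
                    id_fill = TRUE),
    reference_panel("dbnsfp", "scores", files[["dbnsfp"]],
                    c("sift_score", "polyphen2_score", "cadd_phred"))
  )
  write_annotation_config(panels, files[["config"]])
  list(panels = panels, files = files,
       gene_catalog = load_gene_catalog(files[["genes"]]),
       disease_catalog = load_disease_catalog(files[["diseases"]]))
}

#' Generate a synthetic trio with a planted causal variant
#'
#' Draws parental genotypes at the background sites from Hardy-Weinberg
#' proportions at each site's panel frequency (single-allele paternal and
#' proband calls on X: the proband is male) and transmits alleles
#' Mendelianly to the proband. The family VCF contains the sites at which
#' at least one member carries an alternate allele, plus the planted causal
#' variant(s), whose genotypes segregate exactly under the configured model
#' and which are absent from every reference panel, have HIGH impact and
#' read depth of at least 10 in all members. Gene, impact and functional
#' class are written as INFO fields; GT/DP/GQ as FORMAT fields.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory; `trio.vcf`, `trio.ped` and `truth.tsv` are
#'   written there.
#' @return A list with elements `variant_set`, `pedigree`, `truth` (list:
#'   `model`, `gene`, `disease`, `variants` data frame with per-member
#'   genotypes) and `files`.
#' @export
make_family <- function(cfg, dir) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- .synth_universe(cfg)
  s <- u$sites
  n <- nrow(s)
  .set_seed(cfg$seed + 500003L)

  is_x <- s$chrom == "X"
  m1 <- stats::rbinom(n, 1, s$af); m2 <- stats::rbinom(n, 1, s$af)
  f1 <- stats::rbinom(n, 1, s$af); f2 <- stats::rbinom(n, 1, s$af)
  pick_m <- stats::runif(n) < 0.5
  pick_f <- stats::runif(n) < 0.5
  cm <- ifelse(pick_m, m1, m2)
  cf <- ifelse(pick_f, f1, f2)
  gt_mother <- paste0(pmin(m1, m2), "/", pmax(m1, m2))
  gt_father <- ifelse(is_x, as.character(f1),
                      paste0(pmin(f1, f2), "/", pmax(f1, f2)))
  gt_child <- ifelse(is_x, as.character(cm),
                     paste0(pmin(cm, cf), "/", pmax(cm, cf)))
  carrier <- (m1 + m2 + ifelse(is_x, f1, f1 + f2) +
                ifelse(is_x, cm, cm + cf)) > 0
  keep <- which(carrier)

  k <- length(keep)
  depth <- function(n_rec) {
    d <- stats::rpois(n_rec, cfg$mean_depth)
    low <- stats::runif(n_rec) < cfg$low_depth_frac
    d[low] <- sample(0:9, sum(low), replace = TRUE)
    as.integer(d)
  }
  rec <- data.frame(
    chrom = s$chrom[keep], pos = s$pos[keep], id = s$rsid[keep],
    ref = s$ref[keep], alt = s$alt[keep],
    qual = round(stats::runif(k, 50, 3000), 1),
    gene = s$gene[keep], impact = s$impact[keep],
    func_class = s$func_class[keep],
    gt_p = gt_child[keep], gt_m = gt_mother[keep], gt_f = gt_father[keep],
    stringsAsFactors = FALSE)
  rec$dp_p <- depth(k); rec$dp_m <- depth(k); rec$dp_f <- depth(k)

  # planted causal variant(s)
  cz <- u$causal
  ncz <- nrow(cz)
  causal_gt <- switch(cfg$model,
    AR_HOM = data.frame(gt_p = "1/1", gt_m = "0/1", gt_f = "0/1"),
    AR_COMPHET = data.frame(gt_p = c("0/1", "0/1"),
                            gt_m = c("0/1", "0/0"),
                            gt_f = c("0/0", "0/1")),
    AD_HET = data.frame(gt_p = "0/1", gt_m = "0/0", gt_f = "0/0"),
    DE_NOVO = data.frame(gt_p = "0/1", gt_m = "0/0", gt_f = "0/0"),
    XL_HEMI = data.frame(gt_p = "1", gt_m = "0/1", gt_f = "0"))
  causal_rec <- data.frame(
    chrom = cz$chrom, pos = cz$pos, id = "", ref = cz$ref, alt = cz$alt,
    qual = round(stats::runif(ncz, 800, 2500), 1),
    gene = cz$gene, impact = cz$impact, func_class = cz$func_class,
    gt_p = causal_gt$gt_p, gt_m = causal_gt$gt_m, gt_f = causal_gt$gt_f,
    dp_p = pmax(10L, as.integer(stats::rpois(ncz, cfg$mean_depth))),
    dp_m = pmax(10L, as.integer(stats::rpois(ncz, cfg$mean_depth))),
    dp_f = pmax(10L, as.integer(stats::rpois(ncz, cfg$mean_depth))),
    stringsAsFactors = FALSE)
  rec <- rbind(rec, causal_rec)
  ord <- order(chrom_rank(rec$chrom), rec$chrom, rec$pos, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  nr <- nrow(rec)

  samples <- c("PROBAND", "MOTHER", "FATHER")
  meta <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=gene,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=impact,Number=1,Type=String,Description="Consequence impact">',
    '##INFO=<ID=func_class,Number=1,Type=String,Description="Functional class">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  gq <- matrix(sample(30:99, nr * 3L, replace = TRUE), nr, 3L)
  vs <- variant_set(
    chrom = rec$chrom, pos = rec$pos, id = rec$id, ref = rec$ref,
    alt = rec$alt, qual = rec$qual, filter = rep("PASS", nr),
    info = lapply(seq_len(nr), function(i) {
      list(gene = rec$gene[i], impact = rec$impact[i],
           func_class = rec$func_class[i])
    }),
    samples = samples,
    gt = cbind(rec$gt_p, rec$gt_m, rec$gt_f),
    dp = cbind(rec$dp_p, rec$dp_m, rec$dp_f),
    gq = gq, meta = meta)

  ped <- pedigree(proband = "PROBAND", mother = "MOTHER", father = "FATHER",
                  unaffected = character(0), sex_proband = "male")
  files <- c(vcf = file.path(dir, "trio.vcf"),
             ped = file.path(dir, "trio.ped"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(vs, files[["vcf"]])
  write_pedigree(ped, files[["ped"]])
  truth_tab <- data.frame(model = cfg$model, gene = cz$gene, chrom = cz$chrom,
                          pos = cz$pos, ref = cz$ref, alt = cz$alt,
                          gt_proband = causal_gt$gt_p,
                          gt_mother = causal_gt$gt_m,
                          gt_father = causal_gt$gt_f,
                          disease = u$causal_disease,
                          stringsAsFactors = FALSE)
  utils::write.table(truth_tab, files[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(variant_set = vs, pedigree = ped,
       truth = list(model = cfg$model, gene = cz$gene[1L],
                    disease = u$causal_disease, variants = truth_tab),
       files = files)
}

#' Read and write annotation configuration files
#'
#' The configuration is a tab-separated plain-text file with one panel per
#' line: `name`, `kind` (`vcf`/`scores`), `path`, comma-separated
#' `copy_fields`, and `id_fill` (0/1). Relative paths are resolved against
#' the configuration file's directory.
#'
#' @param panels list of [reference_panel()]s.
#' @param path configuration file path.
#' @return `write_annotation_config()` returns `path` invisibly;
#'   `read_annotation_config()` returns an [annotation_config()].
#' @export
write_annotation_config <- function(panels, path) {
  lines <- vapply(panels, function(p) {
    rel <- if (dirname(p$path) == dirname(path)) basename(p$path) else p$path
    sprintf("%s\t%s\t%s\t%s\t%d", p$name, p$kind, rel,
            paste(p$copy_fields, collapse = ","), as.integer(p$id_fill))
  }, character(1))
  writeLines(c("# name\tkind\tpath\tcopy_fields\tid_fill", lines), path)
  invisible(path)
}

#' @rdname write_annotation_config
#' @export
read_annotation_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  panels <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 5L) stop("malformed annotation config line: ", ln)
    p <- f[3L]
    if (!file.exists(p)) p <- file.path(dirname(path), f[3L])
    reference_panel(f[1L], f[2L], p, strsplit(f[4L], ",", fixed = TRUE)[[1L]],
                    id_fill = f[5L] == "1")
  })
  annotation_config(panels)
}
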
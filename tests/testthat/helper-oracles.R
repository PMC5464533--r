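# Independent brute-force oracles. These re-derive expected results from
# first principles (naive per-record loops) and are deliberately written
# without reusing the package's vectorized code paths.

# --- genotype helpers for the oracles ---------------------------------------

oracle_gt_split <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "")) return(NULL)
  parts <- strsplit(gt, "[/|]")[[1]]
  if (any(parts == ".")) return(NULL)
  as.integer(parts)
}

oracle_zygosity <- function(gt) {
  a <- oracle_gt_split(gt)
  if (is.null(a)) return("missing")
  if (length(a) == 1) return(if (a == 0) "hom_ref" else "hemi")
  if (all(a == 0)) return("hom_ref")
  if (length(unique(a)) == 1 && a[1] > 0) return("hom_alt")
  "het"
}

# allele strings carried by a call; NULL when missing
oracle_alleles <- function(gt, ref, alts) {
  a <- oracle_gt_split(gt)
  if (is.null(a)) return(NULL)
  c(ref, alts)[a + 1]
}

# --- filter oracle ----------------------------------------------------------

# per-alt numeric vector from an INFO value (NA where absent / ".")
oracle_per_alt <- function(value, n_alt) {
  if (is.null(value)) return(rep(NA_real_, n_alt))
  if (is.character(value) && length(value) == 1 && grepl(",", value)) {
    value <- strsplit(value, ",")[[1]]
  }
  v <- suppressWarnings(as.numeric(value))
  if (length(v) == n_alt) v else if (length(v) == 1) rep(v, n_alt)
  else rep(NA_real_, n_alt)
}

# naive conjunctive evaluation of one record against a FilterSpec
oracle_filter_record <- function(rec, spec) {
  # rec: list(chrom, pos, qual, gt, dp, alts (character vector), info (named list))
  if (!is.null(spec$zygosity) &&
      !oracle_zygosity(rec$gt) %in% spec$zygosity) return(FALSE)
  if (!is.null(spec$impacts)) {
    im <- rec$info$impact
    if (is.null(im) || !im %in% spec$impacts) return(FALSE)
  }
  if (!is.null(spec$functional_classes)) {
    fc <- rec$info$func_class
    if (is.null(fc) || !fc %in% spec$functional_classes) return(FALSE)
  }
  if (!is.null(spec$min_depth)) {
    if (spec$strict_depth) {
      if (is.na(rec$dp) || rec$dp < spec$min_depth) return(FALSE)
    } else if (!is.na(rec$dp) && rec$dp < spec$min_depth) return(FALSE)
  }
  if (!is.null(spec$min_qual)) {
    if (!is.na(rec$qual) && rec$qual < spec$min_qual) return(FALSE)
  }
  if (!is.null(spec$max_dbsnp_build)) {
    b <- rec$info$dbsnp_build
    if (!is.null(b)) {
      b <- suppressWarnings(as.integer(b))
      if (!is.na(b) && b <= spec$max_dbsnp_build) return(FALSE)
    }
  }
  if (!is.null(spec$regions)) {
    inside <- FALSE
    for (r in seq_len(nrow(spec$regions))) {
      if (rec$chrom == spec$regions$chrom[r] &&
          rec$pos >= spec$regions$start[r] && rec$pos <= spec$regions$end[r]) {
        inside <- TRUE
      }
    }
    if (!inside) return(FALSE)
  }
  if (!is.null(spec$gene_panel)) {
    g <- rec$info$gene
    if (is.null(g) || !toupper(g) %in% spec$gene_panel$symbols) return(FALSE)
  }
  # allele-level block: some alt must pass all frequency + score criteria
  n_alt <- length(rec$alts)
  has_allele_block <- length(spec$max_panel_frequency) > 0 ||
    length(spec$score_thresholds) > 0
  if (has_allele_block) {
    any_alt_ok <- FALSE
    for (k in seq_len(n_alt)) {
      alt_ok <- TRUE
      for (p in names(spec$max_panel_frequency)) {
        f <- oracle_per_alt(rec$info[[paste0(p, "_AF")]], n_alt)[k]
        if (is.na(f)) {
          if (!spec$keep_unannotated_frequency) alt_ok <- FALSE
        } else if (f > spec$max_panel_frequency[[p]]) alt_ok <- FALSE
      }
      for (field in names(spec$score_thresholds)) {
        th <- spec$score_thresholds[[field]]
        v <- oracle_per_alt(rec$info[[field]], n_alt)[k]
        if (!is.na(v)) {
          if (th$direction == "le" && v > th$cutoff) alt_ok <- FALSE
          if (th$direction == "ge" && v < th$cutoff) alt_ok <- FALSE
        }
      }
      if (alt_ok) any_alt_ok <- TRUE
    }
    if (!any_alt_ok) return(FALSE)
  }
  TRUE
}

# extract the oracle's view of record i of a VariantSet for sample s
oracle_record <- function(vs, i, s) {
  list(chrom = vs$fix$chrom[i], pos = vs$fix$pos[i], qual = vs$fix$qual[i],
       gt = vs$gt[i, s], dp = vs$dp[i, s],
       alts = strsplit(vs$fix$alt[i], ",")[[1]], info = vs$info[[i]])
}

oracle_apply_filters <- function(vs, spec, s) {
  vapply(seq_len(n_variants(vs)), function(i) {
    oracle_filter_record(oracle_record(vs, i, s), spec)
  }, logical(1))
}

# --- inheritance oracles ----------------------------------------------------

# single-site rule evaluation from raw trio genotypes (allele-string level);
# mother/father may be NA_character_ to mean "sample absent"
oracle_single_site <- function(model, chrom, ref, alts, gt_p, gt_m, gt_f,
                               sex = "male") {
  carries <- function(gt, a) {
    al <- oracle_alleles(gt, ref, alts)
    if (is.null(al)) return(NA)
    a %in% al
  }
  copies <- function(gt, a) {
    al <- oracle_alleles(gt, ref, alts)
    if (is.null(al)) return(NA_integer_)
    sum(al == a)
  }
  zp <- oracle_zygosity(gt_p)
  have_m <- !is.na(gt_m); have_f <- !is.na(gt_f)
  if (model == "AR_HOM") {
    if (zp != "hom_alt") return(FALSE)
    a <- oracle_alleles(gt_p, ref, alts)[1]
    for (pg in c(if (have_m) gt_m, if (have_f) gt_f)) {
      cp <- copies(pg, a)
      if (!is.na(cp) && !(cp == 1 && oracle_zygosity(pg) == "het")) return(FALSE)
    }
    return(TRUE)
  }
  if (model == "DE_NOVO") {
    if (zp != "het") return(FALSE)
    if (!have_m || !have_f) return(FALSE)
    am <- oracle_alleles(gt_m, ref, alts); af <- oracle_alleles(gt_f, ref, alts)
    if (is.null(am) || is.null(af)) return(FALSE)
    return(all(am == ref) && all(af == ref))
  }
  if (model == "XL_HEMI") {
    if (chrom != "X" || sex != "male") return(FALSE)
    if (!zp %in% c("hemi", "hom_alt")) return(FALSE)
    a <- setdiff(oracle_alleles(gt_p, ref, alts), ref)[1]
    if (have_m) {
      cm <- carries(gt_m, a)
      if (!is.na(cm) && !(cm && oracle_zygosity(gt_m) == "het")) return(FALSE)
    }
    return(TRUE)
  }
  stop("oracle_single_site does not handle ", model)
}

# AD with explicit affected/unaffected genotype lists
oracle_ad_het <- function(ref, alts, gt_p, affected_gts, unaffected_gts) {
  if (oracle_zygosity(gt_p) != "het") return(FALSE)
  cand <- setdiff(oracle_alleles(gt_p, ref, alts), ref)
  for (a in cand) {
    ok <- TRUE
    for (g in affected_gts) {
      al <- oracle_alleles(g, ref, alts)
      if (!is.null(al) && !a %in% al) ok <- FALSE
    }
    for (g in unaffected_gts) {
      al <- oracle_alleles(g, ref, alts)
      if (!is.null(al) && a %in% al) ok <- FALSE
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# compound-het gene decision from per-variant trio genotypes (both parents
# available): variant k is (ref_k, alts_k, gt_p_k, gt_m_k, gt_f_k)
oracle_comphet_gene <- function(vars) {
  hets <- Filter(function(v) oracle_zygosity(v$gt_p) == "het", vars)
  if (length(hets) < 2) return(FALSE)
  mother_only <- FALSE; father_only <- FALSE
  for (v in hets) {
    a <- setdiff(oracle_alleles(v$gt_p, v$ref, v$alts), v$ref)[1]
    am <- oracle_alleles(v$gt_m, v$ref, v$alts)
    af <- oracle_alleles(v$gt_f, v$ref, v$alts)
    if (is.null(am) || is.null(af)) next
    cm <- a %in% am; cf <- a %in% af
    if (cm && !cf) mother_only <- TRUE
    if (cf && !cm) father_only <- TRUE
  }
  mother_only && father_only
}

# --- misc oracles -----------------------------------------------------------

# linear scan over panel rows for interval queries
oracle_linear_query <- function(rows, chrom, start, end) {
  hit <- rows$chrom == chrom & rows$pos >= start & rows$pos <= end
  out <- rows[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one-pass summary recomputation
oracle_summary <- function(vs) {
  quals <- vs$fix$qual[!is.na(vs$fix$qual)]
  list(total = nrow(vs$fix),
       novel = sum(vs$fix$id %in% c("", ".")),
       qual_mean = if (length(quals)) mean(quals) else NULL)
}

# random FilterSpec for property tests
random_spec <- function(panel_names = "1000g", score_fields = "dbnsfp_sift_score") {
  args <- list()
  if (runif(1) < 0.4) {
    args$zygosity <- sample(c("hom_alt", "het", "hemi"), sample(1:3, 1))
  }
  if (runif(1) < 0.5) {
    args$impacts <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), sample(1:3, 1))
  }
  if (runif(1) < 0.4) args$min_depth <- sample(0:30, 1)
  if (runif(1) < 0.3) args$min_qual <- runif(1, 0, 500)
  if (runif(1) < 0.4) args$max_dbsnp_build <- sample(c(120, 129, 135, 150), 1)
  if (runif(1) < 0.5) {
    cuts <- runif(length(panel_names), 0, 0.1)
    names(cuts) <- panel_names
    args$max_panel_frequency <- cuts
    args$keep_unannotated_frequency <- runif(1) < 0.8
  }
  if (runif(1) < 0.25) {
    args$regions <- data.frame(chrom = sample(c("1", "2", "X"), 2),
                               start = c(1, 1), end = c(5e5, 1e6))
  }
  if (runif(1) < 0.3) {
    args$gene_panel <- gene_panel(sprintf("GN%04d", sample.int(60, 20)))
  }
  if (runif(1) < 0.3) {
    args$score_thresholds <- list()
    args$score_thresholds[[sample(score_fields, 1)]] <-
      list(direction = sample(c("le", "ge"), 1), cutoff = runif(1))
  }
  if (runif(1) < 0.2) args$strict_depth <- TRUE
  do.call(filter_spec, args)
}
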
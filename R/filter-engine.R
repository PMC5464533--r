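# The filter analysis: conjunctive predicates over annotated variants,
# multi-individual gene intersection, and Mendelian inheritance models.

#' Construct a candidate report
#'
#' The common result container of the filtering operations: the surviving
#' records, the gene each belongs to, per-record provenance (which filters
#' it passed), per-gene counts, and input/output counts per pipeline stage.
#'
#' @param variants surviving records as a [variant_set()].
#' @param provenance list of character vectors, one per surviving record.
#' @param n_input number of records entering the operation.
#' @param stages data frame with columns `stage`, `n_in`, `n_out`.
#' @return An object of class `CandidateReport`.
#' @export
candidate_report <- function(variants, provenance = NULL, n_input = n_variants(variants),
                             stages = NULL) {
  n <- n_variants(variants)
  if (is.null(provenance)) provenance <- rep(list(character(0)), n)
  stopifnot(length(provenance) == n, n <= n_input)
  genes <- info_field_chr(variants, "gene")
  gene_counts <- if (n > 0L) table(genes[!is.na(genes)]) else table(character(0))
  if (is.null(stages)) {
    stages <- data.frame(stage = "filter", n_in = n_input, n_out = n,
                         stringsAsFactors = FALSE)
  }
  structure(list(variants = variants, gene = genes, provenance = provenance,
                 gene_counts = gene_counts, n_input = n_input, n_output = n,
                 stages = stages),
            class = "CandidateReport")
}

#' @export
print.CandidateReport <- function(x, ...) {
  cat(sprintf("<CandidateReport> %d of %d record(s) surviving in %d gene(s)\n",
              x$n_output, x$n_input, length(x$gene_counts)))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Tabulate a candidate report
#'
#' @param report a `CandidateReport`.
#' @param ... unused.
#' @return A data frame with one row per surviving record: gene, locus,
#'   alleles, per-sample genotypes and the provenance string, ordered by
#'   gene symbol then locus.
#' @export
as.data.frame.CandidateReport <- function(report, ...) {
  vs <- report$variants
  out <- data.frame(gene = report$gene, chrom = vs$fix$chrom, pos = vs$fix$pos,
                    ref = vs$fix$ref, alt = vs$fix$alt,
                    impact = info_field_chr(vs, "impact"),
                    stringsAsFactors = FALSE)
  for (s in vs$samples) {
    out[[paste0("GT_", s)]] <- vs$gt[, s]
    out[[paste0("DP_", s)]] <- vs$dp[, s]
  }
  freq_keys <- sort(unique(grep("_AF$", unlist(lapply(vs$info, names)),
                                value = TRUE)))
  for (key in freq_keys) out[[key]] <- info_field_chr(vs, key)
  out$provenance <- vapply(report$provenance, paste, character(1), collapse = "+")
  ord <- order(is.na(out$gene), out$gene, chrom_rank(out$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-alt numeric values of an INFO field: list of numeric vectors aligned
# to each record's ALT alleles ("." and absent -> NA; scalars recycle)
.per_alt_numeric <- function(vs, key, n_alt) {
  raw <- info_field(vs, key)
  lapply(seq_along(raw), function(i) {
    v <- raw[[i]]
    if (is.null(v)) return(rep(NA_real_, n_alt[i]))
    if (is.character(v) && length(v) == 1L && grepl(",", v, fixed = TRUE)) {
      v <- strsplit(v, ",", fixed = TRUE)[[1L]]
    }
    num <- suppressWarnings(as.numeric(v))
    if (length(num) == n_alt[i]) return(num)
    if (length(num) == 1L) return(rep(num, n_alt[i]))
    rep(NA_real_, n_alt[i])
  })
}

.require_field <- function(vs, key, criterion) {
  present <- any(vapply(vs$info, function(ii) !is.null(ii[[key]]), logical(1)))
  if (!present) {
    stop(sprintf("filter criterion '%s' references annotation field '%s', which is absent from every record",
                 criterion, key))
  }
}

#' Apply a filter specification to one individual's variants
#'
#' Evaluates the conjunction of all active criteria of `spec` (see
#' [filter_spec()]) against every record, using the genotype calls of the
#' named sample for zygosity and depth. Allele-level criteria (frequencies,
#' scores) are evaluated per ALT allele and a record passes that block if
#' any allele passes all of them. A criterion whose annotation field is
#' absent from every record raises a configuration error naming the field.
#'
#' @param vs an annotated [variant_set()].
#' @param spec a [filter_spec()].
#' @param sample sample name whose calls drive zygosity/depth; defaults to
#'   the first sample.
#' @return A [candidate_report()].
#' @export
apply_filters <- function(vs, spec, sample = NULL) {
  stopifnot(inherits(spec, "FilterSpec"))
  n <- n_variants(vs)
  if (length(vs$samples) > 0L) {
    if (is.null(sample)) sample <- vs$samples[1L]
    if (!sample %in% vs$samples) stop("no such sample: ", sample)
  } else if (!is.null(spec$zygosity) || !is.null(spec$min_depth)) {
    stop("zygosity/depth criteria require sample genotype data")
  }
  pass <- matrix(TRUE, nrow = n, ncol = 0)
  add <- function(name, ok) {
    pass <<- cbind(pass, stats::setNames(data.frame(ok), name))
  }

  if (!is.null(spec$zygosity)) {
    z <- zygosity_class(vs$gt[, sample])
    add("zygosity", z %in% spec$zygosity)
  }
  if (!is.null(spec$impacts)) {
    .require_field(vs, "impact", "impacts")
    add("impact", info_field_chr(vs, "impact") %in% spec$impacts)
  }
  if (!is.null(spec$functional_classes)) {
    .require_field(vs, "func_class", "functional_classes")
    add("func_class", info_field_chr(vs, "func_class") %in% spec$functional_classes)
  }
  if (!is.null(spec$min_depth)) {
    dp <- vs$dp[, sample]
    ok <- if (spec$strict_depth) !is.na(dp) & dp >= spec$min_depth
          else is.na(dp) | dp >= spec$min_depth
    add("min_depth", ok)
  }
  if (!is.null(spec$min_qual)) {
    q <- vs$fix$qual
    add("min_qual", is.na(q) | q >= spec$min_qual)
  }
  if (!is.null(spec$max_dbsnp_build)) {
    .require_field(vs, "dbsnp_build", "max_dbsnp_build")
    build <- dbsnp_build_of(vs)
    add("dbsnp_build", is.na(build) | build > spec$max_dbsnp_build)
  }
  if (!is.null(spec$regions)) {
    in_region <- rep(FALSE, n)
    for (r in seq_len(nrow(spec$regions))) {
      in_region <- in_region |
        (vs$fix$chrom == as.character(spec$regions$chrom[r]) &
           vs$fix$pos >= spec$regions$start[r] &
           vs$fix$pos <= spec$regions$end[r])
    }
    add("regions", in_region)
  }
  if (!is.null(spec$gene_panel)) {
    .require_field(vs, "gene", "gene_panel")
    g <- info_field_chr(vs, "gene")
    add("gene_panel", !is.na(g) & toupper(g) %in% spec$gene_panel$symbols)
  }

  # allele-level block: frequencies and score thresholds per ALT allele
  allele_criteria <- length(spec$max_panel_frequency) > 0L ||
    length(spec$score_thresholds) > 0L
  if (allele_criteria && n > 0L) {
    n_alt <- lengths(alt_alleles(vs))
    allele_ok <- lapply(n_alt, function(k) rep(TRUE, k))
    if (!is.null(spec$max_panel_frequency)) {
      for (p in names(spec$max_panel_frequency)) {
        key <- paste0(p, "_AF")
        .require_field(vs, key, "max_panel_frequency")
        freq <- .per_alt_numeric(vs, key, n_alt)
        cutoff <- spec$max_panel_frequency[[p]]
        for (i in seq_len(n)) {
          f <- freq[[i]]
          ok <- ifelse(is.na(f), spec$keep_unannotated_frequency, f <= cutoff)
          allele_ok[[i]] <- allele_ok[[i]] & ok
        }
      }
    }
    if (!is.null(spec$score_thresholds)) {
      for (field in names(spec$score_thresholds)) {
        th <- spec$score_thresholds[[field]]
        .require_field(vs, field, "score_thresholds")
        sc <- .per_alt_numeric(vs, field, n_alt)
        for (i in seq_len(n)) {
          v <- sc[[i]]
          ok <- ifelse(is.na(v), TRUE,
                       if (th$direction == "le") v <= th$cutoff else v >= th$cutoff)
          allele_ok[[i]] <- allele_ok[[i]] & ok
        }
      }
    }
    add("allele_criteria", vapply(allele_ok, any, logical(1)))
  }

  survivors <- if (ncol(pass) == 0L) rep(TRUE, n) else apply(as.matrix(pass), 1, all)
  passed <- colnames(pass)
  report <- candidate_report(
    subset_variants(vs, survivors),
    provenance = rep(list(passed), sum(survivors)),
    n_input = n,
    stages = data.frame(stage = "apply_filters", n_in = n,
                        n_out = sum(survivors), stringsAsFactors = FALSE)
  )
  report
}

#' Genes shared by every individual's surviving variants
#'
#' Intersects, across individuals, the sets of genes that contain at least
#' one surviving variant — the "common genes between all selected
#' individuals" step of the default pipeline.
#'
#' @param reports nonempty (optionally named) list of [candidate_report()]s.
#' @return A [gene_panel()] of the intersection.
#' @export
genes_in_common <- function(reports) {
  if (inherits(reports, "CandidateReport")) reports <- list(reports)
  if (length(reports) == 0L) stop("genes_in_common needs at least one report")
  gene_sets <- lapply(reports, function(r) {
    stopifnot(inherits(r, "CandidateReport"))
    unique(r$gene[!is.na(r$gene)])
  })
  gene_panel(Reduce(intersect, gene_sets), label = "genes_in_common")
}

# ---- pedigree --------------------------------------------------------------

#' Describe a family pedigree
#'
#' Binds the samples of a multi-sample variant set to family roles for the
#' inheritance-model filters.
#'
#' @param proband sample name of the index patient.
#' @param mother,father optional parental sample names.
#' @param affected optional additional affected members (e.g. siblings).
#' @param unaffected optional unaffected members whose genotypes must not
#'   carry a dominant variant.
#' @param sex_proband `"male"`, `"female"` or `"unknown"`; the X-linked
#'   hemizygous model requires a known sex.
#' @return An object of class `Pedigree`.
#' @export
pedigree <- function(proband, mother = NULL, father = NULL,
                     affected = character(0), unaffected = character(0),
                     sex_proband = c("unknown", "male", "female")) {
  sex_proband <- match.arg(sex_proband)
  members <- c(proband, mother, father, affected, unaffected)
  if (anyDuplicated(members)) stop("pedigree sample names must be distinct")
  structure(list(proband = proband, mother = mother, father = father,
                 affected = as.character(affected),
                 unaffected = as.character(unaffected),
                 sex_proband = sex_proband),
            class = "Pedigree")
}

#' Read a PED-like pedigree file
#'
#' Whitespace-separated columns: family, sample, father, mother, sex
#' (1 = male, 2 = female, 0 = unknown), affected (2 = affected,
#' 1 = unaffected). `0` stands for a missing parent. The proband is the
#' first affected sample with at least one named parent, or the first
#' affected sample.
#'
#' @param path path to the pedigree file.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "sample", "father",
                                         "mother", "sex", "affected"))
  aff <- tab[tab$affected == 2, , drop = FALSE]
  if (nrow(aff) == 0L) stop("pedigree has no affected sample: ", path)
  with_parents <- aff[aff$father != "0" | aff$mother != "0", , drop = FALSE]
  pb <- if (nrow(with_parents) > 0L) with_parents[1L, ] else aff[1L, ]
  pedigree(
    proband = pb$sample,
    mother = if (pb$mother != "0") pb$mother else NULL,
    father = if (pb$father != "0") pb$father else NULL,
    affected = setdiff(aff$sample, pb$sample),
    unaffected = setdiff(tab$sample[tab$affected == 1], pb$sample),
    sex_proband = c("unknown", "male", "female")[match(pb$sex, c(0, 1, 2))]
  )
}

#' Write a pedigree to a PED-like file
#' @param ped a [pedigree()].
#' @param path output path.
#' @param family family identifier written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  sex_code <- c(unknown = 0, male = 1, female = 2)[ped$sex_proband]
  rows <- sprintf("%s\t%s\t%s\t%s\t%d\t%d", family, ped$proband,
                  if (is.null(ped$father)) "0" else ped$father,
                  if (is.null(ped$mother)) "0" else ped$mother, sex_code, 2L)
  for (s in ped$affected) rows <- c(rows, sprintf("%s\t%s\t0\t0\t0\t2", family, s))
  for (s in c(ped$mother, ped$father)) {
    sx <- if (!is.null(ped$mother) && s == ped$mother) 2L else 1L
    rows <- c(rows, sprintf("%s\t%s\t0\t0\t%d\t1", family, s, sx))
  }
  for (s in setdiff(ped$unaffected, c(ped$mother, ped$father))) {
    rows <- c(rows, sprintf("%s\t%s\t0\t0\t0\t1", family, s))
  }
  writeLines(rows, path)
  invisible(path)
}

# ---- inheritance models ----------------------------------------------------

.INHERITANCE_MODELS <- c("AR_HOM", "AR_COMPHET", "AD_HET", "DE_NOVO", "XL_HEMI")

# does a call carry allele string `a`? NA when the call is missing
.carries <- function(gt, ref, alts, a) {
  alleles <- gt_allele_strings(gt, ref, alts)
  if (is.null(alleles)) return(NA)
  a %in% alleles
}

.copies_of <- function(gt, ref, alts, a) {
  alleles <- gt_allele_strings(gt, ref, alts)
  if (is.null(alleles)) return(NA_integer_)
  sum(alleles == a)
}

#' Filter variants under a Mendelian inheritance model
#'
#' Applies one of five segregation models to a multi-sample variant set.
#' Parental checks degrade gracefully: a rule involving a parent is only
#' enforced when that parent is in the sample set and has a called genotype
#' at the site (except `DE_NOVO`, which requires verifiable absence in both
#' parents).
#'
#' * `AR_HOM` — proband homozygous for an alternate allele; each available
#'   parent carries exactly one copy (heterozygous carrier) and is not
#'   homozygous alternate.
#' * `AR_COMPHET` — a gene holds two or more distinct heterozygous proband
#'   variants; when both parents are available the configuration must be
#'   trans by transmission (at least one variant carried by the mother and
#'   not the father, and at least one by the father and not the mother);
#'   genes failing the trans check are dropped. Without both parents the
#'   gene qualifies but its records carry a `phase_unverified` provenance
#'   flag.
#' * `AD_HET` — proband heterozygous; every available affected relative
#'   carries the allele and no available unaffected member does.
#' * `DE_NOVO` — proband heterozygous; both parents must be present and
#'   neither carries any alternate allele at the site.
#' * `XL_HEMI` — X-chromosome variants with a male proband carrying the
#'   alternate allele hemizygously (single-allele call) or as an effectively
#'   homozygous call; when the mother is available she must be a
#'   heterozygous carrier.
#'
#' @param vs a multi-sample [variant_set()] containing the pedigree samples.
#' @param ped a [pedigree()].
#' @param model one of `"AR_HOM"`, `"AR_COMPHET"`, `"AD_HET"`, `"DE_NOVO"`,
#'   `"XL_HEMI"`.
#' @return A [candidate_report()] of the records compatible with the model.
#' @export
filter_inheritance <- function(vs, ped, model) {
  stopifnot(inherits(ped, "Pedigree"))
  model <- match.arg(model, .INHERITANCE_MODELS)
  if (!ped$proband %in% vs$samples) {
    stop("proband sample '", ped$proband, "' not present in the variant set")
  }
  has_mother <- !is.null(ped$mother) && ped$mother %in% vs$samples
  has_father <- !is.null(ped$father) && ped$father %in% vs$samples
  if (model == "DE_NOVO" && !(has_mother && has_father)) {
    stop("DE_NOVO requires both parents in the variant set")
  }
  if (model == "XL_HEMI" && ped$sex_proband == "unknown") {
    stop("XL_HEMI requires a known proband sex")
  }
  n <- n_variants(vs)
  alts <- alt_alleles(vs)
  pb_gt <- vs$gt[, ped$proband]
  pb_class <- zygosity_class(pb_gt)
  keep <- rep(FALSE, n)
  prov <- rep(list(character(0)), n)
  tag <- paste0("model_", model)

  site_gt <- function(member, i) vs$gt[i, member]

  if (model %in% c("AR_HOM", "AD_HET", "DE_NOVO", "XL_HEMI")) {
    for (i in seq_len(n)) {
      ref <- vs$fix$ref[i]; aa <- alts[[i]]
      ok <- switch(model,
        AR_HOM = {
          if (pb_class[i] != "hom_alt") FALSE else {
            a <- gt_allele_strings(pb_gt[i], ref, aa)[1L]
            ok_m <- if (has_mother) {
              cm <- .copies_of(site_gt(ped$mother, i), ref, aa, a)
              is.na(cm) || (cm == 1L && zygosity_class(site_gt(ped$mother, i)) == "het")
            } else TRUE
            ok_f <- if (has_father) {
              cf <- .copies_of(site_gt(ped$father, i), ref, aa, a)
              is.na(cf) || (cf == 1L && zygosity_class(site_gt(ped$father, i)) == "het")
            } else TRUE
            ok_m && ok_f
          }
        },
        AD_HET = {
          if (pb_class[i] != "het") FALSE else {
            pb_alleles <- gt_allele_strings(pb_gt[i], ref, aa)
            cand <- setdiff(pb_alleles, ref)
            any(vapply(cand, function(a) {
              aff_ok <- all(vapply(ped$affected, function(s) {
                if (!s %in% vs$samples) return(TRUE)
                carrier <- .carries(site_gt(s, i), ref, aa, a)
                is.na(carrier) || carrier
              }, logical(1)))
              unaff_ok <- all(vapply(ped$unaffected, function(s) {
                if (!s %in% vs$samples) return(TRUE)
                carrier <- .carries(site_gt(s, i), ref, aa, a)
                is.na(carrier) || !carrier
              }, logical(1)))
              aff_ok && unaff_ok
            }, logical(1)))
          }
        },
        DE_NOVO = {
          if (pb_class[i] != "het") FALSE else {
            gm <- gt_indices(site_gt(ped$mother, i))
            gf <- gt_indices(site_gt(ped$father, i))
            length(gm) > 0L && length(gf) > 0L && !anyNA(gm) && !anyNA(gf) &&
              all(gm == 0L) && all(gf == 0L)
          }
        },
        XL_HEMI = {
          if (vs$fix$chrom[i] != "X" || ped$sex_proband != "male") FALSE
          else if (!pb_class[i] %in% c("hemi", "hom_alt")) FALSE
          else {
            a <- setdiff(gt_allele_strings(pb_gt[i], ref, aa), ref)[1L]
            if (has_mother) {
              mg <- site_gt(ped$mother, i)
              carrier <- .carries(mg, ref, aa, a)
              is.na(carrier) ||
                (carrier && zygosity_class(mg) == "het")
            } else TRUE
          }
        })
      if (isTRUE(ok)) {
        keep[i] <- TRUE
        prov[[i]] <- tag
      }
    }
  } else {  # AR_COMPHET
    genes <- info_field_chr(vs, "gene")
    het_idx <- which(pb_class == "het" & !is.na(genes))
    phase_checked <- has_mother && has_father
    for (g in unique(genes[het_idx])) {
      idx <- het_idx[genes[het_idx] == g]
      distinct <- !duplicated(paste(vs$fix$chrom[idx], vs$fix$pos[idx],
                                    vs$fix$ref[idx], vs$fix$alt[idx]))
      idx <- idx[distinct]
      if (length(idx) < 2L) next
      gene_ok <- TRUE
      flag <- character(0)
      if (phase_checked) {
        from_mother_only <- logical(length(idx))
        from_father_only <- logical(length(idx))
        for (k in seq_along(idx)) {
          i <- idx[k]
          ref <- vs$fix$ref[i]; aa <- alts[[i]]
          a <- setdiff(gt_allele_strings(pb_gt[i], ref, aa), ref)[1L]
          cm <- .carries(site_gt(ped$mother, i), ref, aa, a)
          cf <- .carries(site_gt(ped$father, i), ref, aa, a)
          if (!is.na(cm) && !is.na(cf)) {
            from_mother_only[k] <- cm && !cf
            from_father_only[k] <- cf && !cm
          }
        }
        gene_ok <- any(from_mother_only) && any(from_father_only)
      } else {
        flag <- "phase_unverified"
      }
      if (gene_ok) {
        keep[idx] <- TRUE
        for (i in idx) prov[[i]] <- c(tag, flag)
      }
    }
  }

  candidate_report(
    subset_variants(vs, keep),
    provenance = prov[keep],
    n_input = n,
    stages = data.frame(stage = paste0("inheritance_", model), n_in = n,
                        n_out = sum(keep), stringsAsFactors = FALSE)
  )
}
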
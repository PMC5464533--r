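#' Normalize a variant set before annotation
#'
#' The sanity check prepares an uploaded VCF for annotation and filtering:
#'
#' * records in which every sample call is homozygous-reference or fully
#'   missing are removed (a sites-only set with no samples is left intact);
#' * `"chr"` prefixes (any capitalization) are stripped from chromosome
#'   labels;
#' * records are sorted by chromosome in natural human order
#'   (1..22, X, Y, MT, then unknown contigs), then position, REF and ALT;
#' * INFO keys `EFF` and `ANN` left over from a previous consequence
#'   annotation run are deleted.
#'
#' The operation is idempotent: applying it twice gives the same result as
#' applying it once.
#'
#' @param vs a [variant_set()].
#' @return The normalized `VariantSet`.
#' @export
sanity_check <- function(vs) {
  n <- n_variants(vs)
  if (n > 0L && length(vs$samples) > 0L) {
    zyg <- apply(vs$gt, 2, zygosity_class)
    zyg <- matrix(zyg, nrow = n)
    keep <- apply(zyg, 1, function(z) any(!z %in% c("hom_ref", "missing")))
    vs <- subset_variants(vs, keep)
  }
  vs$fix$chrom <- sub("^[Cc][Hh][Rr]", "", vs$fix$chrom)
  vs <- drop_info_keys(vs, c("EFF", "ANN"))
  subset_variants(vs, variant_order(vs))
}

#' Validate a variant set
#'
#' Checks a parsed variant set for structural problems and returns them as a
#' report rather than raising errors. Detected problems:
#'
#' * `unsorted` (warning): adjacent record pairs out of the canonical
#'   chromosome/position order, one entry per inversion;
#' * `duplicate` (error): repeated (chrom, pos, ref, alt) records;
#' * `allele_index` (error): GT allele index beyond the number of ALT alleles;
#' * `allele_chars` (error): REF/ALT alleles containing characters outside
#'   `A`, `C`, `G`, `T`, `N`, `*` (this rejects symbolic ALT alleles);
#' * `undeclared_info` (warning): INFO keys used by records but not declared
#'   in the header, one entry per key.
#'
#' @param vs a [variant_set()].
#' @return A data frame of class `ValidationReport` with columns `record`,
#'   `severity`, `code` and `message`; zero rows if and only if the set is
#'   clean.
#' @export
validate_vcf <- function(vs) {
  rec <- integer(0); sev <- character(0); code <- character(0); msg <- character(0)
  add <- function(r, s, c, m) {
    rec <<- c(rec, r); sev <<- c(sev, s); code <<- c(code, c); msg <<- c(msg, m)
  }
  n <- n_variants(vs)
  if (n > 1L) {
    key_rank <- order(variant_order(vs))  # rank of each record in sorted order
    inv <- which(diff(key_rank) < 0L) + 1L
    for (i in inv) {
      add(i, "warning", "unsorted",
          sprintf("record %d (%s:%d) is out of order relative to record %d",
                  i, vs$fix$chrom[i], vs$fix$pos[i], i - 1L))
    }
    key <- paste(vs$fix$chrom, vs$fix$pos, vs$fix$ref, vs$fix$alt, sep = "\r")
    for (i in which(duplicated(key))) {
      add(i, "error", "duplicate",
          sprintf("record %d duplicates (%s, %d, %s, %s)", i, vs$fix$chrom[i],
                  vs$fix$pos[i], vs$fix$ref[i], vs$fix$alt[i]))
    }
  }
  if (n > 0L) {
    alts <- alt_alleles(vs)
    for (i in seq_len(n)) {
      n_alt <- length(alts[[i]])
      if (length(vs$samples) > 0L) {
        for (s in seq_along(vs$samples)) {
          idx <- gt_indices(vs$gt[i, s])
          bad <- idx[!is.na(idx) & idx > n_alt]
          if (length(bad)) {
            add(i, "error", "allele_index",
                sprintf("record %d sample %s: allele index out of range (%s with %d ALT allele(s))",
                        i, vs$samples[s], vs$gt[i, s], n_alt))
          }
        }
      }
      alleles <- c(vs$fix$ref[i], alts[[i]])
      bad <- alleles[!grepl("^[ACGTN*]+$", alleles)]
      if (length(bad)) {
        add(i, "error", "allele_chars",
            sprintf("record %d: allele(s) %s contain characters outside ACGTN*",
                    i, paste(bad, collapse = ",")))
      }
    }
    declared <- names(.info_types(vs$meta))
    used <- unique(unlist(lapply(vs$info, names)))
    for (key in setdiff(used, declared)) {
      first <- which(vapply(vs$info, function(ii) !is.null(ii[[key]]), logical(1)))[1L]
      add(first, "warning", "undeclared_info",
          sprintf("INFO key '%s' (first used at record %d) is not declared in the header",
                  key, first))
    }
  }
  structure(data.frame(record = rec, severity = sev, code = code,
                       message = msg, stringsAsFactors = FALSE),
            class = c("ValidationReport", "data.frame"))
}

#' @export
print.ValidationReport <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Clean: no validation problems found.\n")
  } else {
    cat(sprintf("%d validation problem(s): %d error(s), %d warning(s)\n",
                nrow(x), sum(x$severity == "error"), sum(x$severity == "warning")))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s\n", x$severity[i], x$message[i]))
    }
  }
  invisible(x)
}

#' Summarize a variant set
#'
#' Computes the headline metrics shown before filtering: the total and novel
#' variant counts (novel = no external identifier), the minimum/maximum/mean
#' of record quality, per-sample read-depth minimum/maximum/mean, and
#' per-sample zygosity counts. Statistics are computed over present values
#' only; a field that is missing everywhere is reported as absent (`NULL`),
#' never as zero.
#'
#' @param vs a [variant_set()].
#' @return A list of class `SummaryStats` with elements `total_variants`,
#'   `novel_variants`, `qual` (list with `min`, `max`, `mean`, or `NULL`),
#'   `depth` (per-sample named list of min/max/mean, or `NULL` entries) and
#'   `zygosity` (class-by-sample count matrix).
#' @export
summarize_vcf <- function(vs) {
  n <- n_variants(vs)
  novel <- if (n == 0L) 0L else sum(vs$fix$id == "" | vs$fix$id == ".")
  stat3 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    list(min = min(x), max = max(x), mean = mean(x))
  }
  depth <- NULL
  zyg <- NULL
  if (length(vs$samples) > 0L) {
    depth <- lapply(seq_along(vs$samples), function(s) stat3(vs$dp[, s]))
    names(depth) <- vs$samples
    classes <- c("hom_ref", "het", "hom_alt", "hemi", "missing")
    zyg <- vapply(seq_along(vs$samples), function(s) {
      z <- zygosity_class(vs$gt[, s])
      vapply(classes, function(cl) sum(z == cl), integer(1))
    }, integer(length(classes)))
    dimnames(zyg) <- list(classes, vs$samples)
  }
  structure(list(total_variants = n, novel_variants = as.integer(novel),
                 qual = stat3(vs$fix$qual), depth = depth, zygosity = zyg),
            class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("Total variants: %d\nNovel variants: %d\n",
              x$total_variants, x$novel_variants))
  if (!is.null(x$qual)) {
    cat(sprintf("Quality: min %.4g, max %.4g, mean %.4g\n",
                x$qual$min, x$qual$max, x$qual$mean))
  }
  for (s in names(x$depth)) {
    d <- x$depth[[s]]
    if (!is.null(d)) {
      cat(sprintf("Depth [%s]: min %d, max %d, mean %.4g\n", s, d$min, d$max, d$mean))
    }
  }
  if (!is.null(x$zygosity)) {
    cat("Zygosity counts:\n")
    print(x$zygosity)
  }
  invisible(x)
}
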
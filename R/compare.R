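# Pairwise call-set comparison: shared positions and genotype concordance
# (e.g. two siblings, or tumor vs germline from the same individual).

.position_key <- function(vs) paste(vs$fix$chrom, vs$fix$pos, sep = "\r")

# resolved allele multiset for sample `s` at record `i`, as a canonical
# string; NA when the call is missing
.gt_multiset <- function(vs, i, s) {
  alleles <- gt_allele_strings(vs$gt[i, s], vs$fix$ref[i],
                               strsplit(vs$fix$alt[i], ",", fixed = TRUE)[[1L]])
  if (is.null(alleles)) NA_character_ else paste(alleles, collapse = "/")
}

.sample_or_first <- function(vs, sample, which_arg) {
  if (length(vs$samples) == 0L) stop("variant set has no samples (", which_arg, ")")
  if (is.null(sample)) return(vs$samples[1L])
  if (!sample %in% vs$samples) {
    stop("sample '", sample, "' not present in ", which_arg, " input")
  }
  sample
}

#' Compare the genotypes of two call sets
#'
#' Matches records of the two sets by position (chromosome + position) and
#' compares genotypes at the shared positions. Genotypes are resolved to
#' allele strings, so the same site is compared correctly even when the two
#' files encode ALT alleles differently; two calls are concordant when their
#' allele multisets are equal, ignoring phase. Positions at which either
#' side's genotype is missing are excluded from the comparison. The
#' concordance percentage is kept at full precision (display rounds to one
#' decimal); with no shared positions it is reported as `NA`.
#'
#' @param a,b sanity-checked [variant_set()]s.
#' @param sample_a,sample_b sample names to compare (default: first sample
#'   of each set).
#' @return An object of class `ComparisonResult` with fields
#'   `positions_in_common`, `concordant_genotypes`, `concordance_percent`,
#'   `discordant` (data frame: chrom, pos, gt_a, gt_b), `private_a`,
#'   `private_b` (counts of alt-carrying records private to each side).
#' @export
compare_vcfs <- function(a, b, sample_a = NULL, sample_b = NULL) {
  sample_a <- .sample_or_first(a, sample_a, "first")
  sample_b <- .sample_or_first(b, sample_b, "second")
  key_a <- .position_key(a)
  key_b <- .position_key(b)
  ia <- which(!duplicated(key_a))
  ib <- match(key_a[ia], key_b)
  shared <- which(!is.na(ib))

  n_common <- 0L
  n_conc <- 0L
  disc <- list()
  for (k in shared) {
    i <- ia[k]; j <- ib[k]
    ga <- .gt_multiset(a, i, sample_a)
    gb <- .gt_multiset(b, j, sample_b)
    if (is.na(ga) || is.na(gb)) next
    n_common <- n_common + 1L
    if (ga == gb) {
      n_conc <- n_conc + 1L
    } else {
      disc[[length(disc) + 1L]] <- data.frame(
        chrom = a$fix$chrom[i], pos = a$fix$pos[i], gt_a = ga, gt_b = gb,
        stringsAsFactors = FALSE)
    }
  }
  discordant <- if (length(disc)) do.call(rbind, disc)
                else data.frame(chrom = character(0), pos = integer(0),
                                gt_a = character(0), gt_b = character(0),
                                stringsAsFactors = FALSE)
  priv <- private_variants(a, b, sample_a, sample_b)
  structure(list(
    positions_in_common = n_common,
    concordant_genotypes = n_conc,
    concordance_percent = if (n_common > 0L) 100 * n_conc / n_common else NA_real_,
    discordant = discordant,
    private_a = n_variants(priv$a), private_b = n_variants(priv$b),
    sample_a = sample_a, sample_b = sample_b),
    class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("Positions in common (both called): %d\n", x$positions_in_common))
  cat(sprintf("Concordant genotypes: %d\n", x$concordant_genotypes))
  if (is.na(x$concordance_percent)) {
    cat("Concordance: not defined (no shared called positions)\n")
  } else {
    cat(sprintf("Concordance: %.1f%%\n", x$concordance_percent))
  }
  cat(sprintf("Private to %s: %d; private to %s: %d\n",
              x$sample_a, x$private_a, x$sample_b, x$private_b))
  invisible(x)
}

#' Variants private to each of two call sets
#'
#' Returns the records of `a` at positions absent from `b` at which the
#' compared sample carries an alternate allele, and vice versa — the
#' operation behind somatic-style comparisons of a tumor call set against
#' the same individual's germline calls.
#'
#' @inheritParams compare_vcfs
#' @return A list with `VariantSet` elements `a` and `b`.
#' @export
private_variants <- function(a, b, sample_a = NULL, sample_b = NULL) {
  sample_a <- .sample_or_first(a, sample_a, "first")
  sample_b <- .sample_or_first(b, sample_b, "second")
  key_a <- .position_key(a)
  key_b <- .position_key(b)
  carries_alt <- function(vs, s) {
    z <- zygosity_class(vs$gt[, s, drop = TRUE])
    z %in% c("het", "hom_alt", "hemi")
  }
  only_a <- !(key_a %in% key_b) & carries_alt(a, sample_a)
  only_b <- !(key_b %in% key_a) & carries_alt(b, sample_b)
  list(a = subset_variants(a, only_a), b = subset_variants(b, only_b))
}
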
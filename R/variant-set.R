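# Canonical human chromosome ordering used everywhere a sort is needed:
# 1..22, X, Y, MT; unknown contigs follow MT in lexicographic order.
.CHROM_ORDER <- c(as.character(1:22), "X", "Y", "MT")

#' Construct a variant set
#'
#' A `VariantSet` is the package's in-memory model of a VCF file: the raw
#' meta-information lines, the sample names, one row per data line with typed
#' fixed fields, a per-record INFO map, and per-sample GT/DP/GQ matrices.
#' Genotype fields other than GT, DP and GQ are not retained.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param id character vector of external identifiers, `";"`-separated,
#'   `""` when a record has none.
#' @param ref,alt reference and alternate allele strings; multiple alternate
#'   alleles are `","`-joined in `alt`.
#' @param qual numeric phred-scaled record quality, `NA` when missing.
#' @param filter character FILTER status (`"PASS"`, failed-filter labels, or
#'   `"."` when missing).
#' @param info list of named lists, one per record, holding typed INFO values
#'   (integer, double, character, or `TRUE` for flags).
#' @param samples character vector of sample names (may be empty for
#'   sites-only files such as frequency panels).
#' @param gt,dp,gq matrices with one row per record and one column per sample:
#'   raw GT strings (`"."` when missing), integer read depths and genotype
#'   qualities (`NA` when missing).
#' @param meta character vector of `##` header lines.
#'
#' @return An object of class `VariantSet`.
#' @export
variant_set <- function(chrom = character(), pos = integer(), id = character(),
                        ref = character(), alt = character(),
                        qual = numeric(), filter = character(),
                        info = list(), samples = character(),
                        gt = NULL, dp = NULL, gq = NULL,
                        meta = "##fileformat=VCFv4.2") {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  if (length(id) == 0L && n > 0L) id <- rep("", n)
  if (length(qual) == 0L && n > 0L) qual <- rep(NA_real_, n)
  if (length(filter) == 0L && n > 0L) filter <- rep(".", n)
  if (length(info) == 0L && n > 0L) info <- rep(list(list()), n)
  s <- length(samples)
  if (is.null(gt)) gt <- matrix(".", n, s)
  if (is.null(dp)) dp <- matrix(NA_integer_, n, s)
  if (is.null(gq)) gq <- matrix(NA_integer_, n, s)
  gt <- matrix(as.character(gt), n, s, dimnames = list(NULL, samples))
  dp <- matrix(as.integer(dp), n, s, dimnames = list(NULL, samples))
  gq <- matrix(as.integer(gq), n, s, dimnames = list(NULL, samples))
  if (n > 0L && any(pos < 1L)) stop("positions must be >= 1")
  fix <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    id = as.character(id), ref = as.character(ref),
                    alt = as.character(alt), qual = as.numeric(qual),
                    filter = as.character(filter), stringsAsFactors = FALSE)
  structure(list(meta = meta, samples = as.character(samples), fix = fix,
                 info = info, gt = gt, dp = dp, gq = gq),
            class = "VariantSet")
}

#' Number of records in a variant set
#' @param vs a `VariantSet`.
#' @return Integer count of data lines.
#' @export
n_variants <- function(vs) nrow(vs$fix)

#' @export
print.VariantSet <- function(x, ...) {
  cat(sprintf("<VariantSet> %d records, %d sample(s)%s\n", n_variants(x),
              length(x$samples),
              if (length(x$samples)) paste0(": ", paste(x$samples, collapse = ", ")) else ""))
  if (n_variants(x) > 0) {
    utils::str(utils::head(x$fix, 5), give.attr = FALSE)
  }
  invisible(x)
}

#' Subset the records of a variant set
#' @param vs a `VariantSet`.
#' @param i integer or logical index over records.
#' @return A `VariantSet` containing the selected records in the given order.
#' @export
subset_variants <- function(vs, i) {
  vs$fix <- vs$fix[i, , drop = FALSE]
  rownames(vs$fix) <- NULL
  vs$info <- vs$info[i]
  vs$gt <- vs$gt[i, , drop = FALSE]
  vs$dp <- vs$dp[i, , drop = FALSE]
  vs$gq <- vs$gq[i, , drop = FALSE]
  vs
}

# rank of a chromosome label in natural human order; unknown contigs sort
# after MT (handled by the caller via a secondary lexicographic key)
chrom_rank <- function(chrom) {
  r <- match(chrom, .CHROM_ORDER)
  r[is.na(r)] <- length(.CHROM_ORDER) + 1L
  r
}

# ordering permutation for the VariantSet sort invariant
variant_order <- function(vs) {
  with(vs$fix, order(chrom_rank(chrom), chrom, pos, ref, alt, method = "radix"))
}

is_variant_sorted <- function(vs) {
  !is.unsorted(variant_order(vs), strictly = FALSE) &&
    all(variant_order(vs) == seq_len(n_variants(vs)))
}

#' Extract an INFO field across records
#'
#' @param vs a `VariantSet`.
#' @param key INFO key name.
#' @return A list of values (element `NULL` where the key is absent). Use
#'   [info_field_chr()] or [info_field_num()] for flattened atomic access.
#' @export
info_field <- function(vs, key) {
  lapply(vs$info, function(i) i[[key]])
}

#' @rdname info_field
#' @export
info_field_chr <- function(vs, key) {
  vapply(vs$info, function(i) {
    v <- i[[key]]
    if (is.null(v)) NA_character_ else paste(as.character(v), collapse = ",")
  }, character(1))
}

#' @rdname info_field
#' @export
info_field_num <- function(vs, key) {
  vapply(vs$info, function(i) {
    v <- i[[key]]
    if (is.null(v) || length(v) == 0L) return(NA_real_)
    suppressWarnings(as.numeric(v[[1L]]))
  }, numeric(1))
}

# split comma-joined ALT strings into per-record character vectors
alt_alleles <- function(vs) strsplit(vs$fix$alt, ",", fixed = TRUE)

# split ";"-joined id strings; "" and "." yield character(0)
id_list <- function(vs) {
  lapply(vs$fix$id, function(x) {
    if (is.na(x) || x == "" || x == ".") character(0)
    else strsplit(x, ";", fixed = TRUE)[[1L]]
  })
}

# ---- genotype handling -----------------------------------------------------

# parse one GT string into integer allele indices (NA for "."); "" and "."
# give integer(0)
gt_indices <- function(gt) {
  if (is.na(gt) || gt == "." || gt == "") return(integer(0))
  suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1L]]))
}

#' Classify genotype calls by zygosity
#'
#' Classifies GT strings into `missing`, `hom_ref`, `het`, `hom_alt` or
#' `hemi`. A call is `missing` when any allele is missing; a single-allele
#' call is `hom_ref` when reference and `hemi` when alternate; diploid calls
#' are `hom_ref` (all 0), `hom_alt` (all equal, non-zero) or `het` otherwise.
#'
#' @param gt character vector of GT strings (e.g. `"0/1"`, `"1"`, `"."`).
#' @return Character vector of zygosity classes.
#' @export
zygosity_class <- function(gt) {
  vapply(gt, function(g) {
    a <- gt_indices(g)
    if (length(a) == 0L || anyNA(a)) return("missing")
    if (length(a) == 1L) return(if (a == 0L) "hom_ref" else "hemi")
    if (all(a == 0L)) return("hom_ref")
    if (all(a == a[1L]) && a[1L] > 0L) return("hom_alt")
    "het"
  }, character(1), USE.NAMES = FALSE)
}

# resolve a GT string to the allele strings it carries (sorted multiset);
# NULL when the call is missing
gt_allele_strings <- function(gt, ref, alts) {
  a <- gt_indices(gt)
  if (length(a) == 0L || anyNA(a)) return(NULL)
  all_alleles <- c(ref, alts)
  sort(all_alleles[a + 1L])
}

# set/replace one INFO key on selected records
set_info <- function(vs, i, key, values) {
  for (k in seq_along(i)) {
    vs$info[[i[k]]][[key]] <- values[[k]]
  }
  vs
}

drop_info_keys <- function(vs, keys) {
  vs$info <- lapply(vs$info, function(ii) ii[setdiff(names(ii), keys)])
  vs
}
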
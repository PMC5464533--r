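#' Declare a variant filter specification
#'
#' A `FilterSpec` is the declarative form of the filter-analysis options:
#' every field is optional (`NULL` = criterion inactive) and a record
#' survives only if it satisfies every active criterion (conjunction).
#' Allele-level criteria (population frequency, pathogenicity scores) are
#' evaluated per ALT allele; a multi-allelic record survives the allele-level
#' block if any of its alleles does.
#'
#' Missing values never count as zero: records lacking DP pass the depth
#' criterion (unless `strict_depth`), records lacking QUAL pass the quality
#' criterion, records without a frequency annotation pass the frequency
#' criterion when `keep_unannotated_frequency` is `TRUE` (the default), and
#' records without a score pass score thresholds.
#'
#' The frequency criterion *excludes common variants*: a record fails for
#' panel `p` when its `"<p>_AF"` annotation exceeds `max_panel_frequency[p]`.
#' (The original tool's description reads "exclude variants with frequency
#' lower than 1%", but its validated use — recovering rare pathogenic
#' variants — requires the reading implemented here.)
#'
#' @param zygosity subset of `c("hom_alt", "het", "hemi")` the named sample's
#'   call must fall in.
#' @param impacts subset of `c("HIGH", "MODERATE", "LOW", "MODIFIER")`
#'   matched against the `impact` INFO field.
#' @param functional_classes optional consequence labels matched against the
#'   `func_class` INFO field.
#' @param min_depth minimum per-sample read depth (DP).
#' @param min_qual minimum record QUAL.
#' @param max_dbsnp_build exclude records whose dbSNP first-build annotation
#'   is present and less than or equal to this value.
#' @param max_panel_frequency named numeric vector of frequency cutoffs in
#'   `[0, 1]`, names are panel prefixes (e.g. `c("1000g" = 0.01)`).
#' @param regions optional data frame with columns `chrom`, `start`, `end`
#'   (1-based closed intervals) the locus must fall in.
#' @param gene_panel optional [gene_panel()]; the record's `gene` INFO field
#'   must be in it.
#' @param score_thresholds optional named list; each element
#'   `list(direction = "le"|"ge", cutoff = x)` is applied to the INFO field
#'   of that name.
#' @param keep_unannotated_frequency if `TRUE`, records without a frequency
#'   annotation pass the frequency criterion.
#' @param strict_depth if `TRUE`, records lacking DP fail the depth
#'   criterion instead of passing it.
#' @return An object of class `FilterSpec`.
#' @export
filter_spec <- function(zygosity = NULL, impacts = NULL,
                        functional_classes = NULL, min_depth = NULL,
                        min_qual = NULL, max_dbsnp_build = NULL,
                        max_panel_frequency = NULL, regions = NULL,
                        gene_panel = NULL, score_thresholds = NULL,
                        keep_unannotated_frequency = TRUE,
                        strict_depth = FALSE) {
  if (!is.null(zygosity)) {
    zygosity <- match.arg(zygosity, c("hom_alt", "het", "hemi"), several.ok = TRUE)
  }
  if (!is.null(impacts)) {
    impacts <- match.arg(impacts, c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                         several.ok = TRUE)
  }
  if (!is.null(min_depth) && min_depth < 0) stop("min_depth must be >= 0")
  if (!is.null(max_panel_frequency)) {
    if (is.null(names(max_panel_frequency)) || any(names(max_panel_frequency) == "")) {
      stop("max_panel_frequency must be a named vector of panel cutoffs")
    }
    if (any(max_panel_frequency < 0 | max_panel_frequency > 1)) {
      stop("frequency cutoffs must lie in [0, 1]")
    }
  }
  if (!is.null(regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
    if (any(regions$start > regions$end)) stop("regions must have start <= end")
  }
  if (!is.null(gene_panel)) stopifnot(inherits(gene_panel, "GenePanel"))
  if (!is.null(score_thresholds)) {
    ok <- vapply(score_thresholds, function(t) {
      is.list(t) && t$direction %in% c("le", "ge") && is.numeric(t$cutoff)
    }, logical(1))
    if (!all(ok) || is.null(names(score_thresholds))) {
      stop("score_thresholds must be a named list of list(direction, cutoff)")
    }
  }
  structure(list(zygosity = zygosity, impacts = impacts,
                 functional_classes = functional_classes,
                 min_depth = min_depth, min_qual = min_qual,
                 max_dbsnp_build = max_dbsnp_build,
                 max_panel_frequency = max_panel_frequency,
                 regions = regions, gene_panel = gene_panel,
                 score_thresholds = score_thresholds,
                 keep_unannotated_frequency = isTRUE(keep_unannotated_frequency),
                 strict_depth = isTRUE(strict_depth)),
            class = "FilterSpec")
}

#' @export
print.FilterSpec <- function(x, ...) {
  active <- names(x)[!vapply(x, is.null, logical(1))]
  active <- setdiff(active, c("keep_unannotated_frequency", "strict_depth"))
  cat("<FilterSpec> active criteria:",
      if (length(active)) paste(active, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Merge override values into a filter specification
#'
#' Fields present (non-`NULL`) in `overrides` replace the corresponding
#' fields of `base`; the two boolean policies are taken from `overrides`
#' only when it is a full `FilterSpec`.
#'
#' @param base a [filter_spec()].
#' @param overrides a `FilterSpec` or a named list of fields to replace.
#' @return The merged `FilterSpec`.
#' @export
merge_filter_spec <- function(base, overrides) {
  stopifnot(inherits(base, "FilterSpec"))
  if (is.null(overrides)) return(base)
  fields <- setdiff(names(base), c("keep_unannotated_frequency", "strict_depth"))
  args <- base[fields]
  for (f in intersect(names(overrides), fields)) {
    if (!is.null(overrides[[f]])) args[[f]] <- overrides[[f]]
  }
  args$keep_unannotated_frequency <-
    if (!is.null(overrides$keep_unannotated_frequency))
      overrides$keep_unannotated_frequency else base$keep_unannotated_frequency
  args$strict_depth <-
    if (!is.null(overrides$strict_depth)) overrides$strict_depth
    else base$strict_depth
  do.call(filter_spec, args)
}

#' Serialize a filter specification to a plain-text (JSON) config file
#'
#' @param spec a [filter_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_spec <- function(spec, path) {
  stopifnot(inherits(spec, "FilterSpec"))
  x <- unclass(spec)
  if (!is.null(x$gene_panel)) x$gene_panel <- unclass(x$gene_panel)
  if (!is.null(x$max_panel_frequency)) {
    x$max_panel_frequency <- as.list(x$max_panel_frequency)
  }
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_filter_spec
#' @return `read_filter_spec()` returns the `FilterSpec`.
#' @export
read_filter_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$gene_panel)) {
    x$gene_panel <- gene_panel(x$gene_panel$symbols, x$gene_panel$label)
  }
  if (!is.null(x$max_panel_frequency)) {
    x$max_panel_frequency <- unlist(x$max_panel_frequency)
  }
  if (!is.null(x$regions)) x$regions <- as.data.frame(x$regions)
  if (!is.null(x$score_thresholds)) {
    x$score_thresholds <- lapply(x$score_thresholds, function(t) {
      list(direction = t$direction, cutoff = as.numeric(t$cutoff))
    })
  }
  do.call(filter_spec, x)
}
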
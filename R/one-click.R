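# The "1-Click" preset: a fixed conservative filter chain plus optional
# inheritance-model and disease-gene restriction, yielding a short candidate
# list in one call.

#' The default (preset) filter specification
#'
#' Returns the preset thresholds of the one-call candidate search:
#'
#' * exclude variants first recorded in dbSNP build 129 or lower (the last
#'   build predating large-scale inclusion of pathogenic SNVs);
#' * exclude variants with read depth lower than 10;
#' * keep only variants with a HIGH or MODERATE consequence impact;
#' * exclude variants whose frequency exceeds 1% in the 1000 Genomes-,
#'   dbSNP- and ESP6500-like panels (unannotated variants are kept);
#' * no pathogenicity-score thresholds — scores are deliberately left to
#'   the user so that a mis-scored variant is not dropped from the initial
#'   list.
#'
#' @return A [filter_spec()].
#' @export
default_spec <- function() {
  filter_spec(
    impacts = c("HIGH", "MODERATE"),
    min_depth = 10,
    max_dbsnp_build = 129,
    max_panel_frequency = c("1000g" = 0.01, dbsnp = 0.01, esp = 0.01),
    keep_unannotated_frequency = TRUE
  )
}

#' Options for the one-call candidate search
#'
#' @param individuals one or more sample names to filter (at least one);
#'   the first is treated as the proband whose surviving records form the
#'   candidate list.
#' @param inheritance_model optional model passed to [filter_inheritance()].
#' @param restrict_to_known_disease_genes keep only candidates in genes with
#'   a known Mendelian-disease association (default `TRUE`); requires
#'   `disease_catalogs`. Set to `FALSE` to allow novel-gene discovery.
#' @param disease_selection optional `DiseaseCatalog` subset; candidates are
#'   restricted to the selected diseases' genes instead of the full known
#'   list.
#' @param disease_catalogs list of `DiseaseCatalog` objects backing the
#'   known-gene restriction.
#' @param overrides optional partial [filter_spec()] (or named list) merged
#'   over [default_spec()].
#' @return An object of class `OneClickOptions`.
#' @export
one_click_options <- function(individuals,
                              inheritance_model = NULL,
                              restrict_to_known_disease_genes = TRUE,
                              disease_selection = NULL,
                              disease_catalogs = NULL,
                              overrides = NULL) {
  if (length(individuals) < 1L) stop("at least one individual is required")
  if (!is.null(inheritance_model)) {
    inheritance_model <- match.arg(inheritance_model, .INHERITANCE_MODELS)
  }
  structure(list(individuals = as.character(individuals),
                 inheritance_model = inheritance_model,
                 restrict_to_known_disease_genes =
                   isTRUE(restrict_to_known_disease_genes),
                 disease_selection = disease_selection,
                 disease_catalogs = disease_catalogs,
                 overrides = overrides),
            class = "OneClickOptions")
}

#' One-call candidate search
#'
#' Runs the preset pipeline on annotated data: the default filter chain
#' ([default_spec()], with any overrides merged) is applied per individual;
#' candidates are restricted to genes with surviving variants in *every*
#' individual; an inheritance model is applied when a model and pedigree are
#' given; and finally candidates are restricted to known disease genes (or
#' to the selected diseases' genes). Every stage's input/output counts are
#' recorded in the report.
#'
#' @param data a multi-sample [variant_set()] holding all individuals, or a
#'   named list of single-sample variant sets keyed by individual (the
#'   multi-sample form is required when an inheritance model is used).
#'   Inputs must carry `gene`, `impact`, frequency and dbSNP-build INFO
#'   annotations (see [annotate_all()]).
#' @param ped optional [pedigree()], required with an inheritance model.
#' @param opts a [one_click_options()].
#' @return A [candidate_report()] for the proband (first individual), with
#'   per-stage counts in `$stages`.
#' @export
one_click <- function(data, ped = NULL, opts) {
  stopifnot(inherits(opts, "OneClickOptions"))
  spec <- merge_filter_spec(default_spec(), opts$overrides)
  multi <- inherits(data, "VariantSet")
  get_vs <- function(ind) {
    if (multi) data
    else {
      vs <- data[[ind]]
      if (is.null(vs)) stop("no variant set supplied for individual ", ind)
      vs
    }
  }

  reports <- lapply(opts$individuals, function(ind) {
    vs <- get_vs(ind)
    sample <- if (ind %in% vs$samples) ind else vs$samples[1L]
    apply_filters(vs, spec, sample)
  })
  names(reports) <- opts$individuals
  stages <- reports[[1L]]$stages
  stages$stage <- paste0("apply_filters:", opts$individuals[1L])

  report <- reports[[1L]]
  if (length(reports) > 1L) {
    common <- genes_in_common(reports)
    keep <- !is.na(report$gene) & toupper(report$gene) %in% common$symbols
    report <- .restrict_report(report, keep, "genes_in_common")
    stages <- rbind(stages, utils::tail(report$stages, 1L))
  }

  if (!is.null(opts$inheritance_model)) {
    if (is.null(ped)) stop("an inheritance model requires a pedigree")
    if (!multi) {
      stop("inheritance filtering requires one multi-sample variant set")
    }
    inh <- tryCatch(
      filter_inheritance(report$variants, ped, opts$inheritance_model),
      error = function(e) {
        stop("inheritance stage (", opts$inheritance_model, "): ",
             conditionMessage(e), call. = FALSE)
      })
    inh$provenance <- lapply(seq_along(inh$provenance), function(i) {
      c(report$provenance[[1L]], inh$provenance[[i]])
    })
    inh$stages <- rbind(stages, inh$stages)
    report <- inh
    stages <- report$stages
  }

  panel <- NULL
  if (!is.null(opts$disease_selection)) {
    panel <- panel_from_diseases(opts$disease_selection)
  } else if (opts$restrict_to_known_disease_genes) {
    if (is.null(opts$disease_catalogs)) {
      stop("restrict_to_known_disease_genes requires disease_catalogs")
    }
    panel <- known_disease_genes(opts$disease_catalogs)
  }
  if (!is.null(panel)) {
    keep <- !is.na(report$gene) & toupper(report$gene) %in% panel$symbols
    report <- .restrict_report(report, keep, paste0("gene_panel:", panel$label))
    stages <- rbind(stages, utils::tail(report$stages, 1L))
  }
  report$stages <- stages
  report$n_input <- stages$n_in[1L]
  report
}

# keep a subset of a report's records, appending a stage row and a
# provenance tag
.restrict_report <- function(report, keep, stage_name) {
  out <- candidate_report(
    subset_variants(report$variants, keep),
    provenance = lapply(report$provenance[keep], function(p) c(p, stage_name)),
    n_input = report$n_input,
    stages = data.frame(stage = stage_name, n_in = report$n_output,
                        n_out = sum(keep), stringsAsFactors = FALSE))
  out
}
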
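# Reference-panel annotation: the generic VCF-against-VCF join plus the
# dbNSFP-style score-table join, with all sources merged into namespaced
# INFO keys "<panel>_<field>".

#' Describe a reference annotation panel
#'
#' A reference panel is a named, coordinate-sorted annotation source: either
#' a VCF (frequency panel, rsID panel, known-mutation panel) or a
#' tab-separated per-allele score table with columns `chrom`, `pos`, `ref`,
#' `alt` and one numeric column per score.
#'
#' @param name short label used as the INFO prefix (must match
#'   `[a-z0-9_]+`), e.g. `"1000g"`, `"dbsnp"`, `"esp"`, `"dbnsfp"`.
#' @param kind `"vcf"` or `"scores"`.
#' @param path path to the panel file (`.vcf`, `.vcf.gz`, or TSV).
#' @param copy_fields fields to copy on a match: INFO keys for a VCF panel,
#'   column names for a score table.
#' @param id_fill if `TRUE`, identifiers (e.g. rs numbers) of matching panel
#'   records are unioned into the target record's IDs.
#' @return An object of class `ReferencePanel`.
#' @export
reference_panel <- function(name, kind = c("vcf", "scores"), path,
                            copy_fields, id_fill = FALSE) {
  kind <- match.arg(kind)
  if (!grepl("^[a-z0-9_]+$", name)) {
    stop("panel name must match [a-z0-9_]+: ", name)
  }
  if (length(copy_fields) == 0L) stop("copy_fields must be nonempty")
  structure(list(name = name, kind = kind, path = path,
                 copy_fields = as.character(copy_fields),
                 id_fill = isTRUE(id_fill)),
            class = "ReferencePanel")
}

# key string for exact-allele matching
.allele_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "\r")
}

#' Build an in-memory coordinate index for a panel
#'
#' Loads a panel file and builds two access structures: a per-chromosome
#' sorted position table supporting interval queries ([panel_query()]) and an
#' exact (chrom, pos, ref, alt) allele map used by the annotation joins.
#' Query cost is logarithmic in panel size.
#'
#' @param panel a [reference_panel()].
#' @return An object of class `PanelIndex`.
#' @seealso [panel_query()], [annotate_with_panel()]
#' @export
build_index <- function(panel) {
  stopifnot(inherits(panel, "ReferencePanel"))
  if (panel$kind == "vcf") {
    pvs <- parse_vcf(panel$path)
    rows <- data.frame(chrom = pvs$fix$chrom, pos = pvs$fix$pos,
                       id = pvs$fix$id, ref = pvs$fix$ref, alt = pvs$fix$alt,
                       stringsAsFactors = FALSE)
    field_values <- lapply(panel$copy_fields, function(f) info_field(pvs, f))
    names(field_values) <- panel$copy_fields
  } else {
    tab <- utils::read.delim(panel$path, stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
    missing_cols <- setdiff(c("chrom", "pos", "ref", "alt", panel$copy_fields),
                            names(tab))
    if (length(missing_cols)) {
      stop("score table ", panel$path, " lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    rows <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                       id = rep("", nrow(tab)), ref = tab$ref, alt = tab$alt,
                       stringsAsFactors = FALSE)
    field_values <- lapply(panel$copy_fields, function(f) {
      lapply(tab[[f]], function(v) if (is.na(v)) NULL else v)
    })
    names(field_values) <- panel$copy_fields
  }
  ord_key <- order(chrom_rank(rows$chrom), rows$chrom, rows$pos, method = "radix")
  if (is.unsorted(ord_key)) {
    first_bad <- which(diff(order(ord_key)) < 0L)[1L] + 1L
    stop(sprintf("panel '%s' is not coordinate-sorted: row %d (%s:%d) is out of order",
                 panel$name, first_bad, rows$chrom[first_bad], rows$pos[first_bad]))
  }
  # expanded per-allele key map: one entry per (row, alt allele)
  alts <- strsplit(rows$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  exp_row <- rep(seq_len(nrow(rows)), n_alt)
  exp_alt_idx <- sequence(n_alt)
  keys <- .allele_key(rows$chrom[exp_row], rows$pos[exp_row],
                      rows$ref[exp_row], unlist(alts))
  by_chrom <- split(seq_len(nrow(rows)), rows$chrom)
  structure(list(panel = panel, rows = rows, fields = field_values,
                 keys = keys, key_row = exp_row, key_alt = exp_alt_idx,
                 by_chrom = by_chrom),
            class = "PanelIndex")
}

#' Query a panel index by genomic interval
#'
#' Returns all panel rows whose position lies in the 1-based closed interval
#' `[start, end]` on `chrom`, via binary search on the per-chromosome sorted
#' position vector.
#'
#' @param index a [build_index()] handle.
#' @param chrom chromosome label.
#' @param start,end interval bounds (1-based, closed).
#' @return A data frame of matching panel rows (`chrom`, `pos`, `id`, `ref`,
#'   `alt`), zero rows when nothing overlaps.
#' @export
panel_query <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "PanelIndex"), start <= end)
  rows_in_chrom <- index$by_chrom[[as.character(chrom)]]
  if (is.null(rows_in_chrom)) return(index$rows[0, , drop = FALSE])
  pos <- index$rows$pos[rows_in_chrom]
  lo <- findInterval(start - 1L, pos) + 1L
  hi <- findInterval(end, pos)
  if (lo > hi) return(index$rows[0, , drop = FALSE])
  out <- index$rows[rows_in_chrom[lo:hi], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pull the value of a panel field for (panel row r, panel alt index k);
# per-alt comma values in the panel are split and selected
.panel_field_value <- function(index, field, r, k) {
  v <- index$fields[[field]][[r]]
  if (is.null(v)) return(NULL)
  if (length(v) > 1L) {
    if (k <= length(v)) return(v[[k]]) else return(NULL)
  }
  if (is.character(v) && grepl(",", v, fixed = TRUE)) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1L]]
    if (k <= length(parts)) return(parts[[k]]) else return(NULL)
  }
  v
}

#' Annotate a target variant set from one reference panel
#'
#' For each target record and each of its ALT alleles, a panel entry matches
#' when chromosome, position, REF and that ALT allele agree exactly. On a
#' match, every field in the panel's `copy_fields` is written into the
#' target's INFO as `<name>_<field>`; for multi-allelic targets the values
#' are comma-joined in ALT order with `"."` for alleles without a match.
#' With `id_fill`, matching panel identifiers are unioned into the target's
#' IDs. Records without any matching allele are left unchanged. Writing over
#' an existing INFO key is an error, never a silent overwrite.
#'
#' @param target a sanity-checked [variant_set()].
#' @param panel a [reference_panel()] or prebuilt [build_index()] handle.
#' @return The annotated `VariantSet`; `chrom`/`pos`/`ref`/`alt` and
#'   genotype calls are never modified.
#' @export
annotate_with_panel <- function(target, panel) {
  index <- if (inherits(panel, "PanelIndex")) panel else build_index(panel)
  spec <- index$panel
  n <- n_variants(target)
  if (n == 0L) return(target)
  alts <- alt_alleles(target)
  n_alt <- lengths(alts)
  t_row <- rep(seq_len(n), n_alt)
  t_alt <- sequence(n_alt)
  t_keys <- .allele_key(target$fix$chrom[t_row], target$fix$pos[t_row],
                        target$fix$ref[t_row], unlist(alts))
  m <- match(t_keys, index$keys)
  hit_rows <- unique(t_row[!is.na(m)])
  if (length(hit_rows) == 0L) return(target)
  sel_by_row <- split(seq_along(t_row), t_row)

  new_keys <- paste0(spec$name, "_", spec$copy_fields)
  for (i in hit_rows) {
    clash <- intersect(new_keys, names(target$info[[i]]))
    if (length(clash)) {
      stop(sprintf("annotation prefix collision at record %d: INFO key(s) %s already present",
                   i, paste(clash, collapse = ", ")))
    }
    sel <- sel_by_row[[as.character(i)]]
    mm <- m[sel]  # panel key index per target alt (NA = no match)
    for (f in spec$copy_fields) {
      vals <- lapply(seq_along(sel), function(j) {
        if (is.na(mm[j])) return(NULL)
        .panel_field_value(index, f, index$key_row[mm[j]], index$key_alt[mm[j]])
      })
      if (all(vapply(vals, is.null, logical(1)))) next
      if (length(vals) == 1L) {
        value <- vals[[1L]]
        if (is.null(value)) next
      } else {
        value <- paste(vapply(vals, function(v) {
          if (is.null(v)) "." else paste(.as_info_chr(v), collapse = ",")
        }, character(1)), collapse = ",")
      }
      target$info[[i]][[paste0(spec$name, "_", f)]] <- value
    }
    if (spec$id_fill) {
      pids <- unlist(lapply(mm[!is.na(mm)], function(k) {
        pid <- index$rows$id[index$key_row[k]]
        if (pid == "" || pid == ".") character(0)
        else strsplit(pid, ";", fixed = TRUE)[[1L]]
      }))
      cur <- if (target$fix$id[i] %in% c("", ".")) character(0)
             else strsplit(target$fix$id[i], ";", fixed = TRUE)[[1L]]
      target$fix$id[i] <- paste(unique(c(cur, pids)), collapse = ";")
    }
  }
  # declare the new INFO keys once
  declared <- names(.info_types(target$meta))
  for (f in spec$copy_fields) {
    key <- paste0(spec$name, "_", f)
    if (!key %in% declared) {
      target$meta <- c(target$meta, sprintf(
        '##INFO=<ID=%s,Number=.,Type=String,Description="Copied from panel %s field %s">',
        key, spec$name, f))
    }
  }
  target
}

.as_info_chr <- function(v) {
  if (is.numeric(v)) .fmt_num(v) else as.character(v)
}

#' @rdname annotate_with_panel
#' @details `annotate_scores()` is the score-table variant of the same join:
#'   matching is on (chrom, pos, ref, alt) and each score column is copied as
#'   `<name>_<column>`; absent scores are omitted, never zero-filled.
#' @export
annotate_scores <- function(target, panel) {
  index <- if (inherits(panel, "PanelIndex")) panel else build_index(panel)
  if (index$panel$kind != "scores") {
    stop("annotate_scores requires a score-table panel; got kind '",
         index$panel$kind, "'")
  }
  annotate_with_panel(target, index)
}

#' Bundle reference panels into an annotation configuration
#'
#' @param panels list of [reference_panel()] objects with pairwise-distinct
#'   names (the names guarantee disjoint INFO prefixes, which makes the merge
#'   order-independent).
#' @return An object of class `AnnotationConfig`.
#' @export
annotation_config <- function(panels) {
  if (inherits(panels, "ReferencePanel")) panels <- list(panels)
  nms <- vapply(panels, function(p) p$name, character(1))
  if (anyDuplicated(nms)) {
    stop("panel names must be unique: ", paste(nms[duplicated(nms)], collapse = ", "))
  }
  structure(list(panels = panels), class = "AnnotationConfig")
}

#' Annotate a target with every panel of a configuration
#'
#' Runs the sanity check on the target, then applies each panel in sequence.
#' Because every panel writes under its own prefix, the merged result is
#' independent of panel order and of splitting the target into chunks.
#' A failure in any panel aborts with that panel's name.
#'
#' @param target a [variant_set()].
#' @param cfg an [annotation_config()] (or list of panels).
#' @return The fully annotated `VariantSet`.
#' @export
annotate_all <- function(target, cfg) {
  if (!inherits(cfg, "AnnotationConfig")) cfg <- annotation_config(cfg)
  out <- sanity_check(target)
  for (p in cfg$panels) {
    out <- tryCatch({
      if (inherits(p, "PanelIndex")) {
        annotate_with_panel(out, p)
      } else if (p$kind == "scores") {
        annotate_scores(out, p)
      } else {
        annotate_with_panel(out, p)
      }
    }, error = function(e) {
      nm <- if (inherits(p, "PanelIndex")) p$panel$name else p$name
      stop("annotation with panel '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # canonicalize: panel-added keys in sorted order so the merged result is
  # byte-identical regardless of panel evaluation order
  prefixes <- vapply(cfg$panels, function(p) {
    if (inherits(p, "PanelIndex")) p$panel$name else p$name
  }, character(1))
  added_rx <- paste0("^(", paste(prefixes, collapse = "|"), ")_")
  out$info <- lapply(out$info, function(ii) {
    added <- grepl(added_rx, names(ii))
    c(ii[!added], ii[sort(names(ii)[added])])
  })
  decl <- startsWith(out$meta, "##INFO=") &
    grepl(added_rx, sub("^##INFO=<ID=", "", out$meta))
  out$meta <- c(out$meta[!decl], sort(out$meta[decl]))
  out
}

#' Read the dbSNP first-build annotation of records
#'
#' Returns the dbSNP build number in which each variant's identifier first
#' appeared, as copied by a dbSNP-like panel (default INFO key
#' `dbsnp_build`). Build 129 is the last dbSNP release predating large-scale
#' inclusion of pathogenic clinical variants, which is why the default
#' filter chain excludes variants first seen in build 129 or earlier.
#'
#' @param vs a [variant_set()] annotated by a dbSNP-like panel.
#' @param field INFO key holding the build number.
#' @return Integer vector, `NA` where a record carries no build annotation.
#' @export
dbsnp_build_of <- function(vs, field = "dbsnp_build") {
  raw <- info_field_chr(vs, field)
  out <- suppressWarnings(as.integer(raw))
  bad <- which(!is.na(raw) & raw != "." & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-integer dbSNP build value '%s' at record %d",
                 raw[bad[1L]], bad[1L]))
  }
  out
}
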
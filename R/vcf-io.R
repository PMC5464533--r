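# Reading and writing VCF 4.1/4.2. File parsing is delegated to
# vcfR::read.vcfR (plain or gzip); this module converts vcfR's raw matrices
# into the typed VariantSet model and serializes it back to conformant text.

# parse ##INFO header declarations into a named vector of types
.info_types <- function(meta) {
  decl <- grep("^##INFO=", meta, value = TRUE)
  ids <- sub('^##INFO=<ID=([^,>]+).*$', "\\1", decl)
  types <- sub('^.*Type=([A-Za-z]+).*$', "\\1", decl)
  types[!types %in% c("Integer", "Float", "Flag", "Character", "String")] <- "String"
  stats::setNames(types, ids)
}

# type one INFO value string according to a declared VCF type
.type_info_value <- function(value, type) {
  if (is.na(type) || type == "String" || type == "Character") return(value)
  parts <- strsplit(value, ",", fixed = TRUE)[[1L]]
  if (type == "Integer") {
    v <- suppressWarnings(as.integer(parts))
    if (any(is.na(v) & parts != ".")) return(value)
    return(v)
  }
  if (type == "Float") {
    v <- suppressWarnings(as.numeric(parts))
    if (any(is.na(v) & parts != ".")) return(value)
    return(v)
  }
  value
}

# parse a vector of raw INFO column strings into a list of named lists
.parse_info_column <- function(info_str, types) {
  lapply(info_str, function(s) {
    if (is.na(s) || s == "." || s == "") return(list())
    fields <- strsplit(s, ";", fixed = TRUE)[[1L]]
    eq <- regexpr("=", fields, fixed = TRUE)
    keys <- ifelse(eq > 0L, substr(fields, 1L, eq - 1L), fields)
    vals <- ifelse(eq > 0L, substr(fields, eq + 1L, nchar(fields)), NA)
    out <- vector("list", length(keys))
    names(out) <- keys
    for (k in seq_along(keys)) {
      if (is.na(vals[k])) {
        out[[k]] <- TRUE  # Flag
      } else {
        out[[k]] <- .type_info_value(vals[k], types[keys[k]])
      }
    }
    out
  })
}

# read header lines of a (possibly gzipped) VCF up to and including #CHROM
.read_header_lines <- function(path, max_lines = 100000L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  out <- character(0)
  repeat {
    chunk <- readLines(con, n = 512L, warn = FALSE)
    if (length(chunk) == 0L) break
    hdr_end <- which(startsWith(chunk, "#CHROM"))
    if (length(hdr_end)) {
      out <- c(out, chunk[seq_len(hdr_end[1L])])
      break
    }
    keep <- startsWith(chunk, "#")
    if (!all(keep)) {
      out <- c(out, chunk[seq_len(which(!keep)[1L] - 1L)])
      break
    }
    out <- c(out, chunk)
    if (length(out) > max_lines) break
  }
  out
}

#' Read a VCF file into a variant set
#'
#' Accepts plain or gzip/bgzip-compressed VCF 4.1/4.2 (`.vcf`, `.vcf.gz`).
#' INFO values are typed according to the header `##INFO` declarations when
#' present and kept as strings otherwise; per-sample GT, DP and GQ are
#' extracted and sample order is preserved.
#'
#' @param path path to the VCF file.
#' @return A [variant_set()].
#' @export
parse_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: no such file: ", path)
  header <- .read_header_lines(path)
  if (length(header) == 0L || !startsWith(header[1L], "##fileformat=VCF")) {
    stop("not a VCF file (line 1 must begin with '##fileformat=VCF'): ", path)
  }
  chrom_line <- header[startsWith(header, "#CHROM")]
  if (length(chrom_line) != 1L) {
    stop(sprintf("garbled VCF header in %s: no #CHROM line found by line %d",
                 path, length(header) + 1L))
  }
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1L]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  meta <- header[startsWith(header, "##")]

  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  types <- .info_types(meta)

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- ""
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."

  vs <- variant_set(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]), id = id,
    ref = fix[, "REF"], alt = alt, qual = qual, filter = filt,
    info = .parse_info_column(unname(fix[, "INFO"]), types),
    samples = samples, meta = meta
  )

  if (length(samples) > 0L && n > 0L) {
    gtm <- v@gt
    fmt <- gtm[, "FORMAT"]
    gt <- matrix(".", n, length(samples), dimnames = list(NULL, samples))
    dp <- matrix(NA_integer_, n, length(samples), dimnames = list(NULL, samples))
    gq <- matrix(NA_integer_, n, length(samples), dimnames = list(NULL, samples))
    for (f in unique(fmt)) {
      rows <- which(fmt == f)
      keys <- strsplit(f, ":", fixed = TRUE)[[1L]]
      i_gt <- match("GT", keys); i_dp <- match("DP", keys); i_gq <- match("GQ", keys)
      for (s in seq_along(samples)) {
        cells <- gtm[rows, samples[s]]
        parts <- strsplit(ifelse(is.na(cells), ".", cells), ":", fixed = TRUE)
        pick <- function(idx) {
          if (is.na(idx)) return(rep(NA_character_, length(parts)))
          vapply(parts, function(p) if (length(p) >= idx) p[idx] else NA_character_,
                 character(1))
        }
        if (!is.na(i_gt)) {
          g <- pick(i_gt)
          g[is.na(g) | g == ""] <- "."
          gt[rows, s] <- g
        }
        dp[rows, s] <- suppressWarnings(as.integer(pick(i_dp)))
        gq[rows, s] <- suppressWarnings(as.integer(pick(i_gq)))
      }
    }
    vs$gt <- gt; vs$dp <- dp; vs$gq <- gq
  }
  vs
}

# compact numeric formatting for VCF fields (no scientific notation, no
# trailing zeros beyond what the value needs)
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "." else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
}

.serialize_info <- function(info) {
  vapply(info, function(ii) {
    if (length(ii) == 0L) return(".")
    parts <- vapply(seq_along(ii), function(k) {
      v <- ii[[k]]
      key <- names(ii)[k]
      if (isTRUE(v) && is.logical(v)) return(key)
      if (is.numeric(v)) v <- .fmt_num(v)
      paste0(key, "=", paste(v, collapse = ","))
    }, character(1))
    paste(parts, collapse = ";")
  }, character(1))
}

# guess a VCF type declaration for an R value
.decl_type <- function(v) {
  if (is.logical(v)) c("0", "Flag")
  else if (is.integer(v)) c(".", "Integer")
  else if (is.numeric(v)) c(".", "Float")
  else c(".", "String")
}

# ensure meta declares every INFO key present plus GT/DP/GQ FORMAT fields
.complete_meta <- function(vs) {
  meta <- vs$meta
  declared <- names(.info_types(meta))
  used <- unique(unlist(lapply(vs$info, names)))
  for (key in setdiff(used, declared)) {
    example <- NULL
    for (ii in vs$info) if (!is.null(ii[[key]])) { example <- ii[[key]]; break }
    d <- .decl_type(example)
    meta <- c(meta, sprintf(
      '##INFO=<ID=%s,Number=%s,Type=%s,Description="Added by mendelkit">',
      key, d[1], d[2]))
  }
  if (length(vs$samples) > 0L) {
    fdecl <- sub('^##FORMAT=<ID=([^,>]+).*$', "\\1",
                 grep("^##FORMAT=", meta, value = TRUE))
    need <- c(GT = '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              DP = '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
              GQ = '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
    meta <- c(meta, need[setdiff(names(need), fdecl)])
  }
  unname(meta)
}

#' Write a variant set to a VCF file
#'
#' Emits a VCF 4.2-conformant file such that `parse_vcf(write_vcf(vs))`
#' reproduces `vs` on the data model. INFO and FORMAT keys used by the
#' records are declared in the header if not already present. A `.gz` suffix
#' selects gzip compression.
#'
#' @param vs a [variant_set()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  meta <- .complete_meta(vs)
  header_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(vs$samples) > 0L) header_cols <- c(header_cols, "FORMAT", vs$samples)
  lines <- c(meta, paste(header_cols, collapse = "\t"))
  n <- n_variants(vs)
  if (n > 0L) {
    id <- vs$fix$id
    id[id == ""] <- "."
    body <- paste(vs$fix$chrom, vs$fix$pos, id, vs$fix$ref, vs$fix$alt,
                  .fmt_num(vs$fix$qual), vs$fix$filter,
                  .serialize_info(vs$info), sep = "\t")
    if (length(vs$samples) > 0L) {
      dp <- matrix(as.character(vs$dp), n)
      gq <- matrix(as.character(vs$gq), n)
      dp[is.na(dp)] <- "."
      gq[is.na(gq)] <- "."
      cells <- matrix(paste(vs$gt, dp, gq, sep = ":"), n)
      sample_part <- do.call(paste, c(split(cells, col(cells)), sep = "\t"))
      body <- paste(body, "GT:DP:GQ", sample_part, sep = "\t")
    }
    lines <- c(lines, body)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
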
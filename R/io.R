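#' Read a probe-intensity or expression matrix from a tab-delimited file
#'
#' The file format follows APT-style summary output: an optional run of
#' `#`-prefixed comment lines, a header row holding the sample identifiers
#' (an optional leading id-column token is tolerated), then one row per
#' probe or feature with the identifier in the first column and one numeric
#' cell per sample.  Values must be finite and non-negative; intensities are
#' stored on the linear scale, any log transform is explicit downstream.
#'
#' @param path Path to a tab-delimited text file.
#' @param kind `"intensity"` (probes x samples fluorescence) or
#'   `"expression"` (features x samples RPKM-scale values).
#' @param scale_tag For expression matrices, the scale of the values:
#'   `"rpkm"`, `"normalized_rpkm"` or `"arbitrary"`.
#' @return A numeric matrix with row and column names in file order.
#'   Expression matrices carry a `scale_tag` attribute.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, kind = c("intensity", "expression"),
                        scale_tag = "rpkm") {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("matrix file '%s' has no data rows", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  body <- cells[-1L]
  nfield <- length(body[[1L]])
  if (nfield < 2L) stopf("matrix file '%s' has no sample columns", path)
  if (length(header) == nfield) {
    sample_ids <- header[-1L]           # leading id-column token present
  } else if (length(header) == nfield - 1L) {
    sample_ids <- header
  } else {
    stopf("header has %d fields but data rows have %d", length(header), nfield)
  }
  bad <- which(lengths(body) != nfield)
  if (length(bad)) stopf("row %d has %d fields, expected %d",
                         bad[1L] + 1L, length(body[[bad[1L]]]), nfield)
  row_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(row_ids))
    stopf("duplicated row id '%s'", row_ids[duplicated(row_ids)][1L])
  if (anyDuplicated(sample_ids))
    stopf("duplicated sample id '%s'", sample_ids[duplicated(sample_ids)][1L])
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    i <- which(is.na(vals))[1L]
    r <- (i - 1L) %/% (nfield - 1L) + 1L
    c <- (i - 1L) %% (nfield - 1L) + 1L
    stopf("non-numeric value '%s' at data row %d, sample column %d",
          raw[i], r, c)
  }
  if (any(!is.finite(vals))) stopf("non-finite value in '%s'", path)
  if (any(vals < 0)) {
    i <- which(vals < 0)[1L]
    stopf("negative value %g at data row %d", vals[i],
          (i - 1L) %/% (nfield - 1L) + 1L)
  }
  m <- matrix(vals, nrow = length(body), ncol = nfield - 1L, byrow = TRUE,
              dimnames = list(row_ids, sample_ids))
  if (kind == "expression") {
    scale_tag <- match.arg(scale_tag, c("rpkm", "normalized_rpkm", "arbitrary"))
    attr(m, "scale_tag") <- scale_tag
  }
  m
}

#' Write a matrix in the tab-delimited dialect read by [read_matrix()]
#'
#' Values are written with 15 significant digits so a read/write round trip
#' preserves them to better than 1e-12.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (is.null(dim(m)) || ncol(m) == 0L || nrow(m) == 0L)
    stopf("refusing to write an empty matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("matrix must have row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(x)
    paste(formatC(x, digits = 15, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED4 or BED6; coordinates are kept 0-based half-open.  When the strand
#' column is absent the strand is `"."`.  Empty intervals (start >= end)
#' are an error.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, one row per record in file order.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  ids <- gr$name
  if (is.null(ids) || anyNA(ids))
    stopf("BED file '%s' must have a name (4th) column", path)
  start0 <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  if (any(end <= start0)) {
    i <- which(end <= start0)[1L]
    stopf("empty interval for '%s' (start %d >= end %d)", ids[i],
          start0[i], end[i])
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(id = ids, chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a two-column mapping table (e.g. probe to probe set)
#'
#' @param path Tab-delimited file with a header and two id columns.
#' @return A two-column character `data.frame` in file order.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2L) stopf("mapping table '%s' needs two columns", path)
  df[, 1:2]
}

#' Read a cross-platform probe translation table
#'
#' Expected columns: `source_probe`, `target_probe`, `identity` (fraction of
#' identical bases, in \[0, 1\]), `best_match` (logical).  Source probe ids
#' must be unique.
#'
#' @param path Tab-delimited file with header.
#' @return A `data.frame` with the four columns above.
#' @export
read_translation_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("source_probe", "target_probe", "identity", "best_match")
  if (!all(need %in% names(df)))
    stopf("translation table must have columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  df$identity <- as.numeric(df$identity)
  if (anyNA(df$identity) || any(df$identity < 0 | df$identity > 1))
    stopf("identity values must lie in [0, 1]")
  df$best_match <- as.logical(df$best_match)
  if (anyNA(df$best_match)) stopf("best_match column must be logical")
  if (anyDuplicated(df$source_probe))
    stopf("duplicated source probe '%s'",
          df$source_probe[duplicated(df$source_probe)][1L])
  df
}

#' Read or write a feature-to-probe map as a two-column TSV
#'
#' The on-disk form is one `(feature_id, probe_id)` row per probe, in list
#' order, so round trips preserve probe order within features.
#'
#' @param path File path.
#' @return For `read_probe_map`, a named list of character vectors (one
#'   ordered probe list per feature).
#' @export
read_probe_map <- function(path) {
  df <- read_pairs(path)
  compose_probe_map_from_pairs(df[[1L]], df[[2L]])
}

#' @param map Named list of probe id vectors.
#' @rdname read_probe_map
#' @export
write_probe_map <- function(map, path) {
  df <- data.frame(feature_id = rep(names(map), lengths(map)),
                   probe_id = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared validator for FeatureProbeMap invariants
check_probe_map <- function(map) {
  if (!length(map)) return(map)
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stopf("probe map must be a named list")
  if (any(lengths(map) == 0L)) stopf("probe map lists must be non-empty")
  dup <- vapply(map, anyDuplicated, 0L) > 0L
  if (any(dup)) stopf("duplicate probes within feature '%s'",
                      names(map)[dup][1L])
  map
}

compose_probe_map_from_pairs <- function(features, probes) {
  keep <- !duplicated(paste0(features, "\r", probes))
  split_ord <- split(probes[keep], factor(features[keep],
                                          levels = unique(features[keep])))
  check_probe_map(lapply(split_ord, as.character))
}
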
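# Coordinate-based probe-set-to-feature assignment and cross-platform probe
# translation.  Interval work is delegated to GenomicRanges; the functions
# here only define the mapping contracts (>= 1 bp overlap, strand-blind;
# full containment for the exonic filter).

as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", nrow(df))
  strand[strand == "."] <- "*"
  if (any(df$end <= df$start)) stopf("invalid interval (end <= start)")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

#' Assign probe sets to features by genomic overlap
#'
#' A `(probeset, feature)` pair is emitted iff the two intervals share at
#' least one base on the same chromosome; strand is ignored.  A probe set
#' overlapping k features yields k pairs.  This mirrors a default
#' `bedtools intersect` of the two BED files.
#'
#' @param features,probesets Interval tables as returned by [read_bed()]
#'   (columns `id`, `chrom`, `start`, `end`, 0-based half-open).
#' @return A `data.frame` with columns `probeset_id`, `feature_id`, sorted
#'   by probeset id then feature id.  May have zero rows.
#' @export
intersect_intervals <- function(features, probesets) {
  if (!nrow(features) || !nrow(probesets))
    stopf("both interval lists must be non-empty")
  hits <- GenomicRanges::findOverlaps(as_granges(probesets),
                                      as_granges(features),
                                      minoverlap = 1L, ignore.strand = TRUE)
  out <- data.frame(
    probeset_id = probesets$id[S4Vectors::queryHits(hits)],
    feature_id = features$id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  out[order(out$probeset_id, out$feature_id), , drop = FALSE]
}

#' Compose a feature-to-probe map from two relations
#'
#' Joins the probe-to-probe-set relation (implied by the intensity file)
#' with the probe-set-to-feature relation (from coordinate overlap).  Each
#' feature's probe list is the union over its probe sets, deduplicated, in
#' first-appearance order so downstream predictor matrices have a
#' reproducible column order.  Features ending up with no probes are
#' omitted and reported in the `"dropped_features"` attribute.
#'
#' @param probe_to_probeset `data.frame` with columns `(probe_id, probeset_id)`.
#' @param probeset_to_feature `data.frame` with columns `(probeset_id, feature_id)`.
#' @param drop_multi_feature Drop probe sets overlapping more than one
#'   feature before composing (off by default: a shared probe set is
#'   assigned to all its features).
#' @return Named list: feature id -> ordered character vector of probe ids.
#' @export
compose_probe_map <- function(probe_to_probeset, probeset_to_feature,
                              drop_multi_feature = FALSE) {
  if (!nrow(probe_to_probeset) || !nrow(probeset_to_feature))
    stopf("both relations must be non-empty")
  p2ps <- data.frame(probe = as.character(probe_to_probeset[[1L]]),
                     ps = as.character(probe_to_probeset[[2L]]),
                     stringsAsFactors = FALSE)
  ps2f <- data.frame(ps = as.character(probeset_to_feature[[1L]]),
                     feat = as.character(probeset_to_feature[[2L]]),
                     stringsAsFactors = FALSE)
  if (drop_multi_feature) {
    n_feat <- tapply(ps2f$feat, ps2f$ps, function(x) length(unique(x)))
    ps2f <- ps2f[ps2f$ps %in% names(n_feat)[n_feat == 1L], , drop = FALSE]
  }
  probes_of_ps <- split(p2ps$probe, factor(p2ps$ps, levels = unique(p2ps$ps)))
  feats <- unique(ps2f$feat)
  map <- vector("list", length(feats))
  names(map) <- feats
  for (f in feats) {
    ps_list <- ps2f$ps[ps2f$feat == f]      # first-appearance order
    probes <- unlist(probes_of_ps[unique(ps_list)], use.names = FALSE)
    map[[f]] <- unique(probes)
  }
  dropped <- names(map)[lengths(map) == 0L]
  map <- map[lengths(map) > 0L]
  map <- check_probe_map(map)
  attr(map, "dropped_features") <- dropped
  map
}

#' Translate a probe map across array platforms
#'
#' A probe is converted to its target-platform id only if its alignment
#' identity reaches `min_identity` and, when `require_best_match` is set,
#' it belongs to a best-match probe set pairing.  With the defaults
#' (`min_identity = 1`, best match required) only probes sharing 100%
#' sequence identity between the arrays survive.  Untranslatable probes are
#' dropped; features whose probe lists become empty are removed and listed
#' in the `"dropped_features"` attribute.
#'
#' @param map Feature-to-probe map (named list).
#' @param table Translation table as from [read_translation_table()].
#' @param min_identity Minimum identity fraction in \[0, 1\].
#' @param require_best_match Require the best-match flag.
#' @return Translated map with the same structure.
#' @export
translate_probes <- function(map, table, min_identity = 1,
                             require_best_match = TRUE) {
  if (min_identity < 0 || min_identity > 1)
    stopf("min_identity must lie in [0, 1]")
  ok <- table$identity >= min_identity &
    (table$best_match | !require_best_match)
  lut <- table$target_probe[ok]
  names(lut) <- table$source_probe[ok]
  out <- lapply(map, function(p) unique(unname(lut[p[p %in% names(lut)]])))
  dropped <- names(out)[lengths(out) == 0L]
  out <- out[lengths(out) > 0L]
  out <- check_probe_map(out)
  attr(out, "dropped_features") <- dropped
  out
}

#' Filter probe sets to uniquely-mapping, fully exonic ones
#'
#' A probe set is kept iff it maps to the genome only once and its interval
#' is fully contained within a single exon (probe sets spanning splice
#' junctions are dropped).  Probe-set intervals stand in for their probes'
#' alignments, which are upstream of this package.
#'
#' @param probesets `data.frame` with columns `id`, `chrom`, `start`, `end`
#'   and logical `maps_uniquely`.
#' @param exons Interval `data.frame` (`chrom`, `start`, `end`).
#' @return Character vector of retained probe-set ids, in input order.
#' @export
exonic_probesets <- function(probesets, exons) {
  uniq <- probesets$maps_uniquely
  if (is.null(uniq)) stopf("probesets need a 'maps_uniquely' column")
  if (!nrow(exons)) return(character(0))
  exons$id <- exons$id %||% seq_len(nrow(exons))
  hits <- GenomicRanges::findOverlaps(as_granges(probesets), as_granges(exons),
                                      type = "within", ignore.strand = TRUE)
  contained <- seq_len(nrow(probesets)) %in% S4Vectors::queryHits(hits)
  probesets$id[uniq & contained]
}
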
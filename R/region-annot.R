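# Overlap of candidate intervals with gene/QTL annotations and the
# fold-enrichment arithmetic for GO terms and QTL density.

#' Overlap candidate intervals with annotation records
#'
#' Closed-interval overlap on 1-based coordinates: a record counts as
#' overlapping when it shares at least one bp with the interval, including
#' exact end-point touches. Total counts deduplicate records (by id) shared
#' between overlapping intervals, so merged or adjacent candidate regions do
#' not double-count genes.
#'
#' @param intervals Data.frame (or `ilus_set`) with chrom, start, end.
#' @param annot Data.frame of annotation records (chrom, start, end, id,
#'   kind), as from [read_annotation_table()].
#' @return List with `per_interval` (the intervals plus an `n_overlap`
#'   column and a list-column `hits` of record ids) and `total` (named
#'   vector of deduplicated record counts per kind, plus `all`).
#' @export
overlap_annotations <- function(intervals, annot) {
  intervals <- as.data.frame(intervals)
  annot <- as.data.frame(annot)
  if (!nrow(intervals)) {
    return(list(per_interval = cbind(intervals, n_overlap = integer(0)),
                total = c(all = 0L)))
  }
  iv <- data.table::as.data.table(intervals[, c("chrom", "start", "end")])
  an <- data.table::as.data.table(annot[, c("chrom", "start", "end")])
  an$rec <- seq_len(nrow(annot))
  iv$ivl <- seq_len(nrow(intervals))
  data.table::setkey(an, chrom, start, end)
  ov <- data.table::foverlaps(iv, an, type = "any", nomatch = NULL)
  hits <- split(ov$rec, factor(ov$ivl, levels = seq_len(nrow(intervals))))
  per_interval <- intervals
  per_interval$n_overlap <- vapply(hits, length, integer(1))
  per_interval$hits <- I(lapply(hits, function(r) annot$id[r]))
  hit_records <- annot[unique(ov$rec), , drop = FALSE]
  hit_records <- hit_records[!duplicated(hit_records$id), , drop = FALSE]
  total <- c(table(hit_records$kind), all = nrow(hit_records))
  list(per_interval = per_interval, total = total)
}

#' Fold enrichment of a term among an input gene list
#'
#' Expected count under the hypergeometric model:
#' `exp = input_total * term_ref / ref_total`; fold = obs / exp. A
#' hypergeometric upper-tail p-value is attached for convenience.
#'
#' @param obs Observed number of input genes carrying the term.
#' @param term_ref Reference genes carrying the term.
#' @param input_total Size of the input gene list.
#' @param ref_total Size of the reference gene list.
#' @return List of class `enrichment_result`: obs, exp, fold, p_hyper, plus
#'   the input counts.
#' @export
fold_enrichment <- function(obs, term_ref, input_total, ref_total) {
  stopifnot(obs >= 0, term_ref > 0, input_total > 0, ref_total > 0,
            obs <= input_total, term_ref <= ref_total)
  expected <- input_total * term_ref / ref_total
  if (expected == 0) stop("expected count is zero")
  p <- phyper(obs - 1, term_ref, ref_total - term_ref, input_total,
              lower.tail = FALSE)
  structure(list(obs = obs, exp = expected, fold = obs / expected,
                 p_hyper = p, term_ref = term_ref,
                 input_total = input_total, ref_total = ref_total),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("obs %d  exp %.2f  fold %.2f  (term %d/%d ref, input %d; p_hyper %.3g)\n",
              x$obs, x$exp, x$fold, x$term_ref, x$ref_total, x$input_total,
              x$p_hyper))
  invisible(x)
}

#' Feature-density fold enrichment over a genomic segment
#'
#' Compares the observed feature density on a (pseudo-)chromosomic segment
#' with a genome-wide expected density given as Mb per feature:
#' `fold = (n_features / segment_len_mb) * expected_density_mb_per_feature`.
#'
#' @param n_features Feature count on the segment.
#' @param segment_len_mb Segment length in Mb.
#' @param expected_density_mb_per_feature Genome-wide expectation, in Mb per
#'   feature.
#' @return List: density_mb_per_feature (the segment's Mb per feature),
#'   fold.
#' @export
density_fold <- function(n_features, segment_len_mb,
                         expected_density_mb_per_feature) {
  stopifnot(n_features > 0, expected_density_mb_per_feature > 0)
  if (segment_len_mb <= 0) stop("segment length must be positive")
  list(density_mb_per_feature = segment_len_mb / n_features,
       fold = n_features / segment_len_mb * expected_density_mb_per_feature)
}
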
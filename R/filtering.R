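#' Filtering parameters for the hit cascade
#'
#' Defaults are the pipeline's calibrated operating point: hits must reach
#' 95% identity over at least 50% of the query length with an e-value of at
#' most 1e-40; a taxon is discarded as promiscuous when fewer than 10% of
#' the read pairs hitting it hit it exclusively; paired-end mates must land
#' on the same reference sequence at most 1 Mbp apart (the allowance covers
#' transcript reads spanning intron junctions).
#'
#' @param min_identity Minimum percent identity (inclusive).
#' @param min_query_coverage Minimum `alignment_length / query_length`
#'   fraction (inclusive).
#' @param max_evalue Maximum e-value (inclusive).
#' @param promiscuity_min_unique_fraction Minimum fraction of read pairs
#'   hitting a taxon that must hit only that taxon.
#' @param max_pair_distance Maximum gap between mate alignment intervals
#'   on the same subject, in bp (inclusive; overlapping intervals count
#'   as distance 0).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_identity = 95,
                          min_query_coverage = 0.50,
                          max_evalue = 1e-40,
                          promiscuity_min_unique_fraction = 0.10,
                          max_pair_distance = 1000000L) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_query_coverage >= 0, min_query_coverage <= 1,
            max_evalue >= 0,
            promiscuity_min_unique_fraction >= 0,
            promiscuity_min_unique_fraction <= 1,
            max_pair_distance >= 0)
  structure(list(min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 max_evalue = max_evalue,
                 promiscuity_min_unique_fraction = promiscuity_min_unique_fraction,
                 max_pair_distance = as.numeric(max_pair_distance)),
            class = "filter_params")
}

#' Identity / coverage / e-value threshold filter
#'
#' Retains hits with `pident >= min_identity`, query coverage
#' `length/qlen >= min_query_coverage` and `evalue <= max_evalue` — all
#' thresholds inclusive. Hits with a query length of 0 are rejected and
#' counted in the `n_zero_qlen` attribute.
#'
#' @param hits Labelled hit table.
#' @param params A [filter_params()] object.
#' @return The surviving subset of `hits`.
#' @export
threshold_filter <- function(hits, params = filter_params()) {
  dt <- data.table::as.data.table(hits)
  zero <- dt$qlen <= 0
  keep <- !zero &
    dt$pident >= params$min_identity &
    dt$length / dt$qlen >= params$min_query_coverage &
    dt$evalue <= params$max_evalue
  out <- dt[keep]
  data.table::setattr(out, "n_zero_qlen", sum(zero))
  out[]
}

#' Keep only each mate's best-bitscore hits
#'
#' For every (read pair, mate) group, retains all hits whose bitscore
#' equals the group maximum. Ties are kept deliberately: several equally
#' good taxa for one read are exactly what triggers a lowest-common-
#' ancestor assignment downstream.
#'
#' @param hits Labelled hit table.
#' @return The surviving subset of `hits`.
#' @export
retain_best_bitscore <- function(hits) {
  dt <- data.table::as.data.table(hits)
  if (nrow(dt) == 0L) return(dt)
  bitscore <- NULL # R CMD check NSE note
  dt[dt[, .I[bitscore == max(bitscore)], by = c("read_id", "mate")]$V1][]
}

#' Remove promiscuous taxa
#'
#' A taxon whose hits are almost never exclusive is most likely collecting
#' conserved-sequence alignments from reads of a related true source, so it
#' is removed outright. Uniqueness is counted at read-pair level: a pair
#' hits taxon S uniquely when S is the only taxon among the pair's retained
#' hits, and `unique_fraction(S)` = pairs hitting only S / pairs hitting S.
#' All taxa with `unique_fraction < promiscuity_min_unique_fraction`
#' (strict) are identified on the incoming table and removed
#' simultaneously, making the outcome independent of any removal order.
#'
#' @param hits Best-bitscore-retained hit table.
#' @param params A [filter_params()] object.
#' @param per_alignment Count uniqueness per alignment instead of per read
#'   pair (sensitivity analysis switch).
#' @return The surviving hit table, with attribute `removed_taxa`: a
#'   data.frame of each removed taxon and its unique fraction.
#' @export
promiscuity_filter <- function(hits, params = filter_params(),
                               per_alignment = FALSE) {
  dt <- data.table::as.data.table(hits)
  if (nrow(dt) == 0L) {
    data.table::setattr(dt, "removed_taxa",
                        data.frame(taxid = integer(0),
                                   unique_fraction = numeric(0)))
    return(dt[])
  }
  unit <- if (per_alignment) paste(dt$read_id, dt$mate, dt$sstart, dt$send,
                                   dt$sseqid, sep = "\r")
          else dt$read_id
  pt <- unique(data.table::data.table(unit = unit, taxid = dt$staxid))
  ntax <- NULL; taxid <- NULL
  pt[, "ntax" := .N, by = "unit"]
  stats <- pt[, list(n_pairs = .N, n_unique = sum(ntax == 1L)), by = "taxid"]
  stats[, "unique_fraction" := stats$n_unique / stats$n_pairs]
  removed <- stats[stats$unique_fraction <
                     params$promiscuity_min_unique_fraction]
  out <- dt[!dt$staxid %in% removed$taxid]
  data.table::setattr(out, "removed_taxa",
                      data.frame(taxid = removed$taxid,
                                 unique_fraction = removed$unique_fraction))
  out[]
}

# Gap between two subject intervals after normalising to (min,max): the
# number of bases strictly between them (the spanned intron length); 0 when
# they overlap or touch.
interval_gap <- function(s1, e1, s2, e2) {
  lo1 <- pmin(s1, e1); hi1 <- pmax(s1, e1)
  lo2 <- pmin(s2, e2); hi2 <- pmax(s2, e2)
  pmax(0, pmax(lo1, lo2) - pmin(hi1, hi2) - 1)
}

#' Keep only concordantly paired hits
#'
#' A hit is concordant when the opposite mate of the same read pair has a
#' hit on the same reference sequence with alignment intervals at most
#' `max_pair_distance` bp apart (overlap counts as 0; otherwise the gap
#' between nearest interval ends, which is strand-robust). Hits taking part
#' in at least one concordant combination are kept; read pairs with hits on
#' only one mate are dropped entirely unless `keep_singletons` is set.
#'
#' The output equals the naive check of all mate1-by-mate2 combinations
#' within each read pair; work and memory are bounded by the largest
#' per-pair hit group.
#'
#' @param hits Hit table with mate labels.
#' @param params A [filter_params()] object.
#' @param keep_singletons Keep hits of read pairs that have hits on one
#'   mate only.
#' @return The surviving subset of `hits`.
#' @export
concordance_filter <- function(hits, params = filter_params(),
                               keep_singletons = FALSE) {
  dt <- data.table::as.data.table(hits)
  if (nrow(dt) == 0L) return(dt)
  # equivalent to checking all mate1 x mate2 combinations per read pair:
  # combinations on different subjects can never be concordant, so joining
  # on (read_id, subject) enumerates exactly the candidate combinations
  row_id <- seq_len(nrow(dt))
  m1 <- data.table::data.table(read_id = dt$read_id, sseqid = dt$sseqid,
                               s = dt$sstart, e = dt$send,
                               i = row_id)[dt$mate == 1L]
  m2 <- data.table::data.table(read_id = dt$read_id, sseqid = dt$sseqid,
                               s = dt$sstart, e = dt$send,
                               i = row_id)[dt$mate == 2L]
  cand <- merge(m1, m2, by = c("read_id", "sseqid"),
                allow.cartesian = TRUE, suffixes = c("_1", "_2"))
  conc <- interval_gap(cand$s_1, cand$e_1, cand$s_2, cand$e_2) <=
    params$max_pair_distance
  keep <- logical(nrow(dt))
  keep[c(cand$i_1[conc], cand$i_2[conc])] <- TRUE
  if (keep_singletons) {
    has1 <- unique(dt$read_id[dt$mate == 1L])
    has2 <- unique(dt$read_id[dt$mate == 2L])
    single <- setdiff(union(has1, has2), intersect(has1, has2))
    keep[dt$read_id %in% single] <- TRUE
  }
  dt[keep][]
}

#' Run the full hit-filtering cascade
#'
#' Applies, in this fixed order: exact-duplicate removal, the
#' identity/coverage/e-value [threshold_filter()], per-mate
#' [retain_best_bitscore()], the [promiscuity_filter()], and the
#' [concordance_filter()].
#'
#' @param hits Labelled hit table.
#' @param params A [filter_params()] object.
#' @param keep_singletons Passed to [concordance_filter()].
#' @param per_alignment Passed to [promiscuity_filter()].
#' @return A list with `hits` (the surviving table), `stage_counts` (hit
#'   counts after every stage), and `removed_taxa` from the promiscuity
#'   stage.
#' @export
filter_hits <- function(hits, params = filter_params(),
                        keep_singletons = FALSE, per_alignment = FALSE) {
  dt <- data.table::as.data.table(hits)
  counts <- c(input = nrow(dt))
  dt <- unique(dt)
  counts["deduplicated"] <- nrow(dt)
  dt <- threshold_filter(dt, params)
  counts["threshold"] <- nrow(dt)
  dt <- retain_best_bitscore(dt)
  counts["best_bitscore"] <- nrow(dt)
  dt <- promiscuity_filter(dt, params, per_alignment = per_alignment)
  removed <- attr(dt, "removed_taxa")
  counts["promiscuity"] <- nrow(dt)
  dt <- concordance_filter(dt, params, keep_singletons = keep_singletons)
  counts["concordance"] <- nrow(dt)
  list(hits = dt, stage_counts = as.list(counts), removed_taxa = removed)
}
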
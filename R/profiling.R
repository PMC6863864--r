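#' Assign each surviving read pair to its lowest common ancestor
#'
#' After filtering, a read pair may still hit several taxa (tied bitscores
#' on conserved sequence). Each pair is counted — exactly once — at the
#' lowest common ancestor of all taxa among its surviving hits: the species
#' itself when the hits agree, an internal node (e.g. the genus) when they
#' do not.
#'
#' @param hits Fully filtered, labelled hit table.
#' @param tree A `taxonomy_tree`.
#' @return A list with `assignments` (data.frame `read_id`, `node`) and
#'   `counts` (named numeric vector of read-pair counts per node taxid).
#' @export
assign_lca <- function(hits, tree) {
  dt <- data.table::as.data.table(hits)
  if (nrow(dt) == 0L)
    return(list(assignments = data.frame(read_id = character(0),
                                         node = integer(0)),
                counts = stats::setNames(numeric(0), character(0))))
  taxa_by_pair <- lapply(split(dt$staxid, dt$read_id), unique)
  # one LCA query per distinct taxa set, not per read pair
  set_key <- vapply(taxa_by_pair,
                    function(tx) paste(sort(tx), collapse = ","), "")
  uniq <- !duplicated(set_key)
  node_by_set <- vapply(taxa_by_pair[uniq],
                        function(tx) lca(tree, tx), integer(1))
  names(node_by_set) <- set_key[uniq]
  node <- node_by_set[set_key]
  counts_tab <- table(node)
  list(assignments = data.frame(read_id = names(taxa_by_pair),
                                node = unname(node),
                                stringsAsFactors = FALSE),
       counts = stats::setNames(as.numeric(counts_tab), names(counts_tab)))
}

new_species_profile <- function(species, species_assigned_total,
                                unresolvable, unassigned_pairs,
                                min_report = 0.1) {
  structure(list(species = species,
                 species_assigned_total = species_assigned_total,
                 unresolvable = unresolvable,
                 unassigned_pairs = as.integer(unassigned_pairs),
                 min_report = min_report,
                 zero_total = species_assigned_total <= 0),
            class = "species_profile")
}

#' Species-level relative proportions from node counts
#'
#' Projects read-pair counts at internal taxonomy nodes down to species
#' leaves with [project_to_species()], then computes each species' percent
#' of the species-assigned total. Proportions are over species-assigned
#' pairs only; mass that cannot reach a species is reported in the
#' `unresolvable` bucket, never silently discarded.
#'
#' @param counts Named numeric vector of per-node read-pair counts, as
#'   produced by [assign_lca()].
#' @param tree A `taxonomy_tree`.
#' @param min_report Display threshold (percent) used by the print method,
#'   the customary >0.1% reporting convention. All species
#'   are retained in the object and in written TSVs.
#' @param unassigned_pairs Count of input read pairs that never produced a
#'   surviving hit, carried through for full accounting.
#' @return A `species_profile`: per-species `taxid`, `name`,
#'   `common_name`, real-valued `count` and `percent`, plus
#'   `species_assigned_total`, `unresolvable` and `unassigned_pairs`.
#'   A zero species-assigned total yields an empty profile flagged
#'   `zero_total`, not a division by zero.
#' @export
quantify <- function(counts, tree, min_report = 0.1, unassigned_pairs = 0L) {
  proj <- project_to_species(tree, counts)
  sp_counts <- proj$species[proj$species > 0]
  total <- sum(sp_counts)
  if (total <= 0) {
    sp <- data.frame(taxid = integer(0), name = character(0),
                     common_name = character(0), count = numeric(0),
                     percent = numeric(0), stringsAsFactors = FALSE)
    return(new_species_profile(sp, 0, proj$unresolvable, unassigned_pairs,
                               min_report))
  }
  taxid <- as.integer(names(sp_counts))
  sp <- data.frame(
    taxid = taxid,
    name = tree$name[match(taxid, tree$taxid)],
    common_name = NA_character_,
    count = as.numeric(sp_counts),
    percent = 100 * as.numeric(sp_counts) / total,
    stringsAsFactors = FALSE)
  sp <- sp[order(-sp$percent, sp$taxid), , drop = FALSE]
  rownames(sp) <- NULL
  new_species_profile(sp, total, proj$unresolvable, unassigned_pairs,
                      min_report)
}

#' @export
print.species_profile <- function(x, ...) {
  cat("Species profile:", nrow(x$species), "species,",
      format(x$species_assigned_total), "species-assigned read pairs\n")
  if (x$zero_total) {
    cat("  (no species-assigned reads)\n")
    return(invisible(x))
  }
  shown <- x$species[x$species$percent > x$min_report, , drop = FALSE]
  if (nrow(shown) > 0L)
    print(data.frame(taxid = shown$taxid, name = shown$name,
                     count = round(shown$count, 2),
                     percent = sprintf("%.2f%%", shown$percent)),
          row.names = FALSE)
  hidden <- nrow(x$species) - nrow(shown)
  if (hidden > 0L)
    cat("  ...", hidden, "species at <=", x$min_report, "% not shown\n")
  if (x$unresolvable > 0)
    cat("  unresolvable (no species descendant):",
        format(x$unresolvable), "\n")
  if (x$unassigned_pairs > 0)
    cat("  unassigned read pairs:", x$unassigned_pairs, "\n")
  invisible(x)
}

#' @export
summary.species_profile <- function(object, ...) {
  cat("species assigned:", format(object$species_assigned_total),
      "| unresolvable:", format(object$unresolvable),
      "| unassigned pairs:", object$unassigned_pairs, "\n")
  invisible(object$species)
}

#' Full profiling pipeline: labelled hits to species proportions
#'
#' Convenience wrapper chaining [attach_taxids()] (when a mapping is
#' given), [filter_hits()], [assign_lca()] and [quantify()], and
#' assembling the per-stage run report.
#'
#' @param hits Hit table from [read_hits()].
#' @param tree A `taxonomy_tree`.
#' @param mapping Optional accession-to-taxid mapping for [attach_taxids()].
#' @param params A [filter_params()] object.
#' @param min_report Display threshold passed to [quantify()].
#' @param total_pairs Optional total number of read pairs queried, used to
#'   report how many pairs never survived to assignment; defaults to the
#'   pairs seen in `hits`.
#' @param ... Passed to [filter_hits()].
#' @return A list with `profile` (a `species_profile`), `counts` (node
#'   counts from the LCA step) and `report` (stage counts, drop counters,
#'   removed taxa).
#' @export
profile_species <- function(hits, tree, mapping = NULL,
                            params = filter_params(), min_report = 0.1,
                            total_pairs = NULL, ...) {
  labelled <- attach_taxids(hits, mapping, tree)
  if (is.null(total_pairs))
    total_pairs <- length(unique(data.table::as.data.table(hits)$read_id))
  filt <- filter_hits(labelled, params, ...)
  asg <- assign_lca(filt$hits, tree)
  n_assigned <- length(asg$assignments$read_id)
  prof <- quantify(asg$counts, tree, min_report = min_report,
                   unassigned_pairs = max(0L, total_pairs - n_assigned))
  report <- list(
    total_pairs = total_pairs,
    n_unmapped_hits = attr(labelled, "n_unmapped"),
    n_unresolved_hits = attr(labelled, "n_unresolved"),
    stage_counts = filt$stage_counts,
    removed_taxa = filt$removed_taxa,
    assigned_pairs = n_assigned,
    species_assigned_total = prof$species_assigned_total,
    unresolvable = prof$unresolvable)
  list(profile = prof, counts = asg$counts, report = report)
}
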
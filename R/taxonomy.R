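#' Load a taxonomy from an NCBI-style dump or a simplified TSV
#'
#' Builds a rooted taxonomy tree from either a `nodes.dmp`-dialect file
#' (pipe-and-tab delimited, as distributed with the NCBI taxonomy) or a
#' simplified 4-column TSV (`taxid`, `parent`, `rank`, `name`). The two
#' formats are accepted interchangeably and produce identical trees. Display
#' names can come from the 4th TSV column or from a separate `names.dmp`
#' file (the "scientific name" class is used).
#'
#' @param nodes_source Path to a `nodes.dmp`-dialect file or a simplified
#'   TSV. Format is auto-detected from the field delimiters.
#' @param names_source Optional path to a `names.dmp`-dialect file.
#' @param merge_map Optional two-column data.frame (or path to a
#'   `merged.dmp`-dialect file) remapping old taxids to current ones before
#'   the tree is built.
#' @return An object of class `taxonomy_tree`: a list with integer vector
#'   `taxid`, and parallel vectors `parent`, `rank`, `name`, `depth`, plus
#'   the root taxid. The root is its own parent.
#' @details Malformed lines are counted and reported via the
#'   `n_malformed` attribute and a warning. A missing root, a node whose
#'   parent is absent, a cyclic parent chain, or a duplicated taxid is a
#'   structured error naming the offending taxid.
#' @seealso [lca()], [species_ancestor()], [project_to_species()]
#' @export
read_taxonomy <- function(nodes_source, names_source = NULL, merge_map = NULL) {
  lines <- readLines(nodes_source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("taxonomy source '", nodes_source, "' contains no records")

  dmp <- grepl("\t\\|", lines[1], fixed = FALSE)
  if (dmp) {
    fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
  }
  nf <- lengths(fields)
  ok <- nf >= 3L
  n_malformed <- sum(!ok)
  if (n_malformed > 0L)
    warning(n_malformed, " malformed taxonomy line(s) skipped")
  fields <- fields[ok]

  taxid  <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
  parent <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  rank   <- trimws(vapply(fields, `[`, "", 3L))
  name   <- if (!dmp & any(nf[ok] >= 4L)) {
    nm <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, "")
    trimws(nm)
  } else rep(NA_character_, length(taxid))

  bad <- is.na(taxid) | is.na(parent) | taxid <= 0L
  if (any(bad)) {
    n_malformed <- n_malformed + sum(bad)
    warning(sum(bad), " taxonomy line(s) with unparseable taxid/parent skipped")
    taxid <- taxid[!bad]; parent <- parent[!bad]
    rank <- rank[!bad]; name <- name[!bad]
  }
  if (anyDuplicated(taxid))
    stop("duplicate taxid in taxonomy: ", taxid[duplicated(taxid)][1L])

  if (!is.null(merge_map)) {
    mm <- if (is.character(merge_map)) {
      ml <- readLines(merge_map)
      ml <- ml[nzchar(trimws(ml))]
      mf <- strsplit(sub("\t\\|$", "", ml), "\t\\|\t|\t")
      data.frame(old = as.integer(vapply(mf, `[`, "", 1L)),
                 new = as.integer(vapply(mf, `[`, "", 2L)))
    } else {
      data.frame(old = as.integer(merge_map[[1L]]), new = as.integer(merge_map[[2L]]))
    }
    hit <- match(parent, mm$old)
    parent[!is.na(hit)] <- mm$new[hit[!is.na(hit)]]
    attr_merge <- mm
  } else attr_merge <- NULL

  if (!is.null(names_source)) {
    nl <- readLines(names_source)
    nl <- nl[nzchar(trimws(nl))]
    nfl <- strsplit(sub("\t\\|$", "", nl), "\t\\|\t")
    cls <- vapply(nfl, function(f) if (length(f) >= 4L) trimws(f[4L]) else "", "")
    sci <- nfl[cls == "scientific name"]
    ntax <- as.integer(vapply(sci, `[`, "", 1L))
    nnam <- vapply(sci, `[`, "", 2L)
    hit <- match(taxid, ntax)
    name[!is.na(hit)] <- nnam[hit[!is.na(hit)]]
  }
  name[is.na(name)] <- paste0("taxid:", taxid[is.na(name)])

  idx <- match(parent, taxid)
  orphan <- is.na(idx) & parent != taxid
  # root convention: parent == self
  root_self <- which(parent == taxid)
  if (any(orphan))
    stop("taxonomy node ", taxid[which(orphan)[1L]],
         " has unknown parent ", parent[which(orphan)[1L]])
  if (length(root_self) == 0L)
    stop("taxonomy has no root (no node is its own parent)")
  if (length(root_self) > 1L)
    stop("taxonomy has multiple roots: ",
         paste(taxid[root_self], collapse = ", "))
  root <- taxid[root_self]

  depth <- compute_depths(taxid, idx, root_self)

  tree <- structure(
    list(taxid = taxid, parent = parent, parent_idx = idx,
         rank = rank, name = name, depth = depth, root = root,
         merge_map = attr_merge),
    class = "taxonomy_tree", n_malformed = n_malformed)
  tree
}

# Depth of every node by pointer-jumping; errors on a cycle.
compute_depths <- function(taxid, parent_idx, root_self) {
  n <- length(taxid)
  depth <- rep(NA_integer_, n)
  depth[root_self] <- 0L
  cur <- seq_len(n)
  steps <- 0L
  while (anyNA(depth)) {
    steps <- steps + 1L
    if (steps > n + 1L) {
      stuck <- taxid[which(is.na(depth))[1L]]
      stop("cyclic parent chain in taxonomy involving taxid ", stuck)
    }
    todo <- which(is.na(depth))
    ready <- todo[!is.na(depth[parent_idx[todo]])]
    if (length(ready) == 0L) {
      stop("cyclic parent chain in taxonomy involving taxid ",
           taxid[todo[1L]])
    }
    depth[ready] <- depth[parent_idx[ready]] + 1L
  }
  depth
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("Taxonomy tree:", length(x$taxid), "nodes, root", x$root,
      sprintf("(%s)", x$name[match(x$root, x$taxid)]), "\n")
  cat("  ranks:", paste(names(sort(table(x$rank), decreasing = TRUE)),
                        collapse = ", "), "\n")
  invisible(x)
}

tax_index <- function(tree, taxids, what = "taxid") {
  idx <- match(taxids, tree$taxid)
  if (anyNA(idx))
    stop("unknown ", what, " in taxonomy: ",
         paste(taxids[is.na(idx)], collapse = ", "))
  idx
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxid; the
#' node an ambiguous read pair is counted at.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxids Non-empty vector of taxids, all present in `tree`.
#' @return A single taxid.
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("lca() requires a non-empty set of taxids")
  idx <- tax_index(tree, taxids)
  cur <- idx[1L]
  for (other in idx[-1L]) {
    a <- cur; b <- other
    while (tree$depth[a] > tree$depth[b]) a <- tree$parent_idx[a]
    while (tree$depth[b] > tree$depth[a]) b <- tree$parent_idx[b]
    while (a != b) { a <- tree$parent_idx[a]; b <- tree$parent_idx[b] }
    cur <- a
  }
  tree$taxid[cur]
}

#' Nearest species-rank ancestor of a taxon
#'
#' Climbs from `t` toward the root and returns the first node whose rank is
#' `"species"` (the node itself counts). Counts at subspecies or strain
#' resolution are folded into their species through this lookup.
#'
#' @param tree A `taxonomy_tree`.
#' @param t A taxid present in `tree`.
#' @return The species taxid, or `NA` if no ancestor-or-self has species
#'   rank (e.g. a genus-level node).
#' @export
species_ancestor <- function(tree, t) {
  i <- tax_index(tree, as.integer(t))
  repeat {
    if (tree$rank[i] == "species") return(tree$taxid[i])
    if (tree$parent_idx[i] == i) return(NA_integer_)
    i <- tree$parent_idx[i]
  }
}

#' Project read counts at internal taxonomy nodes onto species leaves
#'
#' Read pairs whose hits span several species are counted at internal
#' (e.g. genus) nodes by [assign_lca()]. Before proportions are computed,
#' that internal mass is redistributed to species: counts at or below
#' species rank move to their [species_ancestor()]; counts at nodes above
#' species are split among the node's descendant species proportionally to
#' the species counts already resolved in the first step, or uniformly when
#' none of those species carries resolved counts; mass at nodes with no
#' species descendant goes to an explicit `unresolvable` bucket. Total mass
#' is conserved exactly (up to floating-point rounding).
#'
#' @param tree A `taxonomy_tree`.
#' @param counts Named numeric vector: names are taxids, values are
#'   non-negative read-pair counts.
#' @return A list with `species` (named numeric vector of real-valued
#'   counts on species-rank taxids) and `unresolvable` (scalar mass that
#'   could not reach any species).
#' @export
project_to_species <- function(tree, counts) {
  if (length(counts) == 0L)
    return(list(species = stats::setNames(numeric(0), character(0)),
                unresolvable = 0))
  ctax <- as.integer(names(counts))
  cval <- as.numeric(counts)
  if (any(cval < 0)) stop("negative counts are not allowed")
  idx <- tax_index(tree, ctax)

  sp_anc <- vapply(ctax, function(t) species_ancestor(tree, t), integer(1))
  resolved <- tapply(cval[!is.na(sp_anc)], sp_anc[!is.na(sp_anc)], sum)
  species <- stats::setNames(as.numeric(resolved), names(resolved))
  unresolvable <- 0

  internal <- which(is.na(sp_anc) & cval > 0)
  if (length(internal) > 0L) {
    desc <- species_descendants(tree)
    base <- species  # weights come from step-1 resolved counts only,
                     # so the allocation is independent of node order
    for (j in internal) {
      kids <- desc[[as.character(ctax[j])]]
      if (is.null(kids) || length(kids) == 0L) {
        unresolvable <- unresolvable + cval[j]
        next
      }
      w <- base[as.character(kids)]
      w[is.na(w)] <- 0
      if (sum(w) == 0) w <- rep(1, length(kids))
      alloc <- cval[j] * w / sum(w)
      cur <- species[as.character(kids)]
      cur[is.na(cur)] <- 0
      species[as.character(kids)] <- cur + alloc
    }
  }
  list(species = species, unresolvable = unresolvable)
}

# Species-rank descendants of every non-species node, as a named list.
species_descendants <- function(tree) {
  n <- length(tree$taxid)
  sp <- which(tree$rank == "species")
  out <- vector("list", n)
  # walk each species up to the root, registering it along the way;
  # stop registering above another species node? No: a species under a
  # species (unusual) still belongs to ancestors' descendant sets.
  for (s in sp) {
    i <- tree$parent_idx[s]
    prev <- s
    while (TRUE) {
      out[[i]] <- c(out[[i]], tree$taxid[s])
      if (i == tree$parent_idx[i]) break
      prev <- i
      i <- tree$parent_idx[i]
    }
  }
  names(out) <- as.character(tree$taxid)
  out
}
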
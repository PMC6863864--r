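HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "qlen", "staxid")

#' Read tabular alignment hits
#'
#' Reads the extended BLAST outfmt-6 dialect used throughout the package:
#' the 12 standard columns (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`) plus `qlen` (column 13,
#' required by the query-coverage rule) and an optional `staxid`
#' (column 14). Subject coordinates follow the BLAST convention: 1-based,
#' inclusive, with `send < sstart` on the minus strand.
#'
#' The mate (1 or 2) is inferred from the query name suffix — `/1`, `/2`,
#' or a trailing `.1`/`.2` — and the suffix is stripped so `read_id`
#' identifies the pair. Datasets using another convention must pass a
#' `mate_from` function.
#'
#' @param source Path to the hit table (TSV, no header), or a data.frame
#'   already holding the columns above.
#' @param mate_from Optional function mapping the raw query-id vector to a
#'   list with `read_id` and `mate` vectors, overriding suffix detection.
#' @return A `data.table` with one row per hit: `read_id`, `mate` (integer
#'   1/2) and the alignment columns. Unparseable lines are dropped, counted
#'   in the `n_malformed` attribute and warned about; the attribute
#'   `n_input_lines` carries the raw line count.
#' @export
read_hits <- function(source, mate_from = NULL) {
  if (is.data.frame(source)) {
    dt <- data.table::as.data.table(source)
    n_lines <- nrow(dt)
  } else {
    n_lines <- length(readLines(source))
    if (n_lines == 0L) {
      dt <- data.table::as.data.table(
        stats::setNames(rep(list(character(0)), 14L), HIT_COLUMNS))
      dt$mate <- integer(0); dt$read_id <- character(0)
      return(finish_hits(dt, 0L, 0L))
    }
    dt <- data.table::fread(source, header = FALSE, sep = "\t",
                            fill = TRUE, colClasses = list(character = 1:2))
    if (ncol(dt) < 13L)
      stop("hit table has ", ncol(dt),
           " columns; need >= 13 (outfmt 6 + qlen)")
    data.table::setnames(dt, seq_len(min(ncol(dt), 14L)),
                         HIT_COLUMNS[seq_len(min(ncol(dt), 14L))])
  }
  if (!"staxid" %in% names(dt)) dt[, "staxid" := NA_integer_]
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore", "qlen")
  for (cc in num_cols)
    data.table::set(dt, j = cc, value = suppressWarnings(as.numeric(dt[[cc]])))
  data.table::set(dt, j = "staxid",
                  value = suppressWarnings(as.integer(dt[["staxid"]])))

  bad <- is.na(dt$pident) | is.na(dt$length) | is.na(dt$bitscore) |
    is.na(dt$evalue) | is.na(dt$qlen) | is.na(dt$sstart) | is.na(dt$send) |
    !nzchar(dt$qseqid)
  n_malformed <- sum(bad)
  if (n_malformed > 0L) {
    warning(n_malformed, " malformed hit line(s) dropped")
    dt <- dt[!bad]
  }

  if (is.null(mate_from)) {
    qs <- dt$qseqid
    slash <- grepl("/[12]$", qs)
    dot <- grepl("\\.[12]$", qs)
    if (nrow(dt) > 0L && !all(slash | dot))
      stop("cannot infer mate from read names (no '/1','/2' or '.1','.2' ",
           "suffix); supply mate_from = function(qseqid) list(read_id=, mate=)")
    mate <- as.integer(substring(qs, nchar(qs)))
    read_id <- substring(qs, 1L, nchar(qs) - 2L)
  } else {
    mm <- mate_from(dt$qseqid)
    read_id <- mm$read_id
    mate <- as.integer(mm$mate)
  }
  dt[, "mate" := mate]
  dt[, "read_id" := read_id]
  finish_hits(dt, n_malformed, n_lines)
}

finish_hits <- function(dt, n_malformed, n_lines) {
  data.table::setcolorder(
    dt, c("read_id", "mate", HIT_COLUMNS))
  data.table::setattr(dt, "n_malformed", n_malformed)
  data.table::setattr(dt, "n_input_lines", n_lines)
  dt[]
}

#' Attach taxon labels to alignment hits
#'
#' Labels each hit with the taxid of its subject accession using a
#' two-column accession-to-taxid table. Accessions are matched both with
#' and without a trailing version suffix (`.1`). A hit whose own `staxid`
#' column is already populated keeps it; if a mapping entry disagrees with
#' the column, the column wins and a warning reports the count. Hits whose
#' accession cannot be mapped (and that carry no `staxid`) are dropped and
#' counted.
#'
#' @param hits Hit table from [read_hits()].
#' @param mapping Path to a 2-column TSV (`accession`, `taxid`) or a
#'   data.frame of the same shape. `NULL` keeps only already-labelled hits.
#' @param tree Optional `taxonomy_tree`; labelled hits whose taxid does not
#'   resolve in the tree are also dropped and counted separately.
#' @return The labelled hit table, with attributes `n_unmapped` (dropped
#'   for missing mapping) and `n_unresolved` (dropped for taxid absent from
#'   the tree).
#' @export
attach_taxids <- function(hits, mapping = NULL, tree = NULL) {
  dt <- data.table::copy(data.table::as.data.table(hits))
  if (!is.null(mapping)) {
    map <- if (is.data.frame(mapping)) data.table::as.data.table(mapping)
           else data.table::fread(mapping, header = FALSE, sep = "\t",
                                  colClasses = list(character = 1L))
    data.table::setnames(map, 1:2, c("accession", "taxid"))
    map[, "taxid" := as.integer(map[["taxid"]])]
    acc_nover <- sub("\\.[0-9]+$", "", dt$sseqid)
    mapped <- map$taxid[match(dt$sseqid, map$accession)]
    miss <- is.na(mapped)
    mapped[miss] <- map$taxid[match(acc_nover[miss], map$accession)]

    has_col <- !is.na(dt$staxid)
    disagree <- has_col & !is.na(mapped) & mapped != dt$staxid
    if (any(disagree))
      warning(sum(disagree), " hit(s) where staxid column and accession ",
              "mapping disagree; staxid column kept")
    dt[!has_col, "staxid" := mapped[!has_col]]
  }
  n_unmapped <- sum(is.na(dt$staxid))
  if (n_unmapped > 0L) dt <- dt[!is.na(dt$staxid)]

  n_unresolved <- 0L
  if (!is.null(tree)) {
    known <- dt$staxid %in% tree$taxid
    n_unresolved <- sum(!known)
    if (n_unresolved > 0L) {
      warning(n_unresolved, " hit(s) with taxid absent from the taxonomy dropped")
      dt <- dt[known]
    }
  }
  data.table::setattr(dt, "n_unmapped", n_unmapped)
  data.table::setattr(dt, "n_unresolved", n_unresolved)
  dt[]
}

#' Write a species profile as TSV
#'
#' Columns: `taxid`, `name`, `common_name`, `count`, `percent`, sorted by
#' descending percent with taxid as tiebreak. A footer comment records the
#' percent sum. The file round-trips bit-identically through
#' [read_profile()] and a second write.
#'
#' @param profile A `species_profile` from [quantify()].
#' @param destination Output path.
#' @return `destination`, invisibly.
#' @export
write_profile <- function(profile, destination) {
  sp <- profile$species
  con <- file(destination, "w")
  on.exit(close(con))
  writeLines("taxid\tname\tcommon_name\tcount\tpercent", con)
  pct_printed <- numeric(0)
  if (nrow(sp) > 0L) {
    o <- order(-sp$percent, sp$taxid)
    sp <- sp[o, , drop = FALSE]
    pct_str <- sprintf("%.6f", sp$percent)
    writeLines(sprintf("%d\t%s\t%s\t%.6f\t%s", sp$taxid, sp$name,
                       ifelse(is.na(sp$common_name), "", sp$common_name),
                       sp$count, pct_str), con)
    # footer sums the values as printed so a re-read profile writes the
    # identical file
    pct_printed <- as.numeric(pct_str)
  }
  writeLines(sprintf("# percent_sum=%.6f species_assigned_total=%.6f unresolvable=%.6f unassigned_pairs=%d",
                     sum(pct_printed), profile$species_assigned_total,
                     profile$unresolvable, profile$unassigned_pairs), con)
  invisible(destination)
}

#' Read a species profile written by [write_profile()]
#'
#' @param source Path to a profile TSV.
#' @return A `species_profile`.
#' @export
read_profile <- function(source) {
  lines <- readLines(source)
  footer <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")][-1L]
  if (length(body) > 0L) {
    f <- strsplit(body, "\t", fixed = TRUE)
    sp <- data.frame(
      taxid = as.integer(vapply(f, `[`, "", 1L)),
      name = vapply(f, `[`, "", 2L),
      common_name = vapply(f, function(x) if (nzchar(x[3L])) x[3L] else NA_character_, ""),
      count = as.numeric(vapply(f, `[`, "", 4L)),
      percent = as.numeric(vapply(f, `[`, "", 5L)),
      stringsAsFactors = FALSE)
  } else {
    sp <- data.frame(taxid = integer(0), name = character(0),
                     common_name = character(0), count = numeric(0),
                     percent = numeric(0), stringsAsFactors = FALSE)
  }
  kv <- regmatches(footer[1L],
                   gregexpr("[a-z_]+=[-0-9.]+", footer[1L]))[[1L]]
  vals <- stats::setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  new_species_profile(
    sp,
    species_assigned_total = unname(vals["species_assigned_total"]),
    unresolvable = unname(vals["unresolvable"]),
    unassigned_pairs = as.integer(vals["unassigned_pairs"]))
}
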
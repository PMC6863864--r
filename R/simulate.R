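#' Deterministic toy taxonomy for pipeline fixtures
#'
#' Builds a small rooted tree with root / family / genus / species layers
#' from a nested specification. Taxids are assigned in traversal order and
#' are stable across calls, so regenerating from the same spec yields an
#' identical tree.
#'
#' @param groups Named list of families; each family is a named list of
#'   genera; each genus is a character vector of species names.
#' @return A `taxonomy_tree`.
#' @examples
#' tree <- make_toy_taxonomy(list(
#'   Bovidae = list(Bos = c("Bos taurus", "Bos mutus")),
#'   Phasianidae = list(Gallus = "Gallus gallus")))
#' @export
make_toy_taxonomy <- function(groups) {
  if (length(groups) == 0L) stop("empty taxonomy specification")
  taxid <- 1L; parent <- 1L; rank <- "no rank"; name <- "root"
  nxt <- 2L
  for (fam in names(groups)) {
    fam_id <- nxt; nxt <- nxt + 1L
    taxid <- c(taxid, fam_id); parent <- c(parent, 1L)
    rank <- c(rank, "family"); name <- c(name, fam)
    genera <- groups[[fam]]
    for (gen in names(genera)) {
      gen_id <- nxt; nxt <- nxt + 1L
      taxid <- c(taxid, gen_id); parent <- c(parent, fam_id)
      rank <- c(rank, "genus"); name <- c(name, gen)
      for (spn in genera[[gen]]) {
        taxid <- c(taxid, nxt); parent <- c(parent, gen_id)
        rank <- c(rank, "species"); name <- c(name, spn)
        nxt <- nxt + 1L
      }
    }
  }
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines(paste(taxid, parent, rank, name, sep = "\t"), tf)
  read_taxonomy(tf)
}

#' Mixture specification for the read/hit simulators
#'
#' Captures the composition and error model of a simulated paired-end
#' sample. Defaults are the standard short-read simulation operating point:
#' 150 bp reads, 0.005 per-base sequencing error, 500 bp outer distance,
#' 0.001 donor mutation rate with 15% of mutations as indels extended with
#' probability 0.3.
#'
#' @param components Named numeric vector: names are species taxids, values
#'   are read-pair proportions summing to 1.
#' @param read_pairs Total number of read pairs to simulate.
#' @param read_length Read length in bp.
#' @param base_error_rate Per-base sequencing substitution error rate.
#' @param outer_distance Outer distance between the two ends of a pair, bp.
#' @param mutation_rate Donor-genome mutation rate per base.
#' @param indel_fraction Fraction of donor mutations that are indels.
#' @param indel_extension_prob Geometric extension probability of an indel.
#' @param seed Integer seed; every simulator output is reproducible from it.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(components, read_pairs, read_length = 150L,
                         base_error_rate = 0.005, outer_distance = 500L,
                         mutation_rate = 0.001, indel_fraction = 0.15,
                         indel_extension_prob = 0.3, seed = 1L) {
  stopifnot(length(components) >= 1L, !is.null(names(components)),
            abs(sum(components) - 1) <= 1e-9,
            all(components >= 0),
            read_pairs >= 1, read_length >= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            indel_extension_prob >= 0, indel_extension_prob <= 1)
  structure(list(components = components, read_pairs = as.integer(read_pairs),
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 outer_distance = as.integer(outer_distance),
                 mutation_rate = mutation_rate,
                 indel_fraction = indel_fraction,
                 indel_extension_prob = indel_extension_prob,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

# Largest-remainder apportionment of n units over proportions p.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

mutate_seq <- function(chars, rate, indel_fraction, ext_prob) {
  n <- length(chars)
  hits <- which(stats::runif(n) < rate)
  if (length(hits) == 0L) return(chars)
  bases <- c("A", "C", "G", "T")
  out <- as.list(chars)
  for (i in hits) {
    if (stats::runif(1) < indel_fraction) {
      len <- 1L + stats::rgeom(1, prob = 1 - ext_prob)
      if (stats::runif(1) < 0.5) {
        out[[i]] <- c(chars[i], sample(bases, len, replace = TRUE)) # insertion
      } else {
        drop <- i:min(n, i + len - 1L)
        for (j in drop) out[[j]] <- character(0)                    # deletion
      }
    } else {
      out[[i]] <- sample(setdiff(bases, chars[i]), 1L)              # substitution
    }
  }
  unlist(out)
}

add_seq_errors <- function(chars, rate) {
  hits <- which(stats::runif(length(chars)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hits) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  chars
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

#' Simulate error-bearing paired-end reads from genomes
#'
#' A single-pass paired-end read simulator: fragments are placed uniformly
#' on the source genome, donor mutations (substitutions and geometric
#' indels) are applied to the fragment, the two mates are cut from its
#' ends (mate 2 reverse-complemented), and per-base sequencing
#' substitution errors are added. Per-species read counts follow the
#' mixture proportions exactly by largest-remainder apportionment. Output
#' is fully reproducible from the spec seed.
#'
#' @param genomes Named `Biostrings::DNAStringSet` (names are species
#'   taxids) or path to a FASTA whose record names are taxids.
#' @param spec A [mixture_spec()]; every component taxid must have a
#'   genome at least `outer_distance + 10` bp long.
#' @param out_prefix Path prefix; `<prefix>_1.fastq`, `<prefix>_2.fastq`
#'   and `<prefix>_truth.tsv` are written.
#' @return Invisibly, a list with the three output paths and the truth
#'   data.frame (`read_id`, `taxid`).
#' @export
simulate_reads <- function(genomes, spec, out_prefix) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("simulate_reads() requires the Biostrings package")
  if (is.character(genomes))
    genomes <- Biostrings::readDNAStringSet(genomes)
  gseq <- lapply(as.character(genomes), function(s) strsplit(s, "")[[1]])
  names(gseq) <- sub("\\s.*$", "", names(genomes))

  comp_tax <- names(spec$components)
  missing <- setdiff(comp_tax, names(gseq))
  if (length(missing) > 0L)
    stop("no genome for taxid(s): ", paste(missing, collapse = ", "))
  frag_need <- spec$outer_distance
  short <- comp_tax[vapply(gseq[comp_tax], length, 0L) < frag_need]
  if (length(short) > 0L)
    stop("genome(s) shorter than the outer distance: ",
         paste(short, collapse = ", "))

  counts <- apportion(spec$read_pairs, spec$components)
  if (any(counts == 0 & spec$components > 0))
    warning("component(s) ", paste(comp_tax[counts == 0 & spec$components > 0],
                                   collapse = ", "),
            " received zero reads at this read_pairs value")
  set.seed(spec$seed)
  rl <- spec$read_length
  n_total <- sum(counts)
  r1 <- character(n_total); r2 <- character(n_total)
  ids <- character(n_total); tax <- integer(n_total)
  k <- 0L
  for (ci in seq_along(comp_tax)) {
    g <- gseq[[comp_tax[ci]]]
    glen <- length(g)
    for (j in seq_len(counts[ci])) {
      k <- k + 1L
      start <- sample.int(glen - spec$outer_distance + 1L, 1L)
      frag <- g[start:(start + spec$outer_distance - 1L)]
      if (spec$mutation_rate > 0)
        frag <- mutate_seq(frag, spec$mutation_rate,
                           spec$indel_fraction, spec$indel_extension_prob)
      if (length(frag) < rl + 1L)  # heavy deletion load; re-pad from genome
        frag <- c(frag, g[seq_len(rl + 1L - length(frag))])
      m1 <- frag[seq_len(rl)]
      m2 <- revcomp_chars(frag[(length(frag) - rl + 1L):length(frag)])
      if (spec$base_error_rate > 0) {
        m1 <- add_seq_errors(m1, spec$base_error_rate)
        m2 <- add_seq_errors(m2, spec$base_error_rate)
      }
      ids[k] <- sprintf("sim_%07d", k)
      tax[k] <- as.integer(comp_tax[ci])
      r1[k] <- paste(m1, collapse = "")
      r2[k] <- paste(m2, collapse = "")
    }
  }
  f1 <- paste0(out_prefix, "_1.fastq")
  f2 <- paste0(out_prefix, "_2.fastq")
  ft <- paste0(out_prefix, "_truth.tsv")
  write_fastq(paste0(ids, "/1"), r1, f1)
  write_fastq(paste0(ids, "/2"), r2, f2)
  truth <- data.frame(read_id = ids, taxid = tax, stringsAsFactors = FALSE)
  utils::write.table(truth, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fastq_1 = f1, fastq_2 = f2, truth_file = ft, truth = truth))
}

write_fastq <- function(ids, seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("FASTQ output requires the Biostrings package")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Cross-species confusion model for synthetic hit tables
#'
#' Describes, for ordered species pairs, the probability that a read pair
#' originating from `from` also receives an equally scored (tied-bitscore)
#' hit pair on `to` — emulating conserved sequence shared between related
#' species — and the probability of a strictly lower-scoring hit pair
#' (which best-bitscore retention should prune).
#'
#' @param from,to Species taxids (vectors of equal length).
#' @param tie_prob Probability of a tied-bitscore cross hit, per pair.
#' @param low_prob Probability of a lower-bitscore cross hit, per pair.
#' @return A `confusion_model` data.frame.
#' @export
confusion_model <- function(from = integer(0), to = integer(0),
                            tie_prob = numeric(0), low_prob = 0) {
  n <- length(from)
  low_prob <- rep_len(low_prob, n)
  tie_prob <- rep_len(tie_prob, n)
  stopifnot(length(to) == n, all(tie_prob >= 0 & tie_prob <= 1),
            all(low_prob >= 0 & low_prob <= 1))
  structure(data.frame(from = as.integer(from), to = as.integer(to),
                       tie_prob = tie_prob, low_prob = low_prob),
            class = c("confusion_model", "data.frame"))
}

#' Generate a labelled synthetic hit table with known ground truth
#'
#' Stands in for an aligner + reference database: every simulated read pair
#' receives a concordant pair of hits on its own species' reference (high
#' identity, e-value below 1e-40), plus — per the confusion model — tied- or
#' lower-bitscore concordant hit pairs on related species. Optional noise
#' injects singleton-mate pairs, discordantly placed pairs (mates more than
#' the concordance limit apart) and sub-threshold-identity pairs, each
#' tagged in the truth table so every filter stage has known ground truth.
#'
#' @param spec A [mixture_spec()] (sequence-level error fields are unused
#'   here; composition, `read_pairs` and `seed` matter).
#' @param tree A `taxonomy_tree` containing all component and confusion
#'   taxids.
#' @param confusion A [confusion_model()] (default: no cross hits).
#' @param noise List with fractions `singleton`, `discordant`,
#'   `subthreshold` of read pairs to corrupt (defaults 0).
#' @param identity_mean,identity_sd Self-hit identity distribution,
#'   truncated to [95, 100].
#' @return A list with `hits` (data.table in the extended outfmt-6 dialect,
#'   ready for [read_hits()]/[filter_hits()]) and `truth` (`read_id`,
#'   `taxid`, `tag`).
#' @export
generate_hit_table <- function(spec, tree, confusion = confusion_model(),
                               noise = list(), identity_mean = 99,
                               identity_sd = 0.5) {
  noise <- utils::modifyList(
    list(singleton = 0, discordant = 0, subthreshold = 0), noise)
  comp_tax <- as.integer(names(spec$components))
  tax_index(tree, unique(c(comp_tax, confusion$from, confusion$to)))

  set.seed(spec$seed)
  counts <- apportion(spec$read_pairs, spec$components)
  n <- sum(counts)
  src <- rep(comp_tax, counts)
  ids <- sprintf("sim_%07d", seq_len(n))

  tags <- rep("ok", n)
  n_noise <- apportion(n, c(max(0, 1 - sum(unlist(noise))),
                            noise$singleton, noise$discordant,
                            noise$subthreshold))
  if (sum(n_noise[-1L]) > 0) {
    noisy <- sample.int(n, sum(n_noise[-1L]))
    tags[noisy] <- rep(c("singleton", "discordant", "subthreshold"),
                       n_noise[-1L])
  }

  identity <- stats::rnorm(n, identity_mean, identity_sd)
  identity <- pmin(100, pmax(95, identity))
  identity[tags == "subthreshold"] <-
    stats::runif(sum(tags == "subthreshold"), 80, 94.9)
  rl <- spec$read_length
  pos <- sample.int(1000000L, n, replace = TRUE)
  bitscore <- round(2 * rl * identity / 100, 1)

  rows <- list()
  emit <- function(id, taxid, mate, ident, bits, sstart, send) {
    data.table::data.table(
      qseqid = paste0(id, "/", mate),
      sseqid = paste0("REF_", taxid),
      pident = round(ident, 2), length = rl, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = rl, sstart = sstart, send = send,
      evalue = 1e-50, bitscore = bits, qlen = rl, staxid = taxid)
  }

  m2_off <- spec$outer_distance - rl
  m2_shift <- integer(n)
  m2_shift[tags == "discordant"] <- 2000000L
  self1 <- emit(ids, src, 1L, identity, bitscore, pos, pos + rl - 1L)
  # mate 2 on the minus strand: send < sstart
  self2 <- emit(ids, src, 2L, identity, bitscore,
                pos + m2_off + rl - 1L + m2_shift, pos + m2_off + m2_shift)
  keep2 <- tags != "singleton"
  rows <- list(self1, self2[keep2])

  if (nrow(confusion) > 0L) {
    for (ci in seq_len(nrow(confusion))) {
      origin <- which(src == confusion$from[ci] & tags == "ok")
      if (length(origin) == 0L) next
      tied <- origin[stats::runif(length(origin)) < confusion$tie_prob[ci]]
      if (length(tied) > 0L) {
        rows <- c(rows, list(
          emit(ids[tied], confusion$to[ci], 1L, identity[tied],
               bitscore[tied], pos[tied], pos[tied] + rl - 1L),
          emit(ids[tied], confusion$to[ci], 2L, identity[tied],
               bitscore[tied], pos[tied] + m2_off + rl - 1L,
               pos[tied] + m2_off)))
      }
      lower <- origin[stats::runif(length(origin)) < confusion$low_prob[ci]]
      if (length(lower) > 0L) {
        rows <- c(rows, list(
          emit(ids[lower], confusion$to[ci], 1L, identity[lower] - 1,
               bitscore[lower] - 15, pos[lower], pos[lower] + rl - 1L),
          emit(ids[lower], confusion$to[ci], 2L, identity[lower] - 1,
               bitscore[lower] - 15, pos[lower] + m2_off + rl - 1L,
               pos[lower] + m2_off)))
      }
    }
  }
  hits <- data.table::rbindlist(rows)
  data.table::setorderv(hits, c("qseqid", "sseqid"))
  truth <- data.frame(read_id = ids, taxid = src, tag = tags,
                      stringsAsFactors = FALSE)
  list(hits = hits[], truth = truth)
}

#' Seeded, pair-coherent FASTQ subsampling
#'
#' Draws a uniform sample of `n` read pairs without replacement from a
#' FASTQ pair in a single streaming pass, using reservoir sampling: memory
#' is bounded by the reservoir (`n` records per file), not the input size,
#' and both mates of a pair are kept or dropped together. Reproducible from
#' `seed`.
#'
#' @param fastq_1,fastq_2 Input FASTQ paths (plain text).
#' @param n Number of read pairs to keep; must not exceed the input count.
#' @param seed Integer seed.
#' @param out_1,out_2 Output FASTQ paths.
#' @return Invisibly, a list with the output paths and `n_input` pairs seen.
#' @export
subsample_reads <- function(fastq_1, fastq_2, n, seed, out_1, out_2) {
  stopifnot(n >= 0)
  set.seed(seed)
  con1 <- file(fastq_1, "r"); con2 <- file(fastq_2, "r")
  on.exit({ close(con1); close(con2) })
  res1 <- vector("list", n); res2 <- vector("list", n)
  i <- 0L
  repeat {
    rec1 <- readLines(con1, n = 4L)
    rec2 <- readLines(con2, n = 4L)
    if (length(rec1) == 0L && length(rec2) == 0L) break
    if (length(rec1) != 4L || length(rec2) != 4L)
      stop("FASTQ files are truncated or of unequal length")
    i <- i + 1L
    if (i <= n) {
      res1[[i]] <- rec1; res2[[i]] <- rec2
    } else {
      j <- sample.int(i, 1L)
      if (j <= n) { res1[[j]] <- rec1; res2[[j]] <- rec2 }
    }
  }
  if (n > i)
    stop("requested ", n, " pairs but the input has only ", i)
  writeLines(as.character(unlist(res1[seq_len(n)])), out_1)
  writeLines(as.character(unlist(res2[seq_len(n)])), out_2)
  invisible(list(out_1 = out_1, out_2 = out_2, n_input = i))
}
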
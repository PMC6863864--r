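# Shared fixtures and independent oracles for the test suite.

# ---- taxonomy fixtures -----------------------------------------------------

write_tax_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

# root(1) -> families -> genera -> species, as plain TSV rows
livestock_tree <- function() {
  make_toy_taxonomy(list(
    Bovidae = list(Bos = c("Bos taurus", "Bos mutus", "Bos indicus"),
                   Bison = "Bison bison",
                   Bubalus = "Bubalus bubalis",
                   Ovis = "Ovis aries",
                   Capra = "Capra hircus"),
    Phasianidae = list(Gallus = "Gallus gallus",
                       Meleagris = "Meleagris gallopavo",
                       Coturnix = "Coturnix japonica"),
    Suidae = list(Sus = "Sus scrofa")))
}

tid <- function(tree, name) tree$taxid[match(name, tree$name)]

# random rooted tree: node 1 is the root, parents drawn among earlier nodes
random_tree <- function(n, seed, p_species = 0.5) {
  set.seed(seed)
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  rank <- ifelse(stats::runif(n) < p_species, "species", "clade")
  rank[1L] <- "no rank"
  path <- write_tax_tsv(Map(c, seq_len(n), parent, rank,
                            paste0("node", seq_len(n))))
  on.exit(unlink(path))
  read_taxonomy(path)
}

# oracle: intersect full root-paths, take the deepest shared node
lca_oracle <- function(tree, taxids) {
  path_up <- function(t) {
    i <- match(t, tree$taxid)
    out <- i
    while (tree$parent_idx[i] != i) {
      i <- tree$parent_idx[i]
      out <- c(out, i)
    }
    out
  }
  shared <- Reduce(intersect, lapply(taxids, path_up))
  tree$taxid[shared[which.max(tree$depth[shared])]]
}

# ---- hypergeometric oracle -------------------------------------------------

# Exact upper-tail probabilities P(X >= r), r = 0..n, by exhaustive
# enumeration of binomial-coefficient terms. For N <= 56 every binomial
# coefficient and partial sum is an integer below 2^53, so Pascal-triangle
# addition is exact integer arithmetic and the single final division is the
# only rounding. For larger N, each term is assembled from the exact prime
# factorisation of the factorials (Legendre exponents); only the final
# product of prime powers rounds, with relative error ~1e-15.
pascal_C <- local({
  tri <- NULL
  function() {
    if (is.null(tri)) {
      t <- vector("list", 57L)
      t[[1L]] <- 1
      for (m in 1:56) {
        prev <- t[[m]]
        t[[m + 1L]] <- c(prev, 0) + c(0, prev)
      }
      tri <<- t
    }
    tri
  }
})

prime_fact_exp <- local({
  fe <- NULL
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53, 59)
  function() {
    if (is.null(fe)) {
      m <- matrix(0, nrow = 61, ncol = length(primes))
      for (i in seq_along(primes)) {
        p <- primes[i]
        for (mm in 0:60) {
          e <- 0; q <- p
          while (q <= mm) { e <- e + mm %/% q; q <- q * p }
          m[mm + 1L, i] <- e
        }
      }
      fe <<- list(primes = primes, m = m)
    }
    fe
  }
})

hyper_tail_oracle <- function(N, K, n) {
  ks <- max(0L, n - (N - K)):min(n, K)
  if (N <= 56) {
    tri <- pascal_C()
    CK <- tri[[K + 1L]]
    CN_K <- tri[[N - K + 1L]]
    CNn <- tri[[N + 1L]][n + 1L]
    num <- CK[ks + 1L] * CN_K[n - ks + 1L]
  } else {
    fe <- prime_fact_exp()
    lch <- function(a, b) fe$m[a + 1L, , drop = FALSE] -
      fe$m[b + 1L, , drop = FALSE] - fe$m[a - b + 1L, , drop = FALSE]
    eN <- lch(N, n)
    num <- vapply(ks, function(k) {
      e <- lch(K, k) + lch(N - K, n - k) - eN
      prod(fe$primes ^ as.numeric(e))
    }, 0)
    CNn <- 1
  }
  # P(X >= r) = 1 - (sum of PMF below r); exact integer sums where possible
  below <- c(0, cumsum(num))            # below[r+1] = sum_{k < r} num[k]
  r <- 0:n
  idx <- pmin(pmax(r - ks[1L] + 1L, 1L), length(below))
  sums <- below[idx]
  sums[r <= ks[1L]] <- 0
  sums[r > ks[length(ks)]] <- sum(num)  # full mass below r
  (CNn - sums) / CNn
}

# ---- hit-table fixtures ----------------------------------------------------

# minimal well-formed hit row(s) with overridable fields
make_hits <- function(read_id, mate, staxid, sseqid = paste0("REF_", staxid),
                      pident = 99, length = 150, qlen = 150,
                      evalue = 1e-50, bitscore = 290,
                      sstart = 1000, send = 1149) {
  data.table::data.table(
    read_id = read_id, mate = as.integer(mate),
    qseqid = paste0(read_id, "/", mate), sseqid = sseqid,
    pident = pident, length = length, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 150L, sstart = sstart, send = send,
    evalue = evalue, bitscore = bitscore, qlen = qlen,
    staxid = as.integer(staxid))
}

random_hit_table <- function(n_pairs, n_taxa, seed,
                             tie_prob = 0.3, singleton_prob = 0.2) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    id <- sprintf("r%04d", i)
    taxa <- sample.int(n_taxa, 1L + stats::rbinom(1, 2, tie_prob))
    pos <- sample.int(3000000L, 1L)
    mates <- if (stats::runif(1) < singleton_prob) 1L else c(1L, 2L)
    for (tx in taxa) for (m in mates) {
      shift <- if (m == 2L) sample(c(350L, 1500000L), 1L, prob = c(.8, .2)) else 0L
      rows[[length(rows) + 1L]] <- make_hits(
        id, m, tx,
        sseqid = paste0("REF_", sample.int(max(1L, n_taxa %/% 2L), 1L)),
        bitscore = sample(c(280, 290), 1L),
        sstart = pos + shift, send = pos + shift + 149L)
    }
  }
  data.table::rbindlist(rows)
}

# oracle: a hit survives concordance iff some opposite-mate hit of the same
# pair sits on the same subject within the distance limit (all-pairs check)
concordance_oracle <- function(hits, max_dist = 1000000,
                               keep_singletons = FALSE) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    same_pair <- which(hits$read_id == hits$read_id[i])
    if (!any(hits$mate[same_pair] != hits$mate[i])) {
      keep[i] <- keep_singletons
      next
    }
    for (j in same_pair) {
      if (hits$mate[j] == hits$mate[i]) next
      if (hits$sseqid[j] != hits$sseqid[i]) next
      lo1 <- min(hits$sstart[i], hits$send[i]); hi1 <- max(hits$sstart[i], hits$send[i])
      lo2 <- min(hits$sstart[j], hits$send[j]); hi2 <- max(hits$sstart[j], hits$send[j])
      gap <- max(0, max(lo1, lo2) - min(hi1, hi2) - 1)
      if (gap <= max_dist) { keep[i] <- TRUE; break }
    }
  }
  hits[keep]
}

# a known-composition sausage mixture: expected (ingredient weight) vs
# observed (species-assigned read fraction) percents
sausage_comparison <- function() {
  composition_comparison(
    species = c("sheep", "beef", "pork", "horse", "goat",
                "water buffalo", "Tibetan antelope"),
    expected = c(54.49, 34.67, 8.92, 0.99, 0, 0, 0),
    observed = c(54.07, 35.11, 6.67, 1.10, 1.83, 0.70, 0.41))
}
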
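toy_genomes <- function(taxids, len = 2000, seed = 1) {
  set.seed(seed)
  seqs <- vapply(taxids, function(t)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- taxids
  x
}

test_that("toy taxonomies are deterministic with correctly ranked layers", {
  spec <- list(F1 = list(G1 = c("s1", "s2"), G2 = c("s3", "s4")))
  tree <- make_toy_taxonomy(spec)
  # root + family + 2 genera + 4 species = 8 nodes; 2x2 species layout
  expect_equal(length(tree$taxid), 8L)
  expect_equal(sum(tree$rank == "species"), 4L)
  tree2 <- make_toy_taxonomy(spec)
  expect_identical(tree[c("taxid", "parent", "rank", "name")],
                   tree2[c("taxid", "parent", "rank", "name")])
  for (s in tree$taxid[tree$rank == "species"])
    expect_equal(species_ancestor(tree, s), s)
  expect_error(make_toy_taxonomy(list()), "empty")
})

test_that("largest-remainder apportionment hits proportions exactly", {
  tree <- livestock_tree()
  comps <- setNames(c(0.4, 0.3, 0.2, 0.09, 0.01),
                    c(tid(tree, "Bos taurus"), tid(tree, "Ovis aries"),
                      tid(tree, "Sus scrofa"), tid(tree, "Gallus gallus"),
                      tid(tree, "Capra hircus")))
  ms <- mixture_spec(comps, read_pairs = 1000, seed = 1)
  g <- generate_hit_table(ms, tree)
  counts <- table(g$truth$taxid)
  expect_equal(unname(counts[names(comps)]), c(400, 300, 200, 90, 10),
               ignore_attr = TRUE)
  expect_equal(nrow(g$truth), 1000L)
})

test_that("noiseless simulated reads are exact genome substrings", {
  skip_if_not_installed("Biostrings")
  tree <- livestock_tree()
  gg <- tid(tree, "Gallus gallus"); ss <- tid(tree, "Sus scrofa")
  genomes <- toy_genomes(c(gg, ss))
  ms <- mixture_spec(setNames(c(0.6, 0.4), c(gg, ss)), read_pairs = 20,
                     base_error_rate = 0, mutation_rate = 0, seed = 9)
  out <- simulate_reads(genomes, ms, tempfile())
  r1 <- Biostrings::readDNAStringSet(out$fastq_1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(out$fastq_2, format = "fastq")
  expect_equal(length(r1), 20L)
  ids <- sub("/1$", "", names(r1))
  expect_equal(ids, out$truth$read_id)
  for (i in seq_len(20)) {
    src <- genomes[[as.character(out$truth$taxid[i])]]
    expect_equal(Biostrings::countPattern(r1[[i]], src), 1)
    expect_equal(Biostrings::countPattern(
      Biostrings::reverseComplement(r2[[i]]), src), 1)
  }
})

test_that("read simulation is byte-identical under the same seed", {
  skip_if_not_installed("Biostrings")
  tree <- livestock_tree()
  gg <- tid(tree, "Gallus gallus")
  genomes <- toy_genomes(gg)
  ms <- mixture_spec(setNames(1, gg), read_pairs = 30, seed = 123)
  o1 <- simulate_reads(genomes, ms, tempfile())
  o2 <- simulate_reads(genomes, ms, tempfile())
  expect_identical(readLines(o1$fastq_1), readLines(o2$fastq_1))
  expect_identical(readLines(o1$fastq_2), readLines(o2$fastq_2))
  # reads carry errors at the default rates: not all identical to reference
  ms0 <- mixture_spec(setNames(1, gg), read_pairs = 30, seed = 123,
                      base_error_rate = 0, mutation_rate = 0)
  o3 <- simulate_reads(genomes, ms0, tempfile())
  expect_false(identical(readLines(o1$fastq_1), readLines(o3$fastq_1)))
})

test_that("simulation contracts are enforced", {
  skip_if_not_installed("Biostrings")
  tree <- livestock_tree()
  gg <- tid(tree, "Gallus gallus"); ss <- tid(tree, "Sus scrofa")
  expect_error(mixture_spec(setNames(c(0.6, 0.3), c(gg, ss)), 10),
               "sum")
  ms <- mixture_spec(setNames(c(0.999, 0.001), c(gg, ss)), read_pairs = 100,
                     seed = 1)
  expect_warning(simulate_reads(toy_genomes(c(gg, ss)), ms, tempfile()),
                 "zero reads")
  short <- toy_genomes(gg, len = 100)
  expect_error(simulate_reads(short, mixture_spec(setNames(1, gg), 10),
                              tempfile()),
               "shorter than")
})

test_that("hit tables with zero confusion recover exact mixture proportions", {
  tree <- livestock_tree()
  comps <- setNames(c(0.5, 0.3, 0.2),
                    c(tid(tree, "Bos taurus"), tid(tree, "Gallus gallus"),
                      tid(tree, "Sus scrofa")))
  ms <- mixture_spec(comps, read_pairs = 500, seed = 2)
  res <- profile_species(read_hits(generate_hit_table(ms, tree)$hits), tree)
  got <- setNames(res$profile$species$percent,
                  res$profile$species$taxid)[names(comps)]
  expect_equal(unname(got), 100 * unname(comps), tolerance = 1e-12)
})

test_that("sibling-species confusion yields the dominant-source pattern", {
  tree <- livestock_tree()
  gg <- tid(tree, "Gallus gallus")
  conf <- confusion_model(from = c(gg, gg),
                          to = c(tid(tree, "Meleagris gallopavo"),
                                 tid(tree, "Coturnix japonica")),
                          tie_prob = 0.001)
  ms <- mixture_spec(setNames(1, gg), read_pairs = 20000, seed = 4)
  res <- profile_species(read_hits(generate_hit_table(ms, tree, conf)$hits),
                         tree)
  sp <- res$profile$species
  expect_gte(sp$percent[sp$taxid == gg], 99.9)
})

test_that("noise injections are tagged and caught by their filter stage", {
  tree <- livestock_tree()
  gg <- tid(tree, "Gallus gallus")
  ms <- mixture_spec(setNames(1, gg), read_pairs = 400, seed = 6)
  g <- generate_hit_table(ms, tree,
                          noise = list(singleton = 0.1, discordant = 0.1,
                                       subthreshold = 0.1))
  expect_equal(unname(table(g$truth$tag)[c("singleton", "discordant",
                                           "subthreshold")]),
               c(40L, 40L, 40L), ignore_attr = TRUE)
  hits <- read_hits(g$hits)
  # subthreshold pairs die at the threshold stage
  after_thr <- threshold_filter(hits)
  sub_ids <- g$truth$read_id[g$truth$tag == "subthreshold"]
  expect_false(any(after_thr$read_id %in% sub_ids))
  # singleton and discordant pairs die at the concordance stage
  res <- filter_hits(hits)
  bad <- g$truth$read_id[g$truth$tag != "ok"]
  expect_false(any(res$hits$read_id %in% bad))
  ok <- g$truth$read_id[g$truth$tag == "ok"]
  expect_setequal(unique(res$hits$read_id), ok)
})

test_that("subsampling is pair-coherent, seeded, and exact at the edges", {
  skip_if_not_installed("Biostrings")
  tree <- livestock_tree()
  gg <- tid(tree, "Gallus gallus"); ss <- tid(tree, "Sus scrofa")
  ms <- mixture_spec(setNames(c(0.7, 0.3), c(gg, ss)), read_pairs = 200,
                     seed = 10)
  sim <- simulate_reads(toy_genomes(c(gg, ss)), ms, tempfile())
  o1 <- tempfile(); o2 <- tempfile()
  # n == total: same content, any order
  subsample_reads(sim$fastq_1, sim$fastq_2, 200, 1, o1, o2)
  ids <- function(p) sub("^@", "", readLines(p)[c(TRUE, FALSE, FALSE, FALSE)])
  expect_setequal(ids(o1), paste0(sim$truth$read_id, "/1"))
  # mates stay together
  subsample_reads(sim$fastq_1, sim$fastq_2, 50, 7, o1, o2)
  expect_equal(sub("/1$", "", ids(o1)), sub("/2$", "", ids(o2)))
  # determinism
  o3 <- tempfile(); o4 <- tempfile()
  subsample_reads(sim$fastq_1, sim$fastq_2, 50, 7, o3, o4)
  expect_identical(readLines(o1), readLines(o3))
  # n = 0 and n > total
  subsample_reads(sim$fastq_1, sim$fastq_2, 0, 1, o1, o2)
  expect_equal(length(readLines(o1)), 0L)
  expect_error(subsample_reads(sim$fastq_1, sim$fastq_2, 201, 1, o1, o2),
               "only 200")
})

test_that("subsampled species fractions follow the hypergeometric law", {
  skip_if_not_installed("Biostrings")
  tree <- livestock_tree()
  gg <- tid(tree, "Gallus gallus"); ss <- tid(tree, "Sus scrofa")
  N <- 400; K <- 80; n <- 100
  ms <- mixture_spec(setNames(c((N - K) / N, K / N), c(gg, ss)),
                     read_pairs = N, seed = 20)
  sim <- simulate_reads(toy_genomes(c(gg, ss)), ms, tempfile())
  truth_tax <- setNames(sim$truth$taxid, sim$truth$read_id)
  draws <- vapply(1:60, function(s) {
    o1 <- tempfile(); o2 <- tempfile()
    subsample_reads(sim$fastq_1, sim$fastq_2, n, s, o1, o2)
    got <- sub("/1$", "",
               sub("^@", "", readLines(o1)[c(TRUE, FALSE, FALSE, FALSE)]))
    sum(truth_tax[got] == ss)
  }, 0)
  mu <- n * K / N
  sigma <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
  expect_lt(abs(mean(draws) - mu), 3 * sigma / sqrt(60))
  # every draw within 5 sigma of the mean (sanity of without-replacement draw)
  expect_true(all(abs(draws - mu) <= 5 * sigma))
})

test_that("subsample sizes from the detection model deliver the promised LOD", {
  # a species at 5% of 4,000 pairs, LOD 10 reads: the solver's n* must
  # yield >= 10 reads in (essentially) every seeded subsample
  N <- 4000; f <- 0.05; L <- 10
  n_star <- min_subsample_size(N, f, L, 0.9999)
  K <- round(N * f)
  pool <- c(rep(TRUE, K), rep(FALSE, N - K))
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    sum(sample(pool, n_star))
  }, 0)
  # per-draw miss probability is <= 1e-4, so two misses in 200 draws has
  # probability ~2e-4: allow at most one
  expect_lte(sum(hits < L), 1)
})
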
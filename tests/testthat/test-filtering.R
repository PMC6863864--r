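test_that("threshold filter applies inclusive identity/coverage/e-value bounds", {
  tab <- rbind(
    make_hits("r1", 1, 1, pident = 94.9),                   # identity fail
    make_hits("r2", 1, 1, pident = 95.0, length = 75, qlen = 150,
              evalue = 1e-40),                              # all at boundary
    make_hits("r3", 1, 1, length = 74, qlen = 150),         # coverage fail
    make_hits("r4", 1, 1, evalue = 1e-10),                  # e-value fail
    make_hits("r5", 1, 1, qlen = 0))                        # zero query length
  out <- threshold_filter(tab)
  expect_equal(out$read_id, "r2")
  expect_equal(attr(out, "n_zero_qlen"), 1L)
  # Relaxing the e-value to 1e-10 (the comparison mode) readmits r4
  out10 <- threshold_filter(tab, filter_params(max_evalue = 1e-10))
  expect_setequal(out10$read_id, c("r2", "r4"))
})

test_that("best-bitscore retention keeps ties per mate", {
  tab <- rbind(make_hits("r1", 1, 1, bitscore = 200),
               make_hits("r1", 1, 2, bitscore = 200),
               make_hits("r1", 1, 3, bitscore = 150),
               make_hits("r1", 2, 1, bitscore = 120),  # other mate independent
               make_hits("r2", 1, 9, bitscore = 10))
  out <- retain_best_bitscore(tab)
  expect_setequal(out$staxid[out$read_id == "r1" & out$mate == 1], c(1L, 2L))
  expect_equal(out$staxid[out$read_id == "r1" & out$mate == 2], 1L)
  expect_equal(out$staxid[out$read_id == "r2"], 9L)
})

test_that("best-bitscore retention equals naive group-by-max on random tables", {
  for (seed in 1:10) {
    tab <- random_hit_table(40, 6, seed)
    out <- retain_best_bitscore(tab)
    naive <- do.call(rbind, lapply(
      split(tab, paste(tab$read_id, tab$mate)),
      function(g) g[g$bitscore == max(g$bitscore), ]))
    key <- function(d) sort(do.call(paste, d[, c("read_id", "mate", "staxid",
                                                 "sseqid", "bitscore",
                                                 "sstart")]))
    expect_identical(key(out), key(naive))
  }
})

test_that("promiscuity filter removes <10%-unique taxa at pair level", {
  # taxon 2: 20 pairs hit it, 1 uniquely (5% < 10%) -> removed
  tab <- rbind(
    do.call(rbind, lapply(1:19, function(i)
      rbind(make_hits(sprintf("p%02d", i), 1, 1),
            make_hits(sprintf("p%02d", i), 1, 2)))),
    make_hits("p20", 1, 2),
    do.call(rbind, lapply(21:40, function(i) make_hits(sprintf("p%02d", i), 1, 1))))
  out <- promiscuity_filter(tab)
  expect_false(2L %in% out$staxid)
  removed <- attr(out, "removed_taxa")
  expect_equal(removed$taxid, 2L)
  expect_equal(removed$unique_fraction, 1 / 20)
  # pairs that hit {1,2} now hit only 1; p20 (hit only taxon 2) is gone
  expect_true(all(out$staxid == 1L))
  expect_equal(length(unique(out$read_id)), 39L)
  expect_false("p20" %in% out$read_id)

  # taxon B: 3 pairs, 1 unique (33% >= 10%) -> kept
  tab2 <- rbind(make_hits("q1", 1, 1), make_hits("q1", 1, 2),
                make_hits("q2", 1, 1), make_hits("q2", 1, 2),
                make_hits("q3", 1, 2))
  out2 <- promiscuity_filter(tab2)
  expect_true(2L %in% out2$staxid)
})

test_that("promiscuity removal is simultaneous, on the original table", {
  # A and B are mutually promiscuous; iterative removal of one would
  # rescue the other, simultaneous single-pass removal drops both
  tab <- do.call(rbind, lapply(1:10, function(i)
    rbind(make_hits(sprintf("p%02d", i), 1, 1),
          make_hits(sprintf("p%02d", i), 1, 2))))
  out <- promiscuity_filter(tab)
  expect_equal(nrow(out), 0L)
  expect_setequal(attr(out, "removed_taxa")$taxid, c(1L, 2L))
})

test_that("promiscuity filter is idempotent on random tables", {
  for (seed in 1:30) {
    tab <- random_hit_table(30, 5, seed, tie_prob = 0.6)
    once <- promiscuity_filter(tab)
    twice <- promiscuity_filter(once)
    key <- function(d) sort(do.call(paste, as.data.frame(d)))
    expect_identical(key(once), key(twice))
    expect_equal(nrow(attr(twice, "removed_taxa")), 0L)
  }
})

test_that("concordance filter keeps same-subject pairs within 1 Mbp", {
  base <- function(id, m, sstart, send, subj = "chr1")
    make_hits(id, m, 1, sseqid = subj, sstart = sstart, send = send)
  tab <- rbind(
    base("a", 1, 100, 250), base("a", 2, 500, 650),          # concordant
    base("b", 1, 100, 250), base("b", 2, 500, 650, "chr2"),  # diff subject
    base("c", 1, 1, 100), base("c", 2, 1000101, 1000200),    # gap exactly 1 Mbp
    base("d", 1, 1, 100), base("d", 2, 1000102, 1000201),    # gap 1,000,001
    base("e", 1, 100, 250),                                  # singleton
    base("f", 1, 300, 151), base("f", 2, 400, 550))          # reverse strand
  out <- concordance_filter(tab)
  expect_setequal(unique(out$read_id), c("a", "c", "f"))
  out_s <- concordance_filter(tab, keep_singletons = TRUE)
  expect_true("e" %in% out_s$read_id)
  expect_false("b" %in% out_s$read_id)  # both mates present, none concordant
})

test_that("concordance filter equals the all-pairs oracle on random tables", {
  for (seed in 1:12) {
    tab <- random_hit_table(60, 5, seed)
    out <- concordance_filter(tab)
    oracle <- concordance_oracle(tab)
    key <- function(d) sort(do.call(paste, as.data.frame(d)))
    expect_identical(key(out), key(oracle))
    out_s <- concordance_filter(tab, keep_singletons = TRUE)
    oracle_s <- concordance_oracle(tab, keep_singletons = TRUE)
    expect_identical(key(out_s), key(oracle_s))
  }
})

test_that("the cascade is monotone, ordered, and logs sum-consistent counts", {
  tree <- livestock_tree()
  conf <- confusion_model(from = tid(tree, "Bos taurus"),
                          to = tid(tree, "Bos mutus"),
                          tie_prob = 0.5, low_prob = 0.2)
  ms <- mixture_spec(setNames(1, tid(tree, "Bos taurus")),
                     read_pairs = 300, seed = 7)
  g <- generate_hit_table(ms, tree, conf,
                          noise = list(singleton = 0.05, discordant = 0.05,
                                       subthreshold = 0.05))
  hits <- read_hits(g$hits)
  res <- filter_hits(hits, filter_params())
  counts <- unlist(res$stage_counts)
  expect_equal(unname(counts["input"]), nrow(hits))
  expect_true(all(diff(counts) <= 0))  # every stage only removes hits
  expect_equal(unname(counts["concordance"]), nrow(res$hits))
  # duplicated input lines are removed once, with a counter
  dup <- rbind(hits, hits[1, ])
  res2 <- filter_hits(dup, filter_params())
  expect_equal(res2$stage_counts$input - res2$stage_counts$deduplicated, 1L)
})
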
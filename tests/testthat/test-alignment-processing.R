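test_that("unique anchor filtering keeps alignments by novel query coverage", {
  one <- mk_aln(query_start = 0, query_end = 20000)
  expect_equal(nrow(filter_unique_anchor(one, 10000)), 1)

  # identical query intervals: only the longer alignment claims the territory
  two <- rbind(
    mk_aln(query_len = 60000, query_start = 0, query_end = 50000,
           aln_len = 50000, ref_id = "r1"),
    mk_aln(query_len = 60000, query_start = 0, query_end = 50000,
           aln_len = 40000, ref_id = "r2"))
  kept <- filter_unique_anchor(two, 10000)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$aln_len, 50000)

  disjoint <- rbind(
    mk_aln(query_len = 50000, query_start = 0, query_end = 20000),
    mk_aln(query_len = 50000, query_start = 30000, query_end = 50000))
  expect_equal(nrow(filter_unique_anchor(disjoint, 10000)), 2)

  expect_equal(nrow(filter_unique_anchor(mk_aln()[0, ], 10000)), 0)

  # property: each kept alignment contributes >= threshold novel bp when
  # replayed against an independent sweep-line union oracle
  set.seed(21)
  for (trial in 1:15) {
    qlen <- 100000L
    n <- sample(2:12, 1)
    aln <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      s <- sample.int(qlen - 1000, 1)
      e <- min(qlen, s + sample(500:40000, 1))
      mk_aln(query_len = qlen, query_start = s, query_end = e,
             ref_id = paste0("r", i))
    }))
    thr <- sample(c(1000, 5000, 10000), 1)
    kept <- filter_unique_anchor(aln, thr)
    ord <- order(-kept$aln_len)
    for (k in seq_along(ord)) {
      prev <- kept[ord[seq_len(k - 1)], ]
      covered <- oracle_union_len(prev$query_start, prev$query_end)
      with_new <- oracle_union_len(c(prev$query_start, kept$query_start[ord[k]]),
                                   c(prev$query_end, kept$query_end[ord[k]]))
      expect_gte(with_new - covered, thr)
    }
  }
})

test_that("mapping-quality filtering applies only when a score is available", {
  aln <- rbind(mk_aln(mapq = 60), mk_aln(mapq = 0), mk_aln(mapq = NA))
  expect_equal(nrow(filter_mapq(aln, 30)), 2)  # 60 kept, 0 removed, NA kept
  expect_equal(nrow(filter_mapq(aln, 1)), 2)
  expect_equal(nrow(filter_mapq(aln, NA)), 3)
})

test_that("block merging joins same-strand neighbours within d and honours the boundary", {
  pair <- function(sep, strand2 = "+") rbind(
    mk_aln(query_len = 300000, query_start = 0, query_end = 100000,
           ref_len = 10^6, ref_start = 0, ref_end = 100000),
    mk_aln(query_len = 300000, query_start = 150000, query_end = 250000,
           strand = strand2, ref_len = 10^6, ref_start = 100000 + sep,
           ref_end = 200000 + sep))
  expect_equal(nrow(merge_blocks(pair(50000), d = 100000)), 1)
  expect_equal(nrow(merge_blocks(pair(100000), d = 100000)), 1)   # inclusive
  expect_equal(nrow(merge_blocks(pair(100001), d = 100000)), 2)
  expect_equal(nrow(merge_blocks(pair(50000, "-"), d = 100000)), 2)

  b <- merge_blocks(pair(50000), d = 100000)
  expect_equal(b$ref_start, 0L)       # minimum coordinate
  expect_equal(b$ref_end, 250000L)    # maximum coordinate
  expect_equal(b$total_aln_bp, 200000)
  expect_equal(b$n_members, 2L)
})

test_that("member counts are conserved and extreme d matches a run oracle", {
  set.seed(33)
  for (trial in 1:15) {
    aln <- dplyr::bind_rows(lapply(seq_len(sample(2:15, 1)), function(i) {
      s <- sample.int(900000, 1)
      mk_aln(query_id = sample(c("qA", "qB"), 1), query_len = 10^6,
             query_start = s, query_end = min(10^6, s + sample(1000:50000, 1)),
             strand = sample(c("+", "-"), 1), ref_id = sample(c("r1", "r2"), 1),
             ref_len = 10^6, ref_start = s,
             ref_end = min(10^6, s + sample(1000:50000, 1) + 10))
    }))
    aln$ref_end <- pmax(aln$ref_end, aln$ref_start + 1L)
    for (d in c(0, 1e9)) {
      blocks <- merge_blocks(aln, d = d, drop_contained = FALSE)
      expect_equal(sum(blocks$n_members), nrow(aln))
      # oracle: runs of (ref_id, strand) in reference-sorted order per query,
      # further split (d = 0) where reference intervals do not touch
      n_expected <- 0L
      for (q in unique(aln$query_id)) {
        a <- aln[aln$query_id == q, ]
        a <- a[order(a$ref_id, a$ref_start, a$ref_end), ]
        runs <- 1L
        cur_end <- a$ref_end[1]
        if (nrow(a) > 1) for (k in 2:nrow(a)) {
          brk <- a$ref_id[k] != a$ref_id[k - 1] || a$strand[k] != a$strand[k - 1]
          if (d == 0) brk <- brk || a$ref_start[k] > cur_end
          if (brk) { runs <- runs + 1L; cur_end <- a$ref_end[k] }
          else cur_end <- max(cur_end, a$ref_end[k])
        }
        n_expected <- n_expected + runs
      }
      expect_equal(nrow(blocks), n_expected)
    }
    # merged blocks are pairwise non-nested on the query axis
    blocks <- merge_blocks(aln, d = 1e5)
    for (q in unique(blocks$query_id)) {
      b <- blocks[blocks$query_id == q, ]
      if (nrow(b) < 2) next
      for (i in seq_len(nrow(b))) for (j in seq_len(nrow(b))) {
        if (i != j) expect_false(b$query_start[j] <= b$query_start[i] &&
                                   b$query_end[i] <= b$query_end[j])
      }
    }
  }
})

test_that("containment removal keeps maximal blocks with a deterministic tie-break", {
  blk <- function(qs, qe, bp, rid = "r", qid = "q") tibble::tibble(
    query_id = qid, ref_id = rid, strand = "+", ref_start = qs, ref_end = qe,
    query_start = qs, query_end = qe, query_len = 10^6L, ref_len = 10^6L,
    n_members = 1L, total_aln_bp = bp, members = list(NULL))
  nested <- rbind(blk(0, 500, 500), blk(0, 100, 100))
  expect_equal(remove_contained(nested, "query")$query_end, 500)
  disjoint <- rbind(blk(0, 100, 100), blk(200, 300, 100))
  expect_equal(nrow(remove_contained(disjoint, "query")), 2)
  ties <- rbind(blk(0, 100, 800, rid = "r1"), blk(0, 100, 900, rid = "r2"))
  expect_equal(remove_contained(ties, "query")$total_aln_bp, 900)

  # brute-force cross-check on random block sets
  set.seed(44)
  for (trial in 1:10) {
    n <- sample(2:10, 1)
    s <- sample.int(1000, n, replace = TRUE)
    b <- dplyr::bind_rows(lapply(seq_len(n), function(i)
      blk(s[i], s[i] + sample.int(500, 1), sample.int(1000, 1),
          rid = paste0("r", i))))
    kept <- remove_contained(b, "query")
    for (i in seq_len(nrow(b))) {
      strictly_contained <- any(vapply(seq_len(nrow(b)), function(j) {
        j != i && b$query_start[j] <= b$query_start[i] &&
          b$query_end[i] <= b$query_end[j] &&
          !(b$query_start[j] == b$query_start[i] && b$query_end[j] == b$query_end[i])
      }, TRUE))
      if (!strictly_contained &&
          sum(b$query_start == b$query_start[i] & b$query_end == b$query_end[i]) == 1) {
        expect_true(b$ref_id[i] %in% kept$ref_id)
      }
    }
  }
})
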
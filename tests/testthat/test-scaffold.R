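blk <- function(qid = "q", rid = "r", strand = "+", rs = 0, re = 1000,
                qs = 0, qe = re - rs, bp = re - rs, qlen = 10^6) {
  tibble::tibble(query_id = qid, ref_id = rid, strand = strand,
                 ref_start = as.integer(rs), ref_end = as.integer(re),
                 query_start = as.integer(qs), query_end = as.integer(qe),
                 query_len = as.integer(qlen), ref_len = 10^7L,
                 n_members = 1L, total_aln_bp = as.numeric(bp),
                 members = list(NULL))
}

test_that("confidence scores are the documented alignment-mass ratios", {
  expect_equal(as.numeric(compute_confidences(blk())[1, 1:3]), c(1, 1, 1))

  # 900 kbp to chr1, 100 kbp to chr2 -> grouping 0.9
  b <- rbind(blk(rid = "chr1", rs = 0, re = 900000, bp = 900000),
             blk(rid = "chr2", rs = 0, re = 100000, bp = 100000))
  expect_equal(compute_confidences(b)$grouping, 0.9)

  # within chr1: 600 kbp '+', 300 kbp '-' -> orientation 2/3
  b <- rbind(blk(rid = "chr1", rs = 0, re = 600000, bp = 600000),
             blk(rid = "chr1", strand = "-", rs = 2e6, re = 2.3e6, bp = 300000))
  cc <- compute_confidences(b)
  expect_equal(cc$orientation, 600000 / 900000)
  # the distant 300-kbp block does not overlap the primary -> location 2/3
  expect_equal(cc$location, 600000 / 900000)

  # scores are invariant under uniform scaling of block mass and span
  scaled <- b
  for (col in c("ref_start", "ref_end", "query_start", "query_end",
                "total_aln_bp")) scaled[[col]] <- scaled[[col]] * 3
  expect_equal(compute_confidences(scaled)[1:3], cc[1:3])

  expect_error(compute_confidences(b[0, ]), "no blocks")
})

test_that("placement orders by primary reference position and demotes weak or nested queries", {
  b <- rbind(blk("q1", rs = 10000, re = 110000),
             blk("q2", rs = 200000, re = 320000),
             blk("q3", rs = 900000, re = 980000))
  pl <- place_queries(b)$placements
  expect_equal(pl$query_id[order(pl$order_index)], c("q1", "q2", "q3"))
  expect_equal(pl$orientation, rep("+", 3))

  # grouping 0.15 below the 0.2 default -> unplaced
  weak <- rbind(blk("w", rid = "chr1", rs = 0, re = 15000, bp = 15000),
                blk("w", rid = "chr2", rs = 0, re = 85000, bp = 85000,
                    qs = 20000, qe = 105000))
  res <- place_queries(weak)
  expect_equal(res$placements$ref_id, "chr2")  # assigned to the 85% reference
  # mass spread over 7 references: best fraction 0.15 < 0.2 -> unplaced
  weak2 <- dplyr::bind_rows(
    blk("w", rid = "chrBest", rs = 0, re = 15000, bp = 15000),
    lapply(1:6, function(i)
      blk("w", rid = paste0("chr", i), rs = 0, re = 14000, bp = 85000 / 6,
          qs = 20000 * i, qe = 20000 * i + 14000)))
  expect_equal(compute_confidences(weak2)$grouping, 0.15)
  res2 <- place_queries(weak2)
  expect_equal(res2$unplaced$reason, "below_confidence_threshold")

  # a primary nested in another query's primary is demoted to unplaced
  nest <- rbind(blk("big", rs = 0, re = 500000, bp = 500000),
                blk("small", rs = 100000, re = 150000, bp = 50000))
  res3 <- place_queries(nest)
  expect_equal(res3$placements$query_id, "big")
  expect_equal(res3$unplaced,
               tibble::tibble(query_id = "small", reason = "contained_primary"))

  # short queries and excluded references are removed before scoring
  res4 <- place_queries(blk("tiny", qlen = 500),
                        scaffold_config(min_contig_len = 1000))
  expect_equal(res4$unplaced$reason, "below_min_contig_len")
  res5 <- place_queries(blk("q", rid = "chr0"),
                        scaffold_config(excluded_refs = "chr0"))
  expect_equal(nrow(res5$placements), 0)
})

test_that("gap-size inference follows the printed formula with retention bounds", {
  aln1 <- list(ref_start = 0, ref_end = 8000, query_start = 0, query_end = 8800)
  aln2 <- list(ref_start = 10000, ref_end = 11000, query_start = 500,
               query_end = 1000)
  gs <- infer_gap_size(aln1, aln2, len_seq1 = 9000)
  expect_equal(gs$size, 1300L)  # (10000 - 500) - (8000 + 9000 - 8800)
  expect_true(gs$known)

  # a computed size of 0 violates the >= 1 bp rule -> 100-bp unknown
  shift <- function(delta) list(ref_start = 10000, ref_end = 11000,
                                query_start = 500 + 1300 - delta,
                                query_end = 1000 + 1300 - delta)
  z <- infer_gap_size(aln1, shift(0), len_seq1 = 9000)
  expect_equal(z, list(size = 100L, known = FALSE))
  expect_false(infer_gap_size(aln1, shift(-5), len_seq1 = 9000)$known)
  expect_true(infer_gap_size(aln1, shift(1), len_seq1 = 9000)$known)

  # too large (above max_gap) is likewise replaced
  big <- infer_gap_size(aln1, shift(100001), len_seq1 = 9000)
  expect_equal(big, list(size = 100L, known = FALSE))
  expect_true(infer_gap_size(aln1, shift(100000), len_seq1 = 9000)$known)

  # '-' orientation flips query coordinates before the formula applies:
  # flipping both sequences of a '+/+' pair must give the same size
  f1 <- list(ref_start = 0, ref_end = 8000, query_start = 9000 - 8800,
             query_end = 9000 - 0)
  gs_flip <- infer_gap_size(f1, aln2, len_seq1 = 9000, orientation1 = "-")
  expect_equal(gs_flip$size, 1300L)
})

test_that("scaffold emission places 100-bp unknown gaps and renders orientation", {
  set.seed(9)
  queries <- c(a = random_dna(10000), b = random_dna(10000), u = random_dna(500))
  placed <- tibble::tibble(
    query_id = c("a", "b"), ref_id = "chr1", order_index = 0:1,
    orientation = c("+", "-"), grouping = 1, location = 1,
    orientation_conf = 1, p_ref_start = c(0L, 20000L),
    p_ref_end = c(10000L, 30000L), p_query_start = 0L, p_query_end = 10000L,
    query_len = 10000L)
  out <- emit_scaffolds(placed, queries)
  expect_equal(nchar(out$seqs[["chr1_scaffold"]]), 20100)
  expect_equal(substr(out$seqs[["chr1_scaffold"]], 10001, 10100),
               strrep("N", 100))
  gaps <- out$agp[out$agp$component_type %in% c("N", "U"), ]
  expect_equal(gaps$component_type, "U")
  expect_equal(gaps$gap_length, 100L)
  expect_equal(gaps$linkage_evidence, "align_genus")
  # '-' component carries the reverse complement
  expect_equal(substr(out$seqs[["chr1_scaffold"]], 10101, 20100),
               revcomp(queries[["b"]]))
  # unplaced query passes through as a singleton
  expect_equal(out$seqs[["u"]], queries[["u"]])
  expect_equal(nrow(validate_agp(out$agp)), 0)

  # no placements: FASTA identical to input
  none <- emit_scaffolds(placed[0, ], queries)
  expect_identical(none$seqs[names(queries)], queries)

  # concatenated unplaced: one object, fixed gaps
  cc <- emit_scaffolds(placed[0, ], queries,
                       scaffold_config(concat_unplaced = TRUE))
  expect_equal(length(cc$seqs), 1)
  expect_equal(nchar(cc$seqs[[1]]), sum(nchar(queries)) + 200)
})

test_that("a fragmented genome is fully recovered with truth gap sizes", {
  genome <- simulate_genome(13, n_chrom = 2, chrom_len = 4e5)
  tr <- fragment_assembly(genome, 14, target_n50 = 4e4, gap_rate = 1,
                          flip_prob = 0.4)
  res <- run_scaffold(tr$contigs, truth_alignments(tr),
                      scaffold_config(gap_policy = "inferred"))
  expect_identical(sort(agp_adjacencies(res$agp)$canonical),
                   sort(agp_adjacencies(tr$truth_agp)$canonical))
  for (ch in names(genome)) {
    truth_gaps <- tr$truth_agp
    truth_gaps <- truth_gaps$gap_length[truth_gaps$object_id == ch &
                                          truth_gaps$component_type %in% c("N", "U")]
    out_gaps <- res$agp
    out_gaps <- out_gaps$gap_length[out_gaps$object_id == paste0(ch, "_scaffold") &
                                      out_gaps$component_type %in% c("N", "U")]
    expect_true(identical(as.integer(out_gaps), as.integer(truth_gaps)) ||
                  identical(as.integer(out_gaps), rev(as.integer(truth_gaps))))
  }
  # every input query id appears exactly once across placed + unplaced rows
  comp_rows <- res$agp$component_id[!res$agp$component_type %in% c("N", "U")]
  expect_equal(sort(comp_rows), sort(names(tr$contigs)))
})
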
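test_that("gap splitting produces seqlets, a registry, and a faithful AGP", {
  set.seed(17)
  gapless <- c(ctg = random_dna(3000))
  sp <- split_at_gaps(gapless)
  expect_identical(sp$seqlets, gapless)
  expect_equal(nrow(sp$registry), 0)

  one <- c(s = paste0(strrep("A", 300), strrep("N", 100), strrep("C", 300)))
  sp1 <- split_at_gaps(one)
  expect_equal(names(sp1$seqlets), c("s:0-300", "s:400-700"))
  expect_equal(sp1$registry$gap_length, 100L)
  expect_equal(sp1$registry$left_seqlet, "s:0-300")

  left <- random_dna(500); mid <- random_dna(400); right <- random_dna(600)
  two <- c(s = paste0(left, strrep("N", 50), mid, strrep("N", 75), right))
  sp2 <- split_at_gaps(two)
  expect_equal(length(sp2$seqlets), 3)
  expect_equal(sp2$registry$gap_length, c(50L, 75L))
  # the split AGP reconstructs the original sequence exactly
  expect_equal(nrow(validate_agp(sp2$agp)), 0)
  expect_identical(build_fasta_from_agp(sp2$agp, sp2$seqlets)[["s"]], two[["s"]])
})

test_that("patch block filtering enforces length, terminus distance, and containment", {
  pblk <- function(rs, re, rlen, qs = 0, qe = re - rs, qlen = 10^6) {
    tibble::tibble(query_id = "q", ref_id = "t", strand = "+",
                   ref_start = as.integer(rs), ref_end = as.integer(re),
                   query_start = as.integer(qs), query_end = as.integer(qe),
                   query_len = as.integer(qlen), ref_len = as.integer(rlen),
                   n_members = 1L, total_aln_bp = as.numeric(re - rs),
                   members = list(NULL))
  }
  cfg <- patch_config()  # -i 10 kbp, -s 50 kbp
  # 60-kbp block ending 1 kbp from the seqlet end: kept
  expect_equal(nrow(filter_patch_blocks(pblk(139000, 199000, 200000), cfg)), 1)
  # one bp short of 50 kbp: removed; exactly 50 kbp: kept
  expect_equal(nrow(filter_patch_blocks(pblk(0, 49999, 200000), cfg)), 0)
  expect_equal(nrow(filter_patch_blocks(pblk(0, 50000, 200000), cfg)), 1)
  # 80-kbp block in the middle of a 1-Mbp seqlet, far from the query ends:
  # implies containment without coverage and is discarded
  expect_equal(nrow(filter_patch_blocks(
    pblk(400000, 480000, 10^6, qs = 400000, qe = 480000), cfg)), 0)
})

test_that("the patch graph stores gap and query evidence with the stated override rules", {
  reg <- tibble::tibble(object_id = "t", left_seqlet = "A", right_seqlet = "B",
                        gap_length = 100L)
  g <- build_patch_graph(reg, merge_blocks(mk_aln()[0, ]), c("A", "B", "C"))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$metadata[[1]]$type, "gap")

  # one query spanning A then B with a 2-kbp inter-block interval
  span <- function(qid, fill = 2000L) rbind(
    mk_aln(query_id = qid, query_len = 202000, query_start = 0,
           query_end = 100000, ref_id = "A", ref_len = 100000,
           ref_start = 0, ref_end = 100000),
    mk_aln(query_id = qid, query_len = 202000, query_start = 100000 + fill,
           query_end = 202000, ref_id = "B", ref_len = 102000 - fill,
           ref_start = 0, ref_end = 102000 - fill))
  blocks <- merge_blocks(span("q1"), d = 1e5)
  g1 <- build_patch_graph(reg[0, ], blocks, c("A", "B"))
  expect_equal(nrow(g1$edges), 1)
  md <- g1$edges$metadata[[1]]
  expect_equal(md$type, "query")
  expect_equal(md$fill_end - md$fill_start, 2000L)

  # query support replaces gap metadata on the same adjacency
  g2 <- build_patch_graph(reg, blocks, c("A", "B", "C"))
  expect_equal(g2$edges$metadata[[which(g2$edges$seq1 %in% c("A", "B") &
                                          g2$edges$seq2 %in% c("A", "B"))]]$type,
               "query")

  # two alignments supporting the same adjacency delete the edge entirely
  both <- merge_blocks(rbind(span("q1"), span("q2")), d = 1e5)
  g3 <- build_patch_graph(reg[0, ], both, c("A", "B"))
  expect_equal(nrow(g3$edges), 0)
})

test_that("patch synthesis fills joins gaplessly, restores gaps, and respects strand", {
  set.seed(29)
  genome1 <- random_dna(260000)
  # target: two seqlets missing the middle 1300 bp; query spans the junction
  A <- substr(genome1, 1, 130000)
  B <- substr(genome1, 131301, 260000)
  target <- c(tA = A, tB = B)
  query <- c(q = substr(genome1, 60000, 200000))  # genome [59999, 200000)
  qlen <- nchar(query[["q"]])                     # 140001 bp
  # exact alignments of q to the two seqlets via shared genome coordinates
  aln <- rbind(
    mk_aln(query_id = "q", query_len = qlen, query_start = 0,
           query_end = 70001, ref_id = "tA", ref_len = 130000,
           ref_start = 59999, ref_end = 130000),
    mk_aln(query_id = "q", query_len = qlen, query_start = 71301,
           query_end = qlen, ref_id = "tB", ref_len = nchar(B),
           ref_start = 0, ref_end = 68700))
  res <- run_patch(target, query, aln,
                   patch_config(min_block_len = 50000, terminus_distance = 10000))
  expect_equal(length(res$seqs), 1)
  joined <- res$seqs[[1]]
  expect_equal(nchar(joined), nchar(A) + 1300 + nchar(B))
  expect_false(grepl("N", joined))
  expect_identical(joined, genome1)
  expect_equal(res$report$source, "query")
  expect_equal(res$report$fill_end - res$report$fill_start, 1300L)

  # identity: an empty query leaves a gapped target untouched
  gapped <- c(s = paste0(A, strrep("N", 137), B))
  res0 <- run_patch(gapped, character(0), mk_aln()[0, ])
  expect_identical(res0$seqs, gapped)
  expect_equal(res0$report$source, "gap")

  # a '-'-strand filler appears reverse-complemented
  query_rc <- c(qr = revcomp(query[["q"]]))
  aln_rc <- aln
  aln_rc$query_id <- "qr"
  aln_rc$strand <- "-"
  qs <- qlen - aln$query_end; qe <- qlen - aln$query_start
  aln_rc$query_start <- qs; aln_rc$query_end <- qe
  res_rc <- run_patch(target, query_rc, aln_rc,
                      patch_config(min_block_len = 50000))
  expect_identical(res_rc$seqs[[1]], genome1)
  expect_equal(res_rc$report$fill_strand, "-")
})

test_that("complementary assemblies restore all broken adjacencies with zero patch distance", {
  genome <- simulate_genome(23, n_chrom = 2, chrom_len = 3e5)
  tr <- fragment_assembly(genome, 24, target_n50 = 4e4, gap_rate = 0.7,
                          flip_prob = 0)
  scaf <- build_fasta_from_agp(tr$truth_agp, tr$contigs)
  n_gaps <- nrow(tr$events[tr$events$type == "gap", ])
  expect_gt(n_gaps, 0)
  sp <- split_at_gaps(scaf)
  query <- stats::setNames(genome, paste0("q_", names(genome)))
  qagp <- dplyr::bind_rows(lapply(names(genome), function(ch)
    agp_obj(ch, list(comp_part(paste0("q_", ch), nchar(genome[[ch]]))))))
  aln <- cross_alignments(qagp, seq_lens(query), sp$agp, seq_lens(sp$seqlets))
  res <- run_patch(scaf, query, aln,
                   patch_config(min_block_len = 10000, terminus_distance = 1000),
                   min_unique_anchor = 5000)
  # all gaps patched: output identical to the truth genome
  expect_identical(res$seqs[names(genome)], genome)
  joins <- res$report[res$report$source == "query", ]
  expect_equal(nrow(joins), n_gaps)
  # joined-sequence + filler coordinates match the truth events exactly
  truth <- tr$events[tr$events$type == "gap", ]
  for (ch in names(genome)) {
    got <- joins[joins$object_id == ch, ]
    got <- got[order(got$left_end), ]
    want <- truth[truth$chrom == ch, ]
    want <- want[order(want$pos), ]
    expect_equal(nrow(got), nrow(want))
    for (k in seq_len(nrow(got))) {
      d <- patch_distance(
        c(got$left_end[k], got$right_start[k], got$fill_start[k], got$fill_end[k]),
        c(want$pos[k], want$pos[k] + want$length[k], want$pos[k],
          want$pos[k] + want$length[k]))
      expect_equal(d, 0)
    }
  }
  # contig N50 never decreases through patching
  expect_gte(nx_statistics(nchar(res$seqs), 50), nx_statistics(nchar(scaf), 50))
})
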
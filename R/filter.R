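#' Unique anchor filtering of alignments
#'
#' Removes repetitive alignments per query: alignments are considered in
#' decreasing `aln_len` order and one is kept only if its query interval
#' contributes at least `min_unique_anchor` bp not already covered by
#' previously kept alignments of that query, so the strongest alignment
#' claims territory first.
#'
#' @param alignments Alignment tibble (see [read_alignments()]).
#' @param min_unique_anchor Minimum novel query bp an alignment must anchor
#'   (default 10000, the canonical unique-anchor length).
#' @return The kept subset, in input row order.
#' @export
filter_unique_anchor <- function(alignments, min_unique_anchor = 10000) {
  if (nrow(alignments) == 0) return(alignments)
  keep <- logical(nrow(alignments))
  for (idx in split(seq_len(nrow(alignments)), alignments$query_id)) {
    ord <- idx[order(-alignments$aln_len[idx])]
    covered <- matrix(numeric(0), ncol = 2)  # disjoint sorted intervals
    for (i in ord) {
      s <- alignments$query_start[i]; e <- alignments$query_end[i]
      novel <- (e - s) - interval_overlap(covered, s, e)
      if (novel >= min_unique_anchor) {
        keep[i] <- TRUE
        covered <- interval_union_add(covered, s, e)
      }
    }
  }
  alignments[keep, ]
}

# total overlap of [s, e) with a set of disjoint intervals (rows: start, end)
interval_overlap <- function(ivs, s, e) {
  if (nrow(ivs) == 0) return(0)
  sum(pmax(0, pmin(ivs[, 2], e) - pmax(ivs[, 1], s)))
}

# add [s, e) to a disjoint sorted interval set, merging as needed
interval_union_add <- function(ivs, s, e) {
  if (nrow(ivs) > 0) {
    hit <- ivs[, 2] >= s & ivs[, 1] <= e
    if (any(hit)) {
      s <- min(s, ivs[hit, 1]); e <- max(e, ivs[hit, 2])
      ivs <- ivs[!hit, , drop = FALSE]
    }
  }
  out <- rbind(ivs, c(s, e))
  out[order(out[, 1]), , drop = FALSE]
}

#' Filter alignments on mapping quality
#'
#' Alignments with a mapping quality below the threshold are removed;
#' alignments lacking a mapping quality (MUMmer delta, PAF mapq 255) are
#' always kept — the rule applies only when a score is available.
#'
#' @param alignments Alignment tibble.
#' @param min_mapq Minimum mapping quality; `NULL`/`NA` disables the filter.
#' @return The kept subset.
#' @export
filter_mapq <- function(alignments, min_mapq) {
  if (is.null(min_mapq) || is.na(min_mapq)) return(alignments)
  alignments[is.na(alignments$mapq) | alignments$mapq >= min_mapq, ]
}

#' Merge alignments into macro-synteny blocks
#'
#' Per query, alignments are sorted by reference position and consecutive
#' alignments on the same reference sequence and strand whose reference
#' intervals are separated by at most `d` bp (overlap counts as 0; the bound
#' is inclusive) are merged, taking the minimum coordinate as the new start
#' and the maximum as the new end on both axes. Merged blocks contained
#' within other merged blocks with respect to query coordinates are then
#' removed.
#'
#' @param alignments Filtered alignment tibble.
#' @param d Maximum reference-coordinate separation in bp (default 100000).
#' @param drop_contained Apply query-axis containment removal (default TRUE).
#' @return A block tibble: `query_id`, `ref_id`, `strand`, `ref_start`,
#'   `ref_end`, `query_start`, `query_end`, `query_len`, `ref_len`,
#'   `n_members`, `total_aln_bp`, `members` (list column of member rows).
#' @export
merge_blocks <- function(alignments, d = 100000, drop_contained = TRUE) {
  stopifnot(d >= 0)
  if (nrow(alignments) == 0) return(empty_blocks())
  out <- list()
  for (idx in split(seq_len(nrow(alignments)), alignments$query_id)) {
    a <- alignments[idx, ]
    a <- a[order(a$ref_id, a$ref_start, a$ref_end), ]
    run_start <- 1L
    flush <- function(i0, i1) {
      m <- a[i0:i1, ]
      out[[length(out) + 1L]] <<- tibble::tibble(
        query_id = m$query_id[1], ref_id = m$ref_id[1], strand = m$strand[1],
        ref_start = min(m$ref_start), ref_end = max(m$ref_end),
        query_start = min(m$query_start), query_end = max(m$query_end),
        query_len = m$query_len[1], ref_len = m$ref_len[1],
        n_members = nrow(m), total_aln_bp = sum(m$aln_len),
        members = list(m)
      )
    }
    if (nrow(a) > 1) {
      cur_end <- a$ref_end[1]
      for (k in 2:nrow(a)) {
        same <- a$ref_id[k] == a$ref_id[k - 1] && a$strand[k] == a$strand[k - 1]
        sep <- max(0, a$ref_start[k] - cur_end)
        if (same && sep <= d) {
          cur_end <- max(cur_end, a$ref_end[k])
        } else {
          flush(run_start, k - 1L)
          run_start <- k
          cur_end <- a$ref_end[k]
        }
      }
    }
    flush(run_start, nrow(a))
  }
  blocks <- dplyr::bind_rows(out)
  if (drop_contained) blocks <- remove_contained(blocks, axis = "query")
  blocks
}

empty_blocks <- function() {
  tibble::tibble(
    query_id = character(), ref_id = character(), strand = character(),
    ref_start = integer(), ref_end = integer(), query_start = integer(),
    query_end = integer(), query_len = integer(), ref_len = integer(),
    n_members = integer(), total_aln_bp = numeric(), members = list()
  )
}

#' Remove blocks contained within other blocks
#'
#' A block is removed when another block's interval contains it on the chosen
#' axis (query intervals are compared within a query; reference intervals
#' within a reference sequence). For identical intervals the block with the
#' larger `total_aln_bp` is kept, then the lexicographically smaller
#' identity.
#'
#' @param blocks Block tibble from [merge_blocks()].
#' @param axis `"query"` or `"reference"`.
#' @return The surviving subset of `blocks`.
#' @export
remove_contained <- function(blocks, axis = c("query", "reference")) {
  axis <- match.arg(axis)
  if (nrow(blocks) < 2) return(blocks)
  if (axis == "query") {
    grp <- blocks$query_id; s <- blocks$query_start; e <- blocks$query_end
  } else {
    grp <- blocks$ref_id; s <- blocks$ref_start; e <- blocks$ref_end
  }
  bid <- paste(blocks$query_id, blocks$ref_id, blocks$strand,
               blocks$query_start, blocks$ref_start, sep = ":")
  drop <- logical(nrow(blocks))
  for (idx in split(seq_len(nrow(blocks)), grp)) {
    for (i in idx) {
      for (j in idx) {
        if (i == j) next
        if (s[j] <= s[i] && e[i] <= e[j]) {
          if (s[j] == s[i] && e[j] == e[i]) {
            # identical intervals: keep larger alignment mass, then smaller id
            wi <- blocks$total_aln_bp[i]; wj <- blocks$total_aln_bp[j]
            if (wj > wi || (wj == wi && bid[j] < bid[i])) drop[i] <- TRUE
          } else {
            drop[i] <- TRUE
          }
        }
      }
    }
  }
  blocks[!drop, ]
}
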
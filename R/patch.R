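# Gap-restoring edges represent adjacencies asserted by the input assembly
# itself, so they outrank any query-derived evidence in the matching.
GAP_EDGE_WEIGHT <- 1e12

#' Configuration for assembly patching
#'
#' @param terminus_distance Maximum distance (bp, default 10000) from a
#'   target seqlet terminus for a merged alignment to count as terminal.
#' @param min_block_len Merged alignments shorter than this are removed
#'   (bp, default 50000).
#' @param max_filler_len Optional cap on the length of query sequence
#'   inserted at a single join (default unlimited); a guard against
#'   misassembled query sequence, not a misassembly detector.
#' @return A list of class `patch_config`.
#' @export
patch_config <- function(terminus_distance = 10000, min_block_len = 50000,
                         max_filler_len = Inf) {
  stopifnot(terminus_distance >= 0, min_block_len >= 0, max_filler_len >= 0)
  structure(list(terminus_distance = terminus_distance,
                 min_block_len = min_block_len,
                 max_filler_len = max_filler_len),
            class = "patch_config")
}

#' Split target sequences at gaps
#'
#' Breaks every target sequence at its maximal `N` runs into gap-free
#' "seqlets" and records the original adjacencies so they can initialise the
#' patch scaffold graph and be restored verbatim when no query evidence
#' replaces them.
#'
#' @param seqs Named character vector of target sequences.
#' @return List with `seqlets` (named character vector; split pieces are
#'   named `<id>:<start>-<end>`, gapless sequences keep their name),
#'   `registry` (tibble: `object_id`, `left_seqlet`, `right_seqlet`,
#'   `gap_length`), and `agp` (seqlet-to-object mapping).
#' @export
split_at_gaps <- function(seqs) {
  seqlets <- list()
  reg <- list()
  agp_rows <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    runs <- gregexpr("[Nn]+", s)[[1]]
    if (runs[1] == -1) {
      seqlets[[id]] <- s
      agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(id, list(
        list(kind = "component", component_id = id, component_beg = 1L,
             component_end = nchar(s), orientation = "+")))
      next
    }
    gs <- as.integer(runs)                      # 1-based gap starts
    ge <- gs + attr(runs, "match.length") - 1L  # 1-based gap ends
    # alternate seqlet / gap segments tiling the sequence
    segs <- list()
    pos <- 1L
    for (r in seq_along(gs)) {
      if (gs[r] > pos) {
        segs[[length(segs) + 1L]] <- list(kind = "seqlet", beg = pos,
                                          end = gs[r] - 1L)
      }
      segs[[length(segs) + 1L]] <- list(kind = "gap", beg = gs[r], end = ge[r])
      pos <- ge[r] + 1L
    }
    if (pos <= nchar(s)) {
      segs[[length(segs) + 1L]] <- list(kind = "seqlet", beg = pos,
                                        end = nchar(s))
    }
    parts <- list()
    prev_seqlet <- NULL  # name of the seqlet immediately left of one gap run
    for (seg in segs) {
      if (seg$kind == "gap") {
        parts[[length(parts) + 1L]] <- list(kind = "gap",
                                            gap_length = seg$end - seg$beg + 1L,
                                            known = TRUE, gap_type = "scaffold",
                                            evidence = "paired-ends")
      } else {
        nm <- sprintf("%s:%d-%d", id, seg$beg - 1L, seg$end)
        seqlets[[nm]] <- substr(s, seg$beg, seg$end)
        if (!is.null(prev_seqlet)) {
          gap_len <- seg$beg - prev_seqlet$end - 1L
          reg[[length(reg) + 1L]] <- tibble::tibble(
            object_id = id, left_seqlet = prev_seqlet$name, right_seqlet = nm,
            gap_length = gap_len)
        }
        parts[[length(parts) + 1L]] <- list(kind = "component",
                                            component_id = nm,
                                            component_beg = 1L,
                                            component_end = seg$end - seg$beg + 1L,
                                            orientation = "+")
        prev_seqlet <- list(name = nm, end = seg$end)
      }
    }
    agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(id, parts)
  }
  registry <- if (length(reg) > 0) dplyr::bind_rows(reg) else
    tibble::tibble(object_id = character(), left_seqlet = character(),
                   right_seqlet = character(), gap_length = integer())
  list(seqlets = unlist(seqlets), registry = registry,
       agp = dplyr::bind_rows(agp_rows))
}

#' Filter merged blocks for patching
#'
#' Keeps a block only if it is at least `min_block_len` long and its target
#' (seqlet) interval lies within `terminus_distance` of a seqlet terminus.
#' Blocks that imply the target should be contained in the query — not near
#' both query termini yet not near either target terminus — are discarded.
#'
#' @param blocks Query-vs-seqlet block tibble from [merge_blocks()].
#' @param cfg A [patch_config()].
#' @return The surviving subset.
#' @export
filter_patch_blocks <- function(blocks, cfg = patch_config()) {
  if (nrow(blocks) == 0) return(blocks)
  i <- cfg$terminus_distance
  len_ok <- (blocks$ref_end - blocks$ref_start) >= cfg$min_block_len
  near_t_begin <- blocks$ref_start <= i
  near_t_end <- (blocks$ref_len - blocks$ref_end) <= i
  near_target <- near_t_begin | near_t_end
  near_q_both <- blocks$query_start <= i &
    (blocks$query_len - blocks$query_end) <= i
  containment_bad <- !near_q_both & !near_target
  blocks[len_ok & near_target & !containment_bad, ]
}

#' Build the directed patch scaffold graph
#'
#' The graph is initialised with the target's original gap adjacencies.
#' Then, per query aligning to more than one seqlet, blocks sorted by query
#' position contribute one edge per adjacent seqlet pair, storing the
#' inter-block query interval as filler metadata. Query metadata replaces
#' gap metadata on an existing edge (the gap will be filled with sequence);
#' an adjacency supported by more than one alignment pair is deleted
#' entirely.
#'
#' @param registry Gap registry from [split_at_gaps()].
#' @param blocks Filtered block tibble from [filter_patch_blocks()].
#' @param seqlet_ids All seqlet ids (graph nodes).
#' @param cfg A [patch_config()].
#' @return A `scaffold_graph`.
#' @export
build_patch_graph <- function(registry, blocks, seqlet_ids,
                              cfg = patch_config()) {
  g <- scaffold_graph(seqlet_ids)
  for (k in seq_len(nrow(registry))) {
    g <- sg_add_edge(g, registry$left_seqlet[k], "end",
                     registry$right_seqlet[k], "begin",
                     weight = GAP_EDGE_WEIGHT,
                     metadata = list(type = "gap",
                                     gap_length = registry$gap_length[k]))
  }
  # collect query-derived adjacency proposals
  props <- list()
  for (idx in split(seq_len(nrow(blocks)), blocks$query_id)) {
    b <- blocks[idx, ]
    if (length(unique(b$ref_id)) < 2) next
    b <- b[order(b$query_start, b$query_end), ]
    for (k in seq_len(nrow(b) - 1L)) {
      cur <- b[k, ]; nxt <- b[k + 1, ]
      if (cur$ref_id == nxt$ref_id) next
      fill_len <- nxt$query_start - cur$query_end
      if (fill_len > cfg$max_filler_len) next
      from <- c(cur$ref_id, if (cur$strand == "+") "end" else "begin")
      to <- c(nxt$ref_id, if (nxt$strand == "+") "begin" else "end")
      props[[length(props) + 1L]] <- tibble::tibble(
        from_seq = from[1], from_side = from[2], to_seq = to[1],
        to_side = to[2], key = edge_key(from[1], from[2], to[1], to[2]),
        query_id = cur$query_id, fill_start = cur$query_end,
        fill_end = nxt$query_start,
        weight = cur$total_aln_bp + nxt$total_aln_bp)
    }
  }
  if (length(props) > 0) {
    props <- dplyr::bind_rows(props)
    support <- table(props$key)
    multi <- names(support)[support > 1]
    for (k in seq_len(nrow(props))) {
      p <- props[k, ]
      if (p$key %in% multi) next
      meta <- list(type = "query", query_id = p$query_id,
                   fill_start = p$fill_start, fill_end = p$fill_end,
                   from = terminus_key(p$from_seq, p$from_side),
                   to = terminus_key(p$to_seq, p$to_side))
      existing <- g$edges$key == p$key
      if (any(existing)) {
        # replace gap metadata; the adjacency keeps its assembly-asserted rank
        g$edges$metadata[[which(existing)]] <- meta
        g$edges$weight[which(existing)] <- GAP_EDGE_WEIGHT + p$weight
      } else {
        g <- sg_add_edge(g, p$from_seq, p$from_side, p$to_seq, p$to_side,
                         weight = p$weight, metadata = meta)
      }
    }
    # an adjacency supported by more than one alignment pair is dropped,
    # gap-initialised or not
    g$edges <- g$edges[!g$edges$key %in% multi, ]
  }
  g
}

#' Assemble patched sequences from a solved patch graph
#'
#' Concatenates each chain: adjacent seqlets joined through query-derived
#' edges receive the supporting query interval (reverse-complemented when
#' the chain traverses the edge against its stored direction) with no `N`
#' introduced; overlapping adjacencies are joined by trimming the start of
#' the downstream seqlet; surviving gap edges re-emit their original `N`
#' run. Chains that reproduce one original object exactly keep its name.
#'
#' @param solution An `sg_solution` from [sg_solve()].
#' @param seqlets Named character vector of target seqlets.
#' @param query Named character vector of query sequences.
#' @param split Result of [split_at_gaps()] (used to restore original names).
#' @return List with `seqs`, `agp` (output objects over seqlets and query
#'   fillers), and `report` (one row per join with output and source
#'   coordinates).
#' @export
synthesize_patches <- function(solution, seqlets, query, split = NULL) {
  meta_by_key <- stats::setNames(solution$matched$metadata, solution$matched$key)
  # original seqlet order per object, to restore names on untouched chains
  orig_order <- NULL
  if (!is.null(split)) {
    comp <- split$agp[!split$agp$component_type %in% c("N", "U"), ]
    orig_order <- lapply(split_keep_order(comp, comp$object_id),
                         function(a) a$component_id[order(a$part_number)])
  }
  out_seqs <- character(0)
  report <- list()
  agp_rows <- list()
  patch_i <- 0L
  for (ch in solution$chains) {
    # name: original object id when the chain is that object, forward
    nm <- NULL
    if (!is.null(orig_order)) {
      for (obj in names(orig_order)) {
        if (identical(ch$seq_id, orig_order[[obj]]) &&
            all(ch$orientation == "+")) {
          nm <- obj
          break
        }
      }
    }
    if (is.null(nm)) {
      if (nrow(ch) == 1 && ch$orientation[1] == "+") {
        nm <- ch$seq_id[1]
      } else {
        patch_i <- patch_i + 1L
        nm <- sprintf("patch%d", patch_i)
      }
    }
    assembled <- ""
    parts <- list()
    for (k in seq_len(nrow(ch))) {
      sid <- ch$seq_id[k]
      piece <- seqlets[[sid]]
      ori <- ch$orientation[k]
      if (ori == "-") piece <- revcomp(piece)
      comp_beg <- 1L
      comp_end <- nchar(seqlets[[sid]])
      if (k > 1) {
        meta <- meta_by_key[[ch$edge_key[k]]]
        prev_len <- nchar(assembled)
        if (identical(meta$type, "gap")) {
          assembled <- paste0(assembled, strrep("N", meta$gap_length))
          parts[[length(parts) + 1L]] <- list(kind = "gap",
                                              gap_length = meta$gap_length,
                                              known = TRUE,
                                              gap_type = "scaffold",
                                              evidence = "paired-ends")
          report[[length(report) + 1L]] <- tibble::tibble(
            object_id = nm, left_seqlet = ch$seq_id[k - 1], right_seqlet = sid,
            left_end = prev_len, right_start = prev_len + meta$gap_length,
            source = "gap", query_id = NA_character_,
            fill_start = NA_integer_, fill_end = NA_integer_,
            fill_strand = NA_character_)
        } else {
          exit_t <- terminus_key(ch$seq_id[k - 1],
                                 if (ch$orientation[k - 1] == "+") "end" else "begin")
          forward <- identical(meta$from, exit_t)
          fl <- meta$fill_end - meta$fill_start
          if (fl > 0) {
            fill <- seq_slice(query[[meta$query_id]], meta$fill_start, meta$fill_end)
            strand <- "+"
            if (!forward) { fill <- revcomp(fill); strand <- "-" }
            assembled <- paste0(assembled, fill)
            parts[[length(parts) + 1L]] <- list(
              kind = "component", component_id = meta$query_id,
              component_beg = meta$fill_start + 1L,
              component_end = meta$fill_end, orientation = strand)
            report[[length(report) + 1L]] <- tibble::tibble(
              object_id = nm, left_seqlet = ch$seq_id[k - 1], right_seqlet = sid,
              left_end = prev_len, right_start = prev_len + fl,
              source = "query", query_id = meta$query_id,
              fill_start = meta$fill_start, fill_end = meta$fill_end,
              fill_strand = strand)
          } else {
            overlap <- -fl
            if (overlap > 0) {
              # trim the start of the downstream (oriented) seqlet
              piece <- substr(piece, overlap + 1L, nchar(piece))
              if (ori == "+") comp_beg <- comp_beg + overlap else
                comp_end <- comp_end - overlap
            }
            report[[length(report) + 1L]] <- tibble::tibble(
              object_id = nm, left_seqlet = ch$seq_id[k - 1], right_seqlet = sid,
              left_end = prev_len, right_start = prev_len,
              source = if (overlap > 0) "overlap" else "abut",
              query_id = meta$query_id, fill_start = meta$fill_start,
              fill_end = meta$fill_end, fill_strand = NA_character_)
          }
        }
      }
      assembled <- paste0(assembled, piece)
      parts[[length(parts) + 1L]] <- list(kind = "component", component_id = sid,
                                          component_beg = comp_beg,
                                          component_end = comp_end,
                                          orientation = ori)
    }
    out_seqs[[nm]] <- assembled
    agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(nm, parts)
  }
  report <- if (length(report) > 0) dplyr::bind_rows(report) else
    tibble::tibble(object_id = character(), left_seqlet = character(),
                   right_seqlet = character(), left_end = integer(),
                   right_start = integer(), source = character(),
                   query_id = character(), fill_start = integer(),
                   fill_end = integer(), fill_strand = character())
  list(seqs = out_seqs, agp = dplyr::bind_rows(agp_rows), report = report)
}

#' Gapless assembly patching pipeline
#'
#' Splits the target at gaps, filters and merges query-vs-seqlet alignments,
#' builds and solves the directed scaffold graph, and assembles the patched
#' sequences. Alignments may be given against the original target
#' sequences, in which case they are projected onto the seqlets first.
#'
#' @param target Named character vector of target sequences.
#' @param query Named character vector of query sequences.
#' @param alignments Query-vs-target (or query-vs-seqlet) alignment tibble.
#' @param cfg A [patch_config()].
#' @param min_unique_anchor,min_mapq,d Alignment filtering/merging
#'   parameters.
#' @return Object of class `patch_result`: `seqs`, `agp`, `report`,
#'   `graph`, `solution`, `seqlets`.
#' @export
run_patch <- function(target, query, alignments, cfg = patch_config(),
                      min_unique_anchor = 10000, min_mapq = NA, d = 100000) {
  sp <- split_at_gaps(target)
  aln <- alignments
  if (nrow(aln) > 0 && !all(aln$ref_id %in% names(sp$seqlets))) {
    aln <- project_alignments_to_seqlets(aln, sp)
  }
  aln <- aln |>
    filter_mapq(min_mapq) |>
    filter_unique_anchor(min_unique_anchor)
  blocks <- merge_blocks(aln, d = d) |>
    filter_patch_blocks(cfg)
  g <- build_patch_graph(sp$registry, blocks, names(sp$seqlets), cfg)
  sol <- sg_solve(g)
  out <- synthesize_patches(sol, sp$seqlets, query, split = sp)
  structure(list(seqs = out$seqs, agp = out$agp, report = out$report,
                 graph = g, solution = sol, seqlets = sp$seqlets),
            class = "patch_result")
}

# Project query-vs-object alignments onto the gap-split seqlets by
# intersecting reference intervals with seqlet intervals; query coordinates
# are interpolated linearly (exact for indel-free alignments).
project_alignments_to_seqlets <- function(aln, split) {
  comp <- split$agp[!split$agp$component_type %in% c("N", "U"), ]
  out <- list()
  for (k in seq_len(nrow(aln))) {
    a <- aln[k, ]
    sls <- comp[comp$object_id == a$ref_id, ]
    if (nrow(sls) == 0) next
    scale <- (a$query_end - a$query_start) / (a$ref_end - a$ref_start)
    for (j in seq_len(nrow(sls))) {
      s0 <- sls$object_beg[j] - 1L; e0 <- sls$object_end[j]
      lo <- max(a$ref_start, s0); hi <- min(a$ref_end, e0)
      if (hi <= lo) next
      slen <- e0 - s0
      if (a$strand == "+") {
        qs <- a$query_start + round((lo - a$ref_start) * scale)
        qe <- a$query_start + round((hi - a$ref_start) * scale)
      } else {
        qs <- a$query_end - round((hi - a$ref_start) * scale)
        qe <- a$query_end - round((lo - a$ref_start) * scale)
      }
      frac <- (hi - lo) / (a$ref_end - a$ref_start)
      out[[length(out) + 1L]] <- tibble::tibble(
        query_id = a$query_id, query_len = a$query_len,
        query_start = as.integer(qs), query_end = as.integer(qe),
        strand = a$strand, ref_id = sls$component_id[j],
        ref_len = as.integer(slen), ref_start = as.integer(lo - s0),
        ref_end = as.integer(hi - s0),
        num_matches = as.integer(round(a$num_matches * frac)),
        aln_len = as.integer(round(a$aln_len * frac)), mapq = a$mapq)
    }
  }
  if (length(out) == 0) return(empty_alignments())
  dplyr::bind_rows(out)
}

#' @export
print.patch_result <- function(x, ...) {
  joins <- sum(x$report$source %in% c("query", "overlap", "abut"))
  cat("<patch_result>", length(x$seqs), "output sequences,", joins,
      "query-supported joins,", sum(x$report$source == "gap"),
      "gaps restored\n")
  invisible(x)
}

#' @export
tidy.patch_result <- function(x, ...) x$report

#' @export
glance.patch_result <- function(x, ...) {
  tibble::tibble(
    n_output = length(x$seqs),
    n_joins = sum(x$report$source %in% c("query", "overlap", "abut")),
    n_gaps_restored = sum(x$report$source == "gap"),
    output_n50 = nx_statistics(nchar(x$seqs), 50)
  )
}
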
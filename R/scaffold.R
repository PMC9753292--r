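#' Configuration for reference-guided scaffolding
#'
#' @param min_grouping,min_location,min_orientation Confidence thresholds in
#'   `[0, 1]` below which a query is left unplaced (defaults 0.2, 0, 0).
#' @param gap_policy `"fixed"` places a 100-bp unknown gap between adjacent
#'   placed queries; `"inferred"` estimates each gap from the flanking
#'   primary alignments.
#' @param min_gap,max_gap Bounds on an inferred gap size in bp. Every
#'   inferred gap must be at least 1 bp; a size below `max(min_gap, 1)` or
#'   above `max_gap` is replaced by the 100-bp unknown placeholder.
#' @param min_contig_len Queries shorter than this are not scaffolded (bp).
#' @param concat_unplaced Concatenate unplaced queries into one object with
#'   fixed gaps instead of emitting singleton objects.
#' @param excluded_refs Reference sequence ids not used to inform
#'   scaffolding.
#' @return A list of class `scaffold_config`.
#' @export
scaffold_config <- function(min_grouping = 0.2, min_location = 0,
                            min_orientation = 0,
                            gap_policy = c("fixed", "inferred"),
                            min_gap = 1, max_gap = 100000,
                            min_contig_len = 0, concat_unplaced = FALSE,
                            excluded_refs = character()) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(min_grouping >= 0, min_grouping <= 1, min_location >= 0,
            min_location <= 1, min_orientation >= 0, min_orientation <= 1,
            min_gap >= 1)
  structure(list(min_grouping = min_grouping, min_location = min_location,
                 min_orientation = min_orientation, gap_policy = gap_policy,
                 min_gap = min_gap, max_gap = max_gap,
                 min_contig_len = min_contig_len,
                 concat_unplaced = concat_unplaced,
                 excluded_refs = excluded_refs),
            class = "scaffold_config")
}

#' Grouping, location and orientation confidence scores for one query
#'
#' The scores measure how unambiguously a query maps to one reference
#' sequence, locus and strand: grouping is the fraction of the query's
#' aligned bp on its best reference sequence; orientation is the fraction of
#' the best-reference bp on the majority strand; location is the fraction of
#' the best-reference bp in blocks overlapping the primary (longest) block's
#' reference interval, including itself. A query with a single block scores
#' (1, 1, 1).
#'
#' @param blocks Block tibble for a single query.
#' @return One-row tibble: `grouping`, `location`, `orientation`, plus the
#'   best reference id (`ref_id`).
#' @export
compute_confidences <- function(blocks) {
  if (nrow(blocks) == 0) stop("no blocks for query")
  by_ref <- tapply(blocks$total_aln_bp, blocks$ref_id, sum)
  best_ref <- names(by_ref)[order(-by_ref, names(by_ref))][1]
  grouping <- by_ref[[best_ref]] / sum(blocks$total_aln_bp)
  br <- blocks[blocks$ref_id == best_ref, ]
  by_strand <- tapply(br$total_aln_bp, br$strand, sum)
  orientation <- max(by_strand) / sum(br$total_aln_bp)
  p <- primary_block(br)
  overlaps <- br$ref_start < p$ref_end & p$ref_start < br$ref_end
  location <- sum(br$total_aln_bp[overlaps]) / sum(br$total_aln_bp)
  tibble::tibble(grouping = unname(grouping), location = unname(location),
                 orientation = unname(orientation), ref_id = best_ref)
}

# the longest block: greatest aligned bp, ties by larger reference span then
# smaller reference start
primary_block <- function(blocks) {
  ord <- order(-blocks$total_aln_bp,
               -(blocks$ref_end - blocks$ref_start), blocks$ref_start)
  blocks[ord[1], ]
}

#' Order and orient queries against a reference
#'
#' Assigns each query to the reference sequence to which it primarily
#' aligns, designates its longest merged block as the primary alignment,
#' removes primaries contained within other primaries on reference
#' coordinates (demoting those queries to unplaced), sorts primaries by
#' reference start per reference sequence to establish the order, and takes
#' each query's orientation from its primary alignment's strand.
#'
#' @param blocks Block tibble from [merge_blocks()] (query vs. reference).
#' @param cfg A [scaffold_config()].
#' @return List with `placements` (tibble: `query_id`, `ref_id`,
#'   `order_index`, `orientation`, the three confidence scores, the primary
#'   block coordinates `p_ref_start`, `p_ref_end`, `p_query_start`,
#'   `p_query_end`, and `query_len`) and `unplaced` (tibble: `query_id`,
#'   `reason`).
#' @export
place_queries <- function(blocks, cfg = scaffold_config()) {
  unplaced <- list()
  mark <- function(id, why) {
    unplaced[[length(unplaced) + 1L]] <<- tibble::tibble(query_id = id, reason = why)
  }
  blocks <- blocks[!blocks$ref_id %in% cfg$excluded_refs, ]
  cand <- list()
  for (idx in split(seq_len(nrow(blocks)), blocks$query_id)) {
    b <- blocks[idx, ]
    qid <- b$query_id[1]
    if (b$query_len[1] < cfg$min_contig_len) {
      mark(qid, "below_min_contig_len")
      next
    }
    conf <- compute_confidences(b)
    if (conf$grouping < cfg$min_grouping || conf$location < cfg$min_location ||
        conf$orientation < cfg$min_orientation) {
      mark(qid, "below_confidence_threshold")
      next
    }
    p <- primary_block(b[b$ref_id == conf$ref_id, ])
    cand[[length(cand) + 1L]] <- dplyr::mutate(
      p, grouping = conf$grouping, location = conf$location,
      orientation_conf = conf$orientation)
  }
  placements <- tibble::tibble(
    query_id = character(), ref_id = character(), order_index = integer(),
    orientation = character(), grouping = numeric(), location = numeric(),
    orientation_conf = numeric(), p_ref_start = integer(),
    p_ref_end = integer(), p_query_start = integer(),
    p_query_end = integer(), query_len = integer())
  if (length(cand) > 0) {
    primaries <- dplyr::bind_rows(cand)
    kept <- remove_contained(primaries, axis = "reference")
    for (qid in setdiff(primaries$query_id, kept$query_id)) {
      mark(qid, "contained_primary")
    }
    placements <- kept |>
      dplyr::group_by(.data$ref_id) |>
      dplyr::arrange(.data$ref_start, -(.data$ref_end - .data$ref_start),
                     .data$query_id, .by_group = TRUE) |>
      dplyr::mutate(order_index = dplyr::row_number() - 1L) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        query_id = .data$query_id, ref_id = .data$ref_id,
        order_index = .data$order_index, orientation = .data$strand,
        grouping = .data$grouping, location = .data$location,
        orientation_conf = .data$orientation_conf,
        p_ref_start = .data$ref_start, p_ref_end = .data$ref_end,
        p_query_start = .data$query_start, p_query_end = .data$query_end,
        query_len = .data$query_len)
  }
  unplaced <- if (length(unplaced) > 0) dplyr::bind_rows(unplaced) else
    tibble::tibble(query_id = character(), reason = character())
  list(placements = placements, unplaced = unplaced)
}

#' Infer the gap size between two adjacent placed queries
#'
#' Evaluates `(aln2_rs - aln2_qs) - (aln1_re + len(seq1) - aln1_qe)` on the
#' primary alignments of the upstream (`aln1`) and downstream (`aln2`)
#' queries. Query coordinates of reverse-oriented placements are flipped to
#' scaffold orientation before the formula is applied. Every inferred gap
#' must be at least 1 bp: a size below `max(min_gap, 1)` or above `max_gap`
#' is replaced with the 100-bp "unknown" placeholder.
#'
#' @param aln1,aln2 Primary alignments (lists or one-row tibbles with
#'   `ref_start`, `ref_end`, `query_start`, `query_end`), upstream and
#'   downstream respectively.
#' @param len_seq1 Length of the upstream query in bp.
#' @param min_gap,max_gap Retention bounds in bp (defaults 1 and 100000).
#' @param orientation1,orientation2 Placement orientations; `-` flips that
#'   alignment's query coordinates.
#' @param len_seq2 Length of the downstream query (required when
#'   `orientation2 == "-"`).
#' @return List with `size` (bp) and `known` (FALSE when the placeholder was
#'   substituted).
#' @export
infer_gap_size <- function(aln1, aln2, len_seq1, min_gap = 1, max_gap = 100000,
                           orientation1 = "+", orientation2 = "+",
                           len_seq2 = NULL) {
  flip <- function(a, len) {
    list(ref_start = a$ref_start, ref_end = a$ref_end,
         query_start = len - a$query_end, query_end = len - a$query_start)
  }
  if (identical(orientation1, "-")) aln1 <- flip(aln1, len_seq1)
  if (identical(orientation2, "-")) {
    if (is.null(len_seq2)) stop("len_seq2 required for '-' oriented aln2")
    aln2 <- flip(aln2, len_seq2)
  }
  size <- (aln2$ref_start - aln2$query_start) -
    (aln1$ref_end + len_seq1 - aln1$query_end)
  if (size < max(min_gap, 1) || size > max_gap) {
    list(size = 100L, known = FALSE)
  } else {
    list(size = as.integer(size), known = TRUE)
  }
}

#' Emit scaffolds from placements
#'
#' Builds one AGP object per reference group with components in placement
#' order and gap rows between adjacent components, then renders the scaffold
#' sequences. Unplaced queries become singleton objects, or one concatenated
#' object when `concat_unplaced`.
#'
#' @param placed `placements` tibble from [place_queries()].
#' @param queries Named character vector of query sequences.
#' @param cfg A [scaffold_config()].
#' @param unplaced_ids Query ids to pass through unplaced (defaults to every
#'   query without a placement).
#' @return List with `agp` and `seqs`.
#' @export
emit_scaffolds <- function(placed, queries, cfg = scaffold_config(),
                           unplaced_ids = NULL) {
  lens <- seq_lens(queries)
  if (is.null(unplaced_ids)) unplaced_ids <- setdiff(names(queries), placed$query_id)
  agp_rows <- list()
  for (rid in unique(placed$ref_id)) {
    p <- placed[placed$ref_id == rid, ]
    p <- p[order(p$order_index), ]
    parts <- list()
    for (k in seq_len(nrow(p))) {
      if (k > 1) {
        if (cfg$gap_policy == "inferred") {
          up <- p[k - 1, ]; dn <- p[k, ]
          gs <- infer_gap_size(
            list(ref_start = up$p_ref_start, ref_end = up$p_ref_end,
                 query_start = up$p_query_start, query_end = up$p_query_end),
            list(ref_start = dn$p_ref_start, ref_end = dn$p_ref_end,
                 query_start = dn$p_query_start, query_end = dn$p_query_end),
            len_seq1 = lens[[up$query_id]], min_gap = cfg$min_gap,
            max_gap = cfg$max_gap, orientation1 = up$orientation,
            orientation2 = dn$orientation, len_seq2 = lens[[dn$query_id]])
          parts[[length(parts) + 1L]] <- list(kind = "gap", gap_length = gs$size,
                                              known = gs$known,
                                              evidence = "align_genus")
        } else {
          parts[[length(parts) + 1L]] <- list(kind = "gap", gap_length = 100L,
                                              known = FALSE,
                                              evidence = "align_genus")
        }
      }
      parts[[length(parts) + 1L]] <- list(
        kind = "component", component_id = p$query_id[k], component_beg = 1L,
        component_end = lens[[p$query_id[k]]], orientation = p$orientation[k])
    }
    agp_rows[[length(agp_rows) + 1L]] <-
      assemble_agp_object(paste0(rid, "_scaffold"), parts)
  }
  if (length(unplaced_ids) > 0) {
    if (isTRUE(cfg$concat_unplaced)) {
      parts <- list()
      for (k in seq_along(unplaced_ids)) {
        if (k > 1) {
          parts[[length(parts) + 1L]] <- list(kind = "gap", gap_length = 100L,
                                              known = FALSE,
                                              evidence = "align_genus")
        }
        parts[[length(parts) + 1L]] <- list(
          kind = "component", component_id = unplaced_ids[k],
          component_beg = 1L, component_end = lens[[unplaced_ids[k]]],
          orientation = "+")
      }
      agp_rows[[length(agp_rows) + 1L]] <-
        assemble_agp_object("unplaced_scaffold", parts)
    } else {
      for (id in unplaced_ids) {
        agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(id, list(
          list(kind = "component", component_id = id, component_beg = 1L,
               component_end = lens[[id]], orientation = "+")))
      }
    }
  }
  agp <- dplyr::bind_rows(agp_rows)
  list(agp = agp, seqs = build_fasta_from_agp(agp, queries))
}

#' Reference-guided scaffolding pipeline
#'
#' Filters and merges query-vs-reference alignments, scores and places the
#' queries, and emits the scaffold AGP and FASTA.
#'
#' @param query Named character vector of query sequences.
#' @param alignments Query-vs-reference alignment tibble.
#' @param cfg A [scaffold_config()].
#' @param min_unique_anchor,min_mapq,d Alignment filtering/merging
#'   parameters.
#' @return Object of class `scaffold_result`: `agp`, `seqs`, `placements`,
#'   `unplaced`, `blocks`.
#' @export
run_scaffold <- function(query, alignments, cfg = scaffold_config(),
                         min_unique_anchor = 10000, min_mapq = NA, d = 100000) {
  aln <- alignments |>
    filter_mapq(min_mapq) |>
    filter_unique_anchor(min_unique_anchor)
  blocks <- merge_blocks(aln, d = d)
  pq <- place_queries(blocks, cfg)
  no_aln <- setdiff(names(query), c(pq$placements$query_id, pq$unplaced$query_id))
  if (length(no_aln) > 0) {
    pq$unplaced <- dplyr::bind_rows(
      pq$unplaced, tibble::tibble(query_id = no_aln, reason = "no_alignments"))
  }
  out <- emit_scaffolds(pq$placements, query, cfg,
                        unplaced_ids = setdiff(names(query), pq$placements$query_id))
  structure(list(agp = out$agp, seqs = out$seqs, placements = pq$placements,
                 unplaced = pq$unplaced, blocks = blocks),
            class = "scaffold_result")
}

#' @export
print.scaffold_result <- function(x, ...) {
  cat("<scaffold_result>", nrow(x$placements), "placed,",
      nrow(x$unplaced), "unplaced,", length(x$seqs), "output sequences\n")
  invisible(x)
}

#' @export
tidy.scaffold_result <- function(x, ...) x$placements

#' @export
glance.scaffold_result <- function(x, ...) {
  tibble::tibble(
    n_placed = nrow(x$placements),
    n_unplaced = nrow(x$unplaced),
    n_objects = length(unique(x$agp$object_id)),
    output_n50 = nx_statistics(nchar(x$seqs), 50)
  )
}

#' Plot query placements along the reference
#'
#' Draws each placed query's primary alignment interval on its reference
#' sequence, coloured by orientation — a quick visual check of scaffold
#' order and strand assignment.
#'
#' @param object A `scaffold_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaffold_result <- function(object, ...) {
  p <- object$placements
  ggplot2::ggplot(p, ggplot2::aes(y = .data$ref_id)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$p_ref_start, xend = .data$p_ref_end,
      yend = .data$ref_id, colour = .data$orientation),
      linewidth = 4, lineend = "butt") +
    ggplot2::labs(x = "reference position (bp)", y = NULL,
                  colour = "orientation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
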
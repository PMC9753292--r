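#' Configuration for scaffold-solution merging
#'
#' @param min_component_len Components shorter than this (bp, default
#'   100000) are treated as unmergeable singletons: their adjacencies
#'   contribute no edges and they are passed through unchanged.
#' @param restriction_patterns Degenerate-base restriction motifs used to
#'   normalise Hi-C link counts, e.g.
#'   `c("GATC", "GA[ATCG]TC", "CT[ATCG]AG", "TTAA")` for the Arima kit.
#' @param terminal_window Size (bp) of the terminal window of each component
#'   in which Hi-C contacts and restriction sites are counted; capped at
#'   half the component length (default 1e6).
#' @return A list of class `merge_config`.
#' @export
merge_config <- function(min_component_len = 100000,
                         restriction_patterns = c("GATC", "GA[ATCG]TC",
                                                  "CT[ATCG]AG", "TTAA"),
                         terminal_window = 1e6) {
  stopifnot(min_component_len >= 0, terminal_window > 0)
  structure(list(min_component_len = min_component_len,
                 restriction_patterns = restriction_patterns,
                 terminal_window = terminal_window),
            class = "merge_config")
}

#' Build the merge scaffold graph from AGP solutions
#'
#' Every input AGP must order and orient the same component set. For each
#' AGP and each pair of adjacent components, an edge between the facing
#' termini is added (or its weight incremented) by that AGP's weight, with
#' the contributing sources recorded as metadata.
#'
#' @param agps Named list of AGP tibbles (names identify the sources).
#' @param weights Numeric vector of per-source weights (default 1 each).
#' @param component_lens Named vector of component lengths in bp (required
#'   when `min_component_len` filtering applies; defaults to spans seen in
#'   the AGPs).
#' @param cfg A [merge_config()].
#' @return A `scaffold_graph` whose nodes are the component termini.
#' @export
build_merge_graph <- function(agps, weights = NULL, component_lens = NULL,
                              cfg = merge_config()) {
  if (is.null(names(agps))) names(agps) <- paste0("agp", seq_along(agps))
  if (is.null(weights)) weights <- rep(1, length(agps))
  stopifnot(length(weights) == length(agps), all(weights > 0))
  comp_sets <- lapply(agps, function(a)
    sort(unique(a$component_id[!a$component_type %in% c("N", "U")])))
  base <- comp_sets[[1]]
  for (k in seq_along(comp_sets)[-1]) {
    if (!identical(comp_sets[[k]], base)) {
      diffs <- c(setdiff(base, comp_sets[[k]]), setdiff(comp_sets[[k]], base))
      stop("AGP solutions do not order the same component set; differing: ",
           paste(diffs, collapse = ", "))
    }
  }
  if (is.null(component_lens)) component_lens <- component_lens_from_agp(agps[[1]])
  mergeable <- base[component_lens[base] >= cfg$min_component_len]
  g <- scaffold_graph(base)
  for (k in seq_along(agps)) {
    adj <- agp_adjacencies(agps[[k]])
    for (r in seq_len(nrow(adj))) {
      if (!adj$left_id[r] %in% mergeable || !adj$right_id[r] %in% mergeable) next
      from_side <- if (adj$left_or[r] == "+") "end" else "begin"
      to_side <- if (adj$right_or[r] == "+") "begin" else "end"
      g <- sg_add_edge(g, adj$left_id[r], from_side, adj$right_id[r], to_side,
                       weight = weights[k],
                       metadata = list(support = names(agps)[k]),
                       policy = "increment",
                       merge_metadata = function(old, new)
                         list(support = c(old$support, new$support)))
    }
  }
  g
}

component_lens_from_agp <- function(agp) {
  comp <- agp[!agp$component_type %in% c("N", "U"), ]
  spans <- tapply(comp$component_end, comp$component_id, max)
  stats::setNames(as.integer(spans), names(spans))
}

#' Count restriction-site motif matches
#'
#' Counts forward-strand match positions of each degenerate motif
#' (overlapping matches allowed), summed over motifs. Motifs may use
#' `[...]` character classes over A, C, G, T.
#'
#' @param sequence A nucleotide string.
#' @param patterns Character vector of motifs.
#' @return Integer match count.
#' @export
count_restriction_sites <- function(sequence, patterns) {
  if (any(!grepl("^(\\[[ACGT]+\\]|[ACGT])+$", patterns))) {
    stop("invalid restriction motif syntax")
  }
  if (nchar(sequence) == 0) return(0L)
  sum(vapply(patterns, function(p) {
    hits <- gregexpr(paste0("(?=", p, ")"), toupper(sequence), perl = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }, 0L))
}

#' Replace merge-graph weights with Hi-C scores
#'
#' For each edge the Hi-C score h is the number of contacts with one end in
#' each terminus' terminal window, normalised by the total restriction-site
#' count in the two windows (floored at 1). Native AGP-vote weights are
#' replaced; support metadata is retained. Contact counting is symmetric in
#' the pair order.
#'
#' @param g A `scaffold_graph` from [build_merge_graph()].
#' @param contacts Tibble of Hi-C contacts: `comp_a`, `pos_a`, `comp_b`,
#'   `pos_b` (0-based positions within components).
#' @param components Named character vector of component sequences.
#' @param cfg A [merge_config()].
#' @return The re-weighted graph.
#' @export
reweight_with_hic <- function(g, contacts, components, cfg = merge_config()) {
  lens <- seq_lens(components)
  stopifnot(all(contacts$comp_a %in% names(lens)),
            all(contacts$comp_b %in% names(lens)),
            all(contacts$pos_a >= 0 & contacts$pos_a < lens[contacts$comp_a]),
            all(contacts$pos_b >= 0 & contacts$pos_b < lens[contacts$comp_b]))
  win <- function(seq_id, side) {
    w <- min(floor(lens[[seq_id]] / 2), cfg$terminal_window)
    if (side == "begin") c(0, w) else c(lens[[seq_id]] - w, lens[[seq_id]])
  }
  in_win <- function(comp, pos, seq_id, side) {
    wv <- win(seq_id, side)
    comp == seq_id & pos >= wv[1] & pos < wv[2]
  }
  site_count <- function(seq_id, side) {
    wv <- win(seq_id, side)
    count_restriction_sites(substr(components[[seq_id]], wv[1] + 1, wv[2]),
                            cfg$restriction_patterns)
  }
  for (r in seq_len(nrow(g$edges))) {
    e <- g$edges[r, ]
    links <- sum(
      (in_win(contacts$comp_a, contacts$pos_a, e$seq1, e$side1) &
         in_win(contacts$comp_b, contacts$pos_b, e$seq2, e$side2)) |
      (in_win(contacts$comp_a, contacts$pos_a, e$seq2, e$side2) &
         in_win(contacts$comp_b, contacts$pos_b, e$seq1, e$side1)))
    denom <- max(site_count(e$seq1, e$side1) + site_count(e$seq2, e$side2), 1)
    g$edges$weight[r] <- links / denom
  }
  g
}

#' Emit a merged AGP from a solved merge graph
#'
#' Each multi-component chain becomes one AGP object with 100-bp unknown
#' gaps between components (linkage evidence `proximity_ligation` when the
#' graph was Hi-C-weighted, `align_genus` otherwise); unmerged components
#' are output as unmodified singleton objects.
#'
#' @param solution An `sg_solution`.
#' @param component_lens Named vector of component lengths.
#' @param hic Logical: was the graph Hi-C re-weighted?
#' @return A merged AGP tibble.
#' @export
emit_merged_agp <- function(solution, component_lens, hic = FALSE) {
  evidence <- if (hic) "proximity_ligation" else "align_genus"
  agp_rows <- list()
  scaf_i <- 0L
  for (ch in solution$chains) {
    if (nrow(ch) == 1) {
      id <- ch$seq_id[1]
      agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(id, list(
        list(kind = "component", component_id = id, component_beg = 1L,
             component_end = component_lens[[id]], orientation = "+")))
      next
    }
    scaf_i <- scaf_i + 1L
    parts <- list()
    for (k in seq_len(nrow(ch))) {
      if (k > 1) {
        parts[[length(parts) + 1L]] <- list(kind = "gap", gap_length = 100L,
                                            known = FALSE, evidence = evidence)
      }
      parts[[length(parts) + 1L]] <- list(
        kind = "component", component_id = ch$seq_id[k], component_beg = 1L,
        component_end = component_lens[[ch$seq_id[k]]],
        orientation = ch$orientation[k])
    }
    agp_rows[[length(agp_rows) + 1L]] <-
      assemble_agp_object(sprintf("merged_scaffold_%d", scaf_i), parts)
  }
  dplyr::bind_rows(agp_rows)
}

#' Scaffold-solution reconciliation pipeline
#'
#' Builds the AGP-vote scaffold graph, optionally replaces its weights with
#' Hi-C scores, solves it by maximum-weight matching with cycle breaking,
#' and emits the merged AGP (and FASTA when component sequences are given).
#'
#' @param agps Named list of AGP tibbles over the same component set.
#' @param components Named character vector of component sequences
#'   (optional unless `contacts` is given).
#' @param weights Per-source AGP weights (default 1 each).
#' @param contacts Optional Hi-C contact tibble (see [reweight_with_hic()]);
#'   when given, edge weights are replaced by Hi-C scores.
#' @param cfg A [merge_config()].
#' @return Object of class `merge_result`: `agp`, `seqs` (NULL without
#'   component sequences), `graph`, `solution`.
#' @export
run_merge <- function(agps, components = NULL, weights = NULL,
                      contacts = NULL, cfg = merge_config()) {
  component_lens <- if (!is.null(components)) seq_lens(components) else
    component_lens_from_agp(agps[[1]])
  g <- build_merge_graph(agps, weights, component_lens, cfg)
  hic <- !is.null(contacts)
  if (hic) {
    if (is.null(components)) stop("component sequences required for Hi-C re-weighting")
    g <- reweight_with_hic(g, contacts, components, cfg)
  }
  sol <- sg_solve(g)
  agp <- emit_merged_agp(sol, component_lens, hic = hic)
  seqs <- if (!is.null(components)) build_fasta_from_agp(agp, components) else NULL
  structure(list(agp = agp, seqs = seqs, graph = g, solution = sol),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat("<merge_result>", length(unique(x$agp$object_id)), "objects from",
      length(x$graph$seqs), "components\n")
  invisible(x)
}

#' @export
tidy.merge_result <- function(x, ...) agp_adjacencies(x$agp)

#' @export
glance.merge_result <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$graph$seqs),
    n_objects = length(unique(x$agp$object_id)),
    n_adjacencies = nrow(agp_adjacencies(x$agp)),
    matched_weight = sum(x$solution$matched$weight)
  )
}
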
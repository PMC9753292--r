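#' Create an empty scaffold graph
#'
#' A scaffold graph has two nodes per sequence — the begin and end termini —
#' and weighted edges between termini of distinct sequences representing
#' putative adjacencies. The two termini of one sequence are implicitly
#' paired (a sequence is traversed end to end) and are never joined by an
#' explicit edge.
#'
#' @param sequence_ids Character vector of sequence identifiers.
#' @return An object of class `scaffold_graph`.
#' @export
scaffold_graph <- function(sequence_ids = character()) {
  if (anyDuplicated(sequence_ids)) stop("duplicate sequence ids")
  structure(
    list(
      seqs = as.character(sequence_ids),
      edges = empty_sg_edges()
    ),
    class = "scaffold_graph"
  )
}

empty_sg_edges <- function() {
  tibble::tibble(
    seq1 = character(), side1 = character(), seq2 = character(),
    side2 = character(), key = character(), weight = numeric(),
    metadata = list()
  )
}

terminus_key <- function(seq, side) paste0(seq, "\x01", side)

edge_key <- function(seq1, side1, seq2, side2) {
  a <- terminus_key(seq1, side1); b <- terminus_key(seq2, side2)
  ifelse(a <= b, paste(a, b, sep = "\x02"), paste(b, a, sep = "\x02"))
}

#' Add or update a scaffold-graph edge
#'
#' @param g A `scaffold_graph`.
#' @param seq1,side1,seq2,side2 The two termini; `side` is `"begin"` or
#'   `"end"`. Both sequences must already be in the graph and must differ.
#' @param weight Nonnegative edge weight.
#' @param metadata Arbitrary provenance list (gap, patch filler, AGP support,
#'   Hi-C score) stored with the edge.
#' @param policy What to do when the edge already exists: `"error"`,
#'   `"increment"` (add weights, keep/append metadata via `merge_metadata`),
#'   or `"replace"`.
#' @param merge_metadata Optional function(old, new) combining metadata under
#'   the `"increment"` policy; default keeps the old metadata.
#' @return The updated graph.
#' @export
sg_add_edge <- function(g, seq1, side1, seq2, side2, weight, metadata = NULL,
                        policy = c("error", "increment", "replace"),
                        merge_metadata = NULL) {
  policy <- match.arg(policy)
  stopifnot(side1 %in% c("begin", "end"), side2 %in% c("begin", "end"),
            weight >= 0)
  if (identical(seq1, seq2)) {
    stop("edge joins the two termini of the same sequence: ", seq1)
  }
  if (!seq1 %in% g$seqs || !seq2 %in% g$seqs) {
    stop("unknown sequence id: ", setdiff(c(seq1, seq2), g$seqs)[1])
  }
  k <- edge_key(seq1, side1, seq2, side2)
  hit <- which(g$edges$key == k)
  if (length(hit) == 0) {
    g$edges <- dplyr::bind_rows(g$edges, tibble::tibble(
      seq1 = seq1, side1 = side1, seq2 = seq2, side2 = side2, key = k,
      weight = as.numeric(weight), metadata = list(metadata)
    ))
  } else if (policy == "error") {
    stop("edge already exists: ", seq1, ".", side1, " -- ", seq2, ".", side2)
  } else if (policy == "increment") {
    g$edges$weight[hit] <- g$edges$weight[hit] + weight
    if (!is.null(merge_metadata)) {
      g$edges$metadata[[hit]] <- merge_metadata(g$edges$metadata[[hit]], metadata)
    }
  } else {
    g$edges$weight[hit] <- as.numeric(weight)
    g$edges$metadata[hit] <- list(metadata)
  }
  g
}

#' Remove a scaffold-graph edge
#' @param g A `scaffold_graph`.
#' @param seq1,side1,seq2,side2 The edge's termini.
#' @return The updated graph.
#' @export
sg_remove_edge <- function(g, seq1, side1, seq2, side2) {
  k <- edge_key(seq1, side1, seq2, side2)
  g$edges <- g$edges[g$edges$key != k, ]
  g
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat("<scaffold_graph>", length(x$seqs), "sequences,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.scaffold_graph <- function(x, ...) {
  dplyr::select(x$edges, "seq1", "side1", "seq2", "side2", "weight")
}

#' @export
glance.scaffold_graph <- function(x, ...) {
  tibble::tibble(
    n_sequences = length(x$seqs),
    n_edges = nrow(x$edges),
    total_weight = sum(x$edges$weight)
  )
}

# ---- exact maximum-weight matching -----------------------------------------

# Exact maximum-weight matching over the edge tibble. Returns integer row
# indices of matched edges. Deterministic: ties between equal-weight optima
# are broken toward the lexicographically smallest sorted edge-key vector.
# Solved independently per connected component with a memoised include/
# exclude recursion; edges are visited in breadth-first order so that the
# live frontier (and hence the memo) stays small on the sparse, chain-like
# components that scaffold graphs produce.
sg_matching <- function(edges) {
  if (nrow(edges) == 0) return(integer(0))
  ta <- terminus_key(edges$seq1, edges$side1)
  tb <- terminus_key(edges$seq2, edges$side2)
  nodes <- sort(unique(c(ta, tb)))
  ia <- match(ta, nodes); ib <- match(tb, nodes)
  comp <- connected_components(length(nodes), ia, ib)
  matched <- integer(0)
  for (cid in sort(unique(comp))) {
    eidx <- which(comp[ia] == cid)
    matched <- c(matched, eidx[match_component(edges$weight[eidx],
                                               edges$key[eidx],
                                               ia[eidx], ib[eidx])])
  }
  sort(matched)
}

connected_components <- function(n, ia, ib) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, 1L)
}

match_component <- function(w, keys, ia, ib) {
  m <- length(w)
  # breadth-first edge order from the smallest node keeps memo states local
  ord <- bfs_edge_order(ia, ib)
  w <- w[ord]; keys <- keys[ord]; ia <- ia[ord]; ib <- ib[ord]
  # nodes still referenced by edges at position >= i
  future <- vector("list", m + 1L)
  future[[m + 1L]] <- integer(0)
  for (i in m:1) future[[i]] <- union(future[[i + 1L]], c(ia[i], ib[i]))
  tol <- 1e-9
  weq <- function(a, b) abs(a - b) <= tol * max(1, abs(a), abs(b))
  memo <- new.env(parent = emptyenv())
  best <- function(i, used) {
    if (i > m) return(list(w = 0, sel = integer(0)))
    live <- intersect(used, future[[i]])
    kmemo <- paste(i, paste(sort(live), collapse = ","), sep = "|")
    hit <- memo[[kmemo]]
    if (!is.null(hit)) return(hit)
    res <- best(i + 1L, live)                              # exclude edge i
    if (!(ia[i] %in% live) && !(ib[i] %in% live)) {        # include edge i
      sub <- best(i + 1L, c(live, ia[i], ib[i]))
      cand <- list(w = w[i] + sub$w, sel = c(i, sub$sel))
      if (cand$w > res$w + tol * max(1, abs(cand$w)) ||
          (weq(cand$w, res$w) && prefer_keys(keys[cand$sel], keys[res$sel]))) {
        res <- cand
      }
    }
    memo[[kmemo]] <- res
    res
  }
  ord[best(1L, integer(0))$sel]
}

bfs_edge_order <- function(ia, ib) {
  m <- length(ia)
  adj <- split(seq_len(2 * m), c(ia, ib))  # positions; >m means ib side
  seen_node <- new.env(parent = emptyenv())
  seen_edge <- logical(m)
  ord <- integer(0)
  queue <- as.character(sort(unique(c(ia, ib)))[1])
  seen_node[[queue]] <- TRUE
  while (length(queue) > 0) {
    node <- queue[1]; queue <- queue[-1]
    pos <- adj[[node]]
    es <- unique(ifelse(pos > m, pos - m, pos))
    for (e in sort(es)) {
      if (!seen_edge[e]) {
        seen_edge[e] <- TRUE
        ord <- c(ord, e)
        for (nb in as.character(c(ia[e], ib[e]))) {
          if (is.null(seen_node[[nb]])) {
            seen_node[[nb]] <- TRUE
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  ord
}

# prefer a's sorted key vector lexicographically; a longer matching wins a
# prefix tie
prefer_keys <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- min(length(a), length(b))
  if (n > 0) {
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
  }
  length(a) > length(b)
}

# ---- solving ---------------------------------------------------------------

#' Solve a scaffold graph into ordered, oriented chains
#'
#' Computes an exact maximum-weight matching over the inter-sequence edges,
#' overlays the matched adjacencies on the implicit intra-sequence pairings,
#' breaks any resulting cycle by removing its lowest-weight matched edge
#' (ties: lexicographically smallest edge key), and walks the remaining
#' simple paths into chains. A chain enters each sequence at one terminus
#' and leaves at the other; entering at the end terminus means the sequence
#' is reverse ('-') oriented.
#'
#' @param g A `scaffold_graph`.
#' @return An object of class `sg_solution`: `chains` (list of tibbles with
#'   `seq_id`, `orientation`, and per-junction `edge_key` into the preceding
#'   sequence), `matched` (matched edge rows surviving cycle breaking),
#'   `dropped_edges` (edge key + `reason`, one of `unmatched`,
#'   `cycle_break`), and `matching_weight` (total weight of the matching
#'   before cycle breaking).
#' @export
sg_solve <- function(g) {
  if (length(g$seqs) == 0) {
    return(structure(list(chains = list(), matched = empty_sg_edges(),
                          dropped_edges = tibble::tibble(key = character(),
                                                         reason = character()),
                          matching_weight = 0),
                     class = "sg_solution"))
  }
  edges <- g$edges
  midx <- sg_matching(edges)
  dropped <- tibble::tibble(key = setdiff(edges$key, edges$key[midx]),
                            reason = rep("unmatched", nrow(edges) - length(midx)))
  matched <- edges[midx, ]

  # partner lookup: terminus -> matched edge row
  partner_edge <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(matched))) {
    partner_edge[[terminus_key(matched$seq1[r], matched$side1[r])]] <- r
    partner_edge[[terminus_key(matched$seq2[r], matched$side2[r])]] <- r
  }
  other_side <- c(begin = "end", end = "begin")
  edge_other_end <- function(r, seq, side) {
    if (matched$seq1[r] == seq && matched$side1[r] == side) {
      c(matched$seq2[r], matched$side2[r])
    } else {
      c(matched$seq1[r], matched$side1[r])
    }
  }

  # detect cycles: walk from every sequence; a component is a cycle iff the
  # walk returns to the start sequence
  seen <- stats::setNames(rep(FALSE, length(g$seqs)), g$seqs)
  cycle_drop <- integer(0)
  for (s0 in sort(g$seqs)) {
    if (seen[[s0]]) next
    comp_edges <- integer(0)
    seq <- s0; side <- "begin"; is_cycle <- FALSE
    repeat {
      seen[[seq]] <- TRUE
      out_t <- other_side[[side]]
      r <- partner_edge[[terminus_key(seq, out_t)]]
      if (is.null(r)) break
      comp_edges <- c(comp_edges, r)
      nxt <- edge_other_end(r, seq, out_t)
      if (nxt[1] == s0) { is_cycle <- TRUE; break }
      seq <- nxt[1]; side <- nxt[2]
    }
    if (!is_cycle && length(comp_edges) > 0) {
      # also walk the other direction to mark the rest of the path
      seq <- s0; side <- "end"
      repeat {
        out_t <- other_side[[side]]
        r <- partner_edge[[terminus_key(seq, out_t)]]
        if (is.null(r) || r %in% comp_edges) break
        comp_edges <- c(comp_edges, r)
        nxt <- edge_other_end(r, seq, out_t)
        seen[[nxt[1]]] <- TRUE
        seq <- nxt[1]; side <- nxt[2]
      }
    }
    if (is_cycle) {
      cand <- comp_edges[order(matched$weight[comp_edges], matched$key[comp_edges])]
      cycle_drop <- c(cycle_drop, cand[1])
    }
  }
  if (length(cycle_drop) > 0) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      key = matched$key[cycle_drop], reason = "cycle_break"))
    for (r in cycle_drop) {
      rm(list = terminus_key(matched$seq1[r], matched$side1[r]), envir = partner_edge)
      rm(list = terminus_key(matched$seq2[r], matched$side2[r]), envir = partner_edge)
    }
    matched_final <- matched[-cycle_drop, ]
  } else {
    matched_final <- matched
  }

  # rebuild partner lookup on the acyclic matching and emit chains
  partner_edge <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(matched_final))) {
    partner_edge[[terminus_key(matched_final$seq1[r], matched_final$side1[r])]] <- r
    partner_edge[[terminus_key(matched_final$seq2[r], matched_final$side2[r])]] <- r
  }
  edge_other_end2 <- function(r, seq, side) {
    if (matched_final$seq1[r] == seq && matched_final$side1[r] == side) {
      c(matched_final$seq2[r], matched_final$side2[r])
    } else {
      c(matched_final$seq1[r], matched_final$side1[r])
    }
  }
  # chain start termini: termini with no matched partner whose sequence's
  # walk has not been emitted yet
  emitted <- stats::setNames(rep(FALSE, length(g$seqs)), g$seqs)
  chains <- list()
  starts <- sort(c(terminus_key(g$seqs, "begin"), terminus_key(g$seqs, "end")))
  for (st in starts) {
    if (!is.null(partner_edge[[st]])) next
    parts <- strsplit(st, "\x01", fixed = TRUE)[[1]]
    seq <- parts[1]; enter <- parts[2]
    if (emitted[[seq]]) next
    rows <- list()
    repeat {
      emitted[[seq]] <- TRUE
      orient <- if (enter == "begin") "+" else "-"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seq_id = seq, orientation = orient,
        edge_key = if (length(rows) == 0) NA_character_ else rows_key)
      out_t <- other_side[[enter]]
      r <- partner_edge[[terminus_key(seq, out_t)]]
      if (is.null(r)) break
      rows_key <- matched_final$key[r]
      nxt <- edge_other_end2(r, seq, out_t)
      seq <- nxt[1]; enter <- nxt[2]
    }
    chains[[length(chains) + 1L]] <- dplyr::bind_rows(rows)
  }
  structure(
    list(chains = chains, matched = matched_final, dropped_edges = dropped,
         matching_weight = sum(matched$weight)),
    class = "sg_solution"
  )
}

#' @export
print.sg_solution <- function(x, ...) {
  cat("<sg_solution>", length(x$chains), "chains,",
      nrow(x$matched), "matched edges,", nrow(x$dropped_edges), "dropped\n")
  invisible(x)
}

#' @export
tidy.sg_solution <- function(x, ...) {
  if (length(x$chains) == 0) {
    return(tibble::tibble(chain = integer(), position = integer(),
                          seq_id = character(), orientation = character()))
  }
  dplyr::bind_rows(lapply(seq_along(x$chains), function(i) {
    ch <- x$chains[[i]]
    tibble::tibble(chain = i, position = seq_len(nrow(ch)) - 1L,
                   seq_id = ch$seq_id, orientation = ch$orientation)
  }))
}

#' @export
glance.sg_solution <- function(x, ...) {
  tibble::tibble(
    n_chains = length(x$chains),
    n_matched = nrow(x$matched),
    matched_weight = sum(x$matched$weight),
    n_dropped = nrow(x$dropped_edges)
  )
}
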
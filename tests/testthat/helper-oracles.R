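# Independent oracles and small constructors used across the suite.

# one alignment row with sensible defaults
mk_aln <- function(query_id = "q", query_len = 1000L, query_start = 0L,
                   query_end = query_len, strand = "+", ref_id = "r",
                   ref_len = 100000L, ref_start = 0L,
                   ref_end = ref_start + (query_end - query_start),
                   num_matches = query_end - query_start,
                   aln_len = query_end - query_start, mapq = 60L) {
  tibble::tibble(
    query_id = query_id, query_len = as.integer(query_len),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    strand = strand, ref_id = ref_id, ref_len = as.integer(ref_len),
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    num_matches = as.numeric(num_matches), aln_len = as.numeric(aln_len),
    mapq = as.integer(mapq))
}

# total length covered by a set of [s, e) intervals (sweep line)
oracle_union_len <- function(starts, ends) {
  if (length(starts) == 0) return(0)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  total <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[k]; cur_e <- ends[k]
    } else {
      cur_e <- max(cur_e, ends[k])
    }
  }
  total + (cur_e - cur_s)
}

# brute-force maximum-weight matching by enumeration over edge subsets
oracle_matching_weight <- function(u, v, w) {
  m <- length(w)
  if (m == 0) return(0)
  rec <- function(i, used) {
    if (i > m) return(0)
    best <- rec(i + 1L, used)
    if (!(u[i] %in% used) && !(v[i] %in% used)) {
      best <- max(best, w[i] + rec(i + 1L, c(used, u[i], v[i])))
    }
    best
  }
  rec(1L, character(0))
}

# random scaffold graph on <= max_seqs sequences; returns the graph plus the
# raw edge endpoint/weight vectors for the oracle
random_sg <- function(max_seqs = 8, integer_weights = FALSE) {
  n <- sample(2:max_seqs, 1)
  ids <- paste0("s", seq_len(n))
  g <- scaffold_graph(ids)
  m <- sample(1:min(10, n * 2), 1)
  u <- character(0); v <- character(0); w <- numeric(0)
  for (k in seq_len(m)) {
    pair <- sample(ids, 2)
    sides <- sample(c("begin", "end"), 2, replace = TRUE)
    wt <- if (integer_weights) sample(1:5, 1) else round(stats::runif(1, 0.1, 10), 3)
    g2 <- try(sg_add_edge(g, pair[1], sides[1], pair[2], sides[2], wt),
              silent = TRUE)
    if (inherits(g2, "try-error")) next  # duplicate edge; skip
    g <- g2
    u <- c(u, paste0(pair[1], "@", sides[1]))
    v <- c(v, paste0(pair[2], "@", sides[2]))
    w <- c(w, wt)
  }
  list(g = g, u = u, v = v, w = w)
}

# shorthand for building AGP objects in tests
agp_obj <- function(object_id, parts) {
  scafkit:::assemble_agp_object(object_id, parts)
}
comp_part <- function(id, len, orientation = "+", beg = 1L, end = len) {
  list(kind = "component", component_id = id, component_beg = beg,
       component_end = end, orientation = orientation)
}
gap_part <- function(len, known = FALSE, evidence = "align_genus") {
  list(kind = "gap", gap_length = len, known = known, evidence = evidence)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
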
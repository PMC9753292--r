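#' Configuration for homology-based misassembly correction
#'
#' @param terminus_margin Candidate breakpoints closer than this to either
#'   sequence terminus are suppressed (bp, default 5000).
#' @param mode Break between blocks aligning to the same reference sequence
#'   (`"intra"`), different reference sequences (`"inter"`), or both.
#' @param coverage_window Half-width of the coverage validation window around
#'   a breakpoint (bp, default 10000); the window is closed and clamped at
#'   sequence ends.
#' @param min_cov,max_cov Depth bounds for coverage validation; `NA` disables
#'   the corresponding check. When both are `NA` coverage validation is a
#'   no-op (validation is opt-in).
#' @param protected_features Tibble of 0-based half-open intervals (`seqid`,
#'   `start`, `end`) that must never contain a break, e.g. from
#'   [read_gff_intervals()].
#' @return A list of class `correct_config`.
#' @export
correct_config <- function(terminus_margin = 5000, mode = c("both", "intra", "inter"),
                           coverage_window = 10000, min_cov = NA, max_cov = NA,
                           protected_features = NULL) {
  mode <- match.arg(mode)
  stopifnot(terminus_margin >= 0, coverage_window >= 0)
  structure(list(terminus_margin = terminus_margin, mode = mode,
                 coverage_window = coverage_window, min_cov = min_cov,
                 max_cov = max_cov, protected_features = protected_features),
            class = "correct_config")
}

#' Propose misassembly breakpoints from merged alignment blocks
#'
#' Any query with two or more merged blocks is considered for correction.
#' A candidate breakpoint is placed at each boundary between consecutive
#' blocks along the query — the midpoint of the inter-block query interval
#' (the shared coordinate when blocks abut). Candidates are suppressed when
#' within `terminus_margin` of a sequence terminus, when the flanking blocks'
#' reference sequences do not match the requested `mode`, or when inside a
#' protected feature.
#'
#' @param blocks Block tibble from [merge_blocks()] (query vs. reference).
#' @param cfg A [correct_config()].
#' @return Break-plan tibble: `query_id`, `pos` (0-based), `status` in
#'   `applied`, `suppressed_terminus`, `suppressed_feature`; candidates whose
#'   flanking refs fail the mode test are not candidates and are omitted.
#' @export
propose_breakpoints <- function(blocks, cfg = correct_config()) {
  plans <- list()
  for (idx in split(seq_len(nrow(blocks)), blocks$query_id)) {
    b <- blocks[idx, ]
    if (nrow(b) < 2) next
    b <- b[order(b$query_start, b$query_end), ]
    qlen <- b$query_len[1]
    for (k in seq_len(nrow(b) - 1L)) {
      same_ref <- b$ref_id[k] == b$ref_id[k + 1]
      if (cfg$mode == "intra" && !same_ref) next
      if (cfg$mode == "inter" && same_ref) next
      pos <- (b$query_end[k] + b$query_start[k + 1]) %/% 2L
      pos <- min(max(pos, 1L), qlen - 1L)
      status <- "applied"
      if (pos < cfg$terminus_margin || (qlen - pos) < cfg$terminus_margin) {
        status <- "suppressed_terminus"
      } else if (!is.null(cfg$protected_features)) {
        pf <- cfg$protected_features
        hit <- pf$seqid == b$query_id[1] & pf$start <= pos & pos < pf$end
        if (any(hit)) status <- "suppressed_feature"
      }
      plans[[length(plans) + 1L]] <- tibble::tibble(
        query_id = b$query_id[1], pos = as.integer(pos), status = status)
    }
  }
  if (length(plans) == 0) {
    return(tibble::tibble(query_id = character(), pos = integer(),
                          status = character()))
  }
  dplyr::bind_rows(plans)
}

#' Validate proposed breakpoints against read coverage
#'
#' A true misassembly is expected to show exceptionally low or high read
#' depth near the junction. An applied candidate stays applied only if some
#' base within `coverage_window` bp of the breakpoint (closed window, clamped
#' to the sequence) has depth below `min_cov` or above `max_cov`; otherwise
#' the boundary is attributed to genuine structural variation and the status
#' becomes `suppressed_coverage_normal`. With both bounds `NA` the plan is
#' returned unchanged.
#'
#' @param plan Break-plan tibble from [propose_breakpoints()].
#' @param profile Named list: query id -> integer vector of per-base depth.
#' @param cfg A [correct_config()] with `min_cov`/`max_cov` set.
#' @return The updated break-plan tibble.
#' @export
validate_with_coverage <- function(plan, profile, cfg) {
  if (is.na(cfg$min_cov) && is.na(cfg$max_cov)) return(plan)
  v <- cfg$coverage_window
  for (i in seq_len(nrow(plan))) {
    if (plan$status[i] != "applied") next
    depth <- profile[[plan$query_id[i]]]
    if (is.null(depth)) stop("no coverage profile for ", plan$query_id[i])
    pos <- plan$pos[i]
    lo <- max(0L, pos - v) + 1L            # 1-based into the depth vector
    hi <- min(length(depth) - 1L, pos + v) + 1L
    win <- depth[lo:hi]
    exceptional <- (!is.na(cfg$min_cov) && any(win < cfg$min_cov)) ||
      (!is.na(cfg$max_cov) && any(win > cfg$max_cov))
    if (!exceptional) plan$status[i] <- "suppressed_coverage_normal"
  }
  plan
}

#' Apply a break plan to query sequences
#'
#' Splits each query at its applied breakpoints. Fragments are named
#' `<id>:<start>-<end>` with a 0-based half-open suffix; an AGP mapping the
#' fragments back to original coordinates is emitted. Unbroken sequences
#' pass through unchanged.
#'
#' @param seqs Named character vector of query sequences.
#' @param plan Break-plan tibble.
#' @return List with `seqs` (corrected sequences) and `agp` (fragment-to-
#'   original mapping).
#' @export
apply_breaks <- function(seqs, plan) {
  applied <- plan[plan$status == "applied", ]
  out <- list()
  agp_rows <- list()
  for (id in names(seqs)) {
    len <- nchar(seqs[[id]])
    bps <- sort(unique(applied$pos[applied$query_id == id]))
    if (any(bps <= 0 | bps >= len)) stop("breakpoint out of range for ", id)
    if (length(bps) == 0) {
      out[[id]] <- seqs[[id]]
      agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(id, list(
        list(kind = "component", component_id = id, component_beg = 1L,
             component_end = len, orientation = "+")))
      next
    }
    bounds <- c(0L, bps, len)
    parts <- vector("list", length(bounds) - 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      s <- bounds[k]; e <- bounds[k + 1]
      frag_id <- sprintf("%s:%d-%d", id, s, e)
      out[[frag_id]] <- seq_slice(seqs[[id]], s, e)
      parts[[k]] <- list(kind = "component", component_id = frag_id,
                         component_beg = 1L, component_end = e - s,
                         orientation = "+")
    }
    agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(id, parts)
  }
  list(seqs = unlist(out), agp = dplyr::bind_rows(agp_rows))
}

#' Per-base coverage from an interval table
#'
#' Adapter building a [validate_with_coverage()] profile from a table of
#' read alignment intervals (0-based half-open).
#'
#' @param intervals Tibble with `seqid`, `start`, `end`.
#' @param lens Named vector of sequence lengths.
#' @return Named list: sequence id -> integer depth vector.
#' @export
coverage_from_intervals <- function(intervals, lens) {
  out <- lapply(names(lens), function(id) {
    len <- lens[[id]]
    delta <- integer(len + 1L)
    iv <- intervals[intervals$seqid == id, ]
    if (nrow(iv) > 0) {
      stopifnot(all(iv$start >= 0), all(iv$end <= len))
      for (k in seq_len(nrow(iv))) {
        delta[iv$start[k] + 1L] <- delta[iv$start[k] + 1L] + 1L
        delta[iv$end[k] + 1L] <- delta[iv$end[k] + 1L] - 1L
      }
    }
    cumsum(delta)[seq_len(len)]
  })
  stats::setNames(out, names(lens))
}

#' Homology-based assembly correction pipeline
#'
#' Filters and merges query-vs-reference alignments, proposes breakpoints,
#' optionally validates them against read coverage, and applies the breaks.
#'
#' @param query Named character vector of query sequences.
#' @param alignments Query-vs-reference alignment tibble.
#' @param cfg A [correct_config()].
#' @param profile Optional coverage profile (see [coverage_from_intervals()]).
#' @param min_unique_anchor,min_mapq,d Alignment filtering/merging parameters
#'   (see [filter_unique_anchor()], [filter_mapq()], [merge_blocks()]).
#' @return Object of class `correct_result`: `seqs`, `agp`, `plan`, `blocks`.
#' @export
run_correct <- function(query, alignments, cfg = correct_config(),
                        profile = NULL, min_unique_anchor = 10000,
                        min_mapq = NA, d = 100000) {
  aln <- alignments |>
    filter_mapq(min_mapq) |>
    filter_unique_anchor(min_unique_anchor)
  blocks <- merge_blocks(aln, d = d)
  plan <- propose_breakpoints(blocks, cfg)
  if (!is.null(profile)) plan <- validate_with_coverage(plan, profile, cfg)
  res <- apply_breaks(query, plan)
  structure(list(seqs = res$seqs, agp = res$agp, plan = plan, blocks = blocks),
            class = "correct_result")
}

#' @export
print.correct_result <- function(x, ...) {
  cat("<correct_result>", length(x$seqs), "sequences,",
      sum(x$plan$status == "applied"), "breaks applied,",
      sum(x$plan$status != "applied"), "suppressed\n")
  invisible(x)
}

#' @export
tidy.correct_result <- function(x, ...) x$plan

#' @export
glance.correct_result <- function(x, ...) {
  tibble::tibble(
    n_sequences = length(x$seqs),
    n_candidates = nrow(x$plan),
    n_applied = sum(x$plan$status == "applied"),
    n_suppressed = sum(x$plan$status != "applied")
  )
}
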
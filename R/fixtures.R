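# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulate a random genome
#'
#' Generates uniform-composition chromosomes, optionally implanting
#' duplicated segments (repeats) to stress unique-anchor filtering. Output
#' is deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param repeat_fraction Fraction of each chromosome overwritten with
#'   copies of a single repeat unit, in `[0, 1)`.
#' @param repeat_unit_len Repeat unit length in bp.
#' @return Named character vector (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(seed, n_chrom = 2, chrom_len = 5e6,
                            repeat_fraction = 0, repeat_unit_len = 5000) {
  stopifnot(n_chrom >= 1, chrom_len >= 1, repeat_fraction >= 0,
            repeat_fraction < 1)
  with_seed(seed, {
    out <- vapply(seq_len(n_chrom), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                 collapse = "")
      if (repeat_fraction > 0 && chrom_len > 2 * repeat_unit_len) {
        src <- sample.int(chrom_len - repeat_unit_len, 1)
        unit <- substr(s, src, src + repeat_unit_len - 1L)
        n_copies <- floor(repeat_fraction * chrom_len / repeat_unit_len)
        for (k in seq_len(n_copies)) {
          at <- sample.int(chrom_len - repeat_unit_len, 1)
          substr(s, at, at + repeat_unit_len - 1L) <- unit
        }
      }
      s
    }, "")
    stats::setNames(out, paste0("chr", seq_len(n_chrom)))
  })
}

#' Fragment a genome into a synthetic draft assembly
#'
#' Cuts each chromosome into contigs of roughly `target_n50` bp. At each
#' junction a gap may consume genome sequence (recorded as an `N` gap row in
#' the truth AGP) and contigs may be stored reverse-complemented. Optionally
#' pairs of contigs from different chromosomes are joined into chimeric
#' contigs to emulate misassemblies. The truth AGP reconstructs the genome
#' exactly (gap bases excepted) and every injected event is logged.
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param seed Integer RNG seed.
#' @param target_n50 Approximate contig length in bp.
#' @param gap_rate Probability that a junction carries a gap.
#' @param misassembly_rate Fraction of contigs joined into inter-chromosome
#'   chimeras.
#' @param flip_prob Probability a contig is stored reverse-complemented.
#' @param gap_len_range Gap length range in bp (sampled uniformly).
#' @return Object of class `truth_assembly`: `contigs`, `truth_agp`,
#'   `events`, `genome_lens`, `seed`.
#' @export
fragment_assembly <- function(genome, seed, target_n50 = 200000, gap_rate = 0,
                              misassembly_rate = 0, flip_prob = 0.25,
                              gap_len_range = c(50, 200)) {
  stopifnot(gap_rate >= 0, gap_rate <= 1, misassembly_rate >= 0,
            misassembly_rate <= 1)
  with_seed(seed, {
    frag <- list()   # per fragment: chrom, start, end (0-based), gap_after
    events <- list()
    for (chrom in names(genome)) {
      len <- nchar(genome[[chrom]])
      # fragment lengths jittered around target_n50; keeps every fragment
      # above ~60% of the target, as draft contig size distributions do
      cuts <- integer(0)
      pos <- 0
      repeat {
        pos <- pos + round(stats::runif(1, 0.6, 1.4) * target_n50)
        if (pos >= len - 0.6 * target_n50) break
        cuts <- c(cuts, as.integer(pos))
      }
      bounds <- unique(c(0L, cuts, len))
      for (k in seq_len(length(bounds) - 1L)) {
        s <- bounds[k]; e <- bounds[k + 1]
        gap_after <- 0L
        if (k < length(bounds) - 1L && stats::runif(1) < gap_rate) {
          gl <- sample(seq(gap_len_range[1], gap_len_range[2]), 1)
          if (e - gl > s) {
            gap_after <- gl
            e <- e - gl
            events[[length(events) + 1L]] <- tibble::tibble(
              type = "gap", chrom = chrom, pos = e, length = gl,
              contig = NA_character_)
          }
        }
        frag[[length(frag) + 1L]] <- list(chrom = chrom, start = s, end = e,
                                          gap_after = gap_after)
      }
    }
    # assign orientations; name fragments; choose chimera partners
    nfrag <- length(frag)
    flips <- stats::runif(nfrag) < flip_prob
    n_chim <- floor(misassembly_rate * nfrag / 2)
    chim_pairs <- list()
    if (n_chim > 0) {
      chroms <- vapply(frag, `[[`, "", "chrom")
      avail <- seq_len(nfrag)
      for (k in seq_len(n_chim)) {
        i <- sample(avail, 1)
        j_cand <- avail[chroms[avail] != chroms[i]]
        if (length(j_cand) == 0) break
        j <- if (length(j_cand) == 1) j_cand else sample(j_cand, 1)
        chim_pairs[[length(chim_pairs) + 1L]] <- c(i, j)
        avail <- setdiff(avail, c(i, j))
      }
    }
    chim_first <- vapply(chim_pairs, `[`, 0L, 1)
    chim_second <- vapply(chim_pairs, `[`, 0L, 2)
    flips[c(chim_first, chim_second)] <- FALSE  # chimera halves stay forward
    contig_name <- character(nfrag)
    offset <- integer(nfrag)  # 0-based offset of the fragment in its contig
    ci <- 0L
    for (k in seq_len(nfrag)) {
      if (k %in% chim_second) next
      ci <- ci + 1L
      nm <- sprintf("tig%04d", ci)
      contig_name[k] <- nm
      offset[k] <- 0L
      if (k %in% chim_first) {
        j <- chim_second[match(k, chim_first)]
        contig_name[j] <- nm
        offset[j] <- frag[[k]]$end - frag[[k]]$start
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "misassembly", chrom = frag[[k]]$chrom,
          pos = offset[j], length = NA_integer_, contig = nm)
      }
    }
    # build contig sequences (chimera halves concatenate in pair order)
    contigs <- list()
    for (k in order(offset)) {
      piece <- substr(genome[[frag[[k]]$chrom]], frag[[k]]$start + 1L,
                      frag[[k]]$end)
      if (flips[k]) piece <- revcomp(piece)
      nm <- contig_name[k]
      contigs[[nm]] <- if (is.null(contigs[[nm]])) piece else
        paste0(contigs[[nm]], piece)
    }
    contigs <- unlist(contigs)
    # truth AGP: per chromosome, fragments in genome order
    agp_rows <- list()
    for (chrom in names(genome)) {
      idx <- which(vapply(frag, `[[`, "", "chrom") == chrom)
      parts <- list()
      for (k in idx) {
        flen <- frag[[k]]$end - frag[[k]]$start
        parts[[length(parts) + 1L]] <- list(
          kind = "component", component_id = contig_name[k],
          component_beg = offset[k] + 1L, component_end = offset[k] + flen,
          orientation = if (flips[k]) "-" else "+")
        if (frag[[k]]$gap_after > 0) {
          parts[[length(parts) + 1L]] <- list(
            kind = "gap", gap_length = frag[[k]]$gap_after, known = TRUE,
            gap_type = "scaffold", evidence = "paired-ends")
        }
      }
      agp_rows[[length(agp_rows) + 1L]] <- assemble_agp_object(chrom, parts)
    }
    events <- if (length(events) > 0) dplyr::bind_rows(events) else
      tibble::tibble(type = character(), chrom = character(), pos = integer(),
                     length = integer(), contig = character())
    structure(list(contigs = contigs, truth_agp = dplyr::bind_rows(agp_rows),
                   events = events, genome_lens = seq_lens(genome),
                   seed = seed),
              class = "truth_assembly")
  })
}

#' @export
print.truth_assembly <- function(x, ...) {
  cat("<truth_assembly>", length(x$contigs), "contigs over",
      length(x$genome_lens), "chromosomes,", nrow(x$events), "events\n")
  invisible(x)
}

#' Exact truth alignments of assembly contigs to the genome
#'
#' Emits the perfect contig-vs-chromosome alignments implied by a truth
#' AGP, in the standard alignment tibble form — the exact-alignment regime
#' used for end-to-end testing without running an aligner.
#'
#' @param truth A `truth_assembly`.
#' @return Alignment tibble (queries = contigs, references = chromosomes).
#' @export
truth_alignments <- function(truth) {
  lens <- seq_lens(truth$contigs)
  comp <- truth$truth_agp[!truth$truth_agp$component_type %in% c("N", "U"), ]
  tibble::tibble(
    query_id = comp$component_id,
    query_len = as.integer(lens[comp$component_id]),
    query_start = comp$component_beg - 1L,
    query_end = comp$component_end,
    strand = comp$orientation,
    ref_id = comp$object_id,
    ref_len = as.integer(truth$genome_lens[comp$object_id]),
    ref_start = comp$object_beg - 1L,
    ref_end = comp$object_end,
    num_matches = comp$component_end - comp$component_beg + 1L,
    aln_len = comp$component_end - comp$component_beg + 1L,
    mapq = 60L
  )
}

#' Exact alignments between two assemblies of the same genome
#'
#' Projects two component-to-object AGP mappings over shared objects
#' (chromosomes) onto each other: wherever a query-side component and a
#' reference-side component overlap on an object, an exact alignment record
#' is emitted with coordinates composed through the object.
#'
#' @param agp_query,agp_ref AGP tibbles mapping components onto the same
#'   objects (e.g. two `truth_agp`s, or a [split_at_gaps()] AGP).
#' @param lens_query,lens_ref Named component-length vectors.
#' @return Alignment tibble (queries from `agp_query`, references from
#'   `agp_ref`).
#' @export
cross_alignments <- function(agp_query, lens_query, agp_ref, lens_ref) {
  qa <- agp_query[!agp_query$component_type %in% c("N", "U"), ]
  ra <- agp_ref[!agp_ref$component_type %in% c("N", "U"), ]
  out <- list()
  for (obj in intersect(unique(qa$object_id), unique(ra$object_id))) {
    q <- qa[qa$object_id == obj, ]
    r <- ra[ra$object_id == obj, ]
    for (i in seq_len(nrow(q))) {
      for (j in seq_len(nrow(r))) {
        lo <- max(q$object_beg[i], r$object_beg[j]) - 1L  # 0-based
        hi <- min(q$object_end[i], r$object_end[j])
        if (hi <= lo) next
        map <- function(row, k, a, b) {
          cs <- row$component_beg[k] - 1L; ce <- row$component_end[k]
          os <- row$object_beg[k] - 1L
          if (row$orientation[k] == "-") {
            c(ce - (b - os), ce - (a - os))
          } else {
            c(cs + (a - os), cs + (b - os))
          }
        }
        qc <- map(q, i, lo, hi)
        rc <- map(r, j, lo, hi)
        strand <- if (q$orientation[i] == r$orientation[j]) "+" else "-"
        out[[length(out) + 1L]] <- tibble::tibble(
          query_id = q$component_id[i],
          query_len = as.integer(lens_query[q$component_id[i]]),
          query_start = as.integer(qc[1]), query_end = as.integer(qc[2]),
          strand = strand,
          ref_id = r$component_id[j],
          ref_len = as.integer(lens_ref[r$component_id[j]]),
          ref_start = as.integer(rc[1]), ref_end = as.integer(rc[2]),
          num_matches = as.integer(hi - lo), aln_len = as.integer(hi - lo),
          mapq = 60L)
      }
    }
  }
  if (length(out) == 0) return(empty_alignments())
  dplyr::bind_rows(out)
}

#' Simulate Hi-C contact pairs on a truth assembly
#'
#' Draws contact endpoints on the truth genome with exponentially decaying
#' separation (mean `decay_bp`), then maps both ends into contig
#' coordinates via the truth AGP; pairs landing in gap bases are dropped.
#'
#' @param truth A `truth_assembly`.
#' @param n_pairs Number of pairs to draw.
#' @param decay_bp Mean genomic separation in bp.
#' @param seed Integer RNG seed.
#' @return Contact tibble: `comp_a`, `pos_a`, `comp_b`, `pos_b` (0-based
#'   positions within contigs).
#' @export
simulate_hic_pairs <- function(truth, n_pairs, decay_bp = 50000, seed = 1) {
  if (n_pairs == 0) {
    return(tibble::tibble(comp_a = character(), pos_a = integer(),
                          comp_b = character(), pos_b = integer()))
  }
  comp <- truth$truth_agp[!truth$truth_agp$component_type %in% c("N", "U"), ]
  with_seed(seed, {
    chroms <- names(truth$genome_lens)
    wl <- as.numeric(truth$genome_lens)
    pick_chrom <- sample(chroms, n_pairs, replace = TRUE, prob = wl / sum(wl))
    out <- vector("list", n_pairs)
    for (k in seq_len(n_pairs)) {
      len <- truth$genome_lens[[pick_chrom[k]]]
      repeat {
        p1 <- sample.int(len, 1) - 1L
        sep <- round(stats::rexp(1, 1 / decay_bp)) * sample(c(-1L, 1L), 1)
        p2 <- p1 + sep
        if (p2 >= 0 && p2 < len) break
      }
      a <- genome_pos_to_component(comp, pick_chrom[k], p1)
      b <- genome_pos_to_component(comp, pick_chrom[k], p2)
      if (is.null(a) || is.null(b)) next
      out[[k]] <- tibble::tibble(comp_a = a$id, pos_a = a$pos,
                                 comp_b = b$id, pos_b = b$pos)
    }
    dplyr::bind_rows(out)
  })
}

# map a 0-based genome position to (component id, 0-based position); NULL in
# gap bases
genome_pos_to_component <- function(comp, chrom, pos) {
  rows <- which(comp$object_id == chrom & comp$object_beg - 1L <= pos &
                  pos < comp$object_end)
  if (length(rows) == 0) return(NULL)
  r <- rows[1]
  off <- pos - (comp$object_beg[r] - 1L)
  cpos <- if (comp$orientation[r] == "-") {
    comp$component_end[r] - 1L - off
  } else {
    comp$component_beg[r] - 1L + off
  }
  list(id = comp$component_id[r], pos = as.integer(cpos))
}

#' Classify contigs by contamination-screen coverage fractions
#'
#' A pure classifier over per-database covered fractions: a contig with more
#' than 10% rDNA coverage is a putative rDNA contig and is always kept;
#' otherwise it is removed when more than 10% is bacterial, more than 20% is
#' mitochondrial and the contig is under 1 Mbp, or more than 20% is
#' chloroplast and the contig is under 0.5 Mbp.
#'
#' @param profiles Tibble with `contig_id`, `length`, and fraction columns
#'   `bacterial`, `chloroplast`, `mitochondria`, `rDNA` (each in `[0, 1]`).
#' @return The input with a `class` column: `keep`, `remove`, or `rDNA`.
#' @export
screen_contigs <- function(profiles) {
  fr <- c("bacterial", "chloroplast", "mitochondria", "rDNA")
  stopifnot(all(fr %in% names(profiles)),
            all(unlist(profiles[fr]) >= 0), all(unlist(profiles[fr]) <= 1))
  is_rdna <- profiles$rDNA > 0.10
  removed <- !is_rdna & (
    profiles$bacterial > 0.10 |
      (profiles$mitochondria > 0.20 & profiles$length < 1e6) |
      (profiles$chloroplast > 0.20 & profiles$length < 5e5))
  profiles$class <- ifelse(is_rdna, "rDNA", ifelse(removed, "remove", "keep"))
  profiles
}

#' @rdname screen_contigs
#' @param length Contig length in bp.
#' @param bacterial,chloroplast,mitochondria,rDNA Covered fractions.
#' @return `screen_contig()`: a single class string.
#' @export
screen_contig <- function(length, bacterial = 0, chloroplast = 0,
                          mitochondria = 0, rDNA = 0) {
  screen_contigs(tibble::tibble(
    contig_id = "x", length = length, bacterial = bacterial,
    chloroplast = chloroplast, mitochondria = mitochondria,
    rDNA = rDNA))$class
}

#' Euclidean distance between two patch coordinate tuples
#'
#' Compares two patches by the Euclidean distance over their coordinate
#' vectors (start/end coordinates of the two joined sequences and of the
#' patching sequence).
#'
#' @param patch_a,patch_b Numeric coordinate vectors of equal length.
#' @return Nonnegative distance.
#' @export
patch_distance <- function(patch_a, patch_b) {
  if (length(patch_a) != length(patch_b)) {
    stop("patch coordinate tuples differ in arity")
  }
  sqrt(sum((as.numeric(patch_a) - as.numeric(patch_b))^2))
}
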
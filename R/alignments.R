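#' Parse pairwise whole-genome alignments
#'
#' Reads minimap2-style PAF (12 mandatory columns) or MUMmer delta alignments
#' into a single tabular representation. All coordinates are 0-based
#' half-open; query coordinates are always query-forward (the PAF convention;
#' reverse-strand delta records are converted to match). PAF mapping quality
#' 255 ("missing" per the PAF specification) and delta records, which carry no
#' mapping quality, are stored as `NA`.
#'
#' @param input Path to an alignment file, or a character vector of lines.
#' @param format `"paf"` or `"delta"`.
#' @return A tibble with one row per alignment and columns `query_id`,
#'   `query_len`, `query_start`, `query_end`, `strand`, `ref_id`, `ref_len`,
#'   `ref_start`, `ref_end`, `num_matches`, `aln_len`, `mapq`, in file order.
#' @examples
#' paf <- "q1\t1000\t0\t900\t+\tr1\t5000\t100\t1000\t850\t900\t60"
#' read_alignments(paf, format = "paf")
#' @export
read_alignments <- function(input, format = c("paf", "delta")) {
  format <- match.arg(format)
  lines <- if (length(input) == 1 && !grepl("[\t\n>]", input) && file.exists(input)) {
    readLines(input)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines)]
  if (format == "paf") parse_paf(lines) else parse_delta(lines)
}

empty_alignments <- function() {
  tibble::tibble(
    query_id = character(), query_len = integer(), query_start = integer(),
    query_end = integer(), strand = character(), ref_id = character(),
    ref_len = integer(), ref_start = integer(), ref_end = integer(),
    num_matches = integer(), aln_len = integer(), mapq = integer()
  )
}

parse_paf <- function(lines) {
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 12L)
  if (length(bad) > 0) {
    stop("malformed PAF line ", bad[1], ": fewer than 12 columns")
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  n <- function(i) suppressWarnings(as.integer(f(i)))
  out <- tibble::tibble(
    query_id = f(1), query_len = n(2), query_start = n(3), query_end = n(4),
    strand = f(5), ref_id = f(6), ref_len = n(7), ref_start = n(8),
    ref_end = n(9), num_matches = n(10), aln_len = n(11), mapq = n(12)
  )
  bad <- which(is.na(out$query_len) | is.na(out$query_start) | is.na(out$ref_end) |
                 !out$strand %in% c("+", "-"))
  if (length(bad) > 0) stop("malformed PAF line ", bad[1], ": bad field value")
  out$mapq[!is.na(out$mapq) & out$mapq == 255L] <- NA_integer_
  check_alignments(out)
  out
}

parse_delta <- function(lines) {
  # skip file header (paths line and NUCMER/PROMER tag)
  i <- 1L
  recs <- list()
  ref_id <- qry_id <- NA_character_
  ref_len <- qry_len <- NA_integer_
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      parts <- strsplit(sub("^>", "", ln), "\\s+")[[1]]
      if (length(parts) != 4) stop("malformed delta header at line ", i)
      ref_id <- parts[1]; qry_id <- parts[2]
      ref_len <- as.integer(parts[3]); qry_len <- as.integer(parts[4])
      i <- i + 1L
    } else if (grepl("^-?[0-9]+( [0-9]+){6}$", ln)) {
      if (is.na(ref_id)) stop("delta alignment before sequence header at line ", i)
      v <- as.integer(strsplit(ln, " ", fixed = TRUE)[[1]])
      rs <- v[1]; re <- v[2]; qs <- v[3]; qe <- v[4]; nerr <- v[5]
      strand <- if (qs <= qe) "+" else "-"
      q0 <- if (strand == "+") c(qs - 1L, qe) else c(qe - 1L, qs)
      alen <- max(re - rs + 1L, abs(qe - qs) + 1L)
      recs[[length(recs) + 1L]] <- tibble::tibble(
        query_id = qry_id, query_len = qry_len, query_start = q0[1],
        query_end = q0[2], strand = strand, ref_id = ref_id, ref_len = ref_len,
        ref_start = rs - 1L, ref_end = re, num_matches = max(alen - nerr, 0L),
        aln_len = alen, mapq = NA_integer_
      )
      # consume indel offsets up to the 0 terminator
      i <- i + 1L
      while (i <= length(lines) && lines[[i]] != "0") {
        if (!grepl("^-?[0-9]+$", lines[[i]])) stop("malformed delta offsets at line ", i)
        i <- i + 1L
      }
      if (i > length(lines)) stop("unterminated delta alignment block")
      i <- i + 1L
    } else {
      i <- i + 1L  # file header lines
    }
  }
  if (length(recs) == 0) return(empty_alignments())
  out <- dplyr::bind_rows(recs)
  check_alignments(out)
  out
}

check_alignments <- function(aln) {
  with(aln, {
    stopifnot(
      all(query_start >= 0 & query_start < query_end & query_end <= query_len),
      all(ref_start >= 0 & ref_start < ref_end & ref_end <= ref_len),
      all(aln_len >= num_matches), all(num_matches >= 0)
    )
  })
  invisible(aln)
}
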
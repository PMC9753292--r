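#' nX assembly contiguity statistic
#'
#' The nX statistic is the minimum sequence length L such that sequences of
#' length at least L sum to at least x percent of the total assembly length.
#' `nx_statistics(lengths, 50)` is the familiar N50.
#'
#' @param lengths Sequence lengths in bp (all >= 1).
#' @param x Percentage(s) in (0, 100].
#' @return Numeric vector of nX values, one per element of `x`.
#' @examples
#' nx_statistics(c(10, 5, 5), 50)  # 10
#' @export
nx_statistics <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("lengths must be nonempty")
  stopifnot(all(lengths >= 1), all(x > 0), all(x <= 100))
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(sorted)
  total <- cs[length(cs)]
  vapply(x, function(xx) sorted[which(cs >= total * xx / 100)[1]], 0)
}

#' Summary contiguity statistics for a sequence set
#'
#' @param seqs Named character vector of sequences, or numeric lengths.
#' @return One-row tibble: sequence count, total bp, min/max length, N50, N90,
#'   and gap (`N`) base count when sequences are given.
#' @export
assembly_stats <- function(seqs) {
  if (is.character(seqs)) {
    lens <- nchar(seqs)
    gap_bp <- sum(stringr::str_count(toupper(seqs), "N"))
  } else {
    lens <- as.numeric(seqs)
    gap_bp <- NA_real_
  }
  tibble::tibble(
    n_sequences = length(lens),
    total_bp = sum(lens),
    min_bp = min(lens),
    max_bp = max(lens),
    n50 = nx_statistics(lens, 50),
    n90 = nx_statistics(lens, 90),
    gap_bp = gap_bp
  )
}

#' Plot the nX curve of one or more assemblies
#'
#' Draws the minimum sequence length needed to constitute each percentage of
#' the assembly, on a log scale, for visual comparison of contiguity.
#'
#' @param ... Named numeric vectors of sequence lengths (one per assembly).
#' @return A ggplot object.
#' @export
plot_nx <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("assembly", seq_along(sets))
  }
  xs <- seq(1, 100, by = 1)
  df <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    tibble::tibble(assembly = nm, x = xs, nx = nx_statistics(sets[[nm]], xs))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$nx, colour = .data$assembly)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "x (% of assembly)", y = "nX (bp)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Read GFF3 feature intervals
#'
#' Only `seqid`, `start` and `end` are consumed; intervals are returned in the
#' package-internal 0-based half-open convention.
#'
#' @param input Path to a GFF3 file, or a character vector of lines.
#' @return Tibble with `seqid`, `start`, `end` (0-based half-open).
#' @export
read_gff_intervals <- function(input) {
  lines <- if (length(input) == 1 && !grepl("[\t\n]", input) && file.exists(input)) {
    readLines(input)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(seqid = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) < 5L)) stop("malformed GFF3 line")
  tibble::tibble(
    seqid = vapply(fields, `[[`, "", 1),
    start = as.integer(vapply(fields, `[[`, "", 4)) - 1L,
    end = as.integer(vapply(fields, `[[`, "", 5))
  )
}
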
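#' Read an AGP v2.1 file
#'
#' Parses the NCBI AGP format describing how components (contigs) and gaps
#' compose scaffold or chromosome objects. Comment lines (`#`) are skipped.
#' Coordinates are kept in the AGP-native 1-based inclusive convention; all
#' other scafkit coordinates are 0-based half-open, and the conversion happens
#' only at this boundary.
#'
#' @param input Path to an AGP file, or a character vector of lines.
#' @return A tibble with columns `object_id`, `object_beg`, `object_end`,
#'   `part_number`, `component_type`, and either component fields
#'   (`component_id`, `component_beg`, `component_end`, `orientation`) or gap
#'   fields (`gap_length`, `gap_type`, `linkage`, `linkage_evidence`), `NA`
#'   where not applicable. Component types `N`/`U` are gaps; all others are
#'   components.
#' @export
read_agp <- function(input) {
  lines <- if (length(input) == 1 && !grepl("[\t\n]", input) && file.exists(input)) {
    readLines(input)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_agp())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 8L)
  if (length(bad) > 0) stop("malformed AGP line ", bad[1], ": fewer than 8 columns")
  f <- function(i) vapply(fields, function(x) if (length(x) >= i) x[[i]] else "", "")
  type <- f(5)
  is_gap <- type %in% c("N", "U")
  n_int <- function(x) suppressWarnings(as.integer(x))
  out <- tibble::tibble(
    object_id = f(1),
    object_beg = n_int(f(2)),
    object_end = n_int(f(3)),
    part_number = n_int(f(4)),
    component_type = type,
    component_id = ifelse(is_gap, NA_character_, f(6)),
    component_beg = ifelse(is_gap, NA_integer_, n_int(f(6 + 1))),
    component_end = ifelse(is_gap, NA_integer_, n_int(f(8))),
    orientation = ifelse(is_gap, NA_character_, f(9)),
    gap_length = ifelse(is_gap, n_int(f(6)), NA_integer_),
    gap_type = ifelse(is_gap, f(7), NA_character_),
    linkage = ifelse(is_gap, f(8), NA_character_),
    linkage_evidence = ifelse(is_gap, f(9), NA_character_)
  )
  if (any(is.na(out$object_beg) | is.na(out$object_end) | is.na(out$part_number))) {
    stop("malformed AGP line ", which(is.na(out$object_beg) | is.na(out$object_end) |
                                        is.na(out$part_number))[1], ": bad coordinate")
  }
  out
}

empty_agp <- function() {
  tibble::tibble(
    object_id = character(), object_beg = integer(), object_end = integer(),
    part_number = integer(), component_type = character(),
    component_id = character(), component_beg = integer(),
    component_end = integer(), orientation = character(),
    gap_length = integer(), gap_type = character(), linkage = character(),
    linkage_evidence = character()
  )
}

#' Write an AGP tibble to AGP v2.1 text
#'
#' @param agp An AGP tibble as returned by [read_agp()].
#' @param path Optional output path; if `NULL`, lines are returned.
#' @return The file lines, invisibly when `path` is given.
#' @export
write_agp <- function(agp, path = NULL) {
  is_gap <- agp$component_type %in% c("N", "U")
  body <- ifelse(
    is_gap,
    paste(agp$object_id, agp$object_beg, agp$object_end, agp$part_number,
          agp$component_type, agp$gap_length, agp$gap_type, agp$linkage,
          agp$linkage_evidence, sep = "\t"),
    paste(agp$object_id, agp$object_beg, agp$object_end, agp$part_number,
          agp$component_type, agp$component_id, agp$component_beg,
          agp$component_end, agp$orientation, sep = "\t")
  )
  lines <- c("## agp-version 2.1", body)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Validate AGP structure
#'
#' Checks the AGP object-model invariants: rows tile each object contiguously
#' from position 1 with no overlap, part numbers increase from 1 in steps of
#' one, gap lengths match their object span, and component spans match their
#' object span.
#'
#' @param agp An AGP tibble.
#' @return A tibble of violations (`object_id`, `row`, `message`); zero rows
#'   when the AGP is valid.
#' @export
validate_agp <- function(agp) {
  viol <- list()
  add <- function(obj, row, msg) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(object_id = obj, row = row, message = msg)
  }
  for (obj in unique(agp$object_id)) {
    rows <- which(agp$object_id == obj)
    a <- agp[rows, ]
    if (is.unsorted(a$part_number, strictly = TRUE)) {
      ord <- order(a$part_number)
      a <- a[ord, ]; rows <- rows[ord]
    }
    if (!identical(as.integer(a$part_number), seq_len(nrow(a)))) {
      add(obj, rows[1], "part_number not consecutive from 1")
    }
    expect_beg <- 1L
    for (k in seq_len(nrow(a))) {
      span <- a$object_end[k] - a$object_beg[k] + 1L
      if (a$object_beg[k] != expect_beg) {
        add(obj, rows[k], sprintf("object coordinates not contiguous: expected beg %d, got %d",
                                  expect_beg, a$object_beg[k]))
      }
      if (span < 1L) add(obj, rows[k], "object_end < object_beg")
      if (a$component_type[k] %in% c("N", "U")) {
        if (!isTRUE(a$gap_length[k] == span)) add(obj, rows[k], "gap_length mismatch")
      } else {
        clen <- a$component_end[k] - a$component_beg[k] + 1L
        if (is.na(clen) || clen != span) add(obj, rows[k], "component span mismatch")
        if (!a$orientation[k] %in% c("+", "-", "?", "0", "na")) {
          add(obj, rows[k], "invalid orientation")
        }
      }
      expect_beg <- a$object_end[k] + 1L
    }
  }
  if (length(viol) == 0) {
    return(tibble::tibble(object_id = character(), row = integer(), message = character()))
  }
  dplyr::bind_rows(viol)
}

#' Construct object sequences from an AGP and its components
#'
#' Renders each AGP object as a sequence: component slices are taken 1-based
#' inclusive, `-` oriented components are reverse-complemented, and gap rows
#' become runs of `N`.
#'
#' @param agp An AGP tibble.
#' @param components Named character vector of component sequences.
#' @return Named character vector of object sequences, one per AGP object.
#' @export
build_fasta_from_agp <- function(agp, components) {
  vapply(split_keep_order(agp, agp$object_id), function(a) {
    a <- a[order(a$part_number), ]
    parts <- vapply(seq_len(nrow(a)), function(k) {
      if (a$component_type[k] %in% c("N", "U")) {
        return(strrep("N", a$gap_length[k]))
      }
      cid <- a$component_id[k]
      if (!cid %in% names(components)) stop("missing component: ", cid)
      if (a$component_end[k] > nchar(components[[cid]])) {
        stop("component coordinate overflow: ", cid)
      }
      s <- substr(components[[cid]], a$component_beg[k], a$component_end[k])
      if (identical(a$orientation[k], "-")) s <- revcomp(s)
      s
    }, "")
    paste(parts, collapse = "")
  }, "")
}

#' Oriented component adjacencies encoded by an AGP
#'
#' Extracts every pair of adjacent components within each object (gap rows do
#' not interrupt adjacency). `canonical` gives an orientation-symmetric key so
#' that the adjacency A+,B+ and its mirror B-,A- compare equal.
#'
#' @param agp An AGP tibble.
#' @return Tibble with `object_id`, `left_id`, `left_or`, `right_id`,
#'   `right_or`, `canonical`.
#' @export
agp_adjacencies <- function(agp) {
  comp <- agp[!agp$component_type %in% c("N", "U"), ]
  out <- lapply(split_keep_order(comp, comp$object_id), function(a) {
    a <- a[order(a$part_number), ]
    if (nrow(a) < 2) return(NULL)
    tibble::tibble(
      object_id = a$object_id[1],
      left_id = a$component_id[-nrow(a)], left_or = a$orientation[-nrow(a)],
      right_id = a$component_id[-1], right_or = a$orientation[-1]
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(object_id = character(), left_id = character(),
                          left_or = character(), right_id = character(),
                          right_or = character(), canonical = character()))
  }
  flip <- function(o) ifelse(o == "+", "-", "+")
  canon <- ifelse(
    out$left_id <= out$right_id,
    paste0(out$left_id, out$left_or, "|", out$right_id, out$right_or),
    paste0(out$right_id, flip(out$right_or), "|", out$left_id, flip(out$left_or))
  )
  out$canonical <- canon
  out
}

# split() that preserves first-appearance order of groups
split_keep_order <- function(df, key) {
  split(df, factor(key, levels = unique(key)))
}

# Internal builder: parts is a list of lists with kind = "component"
# (component_id, component_beg, component_end, orientation) or kind = "gap"
# (gap_length, known, evidence, gap_type, linkage). Coordinates 1-based.
assemble_agp_object <- function(object_id, parts) {
  rows <- vector("list", length(parts))
  pos <- 1L
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (identical(p$kind, "gap")) {
      len <- as.integer(p$gap_length)
      rows[[k]] <- tibble::tibble(
        object_id = object_id, object_beg = pos, object_end = pos + len - 1L,
        part_number = k,
        component_type = if (isTRUE(p$known)) "N" else "U",
        component_id = NA_character_, component_beg = NA_integer_,
        component_end = NA_integer_, orientation = NA_character_,
        gap_length = len,
        gap_type = p$gap_type %||% "scaffold",
        linkage = p$linkage %||% "yes",
        linkage_evidence = p$evidence %||% "align_genus"
      )
    } else {
      len <- as.integer(p$component_end - p$component_beg + 1L)
      rows[[k]] <- tibble::tibble(
        object_id = object_id, object_beg = pos, object_end = pos + len - 1L,
        part_number = k, component_type = "W",
        component_id = p$component_id,
        component_beg = as.integer(p$component_beg),
        component_end = as.integer(p$component_end),
        orientation = p$orientation %||% "+",
        gap_length = NA_integer_, gap_type = NA_character_,
        linkage = NA_character_, linkage_evidence = NA_character_
      )
    }
    pos <- pos + as.integer(rows[[k]]$object_end - rows[[k]]$object_beg + 1L)
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
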
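#' Read and write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The collection is
#' returned as a tibble with one row per set and the member probe ids in
#' a list-column, preserving file order.
#'
#' @param path File path.
#'
#' @return A tibble of class `gene_set_collection` with columns `name`,
#'   `annotation` and `probes` (list of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("GMT file is empty.")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::map(parts, function(fld) {
    if (length(fld) < 3) {
      abort(sprintf("GMT set '%s' has an empty member list.", fld[1]))
    }
    members <- fld[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(sprintf("GMT set '%s' has an empty member list.", fld[1]))
    }
    list(name = fld[1], annotation = fld[2], probes = members)
  })
  nm <- purrr::map_chr(sets, "name")
  if (anyDuplicated(nm)) {
    abort(paste0("Duplicate gene-set name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  out <- tibble(
    name = nm,
    annotation = purrr::map_chr(sets, "annotation"),
    probes = purrr::map(sets, "probes")
  )
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` tibble.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(all(c("name", "annotation", "probes") %in% names(collection)))
  lines <- purrr::pmap_chr(
    list(collection$name, collection$annotation, collection$probes),
    function(n, a, p) paste(c(n, a, p), collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection in memory
#'
#' @param sets Named list of character vectors (probe ids per set).
#' @param annotation Optional character vector of set descriptions.
#' @return A `gene_set_collection` tibble.
#' @export
gene_set_collection <- function(sets, annotation = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.")
  }
  if (any(lengths(sets) == 0)) {
    abort(paste0("Empty gene set(s): ",
                 paste(names(sets)[lengths(sets) == 0], collapse = ", ")))
  }
  out <- tibble(
    name = names(sets),
    annotation = annotation %||% rep("", length(sets)),
    probes = purrr::map(sets, as.character)
  )
  class(out) <- c("gene_set_collection", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
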
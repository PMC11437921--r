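#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member identifiers.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions are kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Cell-type (gene set) overrepresentation by Fisher exact tests
#'
#' One-sided enrichment test of a query protein set against each marker set,
#' within a stated background: the p-value is the hypergeometric upper tail
#' `P(X >= overlap)` of the 2x2 table (equivalent to the one-sided Fisher
#' exact test). Marker sets are intersected with the background before
#' testing and identifiers are collapsed case-insensitively.
#'
#' @param query character vector of protein/gene ids (must be contained in
#'   `background`).
#' @param background character vector of all quantified ids.
#' @param marker_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame sorted by p-value with columns `set_name`,
#'   `overlap_count`, `set_size`, `query_size`, `background_size`,
#'   `p_value`, `overlap_ids` (semicolon-joined).
#' @export
fisher_enrichment <- function(query, background, marker_sets) {
  norm <- function(x) unique(toupper(as.character(x)))
  query <- norm(query)
  background <- norm(background)
  if (length(background) == 0) stop("empty background")
  if (!all(query %in% background))
    stop("query contains ids absent from the background")
  if (is.null(names(marker_sets)) || any(!nzchar(names(marker_sets))))
    stop("'marker_sets' must be a named list")
  N <- length(background)
  k <- length(query)
  rows <- lapply(names(marker_sets), function(nm) {
    s <- intersect(norm(marker_sets[[nm]]), background)
    ov <- intersect(query, s)
    m <- length(s)
    p <- stats::phyper(length(ov) - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = length(ov), set_size = m,
               query_size = k, background_size = N, p_value = p,
               overlap_ids = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}
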
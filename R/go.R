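#' Read a UniProt-to-GO mapping table
#'
#' @param path TSV with columns `uniprot_id`, `go_id`, `namespace`
#'   (`process` or `function`). The mapping is many-to-many and may
#'   leave IDs unmapped.
#' @return tibble of unique mapping pairs.
#' @export
read_go_mapping <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  mp <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("uniprot_id", "go_id", "namespace"), names(mp))
  if (length(miss)) {
    rlang::abort(paste0("mapping lacks columns: ", paste(miss, collapse = ", ")))
  }
  dplyr::distinct(mp)
}

#' Map annotation IDs to GO terms
#'
#' Offline table join replacing the interactive UniProt-to-GO conversion
#' step: returns the union of terms mapped to the input IDs in the
#' requested namespace. The mapping is not one-to-one - an ID may
#' contribute several terms or none. IDs with no term in the namespace
#' are reported, never silently dropped.
#'
#' @param uniprot_ids character vector (duplicates are ignored).
#' @param mapping mapping tibble from [read_go_mapping()] or
#'   [simulate_go_mapping()].
#' @param namespace `"process"`, `"function"`, or `"both"`.
#' @return list of class `go_terms`: `terms` (character, sorted unique
#'   GO IDs) and `unmapped` (character input IDs with no term).
#' @export
map_to_go <- function(uniprot_ids, mapping, namespace = c("process", "function", "both")) {
  namespace <- match.arg(namespace)
  if (!is.data.frame(mapping) || !nrow(mapping)) {
    rlang::abort("empty GO mapping table")
  }
  ids <- unique(as.character(uniprot_ids))
  mp <- mapping
  if (namespace != "both") mp <- mp[mp$namespace == namespace, , drop = FALSE]
  hit <- mp[mp$uniprot_id %in% ids, , drop = FALSE]
  structure(
    list(terms = sort(unique(hit$go_id)),
         unmapped = sort(setdiff(ids, hit$uniprot_id)),
         namespace = namespace),
    class = "go_terms"
  )
}

#' @export
print.go_terms <- function(x, ...) {
  cat(sprintf("<go_terms> %d %s term(s), %d unmapped ID(s)\n",
              length(x$terms), x$namespace, length(x$unmapped)))
  invisible(x)
}

#' Compare significant-term sets across field sites
#'
#' Computes every exclusive Venn region over two or more per-site term
#' sets (terms in exactly that combination of sites and no others),
#' plus the pairwise shared-term lists used to annotate cross-site
#' figures. Region counts satisfy inclusion-exclusion exactly: summing
#' the counts of all regions containing a site recovers that site's set
#' size.
#'
#' @param site_term_sets named list (>= 2 entries) of character vectors;
#'   `go_terms` objects are accepted and reduced to their `terms`.
#' @return object of class `term_comparison`: `$regions` (tibble:
#'   `region`, `n_sites`, `n_terms`, `terms` list-column), `$pairwise`
#'   (tibble: `site_a`, `site_b`, `n_shared`, `shared` list-column) and
#'   `$sets` (the input sets, deduplicated).
#' @export
compare_sites <- function(site_term_sets) {
  if (!is.list(site_term_sets) || length(site_term_sets) < 2) {
    rlang::abort("need term sets for at least 2 sites")
  }
  if (is.null(names(site_term_sets)) || any(names(site_term_sets) == "")) {
    rlang::abort("`site_term_sets` must be a fully named list")
  }
  sets <- purrr::map(site_term_sets, function(s) {
    if (inherits(s, "go_terms")) s <- s$terms
    unique(as.character(s))
  })
  sites <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)

  combos <- purrr::map(seq_along(sites), function(k) {
    utils::combn(sites, k, simplify = FALSE)
  }) |> unlist(recursive = FALSE)
  regions <- purrr::map(combos, function(cmb) {
    inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
    outside <- rowSums(membership[, setdiff(sites, cmb), drop = FALSE]) > 0
    terms <- universe[inside & !outside]
    tibble::tibble(region = paste(cmb, collapse = "&"),
                   n_sites = length(cmb),
                   n_terms = length(terms),
                   terms = list(sort(terms)))
  }) |> dplyr::bind_rows()

  pairs <- utils::combn(sites, 2, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(p) {
    sh <- sort(intersect(sets[[p[1]]], sets[[p[2]]]))
    tibble::tibble(site_a = p[1], site_b = p[2],
                   n_shared = length(sh), shared = list(sh))
  }) |> dplyr::bind_rows()

  structure(list(regions = regions, pairwise = pairwise, sets = sets),
            class = "term_comparison")
}

#' @export
print.term_comparison <- function(x, ...) {
  cat(sprintf("<term_comparison> %d sites, %d distinct terms\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  print(x$regions[, c("region", "n_terms")], n = nrow(x$regions))
  invisible(x)
}

#' Export a term network for external layout tools
#'
#' Writes significant terms as a graph whose node `frequency` attribute
#' (e.g. the term's frequency in the GO database, which figure tools map
#' to node size) and supplied edges (e.g. semantic-similarity links) are
#' preserved. Edges are taken as given - no clustering or similarity
#' computation happens here.
#'
#' @param nodes tibble with `term` and `frequency` columns.
#' @param edges optional tibble with `from` and `to` columns referring
#'   to `nodes$term`; `NULL` or empty for a node-only graph.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"` (tab-separated; node table
#'   written alongside with suffix `.nodes.tsv`).
#' @return `path`, invisibly.
#' @export
export_network <- function(nodes, edges = NULL, path,
                           format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (!is.data.frame(nodes) || !nrow(nodes)) rlang::abort("empty node set")
  miss <- setdiff(c("term", "frequency"), names(nodes))
  if (length(miss)) {
    rlang::abort(paste0("nodes lack columns: ", paste(miss, collapse = ", ")))
  }
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(0), to = character(0))
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes$term)
  if (length(unknown)) {
    rlang::abort(paste0("edge endpoint(s) not in node set: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = as.data.frame(nodes))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(tibble::as_tibble(edges), path)
    readr::write_tsv(tibble::as_tibble(nodes),
                     paste0(path, ".nodes.tsv"))
  }
  invisible(path)
}
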
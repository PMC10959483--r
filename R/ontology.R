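#' Parse an OBO-format ontology
#'
#' Reads a flat OBO file (format-version 1.2/1.4 subset: `id`, `name`,
#' `is_a`, `alt_id`, `is_obsolete`) into an ontology graph. Only `is_a`
#' edges are kept; obsolete terms are dropped and their stanzas ignored;
#' `alt_id`s are recorded so that annotations using a superseded id can be
#' resolved to the primary id. The child-to-parent graph is verified to be
#' acyclic.
#'
#' @param path Path to an OBO text file.
#' @return An object of class `onto_graph`: a list with elements
#'   `terms` (character vector of term ids), `parents` (named list,
#'   term -> character vector of direct parents), `children` (reverse map),
#'   `labels` (named character of term names), `alt` (named character
#'   mapping alternative ids to primary ids), `roots` (terms with no
#'   parent), and `edges` (tibble with columns `child`, `parent`).
#' @export
parse_obo <- function(path) {
  lines <- readr::read_lines(path)
  # stanza boundaries: [Term] blocks only
  starts <- which(lines == "[Term]")
  other_stanza <- which(startsWith(lines, "[") & lines != "[Term]")
  bounds <- sort(c(starts, other_stanza, length(lines) + 1L))
  ids <- character(0)
  labels <- character(0)
  alt_from <- character(0)
  alt_to <- character(0)
  edge_child <- character(0)
  edge_parent <- character(0)
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    block <- block[nzchar(block)][-1L]
    kv <- stringr::str_match(block, "^([A-Za-z_]+):\\s*(.*?)\\s*(!.*)?$")
    bad <- which(is.na(kv[, 1]))
    if (length(bad) > 0) {
      stop("malformed OBO stanza near line ", s + bad[1], ": '",
           block[bad[1]], "'", call. = FALSE)
    }
    keys <- kv[, 2]
    vals <- stringr::str_trim(kv[, 3])
    if (any(keys == "is_obsolete" & tolower(vals) == "true")) next
    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      stop("malformed OBO stanza near line ", s, ": missing id", call. = FALSE)
    }
    ids <- c(ids, id)
    nm <- vals[keys == "name"]
    labels <- c(labels, if (length(nm) > 0) nm[1] else NA_character_)
    for (a in vals[keys == "alt_id"]) {
      alt_from <- c(alt_from, a)
      alt_to <- c(alt_to, id)
    }
    for (p in vals[keys == "is_a"]) {
      # strip trailing comment already handled; take the bare target id
      tgt <- stringr::str_split_1(p, "\\s+")[1]
      edge_child <- c(edge_child, id)
      edge_parent <- c(edge_parent, tgt)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  keep <- edge_parent %in% ids  # edges into obsolete/unknown parents dropped
  edges <- tibble::tibble(child = edge_child[keep], parent = edge_parent[keep])
  edges <- dplyr::distinct(edges)
  g <- new_onto_graph(ids, edges, stats::setNames(labels, ids),
                      stats::setNames(alt_to, alt_from))
  assert_acyclic(g)
  g
}

new_onto_graph <- function(terms, edges, labels = NULL, alt = NULL) {
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  structure(
    list(
      terms = terms,
      parents = parents,
      children = children,
      labels = labels %||% stats::setNames(rep(NA_character_, length(terms)), terms),
      alt = alt %||% character(0),
      roots = terms[lengths(parents) == 0L],
      edges = edges
    ),
    class = "onto_graph"
  )
}

# Kahn's algorithm; reports cycle members on failure
assert_acyclic <- function(g) {
  indeg <- lengths(g$parents)  # treat child->parent, count outgoing as indeg proxy
  # topological sort over child->parent edges: repeatedly remove parentless terms
  remaining <- g$terms
  pa <- g$parents
  repeat {
    free <- remaining[vapply(pa[remaining], length, 1L) == 0L]
    if (length(free) == 0L) break
    remaining <- setdiff(remaining, free)
    pa[remaining] <- lapply(pa[remaining], setdiff, y = free)
  }
  if (length(remaining) > 0L) {
    stop("ontology is_a graph contains a cycle involving: ",
         paste(remaining, collapse = ", "), call. = FALSE)
  }
  invisible(g)
}

#' @export
print.onto_graph <- function(x, ...) {
  cat("<onto_graph> ", length(x$terms), " terms, ", nrow(x$edges),
      " is_a edges, roots: ", paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an ontology graph back to OBO text
#'
#' Emits a minimal OBO 1.2 file that [parse_obo()] reads back to the same
#' term and edge sets.
#'
#' @param g An `onto_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  out <- c("format-version: 1.2", "")
  for (t in g$terms) {
    blk <- c("[Term]", paste0("id: ", t))
    if (!is.na(g$labels[[t]])) blk <- c(blk, paste0("name: ", g$labels[[t]]))
    alts <- names(g$alt)[g$alt == t]
    blk <- c(blk, paste0("alt_id: ", alts))
    blk <- c(blk, paste0("is_a: ", g$parents[[t]]))
    out <- c(out, blk, "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

check_terms <- function(g, terms, what = "term") {
  missing <- setdiff(terms, g$terms)
  if (length(missing) > 0) {
    stop("unknown ", what, "(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Ancestors of a term
#'
#' All terms reachable from `term` by following child-to-parent `is_a`
#' edges, excluding `term` itself.
#'
#' @param g An `onto_graph`.
#' @param term A term id present in `g`.
#' @return Character vector of ancestor term ids (unordered, unique).
#' @export
onto_ancestors <- function(g, term) {
  check_terms(g, term)
  seen <- character(0)
  frontier <- g$parents[[term]]
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(g$parents[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' Direct children of a term
#'
#' One-edge descendants. With the ontology root for phenotypic
#' abnormality this yields the system-level analysis panel (organ-system
#' top-level terms).
#'
#' @inheritParams onto_ancestors
#' @return Character vector of direct child term ids.
#' @export
onto_children <- function(g, term) {
  check_terms(g, term)
  g$children[[term]] %||% character(0)
}

#' Descendants of a term
#'
#' @inheritParams onto_ancestors
#' @return Character vector of all descendants, excluding `term`.
#' @export
onto_descendants <- function(g, term) {
  check_terms(g, term)
  seen <- character(0)
  frontier <- onto_children(g, term)
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(g$children[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' Induced subgraph rooted at a term
#'
#' Returns the induced ontology on `root` plus all its descendants, used
#' to report which members of an organ-system subgraph are independently
#' significant.
#'
#' @inheritParams onto_ancestors
#' @param root Term id to root the subgraph at.
#' @return An `onto_graph` restricted to `root` and its descendants.
#' @export
rooted_subgraph <- function(g, root) {
  keep <- c(root, onto_descendants(g, root))
  edges <- dplyr::filter(g$edges, .data$child %in% keep, .data$parent %in% keep)
  new_onto_graph(keep, edges, g$labels[keep],
                 g$alt[g$alt %in% keep])
}

# term -> sorted ancestor list for every term (memo-free, linear passes)
ancestor_sets <- function(g) {
  # process in topological order so parents are resolved before children
  order <- character(0)
  pa <- g$parents
  remaining <- g$terms
  repeat {
    free <- remaining[vapply(pa[remaining], length, 1L) == 0L]
    if (length(free) == 0L) break
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
    pa[remaining] <- lapply(pa[remaining], setdiff, y = free)
  }
  anc <- stats::setNames(vector("list", length(g$terms)), g$terms)
  for (t in order) {
    ps <- g$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Map coded events to ontology annotations
#'
#' Applies a concept map (source code to ontology terms, one row per
#' pair) to a table of coded events. A code mapping to several terms
#' fans out to one annotation per term; unmapped codes are dropped and
#' counted. Alternative ids in the map are resolved to primary ids.
#'
#' @param events Data frame with columns `person_id`, `code`, `age_years`.
#' @param concept_map Data frame with columns `source_code`, `term_id`.
#' @param g An `onto_graph`; mapped terms must exist in it.
#' @return Tibble of annotations with columns `person_id`, `term`,
#'   `age_years`, carrying attributes `n_unmapped` (events whose code had
#'   no mapping) and `unmapped_codes`.
#' @export
map_concepts <- function(events, concept_map, g) {
  stopifnot(all(c("person_id", "code", "age_years") %in% names(events)),
            all(c("source_code", "term_id") %in% names(concept_map)))
  cm <- dplyr::distinct(concept_map, .data$source_code, .data$term_id)
  # resolve alt ids to primary ids before validating
  is_alt <- cm$term_id %in% names(g$alt)
  cm$term_id[is_alt] <- unname(g$alt[cm$term_id[is_alt]])
  check_terms(g, unique(cm$term_id), what = "mapped term")
  hit <- dplyr::inner_join(events, cm,
                           by = c(code = "source_code"),
                           relationship = "many-to-many")
  unmapped <- dplyr::anti_join(events, cm, by = c(code = "source_code"))
  ann <- tibble::tibble(
    person_id = hit$person_id,
    term = hit$term_id,
    age_years = hit$age_years
  )
  attr(ann, "n_unmapped") <- nrow(unmapped)
  attr(ann, "unmapped_codes") <- unique(unmapped$code)
  ann
}

#' Propagate annotations to all ancestors (true-path rule)
#'
#' A person annotated with a term is implicitly annotated with every
#' ancestor of that term. The age attached to a propagated ancestor is
#' the minimum age among the annotations contributing it — the earliest
#' evidence of the broader phenotype — which is what age-binned scans
#' consume. The operation is idempotent.
#'
#' @param annotations Data frame with columns `person_id`, `term`, and
#'   optionally `age_years`.
#' @param g An `onto_graph` containing every annotated term (alt ids are
#'   resolved first).
#' @return Tibble `person_id`, `term`, `age_years` (if present on input),
#'   one row per (person, term), closed under the ancestor relation.
#' @export
propagate_annotations <- function(annotations, g) {
  stopifnot(all(c("person_id", "term") %in% names(annotations)))
  ann <- annotations
  is_alt <- ann$term %in% names(g$alt)
  if (any(is_alt)) ann$term[is_alt] <- unname(g$alt[ann$term[is_alt]])
  unknown <- setdiff(unique(ann$term), g$terms)
  if (length(unknown) > 0) {
    stop("annotations contain terms absent from the ontology: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  has_age <- "age_years" %in% names(ann)
  anc <- ancestor_sets(g)
  reach <- lapply(anc, function(a) a)  # ancestors only; self added below
  expand <- tibble::tibble(
    term = rep(g$terms, times = lengths(reach) + 1L),
    out = unlist(mapply(function(t, a) c(t, a), g$terms, reach,
                        SIMPLIFY = FALSE), use.names = FALSE)
  )
  big <- dplyr::inner_join(ann, expand, by = "term",
                           relationship = "many-to-many")
  if (has_age) {
    out <- big |>
      dplyr::group_by(.data$person_id, term = .data$out) |>
      dplyr::summarise(age_years = min(.data$age_years), .groups = "drop")
  } else {
    out <- dplyr::distinct(big, .data$person_id, term = .data$out)
  }
  dplyr::arrange(out, .data$person_id, .data$term)
}

#' Read a concept map from delimited text
#'
#' Two-column tab- or comma-separated text with header columns
#' `source_code`, `term_id`.
#'
#' @param path File path.
#' @param g Optional `onto_graph`; if supplied, targets are validated and
#'   unresolvable targets raise an error.
#' @return Tibble `source_code`, `term_id`.
#' @export
read_concept_map <- function(path, g = NULL) {
  cm <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("source_code", "term_id") %in% names(cm)))
  cm <- dplyr::distinct(cm, .data$source_code, .data$term_id)
  if (!is.null(g)) {
    resolved <- ifelse(cm$term_id %in% names(g$alt),
                       unname(g$alt[cm$term_id]), cm$term_id)
    check_terms(g, unique(resolved), what = "mapped term")
  }
  cm
}
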
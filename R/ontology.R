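# Ontology handling: OBO parsing, root-path enumeration, and the
# path-based phenotype similarity used to refine genomic matches.

#' Parse an OBO 1.2 flat file into an ontology
#'
#' Reads `[Term]` stanzas (id, name, is_a, alt_id, replaced_by,
#' is_obsolete) and assembles the directed acyclic graph of `is_a`
#' relations. Only `is_a` edges define the hierarchy; `relationship:`
#' lines (e.g. part_of) are ignored, following the usual convention for
#' HPO semantic similarity. The root is detected structurally as the
#' unique non-obsolete term without parents, unless `root_id` is given
#' explicitly (use `"HP:0000001"` for the real HPO).
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @param root_id Optional accession to use as root instead of
#'   structural detection.
#' @return An object of class `ontology`: a list with elements `terms`
#'   (named list; each term has `id`, `name`, `parents`, `obsolete`,
#'   `alt_ids`, `replaced_by`), `root_id`, `aliases` (named character
#'   vector mapping alt_id to primary id) and `version`.
#' @examples
#' obo <- c("[Term]", "id: X:1", "name: root",
#'          "[Term]", "id: X:2", "name: child", "is_a: X:1 ! root")
#' ont <- parse_obo(obo)
#' ont$root_id
#' @export
parse_obo <- function(x, root_id = NULL) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else x
  lines <- sub("\\s+$", "", lines)

  version <- ""
  dv <- grep("^data-version:", lines, value = TRUE)
  if (length(dv)) version <- sub("^data-version:\\s*", "", dv[1])

  # stanza boundaries
  starts <- grep("^\\[", lines)
  terms <- list()
  aliases <- character()
  if (length(starts)) {
    ends <- c(starts[-1] - 1L, length(lines))
    for (k in seq_along(starts)) {
      if (lines[starts[k]] != "[Term]") next
      body <- lines[seq(starts[k] + 1L, ends[k])]
      body <- body[nzchar(body)]
      getv <- function(key) {
        v <- body[startsWith(body, paste0(key, ":"))]
        sub(paste0("^", key, ":\\s*"), "", v)
      }
      id <- getv("id")[1]
      if (is.na(id) || !nzchar(id)) next
      isa <- getv("is_a")
      # strip trailing comment "HP:x ! name"
      parents <- unique(sub("\\s*(!.*)?$", "", isa))
      parents <- parents[nzchar(parents)]
      obsolete <- any(grepl("^true", getv("is_obsolete")))
      alt <- getv("alt_id")
      repl <- getv("replaced_by")
      terms[[id]] <- list(
        id = id,
        name = getv("name")[1] %||% "",
        parents = if (obsolete) character() else parents,
        obsolete = obsolete,
        alt_ids = alt,
        replaced_by = if (length(repl)) repl[1] else NA_character_
      )
      if (length(alt)) aliases[alt] <- id
    }
  }
  if (!length(terms)) stop("no [Term] stanzas found")

  active <- Filter(function(t) !t$obsolete, terms)
  if (is.null(root_id)) {
    roots <- names(Filter(function(t) length(t$parents) == 0L, active))
    if (length(roots) == 0L)
      stop("ontology has no root (every term has a parent)")
    if (length(roots) > 1L)
      stop("ontology has multiple root candidates: ",
           paste(roots, collapse = ", "))
    root_id <- roots
  } else if (!root_id %in% names(terms)) {
    stop("declared root '", root_id, "' not found in ontology")
  }

  ont <- structure(list(terms = terms, root_id = root_id,
                        aliases = aliases, version = version),
                   class = "ontology")
  cyc <- .find_cycle(ont)
  if (!is.null(cyc))
    stop("cyclic is_a relation: ", paste(cyc, collapse = " -> "))
  ont
}

#' @export
print.ontology <- function(x, ...) {
  n <- length(x$terms)
  nobs <- sum(vapply(x$terms, function(t) t$obsolete, logical(1)))
  cat("Ontology:", n, "terms (", nobs, "obsolete ), root", x$root_id, "\n")
  invisible(x)
}

# Kahn-style check; returns one cycle as a vector of ids, or NULL.
.find_cycle <- function(ont) {
  active <- Filter(function(t) !t$obsolete, ont$terms)
  ids <- names(active)
  state <- new.env(parent = emptyenv())  # 0 unvisited, 1 on stack, 2 done
  path <- character()
  cycle <- NULL
  visit <- function(id) {
    if (!is.null(cycle)) return()
    s <- state[[id]] %||% 0L
    if (s == 2L) return()
    if (s == 1L) {
      i <- match(id, path)
      cycle <<- c(path[seq(i, length(path))], id)
      return()
    }
    state[[id]] <- 1L
    path <<- c(path, id)
    for (p in active[[id]]$parents) {
      if (p %in% ids) visit(p)
    }
    path <<- path[-length(path)]
    state[[id]] <- 2L
  }
  for (id in ids) visit(id)
  cycle
}

#' Resolve a submitted term accession against an ontology
#'
#' Alt-ids are mapped to their primary term; obsolete terms are replaced
#' via their `replaced_by` pointer when present. Unknown accessions and
#' obsolete terms without replacement return `NA`, to be rejected at
#' submission validation.
#'
#' @param ont An `ontology`.
#' @param id Term accession.
#' @return The resolved primary accession, or `NA_character_`.
#' @export
resolve_term <- function(ont, id) {
  if (id %in% names(ont$aliases)) id <- unname(ont$aliases[[id]])
  t <- ont$terms[[id]]
  if (is.null(t)) return(NA_character_)
  if (t$obsolete) {
    r <- t$replaced_by
    if (is.na(r)) return(NA_character_)
    return(resolve_term(ont, r))
  }
  id
}

#' Enumerate all root paths of a term
#'
#' Returns every distinct directed path (as a node set) from `term_id`
#' up the `is_a` hierarchy to the ontology root, inclusive of both
#' endpoints. Two paths identical as node sets count as one path. The
#' result is deterministic (paths sorted by their canonical key) and
#' independent of traversal order.
#'
#' @param ont An `ontology`.
#' @param term_id Term accession (non-obsolete).
#' @param max_paths Per-term limit guarding against exponential blow-up
#'   in dense DAGs; exceeded limits raise an error.
#' @return A list of character vectors (sorted node-id sets).
#' @export
enumerate_root_paths <- function(ont, term_id, max_paths = 10000L) {
  if (!term_id %in% names(ont$terms))
    stop("unknown term: ", term_id)
  if (ont$terms[[term_id]]$obsolete)
    stop("obsolete term: ", term_id)
  memo <- new.env(parent = emptyenv())
  .root_paths(ont, term_id, memo, max_paths)
}

.root_paths <- function(ont, id, memo, max_paths) {
  hit <- memo[[id]]
  if (!is.null(hit)) return(hit)
  if (id == ont$root_id) {
    res <- list(id)
  } else {
    parents <- ont$terms[[id]]$parents
    if (!length(parents))
      stop("term ", id, " does not reach the root")
    acc <- list()
    for (p in parents) {
      if (is.null(ont$terms[[p]]) || ont$terms[[p]]$obsolete)
        stop("term ", id, " has unknown or obsolete parent ", p)
      for (pp in .root_paths(ont, p, memo, max_paths)) {
        acc[[length(acc) + 1L]] <- sort(c(pp, id))
      }
    }
    keys <- vapply(acc, paste, character(1), collapse = "\r")
    res <- acc[!duplicated(keys)]
    res <- res[order(vapply(res, paste, character(1), collapse = "\r"))]
    if (length(res) > max_paths)
      stop("term ", id, " has more than ", max_paths,
           " root paths; raise max_paths if this is intended")
  }
  memo[[id]] <- res
  res
}

#' Pre-compute the root-path cache of a whole ontology
#'
#' Enumerates the root paths of every non-obsolete term once, so that
#' term and case similarities reduce to in-memory set operations. The
#' cache is what a deployment rebuilds whenever the ontology is updated.
#'
#' @param ont An `ontology`.
#' @param max_paths Per-term path limit (see [enumerate_root_paths()]).
#' @return An object of class `path_cache`: list with `paths` (named
#'   list of path lists), `root_id`, `ontology_version`.
#' @export
precompute_path_cache <- function(ont, max_paths = 10000L) {
  memo <- new.env(parent = emptyenv())
  active <- names(Filter(function(t) !t$obsolete, ont$terms))
  paths <- lapply(active, function(id) .root_paths(ont, id, memo, max_paths))
  names(paths) <- active
  structure(list(paths = paths, root_id = ont$root_id,
                 ontology_version = ont$version),
            class = "path_cache")
}

#' @export
print.path_cache <- function(x, ...) {
  np <- sum(lengths(x$paths))
  cat("Path cache:", length(x$paths), "terms,", np, "root paths\n")
  invisible(x)
}

#' Save / load a path cache as JSON
#'
#' The on-disk format is a single JSON object
#' `{term_id: [[node ids...], ...], "ontology_version": ..., "root_id": ...}`.
#'
#' @param cache A `path_cache`.
#' @param path File path.
#' @return `load_path_cache` returns a `path_cache`.
#' @export
save_path_cache <- function(cache, path) {
  obj <- cache$paths
  obj[["ontology_version"]] <- cache$ontology_version
  obj[["root_id"]] <- cache$root_id
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_path_cache
#' @export
load_path_cache <- function(path) {
  obj <- jsonlite::read_json(path)
  version <- unlist(obj[["ontology_version"]]) %||% ""
  root_id <- unlist(obj[["root_id"]])
  obj[["ontology_version"]] <- NULL
  obj[["root_id"]] <- NULL
  paths <- lapply(obj, function(ps) lapply(ps, function(p) unlist(p)))
  structure(list(paths = paths, root_id = root_id,
                 ontology_version = version),
            class = "path_cache")
}

#' Path-based similarity between two ontology terms
#'
#' The similarity of terms \eqn{c} and \eqn{c'} is the maximum Jaccard
#' index \eqn{|p \cap p'| / |p \cup p'|} over all pairs of root paths
#' \eqn{p} of \eqn{c} and \eqn{p'} of \eqn{c'}. Because paths include
#' both the term and the root, the measure is 1 exactly for identical
#' terms, lies in (0, 1] (any two paths share at least the root), and
#' rewards deep-rooted (precise) annotations: a parent-child pair deep
#' in the ontology scores higher than the same relation near the root.
#'
#' @param cache A `path_cache`.
#' @param c1,c2 Term accessions present in the cache.
#' @return Similarity in `[0, 1]`.
#' @export
term_similarity <- function(cache, c1, c2) {
  p1 <- cache$paths[[c1]]
  p2 <- cache$paths[[c2]]
  if (is.null(p1)) stop("term not in path cache: ", c1)
  if (is.null(p2)) stop("term not in path cache: ", c2)
  if (c1 == c2) return(1)
  best <- 0
  for (p in p1) {
    np <- length(p)
    for (q in p2) {
      ni <- sum(p %in% q)
      j <- ni / (np + length(q) - ni)
      if (j > best) best <- j
    }
  }
  best
}

#' Case-level phenotype similarity (best-match average)
#'
#' For phenotype profiles \eqn{d} and \eqn{d'} (non-empty sets of
#' ontology terms), the similarity is the symmetrised best-match
#' average of term similarities:
#' \deqn{\frac{1}{2|d|}\sum_{c \in d} \max_{c' \in d'} sim(c,c') +
#'       \frac{1}{2|d'|}\sum_{c' \in d'} \max_{c \in d} sim(c,c')}
#' It is symmetric, equals 1 on identical profiles, and collapses to
#' [term_similarity()] for singleton profiles.
#'
#' @param cache A `path_cache`.
#' @param d,d2 Character vectors of term accessions (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @export
case_similarity <- function(cache, d, d2) {
  d <- unique(d); d2 <- unique(d2)
  if (!length(d) || !length(d2)) stop("phenotype profiles must be non-empty")
  sim <- outer(seq_along(d), seq_along(d2),
               Vectorize(function(i, j) term_similarity(cache, d[i], d2[j])))
  mean(apply(sim, 1, max)) / 2 + mean(apply(sim, 2, max)) / 2
}
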
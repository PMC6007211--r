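# Dependency-graph data model and the declarative pattern engine.
#
# A graph holds the sentence tokens as nodes plus labeled directed edges in
# the canonical label set used throughout the package:
#   nsubj, nsubj:pass, dobj, det, amod, compound, nummod, appos, neg, conj,
#   nmod:<prep>   (preposition-collapsed nominal modifier)
#   nmod:es       (entity attached by an entity-separator phrase)
# After conjunct propagation the edge set is a graph, not a tree.

#' Construct a dependency graph
#'
#' @param nodes Token data.frame (`idx`, `surface`, `lemma`, `pos`, `start`,
#'   `end`) as produced by [tokenize()].
#' @param edges data.frame with integer columns `gov`, `dep` and character
#'   `label`.
#' @param root Token index of the root (main predicate).
#' @param text The sentence text the offsets refer to.
#' @param es_links data.frame(`head`, `es_pos`, `fronted`) recording which
#'   noun-phrase heads were introduced by an entity separator.
#' @param es_tokens Integer positions of entity-separator tokens.
#' @param preds Integer positions of clause predicates.
#' @return An `exprel_depgraph`.
#' @export
dep_graph <- function(nodes, edges, root, text = "",
                      es_links = data.frame(head = integer(0),
                                            es_pos = integer(0),
                                            fronted = logical(0)),
                      es_tokens = integer(0), preds = integer(0)) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    stopifnot(all(edges$gov %in% nodes$idx), all(edges$dep %in% nodes$idx),
              all(edges$gov != edges$dep), all(nzchar(edges$label)))
  }
  structure(list(nodes = nodes, edges = edges, root = root, text = text,
                 es_links = es_links, es_tokens = es_tokens, preds = preds),
            class = "exprel_depgraph")
}

#' @export
print.exprel_depgraph <- function(x, ...) {
  cat("<exprel_depgraph> ", nrow(x$nodes), " tokens, ",
      nrow(x$edges), " edges, root = ",
      if (length(x$root) && !is.na(x$root)) x$nodes$surface[x$root] else "?",
      "\n", sep = "")
  if (nrow(x$edges)) {
    lab <- sprintf("  %s(%s-%d, %s-%d)", x$edges$label,
                   x$nodes$surface[x$edges$gov], x$edges$gov,
                   x$nodes$surface[x$edges$dep], x$edges$dep)
    cat(lab, sep = "\n")
  }
  invisible(x)
}

# --- pattern loading -------------------------------------------------------

#' Load a dependency pattern set
#'
#' Patterns are declarative YAML entries with node constraints (regexes over
#' `pos`, `lemma`, `surface`, or membership in a named trigger set), edge
#' constraints (label regex between two variables) and result variables.
#' Ill-formed patterns (disconnected constraint graph, unknown variables or
#' trigger sets, result variables without constraints) raise an error at load
#' time, not at match time.
#'
#' @param path YAML file.
#' @param triggers Trigger lexicons (for validating `lexicon:` references).
#' @return An `exprel_patterns` list.
#' @export
load_patterns <- function(path, triggers) {
  raw <- yaml::read_yaml(path)
  pats <- raw$patterns
  if (is.null(pats) || !length(pats)) stop("no patterns in ", path)
  out <- lapply(pats, function(p) {
    vars <- names(p$nodes)
    if (is.null(p$name) || is.null(vars) || !length(vars))
      stop("pattern missing name or nodes in ", path)
    edges <- lapply(p$edges, function(e) {
      if (!e$from %in% vars || !e$to %in% vars)
        stop("pattern '", p$name, "': edge references unknown variable")
      e
    })
    # connectivity of the constraint graph
    if (length(vars) > 1L) {
      seen <- vars[1]
      repeat {
        grow <- unique(unlist(lapply(edges, function(e)
          if (e$from %in% seen || e$to %in% seen) c(e$from, e$to))))
        grow <- union(seen, grow)
        if (length(grow) == length(seen)) break
        seen <- grow
      }
      if (length(seen) < length(vars))
        stop("pattern '", p$name, "': constraint graph is disconnected")
    }
    res <- p$result %||% vars
    if (!all(res %in% vars))
      stop("pattern '", p$name, "': result variable not constrained")
    for (nc in p$nodes) {
      if (!is.null(nc$lexicon) && is.null(triggers[[nc$lexicon]]))
        stop("pattern '", p$name, "': unknown trigger set '", nc$lexicon, "'")
    }
    list(name = p$name, family = p$family %||% p$name, nodes = p$nodes,
         edges = edges, result = res)
  })
  structure(out, class = "exprel_patterns")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.node_ok <- function(nc, nodes, i, triggers) {
  if (length(nc) == 0L) return(TRUE)
  if (!is.null(nc$pos) && !grepl(nc$pos, nodes$pos[i])) return(FALSE)
  if (!is.null(nc$lemma) && !grepl(nc$lemma, nodes$lemma[i], ignore.case = TRUE))
    return(FALSE)
  if (!is.null(nc$surface) && !grepl(nc$surface, nodes$surface[i], ignore.case = TRUE))
    return(FALSE)
  if (!is.null(nc$lexicon) &&
      !trig_has(triggers[[nc$lexicon]], nodes$surface[i], nodes$lemma[i]))
    return(FALSE)
  TRUE
}

#' Match one pattern against a dependency graph
#'
#' Backtracking search for all injective assignments of pattern variables to
#' graph nodes satisfying every node and edge constraint. Bindings are
#' deduplicated on the pattern's result variables and returned in a
#' deterministic order (sorted by the bound token indices).
#'
#' @param pattern A single pattern (one element of [load_patterns()]'s value).
#' @param graph An `exprel_depgraph`.
#' @param triggers Trigger lexicons for `lexicon:` node constraints.
#' @return A list of named integer vectors (variable -> token index),
#'   restricted to the result variables.
#' @export
dep_match <- function(pattern, graph, triggers) {
  vars <- names(pattern$nodes)
  nodes <- graph$nodes
  n <- nrow(nodes)
  if (n == 0L) return(list())
  cand <- lapply(vars, function(v) {
    nc <- pattern$nodes[[v]]
    which(vapply(seq_len(n), function(i) .node_ok(nc, nodes, i, triggers),
                 logical(1)))
  })
  names(cand) <- vars
  if (any(lengths(cand) == 0L)) return(list())
  edges <- graph$edges
  res <- list()
  assign_next <- function(k, binding) {
    if (k > length(vars)) {
      res[[length(res) + 1L]] <<- binding
      return(invisible())
    }
    v <- vars[k]
    for (i in cand[[v]]) {
      if (i %in% binding) next   # injective
      binding[v] <- i
      ok <- TRUE
      for (e in pattern$edges) {
        gi <- binding[e$from]; di <- binding[e$to]
        if (is.na(gi) || is.na(di)) next
        hit <- any(edges$gov == gi & edges$dep == di & grepl(e$label, edges$label))
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) assign_next(k + 1L, binding)
      binding[v] <- NA_integer_
    }
  }
  empty <- stats::setNames(rep(NA_integer_, length(vars)), vars)
  assign_next(1L, empty)
  if (!length(res)) return(list())
  proj <- lapply(res, function(b) b[pattern$result])
  keys <- vapply(proj, paste, collapse = ",", FUN.VALUE = character(1))
  proj <- proj[!duplicated(keys)]
  ord <- order(vapply(proj, function(b) sum(b * (max(1L, n))^(seq_along(b) - 1)),
                      numeric(1)))
  proj[ord]
}

# --- noun-phrase yield -----------------------------------------------------

.YIELD_LABELS <- c("det", "amod", "compound", "nummod", "appos")
.YIELD_NMOD <- c("nmod:of", "nmod:with")
.CLIP_LEMMAS <- c("than", "compared", "versus", "vs", "vs.")

#' Extract the noun-phrase yield of a head token
#'
#' Collects the head together with its noun-phrase-internal dependents
#' (determiners, adjectival/nominal/numeric modifiers, appositives and
#' of-/with-complements, recursively) and returns the contiguous token span
#' covering them. The span never crosses an entity-separator token
#' ("than", "compared", "versus") and is clipped at `exclude` tokens, keeping
#' the side that contains the head.
#'
#' @param graph An `exprel_depgraph`.
#' @param head Token index.
#' @param exclude Token indices to exclude (e.g. the scale indicator when
#'   rendering a compared aspect).
#' @return List with `from`, `to` (token indices), `start`, `end`
#'   (0-based half-open character offsets) and `text`.
#' @export
np_yield <- function(graph, head, exclude = integer(0)) {
  nodes <- graph$nodes
  stopifnot(head %in% nodes$idx)
  edges <- graph$edges
  keep <- head
  frontier <- head
  while (length(frontier)) {
    nxt <- integer(0)
    for (g in frontier) {
      hit <- edges$gov == g & (edges$label %in% .YIELD_LABELS |
                                 edges$label %in% .YIELD_NMOD)
      nxt <- c(nxt, edges$dep[hit])
    }
    nxt <- setdiff(unique(nxt), keep)
    keep <- c(keep, nxt)
    frontier <- nxt
  }
  lo <- min(keep); hi <- max(keep)
  clip <- which(tolower(nodes$surface) %in% .CLIP_LEMMAS | nodes$pos == "ES" |
                  tolower(nodes$surface) %in% c(",", ";"))
  clip <- sort(unique(c(clip, exclude)))
  for (cpos in clip) {
    if (cpos >= lo && cpos <= hi) {
      if (cpos < head) lo <- max(lo, cpos + 1L)
      else if (cpos > head) hi <- min(hi, cpos - 1L)
    }
  }
  start <- nodes$start[lo]; end <- nodes$end[hi]
  list(from = lo, to = hi, start = start, end = end,
       text = substr(graph$text, start + 1L, end))
}
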
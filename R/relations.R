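# Type A (comparison) and Type B (expression-level) relation extraction on
# top of the pattern engine, plus conjunction expansion.
#
# A Type A relation carries the scale indicator (SI), compared aspect (CA)
# and the two compared entities (CE1, CE2); the entity separator (ES) is
# verified but not extracted as an argument. A Type B relation carries the
# level indicator (LI), expressed aspect (EA), expressed location (EL) and an
# implicit-comparison flag derived from the LI's trigger class.

.negated <- function(graph, idx) {
  any(graph$edges$gov == idx & graph$edges$label == "neg")
}

.es_between <- function(graph, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  any(graph$es_tokens > lo & graph$es_tokens < hi)
}

#' Extract Type A comparison relations
#'
#' Runs the Type A pattern set over the graph, canonicalizes the compared
#' entities (an ES-attached or fronted entity is CE2; otherwise CE1 precedes
#' CE2), verifies that the compared entities are separated by an entity
#' separator, drops negated predicates, and keeps one relation per scale
#' indicator (preferring the pattern-file order, then the binding whose CEs
#' are nearest the SI).
#'
#' @param graph An `exprel_depgraph`.
#' @param triggers Trigger lexicons.
#' @param patterns Type A pattern set.
#' @return List of `exprel_relation_a` objects with token-index fields `si`,
#'   `ca`, `ce1`, `ce2` and rendered spans.
#' @export
extract_type_a <- function(graph, triggers, patterns) {
  if (!length(patterns)) stop("empty Type A pattern set")
  es_heads <- graph$es_links$head
  fronted <- graph$es_links$head[graph$es_links$fronted]
  cands <- list()
  for (pi in seq_along(patterns)) {
    pat <- patterns[[pi]]
    for (b in dep_match(pat, graph, triggers)) {
      si <- b[["si"]]; ca <- b[["ca"]]
      ce1 <- b[["ce1"]]; ce2 <- b[["ce2"]]
      if (anyNA(c(si, ca, ce1, ce2))) next
      symmetric <- !any(vapply(pat$edges, function(e)
        e$from == "ca" && e$to == "ce1", logical(1)))
      in_es <- c(ce1 %in% es_heads, ce2 %in% es_heads)
      if (symmetric && in_es[1] && !in_es[2]) {
        tmp <- ce1; ce1 <- ce2; ce2 <- tmp; in_es <- rev(in_es)
      }
      if (!in_es[2] && ce1 > ce2 && !(ce2 %in% fronted)) next
      if (ce2 %in% es_heads || ce1 %in% fronted || ce2 %in% fronted ||
          .es_between(graph, ce1, ce2)) {
        # separator verified
      } else next
      if (.negated(graph, si)) next
      if ("pred" %in% names(b) && !is.na(b[["pred"]]) &&
          .negated(graph, b[["pred"]])) next
      if (ca %in% c(ce1, ce2)) next
      cands[[length(cands) + 1L]] <- list(
        si = si, ca = ca, ce1 = ce1, ce2 = ce2,
        family = pat$family, prio = pi,
        dist = abs(ce1 - si) + abs(ce2 - si))
    }
  }
  if (!length(cands)) return(list())
  # one relation per scale-indicator token
  best <- list()
  for (cd in cands) {
    key <- as.character(cd$si)
    old <- best[[key]]
    if (is.null(old) || cd$prio < old$prio ||
        (cd$prio == old$prio && cd$dist < old$dist) ||
        (cd$prio == old$prio && cd$dist == old$dist && cd$ce1 < old$ce1))
      best[[key]] <- cd
  }
  out <- lapply(best[order(as.integer(names(best)))], function(cd) {
    structure(list(
      si = cd$si, si_surface = graph$nodes$surface[cd$si],
      ca = cd$ca, ce1 = cd$ce1, ce2 = cd$ce2, family = cd$family,
      ca_span = np_yield(graph, cd$ca, exclude = cd$si),
      ce1_span = np_yield(graph, cd$ce1),
      ce2_span = np_yield(graph, cd$ce2),
      graph = graph), class = "exprel_relation_a")
  })
  unname(out)
}

#' Extract Type B expression-level relations
#'
#' Runs the Type B pattern set, skips level indicators already consumed by a
#' Type A relation in the same sentence (comparison takes precedence), drops
#' negated predicates, picks the expressed location nearest the level
#' indicator when several candidates exist, and sets the implicit-comparison
#' flag from the LI trigger class. A plain-class LI modifier is excluded from
#' the rendered expressed aspect; an implicit-class (comparative) one is
#' kept.
#'
#' @inheritParams extract_type_a
#' @param patterns Type B pattern set.
#' @param consumed Token indices of triggers consumed by Type A relations.
#' @return List of `exprel_relation_b` objects.
#' @export
extract_type_b <- function(graph, triggers, patterns, consumed = integer(0)) {
  if (!length(patterns)) stop("empty Type B pattern set")
  cands <- list()
  for (pi in seq_along(patterns)) {
    pat <- patterns[[pi]]
    for (b in dep_match(pat, graph, triggers)) {
      li <- b[["li"]]; ea <- b[["ea"]]; el <- b[["el"]]
      if (anyNA(c(li, ea, el))) next
      if (li %in% consumed) next
      if (.negated(graph, li)) next
      if (ea == el) next
      cands[[length(cands) + 1L]] <- list(li = li, ea = ea, el = el,
                                          family = pat$family, prio = pi,
                                          dist = abs(el - li))
    }
  }
  if (!length(cands)) return(list())
  best <- list()
  for (cd in cands) {
    key <- as.character(cd$li)
    old <- best[[key]]
    if (is.null(old) || cd$prio < old$prio ||
        (cd$prio == old$prio && cd$dist < old$dist))
      best[[key]] <- cd
  }
  nodes <- graph$nodes
  out <- lapply(best[order(as.integer(names(best)))], function(cd) {
    li_surface <- nodes$surface[cd$li]
    implicit <- trig_has(triggers$li_implicit, li_surface, nodes$lemma[cd$li])
    plain_li <- trig_has(triggers$li_plain, li_surface, nodes$lemma[cd$li])
    structure(list(
      li = cd$li, li_surface = li_surface,
      ea = cd$ea, el = cd$el, family = cd$family,
      implicit_comparison = implicit,
      ea_span = np_yield(graph, cd$ea,
                         exclude = if (plain_li) cd$li else integer(0)),
      el_span = np_yield(graph, cd$el),
      graph = graph), class = "exprel_relation_b")
  })
  unname(out)
}

#' Expand coordinated expressed entities
#'
#' A relation whose compared/expressed aspect covers a coordination of
#' gene/microRNA heads ("the expression of miR-143 and -195") is replicated
#' once per conjunct, with the target entity head recorded on each copy; all
#' other fields are shared. Relations without coordination pass through
#' unchanged.
#'
#' @param relations List of relations from [extract_type_a()] /
#'   [extract_type_b()].
#' @param graph The sentence graph the relations came from.
#' @return Possibly longer list of relations.
#' @export
expand_conjunctions <- function(relations, graph) {
  edges <- graph$edges
  out <- list()
  for (rel in relations) {
    head0 <- if (inherits(rel, "exprel_relation_a")) rel$ca else rel$ea
    # candidate entity-bearing heads: the aspect head and its of-complements
    cand <- head0
    frontier <- head0
    while (length(frontier)) {
      nxt <- edges$dep[edges$gov %in% frontier &
                         edges$label %in% c("nmod:of", "compound")]
      nxt <- setdiff(nxt, cand)
      cand <- c(cand, nxt)
      frontier <- nxt
    }
    conj_sets <- lapply(cand, function(h)
      edges$dep[edges$gov == h & edges$label == "conj"])
    k <- which(lengths(conj_sets) > 0L)
    if (!length(k)) {
      out[[length(out) + 1L]] <- rel
      next
    }
    k <- k[1L]
    heads <- c(cand[k], conj_sets[[k]])
    for (h in sort(heads)) {
      r2 <- rel
      r2$entity_head <- h
      out[[length(out) + 1L]] <- r2
    }
  }
  out
}
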
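# Deterministic shallow dependency analyzer for expression statements.
#
# The analyzer chunks noun phrases, identifies clause predicates (copular,
# passive and active verb groups), and attaches prepositional phrases and
# entity-separator phrases, emitting enhanced dependencies directly in the
# collapsed form the patterns consume (nmod:<prep>, nmod:es) with conjunct
# propagation applied as a post-pass. It is intentionally a small, rule-based
# analyzer specialized for the sentence families this tool extracts from;
# sentences outside those families still parse (every token is attached or
# ignored deterministically) but carry no guarantee of linguistic fidelity.

.NP_POS <- c("DT", "JJ", "JJR", "VBNmod", "NN", "NNS", "CD", "PRP")

# consume a noun-phrase run starting at i; returns heads (conjunct heads,
# primary first), next index, and appends internal edges via the collector
.consume_np <- function(tok, i, add_edge) {
  n <- nrow(tok)
  j <- i
  members <- integer(0)
  while (j <= n) {
    p <- tok$pos[j]
    if (p %in% .NP_POS) {
      members <- c(members, j)
      j <- j + 1L
    } else if (p == "PUNCT" && tok$surface[j] == "(" && j + 2L <= n &&
               tok$pos[j + 1L] %in% c("NN", "NNS", "CD") &&
               tok$surface[j + 2L] == ")" && length(members)) {
      members <- c(members, j + 1L)          # single-token parenthetical
      j <- j + 3L
    } else if (p == "CC" && j + 1L <= n && tok$pos[j + 1L] %in% .NP_POS &&
               length(members)) {
      members <- c(members, -j)              # negative marks the coordinator
      j <- j + 1L
    } else if (p == "PUNCT" && tok$surface[j] == "," && length(members) &&
               j + 1L <= n && tok$pos[j + 1L] %in% .NP_POS) {
      # a comma continues the NP only inside a list coordination: require a
      # coordinator ahead within the nominal run
      k <- j + 1L
      cc_ahead <- FALSE
      while (k <= n && (tok$pos[k] %in% c(.NP_POS, "CC", "RB") ||
                          tok$surface[k] == ",")) {
        if (tok$pos[k] == "CC") { cc_ahead <- TRUE; break }
        k <- k + 1L
      }
      if (!cc_ahead) break
      members <- c(members, -j)              # comma acts as a coordinator
      j <- j + 1L
    } else if (p == "RB" && j + 1L <= n && tok$pos[j + 1L] %in% c("JJ", "JJR", "VBNmod")) {
      j <- j + 1L                            # adverb inside NP ("very high")
    } else break
  }
  if (!length(members)) return(list(heads = integer(0), next_i = i + 1L))
  # split into conjuncts at coordinators that follow a nominal
  groups <- list(); cur <- integer(0)
  k <- 1L
  while (k <= length(members)) {
    m <- members[k]
    if (m < 0) {
      cc_pos <- -m
      prev_nominal <- length(cur) &&
        tok$pos[cur[length(cur)]] %in% c("NN", "NNS", "CD")
      if (prev_nominal) {
        groups[[length(groups) + 1L]] <- cur
        cur <- integer(0)
      }
      # adjectival coordination: coordinator dropped, same group continues
    } else cur <- c(cur, m)
    k <- k + 1L
  }
  if (length(cur)) groups[[length(groups) + 1L]] <- cur
  heads <- integer(0)
  for (g in groups) {
    nom <- g[tok$pos[g] %in% c("NN", "NNS", "PRP")]
    h <- if (length(nom)) nom[length(nom)] else g[length(g)]
    heads <- c(heads, h)
    for (t in g) {
      if (t == h) next
      lab <- switch(tok$pos[t],
                    DT = "det", JJ = "amod", JJR = "amod", VBNmod = "amod",
                    CD = "nummod", NN = if (t < h) "compound" else "appos",
                    NNS = if (t < h) "compound" else "appos",
                    PRP = "compound", NULL)
      if (!is.null(lab)) add_edge(h, t, lab)
    }
  }
  if (length(heads) > 1L)
    for (k in 2:length(heads)) add_edge(heads[1L], heads[k], "conj")
  list(heads = heads, next_i = j)
}

#' Analyze a tokenized sentence into a dependency graph
#'
#' Produces an enhanced dependency graph with preposition-collapsed labels
#' (`nmod:in`, `nmod:of`, ...), entity-separator attachments (`nmod:es`),
#' passive subjects (`nsubj:pass`) and conjunct propagation. Analysis never
#' fails: unanalyzable material is left unattached.
#'
#' @param sentence A sentence object (list with `text` and `tokens`), or a
#'   bare string which is normalized and tokenized first.
#' @param triggers Trigger lexicons (used to recognize entity-separator
#'   phrases and opt-in separator prepositions).
#' @return An `exprel_depgraph`.
#' @export
parse_sentence <- function(sentence, triggers = load_trigger_lexicons()) {
  if (is.character(sentence)) {
    text <- normalize_text(sentence)
    sentence <- list(text = text, tokens = tokenize(text))
  }
  tok <- sentence$tokens
  n <- nrow(tok)
  edges <- data.frame(gov = integer(0), dep = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  add_edge <- function(gov, dep, label) {
    if (gov == dep) return(invisible())
    edges[nrow(edges) + 1L, ] <<- list(gov, dep, label)
  }
  es_links <- data.frame(head = integer(0), es_pos = integer(0),
                         fronted = logical(0))
  add_es <- function(head, es_pos, fronted) {
    es_links[nrow(es_links) + 1L, ] <<- list(head, es_pos, fronted)
  }
  es_tokens <- integer(0)
  preds <- integer(0)

  top_head <- NA_integer_   # head of the last top-level (subject-slot) NP
  last_head <- NA_integer_  # head of the most recent NP (any position)
  cur_pred <- NA_integer_
  cur_passive <- FALSE
  cur_active <- FALSE
  have_obj <- FALSE
  fronted_head <- NA_integer_
  fronted_es_pos <- NA_integer_
  pending_prep <- NULL      # list(lemma, pos, es_after)
  es_after <- FALSE

  lower <- tolower(tok$surface)
  es_words <- triggers$es

  attach_np <- function(heads, i0) {
    h <- heads[1L]
    if (!is.null(pending_prep)) {
      pp <- pending_prep
      lab <- paste0("nmod:", pp$lemma)
      if (pp$lemma %in% es_words && pp$lemma != "than") lab <- "nmod:es"
      gov <- if (pp$lemma %in% c("of", "with")) {
        if (!is.na(last_head)) last_head else cur_pred
      } else if (!is.na(cur_pred)) cur_pred else top_head
      if (!is.na(gov)) {
        add_edge(gov, h, lab)
        if (!is.na(pp$es_pos) || lab == "nmod:es")
          add_es(h, if (!is.na(pp$es_pos)) pp$es_pos else pp$pos, FALSE)
      }
      pending_prep <<- NULL
    } else if (es_after) {
      gov <- if (!is.na(cur_pred)) cur_pred else top_head
      if (is.na(gov) && is.na(top_head) && is.na(cur_pred)) {
        # sentence-initial entity-separator phrase: defer to first predicate
        fronted_head <<- h
      } else if (!is.na(gov)) {
        add_edge(gov, h, "nmod:es")
        add_es(h, es_tokens[length(es_tokens)], FALSE)
      }
      es_after <<- FALSE
    } else if (!is.na(cur_pred) && cur_active && !have_obj) {
      add_edge(cur_pred, h, "dobj")
      have_obj <<- TRUE
    } else if (!is.na(cur_pred) && !cur_active && !cur_passive && !have_obj) {
      # copular predication ("X was miR-224"): NP head becomes the predicate
      add_edge(h, cur_pred, "cop")
      if (!is.na(top_head)) add_edge(h, top_head, "nsubj")
      cur_pred <<- h
      have_obj <<- TRUE
    } else {
      top_head <<- h
    }
    last_head <<- h
  }

  new_clause <- function() {
    cur_pred <<- NA_integer_; cur_passive <<- FALSE; cur_active <<- FALSE
    have_obj <<- FALSE; pending_prep <<- NULL; es_after <<- FALSE
  }

  i <- 1L
  # sentence-initial entity-separator phrase ("Compared to X," /
  # "In comparison to X," / "Relative to X,")
  if (n >= 3L) {
    if (lower[1] %in% c("compared", "relative") && lower[2] %in% c("to", "with")) {
      es_tokens <- c(es_tokens, 1L); fronted_es_pos <- 1L
      es_after <- TRUE
      i <- 3L
    } else if (lower[1] == "in" && n >= 4L && lower[2] == "comparison" &&
               lower[3] %in% c("to", "with")) {
      es_tokens <- c(es_tokens, 1L); fronted_es_pos <- 1L
      es_after <- TRUE
      i <- 4L
    }
    if (es_after) {
      np <- .consume_np(tok, i, add_edge)
      if (length(np$heads)) {
        fronted_head <- np$heads[1L]
        i <- np$next_i
      }
      es_after <- FALSE
      if (i <= n && tok$surface[i] == ",") i <- i + 1L
    }
  }

  while (i <= n) {
    p <- tok$pos[i]
    s <- lower[i]
    if (p %in% .NP_POS) {
      np <- .consume_np(tok, i, add_edge)
      if (length(np$heads)) attach_np(np$heads, i)
      i <- np$next_i
      next
    }
    if (p == "ES") {                      # "than"
      es_tokens <- c(es_tokens, i)
      es_after <- TRUE
      # "than that in X": skip the pronoun placeholder
      if (i + 1L <= n && lower[i + 1L] == "that" &&
          i + 2L <= n && tok$pos[i + 2L] %in% c("IN", "ES")) i <- i + 1L
      i <- i + 1L
      next
    }
    if (s %in% c("compared", "relative") && i + 1L <= n &&
        lower[i + 1L] %in% c("to", "with")) {
      es_tokens <- c(es_tokens, i)
      es_after <- TRUE
      i <- i + 2L
      if (i <= n && lower[i] == "that" && i + 1L <= n &&
          tok$pos[i + 1L] %in% c("IN", "ES")) i <- i + 1L
      next
    }
    if (s %in% c("versus", "vs", "vs.")) {
      es_tokens <- c(es_tokens, i)
      es_after <- TRUE
      i <- i + 1L
      next
    }
    if (p == "IN") {
      # after an entity separator ("than in X", "compared ... in X") the
      # collapsed label stays nmod:<prep> per the comparison-graph
      # convention; the head is additionally flagged as ES-attached
      es_pos <- if (es_after) es_tokens[length(es_tokens)] else NA_integer_
      pending_prep <- list(lemma = tok$lemma[i], pos = i, es_pos = es_pos)
      es_after <- FALSE
      i <- i + 1L
      next
    }
    if (p %in% c("VBE", "V", "VH")) {
      start_pred <- i
      neg_tok <- NA_integer_
      passive <- FALSE; active <- FALSE
      pred <- NA_integer_
      if (p == "VBE") {
        j <- i + 1L
        while (j <= n && tok$pos[j] %in% c("RB", "NEG", "CD")) {
          if (tok$pos[j] == "NEG") neg_tok <- j
          j <- j + 1L
        }
        if (j <= n && tok$pos[j] == "V") {
          pred <- j; passive <- TRUE; i <- j + 1L
        } else if (j <= n && tok$pos[j] %in% c("JJ", "JJR", "VBNmod")) {
          pred <- j; i <- j + 1L
        } else {
          pred <- start_pred; i <- j   # bare copula; NP predication handled later
        }
      } else {
        pred <- i; active <- TRUE
        j <- i + 1L
        i <- j
      }
      cur_pred <- pred; cur_passive <- passive; cur_active <- active
      have_obj <- FALSE
      preds <- c(preds, pred)
      if (!is.na(top_head))
        add_edge(pred, top_head, if (passive) "nsubj:pass" else "nsubj")
      if (!is.na(neg_tok)) add_edge(pred, neg_tok, "neg")
      if (!is.na(fronted_head)) {
        add_edge(pred, fronted_head, "nmod:es")
        add_es(fronted_head, if (!is.na(fronted_es_pos)) fronted_es_pos else 1L, TRUE)
        fronted_head <- NA_integer_
      }
      next
    }
    if (p == "CC") {
      if (!is.na(cur_pred)) { new_clause(); top_head <- NA_integer_ }
      i <- i + 1L
      next
    }
    if (p == "PUNCT") {
      if (s == ";") { new_clause(); top_head <- NA_integer_ }
      if (s == "(") {                   # skip a top-level parenthetical
        depth <- 1L; j <- i + 1L
        while (j <= n && depth > 0L) {
          if (tok$surface[j] == "(") depth <- depth + 1L
          if (tok$surface[j] == ")") depth <- depth - 1L
          j <- j + 1L
        }
        i <- j
        next
      }
      i <- i + 1L
      next
    }
    i <- i + 1L                         # adverbs, stray material
  }

  # conjunct propagation: a conjunct inherits its first conjunct's governors
  if (nrow(edges)) {
    conj <- edges[edges$label == "conj", , drop = FALSE]
    for (k in seq_len(nrow(conj))) {
      g <- conj$gov[k]; d <- conj$dep[k]
      inc <- edges[edges$dep == g & edges$label != "conj", , drop = FALSE]
      for (m in seq_len(nrow(inc))) {
        if (inc$gov[m] == d) next
        dup <- any(edges$gov == inc$gov[m] & edges$dep == d &
                     edges$label == inc$label[m])
        if (!dup) edges[nrow(edges) + 1L, ] <- list(inc$gov[m], d, inc$label[m])
      }
    }
  }

  root <- if (length(preds)) preds[1L] else if (n) 1L else NA_integer_
  dep_graph(tok, edges, root, text = sentence$text, es_links = es_links,
            es_tokens = es_tokens, preds = preds)
}
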
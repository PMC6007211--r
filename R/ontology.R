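# Minimal Disease Ontology support: an OBO is_a reader and the cancer-subtree
# relevance filter.

#' Read an OBO file (terms and is_a links)
#'
#' Minimal reader for the fields the relevance filter needs: term ids, names
#' and `is_a` parents. Obsolete terms are skipped.
#'
#' @param path OBO file.
#' @return List with `name` (id -> name) and `parents` (id -> character
#'   vector of parent ids).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  name <- character(0)
  parents <- list()
  cur <- NULL; in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete && nzchar(cur$id)) {
      name[cur$id] <<- cur$name
      parents[[cur$id]] <<- cur$parents
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(id = "", name = "", parents = character(0))
      in_term <- TRUE; obsolete <- FALSE
      next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, p)
    } else if (grepl("^is_obsolete: *true", ln)) obsolete <- TRUE
  }
  flush()
  list(name = name, parents = parents)
}

#' Build an ontology subtree (transitive is_a closure under a root)
#'
#' @param obo Value of [read_obo()], or a path to an OBO file.
#' @param root Root identifier (default: the cancer root, DOID:162).
#' @return An `exprel_do_subtree` with the member set.
#' @export
do_subtree <- function(obo = exprel_file("extdata", "do_cancer_mini.obo"),
                       root = "DOID:162") {
  if (is.character(obo)) obo <- read_obo(obo)
  if (!root %in% names(obo$parents) && !root %in% names(obo$name))
    stop("root term ", root, " not in ontology")
  # ancestors of each term must be acyclic; walk up with a visited guard
  members <- character(0)
  for (id in names(obo$parents)) {
    seen <- character(0)
    stack <- id
    hit <- FALSE
    while (length(stack)) {
      t <- stack[[1]]; stack <- stack[-1]
      if (t %in% seen) stop("cycle in is_a closure at ", t)
      seen <- c(seen, t)
      if (t == root) { hit <- TRUE; break }
      stack <- c(stack, obo$parents[[t]])
    }
    if (hit) members <- c(members, id)
  }
  structure(list(root = root, members = unique(members), name = obo$name),
            class = "exprel_do_subtree")
}

#' Subtree membership test
#' @param subtree An `exprel_do_subtree`.
#' @param doid DOID string(s).
#' @return Logical vector.
#' @export
in_subtree <- function(subtree, doid) doid %in% subtree$members

#' Relevance filter for tumor-vs-normal curation
#'
#' Keeps records whose disease lies in the cancer subtree of the ontology
#' and whose frame of reference is an explicit or implicit comparison to a
#' control/normal baseline (`Control` or `Control_Implicit`). This is the
#' inclusion rule for expression databases that only record differential
#' expression between tumor and normal samples.
#'
#' @param records Record tibble.
#' @param subtree Cancer subtree from [do_subtree()] (root DOID:162).
#' @return Filtered record tibble (a subset of the input; idempotent).
#' @export
bioxpress_filter <- function(records, subtree = do_subtree()) {
  if (!inherits(subtree, "exprel_do_subtree")) stop("need an ontology subtree")
  keep <- !is.na(records$doid) & in_subtree(subtree, records$doid) &
    records$frame_of_reference %in% c("Control", "Control_Implicit")
  records[keep, , drop = FALSE]
}
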
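# Ontology DAG bookkeeping.  dag_parents: named list child -> parent ids.
# All relation helpers return term-id character vectors and treat ids with
# no recorded edges as isolated nodes.

.check_dag_acyclic <- function(dag_parents) {
  if (!length(dag_parents)) return(invisible(TRUE))
  nodes <- unique(c(names(dag_parents), unlist(dag_parents)))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) stop("cycle in term DAG involving '", v, "'")
    if (state[[v]] == 2L) return(invisible(NULL))
    state[[v]] <<- 1L
    for (p in dag_parents[[v]]) visit(p)
    state[[v]] <<- 2L
    invisible(NULL)
  }
  for (v in nodes) visit(v)
  invisible(TRUE)
}

.dag_children_map <- function(dag_parents) {
  if (!length(dag_parents)) return(list())
  ch <- rep(names(dag_parents), lengths(dag_parents))
  pa <- unlist(dag_parents, use.names = FALSE)
  split(ch, pa)
}

#' Term DAG relations
#'
#' Relation helpers over a [gene_set_collection()]'s parent map:
#' `dag_parents()`/`dag_children()` are one step, `dag_ancestors()`/
#' `dag_offspring()` are transitive closures (excluding the terms
#' themselves), and `dag_siblings()` are terms sharing at least one parent.
#'
#' @param sets `GeneSetCollection`.
#' @param term_ids character vector of term ids.
#' @return character vector of related term ids (never the inputs).
#' @name dag-relations
NULL

#' @rdname dag-relations
#' @export
dag_parents <- function(sets, term_ids) {
  unique(unlist(sets$dag_parents[intersect(term_ids,
                                           names(sets$dag_parents))]))
}

#' @rdname dag-relations
#' @export
dag_children <- function(sets, term_ids) {
  cm <- .dag_children_map(sets$dag_parents)
  unique(unlist(cm[intersect(term_ids, names(cm))]))
}

.transitive <- function(step, start) {
  out <- character()
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(step(frontier), c(out, start))
    out <- c(out, nxt)
    frontier <- nxt
  }
  unique(out)
}

#' @rdname dag-relations
#' @export
dag_ancestors <- function(sets, term_ids) {
  .transitive(function(f) dag_parents(sets, f), term_ids)
}

#' @rdname dag-relations
#' @export
dag_offspring <- function(sets, term_ids) {
  .transitive(function(f) dag_children(sets, f), term_ids)
}

#' @rdname dag-relations
#' @export
dag_siblings <- function(sets, term_ids) {
  pa <- dag_parents(sets, term_ids)
  setdiff(dag_children(sets, pa), term_ids)
}

#' Leaf terms of an assigned set
#'
#' Among `term_ids`, the terms with no other member of `term_ids` strictly
#' below them in the DAG (the most specific assignments).
#'
#' @inheritParams dag-relations
#' @return character vector.
#' @export
dag_leaves_of <- function(sets, term_ids) {
  keep <- vapply(term_ids, function(t) {
    !any(dag_offspring(sets, t) %in% setdiff(term_ids, t))
  }, logical(1L))
  term_ids[keep]
}
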
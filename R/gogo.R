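# Typed GO DAGs and edge-weighted semantic similarity (GOGO).
#
# The similarity of two terms is computed from their ancestor sub-DAGs:
# each term contributes an S-value that decays through typed edges with
# weight W_e = 1/(c + nc(parent)) + d, where nc counts the parent's children
# in the full ontology and d depends on the edge type (is_a 0.4, part_of
# 0.3, with c = 0.67). Gene-level similarity is the best-match average over
# the two genes' term sets.

#' Construct a typed GO-like DAG
#'
#' @param terms character vector of term ids.
#' @param edges data.frame with columns `child`, `parent`, `type`
#'   (`is_a` or `part_of`); edges point child -> parent.
#' @param annotations data.frame with columns `gene`, `term`, `ontology`.
#' @return An object of class `go_dag`.
#' @export
go_dag <- function(terms, edges,
                   annotations = data.frame(gene = character(),
                                            term = character(),
                                            ontology = character())) {
  terms <- unique(as.character(terms))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "type") %in% names(edges)))
  if (!all(edges$type %in% c("is_a", "part_of")))
    stop("edge types must be is_a or part_of")
  if (!all(c(edges$child, edges$parent) %in% terms))
    stop("edges reference unknown terms")
  dag <- structure(list(terms = terms, edges = edges,
                        annotations = annotations),
                   class = "go_dag")
  if (is.null(topological_order(dag))) stop("edge set contains a cycle")
  set_annotations(dag, annotations)
}

set_annotations <- function(dag, annotations) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (nrow(annotations)) {
    stopifnot(all(c("gene", "term", "ontology") %in% names(annotations)))
    unknown <- setdiff(annotations$term, dag$terms)
    if (length(unknown))
      stop("annotations reference unknown terms: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  dag$annotations <- annotations
  # child counts in the full ontology, used by the edge weight
  nc <- table(factor(dag$edges$parent, levels = dag$terms))
  dag$nc <- stats::setNames(as.integer(nc), dag$terms)
  dag
}

# Kahn topological order, children before parents; NULL if cyclic.
topological_order <- function(dag) {
  terms <- dag$terms
  # in-degree from the child side: number of children per term
  in_from_children <- stats::setNames(integer(length(terms)), terms)
  tabp <- table(factor(dag$edges$parent, levels = terms))
  in_from_children[names(tabp)] <- as.integer(tabp)
  by_child <- split(dag$edges$parent, dag$edges$child)
  order <- character(0)
  ready <- names(in_from_children)[in_from_children == 0]  # leaves
  remaining <- in_from_children
  while (length(ready)) {
    t <- ready[1]; ready <- ready[-1]
    order <- c(order, t)
    for (p in by_child[[t]] %||% character(0)) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) ready <- c(ready, p)
    }
  }
  if (length(order) != length(terms)) NULL else order
}

#' Leaf terms of a DAG
#' @param dag a `go_dag`.
#' @return Character vector of terms with no children.
#' @export
godag_leaves <- function(dag) {
  setdiff(dag$terms, unique(dag$edges$parent))
}

# Ancestor closure including the term itself (the term's sub-DAG).
term_dag <- function(term, dag) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  by_child <- split(dag$edges$parent, dag$edges$child)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unlist(by_child[frontier], use.names = FALSE), seen)
  }
  seen
}

# S-values of every node in term's sub-DAG: S(term) = 1 and, walking up,
# S(n) = max over children x of n inside the sub-DAG of W_e(n, type) * S(x).
gogo_svalues <- function(term, dag, c_const = 0.67,
                         d_is_a = 0.4, d_part_of = 0.3) {
  sub <- term_dag(term, dag)
  E <- dag$edges[dag$edges$child %in% sub & dag$edges$parent %in% sub, ]
  S <- stats::setNames(rep(-Inf, length(sub)), sub)
  S[term] <- 1
  ord <- topological_order(
    structure(list(terms = sub, edges = E), class = "go_dag"))
  for (n in ord) {
    if (n == term) next
    kids <- E[E$parent == n, ]
    if (nrow(kids) == 0) next
    d <- ifelse(kids$type == "is_a", d_is_a, d_part_of)
    w <- 1 / (c_const + dag$nc[[n]]) + d
    S[n] <- max(w * S[kids$child])
  }
  S[is.finite(S)]
}

#' Semantic similarity between two GO terms
#'
#' @param t,k term ids present in `dag`.
#' @param dag a `go_dag`.
#' @param c_const denominator constant of the edge weight (default 0.67).
#' @param d_is_a,d_part_of edge-type additive constants (defaults 0.4 and
#'   0.3).
#' @return Similarity in `[0,1]`; 1 when `t == k`.
#' @export
gogo_term_sim <- function(t, k, dag, c_const = 0.67,
                          d_is_a = 0.4, d_part_of = 0.3) {
  St <- gogo_svalues(t, dag, c_const, d_is_a, d_part_of)
  Sk <- gogo_svalues(k, dag, c_const, d_is_a, d_part_of)
  common <- intersect(names(St), names(Sk))
  sum(St[common] + Sk[common]) / (sum(St) + sum(Sk))
}

gene_terms <- function(gene, dag, ontology) {
  a <- dag$annotations
  unique(a$term[a$gene == gene & a$ontology == ontology])
}

#' Functional similarity between two genes
#'
#' Best-match average of term similarities: every term of each gene is
#' matched to its most similar term on the other gene, and the matches are
#' averaged over both term sets.
#'
#' @param g1,g2 gene ids with annotations in `dag`.
#' @param dag a `go_dag`.
#' @param ontology ontology namespace to use (default `"BP"`).
#' @inheritParams gogo_term_sim
#' @return Similarity in `[0,1]`, or `NA` if either gene lacks annotations
#'   in the requested ontology.
#' @export
gogo_gene_sim <- function(g1, g2, dag, ontology = "BP", c_const = 0.67,
                          d_is_a = 0.4, d_part_of = 0.3) {
  t1 <- gene_terms(g1, dag, ontology)
  t2 <- gene_terms(g2, dag, ontology)
  if (length(t1) == 0 || length(t2) == 0) return(NA_real_)
  M <- outer(t1, t2, Vectorize(function(a, b)
    gogo_term_sim(a, b, dag, c_const, d_is_a, d_part_of)))
  (sum(apply(M, 1, max)) + sum(apply(M, 2, max))) / (length(t1) + length(t2))
}

#' Average pairwise GO similarity within a cluster
#'
#' Mean of [gogo_gene_sim()] over all unordered pairs of annotated genes;
#' genes without annotations in the requested ontology are excluded (and
#' reported in a message). With fewer than two annotated genes the score is
#' undefined and `NA` is returned.
#'
#' @param cluster character vector of gene ids.
#' @inheritParams gogo_gene_sim
#' @return Mean similarity in `[0,1]`, or `NA`.
#' @export
gogo_cluster_score <- function(cluster, dag, ontology = "BP", c_const = 0.67,
                               d_is_a = 0.4, d_part_of = 0.3) {
  ann <- dag$annotations
  annotated <- cluster[cluster %in% ann$gene[ann$ontology == ontology]]
  skipped <- setdiff(cluster, annotated)
  if (length(skipped))
    message("genes without ", ontology, " annotations skipped: ",
            paste(skipped, collapse = ", "))
  if (length(annotated) < 2) return(NA_real_)
  pairs <- utils::combn(annotated, 2)
  vals <- vapply(seq_len(ncol(pairs)), function(i)
    gogo_gene_sim(pairs[1, i], pairs[2, i], dag, ontology,
                  c_const, d_is_a, d_part_of),
    numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Read a (subset of an) OBO ontology file
#'
#' Ingests `[Term]` stanzas with their `id`, `namespace`, `is_a` and
#' `relationship: part_of` lines; other relationship types are ignored and
#' counted in a message. Obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @return A `go_dag` (annotations empty; see [read_annotations()]).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0); edges <- list(); ns <- character(0)
  cur <- NULL; ignored <- 0L; in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) terms <<- c(terms, cur)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; in_term <- TRUE; obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    if (startsWith(ln, "is_obsolete: true")) obsolete <- TRUE
    if (startsWith(ln, "namespace:"))
      ns[cur] <- trimws(sub("^namespace:", "", ln))
    if (startsWith(ln, "is_a:")) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- c(cur, p, "is_a")
    }
    if (startsWith(ln, "relationship:")) {
      rel <- trimws(sub("^relationship:", "", ln))
      if (startsWith(rel, "part_of")) {
        p <- trimws(sub("!.*$", "", sub("^part_of", "", rel)))
        edges[[length(edges) + 1L]] <- c(cur, p, "part_of")
      } else ignored <- ignored + 1L
    }
  }
  flush()
  if (ignored > 0)
    message(ignored, " non is_a/part_of relationship(s) ignored")
  E <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1], parent = m[, 2], type = m[, 3],
               stringsAsFactors = FALSE)
  } else data.frame(child = character(), parent = character(),
                    type = character())
  E <- E[E$child %in% terms & E$parent %in% terms, ]
  go_dag(terms, E)
}

#' Write a `go_dag` as an OBO subset
#'
#' @param dag a `go_dag`.
#' @param path output file path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    E <- dag$edges[dag$edges$child == t, ]
    for (r in seq_len(nrow(E))) {
      if (E$type[r] == "is_a")
        writeLines(paste0("is_a: ", E$parent[r]), con)
      else
        writeLines(paste0("relationship: part_of ", E$parent[r]), con)
    }
  }
  invisible(path)
}

#' Read gene annotations from a three-column TSV
#'
#' @param path TSV with header columns `gene`, `term`, `ontology`.
#' @param dag a `go_dag` the annotations attach to.
#' @return The `go_dag` with annotations set.
#' @export
read_annotations <- function(path, dag) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  set_annotations(dag, ann)
}

#' Write gene annotations to TSV
#' @param dag a `go_dag` with annotations.
#' @param path output file path.
#' @export
write_annotations <- function(dag, path) {
  utils::write.table(dag$annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d edges, %d annotations\n",
              length(x$terms), nrow(x$edges), nrow(x$annotations)))
  invisible(x)
}
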
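#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} of drawing at least the observed
#' overlap between a query gene list and a term's gene set, under
#' hypergeometric sampling from the universe: population \eqn{N =
#' |universe|}, successes \eqn{K = |term|}, draws \eqn{n = |query|},
#' observed \eqn{k = |query \cap term|}. Inputs are deduplicated and
#' intersected with the universe.
#'
#' @param query character vector of query genes.
#' @param term_genes character vector of the term's genes.
#' @param universe character vector of all annotated genes.
#' @return list: `p`, `k`, `K`, `n`, `N`.
#' @export
ora_hypergeometric <- function(query, term_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("empty query (after restriction to universe)")
  term_genes <- intersect(unique(term_genes), universe)
  k <- length(intersect(query, term_genes))
  K <- length(term_genes)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, k = k, K = K, n = n, N = N)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [ora_hypergeometric()] for every gene set of one source and adjusts
#' p-values by Benjamini-Hochberg within the collection.
#'
#' @param query query genes.
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe all annotated genes.
#' @param source label recorded in the output (`GO`, `KEGG`, `Reactome`, ...).
#' @return data.frame: `term`, `source`, `k`, `K`, `raw_p`, `adj_p`, sorted
#'   by raw p.
#' @export
enrich_terms <- function(query, gene_sets, universe, source = "GO") {
  stopifnot(is.list(gene_sets), length(gene_sets) > 0)
  rows <- lapply(names(gene_sets), function(tm) {
    o <- ora_hypergeometric(query, gene_sets[[tm]], universe)
    data.frame(term = tm, source = source, k = o$k, K = o$K, raw_p = o$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$raw_p, "BH")
  out[order(out$raw_p, out$term), , drop = FALSE]
}

#' Jaccard similarity of two gene sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty sets are defined as similarity
#' 0 with a warning.
#'
#' @param a,b character vectors.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both sets empty; Jaccard similarity defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Build an ontology DAG for Wang semantic similarity
#'
#' Parses child/parent edges with `is_a` (contribution weight 0.8) and
#' `part_of` (0.6) relations into a validated acyclic parent-link
#' structure.
#'
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param weights named contribution weights per relation, each in (0, 1).
#' @return object of class `ontology_graph`.
#' @export
ontology_graph <- function(edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(is.data.frame(edges),
            all(c("child", "parent", "relation") %in% names(edges)))
  unknown <- setdiff(unique(edges$relation), names(weights))
  if (length(unknown)) {
    stop("unknown relation(s): ", paste(unknown, collapse = ", "))
  }
  if (any(weights <= 0 | weights >= 1)) stop("weights must lie in (0, 1)")
  terms <- unique(c(edges$child, edges$parent))
  parents <- split(
    data.frame(parent = edges$parent, w = unname(weights[edges$relation]),
               stringsAsFactors = FALSE),
    factor(edges$child, levels = terms)
  )
  # cycle check: Kahn's algorithm from the roots (terms with no parents)
  adj <- split(edges$child, edges$parent)
  indeg <- stats::setNames(integer(length(terms)), terms)
  tabc <- table(edges$child)
  indeg[names(tabc)] <- as.integer(tabc)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(terms)) stop("cycle detected in ontology edges")
  structure(list(parents = parents, terms = terms, weights = weights),
            class = "ontology_graph")
}

# S-values of a term's ancestor closure: S[term] = 1, and for each ancestor
# t, S[t] = max over edges (c -> t) on paths from the term of w * S[c].
wang_svalues <- function(term, graph) {
  S <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      pl <- graph$parents[[v]]
      if (is.null(pl) || nrow(pl) == 0) next
      for (i in seq_len(nrow(pl))) {
        cand <- pl$w[i] * S[[v]]
        p <- pl$parent[i]
        if (is.na(S[p]) || cand > S[[p]]) {
          S[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  S
}

#' Wang semantic similarity between two ontology terms
#'
#' Aggregates the weighted contributions of shared ancestors:
#' \deqn{sim(A,B) = \frac{\sum_{t \in T_A \cap T_B} (S_A(t) + S_B(t))}
#'   {SV(A) + SV(B)}}
#' where \eqn{T_X} is the term plus its ancestors, \eqn{S_X(t)} the maximal
#' product of edge weights along paths from \eqn{X} up to \eqn{t}, and
#' \eqn{SV(X) = \sum_t S_X(t)}. Terms in disconnected components share no
#' ancestors and score 0.
#'
#' @param a,b term identifiers present in the ontology.
#' @param graph an [ontology_graph()].
#' @return similarity in `[0, 1]`.
#' @export
wang_similarity <- function(a, b, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!(a %in% graph$terms)) stop("term absent from ontology: ", a)
  if (!(b %in% graph$terms)) stop("term absent from ontology: ", b)
  if (identical(a, b)) return(1)
  SA <- wang_svalues(a, graph)
  SB <- wang_svalues(b, graph)
  common <- intersect(names(SA), names(SB))
  if (length(common) == 0) return(0)
  sum(SA[common] + SB[common]) / (sum(SA) + sum(SB))
}

#' Redundancy reduction of enriched terms via similarity networks
#'
#' Builds, per source, a term-similarity network (Wang similarity for GO
#' terms when an ontology is supplied, Jaccard on gene sets otherwise),
#' keeps edges with similarity strictly greater than `threshold`, partitions
#' each network by greedy (multilevel) modularity maximisation under a fixed
#' internal seed (terms are ordered lexicographically before clustering, so
#' the result does not depend on input order), and selects within each
#' community the term with
#' the smallest adjusted p (ties broken by the lexicographically smaller
#' term id). Isolated terms form their own communities. Results from all
#' sources are combined.
#'
#' @param terms data.frame with columns `term`, `source`, `raw_p`, `adj_p`
#'   (e.g. rbind of [enrich_terms()] outputs).
#' @param gene_sets named list of gene vectors covering all terms (used for
#'   Jaccard similarity).
#' @param threshold edges require similarity > threshold (strict).
#' @param ontology an [ontology_graph()] for GO terms; required for source
#'   `"GO"` unless `go_jaccard = TRUE`.
#' @param go_jaccard fall back to Jaccard similarity for GO terms.
#' @return data.frame: `term`, `source`, `raw_p`, `adj_p`, `community`,
#'   `is_representative`.
#' @export
reduce_terms <- function(terms, gene_sets, threshold = 0.5, ontology = NULL,
                         go_jaccard = FALSE) {
  stopifnot(is.data.frame(terms),
            all(c("term", "source", "adj_p") %in% names(terms)))
  if (!"raw_p" %in% names(terms)) terms$raw_p <- terms$adj_p
  out <- list()
  comm_offset <- 0L
  for (src in sort(unique(terms$source))) {
    ts <- terms[terms$source == src, , drop = FALSE]
    ts <- ts[order(ts$term), , drop = FALSE]
    ids <- ts$term
    use_wang <- src == "GO" && !go_jaccard
    if (use_wang && is.null(ontology)) {
      stop("GO terms supplied without an ontology; pass `ontology` or set ",
           "`go_jaccard = TRUE` to fall back to Jaccard similarity")
    }
    nt <- length(ids)
    edges <- NULL
    if (nt > 1) {
      simfun <- if (use_wang) {
        function(x, y) wang_similarity(x, y, ontology)
      } else {
        if (length(setdiff(ids, names(gene_sets)))) {
          stop("gene sets missing for term(s): ",
               paste(setdiff(ids, names(gene_sets)), collapse = ", "))
        }
        function(x, y) jaccard_similarity(gene_sets[[x]], gene_sets[[y]])
      }
      pairs <- utils::combn(nt, 2)
      sims <- apply(pairs, 2, function(ix) simfun(ids[ix[1]], ids[ix[2]]))
      keep <- sims > threshold
      if (any(keep)) {
        edges <- data.frame(from = ids[pairs[1, keep]],
                            to = ids[pairs[2, keep]],
                            stringsAsFactors = FALSE)
      }
    }
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nt, name = ids)
    if (!is.null(edges)) {
      g <- igraph::add_edges(g, rbind(match(edges$from, ids),
                                      match(edges$to, ids)))
    }
    old <- .Random.seed_save()
    set.seed(1L)
    memb <- igraph::membership(igraph::cluster_louvain(g))
    .Random.seed_restore(old)
    ts$community <- comm_offset + as.integer(memb[ids])
    comm_offset <- max(ts$community)
    ts$is_representative <- FALSE
    for (cm in unique(ts$community)) {
      ix <- which(ts$community == cm)
      best <- ix[order(ts$adj_p[ix], ts$term[ix])][1]
      ts$is_representative[best] <- TRUE
    }
    out[[src]] <- ts
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set format: term, description, then member
#' genes.
#'
#' @param path file path.
#' @return named list of gene vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write a GMT gene-set file
#'
#' @param gene_sets named list of gene vectors.
#' @param path output path.
#' @param descriptions optional descriptions (defaults to the term names).
#' @export
write_gmt <- function(gene_sets, path, descriptions = names(gene_sets)) {
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}
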
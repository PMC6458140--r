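#' Partial correlation test between two traits
#'
#' Partial correlation of traits `i` and `j` given all remaining traits,
#' computed from the inverse of the trait correlation matrix, with a
#' two-sided Fisher-z p-value on `n - (q - 2) - 3` effective degrees of
#' freedom. With `q = 2` this reduces to the plain Pearson correlation test.
#'
#' @param data Numeric n x q matrix or data frame of traits.
#' @param i,j Trait columns (index or name).
#' @return One-row tibble: `trait_a`, `trait_b`, `estimate` (partial
#'   correlation), `p.value`.
#' @export
partial_corr_test <- function(data, i, j) {
  pc <- pcor_matrix(as_trait_matrix(data))
  nm <- colnames(pc$pcor)
  ii <- if (is.character(i)) match(i, nm) else i
  jj <- if (is.character(j)) match(j, nm) else j
  tibble(trait_a = nm[ii], trait_b = nm[jj],
         estimate = pc$pcor[ii, jj], p.value = pc$p[ii, jj])
}

as_trait_matrix <- function(data) {
  m <- as.matrix(as.data.frame(data)[vapply(as.data.frame(data), is.numeric, TRUE)])
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  if (any(!is.finite(m))) abort("trait matrix must be finite")
  if (ncol(m) < 2) abort("need at least two traits")
  if (nrow(m) <= ncol(m) + 2) abort("need n > q + 2 samples")
  if (any(apply(m, 2, sd) == 0)) abort("constant trait column")
  m
}

# full partial-correlation and Fisher-z p-value matrices
pcor_matrix <- function(m) {
  n <- nrow(m)
  q <- ncol(m)
  cc <- cor(m)
  if (kappa(cc, exact = TRUE) > 1e10) {
    abort(paste0(
      "trait correlation matrix is near-singular (condition number > 1e10); ",
      "remove or combine collinear traits"))
  }
  om <- solve(cc)
  d <- 1 / sqrt(diag(om))
  pcor <- -om * tcrossprod(d)
  diag(pcor) <- 1
  df_eff <- n - (q - 2) - 3
  z <- atanh(pmin(pmax(pcor, -1 + 1e-15), 1 - 1e-15)) * sqrt(df_eff)
  p <- 2 * pnorm(-abs(z))
  diag(p) <- NA_real_
  dimnames(pcor) <- dimnames(p) <- list(colnames(m), colnames(m))
  list(pcor = pcor, p = p, n = n)
}

#' Learn the trait conditional-dependence graph
#'
#' Builds the undirected Gaussian graphical model over traits: an edge joins
#' two traits when their full-conditional partial correlation is significant
#' at `alpha`. The resulting zero pattern is what the G-Wishart prior
#' consumes. Learn this on the phenotype-only cohort so that structure
#' learning never reuses the association samples.
#'
#' @param data Numeric n x q matrix or data frame of (preprocessed) traits.
#' @param alpha Significance level for edge inclusion.
#' @return An object of class `trait_graph`: `nodes` (ordered trait names),
#'   `edges` (tibble `trait_a`/`trait_b`), `alpha`, `stats` (all-pairs tibble
#'   with partial correlations and p-values).
#' @export
learn_trait_graph <- function(data, alpha = 0.05) {
  m <- as_trait_matrix(data)
  pc <- pcor_matrix(m)
  nm <- colnames(m)
  pairs <- which(upper.tri(pc$p), arr.ind = TRUE)
  stats <- tibble(
    trait_a = nm[pairs[, 1]], trait_b = nm[pairs[, 2]],
    partial_corr = pc$pcor[pairs], p_value = pc$p[pairs],
    edge = pc$p[pairs] < alpha
  )
  structure(
    list(nodes = nm, edges = stats[stats$edge, c("trait_a", "trait_b")],
         alpha = alpha, stats = stats),
    class = "trait_graph"
  )
}

#' Construct a trait graph from an explicit edge list
#'
#' @param nodes Ordered character vector of trait names (q >= 2).
#' @param edges Two-column matrix/data frame of node-name pairs (may be
#'   empty).
#' @param alpha Optional significance level annotation.
#' @return A `trait_graph`.
#' @export
trait_graph <- function(nodes, edges = NULL, alpha = NA_real_) {
  nodes <- as.character(nodes)
  if (length(nodes) < 2 || anyDuplicated(nodes)) {
    abort("`nodes` must be >= 2 unique names")
  }
  if (is.null(edges) || NROW(edges) == 0) {
    ed <- tibble(trait_a = character(), trait_b = character())
  } else {
    em <- as.matrix(as.data.frame(edges)[, 1:2])
    if (!all(em %in% nodes)) abort("edge endpoints must be nodes")
    if (any(em[, 1] == em[, 2])) abort("self-loops are not allowed")
    # canonical order within pair, by node position
    pos <- matrix(match(em, nodes), ncol = 2)
    swap <- pos[, 1] > pos[, 2]
    em[swap, ] <- em[swap, 2:1, drop = FALSE]
    em <- unique(em)
    ed <- tibble(trait_a = em[, 1], trait_b = em[, 2])
  }
  structure(list(nodes = nodes, edges = ed, alpha = alpha, stats = NULL),
            class = "trait_graph")
}

edge_keys <- function(g) {
  if (nrow(g$edges) == 0) return(character())
  a <- pmin(g$edges$trait_a, g$edges$trait_b)
  b <- pmax(g$edges$trait_a, g$edges$trait_b)
  paste(a, b, sep = "\r")
}

#' @export
print.trait_graph <- function(x, ...) {
  cat(sprintf("<trait_graph> %d nodes, %d edges (alpha = %s)\n",
              length(x$nodes), nrow(x$edges), format(x$alpha)))
  invisible(x)
}

#' @export
tidy.trait_graph <- function(x, ...) {
  if (!is.null(x$stats)) return(x$stats)
  dplyr::mutate(x$edges, edge = TRUE)
}

#' Hamming distance between two trait graphs
#'
#' Number of unordered node pairs whose edge status differs. Both graphs
#' must be over the same node set.
#'
#' @param g1,g2 `trait_graph` objects.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) abort("graphs have different node sets")
  e1 <- edge_keys(g1)
  e2 <- edge_keys(g2)
  length(setdiff(e1, e2)) + length(setdiff(e2, e1))
}

#' Choose the edge-inclusion significance level by structural stability
#'
#' Learns one graph per candidate level and compares all pairs by Hamming
#' distance. The chosen level is the largest level whose graph differs from
#' the next-smaller level's graph by at most `max_dist` edges (ties resolved
#' toward the largest level); when no level qualifies, the smallest level is
#' returned as the conservative fallback. All graphs are returned so the
#' choice can be overridden.
#'
#' @param data Numeric n x q trait matrix or data frame.
#' @param levels Candidate significance levels (>= 2 unless a single level is
#'   supplied, which is returned as-is).
#' @param max_dist Stability threshold on the Hamming distance (default 1).
#' @return List of class `alpha_selection`: `alpha` (chosen level), `graph`
#'   (the chosen `trait_graph`), `distances` (tibble `level_a`, `level_b`,
#'   `hamming`), `graphs` (named list of all candidate graphs).
#' @export
select_alpha <- function(data, levels = c(0.005, 0.01, 0.05), max_dist = 1) {
  levels <- sort(unique(levels))
  graphs <- purrr::map(levels, ~learn_trait_graph(data, .x))
  names(graphs) <- as.character(levels)
  if (length(levels) == 1) {
    return(structure(list(alpha = levels, graph = graphs[[1]],
                          distances = tibble(
      level_a = numeric(), level_b = numeric(), hamming = integer()),
      graphs = graphs), class = "alpha_selection"))
  }
  cmb <- utils::combn(seq_along(levels), 2)
  distances <- tibble(
    level_a = levels[cmb[1, ]], level_b = levels[cmb[2, ]],
    hamming = purrr::map2_int(cmb[1, ], cmb[2, ],
                              ~hamming_distance(graphs[[.x]], graphs[[.y]]))
  )
  stable <- vapply(seq_along(levels)[-1], function(k) {
    hamming_distance(graphs[[k]], graphs[[k - 1]]) <= max_dist
  }, TRUE)
  alpha <- if (any(stable)) levels[max(which(stable)) + 1] else levels[1]
  structure(list(alpha = alpha, graph = graphs[[as.character(alpha)]],
                 distances = distances, graphs = graphs),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat(sprintf("<alpha_selection> chosen alpha = %s\n", format(x$alpha)))
  print(x$distances)
  invisible(x)
}

#' Zero pattern for the G-Wishart prior
#'
#' Symmetric logical q x q matrix with `TRUE` diagonal and `TRUE`
#' off-diagonal exactly at the graph's edges: the entries of the trait
#' precision matrix that are free (non-edges are constrained to exact zero).
#'
#' @param g A `trait_graph`.
#' @return Logical q x q matrix with dimnames set to the node names.
#' @export
precision_pattern <- function(g) {
  q <- length(g$nodes)
  m <- matrix(FALSE, q, q, dimnames = list(g$nodes, g$nodes))
  diag(m) <- TRUE
  if (nrow(g$edges)) {
    ia <- match(g$edges$trait_a, g$nodes)
    ib <- match(g$edges$trait_b, g$nodes)
    m[cbind(ia, ib)] <- TRUE
    m[cbind(ib, ia)] <- TRUE
  }
  m
}

#' Convert a trait graph to an igraph object
#'
#' @param g A `trait_graph`.
#' @return An undirected \pkg{igraph} graph.
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(as.data.frame(g$edges), directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Write a trait graph to disk
#'
#' `"tsv"` writes the edge list (with partial correlations and p-values when
#' available); `"graphml"` writes GraphML via \pkg{igraph}.
#'
#' @param g A `trait_graph`.
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_trait_graph <- function(g, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    ed <- g$edges
    if (!is.null(g$stats)) {
      ed <- dplyr::filter(g$stats, .data$edge)[
        , c("trait_a", "trait_b", "partial_corr", "p_value")]
    }
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a trait graph written by [write_trait_graph()]
#'
#' @param path Path to a `.graphml` file or an edge-list TSV.
#' @param nodes Node names; required for TSV when isolated nodes exist.
#' @return A `trait_graph`.
#' @export
read_trait_graph <- function(path, nodes = NULL) {
  if (grepl("\\.graphml$", path)) {
    ig <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(ig)
    trait_graph(igraph::V(ig)$name, el)
  } else {
    ed <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (is.null(nodes)) nodes <- sort(unique(c(ed[[1]], ed[[2]])))
    trait_graph(nodes, ed[, 1:2])
  }
}

#' Plot a trait graph
#'
#' Nodes are placed by the Fruchterman-Reingold layout and shaded by degree,
#' darker meaning more connected.
#'
#' @param object A `trait_graph`.
#' @param ... Unused.
#' @return A \pkg{ggplot2} object.
#' @export
autoplot.trait_graph <- function(object, ...) {
  ig <- as_igraph(object)
  set.seed(1L)  # layout only; analysis results unaffected
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble(name = object$nodes, x = xy[, 1], y = xy[, 2],
                  degree = igraph::degree(ig))
  seg <- dplyr::left_join(
    dplyr::left_join(object$edges,
                     setNames(nodes[, 1:3], c("trait_a", "xa", "ya")),
                     by = "trait_a"),
    setNames(nodes[, 1:3], c("trait_b", "xb", "yb")), by = "trait_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      colour = "grey60") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$degree),
      shape = 21, size = 8) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1.6, size = 3) +
    ggplot2::scale_fill_gradient(low = "grey90", high = "grey20") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "degree")
}
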
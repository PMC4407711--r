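# Expression-space analysis of the candidate drivers: transcriptomic
# neighbor sets, neighbor-sharing significance, the neighbor-sharing display
# network, and complete-linkage clustering of driver expression.

# gene x tumor matrix of (optionally log2) replicate-averaged expression
expr_matrix_of <- function(expr, log2_scale = TRUE) {
  em <- expr_means(expr)
  wide <- pivot_wider(em, id_cols = "gene_id", names_from = "tumor_id",
                      values_from = "expr")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene_id
  if (log2_scale) m <- log2(m)
  m
}

#' Transcriptomic neighbors of a seed gene
#'
#' Computes the Pearson correlation of the seed gene's expression with every
#' other gene over all tumors and splits genes into a positive
#' (`R >= cutoff`) and a negative (`R <= -cutoff`) neighbor set. The default
#' cutoff 0.63 is the significance threshold for 10 samples.
#'
#' @param expr Expression tibble.
#' @param seed_gene Seed gene id.
#' @param cutoff Correlation cutoff (positive).
#' @param log2_scale Correlate on log2-transformed expression (default), the
#'   conventional scale for array co-expression.
#' @return A list of class `neighbor_set`: `seed_gene`, `positive`,
#'   `negative` (character vectors), `cutoff`, and `R` (named correlations of
#'   all other genes).
#' @export
neighbor_set <- function(expr, seed_gene, cutoff = 0.63, log2_scale = TRUE) {
  m <- expr_matrix_of(expr, log2_scale)
  if (!seed_gene %in% rownames(m)) abort(sprintf("unknown gene '%s'", seed_gene))
  if (ncol(m) < 3) abort("need at least 3 tumors")
  s <- m[seed_gene, ]
  if (sd(s) == 0) abort("undefined correlation: zero-variance seed gene")
  others <- m[setdiff(rownames(m), seed_gene), , drop = FALSE]
  ok <- apply(others, 1, sd) > 0
  R <- as.vector(cor(t(others[ok, , drop = FALSE]), s))
  names(R) <- rownames(others)[ok]
  structure(
    list(
      seed_gene = seed_gene,
      positive = sort(names(R)[R >= cutoff]),
      negative = sort(names(R)[R <= -cutoff]),
      cutoff = cutoff, R = R
    ),
    class = "neighbor_set"
  )
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat(sprintf("neighbor set of %s (|R| >= %.2f): %d positive, %d negative\n",
              x$seed_gene, x$cutoff, length(x$positive), length(x$negative)))
  invisible(x)
}

#' Significance of neighbor-set sharing
#'
#' Upper-tail hypergeometric probability of the observed overlap between two
#' neighbor sets drawn from a universe of `universe_size` genes:
#' `P(overlap >= observed)` when `|setB|` genes are sampled without
#' replacement from a universe containing `|setA|` marked genes.
#'
#' @param setA,setB Character vectors of gene ids (or `neighbor_set` objects,
#'   whose positive and negative sets are pooled).
#' @param universe_size Number of genes in the universe (>= both set sizes).
#' @return One-row tibble `size_a`, `size_b`, `shared`, `expected`, `p`.
#' @export
sharing_significance <- function(setA, setB, universe_size) {
  pool <- function(s) if (inherits(s, "neighbor_set")) c(s$positive, s$negative) else s
  A <- unique(pool(setA)); B <- unique(pool(setB))
  if (length(A) > universe_size || length(B) > universe_size) {
    abort("set larger than universe")
  }
  shared <- length(intersect(A, B))
  tibble(
    size_a = length(A), size_b = length(B), shared = shared,
    expected = length(A) * length(B) / universe_size,
    p = phyper(shared - 1, length(A), universe_size - length(A),
               length(B), lower.tail = FALSE)
  )
}

#' Build the neighbor-sharing display network
#'
#' Connects each driver to its strongly correlated transcriptomic neighbors
#' (default `|R| >= 0.90`), with edge sign recording the correlation
#' direction; neighbors shared between drivers tie the drivers together.
#' Node degree equals the size of the thresholded neighbor sets.
#'
#' @param neighbor_sets List of `neighbor_set` objects (one per driver),
#'   computed at any cutoff; edges are re-thresholded at `display_cutoff`.
#' @param display_cutoff Display correlation cutoff.
#' @return List with `edges` (tibble `driver`, `neighbor`, `R`, `sign`) and
#'   `graph` (an igraph object; drivers flagged by vertex attribute
#'   `is_driver`).
#' @export
build_sharing_network <- function(neighbor_sets, display_cutoff = 0.90) {
  edges <- map(neighbor_sets, function(ns) {
    keep <- abs(ns$R) >= display_cutoff
    if (!any(keep)) return(NULL)
    tibble(
      driver = ns$seed_gene, neighbor = names(ns$R)[keep],
      R = unname(ns$R[keep]),
      sign = ifelse(ns$R[keep] > 0, "positive", "negative")
    )
  }) |> list_rbind()
  drivers <- vapply(neighbor_sets, `[[`, character(1), "seed_gene")
  if (nrow(edges) > 0) {
    # drivers appear in each other's neighbor sets; keep one edge per
    # unordered pair so degrees count shared edges once
    edges <- edges |>
      mutate(.key = paste(pmin(.data$driver, .data$neighbor),
                          pmax(.data$driver, .data$neighbor))) |>
      distinct(.data$.key, .keep_all = TRUE) |>
      select(-".key")
  }
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
      igraph::vertices(drivers, is_driver = TRUE)
  } else {
    verts <- tibble(
      name = c(drivers, setdiff(unique(edges$neighbor), drivers)),
    )
    verts$is_driver <- verts$name %in% drivers
    g <- igraph::graph_from_data_frame(
      edges[c("driver", "neighbor", "R", "sign")],
      directed = FALSE, vertices = verts
    )
  }
  list(edges = edges, graph = g)
}

#' Complete-linkage clustering of driver expression
#'
#' Agglomerative clustering of the listed genes on the correlation distance
#' `1 - R` (Pearson, over tumors) with complete linkage. Zero-variance genes
#' are dropped with a warning.
#'
#' @param expr Expression tibble.
#' @param gene_list Genes to cluster (>= 2 usable).
#' @param log2_scale Correlate on log2 expression (default).
#' @return An [stats::hclust] object.
#' @export
cluster_drivers <- function(expr, gene_list, log2_scale = TRUE) {
  m <- expr_matrix_of(expr, log2_scale)
  missing <- setdiff(gene_list, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("genes not in matrix: %s", paste(missing, collapse = ", ")))
  }
  m <- m[gene_list, , drop = FALSE]
  degenerate <- apply(m, 1, sd) == 0
  if (any(degenerate)) {
    warn(sprintf("dropping zero-variance genes: %s",
                 paste(rownames(m)[degenerate], collapse = ", ")))
    m <- m[!degenerate, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least 2 genes with variance to cluster")
  d <- as.dist(1 - cor(t(m)))
  hclust(d, method = "complete")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object, e.g. from [cluster_drivers()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required to export Newick trees")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
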
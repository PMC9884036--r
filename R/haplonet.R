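#' Statistical-parsimony connection limit
#'
#' Maximum number of mutational steps j for which a connection between two
#' haplotypes is accepted as parsimonious at the given confidence. Uses a
#' uniform-mutation multiple-hit model: j mutations thrown independently on
#' L sites are all at distinct sites with probability
#' prod_{i=0..j-1} (1 - i/L); the limit is the largest j keeping that
#' probability at or above `conf`.
#'
#' @param L alignment length in sites.
#' @param conf confidence level (default 0.95).
#' @return integer step limit.
#' @export
parsimony_limit <- function(L, conf = 0.95) {
  j <- 1
  repeat {
    p <- prod(1 - (0:j) / L) # probability j+1 mutations hit distinct sites
    if (p < conf) return(j)
    j <- j + 1
    if (j >= L) return(L)
  }
}

#' Tie-retaining minimum-spanning haplotype network
#'
#' Builds a minimum-spanning network over haplotypes from pairwise
#' mutational differences: edges are added in increasing step order, and
#' within a step class every edge that joins two components (as they stood
#' when the class opened) is retained, so all tied minimum-spanning
#' alternatives appear. Edges whose step count exceeds the 95%
#' statistical-parsimony limit are kept but flagged.
#'
#' @param tab a `haplotype_table` with >= 2 haplotypes.
#' @param conf parsimony confidence (default 0.95).
#' @return list of class `haplotype_network`: `nodes` data frame (id, total
#'   count, per-group counts), `edges` data frame (from, to, steps,
#'   beyond_limit), `limit` the step limit used.
#' @export
build_haplotype_network <- function(tab, conf = 0.95) {
  ids <- names(tab$haplotypes)
  H <- length(ids)
  if (H < 2) stop("need at least 2 haplotypes")
  m <- do.call(rbind, strsplit(unname(tab$haplotypes), ""))
  L <- ncol(m)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = H)
  d <- matrix(0L, H, H)
  for (i in seq_len(H - 1)) for (j in (i + 1):H) {
    use <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use])
  }
  limit <- parsimony_limit(L, conf)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  comp <- seq_len(H)
  keep <- logical(length(w))
  for (lev in unique(w)) {
    sel <- which(w == lev)
    comp_at_level <- comp # tie retention: compare against entry state
    for (e in sel) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      if (comp_at_level[i] != comp_at_level[j]) {
        keep[e] <- TRUE
        if (comp[i] != comp[j]) comp[comp == comp[j]] <- comp[i]
      }
    }
    if (length(unique(comp)) == 1) break
  }
  edges <- data.frame(from = ids[pairs[keep, 1]],
                      to = ids[pairs[keep, 2]],
                      steps = w[keep],
                      beyond_limit = w[keep] > limit,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, count = rowSums(tab$counts),
                      stringsAsFactors = FALSE)
  nodes <- cbind(nodes, as.data.frame(tab$counts))
  structure(list(nodes = nodes, edges = edges, limit = limit),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges (parsimony limit %d steps, %d beyond)\n",
              nrow(x$nodes), nrow(x$edges), x$limit, sum(x$edges$beyond_limit)))
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes GraphML (via igraph) and a plain edge-list TSV.
#'
#' @param net a `haplotype_network`.
#' @param graphml,edges_tsv output paths (`NULL` to skip either).
#' @return invisible list of written paths.
#' @export
export_haplotype_network <- function(net, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edges_tsv))
    utils::write.table(net$edges, edges_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(graphml = graphml, edges_tsv = edges_tsv))
}
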
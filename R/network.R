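#' Filter a co-expression edge list
#'
#' Keeps edges whose weight is strictly greater than the threshold (the
#' published convention is weight > 0.2), canonicalises gene order, removes
#' self-edges and duplicates, and drops nodes left without edges.
#'
#' @param edges data frame: `gene_a`, `gene_b`, `weight` in `[0, 1]`.
#' @param threshold strict lower bound on the retained weights.
#' @return list: `edges` (filtered, canonical order), `nodes`, `n_nodes`,
#'   `n_edges`.
#' @export
filter_edges <- function(edges, threshold = 0.2) {
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(edges))) stopf("edge list needs gene_a, gene_b, weight")
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0 | edges$weight > 1))
    stopf("malformed weights: must be finite and in [0, 1]")
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  kept <- edges[edges$weight > threshold, , drop = FALSE]
  rownames(kept) <- NULL
  nodes <- sort(unique(c(kept$gene_a, kept$gene_b)))
  list(edges = kept, nodes = nodes, n_nodes = length(nodes),
       n_edges = nrow(kept))
}

#' Assign modules as connected components
#'
#' A stand-in for an external weighted-correlation module detector, intended
#' for fully synthetic runs: modules are the connected components of the
#' filtered network, labelled `M1`, `M2`, ... in decreasing size (ties by the
#' lexicographically smallest member).
#'
#' @param network a [filter_edges()] result.
#' @return named character vector: module label per node.
#' @export
assign_modules_components <- function(network) {
  nodes <- network$nodes
  if (!length(nodes)) return(setNames(character(0), character(0)))
  idx <- seq_along(nodes)
  parent <- idx
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  ia <- match(network$edges$gene_a, nodes)
  ib <- match(network$edges$gene_b, nodes)
  for (r in seq_along(ia)) {
    ra <- find(ia[r]); rb <- find(ib[r])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(idx, find, integer(1))
  sizes <- table(comp)
  first <- tapply(nodes, comp, min)
  ord <- order(-as.integer(sizes), first)
  lab <- setNames(sprintf("M%d", seq_along(ord)), names(sizes)[ord])
  setNames(unname(lab[as.character(comp)]), nodes)
}

#' Identify hub genes per module
#'
#' Ranks the nodes of each module by the sum of their incident intra-module
#' edge weights and returns the top `k` (default 1). Ties are broken by the
#' lexicographically smaller gene id. When `k` exceeds the module size the
#' whole module is returned with a warning.
#'
#' @param network a [filter_edges()] result.
#' @param modules named character vector (module label per node); every
#'   network node must be labelled.
#' @param k hubs per module.
#' @return data frame: `module`, `gene_id`, `weight_sum`, `rank`.
#' @export
find_hubs <- function(network, modules, k = 1L) {
  unlabelled <- setdiff(network$nodes, names(modules))
  if (length(unlabelled))
    stopf("unlabelled nodes: %s", paste(unlabelled, collapse = ", "))
  e <- network$edges
  intra <- modules[e$gene_a] == modules[e$gene_b]
  e <- e[intra, , drop = FALSE]
  ws <- setNames(numeric(length(network$nodes)), network$nodes)
  for (r in seq_len(nrow(e))) {
    ws[e$gene_a[r]] <- ws[e$gene_a[r]] + e$weight[r]
    ws[e$gene_b[r]] <- ws[e$gene_b[r]] + e$weight[r]
  }
  out <- list()
  for (m in sort(unique(modules[network$nodes]))) {
    members <- network$nodes[modules[network$nodes] == m]
    if (k > length(members))
      warning(sprintf("module %s has only %d members (k = %d); returning all",
                      m, length(members), k))
    ord <- members[order(-ws[members], members)]
    top <- utils::head(ord, min(k, length(ord)))
    out[[m]] <- data.frame(module = m, gene_id = top,
                           weight_sum = unname(ws[top]),
                           rank = seq_along(top), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Module expression profile
#'
#' Each module gene is z-scored across samples (zero-variance genes are masked
#' and contribute nothing); the profile is the per-sample mean over module
#' genes, summarised per (variety, treatment, stage) by averaging replicates.
#'
#' @param module_genes character vector of gene ids.
#' @param mat genes x samples abundance matrix.
#' @param meta sample sheet.
#' @return data frame: `variety`, `treatment`, `stage`, `profile`.
#' @export
module_expression_profile <- function(module_genes, mat, meta) {
  present <- intersect(module_genes, rownames(mat))
  if (!length(present)) stopf("no module gene present in the matrix")
  x <- mat[present, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / sdv
  z[sdv == 0, ] <- NA   # constant genes carry no profile information
  prof <- colMeans(z, na.rm = TRUE)
  prof[is.nan(prof)] <- 0
  cond <- unique(meta[, c("variety", "treatment", "stage")])
  out <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    cols <- meta$sample_id[meta$variety == cond$variety[i] &
                             meta$treatment == cond$treatment[i] &
                             meta$stage == cond$stage[i]]
    data.frame(variety = cond$variety[i], treatment = cond$treatment[i],
               stage = cond$stage[i], profile = mean(prof[cols]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-sided Fisher enrichment over a term map
#'
#' For each term, tests over-representation of the gene set among the term's
#' genes with the one-sided Fisher exact test (hypergeometric upper tail),
#' followed by Benjamini-Hochberg correction across terms.
#'
#' @param gene_set character vector, must be a subset of `universe`.
#' @param universe character vector of all genes considered.
#' @param terms named list: term id -> character vector of member genes
#'   (intersected with the universe).
#' @return data frame: `term`, `overlap`, `set_size`, `term_size`,
#'   `universe_size`, `odds_ratio`, `p`, `padj`, sorted by `p`.
#' @export
fisher_enrichment <- function(gene_set, universe, terms) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe))
    stopf("gene set is not contained in the universe")
  N <- length(universe)
  k <- length(gene_set)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    m <- length(tg)
    a <- length(intersect(gene_set, tg))
    b <- k - a
    cc <- m - a
    d <- N - k - m + a
    p <- stats::phyper(a - 1, m, N - m, k, lower.tail = FALSE)
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(term = tm, overlap = a, set_size = k, term_size = m,
               universe_size = N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Three-evidence target-gene screen
#'
#' For each variety, the target genes are the intersection of three evidence
#' sets: drought-induced genes, genes of the drought-associated co-expression
#' module, and genes associated with drought-changed TAD boundaries (dg/dl).
#' Cross-variety shared and variety-specific targets are reported, along with
#' per-gene evidence flags.
#'
#' @param evidence named list per variety, each a list with components
#'   `induced`, `module`, `tad_change` (character vectors of gene ids).
#' @return list of class `ca_target_report`: `per_variety` (named list of
#'   target vectors), `shared`, `specific` (named list), `evidence` (data
#'   frame of per-gene flags per variety).
#' @export
#' @examples
#' ev <- list(v1 = list(induced = c("a", "b", "c"), module = c("b", "c", "d"),
#'                      tad_change = c("c", "d", "e")),
#'            v2 = list(induced = "c", module = "c", tad_change = "c"))
#' screen_target_genes(ev)$shared
screen_target_genes <- function(evidence) {
  if (is.null(names(evidence))) stopf("evidence must be a named per-variety list")
  per_variety <- list()
  flags <- list()
  for (v in names(evidence)) {
    ev <- evidence[[v]]
    need <- c("induced", "module", "tad_change")
    if (!all(need %in% names(ev)))
      stopf("evidence for %s needs components: %s", v, paste(need, collapse = ", "))
    for (nm in need)
      if (!length(ev[[nm]]))
        warning(sprintf("empty evidence set '%s' for %s", nm, v))
    targets <- sort(Reduce(intersect, lapply(ev[need], unique)))
    per_variety[[v]] <- targets
    genes <- sort(unique(unlist(ev[need])))
    flags[[v]] <- data.frame(
      variety = v, gene_id = genes,
      induced = genes %in% ev$induced,
      module = genes %in% ev$module,
      tad_change = genes %in% ev$tad_change,
      target = genes %in% targets, stringsAsFactors = FALSE)
  }
  shared <- Reduce(intersect, per_variety)
  specific <- lapply(per_variety, function(t) setdiff(t, shared))
  out <- list(per_variety = per_variety, shared = shared, specific = specific,
              evidence = do.call(rbind, c(flags, list(make.row.names = FALSE))))
  class(out) <- "ca_target_report"
  out
}

#' @export
print.ca_target_report <- function(x, ...) {
  cat("Three-evidence target-gene screen\n")
  for (v in names(x$per_variety))
    cat(sprintf("  %s: %d targets (%d specific)\n", v,
                length(x$per_variety[[v]]), length(x$specific[[v]])))
  cat(sprintf("  shared across varieties: %d\n", length(x$shared)))
  invisible(x)
}

#' Co-expression edge list from an expression matrix
#'
#' Builds a soft-thresholded signed co-expression edge list (weight =
#' `max(cor, 0)^power`, so weights lie in `[0, 1]`) for use with
#' [filter_edges()]. A lightweight stand-in for external network construction,
#' suitable for synthetic runs.
#'
#' @param mat genes x samples abundance matrix.
#' @param genes gene ids to include (default: all rows).
#' @param power soft-threshold exponent.
#' @return edge-list data frame: `gene_a`, `gene_b`, `weight`.
#' @export
coexpression_edges <- function(mat, genes = rownames(mat), power = 3) {
  x <- t(log2(mat[genes, , drop = FALSE] + 1))
  cc <- suppressWarnings(stats::cor(x))
  cc[is.na(cc)] <- 0
  w <- pmax(cc, 0)^power
  ut <- which(upper.tri(w), arr.ind = TRUE)
  data.frame(gene_a = rownames(cc)[ut[, 1]], gene_b = colnames(cc)[ut[, 2]],
             weight = w[ut], stringsAsFactors = FALSE)
}
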
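#' Pairwise image-feature vs gene-feature regressions
#'
#' Regresses every image feature (y) on every gene-expression feature (x)
#' by simple linear regression and records Pearson's r, R-squared (= r^2
#' for a single regressor) and the two-sided p-value of the zero-slope
#' test, computed in closed form from `t = r * sqrt((n - 2) / (1 - r^2))`
#' on n - 2 degrees of freedom. Pairs involving a zero-variance feature
#' are skipped with a warning. A Benjamini-Hochberg adjusted p-value
#' column is appended for the user's judgment; the classical filter in
#' [association_graph()] uses the raw p-values.
#'
#' @param image_x numeric matrix (samples x image features).
#' @param gene_x numeric matrix (samples x gene features), same rows.
#' @return data.frame: `image_feature`, `gene_feature`, `r`, `r_squared`,
#'   `p_value`, `p_adjusted`.
#' @export
pairwise_association <- function(image_x, gene_x) {
  image_x <- as.matrix(image_x); gene_x <- as.matrix(gene_x)
  n <- nrow(image_x)
  if (nrow(gene_x) != n)
    stop("image and gene matrices disagree on sample count", call. = FALSE)
  if (n < 3)
    stop("need at least 3 samples for a slope test", call. = FALSE)
  if (is.null(colnames(image_x)))
    colnames(image_x) <- paste0("img", seq_len(ncol(image_x)))
  if (is.null(colnames(gene_x)))
    colnames(gene_x) <- paste0("gene", seq_len(ncol(gene_x)))

  const_i <- apply(image_x, 2, stats::sd) == 0
  const_g <- apply(gene_x, 2, stats::sd) == 0
  if (any(const_i) || any(const_g))
    warning("zero-variance features skipped: ",
            paste(c(colnames(image_x)[const_i], colnames(gene_x)[const_g]),
                  collapse = ", "))
  iu <- which(!const_i); gu <- which(!const_g)
  r <- stats::cor(gene_x[, gu, drop = FALSE], image_x[, iu, drop = FALSE])
  # r[g, i]; flatten with image varying slowest to keep pairs grouped
  out <- expand.grid(gene_feature = colnames(gene_x)[gu],
                     image_feature = colnames(image_x)[iu],
                     stringsAsFactors = FALSE)
  rv <- as.numeric(r)
  rv <- pmin(pmax(rv, -1), 1)
  tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(image_feature = out$image_feature,
             gene_feature = out$gene_feature,
             r = rv, r_squared = rv^2, p_value = p,
             p_adjusted = stats::p.adjust(p, "BH"),
             row.names = NULL)
}

#' Univariate Cox proportional-hazards sign of a feature
#'
#' Fits a one-covariate Cox model and returns the sign of its
#' coefficient: positive = higher values mean worse prognosis, negative =
#' protective. When the coefficient is statistically unstable (|z| < 1)
#' or the fit fails to converge, the sign is flagged.
#'
#' @param feature numeric vector (non-constant).
#' @param time,status survival response.
#' @return list: `sign` (+1/-1, or NA when indeterminate), `coef`, `z`,
#'   `stable` (logical: |z| >= 1 and converged).
#' @export
hazard_sign <- function(feature, time, status) {
  check_survival(time, status)
  if (stats::sd(feature) == 0)
    stop("constant feature: hazard sign undefined", call. = FALSE)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, status) ~ feature),
    warning = function(w) suppressWarnings(
      survival::coxph(survival::Surv(time, status) ~ feature)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit))) {
    # monotone partial likelihood (perfect separation): the MLE is infinite
    # but its sign equals the sign of the score at beta = 0,
    # U(0) = sum_k x_k dl/d eta_k evaluated at eta = 0
    u0 <- sum(feature * cox_pll_grad(rep(0, length(feature)), time, status))
    if (u0 == 0)
      return(list(sign = NA_real_, coef = NA_real_, z = NA_real_,
                  stable = FALSE))
    return(list(sign = sign(u0), coef = sign(u0) * Inf, z = sign(u0) * Inf,
                stable = TRUE))
  }
  b <- unname(stats::coef(fit))
  z <- b / sqrt(diag(stats::vcov(fit)))
  list(sign = sign(b), coef = b, z = unname(z), stable = abs(z) >= 1)
}

#' Bipartite image-gene association graph
#'
#' Builds the interpretation graph: image-feature nodes are connected to
#' gene-feature nodes when |r| exceeds `image_gene_threshold` with raw
#' p-value below `alpha`; gene nodes are connected to each other when
#' their pairwise correlation exceeds `gene_gene_threshold` (and both
#' genes already appear in a retained image-gene edge). The correlation
#' thresholds are read as absolute values, since both protective and
#' harmful features can associate. Node attributes carry feature
#' importance (`size`) and the univariate hazard sign (`sign`); isolated
#' nodes are dropped.
#'
#' @param edges data.frame from [pairwise_association()].
#' @param gene_corr gene x gene correlation matrix (dimnames = gene ids),
#'   e.g. `cor(gene_x)`.
#' @param image_gene_threshold minimum |r| for an image-gene edge (0.1).
#' @param gene_gene_threshold minimum |r| for a gene-gene edge (0.5).
#' @param alpha p-value cut-off for image-gene edges (0.05).
#' @param importance optional named vector of node importance scores.
#' @param signs optional named vector of hazard signs (+1/-1).
#' @return an [igraph::graph] with vertex attributes `type` ("image" /
#'   "gene"), `size`, `sign`, and edge attributes `r`, `r_squared`,
#'   `p_value`, `kind` ("image-gene" / "gene-gene").
#' @export
association_graph <- function(edges, gene_corr = NULL,
                              image_gene_threshold = 0.1,
                              gene_gene_threshold = 0.5, alpha = 0.05,
                              importance = NULL, signs = NULL) {
  keep <- abs(edges$r) > image_gene_threshold & edges$p_value < alpha
  ig <- edges[keep, , drop = FALSE]
  el <- data.frame(from = ig$image_feature, to = ig$gene_feature,
                   r = ig$r, r_squared = ig$r_squared,
                   p_value = ig$p_value,
                   kind = rep("image-gene", nrow(ig)),
                   stringsAsFactors = FALSE)
  genes_in <- unique(ig$gene_feature)
  if (!is.null(gene_corr) && length(genes_in) >= 2) {
    gg <- gene_corr[genes_in, genes_in, drop = FALSE]
    idx <- which(upper.tri(gg) & abs(gg) > gene_gene_threshold, arr.ind = TRUE)
    if (nrow(idx))
      el <- rbind(el, data.frame(
        from = rownames(gg)[idx[, 1]], to = colnames(gg)[idx[, 2]],
        r = gg[idx], r_squared = gg[idx]^2, p_value = NA_real_,
        kind = "gene-gene", stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  if (igraph::vcount(g) > 0) {
    vn <- igraph::V(g)$name
    igraph::V(g)$type <- ifelse(vn %in% edges$image_feature, "image", "gene")
    igraph::V(g)$size <- if (is.null(importance)) 1 else
      unname(importance[vn])
    igraph::V(g)$sign <- if (is.null(signs)) NA_real_ else
      unname(signs[vn])
  }
  g
}

#' Export an association graph
#'
#' Writes the graph as GraphML plus a plain-text edge list
#' (`<stem>.graphml`, `<stem>_edges.tsv`) and a node attribute table
#' (`<stem>_nodes.tsv`).
#'
#' @param graph an igraph object from [association_graph()].
#' @param stem output path stem (no extension).
#' @return invisibly, the paths written.
#' @export
write_association_graph <- function(graph, stem) {
  paths <- paste0(stem, c(".graphml", "_edges.tsv", "_nodes.tsv"))
  igraph::write_graph(graph, paths[1], format = "graphml")
  ed <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(ed, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vd <- igraph::as_data_frame(graph, what = "vertices")
  utils::write.table(vd, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
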
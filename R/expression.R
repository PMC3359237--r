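## Organ-level expression: pool mature (non-star) counts by family,
## median-of-ratios size factors, a parametric blind variance-stabilising
## transformation, and hierarchical clustering of organs and families.

#' Pool mature miRNA counts by family
#'
#' Sums per-library counts of all member matures of each family.
#' Mature-star entries are excluded.  Rescued miRNAs (entries failing the
#' conservation filter but aligning perfectly with a precursor) and
#' variants of newly promoted families can be appended before pooling.
#'
#' @param hits data.frame of kept annotation hits (with \code{family},
#'   \code{is_star} and per-library count columns).
#' @param rescued optional data.frame in the same layout.
#' @param promoted_calls optional retained variant calls (with
#'   \code{family} and count columns) for promoted families.
#' @param promoted_families families to include from
#'   \code{promoted_calls}.
#' @param libraries count column names (default: the intersection of
#'   numeric columns, excluding \code{total}/\code{length}).
#' @return integer matrix, rows = families, columns = libraries.
#' @export
poolFamilies <- function(hits, rescued = NULL, promoted_calls = NULL,
                         promoted_families = NULL, libraries = NULL) {
    if (is.null(libraries))
        libraries <- setdiff(
            names(hits)[vapply(hits, is.numeric, logical(1))],
            c("total", "length", "n_subs", "offset5", "offset3"))
    take <- function(d) {
        d <- d[!(if (is.null(d$is_star)) FALSE else d$is_star), ,
               drop = FALSE]
        data.frame(family = as.character(d$family),
                   d[, libraries, drop = FALSE], check.names = FALSE)
    }
    tab <- take(hits)
    if (!is.null(rescued) && nrow(rescued)) tab <- rbind(tab, take(rescued))
    if (!is.null(promoted_calls) && length(promoted_families)) {
        pc <- promoted_calls[as.character(promoted_calls$family) %in%
                                 as.character(promoted_families), ,
                             drop = FALSE]
        if (nrow(pc)) tab <- rbind(tab, take(pc))
    }
    k <- rowsum(as.matrix(tab[, libraries, drop = FALSE]), tab$family)
    k <- k[rowSums(k) > 0, , drop = FALSE]
    storage.mode(k) <- "integer"
    k[order(suppressWarnings(as.numeric(rownames(k))), rownames(k)), ,
      drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' \eqn{s_j = \mathrm{median}_i \; k_{ij} / (\prod_v k_{iv})^{1/m}} over
#' rows with an all-positive geometric mean.  Factors are defined up to
#' the geometric-mean reference, and relative factors are
#' scale-equivariant: multiplying a column by c multiplies its factor,
#' relative to any other column, by c (a column duplicated and doubled
#' gets exactly twice the original's factor).
#'
#' @param k count matrix (families x libraries).
#' @return positive numeric vector, one factor per column.
#' @export
medianRatioSizeFactors <- function(k) {
    k <- as.matrix(k)
    logk <- log(k)
    ok <- rowSums(is.finite(logk)) == ncol(k)
    if (!any(ok))
        stop("no row with all-positive counts: size factors undefined; ",
             "pool more families or filter zero-heavy rows")
    logmeans <- rowMeans(logk[ok, , drop = FALSE])
    sf <- apply(logk[ok, , drop = FALSE], 2L,
                function(col) exp(median(col - logmeans)))
    setNames(sf, colnames(k))
}

#' Blind variance-stabilising transformation for NB counts
#'
#' Normalises counts by size factors (\eqn{q_{ij} = k_{ij}/s_j}), fits a
#' single common dispersion \eqn{\alpha} blind (treating the libraries
#' as replicates) by moment matching of the NB variance function
#' \eqn{Var = \mu + \alpha \mu^2} across rows, and applies the closed
#' form \eqn{t = (2/\sqrt{\alpha}) \, \mathrm{asinh}(\sqrt{\alpha q})},
#' which tends to \eqn{2\sqrt{q}} as \eqn{\alpha \to 0}.  The transform
#' is strictly increasing in the counts.
#'
#' @param k count matrix.
#' @param sf size factors (default: computed from \code{k}).
#' @param alpha optional fixed dispersion; default: moment estimate,
#'   clamped at 0 with a warning when negative.
#' @return list with \code{t} (transformed matrix), \code{alpha},
#'   \code{sf}, \code{q}.
#' @export
varianceStabilize <- function(k, sf = medianRatioSizeFactors(k),
                              alpha = NULL) {
    k <- as.matrix(k)
    q <- sweep(k, 2L, sf, "/")
    if (is.null(alpha)) {
        mu <- rowMeans(q)
        v <- apply(q, 1L, var)
        use <- mu > 0
        ## moment match: E[(v - mu)/mu^2] = alpha under NB
        alpha <- mean((v[use] - mu[use]) / mu[use]^2)
        if (is.na(alpha)) alpha <- 0
        if (alpha < 0) {
            warning("moment estimate of dispersion negative; clamped to 0")
            alpha <- 0
        }
    }
    t <- if (alpha == 0) 2 * sqrt(q)
         else (2 / sqrt(alpha)) * asinh(sqrt(alpha * q))
    list(t = t, alpha = alpha, sf = sf, q = q)
}

#' Hierarchical clustering of organs and families
#'
#' Euclidean distance and complete linkage on both axes; leaf orders are
#' returned for heatmap export, and dendrograms additionally as Newick
#' strings.
#'
#' @param t variance-stabilised matrix (families x organs).
#' @return list with \code{organ_hclust}, \code{family_hclust},
#'   \code{organ_order}, \code{family_order}, \code{heatmap} (reordered
#'   matrix), \code{organ_newick}, \code{family_newick}.
#' @export
clusterExpression <- function(t) {
    t <- as.matrix(t)
    if (nrow(t) < 2L || ncol(t) < 2L)
        stop("need at least 2 rows and 2 columns to cluster")
    hc_org <- hclust(dist(t(t)), method = "complete")
    hc_fam <- hclust(dist(t), method = "complete")
    newick <- function(hc) ape::write.tree(ape::as.phylo(hc))
    list(organ_hclust = hc_org, family_hclust = hc_fam,
         organ_order = hc_org$labels[hc_org$order],
         family_order = hc_fam$labels[hc_fam$order],
         heatmap = t[hc_fam$order, hc_org$order, drop = FALSE],
         organ_newick = newick(hc_org), family_newick = newick(hc_fam))
}

#' Sister pair of a leaf in an hclust tree
#'
#' Utility for dendrogram assertions: the set of leaves merging with
#' \code{leaf} at its first merge.
#'
#' @param hc an \code{hclust} object.
#' @param leaf leaf label.
#' @return character vector of labels joined at the leaf's first merge.
#' @export
firstMergePartners <- function(hc, leaf) {
    i <- match(leaf, hc$labels)
    m <- which(hc$merge == -i, arr.ind = TRUE)[1L, "row"]
    other <- hc$merge[m, ]
    other <- other[other != -i]
    leaves <- function(node)
        if (node < 0) hc$labels[-node]
        else unlist(lapply(hc$merge[node, ], leaves))
    leaves(other)
}
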
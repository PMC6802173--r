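#' Rank genes by relative expression
#'
#' Genes are ranked in descending order of
#' `log2((a + pseudocount) / (b + pseudocount))`, with rank ties broken
#' lexicographically by gene symbol so downstream windows are
#' deterministic.
#'
#' @param exprA,exprB Named numeric vectors (one expression value per
#'   gene), or gene-by-sample matrices (row means are used). Ranking runs
#'   over the shared gene universe.
#' @param pseudocount Added to both sides before the ratio.
#' @return `data.frame` with columns `rank`, `gene`, `log2fc`.
#' @export
rankRelativeExpression <- function(exprA, exprB, pseudocount = 1.0) {
  a <- asGeneVector(exprA)
  b <- asGeneVector(exprB)
  genes <- intersect(names(a), names(b))
  if (!length(genes)) stop("no shared genes between the two tables")
  lfc <- log2((a[genes] + pseudocount) / (b[genes] + pseudocount))
  o <- radixOrder(-lfc, genes)
  data.frame(rank = seq_along(genes), gene = genes[o],
             log2fc = unname(lfc[o]), stringsAsFactors = FALSE)
}

asGeneVector <- function(x) {
  if (is.matrix(x)) x <- rowMeans(x)
  if (is.null(names(x))) stop("expression input needs gene names")
  x
}

#' Moving average of enhancer counts over the expression ranking
#'
#' Genes are ranked by relative expression ([rankRelativeExpression()]);
#' a sliding window of `window` genes (step 1) is then averaged over the
#' per-gene enhancer counts in rank order. A positive association between
#' gene activity and enhancer number shows as high windowed means at the
#' top of the ranking.
#'
#' @param exprA,exprB As in [rankRelativeExpression()].
#' @param counts Named integer vector of enhancer counts per gene
#'   ([mapEnhancersToGenes()]); genes absent from it count 0.
#' @param window Window size in genes (default 100).
#' @param pseudocount Ratio pseudocount.
#' @return `data.frame` with `rank` (window start position, 1-based) and
#'   `meanEnhancers`; `n - window + 1` rows. The underlying ranking is
#'   attached as attribute `"ranking"`.
#' @examples
#' a <- c(g1 = 8, g2 = 4, g3 = 2, g4 = 1); b <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1)
#' movingAverageEnhancerCounts(a, b, c(g1 = 1, g2 = 2, g3 = 3, g4 = 4),
#'                             window = 3)
#' @export
movingAverageEnhancerCounts <- function(exprA, exprB, counts, window = 100,
                                        pseudocount = 1.0) {
  ranking <- rankRelativeExpression(exprA, exprB, pseudocount)
  n <- nrow(ranking)
  if (window < 1L) stop("window must be >= 1")
  if (window > n)
    stop("window (", window, ") exceeds the number of genes (", n, ")")
  cnt <- counts[ranking$gene]
  cnt[is.na(cnt)] <- 0
  cs <- c(0, cumsum(as.numeric(cnt)))
  starts <- seq_len(n - window + 1L)
  out <- data.frame(rank = starts,
                    meanEnhancers = (cs[starts + window] - cs[starts]) / window)
  attr(out, "ranking") <- ranking
  out
}

#' Relative time-course expression profiles
#'
#' Divides each gene's expression by its mean across timepoints, so every
#' row averages exactly to 1. Genes with all-zero expression are excluded
#' with a warning.
#'
#' @param expr Gene-by-timepoint matrix (non-negative).
#' @return Matrix of ratios with the same dimnames (minus excluded genes).
#' @export
relativeTimecourse <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 timepoints")
  if (any(expr < 0)) stop("expression values must be non-negative")
  m <- rowMeans(expr)
  zero <- m == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero gene(s) excluded: ",
            paste(utils::head(rownames(expr)[zero], 5L), collapse = ", "))
    expr <- expr[!zero, , drop = FALSE]
    m <- m[!zero]
  }
  expr / m
}

#' Classify time-course expression into pattern classes
#'
#' Computes relative profiles ([relativeTimecourse()]), log2-transforms
#' them, clusters genes by average-linkage hierarchical clustering and cuts
#' the tree into `nClasses` groups. With the default four classes, groups
#' are labelled by matching their centroids to the four archetype patterns:
#' 1 biphasic (high, low mid, high), 2 monotone decreasing, 3 monotone
#' increasing, 4 flat. The flat label goes to the minimum-variance
#' centroid; the remaining centroids take the template permutation with
#' maximal total correlation.
#'
#' The default distance is Euclidean on the log2 relative profiles: a flat
#' profile has no shape for a scale-invariant metric to latch onto, so
#' correlation distance cannot isolate the flat class (and is undefined on
#' noiseless flat genes); it remains available via `distance =
#' "correlation"` for shape-only clustering of non-flat patterns.
#'
#' @param expr Gene-by-timepoint matrix.
#' @param nClasses Number of classes (default 4; archetype labels only
#'   apply to 4).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List of class `TimeCourseClassing`: `classOf` (named integer),
#'   `relativeProfiles`, `logProfiles`, `centroids` (class x timepoint,
#'   log2 scale), `hclust`.
#' @export
classifyTimecourse <- function(expr, nClasses = 4,
                               distance = c("euclidean", "correlation"),
                               linkage = "average") {
  distance <- match.arg(distance)
  rel <- relativeTimecourse(expr)
  if (nrow(rel) < nClasses)
    stop("fewer genes (", nrow(rel), ") than classes (", nClasses, ")")
  lp <- log2(pmax(rel, 1e-9))
  if (nClasses == 1L) {
    cl <- setNames(rep(1L, nrow(lp)), rownames(lp))
    return(structure(list(classOf = cl, relativeProfiles = rel,
                          logProfiles = lp,
                          centroids = matrix(colMeans(lp), 1L),
                          hclust = NULL),
                     class = "TimeCourseClassing"))
  }
  if (distance == "correlation") {
    sds <- apply(lp, 1L, stats::sd)
    if (any(sds == 0))
      stop("degenerate profiles under correlation distance (zero variance): ",
           paste(utils::head(rownames(lp)[sds == 0], 5L), collapse = ", "))
    d <- stats::as.dist(1 - cor(t(lp)))
  } else {
    d <- dist(lp)
  }
  hc <- hclust(d, method = linkage)
  raw <- cutree(hc, k = nClasses)
  cent <- do.call(rbind, lapply(seq_len(nClasses), function(k)
    colMeans(lp[raw == k, , drop = FALSE])))
  lab <- seq_len(nClasses)
  if (nClasses == 4L) lab <- matchArchetypes(cent)
  cl <- setNames(lab[raw], rownames(lp))
  o <- order(lab)
  structure(list(classOf = cl, relativeProfiles = rel, logProfiles = lp,
                 centroids = cent[o, , drop = FALSE], hclust = hc),
            class = "TimeCourseClassing")
}

## Map 4 cluster centroids (log2 relative scale) to archetype labels:
## flat -> minimum variance; remaining three -> permutation of
## (biphasic, decreasing, increasing) templates maximizing total Pearson
## correlation.
matchArchetypes <- function(cent) {
  T <- ncol(cent)
  tn <- seq(0, 1, length.out = T)
  tpl <- rbind(biphasic = (tn - 0.5)^2, decreasing = -tn, increasing = tn)
  tpl <- tpl - rowMeans(tpl)
  flat <- which.min(apply(cent, 1L, stats::var))
  rest <- setdiff(seq_len(nrow(cent)), flat)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  score <- vapply(perms, function(p)
    sum(vapply(1:3, function(i) cor(cent[rest[i], ], tpl[p[i], ]),
               numeric(1L))), numeric(1L))
  best <- perms[[which.max(score)]]
  lab <- integer(4L)
  lab[flat] <- 4L
  lab[rest] <- best
  lab
}

#' @export
print.TimeCourseClassing <- function(x, ...) {
  cat("TimeCourseClassing:", length(x$classOf), "genes in",
      nrow(x$centroids), "classes\n")
  print(table(class = x$classOf))
  invisible(x)
}

#' Cross-dataset dysregulation screen
#'
#' Per dataset, genes are ranked by the pseudocounted ratio of mean case to
#' mean control expression; the top and bottom `extremeFraction` tails
#' (`floor(extremeFraction * n)` genes each, rank ties broken
#' lexicographically) are the extreme sets. A gene is called dysregulated
#' iff it is an ortholog of a super-enhancer-associated gene and falls in
#' the extreme sets of at least `minHits` datasets; its direction is the
#' majority of up (top tail) vs down (bottom tail) appearances, or
#' `"mixed"` on a tie.
#'
#' @param datasets List of datasets; each a list with `expr` (gene-by-sample
#'   matrix) and `condition` (character vector along columns, `"case"` /
#'   `"control"`).
#' @param seGenes Character vector of SE-associated gene symbols (source
#'   species).
#' @param orthologs Named character vector mapping `seGenes` symbols to the
#'   datasets' symbol space; `NULL` for identity.
#' @param extremeFraction Tail fraction per dataset (default 0.10).
#' @param minHits Minimum supporting datasets (default 3).
#' @param pseudocount Ratio pseudocount.
#' @return `data.frame` with columns `gene`, `direction` (up/down/mixed),
#'   `nUp`, `nDown`, `nHits`, sorted by gene; the per-dataset hit pattern
#'   is attached as attribute `"hits"` (gene x dataset matrix of
#'   -1/0/+1).
#' @export
crossdatasetDysregulated <- function(datasets, seGenes, orthologs = NULL,
                                     extremeFraction = 0.10, minHits = 3,
                                     pseudocount = 1.0) {
  if (length(datasets) < minHits)
    stop("fewer datasets (", length(datasets),
         ") than required hits (", minHits, ")")
  mapped <- if (is.null(orthologs)) seGenes
            else unname(orthologs[intersect(seGenes, names(orthologs))])
  mapped <- unique(mapped[!is.na(mapped)])
  empty <- data.frame(gene = character(), direction = character(),
                      nUp = integer(), nDown = integer(),
                      nHits = integer(), stringsAsFactors = FALSE)
  if (!length(mapped)) {
    warning("no SE-associated genes map into the datasets' symbol space")
    return(empty)
  }
  dirTab <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    cond <- as.character(ds$condition)
    stopifnot(all(cond %in% c("case", "control")))
    ca <- rowMeans(ds$expr[, cond == "case", drop = FALSE])
    co <- rowMeans(ds$expr[, cond == "control", drop = FALSE])
    ratio <- (ca + pseudocount) / (co + pseudocount)
    genes <- rownames(ds$expr)
    o <- radixOrder(-ratio, genes)
    m <- floor(extremeFraction * length(genes))
    top <- genes[o][seq_len(m)]
    bottom <- genes[o][length(genes) - seq_len(m) + 1L]
    v <- setNames(integer(length(genes)), genes)
    v[top] <- 1L
    v[bottom] <- -1L
    dirTab[[di]] <- v
  }
  hits <- vapply(dirTab, function(v) {
    out <- setNames(integer(length(mapped)), mapped)
    common <- intersect(mapped, names(v))
    out[common] <- v[common]
    out
  }, integer(length(mapped)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = length(mapped))
  rownames(hits) <- mapped
  nUp <- rowSums(hits == 1L)
  nDown <- rowSums(hits == -1L)
  nHits <- nUp + nDown
  sel <- nHits >= minHits
  if (!any(sel)) return(structure(empty, hits = hits))
  dir <- ifelse(nUp[sel] > nDown[sel], "up",
                ifelse(nDown[sel] > nUp[sel], "down", "mixed"))
  out <- data.frame(gene = mapped[sel], direction = dir,
                    nUp = nUp[sel], nDown = nDown[sel], nHits = nHits[sel],
                    stringsAsFactors = FALSE)
  out <- out[radixOrder(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, hits = hits)
}
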
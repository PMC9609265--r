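#' Agglomerate features to a taxonomic rank
#'
#' Sums counts over features sharing the same full lineage down to `rank`.
#' With `drop_unclassified = TRUE`, features lacking a classification at that
#' rank are removed (e.g. genera with an empty `g__` segment), mirroring the
#' rule used before per-rank survival testing; otherwise they are retained,
#' grouped by their (partial) lineage, so total counts are conserved.
#'
#' @param table a `feature_table` with taxonomy
#' @param rank one of `"kingdom"`..`"species"`, or `"ASV"` (identity)
#' @param drop_unclassified drop groups unclassified at `rank`?
#' @return a `feature_table` whose features are lineages truncated at `rank`
#' @export
agglomerate <- function(table, rank, drop_unclassified = FALSE) {
  if (identical(rank, "ASV")) return(table)
  ri <- match(rank, TAXONOMIC_RANKS)
  if (is.na(ri)) stop("unknown rank: ", rank)
  if (is.null(table$taxonomy)) stop("agglomeration requires taxonomy")
  ranks <- parse_lineage(table$taxonomy)
  if (drop_unclassified) {
    keep <- !is.na(ranks[, ri])
    if (!any(keep)) stop("no features classified at rank ", rank)
    table <- subset_table(table, features = feature_ids(table)[keep])
    ranks <- ranks[keep, , drop = FALSE]
  }
  key <- make_lineage(ranks, upto = rank)
  groups <- split(seq_along(key), key)
  counts <- vapply(groups, function(ix)
    rowSums(table$counts[, ix, drop = FALSE]), numeric(nrow(table$counts)))
  if (nrow(table$counts) == 1L)
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list(sample_ids(table), names(groups)))
  tax <- stats::setNames(names(groups), names(groups))
  feature_table(counts, tax)
}

#' Relative abundance (per-sample proportions)
#' @param table a `feature_table` or counts matrix (samples x features)
#' @return matrix of row proportions
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("samples with zero total counts: ",
                          paste(rownames(m)[tot <= 0], collapse = ", "))
  sweep(m, 1L, tot, "/")
}

#' Centered log-ratio (clr) transform
#'
#' For each sample row x, `clr_j = log(x_j + c) - mean_k log(x_k + c)` with
#' pseudocount `c`, removing the compositional (unit-sum) constraint so that
#' standard Euclidean statistics apply. Rows of the result sum to zero. The
#' default pseudocount of 0.5 is common compositional practice; `c = 0` is
#' accepted only when all values are strictly positive.
#'
#' @param table a `feature_table` or numeric matrix (samples x features)
#' @param pseudocount non-negative constant added before taking logs
#' @return a `clr_matrix`: samples x features real matrix with attributes
#'   `pseudocount`
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  if (ncol(m) == 0L) stop("empty feature set")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(m <= 0))
    stop("pseudocount 0 requires strictly positive values")
  lm_ <- log(m + pseudocount)
  out <- lm_ - rowMeans(lm_)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("clr_matrix", class(out))
  out
}

#' Rarefaction-averaged alpha diversity
#'
#' For each sample, reads are subsampled without replacement (multivariate
#' hypergeometric) to a fixed depth; richness (number of observed features)
#' and the Shannon index (base 2) are computed on the subsample and averaged
#' over `iterations` draws. Samples below `depth` total reads are excluded
#' with a warning. The study settings are depth 2468 and 100 iterations.
#'
#' @param table a `feature_table`
#' @param depth rarefaction depth (> 0)
#' @param iterations number of rarefaction draws to average
#' @param seed optional integer seed
#' @return data frame: `sample_id`, `richness`, `shannon`, with attributes
#'   `depth` and `iterations`
#' @export
rarefied_alpha <- function(table, depth = 2468, iterations = 100, seed = NULL) {
  if (depth <= 0) stop("depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  depths <- sample_depths(table)
  drop <- depths < depth
  if (any(drop))
    warning(sum(drop), " sample(s) below depth ", depth, " excluded: ",
            paste(sample_ids(table)[drop], collapse = ", "))
  keep <- sample_ids(table)[!drop]
  if (!length(keep)) stop("no samples at or above depth ", depth)
  res <- t(vapply(keep, function(s) {
    x <- table$counts[s, ]
    total <- sum(x)
    cum <- cumsum(x)
    rich <- sh <- numeric(iterations)
    for (it in seq_len(iterations)) {
      cnt <- rarefy_once(x, cum, total, depth)
      p <- cnt[cnt > 0] / depth
      rich[it] <- length(p)
      sh[it] <- -sum(p * log2(p))
    }
    c(mean(rich), mean(sh))
  }, numeric(2)))
  out <- data.frame(sample_id = keep, richness = res[, 1L],
                    shannon = res[, 2L], stringsAsFactors = FALSE)
  attr(out, "depth") <- depth
  attr(out, "iterations") <- iterations
  out
}

# one multivariate-hypergeometric draw: subsample `depth` reads w/o replacement
rarefy_once <- function(x, cum, total, depth) {
  if (depth == total) return(x)
  idx <- sample.int(total, depth)
  tabulate(findInterval(idx - 1L, cum) + 1L, nbins = length(x))
}

#' Jensen-Shannon divergence matrix
#'
#' Pairwise JSD between per-sample relative-abundance vectors,
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m = (p + q) / 2` and Shannon
#' entropy H in bits (base-2 logs), so values lie in \[0, 1\]. `0 log 0` is
#' taken as 0. Rows are renormalized to probabilities first.
#'
#' @param table a `feature_table` or a matrix of (relative) abundances
#' @return symmetric numeric matrix with zero diagonal and sample-id dimnames
#' @export
jsd_matrix <- function(table) {
  p <- relative_abundance(table)
  n <- nrow(p)
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  hs <- apply(p, 1L, H)
  D <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- (p[i, ] + p[j, ]) / 2
    d <- H(m) - (hs[i] + hs[j]) / 2
    D[i, j] <- D[j, i] <- max(d, 0)  # clamp tiny negatives from roundoff
  }
  D
}

#' Write / read a square distance matrix as TSV
#' @param D symmetric matrix with dimnames
#' @param path file path
#' @return matrix (reader) or `path` invisibly (writer)
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Principal coordinate analysis (classical MDS)
#'
#' Embeds a distance matrix via double-centering of `-D^2/2`
#' (through [stats::cmdscale()]). Negative eigenvalues, which arise for
#' non-Euclidean dissimilarities such as JSD, are reported rather than
#' silently dropped; the proportion explained is relative to the sum of
#' positive eigenvalues. Axis signs follow a fixed convention (first
#' nonzero coordinate of each axis made positive) so results are
#' deterministic.
#'
#' @param D symmetric distance matrix
#' @param k number of coordinate axes to retain (`<= n - 1`)
#' @return object of class `pcoa`: list with `points` (n x k), `eig` (all
#'   eigenvalues, descending), `prop_explained`
#' @export
pcoa <- function(D, k = 2) {
  n <- nrow(D)
  if (k > n - 1L) stop("k must be <= n - 1")
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  pos <- fit$eig[fit$eig > 0]
  structure(list(points = pts, eig = fit$eig,
                 prop_explained = fit$eig[seq_len(ncol(pts))] / sum(pos)),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("pcoa: %d samples, %d axes; proportion explained: %s\n",
              nrow(x$points), ncol(x$points),
              paste(sprintf("%.1f%%", 100 * x$prop_explained), collapse = ", ")))
  invisible(x)
}
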
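# Recursive EM Gaussian-mixture clustering of interaction z-score profiles.

#' Select interaction profiles for clustering
#'
#' A gene enters clustering if its L interaction z-score has absolute value
#' greater than `threshold` in at least one medium (the union of enhancers
#' and suppressors across media). Strains lacking a z-score in any medium
#' (no growth curve at dose 0 there) cannot satisfy the rule and are
#' excluded; their sentinel status is retained for display exports.
#'
#' @param scores an `interaction_table` covering both media.
#' @param threshold selection cutoff on |z_L| (default 2, strict).
#' @param media the two media, in feature-column order.
#' @return numeric matrix (genes x 4 features: `z_L`/`z_K` per medium) of
#'   class `"profile_matrix"`, with the per-medium shifts in attribute
#'   `"shift"` and sentinel strain ids in attribute `"sentinel"`.
#' @export
select_profiles <- function(scores, threshold = 2,
                            media = c("glycolytic", "respiratory")) {
  if (!all(media %in% scores$medium))
    stop("scores must cover media: ", paste(media, collapse = ", "))
  wide <- NULL
  for (m in media) {
    s <- scores[scores$medium == m,
                c("strain_id", "z_L", "z_K", "shift_L", "no_growth_d0")]
    names(s)[-1] <- paste0(names(s)[-1], ".", m)
    wide <- if (is.null(wide)) s else merge(wide, s, by = "strain_id")
  }
  zl <- as.matrix(wide[paste0("z_L.", media)])
  zk <- as.matrix(wide[paste0("z_K.", media)])
  sentinel <- wide$strain_id[rowSums(
    as.matrix(wide[paste0("no_growth_d0.", media)])) > 0]
  complete <- rowSums(!is.finite(cbind(zl, zk))) == 0
  keep <- complete & rowSums(abs(zl) > threshold) > 0
  feat <- cbind(zl, zk)[keep, , drop = FALSE]
  colnames(feat) <- c(paste0("z_L.", media), paste0("z_K.", media))
  rownames(feat) <- wide$strain_id[keep]
  if (!nrow(feat)) warning("no profiles satisfy the selection rule")
  shift <- as.matrix(wide[keep, paste0("shift_L.", media), drop = FALSE])
  rownames(shift) <- rownames(feat)
  structure(feat, shift = shift, sentinel = sentinel,
            threshold = threshold, class = c("profile_matrix", "matrix"))
}

# --- diagonal-covariance Gaussian mixture EM ------------------------------

.gmm_loglik_mat <- function(x, mu, v, w) {
  # n x k matrix of log(w_j) + log N(x | mu_j, diag v_j)
  n <- nrow(x); k <- nrow(mu)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lg <- -0.5 * (sweep(x, 2, mu[j, ])^2) %*% (1 / v[j, ]) -
      0.5 * sum(log(2 * pi * v[j, ]))
    out[, j] <- lg + log(w[j])
  }
  out
}

.em_diag <- function(x, k, tol = 1e-6, max_iter = 500, var_floor = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  # initialize component means from k random distinct rows (consumes the
  # caller's RNG); a random-partition init would place all means near the
  # grand mean and can fail to separate distant clusters
  mu <- x[sample.int(n, k), , drop = FALSE] +
    matrix(stats::rnorm(k * d, 0, 1e-8), k, d)
  gv <- pmax(apply(x, 2, stats::var), var_floor)
  # scale-aware floor: an absolute 1e-6 alone lets a component collapse onto
  # a single row, and the resulting density spike dominates the likelihood
  floor_vec <- pmax(var_floor, 1e-3 * gv)
  v <- matrix(gv, k, d, byrow = TRUE)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  nk <- rep(n / k, k)
  for (it in seq_len(max_iter)) {
    lw <- .gmm_loglik_mat(x, mu, v, w)
    m <- apply(lw, 1, max)
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lw - lse)
    nk <- pmax(colSums(resp), 1e-10)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
    w <- nk / n
    mu <- t(resp) %*% x / nk
    for (j in seq_len(k)) {
      v[j, ] <- pmax(colSums(resp[, j] * sweep(x, 2, mu[j, ])^2) / nk[j],
                     floor_vec)
    }
  }
  list(k = k, mu = mu, var = v, weight = w, resp = resp,
       degenerate = any(nk < 2) && k > 1,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace)
}

#' Fit one round of EM Gaussian-mixture clustering
#'
#' Fits diagonal-covariance Gaussian mixtures for `k = 1..k_max`, each with
#' `n_restarts` random initializations, and selects `k` by BIC
#' (`-2 logLik + p log n`, `p = (k - 1) + 2 k d`). Rows are assigned to the
#' component with maximum posterior responsibility. Deterministic for a
#' given seed. Component labels are ordered by decreasing size (ties by
#' smallest member row index).
#'
#' @param x numeric matrix of profiles (rows = genes).
#' @param k_max largest mixture size considered.
#' @param n_restarts random restarts per `k`.
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param var_floor absolute diagonal variance floor; an additional
#'   relative floor of 1e-3 of each feature's global variance guards
#'   against likelihood spikes from components collapsing onto single
#'   rows, and restarts in which a component captures fewer than 2 rows
#'   are discarded.
#' @return list: `k`, `assignment` (integer per row), `bic` (per k),
#'   `loglik`, `model` (means, variances, weights, responsibilities,
#'   per-iteration log-likelihood trace of the winning fit).
#' @export
fit_round <- function(x, k_max = 16, n_restarts = 10, seed = 1,
                      tol = 1e-6, max_iter = 500, var_floor = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to cluster")
  set.seed(seed)
  k_hi <- min(k_max, nrow(x) - 1L)
  bic <- rep(NA_real_, k_hi)
  best <- vector("list", k_hi)
  n <- nrow(x); d <- ncol(x)
  for (k in seq_len(k_hi)) {
    fit_k <- NULL
    for (s in seq_len(if (k == 1) 1 else n_restarts)) {
      f <- .em_diag(x, k, tol = tol, max_iter = max_iter,
                    var_floor = var_floor)
      if (f$degenerate) next  # a component captured < 2 rows
      if (is.null(fit_k) || f$loglik > fit_k$loglik) fit_k <- f
    }
    if (is.null(fit_k)) next  # all restarts degenerate at this k
    p <- (k - 1) + 2 * k * d
    bic[k] <- -2 * fit_k$loglik + p * log(n)
    best[[k]] <- fit_k
  }
  k_sel <- which.min(bic)
  model <- best[[k_sel]]
  assign_raw <- max.col(model$resp, ties.method = "first")
  # relabel components: decreasing size, ties by first member row
  present <- sort(unique(assign_raw))
  sizes <- vapply(present, function(j) sum(assign_raw == j), 0L)
  firsts <- vapply(present, function(j) which(assign_raw == j)[1], 0L)
  ord <- present[order(-sizes, firsts)]
  assignment <- match(assign_raw, ord)
  list(k = length(present), assignment = assignment, bic = bic,
       loglik = model$loglik, model = model)
}

# pedigree name: round 1 path (j)        -> "1-0-j"
#                round 2 path (j, m)     -> "2-0.j-m"
#                round 3 path (j, m, q)  -> "3-0.j.m-q"   (0-based indices)
.pedigree_name <- function(path) {
  r <- length(path)
  prefix <- paste(c(0L, utils::head(path, -1L)), collapse = ".")
  sprintf("%d-%s-%d", r, prefix, path[r])
}

#' Recursive EM clustering of an interaction profile matrix
#'
#' Applies [fit_round()] recursively: each cluster with at least `min_size`
#' members is re-clustered, and recursion stops for a node when the
#' BIC-selected `k` is 1 ("no new clusters"), the node is too small, or the
#' depth limit is reached. Clusters are named by pedigree, e.g. `"1-0-0"`
#' (first cluster of round 1), `"2-0.0-3"` (its fourth child in round 2),
#' `"3-0.0.3-1"` (second child of that cluster in round 3).
#'
#' @param x a [select_profiles()] matrix (or any numeric matrix with row
#'   names).
#' @param k_max,n_restarts,tol,max_iter,var_floor passed to [fit_round()].
#' @param min_size minimum cluster size for further recursion.
#' @param max_depth maximum number of rounds.
#' @param seed master seed; each node consumes a deterministic child seed
#'   in depth-first order.
#' @return object of class `"remc"`: list with `membership` (data.frame
#'   `gene`, `leaf`), `nodes` (per named cluster: members, round, selected
#'   k, log-likelihood), and the input matrix.
#' @export
remc <- function(x, k_max = 16, n_restarts = 10, min_size = 8,
                 max_depth = 4, seed = 1, tol = 1e-6, max_iter = 500,
                 var_floor = 1e-6) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  nodes <- list()
  leaves <- list()
  counter <- 0L
  recurse <- function(rows, path) {
    round_ <- length(path) + 1L
    counter <<- counter + 1L
    node_seed <- child_seed(seed, 100L + counter)
    fr <- fit_round(x[rows, , drop = FALSE], k_max = k_max,
                    n_restarts = n_restarts, seed = node_seed, tol = tol,
                    max_iter = max_iter, var_floor = var_floor)
    if (fr$k == 1L && round_ > 1L) return(FALSE)  # no new clusters here
    for (j in seq_len(fr$k)) {
      members <- rows[fr$assignment == j]
      child_path <- c(path, j - 1L)
      name <- .pedigree_name(child_path)
      nodes[[name]] <<- list(name = name, round = round_,
                             members = rownames(x)[members],
                             n = length(members), k_selected = fr$k,
                             loglik = fr$loglik)
      split_further <- length(members) >= min_size &&
        length(members) >= 2L && round_ < max_depth
      is_leaf <- TRUE
      if (split_further) is_leaf <- !recurse(members, child_path)
      if (is_leaf) leaves[[name]] <<- rownames(x)[members]
    }
    TRUE
  }
  if (nrow(x) < 2) stop("need at least 2 profiles for clustering")
  recurse(seq_len(nrow(x)), integer(0))
  membership <- do.call(rbind, lapply(names(leaves), function(nm)
    data.frame(gene = leaves[[nm]], leaf = nm, stringsAsFactors = FALSE)))
  membership <- membership[match(rownames(x), membership$gene), ]
  rownames(membership) <- NULL
  structure(list(membership = membership, nodes = nodes, leaves = leaves,
                 matrix = x, seed = seed),
            class = "remc")
}

#' @export
print.remc <- function(x, ...) {
  cat(sprintf("Recursive EM clustering: %d profiles, %d clusters (%d leaves)\n",
              nrow(x$matrix), length(x$nodes), length(x$leaves)))
  for (nm in names(x$nodes)) {
    nd <- x$nodes[[nm]]
    leaf <- if (nm %in% names(x$leaves)) " *" else ""
    cat(sprintf("%s%s (n = %d)%s\n",
                strrep("  ", nd$round - 1L), nm, nd$n, leaf))
  }
  invisible(x)
}

#' @export
plot.remc <- function(x, ...) {
  m <- x$matrix[order(x$membership$leaf), , drop = FALSE]
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  axes = FALSE, xlab = "feature", ylab = "gene", ...)
  invisible(x)
}

#' Hierarchical row order for heatmap display
#'
#' Average-linkage hierarchical clustering on Euclidean distance over the
#' profile features, as used to order genes within a cluster for heatmaps.
#'
#' @param m numeric matrix (rows to order).
#' @return integer permutation of `1:nrow(m)`.
#' @export
order_for_heatmap <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) <= 2L) return(seq_len(nrow(m)))
  stats::hclust(stats::dist(m, method = "euclidean"),
                method = "average")$order
}

#' Heatmap-ready matrix for a cluster or gene set
#'
#' Returns the selected genes' 4 z-score features plus the per-medium shift
#' columns, ordered by [order_for_heatmap()] on the features. For sentinel
#' strains (no growth curve at dose 0 in a medium) the convention of the
#' display exports applies: the interaction cell carries the sentinel value
#' 0.0001 and the shift cell is `NA`.
#'
#' @param pm a [select_profiles()] matrix.
#' @param genes character vector of genes (default: all rows).
#' @return numeric matrix: features then shift columns, ordered rows.
#' @export
cluster_heatmap_matrix <- function(pm, genes = rownames(pm)) {
  genes <- intersect(genes, rownames(pm))
  if (!length(genes)) stop("none of the requested genes are in the matrix")
  feat <- pm[genes, , drop = FALSE]
  ord <- order_for_heatmap(feat)
  feat <- feat[ord, , drop = FALSE]
  shift <- attr(pm, "shift")[genes[ord], , drop = FALSE]
  out <- cbind(feat, shift)
  class(out) <- "matrix"
  sent <- intersect(rownames(out), attr(pm, "sentinel"))
  if (length(sent)) {
    out[sent, seq_len(ncol(feat))] <- 0.0001
    out[sent, ncol(feat) + seq_len(ncol(shift))] <- NA_real_
  }
  out
}
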
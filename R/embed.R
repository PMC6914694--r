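# PCA reduction and 2D embeddings (linear top-2, t-SNE on selected weights).
#
# The PCA is computed once on the full stack, before any train/test split:
# unsupervised dimension reduction prior to partitioning does not leak label
# information into held-out subjects, and this contract is relied on by the
# classification stage.

#' Principal components of an edge-vector stack
#'
#' Centers the rows' columns and computes principal components via the
#' eigendecomposition of whichever of the two Gram matrices is smaller
#' (`X X'` when edges outnumber networks, which is the typical regime with
#' ~35k edges and a few thousand networks; `X'X` otherwise). Keeps
#' `min(N - 1, m)` components. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so results are
#' deterministic.
#'
#' @param stack an `edge_stack`, or a plain numeric matrix (rows = networks).
#' @return an object of class `pca_model`: list with `mean` (length-m column
#'   means), `components` (k x m orthonormal rows), `explained_variance_ratio`
#'   (length k, nonincreasing), `scores` (N x k component weights), and
#'   `row_meta` when available.
#' @export
fit_pca <- function(stack) {
  if (inherits(stack, "edge_stack")) {
    x <- stack$values
    row_meta <- stack$row_meta
  } else {
    x <- as.matrix(stack)
    row_meta <- NULL
  }
  n_obs <- nrow(x)
  if (is.null(n_obs) || n_obs < 3L) stopf("PCA needs at least 3 rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  k <- min(n_obs - 1L, ncol(x))
  if (ncol(x) >= n_obs) {
    g <- tcrossprod(xc)                        # N x N
    e <- eigen(g, symmetric = TRUE)
    pos <- which(e$values > max(e$values, 0) * 1e-12)
    pos <- pos[seq_len(min(length(pos), k))]
    sv <- sqrt(e$values[pos])
    comp <- crossprod(xc, e$vectors[, pos, drop = FALSE]) /
      rep(sv, each = ncol(x))                  # m x k, orthonormal columns
    scores <- e$vectors[, pos, drop = FALSE] * rep(sv, each = n_obs)
    var_k <- e$values[pos] / (n_obs - 1L)
    total_var <- sum(diag(g)) / (n_obs - 1L)
    comp <- t(comp)
  } else {
    cv <- crossprod(xc) / (n_obs - 1L)         # m x m
    e <- eigen(cv, symmetric = TRUE)
    keep <- seq_len(k)
    comp <- t(e$vectors[, keep, drop = FALSE])
    scores <- xc %*% t(comp)
    var_k <- pmax(e$values[keep], 0)
    total_var <- sum(pmax(e$values, 0))
  }
  # sign convention: largest-|loading| entry of each component is positive
  flip <- apply(comp, 1L, function(r) sign(r[which.max(abs(r))]))
  flip[flip == 0] <- 1
  comp <- comp * flip
  scores <- sweep(scores, 2L, flip, "*")
  structure(list(mean = mu, components = comp,
                 explained_variance_ratio = var_k / total_var,
                 scores = scores, row_meta = row_meta),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf("PCA model: %d components over %d edges (top-2 variance %.1f%%, 99%% at k=%d)\n",
              nrow(x$components), ncol(x$components),
              100 * sum(evr[seq_len(min(2, length(evr)))]),
              select_components(x, 0.99)))
  invisible(x)
}

#' Number of components needed to reach a variance fraction
#'
#' @param model a `pca_model`.
#' @param variance_fraction target cumulative fraction in (0, 1]; default
#'   0.99, the fraction used by the `tsne99` embedding.
#' @return smallest k whose cumulative explained variance ratio reaches the
#'   target (all components if the target is never reached).
#' @export
select_components <- function(model, variance_fraction = 0.99) {
  stopifnot(inherits(model, "pca_model"))
  if (!is_number(variance_fraction) || variance_fraction <= 0 ||
      variance_fraction > 1) {
    stopf("variance_fraction must lie in (0, 1]")
  }
  cum <- cumsum(model$explained_variance_ratio)
  k <- which(cum >= variance_fraction - 1e-12)[1L]
  if (is.na(k)) k <- length(cum)
  as.integer(k)
}

new_embedding <- function(coords, row_meta, method, seed = NA_integer_) {
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, row_meta = row_meta, method = method,
                 replicate_seed = seed),
            class = "net_embedding")
}

#' @export
print.net_embedding <- function(x, ...) {
  cat(sprintf("2D embedding (%s%s): %d points\n", x$method,
              if (is.na(x$replicate_seed)) ""
              else sprintf(", seed %d", x$replicate_seed),
              nrow(x$coords)))
  invisible(x)
}

#' Linear 2D embedding: first component weight vs second
#'
#' @param model a `pca_model` with at least two informative components.
#' @return a `net_embedding` with `method = "pca2"`.
#' @export
embed_linear <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  evr <- model$explained_variance_ratio
  if (length(evr) < 2L || evr[2L] <= 1e-12) {
    stopf("data are effectively rank 1; a 2D linear embedding needs 2 components")
  }
  new_embedding(model$scores[, 1:2, drop = FALSE], model$row_meta, "pca2")
}

#' Nonlinear 2D embedding with t-SNE
#'
#' Embeds component weights in 2D by minimising the Kullback-Leibler
#' divergence between Gaussian high-dimensional affinities (calibrated to
#' `perplexity`) and the Student-t low-dimensional kernel. The optimisation
#' is initialised from the first two columns of `weights` rescaled to a small
#' standard deviation, plus seeded Gaussian jitter, which stabilises
#' replicates while leaving seed-to-seed variability; a fixed seed gives
#' bit-identical coordinates.
#'
#' @param weights N x k matrix of component weights (k >= 2), e.g.
#'   `model$scores[, 1:select_components(model, 0.99)]`.
#' @param perplexity effective neighbour count; requires `N > 3 * perplexity`.
#' @param n_iter optimisation iterations.
#' @param seed integer seed.
#' @param row_meta optional per-row metadata carried into the result.
#' @param method method tag, `"tsne2"` or `"tsne99"`.
#' @param theta Barnes-Hut accuracy parameter; 0 runs the exact algorithm
#'   (the default at this package's problem sizes).
#' @return a `net_embedding`.
#' @export
embed_tsne <- function(weights, perplexity = 30, n_iter = 1000L,
                       seed = 1L, row_meta = NULL,
                       method = c("tsne2", "tsne99"), theta = 0) {
  method <- match.arg(method)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) < 2L) stopf("t-SNE input needs at least 2 columns")
  if (n <= 3 * perplexity) {
    stopf("perplexity %g too large: need N > 3 * perplexity = %g (N = %d)",
          perplexity, 3 * perplexity, n)
  }
  set.seed(as.integer(seed))
  init <- scale(weights[, 1:2, drop = FALSE])
  init[is.na(init)] <- 0
  init <- init * 1e-4 + matrix(rnorm(2L * n, sd = 1e-6), n, 2L)
  fit <- Rtsne::Rtsne(weights, dims = 2L, perplexity = perplexity,
                      theta = theta, max_iter = as.integer(n_iter),
                      Y_init = init, pca = FALSE, check_duplicates = FALSE,
                      verbose = FALSE)
  new_embedding(fit$Y, row_meta, method, as.integer(seed))
}

#' Run replicate t-SNE embeddings
#'
#' t-SNE is stochastic, so the downstream classification and clustering
#' statistics are averaged over replicate embeddings (50 in the reference
#' analysis). Replicate r uses seed `base_seed + r - 1`.
#'
#' @inheritParams embed_tsne
#' @param n_reps number of replicates (>= 1).
#' @param base_seed seed of the first replicate.
#' @return list of `net_embedding` objects.
#' @export
run_replicates <- function(weights, perplexity = 30, n_iter = 1000L,
                           n_reps = 50L, base_seed = 1L, row_meta = NULL,
                           method = c("tsne2", "tsne99"), theta = 0) {
  if (!is_count(n_reps)) stopf("n_reps must be an integer >= 1")
  method <- match.arg(method)
  lapply(seq_len(n_reps), function(r) {
    embed_tsne(weights, perplexity = perplexity, n_iter = n_iter,
               seed = as.integer(base_seed) + r - 1L, row_meta = row_meta,
               method = method, theta = theta)
  })
}

#' Write an embedding as TSV
#' @param embedding a `net_embedding`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "net_embedding"))
  df <- as.data.frame(embedding$coords)
  if (!is.null(embedding$row_meta)) df <- cbind(df, embedding$row_meta)
  df$method <- embedding$method
  df$seed <- embedding$replicate_seed
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of an embedding coloured by a metadata column
#'
#' @param x a `net_embedding`.
#' @param colour_by row_meta column used for colours ("condition", "group",
#'   or "subject_id").
#' @param ... passed to [graphics::plot()].
#' @export
plot.net_embedding <- function(x, colour_by = "condition", ...) {
  lab <- if (!is.null(x$row_meta) && colour_by %in% names(x$row_meta)) {
    factor(x$row_meta[[colour_by]])
  } else {
    factor(rep("all", nrow(x$coords)))
  }
  graphics::plot(x$coords, col = as.integer(lab), pch = 16, cex = 0.5,
                 xlab = "dim 1", ylab = "dim 2",
                 main = sprintf("%s embedding", x$method), ...)
  graphics::legend("topright", legend = levels(lab),
                   col = seq_along(levels(lab)), pch = 16, cex = 0.8)
  invisible(x)
}
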
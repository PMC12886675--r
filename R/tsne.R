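# Exact t-SNE (no approximation): Gaussian input affinities with per-point
# precision calibrated to the target perplexity by bisection, Student-t
# low-dimensional kernel, gradient descent with momentum, gain adaptation
# and early exaggeration — the reference algorithm, practical here because
# the embedded sets are small (hundreds to a few thousand points).

tsne_affinities <- function(x, perplexity, tol = 1e-5) {
  n <- nrow(x)
  sumx <- rowSums(x^2)
  d2 <- pmax(outer(sumx, sumx, "+") - 2 * tcrossprod(x), 0)
  diag(d2) <- 0
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta_lo <- -Inf; beta_hi <- Inf; beta <- 1
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; pj <- w } else {
        pj <- w / sw
        h <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      }
      if (abs(h - target) < tol) break
      if (h > target) {      # entropy too high -> sharpen
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- pj
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' Exact t-SNE embedding
#'
#' @param x numeric matrix (samples x features).
#' @param perplexity target perplexity (default 30); requires
#'   `nrow(x) - 1 >= 3 * perplexity`.
#' @param max_iter gradient-descent iterations (default 1000).
#' @param seed integer seed (initialisation is the only randomness).
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, max_iter = 1000, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n - 1 < 3 * perplexity) {
    stop("perplexity ", perplexity, " too large for n = ", n,
         "; need n - 1 >= 3 * perplexity — lower `perplexity`",
         call. = FALSE)
  }
  p <- tsne_affinities(x, perplexity)
  with_seed(seed, {
    y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    eta <- 200
    exagg <- 4
    p_run <- p * exagg
    for (it in seq_len(max_iter)) {
      if (it == 101) p_run <- p
      sumy <- rowSums(y^2)
      num <- 1 / (1 + pmax(outer(sumy, sumy, "+") - 2 * tcrossprod(y), 0))
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      l <- (p_run - q) * num
      grad <- 4 * (diag(rowSums(l)) - l) %*% y
      mom <- if (it < 250) 0.5 else 0.8
      gains <- pmax(0.01,
                    ifelse(sign(grad) != sign(inc), gains + 0.2,
                           gains * 0.8))
      inc <- mom * inc - eta * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    y
  })
}

#' t-SNE separability of labelled features
#'
#' Embeds the features in 2-D with exact t-SNE and scores how well the
#' labels separate in the embedding by the mean silhouette width computed
#' on the 2-D coordinates — the quantitative surrogate for the visual
#' cluster contrast between raw features and learned embeddings.
#'
#' @param features numeric matrix or data frame (samples x features).
#' @param labels class labels (>= 2 distinct values, n >= 10).
#' @param seed integer seed.
#' @param perplexity,max_iter passed to [tsne_embed()].
#' @return list with `coords` (tibble `dim1, dim2, label`) and
#'   `silhouette` (mean silhouette width).
#' @export
tsne_separability <- function(features, labels, seed = 1L,
                              perplexity = 30, max_iter = 1000) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need at least 10 samples", call. = FALSE)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("need at least 2 distinct labels", call. = FALSE)
  }
  y <- tsne_embed(features, perplexity = perplexity, max_iter = max_iter,
                  seed = seed)
  list(
    coords = tibble::tibble(dim1 = y[, 1], dim2 = y[, 2], label = labels),
    silhouette = silhouette_score(y, labels)
  )
}

#' Mean silhouette width of labelled points
#'
#' @param coords numeric matrix of coordinates.
#' @param labels class labels.
#' @return mean silhouette width in [-1, 1].
#' @export
silhouette_score <- function(coords, labels) {
  sil <- cluster::silhouette(as.integer(as.factor(labels)),
                             stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' t-SNE scatter plot
#'
#' @param sep result of [tsne_separability()].
#' @return a ggplot.
#' @export
plot_tsne <- function(sep) {
  ggplot2::ggplot(sep$coords,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(title = sprintf("silhouette = %.3f", sep$silhouette)) +
    ggplot2::theme_minimal()
}
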
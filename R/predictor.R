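# Phase 3: 2-cluster K-means on the latent representation and the mapping
# of clusters to class labels. The clustering is a bespoke Lloyd iteration
# (assign each point to its nearest centroid, recompute centroids as
# within-cluster means) with greedy farthest-point seeding and restarts.

# Squared Euclidean distances between the rows of X (n x d) and the rows of
# C (c x d); returns an n x c matrix.
sq_dist_to_centroids <- function(X, C) {
  D <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  pmax(D, 0)  # guard tiny negative values from cancellation
}

# Nearest-centroid assignment; ties break to the lowest cluster index.
nearest_centroid <- function(X, C) {
  max.col(-sq_dist_to_centroids(X, C), ties.method = "first")
}

# k-means++ seeding: a random first centre, then each further centre drawn
# among the points with probability proportional to the squared distance
# to its nearest chosen centre. The d^2 weighting spreads the seeds while
# the sampling keeps restarts diverse.
seed_centroids <- function(X, c) {
  n <- nrow(X)
  first <- sample.int(n, 1L)
  centres <- first
  d2 <- rowSums((X - rep(X[first, ], each = n))^2)
  while (length(centres) < c) {
    nxt <- if (sum(d2) > 0) {
      sample.int(n, 1L, prob = d2)
    } else {
      sample.int(n, 1L)  # all points coincide with a centre
    }
    centres <- c(centres, nxt)
    d2 <- pmin(d2, rowSums((X - rep(X[nxt, ], each = n))^2))
  }
  X[centres, , drop = FALSE]
}

lloyd_once <- function(X, c, tol, max_iter) {
  C <- seed_centroids(X, c)
  assign_old <- rep(0L, nrow(X))
  iter <- 0L
  inertia_trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    assign_new <- nearest_centroid(X, C)
    inertia_trace[iter] <-
      sum(sq_dist_to_centroids(X, C)[cbind(seq_along(assign_new),
                                           assign_new)])
    C_new <- C
    for (b in seq_len(c)) {
      members <- assign_new == b
      if (any(members)) {
        C_new[b, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        # empty cluster: reseed at the point farthest from its centroid
        d2 <- sq_dist_to_centroids(X, C_new)
        worst <- which.max(d2[cbind(seq_len(nrow(X)), assign_new)])
        C_new[b, ] <- X[worst, ]
        assign_new[worst] <- b
      }
    }
    moved <- max(sqrt(rowSums((C_new - C)^2)))
    C <- C_new
    if (identical(assign_new, assign_old) || moved < tol ||
        iter >= max_iter) {
      assign_old <- assign_new
      break
    }
    assign_old <- assign_new
  }
  final_assign <- nearest_centroid(X, C)
  inertia <- sum(sq_dist_to_centroids(X, C)[cbind(seq_along(final_assign),
                                                  final_assign)])
  list(centroids = C, assignments = final_assign, inertia = inertia,
       n_iter = iter, inertia_trace = inertia_trace)
}

#' Fit K-means by Lloyd iteration
#'
#' Partitions the rows of `X` into `c` clusters so each point belongs to
#' the cluster with the nearest mean (squared Euclidean distance), the
#' centroid of each cluster being the mean of its members. Runs
#' `n_restarts` seeded restarts and keeps the solution with the lowest
#' inertia (total within-cluster sum of squares). An empty cluster arising
#' during iteration is reseeded at the point farthest from its assigned
#' centroid.
#'
#' @param X Numeric `n x d` matrix (rows = points), all entries finite.
#' @param c Number of clusters (2 in the semi-supervised pipeline).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param tol Convergence threshold on the maximum centroid displacement.
#' @param max_iter Iteration cap per restart.
#' @param n_restarts Number of seeded restarts.
#' @return An object of class `gmean_kmeans`: list with `centroids`
#'   (`c x d`), `assignments` (1-based cluster index per row), `inertia`,
#'   `n_iter`, `c` and `seed`.
#' @export
kmeans_fit <- function(X, c = 2L, seed = 1L, tol = 1e-4, max_iter = 300L,
                       n_restarts = 20L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("kmeans_fit: X must be finite")
  if (nrow(X) < c) {
    stopf("kmeans_fit: %d points cannot form %d clusters", nrow(X), c)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(X, c, tol, max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(centroids = best$centroids,
                 assignments = best$assignments,
                 inertia = best$inertia, n_iter = best$n_iter,
                 inertia_trace = best$inertia_trace,
                 c = as.integer(c), seed = as.integer(seed)),
            class = "gmean_kmeans")
}

#' @export
print.gmean_kmeans <- function(x, ...) {
  cat(sprintf("K-means: %d clusters in %d-d, inertia %.4g (%d Lloyd iterations)\n",
              x$c, ncol(x$centroids), x$inertia, x$n_iter))
  invisible(x)
}

#' Assign points to the clusters of a fitted model
#'
#' Each row of `X` maps to the cluster whose centroid minimizes the squared
#' Euclidean distance; ties break to the lowest cluster index.
#'
#' @param model A [kmeans_fit()] object.
#' @param X Numeric `m x d` matrix with `d` matching the centroids.
#' @return Integer vector of 1-based cluster indices (length `m`).
#' @export
kmeans_assign <- function(model, X) {
  stopifnot(inherits(model, "gmean_kmeans"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(integer(0))
  if (ncol(X) != ncol(model$centroids)) {
    stopf("kmeans_assign: points have %d columns, centroids %d",
          ncol(X), ncol(model$centroids))
  }
  nearest_centroid(X, model$centroids)
}

#' Map clusters to class labels using labelled latents
#'
#' Computes the mean latent vector of each class from labelled training
#' data and maps every cluster to the class whose mean is nearest its
#' centroid. If both clusters prefer the same class, the bijection (for
#' `c = 2`) maximizing agreement with the labelled data is chosen; exact
#' ties resolve to the identity map. Test labels are never consulted, so
#' prediction of the unlabelled set remains honest semi-supervision.
#'
#' @param model A fitted [kmeans_fit()] model with `c = 2`.
#' @param labelled_latents Latent matrix of labelled records (same
#'   extractor as the data the model was fitted on).
#' @param labels Binary label vector aligned with `labelled_latents`; both
#'   classes must be present.
#' @return An object of class `gmean_cluster_map`: integer vector
#'   `mapping` with `mapping[b]` the class of cluster `b`.
#' @export
map_clusters_to_labels <- function(model, labelled_latents, labels) {
  stopifnot(inherits(model, "gmean_kmeans"))
  labels <- as.integer(labels)
  check_binary(labels, "labels")
  if (!all(c(0L, 1L) %in% labels)) {
    stopf("map_clusters_to_labels: both classes must appear in labels")
  }
  X <- as.matrix(labelled_latents)
  if (model$c != 2L) {
    stopf("map_clusters_to_labels: the cluster-to-class map is defined for c = 2")
  }
  class_means <- rbind(colMeans(X[labels == 0L, , drop = FALSE]),
                       colMeans(X[labels == 1L, , drop = FALSE]))
  D <- sq_dist_to_centroids(model$centroids, class_means)  # c x 2
  nearest <- max.col(-D, ties.method = "first") - 1L
  if (nearest[1L] == nearest[2L]) {
    # both centroids prefer one class: pick the bijection that agrees more
    # with the labelled data; tie -> identity
    assign_lab <- kmeans_assign(model, X)
    agree_identity <- mean((assign_lab - 1L) == labels)
    agree_swap <- mean((2L - assign_lab) == labels)
    nearest <- if (agree_swap > agree_identity) c(1L, 0L) else c(0L, 1L)
  }
  structure(list(mapping = nearest), class = "gmean_cluster_map")
}

#' Predict class labels for latent points
#'
#' The composition of [kmeans_assign()] and a [map_clusters_to_labels()]
#' map.
#'
#' @param model A fitted [kmeans_fit()] model.
#' @param map A `gmean_cluster_map`.
#' @param X Latent matrix of the points to label.
#' @return Integer vector of labels in `{0, 1}`, one per row of `X`.
#' @export
predict_labels <- function(model, map, X) {
  stopifnot(inherits(map, "gmean_cluster_map"))
  clusters <- kmeans_assign(model, X)
  map$mapping[clusters]
}

#' Save / load a fitted K-means predictor as a text file
#'
#' A small tab-separated file carrying the centroids, the cluster-to-class
#' map and the seed, written alongside the backbone checkpoint.
#'
#' @param model A `gmean_kmeans`.
#' @param map A `gmean_cluster_map` (or `NULL`).
#' @param path File path.
#' @return `path` (write) or a list `(model, map)` (read).
#' @export
write_kmeans <- function(model, map, path) {
  lines <- c(sprintf("# gmean kmeans: c=%d seed=%d inertia=%.17g",
                     model$c, model$seed, model$inertia),
             sprintf("map\t%s",
                     paste(if (is.null(map)) rep(NA, model$c) else
                       map$mapping, collapse = "\t")),
             vapply(seq_len(model$c), function(b) {
               paste(c(sprintf("centroid_%d", b),
                       sprintf("%.17g", model$centroids[b, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kmeans
#' @export
read_kmeans <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  c_ <- as.integer(sub(".*c=(\\d+).*", "\\1", hdr))
  seed <- as.integer(sub(".*seed=(-?\\d+).*", "\\1", hdr))
  map_fields <- strsplit(lines[2L], "\t")[[1L]][-1L]
  centroids <- do.call(rbind, lapply(lines[-(1:2)], function(l) {
    as.numeric(strsplit(l, "\t")[[1L]][-1L])
  }))
  model <- structure(list(centroids = centroids, assignments = integer(0),
                          inertia = as.numeric(sub(".*inertia=([^ ]+).*",
                                                   "\\1", hdr)),
                          n_iter = NA_integer_, c = c_, seed = seed),
                     class = "gmean_kmeans")
  map <- if (anyNA(suppressWarnings(as.integer(map_fields)))) NULL else {
    structure(list(mapping = as.integer(map_fields)),
              class = "gmean_cluster_map")
  }
  list(model = model, map = map)
}

# ---- Comparator predictors -------------------------------------------------
# Thin adapters over established implementations, used only by the
# model-comparison harness; the bespoke K-means above is the package's own
# predictor. Each is trained on labelled latents (supervised, unlike
# K-means) and returns labels in {0, 1} for the test latents.

comparator_predict <- function(kind, train_latents, train_labels,
                               test_latents, seed = 1L) {
  train_df <- as.data.frame(train_latents)
  test_df <- as.data.frame(test_latents)
  colnames(test_df) <- colnames(train_df)
  with_seed(seed, switch(
    kind,
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stopf("the rf comparator requires the randomForest package")
      }
      fit <- randomForest::randomForest(train_df,
                                        y = train_labels)  # regression mode
      as.integer(stats::predict(fit, test_df) >= 0.5)
    },
    svr = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stopf("the svr comparator requires the e1071 package")
      }
      fit <- e1071::svm(train_df, y = train_labels, type = "eps-regression")
      as.integer(stats::predict(fit, test_df) >= 0.5)
    },
    tree = {
      if (!requireNamespace("rpart", quietly = TRUE)) {
        stopf("the tree comparator requires the rpart package")
      }
      dat <- cbind(train_df, .y = factor(train_labels, levels = c(0, 1)))
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class")
      as.integer(as.character(stats::predict(fit, test_df, type = "class")))
    },
    stopf("unknown comparator predictor '%s'", kind)))
}
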
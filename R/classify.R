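# Behaviour prediction: CART grown with Gini impurity, minimal
# cost-complexity (weakest-link) pruning with the penalty chosen on a held
# out set, and bagged-forest feature importances. The classifier is built in
# the package; rpart serves only as a parity oracle in the tests.

#' Gini impurity of a class distribution
#'
#' `sum_i p(i) * (1 - p(i))`; for two classes this is `2 p (1 - p)`, maximal
#' (0.5) at p = 0.5 and zero for a pure node.
#'
#' @param p vector of class probabilities (non-negative, summing to 1 within
#'   1e-9).
#' @return impurity in [0, 1 - 1/C].
#' @export
gini_impurity <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("class probabilities must be >= 0 and sum to 1", call. = FALSE)
  }
  sum(p * (1 - p))
}

gini_from_counts <- function(n1, n0) {
  n <- n1 + n0
  ifelse(n == 0, 0, 1 - (n1 / n)^2 - (n0 / n)^2)
}

# Best "feature <= threshold" split of rows (y01 in {0,1}) among `feats`.
# Thresholds are midpoints of adjacent distinct sorted values. Returns NULL
# when no split strictly decreases weighted Gini impurity.
best_split <- function(X, rows, y01, min_leaf, feats) {
  n <- length(rows)
  y <- y01[rows]
  parent_gini <- gini_from_counts(sum(y), n - sum(y))
  if (parent_gini == 0 || n < 2 * min_leaf) return(NULL)
  best <- NULL
  for (f in feats) {
    x <- X[rows, f]
    o <- order(x)
    xs <- x[o]
    ys <- y[o]
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(valid)) next
    cum1 <- cumsum(ys)[i]
    nl <- i
    gl <- 1 - (cum1 / nl)^2 - ((nl - cum1) / nl)^2
    nr <- n - nl
    r1 <- sum(ys) - cum1
    gr <- 1 - (r1 / nr)^2 - ((nr - r1) / nr)^2
    weighted <- (nl * gl + nr * gr) / n
    weighted[!valid] <- Inf
    j <- which.min(weighted)
    dec <- parent_gini - weighted[j]
    if (dec > 1e-12 && (is.null(best) || dec > best$decrease + 1e-15)) {
      best <- list(feature = f, threshold = unname((xs[j] + xs[j + 1L]) / 2),
                   decrease = dec,
                   left = rows[o[seq_len(j)]],
                   right = rows[o[(j + 1L):n]])
    }
  }
  best
}

# Grow a CART to purity (or min_leaf / no impurity-decreasing split).
# `sample_feats`, if given, draws the candidate feature subset at each split
# (used by the forest). Returns a flat list of nodes; node 1 is the root.
grow_tree <- function(X, y01, classes, min_leaf = 1L, sample_feats = NULL) {
  nodes <- list()
  new_node <- function(rows) {
    n1 <- sum(y01[rows])
    n0 <- length(rows) - n1
    # class tie at a leaf goes to ACD (fixed convention)
    pred <- if (n1 > n0) classes[2L] else if (n0 > n1) classes[1L] else
      if ("ACD" %in% classes) "ACD" else classes[1L]
    list(feature = NA_character_, threshold = NA_real_,
         n = length(rows), counts = c(n0 = n0, n1 = n1),
         gini = gini_from_counts(n1, n0),
         pred = pred,
         left = NA_integer_, right = NA_integer_)
  }
  build <- function(rows) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- new_node(rows)
    feats <- if (is.null(sample_feats)) colnames(X) else sample_feats()
    sp <- best_split(X, rows, y01, min_leaf, feats)
    if (!is.null(sp)) {
      lid <- build(sp$left)
      rid <- build(sp$right)
      nodes[[id]]$feature <<- sp$feature
      nodes[[id]]$threshold <<- sp$threshold
      nodes[[id]]$left <<- lid
      nodes[[id]]$right <<- rid
    }
    id
  }
  build(seq_along(y01))
  structure(list(nodes = nodes, classes = classes, n = length(y01)),
            class = "cart_tree")
}

tree_is_leaf <- function(tree, id, pruned = integer(0)) {
  is.na(tree$nodes[[id]]$left) || id %in% pruned
}

n_leaves <- function(tree, pruned = integer(0)) {
  count <- function(id) {
    if (tree_is_leaf(tree, id, pruned)) return(1L)
    count(tree$nodes[[id]]$left) + count(tree$nodes[[id]]$right)
  }
  count(1L)
}

# R(T_t): total sample-weighted Gini impurity of the leaves under node id.
subtree_risk <- function(tree, id, pruned = integer(0)) {
  node <- tree$nodes[[id]]
  if (tree_is_leaf(tree, id, pruned)) return(node$n / tree$n * node$gini)
  subtree_risk(tree, node$left, pruned) + subtree_risk(tree, node$right, pruned)
}

#' Minimal cost-complexity pruning path
#'
#' Weakest-link pruning: at each step the internal node(s) minimizing
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)` are collapsed, where `R` is
#' the sample-weighted Gini impurity of leaves. Yields a nested sequence of
#' subtrees at strictly increasing effective alphas, ending at the root leaf.
#'
#' @param tree a grown `cart_tree`.
#' @return object of class `pruning_path`: data.frame `path` with columns
#'   `alpha`, `n_leaves`, and the per-step sets of collapsed node ids.
#' @export
cost_complexity_path <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  pruned <- integer(0)
  alphas <- 0
  pruned_sets <- list(integer(0))
  leaves <- n_leaves(tree)
  nl <- leaves
  # internal nodes still reachable from the root (descendants of collapsed
  # nodes are no longer part of the effective subtree)
  internal_ids <- function(pruned) {
    out <- integer(0)
    walk <- function(id) {
      if (tree_is_leaf(tree, id, pruned)) return(invisible())
      out <<- c(out, id)
      walk(tree$nodes[[id]]$left)
      walk(tree$nodes[[id]]$right)
    }
    walk(1L)
    out
  }
  while (!tree_is_leaf(tree, 1L, pruned)) {
    ids <- internal_ids(pruned)
    g <- vapply(ids, function(id) {
      node <- tree$nodes[[id]]
      r_node <- node$n / tree$n * node$gini
      (r_node - subtree_risk(tree, id, pruned)) /
        (n_leaves_at(tree, id, pruned) - 1L)
    }, numeric(1))
    gmin <- min(g)
    weakest <- ids[g <= gmin + 1e-15]
    pruned <- union(pruned, weakest)
    alphas <- c(alphas, gmin)
    pruned_sets <- c(pruned_sets, list(pruned))
    nl <- c(nl, n_leaves(tree, pruned))
  }
  keep <- !duplicated(round(alphas, 15), fromLast = TRUE)  # merge equal alphas
  structure(list(path = data.frame(alpha = alphas[keep],
                                   n_leaves = nl[keep]),
                 pruned_sets = pruned_sets[keep],
                 tree = tree),
            class = "pruning_path")
}

n_leaves_at <- function(tree, id, pruned = integer(0)) {
  if (tree_is_leaf(tree, id, pruned)) return(1L)
  n_leaves_at(tree, tree$nodes[[id]]$left, pruned) +
    n_leaves_at(tree, tree$nodes[[id]]$right, pruned)
}

route_rows <- function(tree, X, pruned = integer(0)) {
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    while (!tree_is_leaf(tree, id, pruned)) {
      node <- tree$nodes[[id]]
      id <- if (X[i, node$feature] <= node$threshold) node$left else node$right
    }
    tree$nodes[[id]]$pred
  }, character(1))
}

#' Predict behaviour with a CART
#'
#' Routes each row deterministically to a leaf (half-open convention: a value
#' exactly at a threshold follows the `<=` branch) and returns the leaf's
#' majority class; leaf ties are labelled `ACD`.
#'
#' @param tree a `cart_tree` (or the `$tree` element of [fit_cart()]).
#' @param newdata data.frame carrying every feature the tree splits on.
#' @return character vector of behaviour labels.
#' @export
predict_cart <- function(tree, newdata) {
  stopifnot(inherits(tree, "cart_tree"))
  used <- unique(stats::na.omit(vapply(tree$nodes, `[[`, character(1),
                                       "feature")))
  missing_feats <- setdiff(used, names(newdata))
  if (length(missing_feats) > 0) {
    stop("missing feature(s): ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  X <- if (length(used) > 0) {
    as.matrix(newdata[, used, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = nrow(newdata), ncol = 0)
  }
  route_rows(tree, X)
}

# materialize a pruned subtree: collapsed nodes become leaves
apply_pruning <- function(tree, pruned) {
  for (id in pruned) {
    tree$nodes[[id]]$feature <- NA_character_
    tree$nodes[[id]]$threshold <- NA_real_
    tree$nodes[[id]]$left <- NA_integer_
    tree$nodes[[id]]$right <- NA_integer_
  }
  tree
}

#' Fit a pruned CART behaviour classifier
#'
#' Splits the labelled rows 70:30 into training and test sets by random
#' sampling without replacement (unstratified), grows a Gini CART to purity
#' on the training set, computes the minimal cost-complexity pruning path,
#' evaluates every subtree on the held-out set, and returns the subtree at
#' the test-accuracy-maximizing alpha (ties prefer the larger alpha, i.e. the
#' smaller tree). Rows labelled `UNKNOWN` are excluded.
#'
#' @param cells data.frame with a `behaviour` column (`ACD`/`DIFF`) and
#'   numeric feature columns.
#' @param features character vector of feature column names; defaults to all
#'   numeric columns.
#' @param split_ratio training fraction (default 0.7).
#' @param seed integer seed for the train/test split.
#' @param min_leaf minimum rows per leaf.
#' @return list with `tree` (pruned `cart_tree`), `full_tree`, `path`
#'   (data.frame: alpha, n_leaves, train/test accuracy), `alpha`,
#'   `test_accuracy`, `train_index`, `features`.
#' @export
fit_cart <- function(cells, features = NULL, split_ratio = 0.7, seed = NULL,
                     min_leaf = 1L) {
  cells <- cells[cells$behaviour != "UNKNOWN", , drop = FALSE]
  if (nrow(cells) < 10L) stop("need >= 10 labelled rows", call. = FALSE)
  if (is.null(features)) {
    features <- names(cells)[vapply(cells, is.numeric, logical(1))]
  }
  if (length(features) == 0L) stop("no numeric features", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cells)
  train_idx <- sort(sample.int(n, size = round(split_ratio * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  X <- as.matrix(cells[, features, drop = FALSE])
  classes <- c("DIFF", "ACD")  # y01: 1 = ACD
  y01 <- as.integer(cells$behaviour == "ACD")

  tree <- grow_tree(X[train_idx, , drop = FALSE], y01[train_idx], classes,
                    min_leaf = min_leaf)
  pp <- cost_complexity_path(tree)
  acc <- function(idx, pruned) {
    if (length(idx) == 0L) return(NA_real_)
    pred <- route_rows(tree, X[idx, , drop = FALSE], pruned)
    mean(pred == ifelse(y01[idx] == 1L, "ACD", "DIFF"))
  }
  train_acc <- vapply(pp$pruned_sets, acc, numeric(1), idx = train_idx)
  test_acc <- vapply(pp$pruned_sets, acc, numeric(1), idx = test_idx)
  best <- max(test_acc)
  pick <- max(which(test_acc >= best - 1e-12))  # tie -> larger alpha
  pruned_tree <- apply_pruning(tree, pp$pruned_sets[[pick]])
  list(tree = pruned_tree,
       full_tree = tree,
       path = cbind(pp$path, train_accuracy = train_acc,
                    test_accuracy = test_acc),
       alpha = pp$path$alpha[pick],
       test_accuracy = test_acc[pick],
       train_index = train_idx,
       features = features)
}

#' Root split of a tree
#'
#' @param tree a `cart_tree`.
#' @return list with `feature` and `threshold` (`NA`s for a single-leaf
#'   tree).
#' @export
root_split <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  list(feature = tree$nodes[[1L]]$feature,
       threshold = tree$nodes[[1L]]$threshold)
}

#' Bagged-forest feature importances
#'
#' Fits `n_trees` Gini CARTs to bootstrap resamples of the labelled rows with
#' `ceiling(sqrt(d))` features drawn at random at each split. The importance
#' of a feature is the total sample-weighted Gini impurity decrease of all
#' splits made on it, summed over trees and normalized to sum to 1.
#'
#' @inheritParams fit_cart
#' @param n_trees number of trees (default 1000).
#' @param min_leaf minimum rows per leaf (default 5, a standard forest
#'   setting).
#' @return named numeric vector of importances summing to 1.
#' @export
forest_importances <- function(cells, features = NULL, n_trees = 1000,
                               seed = NULL, min_leaf = 5L) {
  cells <- cells[cells$behaviour != "UNKNOWN", , drop = FALSE]
  if (nrow(cells) < 10L) stop("need >= 10 labelled rows", call. = FALSE)
  if (is.null(features)) {
    features <- names(cells)[vapply(cells, is.numeric, logical(1))]
  }
  if (length(features) == 0L) stop("no numeric features", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(cells[, features, drop = FALSE])
  y01 <- as.integer(cells$behaviour == "ACD")
  n <- nrow(X)
  mtry <- max(1L, ceiling(sqrt(length(features))))
  imp <- stats::setNames(numeric(length(features)), features)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    Xb <- X[boot, , drop = FALSE]
    yb <- y01[boot]
    tree <- grow_tree(Xb, yb, c("DIFF", "ACD"), min_leaf = min_leaf,
                      sample_feats = function() sample(features, mtry))
    for (node in tree$nodes) {
      if (is.na(node$left)) next
      l <- tree$nodes[[node$left]]
      r <- tree$nodes[[node$right]]
      dec <- node$n / n * node$gini -
        (l$n / n * l$gini + r$n / n * r$gini)
      imp[node$feature] <- imp[node$feature] + dec
    }
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("<cart_tree> %d nodes, %d leaves, n = %d\n",
              length(x$nodes), n_leaves(x), x$n))
  invisible(x)
}
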
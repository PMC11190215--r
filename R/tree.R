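#' Decision-tree baseline configuration
#'
#' A C4.5-style univariate decision tree on flat threshold features: binary
#' splits at midpoints of consecutive distinct feature values, chosen to
#' maximize the gain ratio (information gain divided by split
#' information, in bits). Pruning is off by default.
#'
#' @param min_samples_leaf Minimum samples in each child (default 2).
#' @param max_depth Maximum tree depth (`Inf` = unlimited).
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(min_samples_leaf = 2L, max_depth = Inf) {
  stopifnot(min_samples_leaf >= 1, max_depth >= 1)
  cfg <- list(min_samples_leaf = as.integer(min_samples_leaf),
              max_depth = max_depth)
  class(cfg) <- "tree_config"
  cfg
}

#' Flatten audiograms to the 12-dimensional tree feature vector
#'
#' Seven air thresholds followed by five bone thresholds. Unmeasured bone
#' values are replaced by the paired air threshold (an air-bone gap of
#' zero); an unmeasured 125 Hz air threshold is carried forward from
#' 250 Hz. Documented sentinel choices, not imputation of clinical values.
#'
#' @param set An audiogram set.
#' @return An n x 12 numeric matrix.
#' @export
flatten_features <- function(set) {
  ac <- threshold_matrix(set, "air")
  bc <- threshold_matrix(set, "bone")
  ac[is.na(ac[, 1]), 1] <- ac[is.na(ac[, 1]), 2]
  air_at_bone <- ac[, as.character(frequency_grid()$bone), drop = FALSE]
  bc[is.na(bc)] <- air_at_bone[is.na(bc)]
  m <- cbind(ac, bc)
  colnames(m) <- c(ac_cols(), bc_cols())
  m
}

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Best gain-ratio split for one node. Returns NULL if no admissible split.
best_split <- function(x, y_idx, K, min_leaf) {
  n <- length(y_idx)
  total <- tabulate(y_idx, K)
  H_parent <- entropy_bits(total)
  if (H_parent == 0) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    xv <- x[, j]
    ord <- order(xv)
    xs <- xv[ord]; ys <- y_idx[ord]
    ind <- matrix(0L, n, K); ind[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(ind, 2, cumsum)
    if (n == 1L) next
    cut_pos <- which(diff(xs) > 0)               # split between i and i+1
    cut_pos <- cut_pos[cut_pos >= min_leaf & (n - cut_pos) >= min_leaf]
    if (!length(cut_pos)) next
    for (i in cut_pos) {
      left <- cum[i, ]; right <- total - left
      nl <- i; nr <- n - i
      H_split <- (nl * entropy_bits(left) + nr * entropy_bits(right)) / n
      gain <- H_parent - H_split
      if (gain <= 1e-12) next
      pl <- nl / n
      split_info <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
      gr <- gain / split_info
      if (is.null(best) || gr > best$gain_ratio) {
        best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2,
                     gain = gain, gain_ratio = gr, split_info = split_info)
      }
    }
  }
  best
}

grow_tree <- function(x, y_idx, K, cfg, depth) {
  counts <- tabulate(y_idx, K)
  leaf <- function() list(type = "leaf",
                          class = which.max(counts),  # ties: first class
                          counts = counts,
                          proba = counts / sum(counts))
  if (length(unique(y_idx)) == 1L || depth >= cfg$max_depth)
    return(leaf())
  sp <- best_split(x, y_idx, K, cfg$min_samples_leaf)
  if (is.null(sp)) return(leaf())
  go_left <- x[, sp$feature] <= sp$threshold
  list(type = "node", feature = sp$feature, threshold = sp$threshold,
       gain = sp$gain, gain_ratio = sp$gain_ratio,
       left = grow_tree(x[go_left, , drop = FALSE], y_idx[go_left], K,
                        cfg, depth + 1),
       right = grow_tree(x[!go_left, , drop = FALSE], y_idx[!go_left], K,
                         cfg, depth + 1))
}

#' Train the gain-ratio decision-tree baseline
#'
#' Top-down induction on the flat 12-dimensional threshold features,
#' maximizing gain ratio at every node; leaves predict the majority class
#' (ties resolve to the first class in fixed order). Deterministic given
#' the data.
#'
#' @param features An n x p numeric matrix, e.g. from
#'   [flatten_features()].
#' @param labels Clinical class labels parallel to the rows.
#' @param cfg A [tree_config()].
#' @return A list of class `audiotype_tree`.
#' @export
train_tree_baseline <- function(features, labels, cfg = tree_config()) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite")
  y_idx <- labels_to_index(labels)
  if (nrow(features) != length(y_idx))
    stop("features and labels must have equal length")
  if (nrow(features) < 1L) stop("need at least 1 training sample")
  root <- grow_tree(features, y_idx, 4L, cfg, depth = 0)
  out <- list(root = root, config = cfg,
              classes = hearing_loss_levels(clinical_only = TRUE),
              n_features = ncol(features))
  class(out) <- "audiotype_tree"
  out
}

tree_apply <- function(node, x, idx, out) {
  if (node$type == "leaf") {
    out[idx, ] <- matrix(node$proba, length(idx), length(node$proba),
                         byrow = TRUE)
    return(out)
  }
  go_left <- x[idx, node$feature] <= node$threshold
  if (any(go_left)) out <- tree_apply(node$left, x, idx[go_left], out)
  if (any(!go_left)) out <- tree_apply(node$right, x, idx[!go_left], out)
  out
}

#' Tree class-probability predictions (leaf class proportions)
#'
#' @param model An `audiotype_tree`.
#' @param features Feature matrix with the training layout.
#' @return n x 4 matrix of leaf-frequency probabilities.
#' @export
predict_tree_proba <- function(model, features) {
  stopifnot(inherits(model, "audiotype_tree"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("feature count mismatch")
  P <- matrix(0, nrow(features), 4, dimnames = list(NULL, model$classes))
  if (nrow(features) == 0L) return(P)
  tree_apply(model$root, features, seq_len(nrow(features)), P)
}

#' Tree hard-label predictions
#'
#' @inheritParams predict_tree_proba
#' @return Factor of predicted labels; ties go to the earlier class.
#' @export
predict_tree_label <- function(model, features) {
  proba_to_label(predict_tree_proba(model, features))
}
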
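#' Encode audiograms as fixed-length feature sequences
#'
#' Each record becomes a 7-step sequence ordered by the air frequency grid
#' (125 ... 8000 Hz), with two features per step: the air and bone
#' thresholds at that frequency. Bone conduction is never measured at 125
#' or 8000 Hz and optionally at 250 Hz, so each step carries a
#' bone-present flag; absent bone values stay `NA` here and are filled with
#' the channel centre only after normalization.
#'
#' @param set A complete (QC-passing) audiogram set.
#' @return A list of class `feature_sequences`: `air` (n x 7 matrix),
#'   `bone` (n x 7 matrix with `NA` where unmeasured), `bone_present`
#'   (n x 7 logical), `freqs` (the air grid).
#' @export
encode_sequences <- function(set) {
  if (!all(is_complete(set)))
    stop("encode_sequences requires complete audiograms; record ",
         which(!is_complete(set))[1], " is incomplete")
  grid <- frequency_grid()
  ac <- threshold_matrix(set, "air")
  bc5 <- threshold_matrix(set, "bone")
  bone <- matrix(NA_real_, nrow(ac), 7,
                 dimnames = list(NULL, colnames(ac)))
  bone[, as.character(grid$bone)] <- bc5
  out <- list(air = ac, bone = bone, bone_present = !is.na(bone),
              freqs = grid$air)
  class(out) <- "feature_sequences"
  out
}

#' Fit a feature normalizer on training sequences
#'
#' Statistics are computed per channel (air, bone) over the observed values
#' only, pooled across all time steps, and always from training data alone.
#' Four schemes are supported:
#' \describe{
#'   \item{zscore}{(x - mean) / sd, population (ddof = 0) sd; the
#'     transformed training channel has mean 0 and sd 1.}
#'   \item{minmax}{(x - min) / (max - min), linear rescaling to `[0, 1]`.}
#'   \item{robust}{(x - median) / IQR with linear-interpolation quantiles.}
#'   \item{maxabs}{x / max(|x|), preserving sign and sparsity.}
#' }
#'
#' @param train A `feature_sequences` object (training fold only).
#' @param method One of `"zscore"`, `"minmax"`, `"robust"`, `"maxabs"`.
#' @param pooled If `TRUE`, estimate one set of statistics over both
#'   channels combined instead of per channel.
#' @return A list of class `normalizer` with the method and per-channel
#'   centre/scale.
#' @export
fit_normalizer <- function(train,
                           method = c("zscore", "minmax", "robust", "maxabs"),
                           pooled = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(train, "feature_sequences"))
  if (nrow(train$air) < 2L)
    stop("need at least 2 training sequences to fit a normalizer")
  chan_stats <- function(x) {
    x <- x[!is.na(x)]
    cs <- switch(method,
      zscore = {
        mu <- mean(x)
        sdp <- sqrt(mean((x - mu)^2))     # population sd
        c(center = mu, scale = sdp)
      },
      minmax = c(center = min(x), scale = max(x) - min(x)),
      robust = {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        c(center = q[2], scale = q[3] - q[1])
      },
      maxabs = c(center = 0, scale = max(abs(x)))
    )
    if (cs[["scale"]] == 0)
      stop("degenerate channel: ", method, " scale statistic is zero")
    cs
  }
  if (pooled) {
    s <- chan_stats(c(train$air, train$bone))
    params <- list(air = s, bone = s)
  } else {
    params <- list(air = chan_stats(train$air), bone = chan_stats(train$bone))
  }
  out <- list(method = method, pooled = pooled, params = params)
  class(out) <- "normalizer"
  out
}

#' Apply a fitted normalizer to sequences
#'
#' Observed values are transformed with the training-fold statistics;
#' absent bone values are then filled with 0, the channel centre after any
#' of the four transforms (exactly the mean for z-score). The bone-present
#' flags are preserved and can serve as an optional third input channel.
#'
#' @param norm A fitted [fit_normalizer()] object.
#' @param seqs A `feature_sequences` object.
#' @return A list of class `encoded_sequences`: `x` an n x 7 x 2 array
#'   (channels air, bone; no `NA`s), `bone_present` the flag matrix.
#' @export
apply_normalizer <- function(norm, seqs) {
  stopifnot(inherits(norm, "normalizer"),
            inherits(seqs, "feature_sequences"))
  tf <- function(x, p) (x - p[["center"]]) / p[["scale"]]
  air <- tf(seqs$air, norm$params$air)
  bone <- tf(seqs$bone, norm$params$bone)
  # unmeasured thresholds (optional 125 Hz air; 125/8000 and optional
  # 250 Hz bone) take the post-transform channel centre
  air[is.na(air)] <- 0
  bone[is.na(bone)] <- 0
  n <- nrow(air)
  x <- array(0, dim = c(n, 7, 2), dimnames = list(NULL, colnames(seqs$air),
                                                  c("air", "bone")))
  x[, , 1] <- air
  x[, , 2] <- bone
  out <- list(x = x, bone_present = seqs$bone_present, method = norm$method)
  class(out) <- "encoded_sequences"
  out
}

#' Balanced class weights for imbalance correction
#'
#' The standard balanced heuristic w_c = N / (K * n_c), where N is the
#' total sample count, K the number of classes and n_c the count of class
#' c. Minority classes receive proportionally larger weights and
#' sum(n_c * w_c) = N.
#'
#' @param labels Character or factor labels, each one of the four clinical
#'   classes; every class must be represented.
#' @return Named numeric vector of weights in fixed class order.
#' @examples
#' compute_class_weights(rep(c("normal", "conductive", "mixed",
#'                             "sensorineural"), c(2584, 657, 4028, 7777)))
#' @export
compute_class_weights <- function(labels) {
  lv <- hearing_loss_levels(clinical_only = TRUE)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), lv)
  if (length(bad))
    stop("labels outside the clinical classes: ", paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = lv))
  if (any(counts == 0))
    stop("empty class: ", paste(names(counts)[counts == 0], collapse = ", "))
  n <- length(labels)
  w <- n / (length(lv) * as.numeric(counts))
  names(w) <- lv
  w
}
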
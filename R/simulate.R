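#' Synthetic audiogram generator configuration
#'
#' Defaults emulate the class make-up of a large clinical audiometry
#' archive: 17.17% normal, 4.37% conductive, 26.71% mixed and 51.69%
#' sensorineural. Audiograms are drawn from a parametric curve family --
#' a per-class base level plus a per-octave slope and per-frequency jitter
#' defines the bone-level curve, and the air curve sits above it by a
#' class-specific air-bone gap -- then accepted only if they pass every
#' validity check and the rule engine returns exactly the intended class
#' (rejection sampling against the labelling oracle).
#'
#' @param n Number of audiograms to generate.
#' @param class_proportions Named or ordered probabilities for
#'   (normal, conductive, mixed, sensorineural); must sum to 1.
#' @param seed Integer seed; the generator owns its random stream and never
#'   perturbs the caller's.
#' @param quantize_step Threshold quantization in dB (default 5, matching
#'   clinical audiometer steps; set to 1 for boundary stress tests).
#' @param p_ac125 Probability that the optional 125 Hz air threshold is
#'   recorded (default 0.9).
#' @param p_bc250 Probability that the optional 250 Hz bone threshold is
#'   recorded, where its level permits (default 0.5).
#' @param base_range Named list of per-class base-level ranges (dB HL) for
#'   the bone-level curve.
#' @param slope_range Named list of per-class slope ranges (dB per octave).
#' @param jitter_sd Per-frequency jitter standard deviation in dB.
#' @param gap_range Air-bone gap range (dB) for the gap-present classes
#'   (conductive, mixed).
#' @param small_gap_max Maximum incidental gap (dB) for the gap-absent
#'   classes (normal, sensorineural); kept below the 10 dB presence
#'   criterion.
#' @param max_attempts Maximum candidate draws per accepted audiogram
#'   before generation aborts with an error.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 1000L,
                             class_proportions = c(normal = 0.1717,
                                                   conductive = 0.0437,
                                                   mixed = 0.2671,
                                                   sensorineural = 0.5169),
                             seed = 1L,
                             quantize_step = 5,
                             p_ac125 = 0.9,
                             p_bc250 = 0.5,
                             base_range = list(normal = c(-5, 12),
                                               conductive = c(-5, 12),
                                               mixed = c(25, 50),
                                               sensorineural = c(25, 55)),
                             slope_range = list(normal = c(-1.5, 1.5),
                                                conductive = c(-1.5, 1.5),
                                                mixed = c(-1, 2),
                                                sensorineural = c(0, 2)),
                             jitter_sd = 2,
                             gap_range = c(15, 40),
                             small_gap_max = 9,
                             max_attempts = 1000L) {
  p <- as.numeric(class_proportions)
  if (length(p) != 4L || any(p < 0))
    stop("class_proportions must be 4 nonnegative probabilities")
  # printed percentage tables carry rounding error (e.g. 99.94% totals);
  # accept within 1e-3 and renormalize exactly
  if (abs(sum(p) - 1) > 1e-3)
    stop("class_proportions must sum to 1 (got ", sum(p), ")")
  p <- p / sum(p)
  names(p) <- hearing_loss_levels(clinical_only = TRUE)
  stopifnot(n >= 0, quantize_step > 0, max_attempts >= 1,
            small_gap_max < 10)
  cfg <- list(n = as.integer(n), class_proportions = p,
              seed = as.integer(seed), quantize_step = quantize_step,
              p_ac125 = p_ac125, p_bc250 = p_bc250,
              base_range = base_range, slope_range = slope_range,
              jitter_sd = jitter_sd, gap_range = gap_range,
              small_gap_max = small_gap_max,
              max_attempts = as.integer(max_attempts))
  class(cfg) <- "generator_config"
  cfg
}

# Run code under a private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

quantize <- function(x, step) round(x / step) * step

# Draw m candidate audiograms of one target class (unvalidated).
draw_candidates <- function(m, target, cfg) {
  grid <- frequency_grid()
  oct_idx <- 0:6                       # octave index over the air grid
  base <- stats::runif(m, cfg$base_range[[target]][1],
                       cfg$base_range[[target]][2])
  slope <- stats::runif(m, cfg$slope_range[[target]][1],
                        cfg$slope_range[[target]][2])
  jit <- matrix(stats::rnorm(m * 7, 0, cfg$jitter_sd), m, 7)
  L <- outer(base, rep(1, 7)) + outer(slope, oct_idx) + jit
  L <- quantize(L, cfg$quantize_step)
  # bone-level curve must stay in audiometer bone range at 250-4000 Hz
  L[, 2:6] <- pmin(pmax(L[, 2:6], -10), 60)
  L[, c(1, 7)] <- pmin(pmax(L[, c(1, 7)], -10), 110)

  if (target %in% c("conductive", "mixed")) {
    gap_base <- stats::runif(m, cfg$gap_range[1], cfg$gap_range[2])
    gap <- outer(gap_base, rep(1, 7)) + matrix(stats::runif(m * 7, -5, 5), m, 7)
    gap <- pmin(pmax(quantize(gap, cfg$quantize_step), 10), 45)
  } else {
    gap <- matrix(quantize(stats::runif(m * 7, 0, cfg$small_gap_max),
                           cfg$quantize_step), m, 7)
    # largest representable gap strictly below the 10 dB presence criterion
    gap_cap <- cfg$quantize_step * floor((10 - 1e-9) / cfg$quantize_step)
    gap <- pmin(gap, min(gap_cap, cfg$small_gap_max))
  }
  ac <- L + gap
  ac[, 1:2] <- pmin(pmax(ac[, 1:2], -10), 90)   # <= 250 Hz limit
  ac[, 3:7] <- pmin(pmax(ac[, 3:7], -10), 110)

  bc <- L[, 2:6]
  # optional thresholds
  drop125 <- stats::runif(m) >= cfg$p_ac125
  ac[drop125, 1] <- NA
  keep250 <- stats::runif(m) < cfg$p_bc250 & bc[, 1] <= 40
  bc[!keep250, 1] <- NA
  list(ac = ac, bc = bc)
}

# Vectorized rejection sampling: n accepted audiograms of one class.
generate_class <- function(n, target, cfg, qc = qc_config(),
                           rules = rule_config()) {
  if (n == 0L)
    return(list(ac = matrix(numeric(), 0, 7), bc = matrix(numeric(), 0, 5)))
  acc_ac <- matrix(NA_real_, n, 7)
  acc_bc <- matrix(NA_real_, n, 5)
  got <- 0L
  drawn <- 0L
  while (got < n) {
    m <- max(64L, ceiling((n - got) * 1.6))
    if (drawn + m > n * cfg$max_attempts)
      m <- n * cfg$max_attempts - drawn
    if (m <= 0L)
      stop(sprintf(
        "generation failed for class '%s': %d attempts yielded %d/%d valid audiograms",
        target, drawn, got, n))
    cand <- draw_candidates(m, target, cfg)
    drawn <- drawn + m
    ok <- qc_valid_matrix(cand$ac, cand$bc, qc)
    if (any(ok)) {
      sub <- candidate_set(cand$ac[ok, , drop = FALSE],
                           cand$bc[ok, , drop = FALSE])
      ok2 <- as.character(classify_audiograms(sub, rules)) == target
      take <- which(ok)[ok2]
      take <- take[seq_len(min(length(take), n - got))]
      if (length(take)) {
        idx <- got + seq_along(take)
        acc_ac[idx, ] <- cand$ac[take, , drop = FALSE]
        acc_bc[idx, ] <- cand$bc[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
  }
  list(ac = acc_ac, bc = acc_bc)
}

candidate_set <- function(ac, bc) {
  n <- nrow(ac)
  audiogram_set(subject_id = sprintf("tmp%06d", seq_len(n)),
                ear = rep("left", n), ac = ac, bc = bc)
}

#' Sample one audiogram of a target class
#'
#' Rejection-samples the parametric curve family until the validity checks
#' pass and the rule engine returns exactly `target`.
#'
#' @param target One of the four clinical classes.
#' @param cfg A [generator_config()]; `cfg$seed` drives the draw.
#' @return A one-row labelled `audiogram_set`.
#' @export
sample_audiogram <- function(target = hearing_loss_levels(TRUE),
                             cfg = generator_config()) {
  target <- match.arg(target)
  with_private_seed(cfg$seed, {
    r <- generate_class(1L, target, cfg)
    audiogram_set(subject_id = "synthetic-1", ear = "left",
                  ac = r$ac, bc = r$bc, label = target)
  })
}

#' Generate a labelled synthetic audiogram dataset
#'
#' Class membership is drawn from `cfg$class_proportions` (seeded
#' multinomial); each record is then rejection-sampled so that it passes
#' every validity check and the rule engine reproduces its label exactly.
#' Fully reproducible from `cfg$seed`; the caller's random state is left
#' untouched.
#'
#' @param cfg A [generator_config()].
#' @return A labelled `audiogram_set` with `cfg$n` rows. Subjects are
#'   synthetic (`syn-000001`, ...), ears alternate left/right.
#' @examples
#' d <- generate_audiograms(generator_config(n = 50, seed = 7))
#' table(d$label)
#' @export
generate_audiograms <- function(cfg = generator_config()) {
  lv <- hearing_loss_levels(clinical_only = TRUE)
  if (cfg$n == 0L) {
    empty <- audiogram_set(character(), character(),
                           matrix(numeric(), 0, 7), matrix(numeric(), 0, 5),
                           label = character())
    return(empty)
  }
  with_private_seed(cfg$seed, {
    classes <- sample(lv, cfg$n, replace = TRUE,
                      prob = cfg$class_proportions)
    ac <- matrix(NA_real_, cfg$n, 7)
    bc <- matrix(NA_real_, cfg$n, 5)
    for (cl in lv) {
      idx <- which(classes == cl)
      if (!length(idx)) next
      r <- generate_class(length(idx), cl, cfg)
      ac[idx, ] <- r$ac
      bc[idx, ] <- r$bc
    }
    audiogram_set(
      subject_id = sprintf("syn-%06d", seq_len(cfg$n)),
      ear = rep(c("left", "right"), length.out = cfg$n),
      ac = ac, bc = bc, label = classes)
  })
}
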
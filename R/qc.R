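#' Audiogram validity screening configuration
#'
#' Encodes the inclusion rules applied to every audiometry record before
#' labelling, after Margolis and Saly. Two clauses of the published rules
#' are ambiguous and are therefore configurable:
#' \itemize{
#'   \item the reduced air/bone maxima ("when the limit is 90/40 dB HL")
#'     apply by default at frequencies at or below 250 Hz, where audiometer
#'     output limits are lower (`low_freq_strict = TRUE`); setting it to
#'     `FALSE` applies them above 250 Hz instead;
#'   \item the adjacent-octave step rule is by default symmetric,
#'     `step_lo <= AC(f) - AC(f_lower) <= step_hi` with bounds
#'     (-30, 30) dB inclusive; a literal one-sided (0, 30) reading would
#'     reject every rising (improving) audiogram.
#' }
#'
#' @param air_min,air_max Air-conduction range in dB HL (default -10, 110).
#' @param air_max_low Air maximum at the strict low frequencies (default 90).
#' @param bone_min,bone_max Bone-conduction range (default -10, 60).
#' @param bone_max_low Bone maximum at the strict low frequencies (default 40).
#' @param step_lo,step_hi Inclusive bounds on the signed adjacent-octave air
#'   difference AC(f) - AC(f_lower) (default -30, 30).
#' @param gap_lo,gap_hi Inclusive bounds on the signed air-bone difference
#'   AC(f) - BC(f) (default -10, 50).
#' @param low_freq_strict Apply the reduced maxima at f <= 250 Hz (default)
#'   rather than f > 250 Hz.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(air_min = -10, air_max = 110, air_max_low = 90,
                      bone_min = -10, bone_max = 60, bone_max_low = 40,
                      step_lo = -30, step_hi = 30,
                      gap_lo = -10, gap_hi = 50,
                      low_freq_strict = TRUE) {
  cfg <- list(air_min = air_min, air_max = air_max, air_max_low = air_max_low,
              bone_min = bone_min, bone_max = bone_max,
              bone_max_low = bone_max_low,
              step_lo = step_lo, step_hi = step_hi,
              gap_lo = gap_lo, gap_hi = gap_hi,
              low_freq_strict = isTRUE(low_freq_strict))
  stopifnot(cfg$air_min < cfg$air_max, cfg$bone_min < cfg$bone_max,
            cfg$step_lo <= cfg$step_hi, cfg$gap_lo <= cfg$gap_hi)
  class(cfg) <- "qc_config"
  cfg
}

reason <- function(code, conduction, freq, value, extra = NA_real_) {
  data.frame(code = code, conduction = conduction, freq = freq,
             value = value, extra = extra, stringsAsFactors = FALSE)
}

no_reasons <- function() {
  data.frame(code = character(), conduction = character(), freq = integer(),
             value = numeric(), extra = numeric(), stringsAsFactors = FALSE)
}

qc_row <- function(set, i) {
  list(ac = threshold_matrix(set, "air")[i, ],
       bc = threshold_matrix(set, "bone")[i, ])
}

#' Completeness check
#'
#' Requires air thresholds at the six octaves 250--8000 Hz and bone
#' thresholds at 500--4000 Hz; 125 Hz air and 250 Hz bone are optional.
#' Reports one `missing_frequency` reason per absent required threshold.
#'
#' @param set An audiogram set.
#' @param i Row index of the record to check.
#' @return A data frame of rejection reasons (zero rows when the record
#'   passes) with columns `code`, `conduction`, `freq`, `value`, `extra`.
#' @export
check_completeness <- function(set, i) {
  r <- qc_row(set, i)
  out <- no_reasons()
  for (f in c(250, 500, 1000, 2000, 4000, 8000))
    if (is.na(r$ac[as.character(f)]))
      out <- rbind(out, reason("missing_frequency", "air", f, NA_real_))
  for (f in c(500, 1000, 2000, 4000))
    if (is.na(r$bc[as.character(f)]))
      out <- rbind(out, reason("missing_frequency", "bone", f, NA_real_))
  out
}

#' Air-conduction range check
#'
#' Flags air thresholds outside -10 to 110 dB HL, with the stricter
#' 90 dB HL maximum at the low frequencies (see [qc_config()]).
#'
#' @inheritParams check_completeness
#' @param cfg A [qc_config()].
#' @return Rejection-reason data frame (`air_out_of_range` rows).
#' @export
check_air_range <- function(set, i, cfg = qc_config()) {
  r <- qc_row(set, i)
  out <- no_reasons()
  freqs <- frequency_grid()$air
  for (j in seq_along(freqs)) {
    v <- r$ac[j]
    if (is.na(v)) next
    strict <- if (cfg$low_freq_strict) freqs[j] <= 250 else freqs[j] > 250
    hi <- if (strict) cfg$air_max_low else cfg$air_max
    if (v < cfg$air_min || v > hi)
      out <- rbind(out, reason("air_out_of_range", "air", freqs[j], v))
  }
  out
}

#' Adjacent-octave air step check
#'
#' Flags any adjacent pair of measured air thresholds whose signed
#' difference AC(f) - AC(f_lower) falls outside the configured bounds
#' (default |difference| <= 30 dB, inclusive).
#'
#' @inheritParams check_air_range
#' @return Rejection-reason data frame (`air_step_violation` rows; `value`
#'   holds AC(f), `extra` holds AC(f_lower)).
#' @export
check_air_steps <- function(set, i, cfg = qc_config()) {
  r <- qc_row(set, i)
  out <- no_reasons()
  freqs <- frequency_grid()$air
  present <- which(!is.na(r$ac))
  if (length(present) < 2L) return(out)
  for (k in seq_len(length(present) - 1L)) {
    a <- present[k]; b <- present[k + 1L]
    if (b != a + 1L) next  # only adjacent grid octaves
    d <- r$ac[b] - r$ac[a]
    if (d < cfg$step_lo || d > cfg$step_hi)
      out <- rbind(out, reason("air_step_violation", "air", freqs[b],
                               r$ac[b], r$ac[a]))
  }
  out
}

#' Bone-conduction range check
#'
#' Flags bone thresholds outside -10 to 60 dB HL, with the stricter
#' 40 dB HL maximum at 250 Hz (see [qc_config()]).
#'
#' @inheritParams check_air_range
#' @return Rejection-reason data frame (`bone_out_of_range` rows).
#' @export
check_bone_range <- function(set, i, cfg = qc_config()) {
  r <- qc_row(set, i)
  out <- no_reasons()
  freqs <- frequency_grid()$bone
  for (j in seq_along(freqs)) {
    v <- r$bc[j]
    if (is.na(v)) next
    strict <- if (cfg$low_freq_strict) freqs[j] <= 250 else freqs[j] > 250
    hi <- if (strict) cfg$bone_max_low else cfg$bone_max
    if (v < cfg$bone_min || v > hi)
      out <- rbind(out, reason("bone_out_of_range", "bone", freqs[j], v))
  }
  out
}

#' Air-bone relation check
#'
#' At every frequency where both conductions were measured, the signed gap
#' g = AC(f) - BC(f) must satisfy -10 <= g <= 50 dB (inclusive): bone may
#' not exceed air by more than 10 dB, and the air-bone gap may not exceed
#' 50 dB.
#'
#' @inheritParams check_air_range
#' @return Rejection-reason data frame (`air_bone_relation` rows; `value`
#'   holds the signed gap).
#' @export
check_air_bone_relation <- function(set, i, cfg = qc_config()) {
  r <- qc_row(set, i)
  out <- no_reasons()
  freqs <- frequency_grid()$bone
  air_at <- r$ac[as.character(freqs)]
  for (j in seq_along(freqs)) {
    if (is.na(r$bc[j]) || is.na(air_at[j])) next
    g <- air_at[j] - r$bc[j]
    if (g < cfg$gap_lo || g > cfg$gap_hi)
      out <- rbind(out, reason("air_bone_relation", "bone", freqs[j], g))
  }
  out
}

# Vectorized validity predicate over precomputed threshold matrices.
# Mirrors the five per-record checks exactly; used by apply_qc and by the
# synthetic generator's rejection loop, where per-record reason reporting
# would be wasteful.
qc_valid_matrix <- function(ac, bc, cfg = qc_config()) {
  airf <- frequency_grid()$air
  bonef <- frequency_grid()$bone
  n <- nrow(ac)
  ok <- rep(TRUE, n)

  req_air <- match(c(250, 500, 1000, 2000, 4000, 8000), airf)
  req_bone <- match(c(500, 1000, 2000, 4000), bonef)
  ok <- ok & rowSums(is.na(ac[, req_air, drop = FALSE])) == 0 &
    rowSums(is.na(bc[, req_bone, drop = FALSE])) == 0

  strict_air <- if (cfg$low_freq_strict) airf <= 250 else airf > 250
  hi_air <- ifelse(strict_air, cfg$air_max_low, cfg$air_max)
  bad <- sweep(ac, 2, hi_air, ">") | ac < cfg$air_min
  ok <- ok & rowSums(bad, na.rm = TRUE) == 0

  for (j in 2:length(airf)) {
    d <- ac[, j] - ac[, j - 1L]
    bad <- !is.na(d) & (d < cfg$step_lo | d > cfg$step_hi)
    ok <- ok & !bad
  }

  strict_bone <- if (cfg$low_freq_strict) bonef <= 250 else bonef > 250
  hi_bone <- ifelse(strict_bone, cfg$bone_max_low, cfg$bone_max)
  bad <- sweep(bc, 2, hi_bone, ">") | bc < cfg$bone_min
  ok <- ok & rowSums(bad, na.rm = TRUE) == 0

  g <- ac[, match(bonef, airf), drop = FALSE] - bc
  bad <- !is.na(g) & (g < cfg$gap_lo | g > cfg$gap_hi)
  ok <- ok & rowSums(bad) == 0
  ok
}

qc_reasons_for <- function(set, i, cfg) {
  rbind(no_reasons(),
        check_completeness(set, i),
        check_air_range(set, i, cfg),
        check_air_steps(set, i, cfg),
        check_bone_range(set, i, cfg),
        check_air_bone_relation(set, i, cfg))
}

#' Apply all validity checks to an audiogram set
#'
#' A record is kept iff all five checks (completeness, air range, air
#' adjacent-octave steps, bone range, air-bone relation) report no reason.
#' QC is a pure filter: records are never modified and input order is
#' preserved among the kept records.
#'
#' @param set An audiogram set.
#' @param cfg A [qc_config()].
#' @return A list of class `qc_report`: `kept` (audiogram set),
#'   `rejected` (audiogram set of the rejected records), `reasons` (list of
#'   reason data frames parallel to `rejected`), `counts` (named integer
#'   vector of reason-code totals), `n_input`.
#' @export
apply_qc <- function(set, cfg = qc_config()) {
  set <- as_audiogram_set(as.data.frame(set))
  n <- nrow(set)
  keep <- qc_valid_matrix(threshold_matrix(set, "air"),
                          threshold_matrix(set, "bone"), cfg)
  reasons <- lapply(which(!keep), function(i) qc_reasons_for(set, i, cfg))
  codes <- c("missing_frequency", "air_out_of_range", "air_step_violation",
             "bone_out_of_range", "air_bone_relation")
  all_codes <- unlist(lapply(reasons, function(r) unique(r$code)))
  counts <- vapply(codes, function(cd) sum(all_codes == cd), integer(1))
  out <- list(kept = set[keep, , drop = FALSE],
              rejected = set[!keep, , drop = FALSE],
              reasons = reasons,
              counts = counts,
              n_input = n)
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Audiogram QC report: %d input, %d kept, %d rejected\n",
              x$n_input, nrow(x$kept), nrow(x$rejected)))
  for (cd in names(x$counts))
    if (x$counts[[cd]] > 0)
      cat(sprintf("  %-20s %d record(s)\n", cd, x$counts[[cd]]))
  invisible(x)
}
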
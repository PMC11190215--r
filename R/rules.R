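#' Diagnostic rule configuration
#'
#' Parameters of the four-class decision rules. Normal hearing follows the
#' WHO criterion: PTA4 (mean threshold at 500, 1000, 2000 and 4000 Hz)
#' below 20 dB HL. An air-bone gap is "present" when AC - BC reaches
#' 10 dB at three or more of the four PTA frequencies, or 15 dB at any
#' single one; both bounds inclusive. High-frequency means back the
#' sensorineural decision: air over 4000 and 8000 Hz, bone over the grid
#' frequencies within 4--6 kHz, i.e. 4000 Hz only, since bone conduction is
#' never measured above 4 kHz.
#'
#' @param pta_cutoff PTA4 hearing-loss cutoff in dB HL (default 20,
#'   loss when mean >= cutoff).
#' @param gap_multi_threshold Gap size counting toward the multi-frequency
#'   presence criterion (default 10 dB).
#' @param gap_multi_min_count Minimum number of frequencies at or above
#'   `gap_multi_threshold` (default 3).
#' @param gap_single_threshold Single-frequency gap presence criterion
#'   (default 15 dB).
#' @param gap_freqs Frequencies over which gaps are evaluated
#'   (default 500--4000 Hz).
#' @param air_hf_freqs Air high-frequency criterion frequencies
#'   (default 4000, 8000 Hz).
#' @param bone_hf_freqs Bone high-frequency criterion frequencies
#'   (default 4000 Hz).
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(pta_cutoff = 20,
                        gap_multi_threshold = 10, gap_multi_min_count = 3,
                        gap_single_threshold = 15,
                        gap_freqs = c(500, 1000, 2000, 4000),
                        air_hf_freqs = c(4000, 8000),
                        bone_hf_freqs = 4000) {
  stopifnot(gap_single_threshold >= gap_multi_threshold,
            gap_multi_threshold > 0,
            gap_multi_min_count <= length(gap_freqs))
  cfg <- list(pta_cutoff = pta_cutoff,
              gap_multi_threshold = gap_multi_threshold,
              gap_multi_min_count = gap_multi_min_count,
              gap_single_threshold = gap_single_threshold,
              gap_freqs = gap_freqs,
              air_hf_freqs = air_hf_freqs,
              bone_hf_freqs = bone_hf_freqs)
  class(cfg) <- "rule_config"
  cfg
}

#' Mean threshold over selected frequencies
#'
#' Unrounded arithmetic mean of the stored thresholds; every requested
#' frequency must have been measured.
#'
#' @param set An audiogram set.
#' @param conduction `"air"` or `"bone"`.
#' @param freqs Frequencies in Hz, all on the conduction's grid.
#' @return Numeric vector, one mean per record (dB HL).
#' @export
mean_threshold <- function(set, conduction = c("air", "bone"),
                           freqs = c(500, 1000, 2000, 4000)) {
  conduction <- match.arg(conduction)
  m <- threshold_matrix(set, conduction)
  miss <- setdiff(as.character(freqs), colnames(m))
  if (length(miss))
    stop(sprintf("frequency %s Hz not on the %s grid",
                 paste(miss, collapse = ", "), conduction))
  sub <- m[, as.character(freqs), drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(is.na(sub), arr.ind = TRUE)
    stop(sprintf("record %d lacks %s threshold at %s Hz",
                 bad[1, 1], conduction, colnames(sub)[bad[1, 2]]))
  }
  rowMeans(sub)
}

#' Air-bone gap profiles
#'
#' For every record, the signed per-frequency difference AC - BC over the
#' gap frequencies, plus the presence flag: a gap is present when at least
#' `gap_multi_min_count` gaps reach `gap_multi_threshold`, or any single
#' gap reaches `gap_single_threshold` (bounds inclusive). Negative gaps
#' (bone worse than air, within QC tolerance) never count toward presence.
#'
#' @param set An audiogram set.
#' @param cfg A [rule_config()].
#' @return A list with `gaps` (records x frequencies matrix) and `present`
#'   (logical vector).
#' @export
air_bone_gaps <- function(set, cfg = rule_config()) {
  fs <- as.character(cfg$gap_freqs)
  ac <- threshold_matrix(set, "air")[, fs, drop = FALSE]
  bc <- threshold_matrix(set, "bone")[, fs, drop = FALSE]
  if (anyNA(ac) || anyNA(bc))
    stop("air and bone thresholds must be present at all gap frequencies")
  g <- ac - bc
  present <- rowSums(g >= cfg$gap_multi_threshold) >= cfg$gap_multi_min_count |
    apply(g, 1, max) >= cfg$gap_single_threshold
  list(gaps = g, present = present)
}

#' Classify audiograms into hearing-loss types
#'
#' Deterministic application of the diagnostic rule table. With PTA4 the
#' 500--4000 Hz mean, HF the high-frequency mean, and "gap" the air-bone
#' gap presence flag of [air_bone_gaps()]:
#' \itemize{
#'   \item normal: air PTA4 < 20 and bone PTA4 < 20 and no gap;
#'   \item conductive: air PTA4 >= 20, bone PTA4 < 20, gap present;
#'   \item sensorineural: air PTA4 >= 20 and air HF >= 20 and
#'     bone PTA4 >= 20 and bone HF >= 20, no gap;
#'   \item mixed: air PTA4 >= 20 and bone PTA4 >= 20, gap present;
#'   \item indeterminate: any combination matched by none of the above
#'     (e.g. normal PTA4 alongside a large gap). Such records are reported
#'     and excluded from model training.
#' }
#' All means are compared unrounded; the 20 dB boundary classifies as loss
#' (">= 20").
#'
#' @param set An audiogram set; records must pass the completeness check.
#' @param cfg A [rule_config()].
#' @return Factor of labels with levels [hearing_loss_levels()].
#' @export
classify_audiograms <- function(set, cfg = rule_config()) {
  if (!all(is_complete(set)))
    stop("classify requires complete audiograms (run apply_qc first); record ",
         which(!is_complete(set))[1], " is incomplete")
  cut <- cfg$pta_cutoff
  air_pta <- mean_threshold(set, "air", cfg$gap_freqs)
  bone_pta <- mean_threshold(set, "bone", cfg$gap_freqs)
  air_hf <- mean_threshold(set, "air", cfg$air_hf_freqs)
  bone_hf <- mean_threshold(set, "bone", cfg$bone_hf_freqs)
  gap <- air_bone_gaps(set, cfg)$present

  lab <- rep("indeterminate", nrow(set))
  lab[air_pta < cut & bone_pta < cut & !gap] <- "normal"
  lab[air_pta >= cut & bone_pta < cut & gap] <- "conductive"
  lab[air_pta >= cut & air_hf >= cut & bone_pta >= cut & bone_hf >= cut &
        !gap] <- "sensorineural"
  lab[air_pta >= cut & bone_pta >= cut & gap] <- "mixed"
  factor(lab, levels = hearing_loss_levels())
}

#' Attach rule-engine labels to an audiogram set
#'
#' @param set An audiogram set.
#' @param cfg A [rule_config()].
#' @return The set with a `label` character column.
#' @export
label_audiograms <- function(set, cfg = rule_config()) {
  set$label <- as.character(classify_audiograms(set, cfg))
  set
}
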
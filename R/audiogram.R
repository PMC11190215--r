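#' Octave frequency grids for pure-tone audiometry
#'
#' Air-conduction thresholds are measured at seven octave frequencies from
#' 125 to 8000 Hz; bone-conduction testing skips the two extremes, leaving
#' five frequencies from 250 to 4000 Hz. The pure-tone average (PTA4) uses
#' 500--4000 Hz, the air high-frequency average uses 4000 and 8000 Hz, and
#' the bone high-frequency criterion is evaluated at 4000 Hz, the only bone
#' grid frequency at or above 4 kHz.
#'
#' @return A list with elements `air`, `bone`, `pta`, `air_hf`, `bone_hf`,
#'   each an increasing integer vector of frequencies in Hz.
#' @examples
#' frequency_grid()$pta
#' @export
frequency_grid <- function() {
  list(
    air     = c(125L, 250L, 500L, 1000L, 2000L, 4000L, 8000L),
    bone    = c(250L, 500L, 1000L, 2000L, 4000L),
    pta     = c(500L, 1000L, 2000L, 4000L),
    air_hf  = c(4000L, 8000L),
    bone_hf = 4000L
  )
}

#' Hearing loss class labels
#'
#' The four clinical classes in fixed order (normal, conductive, mixed,
#' sensorineural) plus `indeterminate` for threshold combinations matched by
#' none of the four diagnostic rules. `indeterminate` never enters training
#' sets and is never produced by the synthetic generator.
#'
#' @param clinical_only If `TRUE`, return only the four clinical classes.
#' @return Character vector of label values.
#' @export
hearing_loss_levels <- function(clinical_only = FALSE) {
  lv <- c("normal", "conductive", "mixed", "sensorineural")
  if (clinical_only) lv else c(lv, "indeterminate")
}

ac_cols <- function() paste0("ac_", frequency_grid()$air)
bc_cols <- function() paste0("bc_", frequency_grid()$bone)

#' Construct a set of audiograms
#'
#' An audiogram set is a plain data frame with one row per tested ear:
#' columns `subject_id`, `ear` (`"left"`/`"right"`), air-conduction
#' thresholds `ac_125` ... `ac_8000` and bone-conduction thresholds
#' `bc_250` ... `bc_4000` in dB HL (`NA` = not measured), and an optional
#' `label` column. All package functions accept and return this layout.
#'
#' @param subject_id Character vector of subject identifiers.
#' @param ear Character vector, each `"left"` or `"right"`.
#' @param ac Numeric matrix or data frame with 7 columns, air thresholds
#'   ordered by the air grid; `NA` marks an unmeasured frequency.
#' @param bc Numeric matrix or data frame with 5 columns, bone thresholds
#'   ordered by the bone grid.
#' @param label Optional character vector of hearing-loss labels.
#' @return A data frame of class `audiogram_set`.
#' @examples
#' audiogram_set("s1", "left", ac = rbind(rep(10, 7)), bc = rbind(rep(5, 5)))
#' @export
audiogram_set <- function(subject_id, ear, ac, bc, label = NULL) {
  n <- length(subject_id)
  ear <- as.character(ear)
  if (length(ear) != n)
    stop("subject_id and ear must have equal length")
  if (!all(ear %in% c("left", "right")))
    stop("ear must be 'left' or 'right'")
  ac <- as.matrix(ac); bc <- as.matrix(bc)
  if (nrow(ac) != n || ncol(ac) != 7L)
    stop("ac must be an n x 7 matrix (air grid order)")
  if (nrow(bc) != n || ncol(bc) != 5L)
    stop("bc must be an n x 5 matrix (bone grid order)")
  df <- data.frame(subject_id = as.character(subject_id), ear = ear,
                   stringsAsFactors = FALSE)
  for (j in 1:7) df[[ac_cols()[j]]] <- as.numeric(ac[, j])
  for (j in 1:5) df[[bc_cols()[j]]] <- as.numeric(bc[, j])
  if (!is.null(label)) {
    if (length(label) != n) stop("label length must match number of records")
    bad <- setdiff(unique(label[!is.na(label)]), hearing_loss_levels())
    if (length(bad))
      stop("unknown label value(s): ", paste(bad, collapse = ", "))
    df$label <- as.character(label)
  }
  as_audiogram_set(df)
}

#' Coerce a data frame to an audiogram set
#'
#' Validates that the threshold columns exist and are numeric and finite
#' where present, and attaches the `audiogram_set` class.
#'
#' @param df A data frame with the audiogram-set columns.
#' @return The validated data frame of class `audiogram_set`.
#' @export
as_audiogram_set <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("subject_id", "ear", ac_cols(), bc_cols())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing audiogram columns: ", paste(miss, collapse = ", "))
  for (col in c(ac_cols(), bc_cols())) {
    df[[col]] <- as.numeric(df[[col]])
    v <- df[[col]]
    if (any(!is.na(v) & !is.finite(v)))
      stop("non-finite threshold in column ", col)
  }
  df$subject_id <- as.character(df$subject_id)
  df$ear <- as.character(df$ear)
  if (!all(df$ear %in% c("left", "right")))
    stop("ear must be 'left' or 'right'")
  class(df) <- unique(c("audiogram_set", class(df)))
  df
}

#' Look up a stored threshold
#'
#' Returns the stored threshold exactly, or `NA` when that frequency was not
#' measured; never substitutes a default. Frequencies off the conduction's
#' grid are a domain error (e.g. bone conduction is never tested at 8000 Hz).
#'
#' @param set An audiogram set.
#' @param i Row index of the record.
#' @param conduction `"air"` or `"bone"`.
#' @param freq Frequency in Hz, on the corresponding grid.
#' @return The threshold in dB HL, or `NA` if absent.
#' @export
get_threshold <- function(set, i, conduction = c("air", "bone"), freq) {
  conduction <- match.arg(conduction)
  grid <- frequency_grid()[[if (conduction == "air") "air" else "bone"]]
  if (!freq %in% grid)
    stop(sprintf("%d Hz is not on the %s-conduction grid", freq, conduction))
  col <- paste0(if (conduction == "air") "ac_" else "bc_", freq)
  set[[col]][i]
}

#' Threshold matrices of an audiogram set
#'
#' @param set An audiogram set.
#' @param conduction `"air"` or `"bone"`.
#' @return Numeric matrix (records x grid frequencies), columns named by Hz.
#' @export
threshold_matrix <- function(set, conduction = c("air", "bone")) {
  conduction <- match.arg(conduction)
  cols <- if (conduction == "air") ac_cols() else bc_cols()
  m <- as.matrix(as.data.frame(set)[cols])
  colnames(m) <- sub("^(ac|bc)_", "", cols)
  storage.mode(m) <- "double"
  m
}

#' Is each audiogram complete?
#'
#' A record is complete when air conduction is present at all of
#' 250--8000 Hz (125 Hz optional) and bone conduction at all of
#' 500--4000 Hz (250 Hz optional).
#'
#' @param set An audiogram set.
#' @return Logical vector, one entry per record.
#' @export
is_complete <- function(set) {
  ac <- threshold_matrix(set, "air")
  bc <- threshold_matrix(set, "bone")
  req_air <- as.character(c(250, 500, 1000, 2000, 4000, 8000))
  req_bone <- as.character(c(500, 1000, 2000, 4000))
  rowSums(is.na(ac[, req_air, drop = FALSE])) == 0 &
    rowSums(is.na(bc[, req_bone, drop = FALSE])) == 0
}
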
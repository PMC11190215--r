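#' Read audiograms from CSV, JSON-lines or XML
#'
#' Three interchange formats are supported:
#' \describe{
#'   \item{csv}{UTF-8, header row; columns `subject_id`, `ear`,
#'     `ac_125` ... `ac_8000`, `bc_250` ... `bc_4000`, optional `label`;
#'     blank cell = frequency not measured.}
#'   \item{jsonl}{One JSON object per line with fields `subject_id`, `ear`,
#'     `ac` and `bc` (objects mapping frequency to dB HL, absent frequencies
#'     omitted) and optional `label`.}
#'   \item{xml}{Per-point tonal records:
#'     `<audiograms><subject id="..."><ear side="left" label="...">`
#'     `<tonal_point conduction="air|bone" frequency="Hz" level="dB"`
#'     ` masked="true|false"/>` `</ear></subject></audiograms>`.
#'     When both a masked and an unmasked point exist at one (conduction,
#'     frequency), the masked value is kept for bone conduction and the
#'     unmasked value for air conduction, following clinical convention;
#'     any other duplicate is an error.}
#' }
#' Thresholds are preserved exactly and missing frequencies stay absent;
#' the reader never substitutes defaults.
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"jsonl"`, `"xml"`. Default guesses from
#'   the file extension.
#' @return An `audiogram_set` data frame.
#' @seealso [write_audiograms()]
#' @export
read_audiograms <- function(path, format = c("auto", "csv", "jsonl", "xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    csv   = read_audiograms_csv(path),
    jsonl = read_audiograms_jsonl(path),
    xml   = read_audiograms_xml(path)
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", jsonl = "jsonl", json = "jsonl", xml = "xml",
    stop("cannot guess format from extension '", ext,
         "'; pass format= explicitly")
  )
}

read_audiograms_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L && ncol(df) == 0L)
    stop("parse error in ", path, ": empty file")
  need <- c("subject_id", "ear", ac_cols(), bc_cols())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if ("label" %in% names(df)) {
    df$label <- as.character(df$label)
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  }
  as_audiogram_set(df[intersect(c(need, "label"), names(df))])
}

read_audiograms_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error in ", path, ": empty file")
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error in ", path, " line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    for (f in c("subject_id", "ear"))
      if (is.null(obj[[f]]))
        stop("parse error in ", path, " line ", i, ": missing field ", f)
    obj
  })
  grid <- frequency_grid()
  fill <- function(obj, field, freqs) {
    out <- rep(NA_real_, length(freqs))
    vals <- obj[[field]]
    if (!is.null(vals)) {
      bad <- setdiff(names(vals), as.character(freqs))
      if (length(bad))
        stop("frequency off the ", field, " grid: ",
             paste(bad, collapse = ", "))
      out[match(as.integer(names(vals)), freqs)] <-
        vapply(vals, as.numeric, numeric(1))
    }
    out
  }
  ac <- t(vapply(recs, fill, numeric(7), field = "ac", freqs = grid$air))
  bc <- t(vapply(recs, fill, numeric(5), field = "bc", freqs = grid$bone))
  labels <- vapply(recs, function(r)
    if (is.null(r$label)) NA_character_ else as.character(r$label),
    character(1))
  audiogram_set(
    subject_id = vapply(recs, function(r) as.character(r$subject_id), ""),
    ear = vapply(recs, function(r) as.character(r$ear), ""),
    ac = ac, bc = bc,
    label = if (all(is.na(labels))) NULL else labels
  )
}

read_audiograms_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  subjects <- xml2::xml_find_all(doc, ".//subject")
  if (!length(subjects)) stop("parse error in ", path, ": no <subject> elements")
  grid <- frequency_grid()
  rows <- list()
  for (subj in subjects) {
    sid <- xml2::xml_attr(subj, "id")
    if (is.na(sid)) stop("parse error: <subject> without id attribute")
    for (earnode in xml2::xml_find_all(subj, "./ear")) {
      side <- xml2::xml_attr(earnode, "side")
      if (is.na(side) || !side %in% c("left", "right"))
        stop("parse error: <ear> of subject ", sid,
             " must have side='left'|'right'")
      label <- xml2::xml_attr(earnode, "label")
      pts <- xml2::xml_find_all(earnode, "./tonal_point")
      cond <- xml2::xml_attr(pts, "conduction")
      freq <- as.integer(xml2::xml_attr(pts, "frequency"))
      lvl  <- as.numeric(xml2::xml_attr(pts, "level"))
      mask <- tolower(xml2::xml_attr(pts, "masked")) %in% "true"
      if (any(is.na(cond) | is.na(freq) | is.na(lvl)))
        stop("parse error: malformed <tonal_point> under subject ", sid,
             " ear ", side)
      if (any(!cond %in% c("air", "bone")))
        stop("parse error: conduction must be 'air' or 'bone' (subject ",
             sid, ")")
      off_air <- cond == "air" & !freq %in% grid$air
      off_bone <- cond == "bone" & !freq %in% grid$bone
      if (any(off_air | off_bone))
        stop("parse error: frequency off grid for subject ", sid, " ear ",
             side, ": ", paste(freq[off_air | off_bone], collapse = ", "))
      ac <- rep(NA_real_, 7); bc <- rep(NA_real_, 5)
      for (key in unique(paste(cond, freq))) {
        sel <- paste(cond, freq) == key
        k_cond <- cond[sel][1]; k_freq <- freq[sel][1]
        if (sum(sel) > 1L) {
          # masking precedence: masked wins for bone, unmasked for air
          want <- if (k_cond == "bone") mask[sel] else !mask[sel]
          if (sum(want) != 1L)
            stop("duplicate tonal_point (", k_cond, ", ", k_freq,
                 " Hz) for subject ", sid, " ear ", side)
          value <- lvl[sel][want]
        } else value <- lvl[sel]
        if (k_cond == "air") ac[match(k_freq, grid$air)] <- value
        else bc[match(k_freq, grid$bone)] <- value
      }
      rows[[length(rows) + 1L]] <- list(sid = sid, side = side,
                                        label = label, ac = ac, bc = bc)
    }
  }
  if (!length(rows)) stop("parse error in ", path, ": no <ear> records")
  labels <- vapply(rows, function(r) r$label, character(1))
  audiogram_set(
    subject_id = vapply(rows, function(r) r$sid, ""),
    ear = vapply(rows, function(r) r$side, ""),
    ac = t(vapply(rows, function(r) r$ac, numeric(7))),
    bc = t(vapply(rows, function(r) r$bc, numeric(5))),
    label = if (all(is.na(labels))) NULL else labels
  )
}

#' Write audiograms to CSV, JSON-lines or XML
#'
#' Writing then reading back reproduces the set exactly (thresholds, ids,
#' ears and labels); absent frequencies stay blank/omitted.
#'
#' @param set An `audiogram_set`.
#' @param path Output path.
#' @param format One of `"csv"`, `"jsonl"`, `"xml"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_audiograms <- function(set, path,
                             format = c("auto", "csv", "jsonl", "xml")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  set <- as_audiogram_set(as.data.frame(set))
  if (nrow(set) == 0L) stop("refusing to write an empty audiogram set")
  switch(format,
    csv = {
      cols <- c("subject_id", "ear", ac_cols(), bc_cols(),
                intersect("label", names(set)))
      utils::write.csv(as.data.frame(set)[cols], path, row.names = FALSE,
                       na = "", quote = TRUE)
    },
    jsonl = {
      grid <- frequency_grid()
      con <- file(path, "w", encoding = "UTF-8")
      on.exit(close(con))
      ac <- threshold_matrix(set, "air"); bc <- threshold_matrix(set, "bone")
      for (i in seq_len(nrow(set))) {
        obj <- list(subject_id = set$subject_id[i], ear = set$ear[i])
        a <- ac[i, ]; b <- bc[i, ]
        obj$ac <- as.list(a[!is.na(a)])
        obj$bc <- as.list(b[!is.na(b)])
        if (!is.null(set$label) && !is.na(set$label[i]))
          obj$label <- set$label[i]
        writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
      }
    },
    xml = {
      doc <- xml2::xml_new_root("audiograms")
      ac <- threshold_matrix(set, "air"); bc <- threshold_matrix(set, "bone")
      grid <- frequency_grid()
      for (i in seq_len(nrow(set))) {
        subj <- xml2::xml_add_child(doc, "subject", id = set$subject_id[i])
        earnode <- xml2::xml_add_child(subj, "ear", side = set$ear[i])
        if (!is.null(set$label) && !is.na(set$label[i]))
          xml2::xml_set_attr(earnode, "label", set$label[i])
        for (j in which(!is.na(ac[i, ])))
          xml2::xml_add_child(earnode, "tonal_point", conduction = "air",
                              frequency = as.character(grid$air[j]),
                              level = format(ac[i, j], scientific = FALSE),
                              masked = "false")
        for (j in which(!is.na(bc[i, ])))
          xml2::xml_add_child(earnode, "tonal_point", conduction = "bone",
                              frequency = as.character(grid$bone[j]),
                              level = format(bc[i, j], scientific = FALSE),
                              masked = "true")
      }
      xml2::write_xml(doc, path)
    }
  )
  invisible(path)
}
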
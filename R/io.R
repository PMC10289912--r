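#' Read spectra from a delimited text file
#'
#' Two layouts are supported. `wide`: first column is the wavenumber axis and
#' every further column is one spectrum, its header encoding identity as
#' `sample_id[:replicate_id][:group]`. `long`: columns `sample_id`,
#' `replicate_id`, `group`, `wavenumber`, `intensity`, one row per point.
#' The delimiter is inferred from the extension (`.csv` comma, otherwise
#' tab); files are read and written as UTF-8.
#'
#' @param path Path to a CSV/TSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A [spectra_set()]. All spectra must share one strictly increasing
#'   wavenumber axis; a mismatch raises an error.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          comment.char = "")
  if (layout == "wide") {
    wn <- as.numeric(df[[1L]])
    if (anyNA(wn) || is.unsorted(wn, strictly = TRUE))
      stop("wavenumber column must be numeric and strictly increasing",
           call. = FALSE)
    heads <- colnames(df)[-1L]
    if (!length(heads))
      return(spectra_set(wn, matrix(numeric(0), 0, length(wn)),
                         character(0)))
    parts <- strsplit(heads, ":", fixed = TRUE)
    sid <- vapply(parts, `[`, "", 1L)
    rid <- vapply(parts, function(p) if (length(p) >= 2L && nzchar(p[2L]))
      p[2L] else NA_character_, "")
    grp <- vapply(parts, function(p) if (length(p) >= 3L && nzchar(p[3L]))
      p[3L] else NA_character_, "")
    spectra_set(wn, t(as.matrix(df[-1L])), sid,
                suppressWarnings(as.integer(rid)), grp)
  } else {
    need <- c("sample_id", "replicate_id", "group", "wavenumber", "intensity")
    if (!all(need %in% colnames(df)))
      stop("long layout needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!nrow(df))
      return(spectra_set(numeric(0), matrix(numeric(0), 0, 0), character(0)))
    grp_chr <- as.character(df$group)
    grp_chr[!is.na(grp_chr) & grp_chr == ""] <- NA_character_
    key <- paste(df$sample_id, df$replicate_id, sep = "\r")
    keys <- unique(key)
    first <- key == keys[1L]
    wn <- as.numeric(df$wavenumber[first])
    if (is.unsorted(wn, strictly = TRUE))
      stop("wavenumbers must be strictly increasing within each spectrum",
           call. = FALSE)
    mat <- matrix(NA_real_, length(keys), length(wn))
    sid <- rid <- grp <- character(length(keys))
    for (k in seq_along(keys)) {
      rows <- which(key == keys[k])
      if (length(rows) != length(wn) ||
          !isTRUE(all.equal(as.numeric(df$wavenumber[rows]), wn)))
        stop("axis mismatch across spectra in ", path, call. = FALSE)
      mat[k, ] <- as.numeric(df$intensity[rows])
      sid[k] <- as.character(df$sample_id[rows[1L]])
      rid[k] <- as.character(df$replicate_id[rows[1L]])
      grp[k] <- grp_chr[rows[1L]]
    }
    spectra_set(wn, mat, sid, suppressWarnings(as.integer(rid)), grp)
  }
}

#' Write spectra to a delimited text file
#'
#' Inverse of [read_spectra()]; a written file re-reads to an equal set (up
#' to floating-point round-trip of the decimal representation).
#'
#' @param x A [spectra_set()].
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  grp <- as.character(x$group)
  if (layout == "wide") {
    heads <- x$sample_id
    has_rid <- !is.na(x$replicate_id)
    has_grp <- !is.na(grp)
    heads <- paste0(heads,
                    ifelse(has_rid | has_grp,
                           paste0(":", ifelse(has_rid, x$replicate_id, "")),
                           ""),
                    ifelse(has_grp, paste0(":", grp), ""))
    df <- data.frame(wavenumber = x$wavenumber, check.names = FALSE)
    mat <- t(x$intensity)
    colnames(mat) <- heads
    df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  } else {
    n <- n_spectra(x); p <- n_points(x)
    df <- data.frame(
      sample_id = rep(x$sample_id, each = p),
      replicate_id = rep(x$replicate_id, each = p),
      group = rep(grp, each = p),
      wavenumber = rep(x$wavenumber, times = n),
      intensity = as.vector(t(x$intensity)))
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
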
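#' Canonical class order for four-group serum studies
#'
#' The fixed label order used everywhere a four-class vector, matrix or table
#' is produced: healthy controls, bladder cancer (BC), adrenal cancer (AC),
#' acute myeloid leukemia (AML).
#'
#' @return Character vector of the four canonical class labels.
#' @export
sers_classes <- function() c("healthy", "BC", "AC", "AML")

#' Prominent serum SERS peak lexicon
#'
#' The 17 prominent blood-serum SERS bands (494--1654 cm^-1) with their
#' literature vibrational-mode / biochemical assignments. Used as a static
#' lookup by the interpretation stage; no assignment inference is performed.
#'
#' @return A data frame with columns `position` (Raman shift, cm^-1, strictly
#'   increasing) and `assignment` (free text).
#' @export
peak_lexicon <- function() {
  data.frame(
    position = c(494, 531, 589, 639, 725, 812, 887, 959, 1004, 1073, 1093,
                 1135, 1206, 1330, 1443, 1581, 1654),
    assignment = c(
      "Ring vibration, cellulose, guanine, L-arginine",
      "Cholesterol ester",
      "Ascorbic acid, amide-VI",
      "C-S stretching vibration, L-tyrosine, lactose",
      "C-H bending vibration, adenine, coenzyme A",
      "C-C-O stretching vibration, L-serine, glutathione",
      "C-O-H bending vibration, glutathione, D-(+)-galactosamine",
      "alpha-Helix, L-proline, L-valine",
      "C-C symmetric stretch, phenylalanine",
      "C-N stretching vibration, collagen",
      "C-N stretching vibration, D-mannos",
      "C-N stretching vibration, D-mannos",
      "Ring vibration, L-tryptophan, phenylalanine",
      "C-H stretching vibration, nucleic acid bases",
      "CH2 bending vibration, glycine, L-proline, stearic acid",
      "C=C bending vibration, phenylalanine, acetoacetate, riboflavin",
      "C=O stretching vibration, phospholipids, amide-I, alpha-Helix"
    ),
    stringsAsFactors = FALSE
  )
}

#' Construct a set of spectra on a shared wavenumber axis
#'
#' `spectra_set` is the unit every pipeline stage consumes and produces: a
#' matrix of intensities (one row per spectrum) over one common wavenumber
#' grid, plus per-spectrum identity, replicate index and group label.
#'
#' @param wavenumber Numeric vector of Raman shifts (cm^-1), strictly
#'   increasing and finite.
#' @param intensity Numeric matrix, one row per spectrum, `length(wavenumber)`
#'   columns. A single spectrum may be given as a vector.
#' @param sample_id Character vector of per-spectrum sample identifiers.
#' @param replicate_id Optional integer vector of measurement indices
#'   (typically 1--5); `NA` when not applicable.
#' @param group Optional group labels, a subset of [sers_classes()]; `NA`
#'   marks unlabeled spectra (prediction-only use).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumber, intensity, sample_id,
                        replicate_id = NULL, group = NULL) {
  wavenumber <- as.numeric(wavenumber)
  if (is.null(dim(intensity))) intensity <- matrix(intensity, nrow = 1L)
  intensity <- as.matrix(intensity)
  n <- nrow(intensity)
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumbers must be finite", call. = FALSE)
  if (is.unsorted(wavenumber, strictly = TRUE))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  if (ncol(intensity) != length(wavenumber))
    stop("intensity must have one column per wavenumber", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  dimnames(intensity) <- NULL
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n)
    stop("sample_id must have one entry per spectrum", call. = FALSE)
  if (is.null(replicate_id)) replicate_id <- rep(NA_integer_, n)
  replicate_id <- as.integer(replicate_id)
  if (length(replicate_id) == 1L) replicate_id <- rep(replicate_id, n)
  if (length(replicate_id) != n)
    stop("replicate_id must have one entry per spectrum", call. = FALSE)
  if (is.null(group)) group <- rep(NA_character_, n)
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n)
    stop("group must have one entry per spectrum", call. = FALSE)
  bad <- !is.na(group) & !(group %in% sers_classes())
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(group[bad]), collapse = ", "),
         call. = FALSE)
  structure(
    list(wavenumber = wavenumber,
         intensity = intensity,
         sample_id = sample_id,
         replicate_id = replicate_id,
         group = factor(group, levels = sers_classes())),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points, %.0f-%.0f cm^-1\n",
              n_spectra(x), n_points(x),
              min(x$wavenumber), max(x$wavenumber)))
  tab <- table(x$group, useNA = "ifany")
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.spectra_set <- function(object, ...) {
  cat(sprintf("spectra_set: %d spectra, %d samples, %d points\n",
              n_spectra(object), length(unique(object$sample_id)),
              n_points(object)))
  cat(sprintf("axis: %.1f to %.1f cm^-1 (step ~%.2f)\n",
              min(object$wavenumber), max(object$wavenumber),
              mean(diff(object$wavenumber))))
  print(table(group = object$group, useNA = "ifany"))
  invisible(object)
}

#' Number of spectra / axis points in a set
#' @param x A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(x) nrow(x$intensity)

#' @rdname n_spectra
#' @export
n_points <- function(x) length(x$wavenumber)

#' @export
`[.spectra_set` <- function(x, i, ...) {
  i <- seq_len(n_spectra(x))[i]
  spectra_set(x$wavenumber, x$intensity[i, , drop = FALSE],
              x$sample_id[i], x$replicate_id[i],
              as.character(x$group[i]))
}

#' Concatenate spectra sets sharing one axis
#' @param ... `spectra_set` objects on identical wavenumber grids.
#' @return The combined `spectra_set`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  ax <- sets[[1L]]$wavenumber
  for (s in sets)
    if (!isTRUE(all.equal(s$wavenumber, ax)))
      stop("cannot bind spectra on different axes", call. = FALSE)
  spectra_set(ax,
              do.call(rbind, lapply(sets, `[[`, "intensity")),
              unlist(lapply(sets, `[[`, "sample_id")),
              unlist(lapply(sets, `[[`, "replicate_id")),
              unlist(lapply(sets, function(s) as.character(s$group))))
}

#' Average replicate measurements per sample
#'
#' Collapses the replicate spectra of each sample to their pointwise
#' arithmetic mean, mirroring the convention of averaging the five
#' measurements taken at random locations of each dried serum spot into one
#' final spectrum per sample.
#'
#' @param x A `spectra_set` with one or more replicates per `sample_id`.
#' @return A `spectra_set` with one spectrum per sample (replicate_id `NA`);
#'   group labels are preserved and must agree across a sample's replicates.
#' @export
average_replicates <- function(x) {
  ids <- unique(x$sample_id)
  grp <- character(length(ids))
  for (k in seq_along(ids)) {
    g <- unique(as.character(x$group[x$sample_id == ids[k]]))
    if (length(g) > 1L)
      stop("conflicting group labels for sample ", ids[k], call. = FALSE)
    grp[k] <- g
  }
  m <- rowsum(x$intensity, group = x$sample_id, reorder = FALSE)
  cnt <- as.vector(table(factor(x$sample_id, levels = rownames(m))))
  m <- m / cnt
  ord <- match(ids, rownames(m))
  spectra_set(x$wavenumber, m[ord, , drop = FALSE], ids,
              rep(NA_integer_, length(ids)), grp)
}

#' Pointwise mean spectrum of a group (or of the whole set)
#' @param x A `spectra_set`.
#' @param group Optional group label; when given, only that group's spectra
#'   are averaged.
#' @return Numeric vector over the shared axis.
#' @export
mean_spectrum <- function(x, group = NULL) {
  idx <- if (is.null(group)) seq_len(n_spectra(x)) else which(x$group == group)
  if (!length(idx)) stop("no spectra in group ", group, call. = FALSE)
  colMeans(x$intensity[idx, , drop = FALSE])
}
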
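#' Sample-level cross-validation fold plan
#'
#' Randomly partitions samples into `n_folds` folds (default stratified by
#' group, which keeps the 30/30/30/20 design balanced at 6/6/6/4 per fold)
#' and fixes the five train/validation/test rotations: in rotation `r`,
#' fold `r` is the test set, the next fold the validation set and the
#' remaining folds the training set. Splitting precedes augmentation so no
#' augmented test spectrum can share source samples with training data.
#'
#' @param x A [spectra_set()] (one spectrum per sample is typical; replicate
#'   spectra of one sample always land in the same fold).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param stratified Preserve group proportions per fold (default `TRUE`).
#' @return An object of class `fold_plan` with `assignments` (named integer
#'   vector, sample_id -> fold) and `rotations`.
#' @export
make_folds <- function(x, n_folds = 5L, seed = 1L, stratified = TRUE) {
  ids <- unique(x$sample_id)
  if (n_folds > length(ids))
    stop("more folds than samples", call. = FALSE)
  grp <- as.character(x$group)[match(ids, x$sample_id)]
  set.seed(seed)
  fold <- integer(length(ids)); names(fold) <- ids
  if (stratified) {
    if (anyNA(grp)) stop("stratified folds need group labels", call. = FALSE)
    load <- integer(n_folds)
    for (g in unique(grp)) {
      gi <- sample(which(grp == g))
      m <- length(gi)
      base <- m %/% n_folds
      alloc <- rep(base, n_folds)
      extra <- m - base * n_folds
      if (extra > 0) {
        # remainders go to the currently least-loaded folds (random ties)
        ord <- order(load + alloc, stats::runif(n_folds))
        alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
      }
      fold[gi] <- rep.int(seq_len(n_folds), alloc)
      load <- load + alloc
    }
  } else {
    perm <- sample(seq_along(ids))
    fold[perm] <- ((seq_along(perm) - 1L) %% n_folds) + 1L
  }
  rotations <- lapply(seq_len(n_folds), function(r) {
    v <- (r %% n_folds) + 1L
    list(test = r, val = v, train = setdiff(seq_len(n_folds), c(r, v)))
  })
  structure(list(n_folds = as.integer(n_folds), assignments = fold,
                 rotations = rotations),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds, %d samples; fold sizes: %s\n",
              x$n_folds, length(x$assignments),
              paste(tabulate(x$assignments, x$n_folds), collapse = ", ")))
  invisible(x)
}

runif_dirichlet <- function(k) {
  w <- stats::rgamma(k, 1)
  w / sum(w)
}

#' Within-class convex-combination augmentation
#'
#' For every original spectrum ("anchor"), `factor` synthetic spectra are
#' generated, each a convex combination of `n_components` distinct spectra
#' of the same group drawn from the same subset: the anchor itself plus
#' `n_components - 1` others sampled uniformly without replacement, with
#' weights drawn from the uniform Dirichlet over the simplex. Convexity
#' keeps every synthetic intensity within the pointwise range of its
#' sources, so the group's spectral distribution is maintained while
#' diversity increases.
#'
#' @param x A [spectra_set()]; every group present must have at least
#'   `n_components` spectra.
#' @param factor Synthetic spectra per original (default 10).
#' @param n_components Spectra per combination (default 3).
#' @param seed Integer seed.
#' @param weights Optional fixed weight vector (length `n_components`,
#'   non-negative, summing to 1) overriding the Dirichlet draw; useful for
#'   degenerate-combination checks.
#' @return A `spectra_set` of `factor * n_spectra(x)` synthetic spectra with
#'   inherited group labels and a `combos` attribute (data frame of source
#'   sample_ids and weights, one row per synthetic spectrum).
#' @export
augment_spectra <- function(x, factor = 10L, n_components = 3L, seed = 1L,
                            weights = NULL) {
  stopifnot(factor >= 1L, n_components >= 2L)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n_components, all(weights >= 0),
              abs(sum(weights) - 1) < 1e-12)
  }
  grp <- as.character(x$group)
  if (anyNA(grp)) stop("augmentation needs group labels", call. = FALSE)
  cnt <- table(grp)
  small <- names(cnt)[cnt < n_components]
  if (length(small))
    stop("group(s) with fewer than ", n_components, " spectra: ",
         paste(small, collapse = ", "), call. = FALSE)
  set.seed(seed)
  n <- n_spectra(x); p <- n_points(x)
  out <- matrix(NA_real_, n * factor, p)
  sid <- grv <- character(n * factor)
  combo <- vector("list", n * factor)
  row <- 0L
  for (i in seq_len(n)) {
    mates <- setdiff(which(grp == grp[i]), i)
    for (j in seq_len(factor)) {
      src <- c(i, sample(mates, n_components - 1L))
      w <- if (is.null(weights)) runif_dirichlet(n_components) else weights
      row <- row + 1L
      out[row, ] <- drop(w %*% x$intensity[src, , drop = FALSE])
      sid[row] <- sprintf("%s#%d", x$sample_id[i], j)
      grv[row] <- grp[i]
      combo[[row]] <- c(x$sample_id[src], w)
    }
  }
  res <- spectra_set(x$wavenumber, out, sid, NULL, grv)
  cm <- do.call(rbind, combo)
  combos <- data.frame(cm[, seq_len(n_components), drop = FALSE],
                       apply(cm[, n_components + seq_len(n_components),
                                drop = FALSE], 2L, as.numeric),
                       stringsAsFactors = FALSE)
  colnames(combos) <- c(paste0("src", seq_len(n_components)),
                        paste0("w", seq_len(n_components)))
  attr(res, "combos") <- combos
  res
}

#' Build augmented train/validation/test datasets for one rotation
#'
#' Splits the samples according to the fold plan, augments each of the three
#' subsets independently (a combination never mixes spectra across subsets,
#' so leakage is excluded by construction), then min-max normalizes the
#' augmented spectra.
#'
#' @param x A [spectra_set()] (deep-track input: already resampled to the
#'   network length if desired).
#' @param plan A [make_folds()] plan covering `x`'s samples.
#' @param rotation Rotation index in `1:plan$n_folds`.
#' @param factor,n_components,seed Passed to [augment_spectra()]; each
#'   subset uses a distinct seed derived from `seed` and `rotation`.
#' @param normalize Min-max normalize after augmentation (default `TRUE`).
#' @param augment Set `FALSE` to return the raw splits.
#' @return List of `spectra_set`s: `train`, `val`, `test`.
#' @export
build_datasets <- function(x, plan, rotation, factor = 10L,
                           n_components = 3L, seed = 1L, normalize = TRUE,
                           augment = TRUE) {
  stopifnot(inherits(plan, "fold_plan"),
            rotation >= 1L, rotation <= plan$n_folds)
  fold <- plan$assignments[x$sample_id]
  if (anyNA(fold)) stop("fold plan does not cover all samples", call. = FALSE)
  rot <- plan$rotations[[rotation]]
  pick <- function(fs) x[fold %in% fs]
  subsets <- list(train = pick(rot$train), val = pick(rot$val),
                  test = pick(rot$test))
  out <- vector("list", 3L); names(out) <- names(subsets)
  for (k in seq_along(subsets)) {
    s <- subsets[[k]]
    if (augment)
      s <- augment_spectra(s, factor = factor, n_components = n_components,
                           seed = (seed + 7919L * rotation + k) %% .Machine$integer.max)
    if (normalize) s <- minmax_normalize(s)
    out[[k]] <- s
  }
  out
}
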
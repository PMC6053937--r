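# Acoustic-structure comparison of species' alarm calls. Feature tables are
# consumed, not computed from audio: one row per analysed call, seven
# spectro-temporal measurements per row.

#' Canonical acoustic feature names
#'
#' Seven per-call measurements: call duration, visibility of harmonics,
#' number of distinct structural components, presence of pulses, the 25%
#' energy quartile, the 25-75% energy-quartile bandwidth, and the third
#' dominant frequency (DF3; the first two dominant frequencies are excluded
#' upstream for collinearity).
#'
#' @return character vector of the seven feature column names.
#' @export
acoustic_feature_names <- function() {
  c("duration_s", "harmonics", "n_components", "pulses",
    "q25_hz", "bandwidth_hz", "df3_hz")
}

check_feature_table <- function(table) {
  stopifnot(is.data.frame(table))
  feats <- acoustic_feature_names()
  miss <- setdiff(c("species", feats), names(table))
  if (length(miss))
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(table[feats])
  if (any(!is.finite(X)) || any(X < 0))
    stop("acoustic features must be finite and nonnegative")
  invisible(feats)
}

#' Standardize acoustic features by their column maxima
#'
#' Divides every feature by the maximum observed value of that feature, so
#' that all seven dimensions range over (0, 1\] and contribute with equal
#' weight to the Euclidean distance. Idempotent: a table already standardized
#' is returned unchanged.
#'
#' @param table per-call feature data frame with a `species` column and the
#'   seven columns of [acoustic_feature_names()].
#' @return the table with feature columns rescaled.
#' @export
standardize_features <- function(table) {
  feats <- check_feature_table(table)
  for (f in feats) {
    m <- max(table[[f]])
    if (m <= 0)
      stop("feature '", f, "' is all zero; max-standardization undefined")
    table[[f]] <- table[[f]] / m
  }
  table
}

#' Per-species acoustic centroid
#'
#' The species-level acoustic signature used for between-species comparison:
#' the arithmetic mean of each feature across that species' analysed calls.
#'
#' @inheritParams standardize_features
#' @param species species id present in the table.
#' @return named numeric vector of length 7.
#' @export
species_centroid <- function(table, species) {
  feats <- check_feature_table(table)
  rows <- table$species == species
  if (!any(rows)) stop("unknown species: ", species)
  colMeans(as.matrix(table[rows, feats, drop = FALSE]))
}

#' Acoustic similarity matrix between species' alarm calls
#'
#' Similarity is 1 minus the Euclidean distance between species in the
#' standardized 7-dimensional feature space. With max-standardized features
#' each dimension lies in \[0, 1\], so the raw distance can reach sqrt(7);
#' the default `scale = TRUE` divides the distance by sqrt(7) so that the
#' similarity is guaranteed to lie in \[0, 1\] (0 = maximally dissimilar,
#' 1 = identical). `method = "centroid"` (default) compares species mean
#' feature vectors; `method = "pairwise"` averages 1 - distance over all
#' between-species call pairs.
#'
#' @inheritParams standardize_features
#' @param method `"centroid"` or `"pairwise"` aggregation across calls.
#' @param scale divide distances by sqrt(7) to keep similarity in \[0, 1\].
#' @param standardize max-standardize the table first (default `TRUE`; set
#'   `FALSE` only if the table is already standardized).
#' @return symmetric species x species similarity matrix with unit diagonal.
#' @export
acoustic_similarity <- function(table, method = c("centroid", "pairwise"),
                                scale = TRUE, standardize = TRUE) {
  method <- match.arg(method)
  feats <- check_feature_table(table)
  if (standardize) table <- standardize_features(table)
  sp <- sort(unique(table$species))
  k <- length(feats)
  div <- if (scale) sqrt(k) else 1
  S <- matrix(NA_real_, length(sp), length(sp),
              dimnames = list(species = sp, species = sp))
  if (method == "centroid") {
    cent <- t(vapply(sp, function(s) species_centroid(table, s),
                     numeric(k)))
    d <- as.matrix(stats::dist(cent))
    S[] <- 1 - d / div
  } else {
    X <- as.matrix(table[feats])
    for (a in seq_along(sp)) for (b in seq_len(a)) {
      ia <- which(table$species == sp[a]); ib <- which(table$species == sp[b])
      if (a == b && length(ia) == 1L) { S[a, a] <- 1; next }
      pairs <- expand.grid(i = ia, j = ib)
      if (a == b) pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
      d <- sqrt(rowSums((X[pairs$i, , drop = FALSE] -
                           X[pairs$j, , drop = FALSE])^2))
      S[a, b] <- S[b, a] <- mean(1 - d / div)
    }
    diag(S)[] <- 1  # a species is by definition identical to itself
  }
  S
}
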
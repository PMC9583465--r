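#' Fit the triangular three-set fuzzification scheme
#'
#' Learns, per feature, the minimum and maximum over the *training* rows
#' only; the midpoint is their average. Each crisp feature X is later mapped
#' to three overlapping linguistic sets: `X_low` supported on
#' `[min, mid]`, `X_medium` on `[min, max]` (peak at the midpoint) and
#' `X_high` on `[mid, max]`, all triangular. Fitting on training data only
#' is the leakage contract: the scheme never changes when test rows change.
#'
#' @param training data.frame (or matrix) of crisp feature columns; any
#'   non-numeric columns are ignored.
#' @return An object of class `fuzzification_scheme`: per-feature `min`,
#'   `max`, `mid`.
#' @examples
#' sc <- fit_fuzzification(data.frame(Ax = c(1, 3, 5)))
#' sc$mid
#' @export
fit_fuzzification <- function(training) {
  training <- as.data.frame(training)
  num <- vapply(training, is.numeric, TRUE)
  training <- training[num]
  if (ncol(training) == 0L) stop_oscml("no numeric feature columns to fuzzify")
  mins <- vapply(training, min, 0)
  maxs <- vapply(training, max, 0)
  flat <- names(training)[maxs <= mins]
  if (length(flat) > 0)
    stop_oscml("constant feature(s) cannot be fuzzified (zero-width support): ",
               paste(flat, collapse = ", "))
  structure(list(features = names(training), min = mins, max = maxs,
                 mid = (mins + maxs) / 2),
            class = "fuzzification_scheme")
}

triangle_memberships <- function(x, lo, mid, hi) {
  x <- pmin(pmax(x, lo), hi)  # clip the input to the training support
  low <- ifelse(x <= mid, (mid - x) / (mid - lo), 0)
  med <- ifelse(x <= mid, (x - lo) / (mid - lo), (hi - x) / (hi - mid))
  high <- ifelse(x >= mid, (x - mid) / (hi - mid), 0)
  cbind(low = low, medium = med, high = high)
}

#' Apply a fuzzification scheme
#'
#' Maps each crisp feature to its three membership values. Test values
#' outside the training support are clipped to the support before the
#' triangles are evaluated, so a value below the training minimum gets
#' memberships (1, 0, 0) and one above the maximum (0, 0, 1). Within the
#' support the three memberships always sum to 1.
#'
#' @param scheme a [fit_fuzzification()] scheme.
#' @param table data.frame containing (at least) the scheme's features.
#' @return data.frame of `3 * length(scheme$features)` membership columns
#'   named `<feature>_low`, `<feature>_medium`, `<feature>_high`, grouped in
#'   the crisp column order; non-feature columns of `table` are preserved
#'   in front.
#' @export
fuzzify <- function(scheme, table) {
  stopifnot(inherits(scheme, "fuzzification_scheme"))
  table <- as.data.frame(table)
  missing <- setdiff(scheme$features, names(table))
  if (length(missing) > 0)
    stop_oscml("table lacks fuzzified feature(s): ",
               paste(missing, collapse = ", "))
  cols <- list()
  for (feat in scheme$features) {
    m <- triangle_memberships(table[[feat]], scheme$min[[feat]],
                              scheme$mid[[feat]], scheme$max[[feat]])
    cols[[paste0(feat, "_low")]] <- m[, "low"]
    cols[[paste0(feat, "_medium")]] <- m[, "medium"]
    cols[[paste0(feat, "_high")]] <- m[, "high"]
  }
  meta <- table[setdiff(names(table), scheme$features)]
  cbind(meta, as.data.frame(cols))
}

#' Fuzzy feature names for a crisp name vector
#'
#' @param features crisp feature names (default the canonical 16).
#' @return Character vector of `3 * length(features)` membership column
#'   names in crisp-column order.
#' @export
fuzzy_feature_names <- function(features = feature_names()) {
  as.vector(t(outer(features, c("_low", "_medium", "_high"), paste0)))
}
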
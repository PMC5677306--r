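#' Trials-by-features matrix with labels
#'
#' @param values numeric matrix, N trials x d features, all finite.
#' @param labels per-row class codes in \{1, 2\}.
#' @param feature_names optional ordered feature descriptors, length d.
#' @return a \code{feature_matrix} object.
#' @export
feature_matrix <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("feature values contain non-finite entries")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("labels must have one entry per row")
  if (is.null(feature_names))
    feature_names <- sprintf("f%d", seq_len(ncol(values)))
  if (length(feature_names) != ncol(values))
    stop("feature_names length must equal the feature count")
  colnames(values) <- feature_names
  structure(list(values = values, labels = labels,
                 feature_names = as.character(feature_names)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Concatenate two feature matrices column-wise
#'
#' Builds the combined feature vector: the first block (CWT log
#' band-powers in the standard pipeline) followed by the second (DWT
#' sub-band statistics), giving 48 + 48 = 96 features for two-channel
#' trials under the default configurations.
#'
#' @param C,D \code{feature_matrix} objects over the same trials, in the
#'   same order, with identical labels.
#' @return a \code{feature_matrix} of width \code{d_C + d_D}.
#' @export
concat_features <- function(C, D) {
  stopifnot(inherits(C, "feature_matrix"), inherits(D, "feature_matrix"))
  if (nrow(C$values) != nrow(D$values))
    stop("row-count mismatch: ", nrow(C$values), " vs ", nrow(D$values))
  dis <- which(C$labels != D$labels)
  if (length(dis) > 0)
    stop("label mismatch at trial ", dis[1])
  if (ncol(D$values) == 0L) return(C)
  if (ncol(C$values) == 0L) return(D)
  feature_matrix(cbind(C$values, D$values), C$labels,
                 c(C$feature_names, D$feature_names))
}

#' Fit a standardizing PCA retaining a variance fraction
#'
#' Features are z-scored (the CWT log-powers and DWT statistics live on
#' incommensurate scales, so unstandardized PCA would be dominated by the
#' highest-variance statistics), then projected onto the leading
#' principal components.  K is the smallest component count whose
#' cumulative explained variance reaches \code{threshold}.  Eigenvector
#' signs are fixed (largest-magnitude loading positive) so the fit is
#' deterministic.
#'
#' @param F_train a \code{feature_matrix} of training rows only (N >= 2).
#' @param threshold retained-variance fraction, default 0.98.
#' @return a \code{pca_model}: \code{center}, \code{scale}, orthonormal
#'   \code{W} (d x K), \code{eigenvalues} (descending, all components),
#'   \code{K}, \code{variance_threshold}.
#' @export
fit_pca <- function(F_train, threshold = 0.98) {
  stopifnot(inherits(F_train, "feature_matrix"))
  X <- F_train$values
  if (nrow(X) < 2) stop("need at least 2 training rows")
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (all(scl == 0)) stop("all features are constant; PCA undefined")
  scl[scl == 0] <- 1                      # constant feature: centered to 0
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  keep <- ev > max(ev) * 1e-12            # numerically nonzero spectrum
  ev <- ev[keep]
  V <- pr$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  cumvar <- cumsum(ev) / sum(ev)
  K <- which(cumvar >= threshold - 1e-12)[1]
  structure(list(center = ctr, scale = scl,
                 W = V[, seq_len(K), drop = FALSE],
                 eigenvalues = ev, K = as.integer(K),
                 variance_threshold = threshold),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> %d -> %d components (%.1f%% variance retained)\n",
    length(x$center), x$K,
    100 * sum(x$eigenvalues[seq_len(x$K)]) / sum(x$eigenvalues)))
  invisible(x)
}

#' Project a feature matrix through a fitted PCA
#'
#' Computes \code{S = ((F - center) / scale) \%*\% W}; labels are carried
#' through unchanged.
#'
#' @param F a \code{feature_matrix} with the same width the model was
#'   fitted on.
#' @param model a \code{pca_model}.
#' @return a \code{feature_matrix}, N x K.
#' @export
apply_pca <- function(F, model) {
  stopifnot(inherits(F, "feature_matrix"), inherits(model, "pca_model"))
  if (ncol(F$values) != length(model$center))
    stop("feature width ", ncol(F$values),
         " does not match the fitted width ", length(model$center))
  Z <- sweep(sweep(F$values, 2, model$center), 2, model$scale, "/")
  feature_matrix(Z %*% model$W, F$labels,
                 sprintf("pc%d", seq_len(model$K)))
}

# ---- serialization: key-value header + numeric block -----------------------

#' Write / read a feature matrix as plain text
#'
#' Format: a "miwave-features 1" magic line, key-value header
#' (\code{n}, \code{d}, \code{labels}, \code{features}), a blank line,
#' then one row of \%.17g numbers per trial (bit-exact round trip).
#'
#' @param fm a \code{feature_matrix}.
#' @param path file path.
#' @return \code{path} (writer) or a \code{feature_matrix} (reader).
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- tryCatch(file(path, "wt"),
                  error = function(e) stop("cannot write to: ", path),
                  warning = function(w) stop("cannot write to: ", path))
  on.exit(close(con))
  writeLines(c("miwave-features 1",
               sprintf("n: %d", nrow(fm$values)),
               sprintf("d: %d", ncol(fm$values)),
               paste0("labels: ", paste(fm$labels, collapse = ",")),
               paste0("features: ", paste(fm$feature_names, collapse = ",")),
               ""), con)
  writeLines(apply(matrix(sprintf("%.17g", fm$values), nrow = nrow(fm$values)),
                   1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("cannot read feature file: ", path)
  lines <- readLines(path)
  if (lines[1] != "miwave-features 1")
    stop("not a miwave feature file: ", path)
  blank <- which(lines == "")[1]
  kv <- strsplit(lines[2:(blank - 1)], ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  g <- function(k) vals[match(k, keys)]
  n <- as.integer(g("n")); d <- as.integer(g("d"))
  labels <- as.integer(strsplit(g("labels"), ",", fixed = TRUE)[[1]])
  fn <- strsplit(g("features"), ",", fixed = TRUE)[[1]]
  rows <- lines[(blank + 1):length(lines)]
  rows <- rows[nzchar(rows)]
  if (length(rows) != n) stop("expected ", n, " rows, found ", length(rows))
  X <- matrix(as.numeric(unlist(strsplit(trimws(rows), "[[:space:]]+"))),
              nrow = n, ncol = d, byrow = TRUE)
  feature_matrix(X, labels, fn)
}
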
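#' Build the binary nontarget-label channel (N)
#'
#' One row per scene, one column per vocabulary label, entry 1 when the
#' label occurs in the scene.
#'
#' @param labels Long data.frame with columns `scene_id` and `label`.
#' @param vocabulary Character vector of labels (or a named probability
#'   vector, in which case its names are used). Must cover every label in
#'   `labels`; column order follows the vocabulary.
#' @param scene_ids All scene ids (row order); defaults to the unique scene
#'   ids present in `labels`, but must be given explicitly when some scenes
#'   have empty label sets.
#' @return Binary matrix scenes x labels.
#' @export
#' @examples
#' labs <- data.frame(scene_id = c("s1", "s1", "s2"),
#'                    label = c("tree", "bench", "tree"))
#' build_nontarget_channel(labs, c("tree", "bench", "rock"))
build_nontarget_channel <- function(labels, vocabulary, scene_ids = NULL) {
  if (!is.character(vocabulary)) vocabulary <- names(vocabulary)
  if (is.null(vocabulary))
    stop_input("vocabulary must be a character vector or named vector")
  unknown <- setdiff(unique(labels$label), vocabulary)
  if (length(unknown))
    stop_input("label(s) not in vocabulary: ",
               paste(unknown, collapse = ", "))
  if (is.null(scene_ids)) scene_ids <- unique(labels$scene_id)
  out <- matrix(0, length(scene_ids), length(vocabulary),
                dimnames = list(scene_ids, vocabulary))
  if (nrow(labels))
    out[cbind(match(labels$scene_id, scene_ids),
              match(labels$label, vocabulary))] <- 1
  out
}

#' Fit a per-channel PCA for complexity equalization
#'
#' Projects one feature channel onto its first `k` principal components so
#' that channels of very different dimensionality (62-dim detector
#' summaries, ~36 binary labels, 512-dim coarse features) enter the
#' regression with equal complexity. Columns are z-standardized first by
#' default (channels mix binary and continuous scales); zero-variance
#' columns get unit scale to avoid division by zero and contribute nothing.
#'
#' @param x Channel matrix (scenes x dims).
#' @param k Number of components to retain (default 20). Must satisfy
#'   `k <= min(nrow(x) - 1, ncol(x))`.
#' @param standardize Z-standardize columns before the PCA.
#' @return Object of class `channel_pca` with elements `center`, `scale`,
#'   `rotation` (dims x k, orthonormal columns), `sdev`,
#'   `variance_captured`, `k`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' p <- fit_channel_pca(x, k = 3)
#' p$variance_captured
fit_channel_pca <- function(x, k = 20, standardize = TRUE) {
  x <- as.matrix(x)
  if (k < 1 || k > min(nrow(x) - 1, ncol(x)))
    stop_input("k must lie in [1, min(n_scenes - 1, dims)]")
  ctr <- colMeans(x)
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  sv <- svd(xs, nu = 0, nv = k)
  sdev <- sv$d / sqrt(nrow(x) - 1)
  rotation <- sv$v
  dimnames(rotation) <- list(colnames(x), NULL)
  structure(list(center = ctr, scale = scl, rotation = rotation,
                 sdev = sdev, k = as.integer(k),
                 variance_captured = sum(sdev[seq_len(k)]^2) / sum(sdev^2),
                 features = colnames(x)),
            class = "channel_pca")
}

#' Project a channel matrix onto fitted principal components
#'
#' @param object A [fit_channel_pca()] result.
#' @param newdata Matrix (or data.frame) containing the channel's feature
#'   columns; matched by name when available.
#' @param ... Unused.
#' @return Score matrix (scenes x k).
#' @export
predict.channel_pca <- function(object, newdata, ...) {
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing))
      stop_input("newdata lacks channel features: ",
                 paste(utils::head(missing, 3), collapse = ", "))
    newdata <- newdata[, object$features, drop = FALSE]
  }
  newdata <- if (is.data.frame(newdata)) data.matrix(newdata) else
    as.matrix(newdata)
  if (ncol(newdata) != nrow(object$rotation))
    stop_input("newdata has ", ncol(newdata), " columns; channel PCA was ",
               "fit on ", nrow(object$rotation))
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  xs %*% object$rotation
}

#' @export
print.channel_pca <- function(x, ...) {
  cat("Channel PCA:", nrow(x$rotation), "features ->", x$k,
      "components; variance captured",
      sprintf("%.1f%%", 100 * x$variance_captured), "\n")
  invisible(x)
}

#' Assemble a design matrix from a channel subset
#'
#' Horizontally concatenates the k-component projections of the requested
#' channels; the design for subset "NC" with k = 20 has 40 columns named
#' N1..N20, C1..C20. Designs for nested subsets are column-submatrices of
#' the full design.
#'
#' @param subset Channel subset: a string like `"NC"` or a character vector
#'   like `c("N", "C")`.
#' @param pcas Named list of fitted [fit_channel_pca()] objects (one per
#'   channel used).
#' @param channels Named list of channel matrices to project.
#' @return Design matrix (scenes x `k * length(subset)`).
#' @export
assemble_design <- function(subset, pcas, channels) {
  subset <- parse_subset(subset)
  if (!length(subset)) stop_input("channel subset must be non-empty")
  missing <- setdiff(subset, names(pcas))
  if (length(missing))
    stop_input("no fitted PCA for channel(s): ",
               paste(missing, collapse = ", "))
  parts <- lapply(subset, function(ch) {
    sc <- predict(pcas[[ch]], channels[[ch]])
    colnames(sc) <- sprintf("%s%d", ch, seq_len(ncol(sc)))
    sc
  })
  do.call(cbind, parts)
}

## "NC" -> c("N", "C"); validates channel names
parse_subset <- function(subset) {
  if (length(subset) == 1 && nchar(subset) > 1)
    subset <- strsplit(subset, "")[[1]]
  bad <- setdiff(subset, c("T", "N", "C"))
  if (length(bad))
    stop_input("unknown channel(s): ", paste(bad, collapse = ", "))
  subset
}
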
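#' Construct a secretion table
#'
#' Container for a multiplex immunoassay plate: a samples x analytes
#' concentration matrix (pg/mL) with a congruent below-range censoring
#' mask and a transform state (`raw`, `ln` or `z`).
#'
#' @param conc numeric matrix, samples in rows, analytes in columns
#'   (dimnames used as sample ids / analyte names).
#' @param censored logical matrix of the same shape; TRUE marks a
#'   below-range (censored) reading. Default: no censoring.
#' @param transform one of `"raw"`, `"ln"`, `"z"`.
#' @param sample_groups optional character vector of group labels per
#'   sample.
#' @param imputed has below-range imputation been applied.
#' @return object of class `secretion_table`.
#' @export
secretion_table <- function(conc, censored = NULL, transform = "raw",
                            sample_groups = NULL, imputed = FALSE) {
  stopifnot(is.matrix(conc))
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(conc), ncol(conc))
  }
  stopifnot(is.logical(censored), all(dim(censored) == dim(conc)))
  if (is.null(rownames(conc))) rownames(conc) <- sprintf("S%02d", seq_len(nrow(conc)))
  if (is.null(colnames(conc))) colnames(conc) <- sprintf("A%02d", seq_len(ncol(conc)))
  dimnames(censored) <- dimnames(conc)
  if (transform == "raw" && any(conc[!censored & !is.na(conc)] < 0)) {
    stop("raw concentrations must be non-negative")
  }
  structure(list(conc = conc, censored = censored, transform = transform,
                 sample_groups = sample_groups, imputed = imputed),
            class = "secretion_table")
}

#' Read / write a plate CSV with "OOR<" markers
#'
#' Plate exports mark below-range readings with an `OOR<` string in place
#' of a number; the reader parses these into the censoring mask (value NA)
#' and the writer emits them back.
#'
#' @param path CSV path (first column = sample id, remaining columns =
#'   analytes).
#' @param tab a [secretion_table()].
#' @return `read_secretion_csv`: a [secretion_table()];
#'   `write_secretion_csv`: `path`, invisibly.
#' @export
read_secretion_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  censored <- matrix(grepl("^\\s*OOR", vals), nrow(vals), ncol(vals))
  conc <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  conc[censored] <- NA_real_
  dimnames(conc) <- list(ids, colnames(vals))
  secretion_table(conc, censored = censored)
}

#' @rdname read_secretion_csv
#' @export
write_secretion_csv <- function(tab, path) {
  stopifnot(inherits(tab, "secretion_table"))
  out <- matrix(sprintf("%.15g", tab$conc), nrow(tab$conc), ncol(tab$conc))
  out[tab$censored] <- "OOR<"
  df <- data.frame(sample = rownames(tab$conc), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample", colnames(tab$conc))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute below-range readings with the analyte minimum
#'
#' Each censored (below-range) entry is replaced by the lowest uncensored
#' value observed for that analyte — the standard floor-substitution rule
#' for readings below the quantifiable standard curve. Analytes with every
#' entry censored cannot be imputed; they are left censored and flagged.
#' The operation is idempotent: the censoring mask is preserved and
#' imputation always re-derives the same column minima from the uncensored
#' entries.
#'
#' @param tab a raw [secretion_table()].
#' @return the table with censored entries filled; attribute
#'   `uncensorable` on the result lists analytes that stayed fully
#'   censored.
#' @export
impute_oor <- function(tab) {
  stopifnot(inherits(tab, "secretion_table"))
  if (tab$transform != "raw") stop("impute before transforming")
  conc <- tab$conc
  uncensorable <- character(0)
  for (j in seq_len(ncol(conc))) {
    obs <- conc[!tab$censored[, j], j]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) {
      uncensorable <- c(uncensorable, colnames(conc)[j])
      next
    }
    conc[tab$censored[, j], j] <- min(obs)
  }
  if (length(uncensorable) > 0) {
    warning("analyte(s) fully below range, left censored: ",
            paste(uncensorable, collapse = ", "))
  }
  out <- secretion_table(conc, censored = tab$censored,
                         transform = "raw",
                         sample_groups = tab$sample_groups, imputed = TRUE)
  attr(out, "uncensorable") <- uncensorable
  out
}

#' Natural-log or z-score transform of a plate
#'
#' `ln` applies the elementwise natural log (requires strictly positive
#' entries; zeros must first be lifted with `pseudo_floor`). `zscore`
#' standardizes each analyte over samples using the sample (n - 1)
#' standard deviation, giving per-analyte mean 0 and sd 1.
#'
#' @param tab an imputed [secretion_table()].
#' @param mode `"ln"` or `"zscore"`.
#' @param pseudo_floor optional positive floor added nowhere but applied as
#'   `pmax(conc, pseudo_floor)` before `ln`, for plates containing zeros.
#' @return transformed [secretion_table()] (`transform` set to `"ln"` /
#'   `"z"`).
#' @export
transform_secretion <- function(tab, mode = c("ln", "zscore"),
                                pseudo_floor = NULL) {
  stopifnot(inherits(tab, "secretion_table"))
  mode <- match.arg(mode)
  conc <- tab$conc
  if (mode == "ln") {
    if (tab$transform != "raw") stop("ln expects a raw (imputed) table")
    if (!is.null(pseudo_floor)) {
      stopifnot(pseudo_floor > 0)
      conc <- pmax(conc, pseudo_floor)
    }
    if (any(conc[!is.na(conc)] <= 0)) {
      stop("ln transform needs strictly positive entries; ",
           "supply a pseudo_floor for zeros")
    }
    out <- log(conc)
    state <- "ln"
  } else {
    out <- scale(conc, center = TRUE, scale = TRUE)
    attr(out, "scaled:center") <- NULL
    attr(out, "scaled:scale") <- NULL
    state <- "z"
  }
  secretion_table(out, censored = tab$censored, transform = state,
                  sample_groups = tab$sample_groups, imputed = tab$imputed)
}

#' Pairwise Pearson correlation between samples
#'
#' Pearson correlation coefficient for each pairwise combination of samples
#' (rows), over analytes. Symmetric with unit diagonal. A zero-variance
#' sample has no defined correlation; its row and column are reported as NA
#' and the sample is listed in the `flagged` attribute.
#'
#' @param tab a [secretion_table()] (any transform state) or numeric
#'   matrix, samples in rows.
#' @return samples x samples correlation matrix with attribute `flagged`.
#' @export
correlation_matrix <- function(tab) {
  x <- if (inherits(tab, "secretion_table")) tab$conc else tab
  if (ncol(x) < 2) stop("need at least two analytes for sample correlations")
  sds <- apply(x, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(x)))
  flagged <- rownames(x)[sds == 0]
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  attr(cc, "flagged") <- flagged
  cc
}

#' Hierarchical clustering of secretion profiles
#'
#' Agglomerative clustering of samples (rows) and analytes (columns) on
#' Euclidean distance — the heatmap-with-dendrograms view of a z-scored
#' plate. Default linkage is average; the leaf order is the deterministic
#' `stats::hclust` order (lower-index-first on ties).
#'
#' @param tab a z-transformed [secretion_table()] (other states allowed
#'   with a warning) or numeric matrix.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param k optional number of sample clusters to cut into.
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`
#'   (leaf orders as label vectors) and, when `k` is given,
#'   `row_clusters` (named cluster assignment from [stats::cutree()]).
#' @export
cluster_profiles <- function(tab, linkage = "average", k = NULL) {
  x <- if (inherits(tab, "secretion_table")) {
    if (tab$transform != "z") {
      warning("clustering a non-z-scored table; analytes on raw scales ",
              "dominate the Euclidean distance")
    }
    tab$conc
  } else tab
  rh <- stats::hclust(stats::dist(x), method = linkage)
  out <- list(row_hclust = rh,
              row_order = rownames(x)[rh$order])
  if (nrow(x) >= 2 && ncol(x) >= 2) {
    ch <- stats::hclust(stats::dist(t(x)), method = linkage)
    out$col_hclust <- ch
    out$col_order <- colnames(x)[ch$order]
  }
  if (!is.null(k)) out$row_clusters <- stats::cutree(rh, k = k)
  out
}

#' PCA of secretion profiles
#'
#' Principal component analysis of the samples x analytes matrix (analytes
#' centered; not scaled — z-score first if analytes should carry equal
#' weight). Components are orthonormal; explained-variance fractions are
#' non-increasing and sum to at most 1.
#'
#' @param tab a [secretion_table()] or numeric matrix, samples in rows.
#' @param n_components number of components to keep (truncated to the
#'   matrix rank, with a warning).
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained` (variance fractions).
#' @export
pca_scores <- function(tab, n_components = 2) {
  x <- if (inherits(tab, "secretion_table")) tab$conc else tab
  if (nrow(x) < 2) stop("PCA needs at least two samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncated")
    n_components <- rank
  }
  keep <- seq_len(n_components)
  list(scores = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[keep])
}

#' Per-analyte positivity thresholds from a background population
#'
#' Default device-style thresholds: mean + `k` standard deviations of a
#' declared background (non-secreting) population, per analyte.
#'
#' @param background numeric matrix (background cells x analytes).
#' @param k number of standard deviations above the background mean.
#' @return named numeric vector of thresholds.
#' @export
background_thresholds <- function(background, k = 2) {
  colMeans(background) + k * apply(background, 2, stats::sd)
}

#' Classify single-cell secretors
#'
#' A cell is an active secretor iff at least one analyte exceeds its
#' positivity threshold. Polyfunctionality is the count of analytes above
#' threshold per cell (cells secreting two or more are conventionally
#' called polyfunctional).
#'
#' @param mat numeric matrix, cells x analytes.
#' @param thresholds named per-analyte thresholds covering every column of
#'   `mat` (an error lists any analyte without one).
#' @return list with `secretor` (logical per cell), `polyfunctionality`
#'   (integer per cell), `fraction` (secretors / cells) and
#'   `polyfunctional_fraction` (cells with >= 2 positive analytes).
#' @export
classify_secretors <- function(mat, thresholds) {
  stopifnot(is.matrix(mat))
  missing_thr <- setdiff(colnames(mat), names(thresholds))
  if (is.null(colnames(mat))) {
    if (length(thresholds) != ncol(mat)) {
      stop("unnamed matrix: thresholds must have one entry per column")
    }
  } else if (length(missing_thr) > 0) {
    stop("no positivity threshold for analyte(s): ",
         paste(missing_thr, collapse = ", "))
  }
  thr <- if (is.null(colnames(mat))) thresholds else thresholds[colnames(mat)]
  above <- sweep(mat, 2, thr, ">")
  poly <- as.integer(rowSums(above))
  secretor <- poly >= 1L
  list(secretor = secretor, polyfunctionality = poly,
       fraction = mean(secretor),
       polyfunctional_fraction = mean(poly >= 2L))
}
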
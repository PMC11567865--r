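# Preprocessing of raw subject-by-peptide tables: log2/median centering,
# merging of highly correlated peptide pairs, nonparanormal transform,
# pairwise-complete correlation with PSD repair.

#' Log2-transform and median-center columns
#'
#' Light:heavy SRM ratios are strictly positive; each column is
#' log2-transformed and shifted so its median over non-missing entries is 0.
#'
#' @param raw_ratios n x p numeric matrix of positive ratios (NA allowed).
#' @return matrix of the same shape; every column has median 0.
#' @export
log2_median_center <- function(raw_ratios) {
  X <- as.matrix(raw_ratios)
  bad <- which(!is.na(X) & X <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive ratio at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  L <- log2(X)
  meds <- apply(L, 2, median, na.rm = TRUE)
  sweep(L, 2, meds, "-")
}

#' Merge highly correlated peptide pairs
#'
#' Two peptides designed to detect the same protein are merged into their
#' per-subject mean when their pairwise-complete Pearson correlation reaches
#' `r_threshold`. When one member is missing the mean of available values
#' is used. Pairs below threshold are kept as separate columns.
#'
#' @param X n x p matrix with column names.
#' @param candidate_pairs data frame or 2/3-column matrix with columns
#'   `a`, `b` (existing column names) and optionally `merged_id`.
#' @param r_threshold Pearson correlation cutoff (default 0.8).
#' @return list with `X` (merged matrix) and `plan` (data frame recording
#'   which pairs merged, their correlations, and merged column name).
#' @export
merge_correlated_pairs <- function(X, candidate_pairs, r_threshold = 0.8) {
  X <- as.matrix(X)
  cp <- as.data.frame(candidate_pairs, stringsAsFactors = FALSE)
  names(cp)[1:2] <- c("a", "b")
  if (is.null(cp$merged_id)) cp$merged_id <- paste(cp$a, cp$b, sep = ".")
  missing_cols <- setdiff(c(cp$a, cp$b), colnames(X))
  if (length(missing_cols))
    stop("candidate pair references unknown column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(c(cp$a, cp$b)))
    stop("a column may appear in at most one candidate pair")
  cp$r <- vapply(seq_len(nrow(cp)), function(i) {
    suppressWarnings(cor(X[, cp$a[i]], X[, cp$b[i]],
                         use = "pairwise.complete.obs"))
  }, numeric(1))
  cp$merged <- !is.na(cp$r) & cp$r >= r_threshold
  drop <- character()
  for (i in which(cp$merged)) {
    m <- rowMeans(X[, c(cp$a[i], cp$b[i]), drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA
    X <- cbind(X, m)
    colnames(X)[ncol(X)] <- cp$merged_id[i]
    drop <- c(drop, cp$a[i], cp$b[i])
  }
  if (length(drop)) X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  list(X = X, plan = cp, r_threshold = r_threshold)
}

#' Nonparanormal (rank-based Gaussian) transform
#'
#' Columnwise semiparametric Gaussianization: a value with (average) rank k
#' among the m non-missing entries of its column maps to
#' `qnorm(k / (m + 1))`, then the column is rescaled to unit sample
#' standard deviation. The transform is invariant to strictly increasing
#' marginal distortions. The `"truncation"` variant instead applies the
#' Winsorized empirical CDF `(k - 1/2)/m` clipped to
#' `[delta, 1 - delta]` with `delta = 1/(4 m^(1/4) sqrt(pi log m))`.
#'
#' @param X n x p numeric matrix (NA allowed).
#' @param variant `"shrinkage"` (default) or `"truncation"`.
#' @return matrix of the same shape with Gaussianized columns.
#' @export
nonparanormal_transform <- function(X, variant = c("shrinkage", "truncation")) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    obs <- !is.na(x)
    m <- sum(obs)
    if (length(unique(x[obs])) < 2)
      stop(sprintf("column %s is constant; cannot Gaussianize",
                   colnames(X)[j] %||% j))
    r <- rank(x[obs], ties.method = "average")
    if (variant == "shrinkage") {
      z <- qnorm(r / (m + 1))
    } else {
      delta <- 1 / (4 * m^0.25 * sqrt(pi * log(m)))
      u <- pmin(pmax((r - 0.5) / m, delta), 1 - delta)
      z <- qnorm(u)
    }
    out[obs, j] <- z / sd(z)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise-complete correlation with PSD repair
#'
#' Pearson correlations computed over jointly observed rows for every
#' column pair (pairwise deletion). If the resulting matrix is not positive
#' semidefinite - routine at realistic missingness - it is repaired by
#' clipping eigenvalues at `1e-8` and re-normalizing to unit diagonal, and
#' the repair is flagged.
#'
#' @param X n x p matrix (NA allowed).
#' @param min_joint minimum jointly observed rows per pair (default 10).
#' @return list with `R` (p x p correlation), `n_effective` (minimum
#'   pairwise-complete count), `n_pairwise` (full count matrix),
#'   `psd_repaired` (logical).
#' @export
pairwise_complete_correlation <- function(X, min_joint = 10) {
  X <- as.matrix(X)
  obs <- !is.na(X)
  counts <- crossprod(obs)
  off <- counts[upper.tri(counts)]
  if (any(off < min_joint)) {
    idx <- which(upper.tri(counts) & counts < min_joint, arr.ind = TRUE)[1, ]
    stop(sprintf("columns %s and %s share only %d observed rows (< %d)",
                 colnames(X)[idx[1]] %||% idx[1],
                 colnames(X)[idx[2]] %||% idx[2],
                 counts[idx[1], idx[2]], min_joint))
  }
  R <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    lam <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    diag(R) <- 1
    R <- (R + t(R)) / 2
    repaired <- TRUE
    message("pairwise-complete correlation was not PSD; ",
            "repaired by eigenvalue clipping")
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  list(R = R, n_effective = as.integer(min(off)),
       n_pairwise = counts, psd_repaired = repaired)
}

#' Read a subject-by-variable table
#'
#' CSV/TSV with a header of node ids; missing entries empty or "NA". An
#' optional `subject_id` column is split off.
#'
#' @param path file path (delimiter inferred from extension).
#' @return list with `X` (numeric matrix) and `subject_id`.
#' @export
read_subject_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  sid <- NULL
  if ("subject_id" %in% names(d)) {
    sid <- as.character(d$subject_id)
    d$subject_id <- NULL
  }
  list(X = as.matrix(d), subject_id = sid %||% as.character(seq_len(nrow(d))))
}
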
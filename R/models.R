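# Network-informed regressions: module-cognition associations adjusted
# for demographics, and three-way moderation of tangle burden by
# p-tau x module level x physical activity.

#' Per-subject module score
#'
#' Rowwise mean of the member columns of a module; missing values are
#' skipped (a subject missing every member gets NA).
#'
#' @param X subject-by-variable matrix with column names.
#' @param assignment named module assignment (node_id -> module id).
#' @param module_id which module.
#' @return numeric vector, one score per subject.
#' @export
module_score <- function(X, assignment, module_id) {
  members <- names(assignment)[assignment == module_id]
  members <- intersect(members, colnames(X))
  if (!length(members)) stop("module ", module_id, " has no member columns")
  s <- rowMeans(X[, members, drop = FALSE], na.rm = TRUE)
  s[is.nan(s)] <- NA
  s
}

#' Module-cognition association adjusted for demographics
#'
#' One linear model per module:
#' `cognition ~ module score + age + sex + education`, rows with missing
#' values listwise-deleted. Returns the module-score coefficient row per
#' module (estimate, SE, t, p, n).
#'
#' @param module_scores matrix/data frame, one column per module.
#' @param cognition_z global cognition z-score per subject.
#' @param covariates data frame with `age`, `sex`, `education`.
#' @return data frame, one row per module.
#' @export
module_cognition_association <- function(module_scores, cognition_z,
                                         covariates) {
  module_scores <- as.matrix(module_scores)
  need <- c("age", "sex", "education")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariates lack: ", paste(miss, collapse = ", "))
  for (v in need)
    if (var(covariates[[v]], na.rm = TRUE) == 0)
      stop("zero-variance covariate: ", v)
  out <- lapply(seq_len(ncol(module_scores)), function(j) {
    d <- data.frame(y = cognition_z, score = module_scores[, j],
                    covariates[need])
    d <- d[complete.cases(d), , drop = FALSE]
    if (nrow(d) < 30) stop("fewer than 30 complete rows for module ", j)
    fit <- lm(y ~ score + age + sex + education, data = d)
    if (fit$rank < 5)
      stop("rank-deficient design for module ", j, "; collinear columns: ",
           paste(names(which(is.na(coef(fit)))), collapse = ", "))
    cf <- summary(fit)$coefficients["score", ]
    data.frame(module = colnames(module_scores)[j] %||% j,
               estimate = cf[1], std_error = cf[2], t = cf[3], p = cf[4],
               n = nrow(d), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Three-way moderation of tangle burden
#'
#' Single OLS model of tangle pathology on two p-tau peptides, a synaptic
#' module score and continuous physical activity, with all implied
#' two-way products and the two three-way products
#' (`ptau x module x activity` for each p-tau). Predictors are
#' mean-centered before products are formed, so lower-order coefficients
#' are effects at average levels; the three-way coefficients are
#' centering-invariant. Rows with any missing value are dropped.
#'
#' @param tangles outcome: cellular tangle pathology burden.
#' @param ptau_1,ptau_2 the two p-tau peptide levels.
#' @param module_score synaptic module score (see [module_score()]).
#' @param activity continuous daily activity counts.
#' @param covariates optional data frame of additional adjustment columns.
#' @return object of class `moderation_fit`: coefficient table
#'   (estimate, SE, t, p), `n`, `formula`.
#' @export
threeway_moderation <- function(tangles, ptau_1, ptau_2, module_score,
                                activity, covariates = NULL) {
  d <- data.frame(tangles = tangles, ptau_1 = ptau_1, ptau_2 = ptau_2,
                  module = module_score, activity = activity)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 100) stop("fewer than 100 complete rows")
  if (var(d$activity) == 0)
    stop("activity is constant; moderation not identifiable")
  for (v in c("ptau_1", "ptau_2", "module", "activity"))
    d[[v]] <- d[[v]] - mean(d[[v]])
  rhs <- paste(
    "ptau_1 + ptau_2 + module + activity",
    "+ ptau_1:module + ptau_1:activity + ptau_2:module + ptau_2:activity",
    "+ module:activity + ptau_1:module:activity + ptau_2:module:activity")
  extra <- setdiff(names(d), c("tangles", "ptau_1", "ptau_2", "module",
                               "activity"))
  if (length(extra)) rhs <- paste(rhs, "+", paste(extra, collapse = " + "))
  f <- as.formula(paste("tangles ~", rhs))
  fit <- lm(f, data = d)
  if (any(is.na(coef(fit)))) stop("rank-deficient moderation design")
  cf <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    std_error = cf[, 2], t = cf[, 3], p = cf[, 4],
                    row.names = NULL)
  structure(list(coefficients = tab, n = nrow(d),
                 formula = deparse(f), fit = fit),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("moderation_fit (n = %d): %s\n", x$n, x$formula))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' @importFrom stats as.formula
NULL
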
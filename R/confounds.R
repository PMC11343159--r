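# Confound regression: design construction and OLS residualization.
#
# All behavior and imaging matrices are residualized against demographic
# covariates before entering the PLS; the covariate set is modality
# specific (FC adds head-motion and image-intensity summaries, thickness
# and volume add intracranial volume, surface area adds total surface
# area). Categorical covariates are reference-coded so the design stays
# full rank with an intercept.

baseCovariates <- c("age", "age2", "sex", "site", "ethnicity")

modalityExtras <- function(modality) {
  switch(modality,
         fc = ,
         taskMID = ,
         taskENback = ,
         taskSST = c("meanFD", "meanDVARS"),
         thickness = ,
         volume = "icv",
         area = "totalSA",
         behavior = ,
         tractFA = ,
         tractMD = character(0),
         stop("unknown modality '", modality, "'"))
}

#' Build a modality-specific confound design matrix
#'
#' The base design holds an intercept, age, age squared, a sex indicator,
#' and reference-coded site and ethnicity indicator blocks. Functional
#' connectivity (rest and task) additionally adjusts for mean framewise
#' displacement and mean DVARS; thickness and volume for total intracranial
#' volume; surface area for total surface area; behavior and tract metrics
#' use the base set only.
#'
#' @param cohort covariate data.frame (one row per participant) with
#'   columns `age`, `age2`, `sex`, `site`, `ethnicity` and any extras the
#'   modality requires.
#' @param modality one of `"behavior"`, `"area"`, `"thickness"`,
#'   `"volume"`, `"fc"`, `"taskMID"`, `"taskENback"`, `"taskSST"`,
#'   `"tractFA"`, `"tractMD"`.
#' @return numeric design matrix with named columns, full column rank.
#' @export
buildDesign <- function(cohort, modality) {
  covs <- c(baseCovariates, modalityExtras(modality))
  missingCov <- setdiff(covs, colnames(cohort))
  if (length(missingCov))
    stop("cohort table lacks covariate(s): ",
         paste(missingCov, collapse = ", "))
  for (cv in covs) {
    bad <- is.na(cohort[[cv]])
    if (any(bad))
      stop("missing covariate '", cv, "' for participant(s): ",
           paste(rownames(cohort)[bad], collapse = ", "))
  }
  n <- nrow(cohort)
  X <- matrix(1, n, 1, dimnames = list(rownames(cohort), "intercept"))
  for (cv in covs) {
    v <- cohort[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, matrix(v, ncol = 1, dimnames = list(NULL, cv)))
    } else {
      v <- droplevels(factor(v))
      if (nlevels(v) >= 2) {
        D <- stats::model.matrix(~v)[, -1, drop = FALSE]
        colnames(D) <- paste0(cv, levels(v)[-1])
        X <- cbind(X, D)
      } # single level: block empty, design unchanged
    }
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  X
}

#' Residualize a feature matrix against a design
#'
#' Replaces each column by its ordinary-least-squares residual on the
#' design. Residual columns are orthogonal to every design column and,
#' with an intercept in the design, have mean zero. The operation is
#' idempotent.
#'
#' @param matrix participants x features numeric matrix; rows must align
#'   with the design.
#' @param design design matrix from [buildDesign()] (full column rank).
#' @return matrix of residuals with the input's dimnames.
#' @export
#' @examples
#' X <- cbind(1, c(0, 1, 2, 3))
#' residualize(matrix(c(1, 2, 2, 4), 4, 1), X)
residualize <- function(matrix, design) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (nrow(matrix) != nrow(design))
    stop("matrix and design have different numbers of rows")
  if (!is.null(rownames(matrix)) && !is.null(rownames(design)) &&
      !identical(rownames(matrix), rownames(design)))
    stop("matrix and design rows are not aligned")
  q <- qr(design)
  if (q$rank < ncol(design))
    stop("design matrix is rank deficient")
  res <- qr.resid(q, matrix)
  dimnames(res) <- dimnames(matrix)
  res
}

#' Drop zero-variance behavior items
#'
#' Items that are constant in the given subsample carry no information and
#' would break downstream z-scoring; they are removed before
#' residualization, separately within each subsample.
#'
#' @param behavior participants x items matrix.
#' @return list with `behavior` (retained columns) and `dropped`
#'   (character vector of removed item labels).
#' @export
dropDegenerateItems <- function(behavior) {
  v <- apply(behavior, 2, var)
  dropped <- colnames(behavior)[v == 0]
  if (length(dropped) == ncol(behavior))
    warning("all ", length(dropped), " items are constant")
  list(behavior = behavior[, v > 0, drop = FALSE], dropped = dropped)
}
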
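# Accuracy statistics for comparing estimated trait values P against
# ground-truth observations O.

#' Mean bias error
#'
#' `MBE = (1/N) * sum(P - O)`; the sign gives the direction of the bias
#' (positive = overestimation).
#'
#' @param estimated numeric vector of estimates P.
#' @param observed numeric vector of ground-truth values O (same length).
#' @return The mean bias error.
#' @examples
#' mbe(c(2, 4), c(1, 2))  # 1.5
#' @export
mbe <- function(estimated, observed) {
  .checkPaired(estimated, observed)
  mean(estimated - observed)
}

#' Root mean square error
#'
#' `RMSE = sqrt(sum((P - O)^2) / N)`, the spread of the residuals.
#'
#' @inheritParams mbe
#' @return The root mean square error (always `>= abs(mbe)`).
#' @export
rmse <- function(estimated, observed) {
  .checkPaired(estimated, observed)
  sqrt(mean((estimated - observed)^2))
}

#' Coefficient of determination
#'
#' The squared Pearson correlation,
#' `R^2 = ((n*sum(xy) - sum(x)*sum(y))^2) /
#' ((n*sum(x^2) - sum(x)^2) * (n*sum(y^2) - sum(y)^2))`.
#' Undefined (an error) when either series is constant.
#'
#' @inheritParams mbe
#' @return R^2 in `[0, 1]`.
#' @export
rSquared <- function(estimated, observed) {
  .checkPaired(estimated, observed)
  x <- estimated; y <- observed
  n <- length(x)
  if (n < 2L) stop("R^2 requires at least two pairs")
  sx <- n * sum(x^2) - sum(x)^2
  sy <- n * sum(y^2) - sum(y)^2
  if (sx <= 0 || sy <= 0)
    stop("R^2 is undefined for a constant series")
  ((n * sum(x * y) - sum(x) * sum(y))^2) / (sx * sy)
}

.checkPaired <- function(estimated, observed) {
  if (!length(estimated)) stop("empty series")
  if (length(estimated) != length(observed))
    stop("estimated and observed must have equal length")
  if (anyNA(estimated) || anyNA(observed))
    stop("series must not contain NA")
}

#' Benchmark report: accuracy metrics per trait
#'
#' Joins estimated and ground-truth tables by `file_name` and computes RMSE,
#' MBE and R^2 for every shared numeric trait column. Estimate files without
#' a truth row (and vice versa) are excluded with a warning.
#'
#' @param estimates data.frame with a `file_name` column and trait columns.
#' @param truth data.frame with a `file_name` column and matching trait
#'   columns.
#' @param traits optional character vector restricting the traits compared.
#' @return A data.frame with columns `trait`, `n`, `rmse`, `mbe`,
#'   `r_squared`.
#' @export
benchmarkReport <- function(estimates, truth, traits = NULL) {
  stopifnot("file_name" %in% names(estimates), "file_name" %in% names(truth))
  unmatched <- setdiff(union(estimates$file_name, truth$file_name),
                       intersect(estimates$file_name, truth$file_name))
  if (length(unmatched))
    warning("excluded files without a matching pair: ",
            paste(unmatched, collapse = ", "))
  merged <- merge(estimates, truth, by = "file_name",
                  suffixes = c(".est", ".obs"))
  shared <- intersect(names(estimates), names(truth))
  shared <- setdiff(shared, "file_name")
  shared <- shared[vapply(shared, function(tr)
    is.numeric(truth[[tr]]), logical(1))]
  if (!is.null(traits)) shared <- intersect(shared, traits)
  rows <- lapply(shared, function(tr) {
    p <- merged[[paste0(tr, ".est")]]
    o <- merged[[paste0(tr, ".obs")]]
    ok <- is.finite(p) & is.finite(o)
    data.frame(trait = tr, n = sum(ok),
               rmse = if (any(ok)) rmse(p[ok], o[ok]) else NA_real_,
               mbe = if (any(ok)) mbe(p[ok], o[ok]) else NA_real_,
               r_squared = if (sum(ok) >= 2L) rSquared(p[ok], o[ok])
                           else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
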
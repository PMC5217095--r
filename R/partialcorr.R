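#' Full-partial correlation of two variables
#'
#' Pearson correlation of the OLS residuals of `y` and `x` after regressing
#' both on the shared covariates (with intercept). With no covariates this is
#' the plain Pearson correlation. Significance uses a t-test with
#' n - q - 2 degrees of freedom, where q counts the covariate design columns
#' (a 2-level factor contributes one).
#'
#' @param data Data frame.
#' @param y,x Column names of the two variables.
#' @param covariates Character vector of covariate columns (may be empty).
#' @return One-row tibble: `r`, `statistic`, `p.value`, `df`, `n`.
#' @export
partial_correlation <- function(data, y, x, covariates = character()) {
  d <- as.data.frame(data[, c(y, x, covariates), drop = FALSE])
  if (!all(complete.cases(d))) abort("missing values in inputs")
  X <- covariate_matrix(d, covariates)
  yv <- as.numeric(d[[y]]); xv <- as.numeric(d[[x]])
  ry <- stats::lm.fit(X, yv)$residuals
  rx <- stats::lm.fit(X, xv)$residuals
  tol_y <- 1e-10 * max(1, abs(yv)); tol_x <- 1e-10 * max(1, abs(xv))
  if (sd(ry) < tol_y || sd(rx) < tol_x)
    abort("constant residuals: partial correlation undefined")
  n <- nrow(d); q <- ncol(X) - 1
  r <- cor(ry, rx)
  df <- n - q - 2
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  tibble(r = r, statistic = tstat, p.value = 2 * pt(-abs(tstat), df),
         df = df, n = n)
}

covariate_matrix <- function(d, covariates) {
  if (length(covariates) == 0) return(matrix(1, nrow(d), 1))
  for (cv in covariates)
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = " + "))),
    data = d)
}

#' Vertex-wise partial-correlation map with FDR
#'
#' Computes the full-partial correlation of each vertex's thickness with a
#' per-participant variable (typically all-task FD), controlling for shared
#' covariates (typically age and gender), and applies Benjamini-Hochberg FDR
#' across the whole map. Vertices with constant residuals are excluded from
#' the map and the FDR family; their count is recorded.
#'
#' @param thickness `mf_thickness` object or participants-by-vertices matrix
#'   with participant IDs as rownames.
#' @param data Data frame with `participant_id`, the `x` variable and the
#'   covariates; rows are matched to the thickness matrix by ID.
#' @param x Column correlated against thickness; default `"fd_all_task"`.
#' @param covariates Covariate columns; default `c("age", "gender")`.
#' @return Object of class `mf_vertex_map`; [tidy()] returns the per-vertex
#'   tibble (`vertex`, `hemisphere`, `r`, `p`, `q`).
#' @export
vertexwise_partial_corr <- function(thickness, data, x = "fd_all_task",
                                    covariates = c("age", "gender")) {
  th <- if (inherits(thickness, "mf_thickness")) thickness else
    new_thickness(thickness)
  mat <- th$thickness
  ids <- rownames(mat)
  if (!all(ids %in% data$participant_id))
    abort("data lacks rows for some thickness participants")
  d <- as.data.frame(data[match(ids, data$participant_id), , drop = FALSE])
  X <- covariate_matrix(d, covariates)
  n <- nrow(mat); q <- ncol(X) - 1
  if (n <= q + 2) abort("too few participants for the covariate set")

  # residualize x and every vertex column via one projection
  H <- X %*% solve(crossprod(X), t(X))
  rx <- as.numeric(d[[x]]) - H %*% as.numeric(d[[x]])
  RT <- mat - H %*% mat
  rx_ss <- sum(rx^2)
  col_ss <- colSums(RT^2)
  # residual sums of squares at numerical-noise scale mean a constant column
  tol <- n * (1e-10 * max(1, max(abs(mat))))^2
  ok <- col_ss > tol & rx_ss > tol
  r <- rep(NA_real_, ncol(mat))
  r[ok] <- as.numeric(crossprod(rx, RT[, ok, drop = FALSE])) /
    sqrt(rx_ss * col_ss[ok])
  df <- n - q - 2
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  qv <- rep(NA_real_, length(p))
  qv[ok] <- p.adjust(p[ok], method = "BH")

  structure(list(
    map = tibble(vertex = seq_len(ncol(mat)), hemisphere = th$hemisphere,
                 r = r, p = p, q = qv),
    n = n, df = df, x = x, covariates = covariates,
    n_excluded = sum(!ok)
  ), class = "mf_vertex_map")
}

#' @export
print.mf_vertex_map <- function(x, ...) {
  cat(sprintf("<mf_vertex_map> %d vertices (n = %d): %s ~ thickness | %s; %d with q < 0.05%s\n",
              nrow(x$map), x$n, x$x, paste(x$covariates, collapse = " + "),
              sum(x$map$q < 0.05, na.rm = TRUE),
              if (x$n_excluded > 0)
                sprintf("; %d constant vertices excluded", x$n_excluded)
              else ""))
  invisible(x)
}

#' @export
tidy.mf_vertex_map <- function(x, ...) x$map

#' @export
glance.mf_vertex_map <- function(x, ...) {
  tibble(n = x$n, n_vertices = nrow(x$map),
         n_significant = sum(x$map$q < 0.05, na.rm = TRUE),
         n_excluded = x$n_excluded,
         median_r = median(x$map$r, na.rm = TRUE))
}

#' @describeIn vertexwise_partial_corr Empirical CDF of the vertex-wise
#'   correlations.
#' @param object `mf_vertex_map` object.
#' @param ... Unused.
#' @export
autoplot.mf_vertex_map <- function(object, ...) {
  df <- object$map[!is.na(object$map$r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = sprintf("partial r (thickness ~ %s)", object$x),
                  y = "cumulative proportion of vertices")
}
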
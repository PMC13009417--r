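#' Restricted cubic spline basis
#'
#' Builds the natural (restricted) cubic spline basis in the truncated-power
#' parameterization: piecewise cubic between the knots and constrained to be
#' linear beyond the boundary knots. With `k` knots the basis has `k - 1`
#' columns: the linear term plus `k - 2` restricted cubic terms.
#'
#' The `j`-th cubic column (for interior knot `t_j`, `j = 1..k-2`) is
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'       + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2,}
#' the usual construction with columns scaled by the squared boundary span so
#' all terms are on roughly the scale of `x`.
#'
#' @param x numeric vector of evaluation points (here: follow-up month).
#' @param knots optional numeric vector of knot locations (sorted, distinct).
#'   When `NULL`, knots are placed at `knot_quantiles` of `x`.
#' @param n_knots number of knots when `knots` is `NULL` (default 4).
#' @param knot_quantiles quantiles of `x` used for default knot placement.
#' @return numeric matrix with `length(x)` rows and `k - 1` columns, with the
#'   knots attached as `attr(, "knots")`.
#' @examples
#' b <- rcs_basis(0:24, knots = c(1, 6, 12, 24))
#' ncol(b) # 3
#' @export
rcs_basis <- function(x, knots = NULL, n_knots = 4L,
                      knot_quantiles = c(0.05, 0.35, 0.65, 0.95)) {
  if (is.null(knots)) {
    n_knots <- check_count(n_knots, "n_knots", min = 3L)
    if (length(knot_quantiles) != n_knots) {
      stop2("'knot_quantiles' must have length n_knots (", n_knots, ")")
    }
    if (length(unique(x)) < n_knots) {
      stop2("fewer distinct values (", length(unique(x)),
            ") than knots (", n_knots, "); use fewer knots")
    }
    knots <- unname(quantile(x, knot_quantiles, type = 7, names = FALSE))
  }
  knots <- sort(unique(as.numeric(knots)))
  k <- length(knots)
  if (k < 3L) stop2("need at least 3 distinct knots, got ", k)
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- x
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  span2 <- (tk - knots[1L])^2
  cub <- function(u) pmax(u, 0)^3
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (cub(x - tj) -
                        cub(x - tk1) * (tk - tj) / (tk - tk1) +
                        cub(x - tk) * (tk1 - tj) / (tk - tk1)) / span2
  }
  colnames(out) <- paste0("rcs", seq_len(k - 1L))
  attr(out, "knots") <- knots
  out
}
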
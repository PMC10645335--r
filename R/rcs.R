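#' Restricted cubic spline basis (4 knots, Harrell convention)
#'
#' Truncated-power restricted cubic spline with knots t1..t4: a linear term
#' plus two nonlinear terms
#' \deqn{s_j(x) = [(x - t_j)_+^3 - (x - t_3)_+^3 (t_4 - t_j)/(t_4 - t_3)
#'   + (x - t_4)_+^3 (t_3 - t_j)/(t_4 - t_3)] / (t_4 - t_1)^2}
#' for j = 1, 2, normalized by the squared boundary-knot span.  The basis
#' is linear beyond the boundary knots and the nonlinear terms vanish at
#' and below the first knot.  Automatic knots sit at the 5th/35th/65th/95th
#' percentiles of the covariate.
#'
#' @param x Covariate values.
#' @param knots Four increasing knot locations, or `"auto"`.
#' @param name Column-name stem for the design columns.
#' @return Object of class `rcs_basis`: list with `knots`, `name`, and
#'   `design` (matrix `name`, `name_s1`, `name_s2`); use [predict()] to
#'   evaluate the basis at new values.
#' @export
rcs_basis <- function(x, knots = "auto", name = "x") {
  if (identical(knots, "auto")) {
    if (length(unique(x)) < 4L)
      stop("need >= 4 distinct values for automatic knots")
    knots <- unname(stats::quantile(x, c(0.05, 0.35, 0.65, 0.95), type = 7))
  }
  knots <- sort(as.numeric(knots))
  if (length(knots) != 4L || anyDuplicated(knots))
    stop("need 4 distinct knots")
  obj <- structure(list(knots = knots, name = name), class = "rcs_basis")
  obj$design <- predict(obj, x)
  obj
}

#' @export
predict.rcs_basis <- function(object, newx, ...) {
  k <- object$knots
  span2 <- (k[4L] - k[1L])^2
  cub <- function(u) pmax(newx - u, 0)^3
  s <- matrix(0, length(newx), 2L)
  for (j in 1:2)
    s[, j] <- (cub(k[j]) - cub(k[3L]) * (k[4L] - k[j]) / (k[4L] - k[3L]) +
                 cub(k[4L]) * (k[3L] - k[j]) / (k[4L] - k[3L])) / span2
  m <- cbind(newx, s)
  colnames(m) <- paste0(object$name, c("", "_s1", "_s2"))
  m
}
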
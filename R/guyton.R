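#' Saturating cardiac function curve
#'
#' Monotone non-decreasing Starling-form family used for the cardiac side of
#' the venous-return diagram: `flow(rap) = f_max * (1 - exp(-(rap - rap0)/tau))`
#' clipped below at 0. `f_max` is the plateau flow (L/min), `rap0` the right
#' atrial pressure at which flow starts (mmHg), `tau` the rise constant
#' (mmHg).
#'
#' @param rap right atrial pressure, mmHg (vectorised)
#' @param params list with elements `f_max`, `rap0`, `tau`
#' @return Flow in L/min, same length as `rap`.
#' @export
cardiac_function_curve <- function(rap, params) {
  check_scalar_num(params$f_max, "f_max", lower = 0, strict_lower = TRUE)
  check_scalar_num(params$tau, "tau", lower = 0, strict_lower = TRUE)
  pmax(0, params$f_max * (1 - exp(-(rap - params$rap0) / params$tau)))
}

#' Venous-return / cardiac-function diagram with operating point
#'
#' Constructs the Guytonian diagram: a venous-return line
#' `VR(rap) = (MCFP - rap) / Rv`, affine and strictly decreasing with its
#' zero crossing at `rap = MCFP`, and a saturating cardiac function curve.
#' The operating point is the intersection, solved by bisection on
#' `VR(rap) - cardiac(rap)` to a tolerance of 1e-9 mmHg. If the two curves
#' do not cross on the grid the diagram is returned with a `NULL` operating
#' point and `no_solution = TRUE`.
#'
#' @param mcfp mean circulatory filling pressure, mmHg
#' @param rv venous resistance, mmHg per L/min (> 0)
#' @param cardiac_params parameters for [cardiac_function_curve()], or a
#'   function of `rap` returning flow
#' @param rap_grid grid of right atrial pressures; defaults to 201 points on
#'   `[rap_min, mcfp]`
#' @param rap_min lower end of the default grid (mmHg)
#' @param condition_label free-text label (e.g. "baseline", "epinephrine on")
#' @param tol bisection tolerance, mmHg
#' @return Object of class `guyton_diagram`: `rap_grid`, `vr_line`,
#'   `cardiac_curve`, `operating_point` (list `rap`, `flow` or `NULL`),
#'   `no_solution`, `mcfp`, `rv`, `condition_label`.
#' @export
guyton_diagram <- function(mcfp, rv, cardiac_params = list(f_max = 6, rap0 = -4, tau = 4),
                           rap_grid = NULL, rap_min = 0,
                           condition_label = "baseline", tol = 1e-9) {
  check_scalar_num(rv, "rv", lower = 0, strict_lower = TRUE)
  check_scalar_num(mcfp, "mcfp")
  cardiac <- if (is.function(cardiac_params)) cardiac_params
             else function(rap) cardiac_function_curve(rap, cardiac_params)
  if (is.null(rap_grid)) {
    if (rap_min >= mcfp) stop("rap_min must be below mcfp", call. = FALSE)
    rap_grid <- seq(rap_min, mcfp, length.out = 201L)
  }
  vr_line <- (mcfp - rap_grid) / rv
  cc <- cardiac(rap_grid)
  g <- function(rap) (mcfp - rap) / rv - cardiac(rap)
  lo <- min(rap_grid); hi <- max(rap_grid)
  op <- NULL; no_solution <- FALSE
  glo <- g(lo); ghi <- g(hi)
  if (glo == 0) {
    op <- list(rap = lo, flow = (mcfp - lo) / rv)
  } else if (ghi == 0) {
    op <- list(rap = hi, flow = (mcfp - hi) / rv)
  } else if (glo * ghi < 0) {
    # bisection: g is continuous and changes sign on [lo, hi]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (gm == 0) { lo <- mid; hi <- mid; break }
      if (glo * gm < 0) hi <- mid else { lo <- mid; glo <- gm }
    }
    rap_star <- (lo + hi) / 2
    op <- list(rap = rap_star, flow = (mcfp - rap_star) / rv)
  } else {
    no_solution <- TRUE
  }
  structure(list(rap_grid = rap_grid, vr_line = vr_line, cardiac_curve = cc,
                 operating_point = op, no_solution = no_solution,
                 mcfp = mcfp, rv = rv, condition_label = condition_label),
            class = "guyton_diagram")
}

#' @export
print.guyton_diagram <- function(x, ...) {
  cat(sprintf("Guyton diagram [%s]: MCFP %.2f mmHg, Rv %.3f mmHg/(L/min)\n",
              x$condition_label, x$mcfp, x$rv))
  if (x$no_solution) {
    cat("  no operating point on grid\n")
  } else {
    cat(sprintf("  operating point: RAP %.3f mmHg, flow %.3f L/min\n",
                x$operating_point$rap, x$operating_point$flow))
  }
  invisible(x)
}

#' @export
as.data.frame.guyton_diagram <- function(x, ...) {
  data.frame(rap = x$rap_grid, vr = x$vr_line, cardiac = x$cardiac_curve,
             condition = x$condition_label)
}

#' Plot a venous-return diagram
#'
#' @param x a `guyton_diagram`
#' @param ... further `guyton_diagram` objects to overlay (e.g. drug-on vs
#'   baseline)
#' @return A ggplot object.
#' @export
plot.guyton_diagram <- function(x, ...) {
  extra <- Filter(function(d) inherits(d, "guyton_diagram"), list(...))
  dfs <- lapply(c(list(x), extra), as.data.frame)
  df <- do.call(rbind, dfs)
  long <- rbind(
    data.frame(rap = df$rap, flow = df$vr, curve = "venous return",
               condition = df$condition),
    data.frame(rap = df$rap, flow = df$cardiac, curve = "cardiac function",
               condition = df$condition))
  ops <- do.call(rbind, lapply(c(list(x), extra), function(d) {
    if (d$no_solution) return(NULL)
    data.frame(rap = d$operating_point$rap, flow = d$operating_point$flow,
               condition = d$condition_label)
  }))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = rap, y = flow,
                                          linetype = curve,
                                          colour = condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Right atrial pressure (mmHg)", y = "Flow (L/min)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ops))
    p <- p + ggplot2::geom_point(data = ops, inherit.aes = FALSE,
                                 ggplot2::aes(x = rap, y = flow,
                                              colour = condition),
                                 size = 2)
  p
}
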
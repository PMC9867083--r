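#' Plot a polygonogram
#'
#' Nodes on a circle (lexicographic order, deterministic), edges coloured
#' black for additive, red for synergistic, blue for antagonistic.
#'
#' @param x a [build_polygonogram()] result.
#' @param ... further arguments (ignored).
#' @export
plot.polygonogram <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1)
  if (length(x$nodes) == 0L) {
    graphics::title("Polygonogram (empty)")
    return(invisible(x))
  }
  theta <- seq(0, 2 * pi, length.out = length(x$nodes) + 1)[-1]
  px <- cos(theta); py <- sin(theta)
  names(px) <- names(py) <- x$nodes
  if (nrow(x$edges))
    graphics::segments(px[x$edges$from], py[x$edges$from],
                       px[x$edges$to], py[x$edges$to],
                       col = x$edges$colour,
                       lwd = ifelse(x$edges$classification == "additive",
                                    1.5, 3))
  graphics::points(px, py, pch = 21, bg = "white", cex = 3)
  graphics::text(px * 1.22, py * 1.22, x$nodes, cex = 0.8)
  graphics::title("Polygonogram")
  invisible(x)
}

#' Draw a fixed-dose isobologram
#'
#' Adjunct dose on the X axis, main-drug dose on the Y axis. The oblique
#' line joining the two solo ED50s is the line of additivity; the vertical
#' line marks the constant adjunct dose of the mixture. Point A is the
#' theoretically additive mixture (on the additivity line), point E the
#' experimental one, both drawn with their SEM whiskers on the main-drug
#' axis.
#'
#' @param assessment a [classify_interaction()] result whose `additive`
#'   component was built by [additive_ed50_total()] with a single adjunct.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot_isobologram <- function(assessment, ...) {
  stopifnot(inherits(assessment, "interaction_assessment"),
            inherits(assessment$additive, "additive_ed50"))
  add <- assessment$additive
  if (length(add$adjuncts) != 1L)
    stop("isobolograms are drawn for single-adjunct combinations")
  adj <- add$adjuncts[[1]]
  asm <- add$asm
  # main-drug components of the mixture points (total minus fixed dose)
  yA <- add$ed50_add_total - add$fixed_total
  yE <- assessment$ed50_exp_total - add$fixed_total
  xlim <- c(0, adj$ed50_alone * 1.05)
  ylim <- c(0, max(asm$ed50 + 2 * asm$sem, yE + 2 * assessment$sem_exp) * 1.1)
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = sprintf("%s dose (mg/kg)", adj$compound),
                 ylab = sprintf("%s dose (mg/kg)", asm$label),
                 main = if (is.null(assessment$label)) "" else
                   assessment$label, ...)
  graphics::segments(0, asm$ed50, adj$ed50_alone, 0, lwd = 2)
  graphics::abline(v = adj$fixed_dose, lty = 2)
  graphics::arrows(adj$fixed_dose, yA - 1.959964 * add$sem_add,
                   adj$fixed_dose, yA + 1.959964 * add$sem_add,
                   angle = 90, code = 3, length = 0.04)
  graphics::arrows(adj$fixed_dose, yE - 1.959964 * assessment$sem_exp,
                   adj$fixed_dose, yE + 1.959964 * assessment$sem_exp,
                   angle = 90, code = 3, length = 0.04,
                   col = if (assessment$classification == "synergistic")
                     "red" else "black")
  graphics::points(adj$fixed_dose, yA, pch = 21, bg = "white", cex = 1.4)
  graphics::points(adj$fixed_dose, yE, pch = 19, cex = 1.2,
                   col = if (assessment$classification == "synergistic")
                     "red" else "black")
  graphics::text(adj$fixed_dose, yA, " A", adj = -0.4)
  graphics::text(adj$fixed_dose, yE, " E", adj = -0.4)
  invisible(assessment)
}

#' Plot a fitted log-probit dose-response curve
#'
#' Observed protection proportions over dose (log axis) with the fitted
#' cumulative-normal curve and the ED50 marked.
#'
#' @param x an `ed50_fit`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.ed50_fit <- function(x, ...) {
  a <- x$assay
  graphics::plot(a$dose, a$protected / a$n, log = "x", ylim = c(0, 1),
                 xlab = "dose (mg/kg)", ylab = "proportion protected",
                 pch = 19, main = sprintf("%s (%g min)", x$compound,
                                          x$pretreatment_min), ...)
  d <- exp(seq(log(min(a$dose) / 2), log(max(a$dose) * 2), length.out = 200))
  graphics::lines(d, stats::pnorm(x$slope * (log10(d) - x$log10_ed50)))
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$ed50, lty = 2)
  invisible(x)
}
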
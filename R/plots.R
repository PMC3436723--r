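#' Density plot of NP-likeness score distributions
#'
#' Overlays one kernel-density curve per named score set (Gaussian kernel,
#' Silverman's bandwidth, 512 evaluation points spanning the data range
#' plus three bandwidths — the defaults of [stats::density()]), the usual
#' way training and query collections are compared. Deterministic given the
#' inputs.
#'
#' @param ... named score sets: tibbles with an `np_likeness` column
#'   (e.g. from [score_molecules()] or [read_scores()]). A single named
#'   list of such tibbles also works.
#' @param path optional output file; when it ends in `.pdf` (recommended)
#'   the plot is written as PDF.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when `path` is given.
#' @export
plot_score_density <- function(..., path = NULL, width = 7, height = 5) {
  sets <- list(...)
  if (length(sets) == 1L && !is.data.frame(sets[[1L]])) sets <- sets[[1L]]
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    abort("supply one or more *named* score sets")
  dens <- purrr::imap(sets, function(s, nm) {
    x <- s$np_likeness
    if (length(x) < 2L || stats::sd(x) == 0) {
      # degenerate set: a narrow spike at the common value
      d <- stats::density(x, bw = max(1e-3, abs(x[1L]) * 1e-3), n = 512L)
    } else {
      d <- stats::density(x, kernel = "gaussian", bw = "nrd0", n = 512L,
                          cut = 3)
    }
    tibble(set = nm, np_likeness = d$x, density = d$y)
  })
  df <- dplyr::bind_rows(dens)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$np_likeness,
                                        y = .data$density,
                                        colour = .data$set)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "NP-likeness score", y = "Density", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height,
                    device = if (grepl("\\.pdf$", path)) grDevices::pdf)
    return(invisible(p))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Density plot for a single score set
#'
#' @param object an `npl_scores` tibble from [score_molecules()].
#' @param name legend label for the set.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.npl_scores <- function(object, name = "query", ...) {
  args <- stats::setNames(list(object), name)
  do.call(plot_score_density, args)
}
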
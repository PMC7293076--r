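#' Plot the prey-type mix hunted by the best individual over generations
#'
#' Stacked proportions of the four capture classes (boar/stag x
#' solo/cooperative) of each generation's best individual.
#'
#' @param history A `ReplicateHistory`.
#' @param ... Passed to [graphics::plot()].
#' @return The per-generation proportion matrix, invisibly.
#' @export
plotHuntProportions <- function(history, ...) {
  rec <- history$records
  counts <- t(as.matrix(rec[, c("best_boar_solo", "best_boar_coop",
                                "best_stag_solo", "best_stag_coop")]))
  tot <- pmax(colSums(counts), 1L)
  prop <- t(counts) / tot
  graphics::matplot(rec$generation, prop, type = "l", lty = 1, lwd = 2,
                    col = c("darkgreen", "forestgreen", "orchid", "purple4"),
                    xlab = "generation", ylab = "proportion of prey hunted",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("darkgreen", "forestgreen", "orchid", "purple4"),
                   legend = c("boar solo", "boar coop", "stag solo", "stag coop"))
  invisible(prop)
}

#' Bar plot of transitioned-replicate counts per condition
#'
#' @param counts Named integer vector: transitioned replicates per condition.
#' @param totals Total replicates per condition (recycled).
#' @param ... Passed to [graphics::barplot()].
#' @export
plotTransitionCounts <- function(counts, totals = NULL, ...) {
  bp <- graphics::barplot(counts, ylab = "replicates transitioned",
                          col = "steelblue", ...)
  if (!is.null(totals))
    graphics::text(bp, counts, labels = paste0(counts, "/", totals), pos = 3,
                   xpd = NA)
  invisible(bp)
}

#' Histogram of mutant stag preferences
#'
#' Mirrors the mutant-landscape screening display: the distribution of
#' estimated stag preferences among mutants exceeding the selection
#' threshold.
#'
#' @param screen A [mutantScreen()] result.
#' @param selected_only Plot only mutants above the threshold (default).
#' @param ... Passed to [graphics::hist()].
#' @export
plotMutantPreferences <- function(screen, selected_only = TRUE, ...) {
  p <- if (selected_only) screen$p_stag[screen$selected] else screen$p_stag
  graphics::hist(p, xlab = "estimated P(hunt stag)", col = "grey70",
                 main = sprintf("%d of %d mutants above threshold %g",
                                sum(screen$selected), nrow(screen),
                                attr(screen, "threshold")), ...)
}
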
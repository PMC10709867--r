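#' Plot outcome-category and deletion-size frequencies of a tally
#'
#' @param object A [tally_outcomes()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.junction_tally <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "frequency among junction reads",
                  title = sprintf("%d junction / %d total reads",
                                  object$junction_reads, object$total_reads)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the MMEJ probability lower-bound curve
#'
#' @param object An [mmej_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mmej_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$p_mmej)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "deletion size n (bp)",
                  y = "lower bound on P(microhomology)",
                  title = "Probability of flanking microhomology vs deletion size") +
    ggplot2::theme_minimal()
}

#' Plot a deleted-position profile
#'
#' Bar chart of PAM-relative positions removed among small deletions;
#' staggered Cas9 cleavage concentrates mass on -4, -5 and -6.
#'
#' @param profile Tibble from [deletion_position_profile()].
#' @return A ggplot.
#' @export
plot_deletion_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$position), y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "PAM-relative position", y = "deleted-base count") +
    ggplot2::theme_minimal()
}
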
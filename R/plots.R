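## ggplot2 presentations of the main result types.

#' Plot clone-group sizes
#'
#' Bar chart of read counts per CDR3 group, unproductive groups hatched out
#' by fill.
#'
#' @param object A `clone_groups` from [group_by_cdr3()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clone_groups <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group_id <- factor(df$group_id, levels = df$group_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_id, y = .data$total_count,
                                   fill = .data$productive)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#bdbdbd"),
                               name = "productive") +
    ggplot2::labs(x = "CDR3 group", y = "reads",
                  title = "Clone-specific reads per CDR3 group") +
    ggplot2::theme_minimal()
}

#' Plot the trafficking matrix
#'
#' Heatmap of group presence across samples (log10 read counts).
#'
#' @param object A `trafficking_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trafficking_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(object$counts,
                                              responseName = "count"))
  names(df)[1:2] <- c("group_id", "sample_id")
  df$log_count <- ifelse(df$count > 0, log10(df$count), NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$group_id,
                                   fill = .data$log_count)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "log10 reads") +
    ggplot2::labs(x = "sample", y = "CDR3 group",
                  title = "Interfollicular trafficking of clone groups") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a substitution spectrum
#'
#' Bar chart of the 12 ordered substitutions; the formalin-type G>A / C>T
#' transitions are highlighted.
#'
#' @param object A `mutation_spectrum` from [substitution_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mutation_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$substitution <- paste0(df$from_base, ">", df$to_base)
  df$deamination <- df$substitution %in% c("G>A", "C>T")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$substitution, y = .data$count,
                                   fill = .data$deamination)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "#7570b3"),
                               name = "G>A / C>T") +
    ggplot2::labs(x = "substitution (sense strand)", y = "mutations",
                  title = "Substitution spectrum") +
    ggplot2::theme_minimal()
}
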
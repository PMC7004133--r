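#' @import ggplot2
NULL

#' Plot insertion-age histograms
#'
#' Side-by-side age distributions of dated elements, optionally split by a
#' grouping column (e.g. genome), with the speciation time marked.
#'
#' @param ages Ages tibble ([date_elements()]), optionally with a `genome`
#'   column; rows not `dated` are dropped.
#' @param bin_width Bin width (Mya).
#' @param speciation_mya Vertical reference line (`NULL` to omit).
#' @return A ggplot object.
#' @export
plot_age_histogram <- function(ages, bin_width = 1.0, speciation_mya = 5.88) {
  d <- ages |> filter(.data$status == "dated")
  p <- ggplot(d, aes(x = .data$age_mya)) +
    geom_histogram(binwidth = bin_width, boundary = 0,
                   fill = "grey35", colour = "white") +
    labs(x = "Insertion age (Mya)", y = "Elements") +
    theme_minimal()
  if ("genome" %in% names(d)) {
    p <- ggplot(d, aes(x = .data$age_mya, fill = .data$genome)) +
      geom_histogram(binwidth = bin_width, boundary = 0,
                     position = "dodge", colour = "white") +
      labs(x = "Insertion age (Mya)", y = "Elements", fill = "Genome") +
      theme_minimal()
  }
  if (!is.null(speciation_mya)) {
    p <- p + geom_vline(xintercept = speciation_mya, linetype = "dashed")
  }
  p
}

#' Plot insertion ages by orthology category
#'
#' @param report An `ortho_report` from [age_by_category()].
#' @return A ggplot object (boxplots of age per category, split line at the
#'   speciation time).
#' @export
plot_age_by_category <- function(report) {
  d <- report$detail |> filter(!is.na(.data$age_mya))
  ggplot(d, aes(x = .data$category, y = .data$age_mya)) +
    geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    geom_hline(yintercept = report$speciation_mya, linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "Insertion age (Mya)") +
    theme_minimal()
}

#' Plot age distributions of fixed versus polymorphic insertions
#'
#' @param status Tibble from [classify_fixed_polymorphic()].
#' @param ages Ages tibble.
#' @param speciation_mya Dashed reference line (Mya).
#' @return A ggplot object.
#' @export
plot_polymorphism_ages <- function(status, ages, speciation_mya = 5.88) {
  d <- status |>
    left_join(ages |> select("element_id", "age_mya"), by = "element_id") |>
    filter(!is.na(.data$age_mya))
  ggplot(d, aes(x = .data$age_mya, fill = .data$status)) +
    geom_histogram(binwidth = 1, boundary = 0, position = "dodge",
                   colour = "white") +
    geom_vline(xintercept = speciation_mya, linetype = "dashed") +
    labs(x = "Insertion age (Mya)", y = "Elements", fill = NULL) +
    theme_minimal()
}
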
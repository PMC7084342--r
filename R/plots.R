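#' Plot a per-gene AT/GC skew profile
#'
#' @param object A [pcg_skew_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot skew_profile
#' @export
autoplot.skew_profile <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("at_skew", "gc_skew"),
                        names_to = "skew", values_to = "value") |>
    mutate(gene = factor(.data$gene, levels = unique(object$gene)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$value,
                                     group = .data$skew,
                                     colour = .data$skew)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "skew",
                  title = attr(object, "label") %||% NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot relative synonymous codon usage as stacked bars
#'
#' One bar per amino acid, stacked by codon, the conventional RSCU
#' display for mitogenome codon-usage comparisons.
#'
#' @param object An [rscu()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rscu_table
#' @export
autoplot.rscu_table <- function(object, ...) {
  dat <- object |> filter(!is.na(.data$rscu))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$aa3, y = .data$rscu,
                                    fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-gene Ka, Ks and omega across genome pairs
#'
#' @param divergence_tbl Output of [pairwise_gene_matrix()] (possibly
#'   row-bound over genes).
#' @return A ggplot (per-gene mean Ka/Ks with per-pair points).
#' @export
plot_kaks <- function(divergence_tbl) {
  dat <- divergence_tbl |> filter(!is.na(.data$omega))
  means <- dat |>
    group_by(.data$gene) |>
    summarise(omega = mean(.data$omega), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$omega)) +
    ggplot2::geom_col(data = means, fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(shape = paste(.data$a, .data$b,
                                                   sep = " vs "))) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red") +
    ggplot2::labs(x = NULL, y = "Ka/Ks", shape = "pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
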
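#' Decompose a haplotype network into haplotype classes
#'
#' A haplotype class groups the haplotypes that share the same number of
#' subtending branches (node degree). Classes are the unit over which branch
#' diversity is computed: each class is characterized by its branch count
#' `n_branches`, the number of haplotypes `n_haplotypes` it contains, and the
#' number of individuals `n_individuals` carried by those haplotypes.
#'
#' @param network A `hap_network` (node counts must be individuals).
#' @param count_alternative Override the network's stored flag for whether
#'   alternative links contribute to degrees.
#' @return A tibble of class `hap_classes`, sorted by ascending
#'   `n_branches`, with columns `n_branches`, `n_haplotypes`,
#'   `n_individuals`, `freq` (`n_individuals / n`). Attributes: `n`, `n_hap`,
#'   `n_classes`.
#' @export
#' @examples
#' aln <- hap_realize(model_fixtures()$branched21)
#' net <- build_msn(hap_distances(hap_collapse(aln)),
#'                  counts = hap_collapse(aln)$count)
#' hap_class_decomposition(net)
hap_class_decomposition <- function(network, count_alternative = NULL) {
  deg <- hap_degrees(network, count_alternative = count_alternative)
  n <- sum(deg$count)
  out <- deg |>
    dplyr::group_by(n_branches = .data$degree) |>
    dplyr::summarise(
      n_haplotypes = dplyr::n(),
      n_individuals = sum(.data$count),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$n_branches) |>
    dplyr::mutate(freq = .data$n_individuals / n)
  attr(out, "n") <- as.integer(n)
  attr(out, "n_hap") <- nrow(deg)
  attr(out, "n_classes") <- nrow(out)
  class(out) <- c("hap_classes", class(out))
  out
}

validate_hap_classes <- function(classes) {
  if (!inherits(classes, "hap_classes")) {
    stop_hapnet("Expected a `hap_classes` (see `hap_class_decomposition()`).",
                "bad_input")
  }
  invisible(classes)
}

#' @export
print.hap_classes <- function(x, ...) {
  cat("# Haplotype classes: ", nrow(x), " (", attr(x, "n_hap"),
      " haplotypes, ", attr(x, "n"), " individuals)\n", sep = "")
  NextMethod()
}
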
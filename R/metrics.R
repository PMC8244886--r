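#' Haplotype diversity (Hd)
#'
#' The probability that two individuals sampled without replacement from the
#' population carry different haplotypes:
#' `Hd = (1 - sum(f_h^2)) * n / (n - 1)`, where `f_h` is the frequency of
#' haplotype `h`. Equivalent to `1 - sum(c * (c - 1)) / (n * (n - 1))` over
#' the haplotype counts `c`, the exact without-replacement pair probability.
#'
#' @param counts Integer vector of individuals per haplotype (or a
#'   `hap_table`, whose `count` column is used).
#' @param n Total individuals; defaults to `sum(counts)`.
#' @param allow_degenerate With a single individual the metric is undefined;
#'   set `TRUE` to return 0 instead of erroring.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' hap_hd(c(6, 3, 3, 3, 3, 3)) # 0.857...
#' hap_hd(rep(1, 21)) # 1
hap_hd <- function(counts, n = NULL, allow_degenerate = FALSE) {
  if (inherits(counts, "hap_table")) counts <- counts$count
  if (!is_count_vector(counts)) {
    stop_hapnet("`counts` must be positive integers.", "bad_input")
  }
  n <- n %||% sum(counts)
  if (sum(counts) != n) {
    stop_hapnet("`counts` must sum to `n`.", "bad_input")
  }
  if (n < 2) {
    if (allow_degenerate) return(0)
    stop_hapnet("Hd is undefined for n < 2.", "undefined_metric")
  }
  (1 - sum((counts / n)^2)) * n / (n - 1)
}

#' Node diversity (Nd)
#'
#' A degree-based topological index computed from the haplotype-class
#' decomposition:
#' `Nd = (1 - sum(nhHc * (nbHc / nH)^2)) * nH / (nH - 1)`,
#' where `nhHc` is the number of haplotypes and `nbHc` the branch count of
#' class `Hc`, and `nH` the total number of haplotypes. The inner terms
#' divide branch counts by the number of haplotypes, which is not a
#' frequency, so Nd has no probabilistic interpretation and can leave
#' `[0, 1]` on degenerate inputs (a two-haplotype network gives exactly 1).
#' Values are reported as computed, never clamped.
#'
#' @param classes A `hap_classes` decomposition, or a numeric vector of
#'   branch counts per class (then `n_haplotypes` is required).
#' @param n_haplotypes Haplotypes per class, parallel to `classes` when the
#'   latter is a plain vector.
#' @return A number (usually in `[0, 1]`, not guaranteed).
#' @export
#' @examples
#' hap_nd(c(1, 2, 4), c(4, 1, 1)) # 0.4
hap_nd <- function(classes, n_haplotypes = NULL) {
  if (inherits(classes, "hap_classes")) {
    nb <- classes$n_branches
    nh <- classes$n_haplotypes
  } else {
    nb <- classes
    nh <- n_haplotypes
    if (is.null(nh) || length(nh) != length(nb)) {
      stop_hapnet(
        "Provide `n_haplotypes` parallel to the branch-count vector.",
        "bad_input"
      )
    }
  }
  if (anyDuplicated(nb)) {
    stop_hapnet("Branch counts must be unique across classes.", "bad_input")
  }
  nH <- sum(nh)
  if (nH < 2) {
    stop_hapnet("Nd is undefined for fewer than 2 haplotypes.",
                "undefined_metric")
  }
  (1 - sum(nh * (nb / nH)^2)) * nH / (nH - 1)
}

#' Combined haplotype network diversity (HNd)
#'
#' The product `Hd * Nd`, combining genetic diversity with the node
#' diversity index. Like Nd it has no probabilistic interpretation; it is
#' reported for comparison with HBd.
#'
#' @param hd,nd The two component metrics.
#' @return Their product.
#' @export
hap_hnd <- function(hd, nd) hd * nd

#' Branch diversity (Bd)
#'
#' The probability that two individuals sampled without replacement carry
#' haplotypes from different haplotype classes:
#' `Bd = (1 - sum(f_Hc^2)) * n / (n - 1)`, where `f_Hc` is the fraction of
#' individuals in class `Hc`. Bd is 0 whenever the network has a single
#' class (one or two haplotypes, or a pure cycle), grows with the number of
#' classes and with frequency-evenness among them, and decreases toward its
#' asymptote as `n` grows at fixed class proportions.
#'
#' @param classes Integer vector of individuals per haplotype class, or a
#'   `hap_classes` decomposition.
#' @param n Total individuals; defaults to the sum.
#' @param allow_degenerate Return 0 instead of erroring when `n < 2`.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' hap_bd(c(15, 3, 3)) # 0.4714...
#' hap_bd(c(15, 6)) # 0.4285...
hap_bd <- function(classes, n = NULL, allow_degenerate = FALSE) {
  if (inherits(classes, "hap_classes")) classes <- classes$n_individuals
  if (!is_count_vector(classes)) {
    stop_hapnet("`classes` must be positive integers.", "bad_input")
  }
  n <- n %||% sum(classes)
  if (sum(classes) != n) {
    stop_hapnet("Class counts must sum to `n`.", "bad_input")
  }
  if (n < 2) {
    if (allow_degenerate) return(0)
    stop_hapnet("Bd is undefined for n < 2.", "undefined_metric")
  }
  (1 - sum((classes / n)^2)) * n / (n - 1)
}

#' Haplotype network branch diversity (HBd)
#'
#' The combined complexity metric merging genetic diversity (haplotype
#' frequencies) with topological diversity (haplotype-class frequencies):
#'
#' `HBd = (1 - sum(f_h^2)) * (1 - sum(f_Hc^2)) * n / (n - 1)`
#'
#' The default applies the sample-size correction `n / (n - 1)` once to the
#' product, which is how the metric's published reference values are
#' computed. Setting `both_corrected = TRUE` instead multiplies the two
#' individually corrected metrics, `Hd * Bd`, for sensitivity checks; that
#' variant carries the correction twice and is slightly larger.
#'
#' @param hap_counts Individuals per haplotype.
#' @param class_counts Individuals per haplotype class.
#' @param n Total individuals; both count vectors must sum to it.
#' @param both_corrected Use `Hd * Bd` (double correction) instead of the
#'   single-correction form.
#' @param allow_degenerate Return 0 instead of erroring when `n < 2`.
#' @return A number in `[0, 1]`, bounded by `min(Hd, Bd)`.
#' @export
#' @examples
#' hap_hbd(c(6, 3, 3, 3, 3, 3), c(15, 6)) # 0.3498... (prints 0.35)
hap_hbd <- function(hap_counts, class_counts, n = NULL,
                    both_corrected = FALSE, allow_degenerate = FALSE) {
  if (inherits(hap_counts, "hap_table")) hap_counts <- hap_counts$count
  if (inherits(class_counts, "hap_classes")) {
    class_counts <- class_counts$n_individuals
  }
  if (!is_count_vector(hap_counts) || !is_count_vector(class_counts)) {
    stop_hapnet("Count vectors must be positive integers.", "bad_input")
  }
  n <- n %||% sum(hap_counts)
  if (sum(hap_counts) != n || sum(class_counts) != n) {
    stop_hapnet("Both count vectors must sum to `n`.", "bad_input")
  }
  if (n < 2) {
    if (allow_degenerate) return(0)
    stop_hapnet("HBd is undefined for n < 2.", "undefined_metric")
  }
  sum_fh2 <- sum((hap_counts / n)^2)
  sum_fc2 <- sum((class_counts / n)^2)
  if (both_corrected) {
    (1 - sum_fh2) * (n / (n - 1)) * (1 - sum_fc2) * (n / (n - 1))
  } else {
    (1 - sum_fh2) * (1 - sum_fc2) * n / (n - 1)
  }
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site pairwise difference across all individual pairs:
#' `pi = sum_{i<j} c_i c_j d_ij / (L * choose(n, 2))`, summing over
#' haplotype pairs weighted by their individual counts (within-haplotype
#' pairs contribute zero), with `L` the number of compared sites. No
#' `n/(n-1)` correction is applied (plain mean over pairs); pi feeds no
#' other metric and is reported for comparison only.
#'
#' @param table A `hap_table`, or an integer vector of haplotype counts.
#' @param dist Haplotype distance matrix (steps), e.g. [hap_distances()].
#' @param seq_length Number of sites the distances were computed over;
#'   defaults to the `compared_sites` attribute of `dist`.
#' @return A non-negative number.
#' @export
hap_pi <- function(table, dist, seq_length = NULL) {
  counts <- if (inherits(table, "hap_table")) table$count else table
  if (!is_count_vector(counts)) {
    stop_hapnet("Haplotype counts must be positive integers.", "bad_input")
  }
  n <- sum(counts)
  if (n < 2) {
    stop_hapnet("pi is undefined for n < 2.", "undefined_metric")
  }
  seq_length <- seq_length %||% attr(dist, "compared_sites")
  if (is.null(seq_length) || seq_length < 1) {
    stop_hapnet("`seq_length` must be a positive number of sites.",
                "bad_input")
  }
  if (!is.matrix(dist) || nrow(dist) != length(counts)) {
    stop_hapnet("`dist` must be a haplotype distance matrix matching the counts.",
                "bad_input")
  }
  total <- 0
  nH <- length(counts)
  for (i in seq_len(nH - 1)) {
    for (j in seq(i + 1, nH)) {
      total <- total + counts[i] * counts[j] * dist[i, j]
    }
  }
  total / (seq_length * choose(n, 2))
}
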
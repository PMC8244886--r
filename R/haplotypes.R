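#' Collapse aligned sequences into haplotypes
#'
#' Two individuals share a haplotype iff their aligned sequences are
#' identical under the chosen ambiguity policy:
#'
#' * `"strict"` (default): sequences must match character-for-character.
#'   Reproducible without coupling between records, so it is the default.
#' * `"ignore-ambiguous-sites"`: alignment columns containing an `N`, a gap,
#'   or an IUPAC ambiguity code in *any* record are dropped before comparison
#'   (complete deletion), so an ambiguous call cannot split a haplotype.
#'
#' @param alignment A [hap_alignment].
#' @param policy Ambiguity policy, `"strict"` or `"ignore-ambiguous-sites"`.
#' @return A tibble of class `hap_table` with one row per haplotype, ordered
#'   by descending individual count (ties by first occurrence): columns
#'   `haplotype` (label `H1`, `H2`, ...), `sequence` (full-length sequence of
#'   the first member), `count`, `freq` (`count / n`), and `members`
#'   (list-column of individual ids). Attributes: `n` (individuals), `n_hap`,
#'   `policy`, `seq_length`, and `kept_sites` (columns surviving the policy,
#'   used for downstream distances).
#' @seealso [hap_distances()], [build_msn()], [hap_complexity()]
#' @export
#' @examples
#' aln <- hap_alignment(paste0("s", 1:3), c("ACGT", "ACGT", "ACGA"))
#' hap_collapse(aln)
hap_collapse <- function(alignment,
                         policy = c("strict", "ignore-ambiguous-sites")) {
  validate_alignment(alignment)
  policy <- match.arg(policy)
  seq_length <- attr(alignment, "seq_length")

  kept <- seq_len(seq_length)
  keys <- alignment$sequence
  if (policy == "ignore-ambiguous-sites") {
    mat <- seq_char_matrix(alignment$sequence)
    ambiguous <- apply(mat, 2, function(col) any(!col %in% c("A", "C", "G", "T")))
    kept <- which(!ambiguous)
    keys <- apply(mat[, kept, drop = FALSE], 1, paste, collapse = "")
    if (length(kept) == 0) keys <- rep("", nrow(alignment))
  }

  first_seen <- !duplicated(keys)
  key_order <- keys[first_seen]
  grp <- match(keys, key_order)
  counts <- tabulate(grp, nbins = length(key_order))
  members <- split(alignment$id, factor(grp, levels = seq_along(key_order)))

  ord <- order(-counts, seq_along(counts))
  n <- nrow(alignment)
  out <- tibble(
    haplotype = paste0("H", seq_along(ord)),
    sequence = alignment$sequence[first_seen][ord],
    count = as.integer(counts[ord]),
    freq = counts[ord] / n,
    members = unname(members[ord])
  )
  attr(out, "n") <- as.integer(n)
  attr(out, "n_hap") <- nrow(out)
  attr(out, "policy") <- policy
  attr(out, "seq_length") <- as.integer(seq_length)
  attr(out, "kept_sites") <- as.integer(kept)
  class(out) <- c("hap_table", class(out))
  out
}

# Character matrix (individuals x sites) from aligned sequences.
seq_char_matrix <- function(sequences) {
  matrix(
    unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
    nrow = length(sequences),
    byrow = TRUE
  )
}

validate_hap_table <- function(table) {
  if (!inherits(table, "hap_table")) {
    stop_hapnet("Expected a `hap_table` (see `hap_collapse()`).", "bad_input")
  }
  invisible(table)
}

#' @export
print.hap_table <- function(x, ...) {
  cat("# Haplotypes: ", nrow(x), " from ", attr(x, "n"),
      " individuals (policy: ", attr(x, "policy"), ")\n", sep = "")
  NextMethod()
}
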
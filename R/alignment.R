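#' Construct an aligned-sequence table
#'
#' An alignment is a tibble with one row per individual and columns `id`,
#' `sequence`, and `population`. Sequences are normalized on construction:
#' uppercased, with `U` mapped to `T` so RNA-dialect input collapses onto the
#' same haplotypes as DNA input. All sequences must have identical length and
#' use only DNA characters (`A`, `C`, `G`, `T`), IUPAC ambiguity codes, `N`,
#' or the gap character `-`.
#'
#' @param id Character vector of unique, non-empty individual identifiers.
#' @param sequence Character vector of aligned sequences, one per individual.
#' @param population Optional character vector of population labels; defaults
#'   to `"unassigned"`.
#'
#' @return A tibble of class `hap_alignment` with columns `id`, `sequence`,
#'   `population`, carrying the alignment length in attribute `seq_length`.
#' @seealso [read_fasta()], [read_popmap()], [hap_collapse()]
#' @export
#' @examples
#' hap_alignment(c("s1", "s2"), c("ACGT", "ACGA"))
hap_alignment <- function(id, sequence, population = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  if (length(id) == 0) {
    stop_hapnet("Alignment has no records.", "empty_alignment")
  }
  if (length(id) != length(sequence)) {
    stop_hapnet("`id` and `sequence` must have the same length.", "bad_input")
  }
  if (anyNA(id) || any(!nzchar(id))) {
    stop_hapnet("Individual ids must be non-empty.", "bad_ids")
  }
  if (anyDuplicated(id)) {
    dups <- unique(id[duplicated(id)])
    stop_hapnet(
      paste0("Duplicate individual ids: ", paste(dups, collapse = ", ")),
      "duplicate_ids"
    )
  }
  lens <- nchar(sequence)
  if (length(unique(lens)) > 1L) {
    ref <- lens[1]
    off <- id[lens != ref]
    stop_hapnet(
      paste0(
        "Sequences are not aligned: length differs from first record (",
        ref, ") for: ", paste(off, collapse = ", ")
      ),
      "alignment_length"
    )
  }
  if (lens[1] < 1) {
    stop_hapnet("Aligned sequences must have length >= 1.", "empty_sequence")
  }
  bad <- grepl("[^ACGTUNRYSWKMBDHV-]", sequence)
  if (any(bad)) {
    stop_hapnet(
      paste0(
        "Non-DNA characters in sequences of: ",
        paste(id[bad], collapse = ", ")
      ),
      "bad_alphabet"
    )
  }
  population <- population %||% rep("unassigned", length(id))
  out <- tibble(
    id = id,
    sequence = sequence,
    population = as.character(population)
  )
  attr(out, "seq_length") <- as.integer(lens[1])
  class(out) <- c("hap_alignment", class(out))
  out
}

#' Read an aligned FASTA file
#'
#' Reads pre-aligned sequences (one record per individual). Record order is
#' preserved; sequences are uppercased and `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A [hap_alignment] tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_hapnet(paste0("File not found: ", path), "io")
  }
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    stop_hapnet(paste0("FASTA file has no records: ", path),
                "empty_alignment")
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       seqtype = "DNA"),
    error = function(e) {
      stop_hapnet(paste0("Cannot parse FASTA ", path, ": ",
                         conditionMessage(e)), "io")
    }
  )
  if (length(recs) == 0) {
    stop_hapnet(paste0("FASTA file has no records: ", path), "empty_alignment")
  }
  hap_alignment(names(recs), vapply(recs, as.character, character(1)))
}

#' Write an alignment to FASTA
#'
#' @param alignment A [hap_alignment].
#' @param path Output file path.
#' @return `alignment`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  validate_alignment(alignment)
  seqinr::write.fasta(
    sequences = as.list(alignment$sequence),
    names = alignment$id,
    file.out = path,
    as.string = TRUE,
    nbchar = 80
  )
  invisible(alignment)
}

#' Attach population labels from a CSV map
#'
#' The map mirrors the per-individual "sites" files that usually accompany
#' phylogeographic FASTA data: one row per individual, mapping its id to a
#' population label. Labels are carried through for reporting only; no
#' diversity metric depends on them.
#'
#' @param alignment A [hap_alignment].
#' @param path Path to a CSV file with (by default) columns `id` and
#'   `population`.
#' @param id_col,pop_col Column names to use for ids and labels.
#' @return The alignment with its `population` column filled. Individuals
#'   absent from the map keep the label `"unassigned"` (with a warning); map
#'   rows whose id is not in the alignment are an error.
#' @export
read_popmap <- function(alignment, path, id_col = "id",
                        pop_col = "population") {
  validate_alignment(alignment)
  if (!file.exists(path)) {
    stop_hapnet(paste0("File not found: ", path), "io")
  }
  map <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(map) == 0) {
    warn("Population map is empty; all individuals labeled 'unassigned'.")
    alignment$population <- "unassigned"
    return(alignment)
  }
  if (!all(c(id_col, pop_col) %in% names(map))) {
    stop_hapnet(
      paste0("Population map must have columns '", id_col, "' and '",
             pop_col, "'."),
      "popmap_schema"
    )
  }
  ids <- as.character(map[[id_col]])
  if (anyDuplicated(ids)) {
    stop_hapnet("Duplicate ids in population map.", "duplicate_ids")
  }
  missing <- setdiff(ids, alignment$id)
  if (length(missing) > 0) {
    stop_hapnet(
      paste0("Population map ids not present in alignment: ",
             paste(missing, collapse = ", ")),
      "unknown_id"
    )
  }
  labels <- stats::setNames(as.character(map[[pop_col]]), ids)
  pop <- unname(labels[alignment$id])
  unmapped <- is.na(pop)
  if (any(unmapped)) {
    warn(paste0(
      sum(unmapped), " individual(s) not in the population map; ",
      "labeled 'unassigned'."
    ))
    pop[unmapped] <- "unassigned"
  }
  alignment$population <- pop
  alignment
}

#' Write a population map CSV
#'
#' @param alignment A [hap_alignment].
#' @param path Output CSV path.
#' @return `alignment`, invisibly.
#' @export
write_popmap <- function(alignment, path) {
  validate_alignment(alignment)
  readr::write_csv(alignment[, c("id", "population")], path, progress = FALSE)
  invisible(alignment)
}

validate_alignment <- function(alignment) {
  if (!inherits(alignment, "hap_alignment")) {
    stop_hapnet("Expected a `hap_alignment` (see `hap_alignment()`).",
                "bad_input")
  }
  invisible(alignment)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("# Aligned sequences: ", nrow(x), " individuals x ",
      attr(x, "seq_length"), " sites\n", sep = "")
  NextMethod()
}
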
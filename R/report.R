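#' Compute all haplotype-network complexity metrics from an alignment
#'
#' End-to-end driver: collapses the alignment into haplotypes, computes
#' pairwise mutational distances, builds the minimum spanning network,
#' decomposes it into haplotype classes, and evaluates Hd, Nd, HNd, Bd,
#' HBd, and pi.
#'
#' A network needs at least two haplotypes and two individuals. With fewer,
#' the metrics are undefined; with `lenient = TRUE` they are all reported as
#' 0 and the report is flagged degenerate instead of erroring.
#'
#' @param alignment A [hap_alignment].
#' @param dataset Name recorded in the report (defaults to `"dataset"`).
#' @param policy Ambiguity policy passed to [hap_collapse()].
#' @param epsilon Slack for alternative links, see [build_msn()].
#' @param count_alternative Count alternative links in node degrees?
#' @param both_corrected Use the double-corrected HBd variant, see
#'   [hap_hbd()].
#' @param lenient Report zeros (flagged degenerate) instead of erroring on
#'   single-haplotype or single-individual input.
#' @return A `hap_complexity` object: list with `metrics` (one-row tibble:
#'   `dataset`, `n`, `n_hap`, `n_classes`, `Hd`, `Bd`, `HBd`, `Nd`, `HNd`,
#'   `pi`), the intermediate `table`, `network`, `classes`, a `settings`
#'   list, and a `degenerate` flag. Use [glance()][generics::glance] /
#'   [tidy()][generics::tidy] for tibble views and [write_report()] to
#'   serialize.
#' @export
#' @examples
#' aln <- hap_realize(model_fixtures()$star21)
#' rep <- hap_complexity(aln, dataset = "star")
#' glance(rep)
hap_complexity <- function(alignment,
                           dataset = "dataset",
                           policy = c("strict", "ignore-ambiguous-sites"),
                           epsilon = 0L,
                           count_alternative = TRUE,
                           both_corrected = FALSE,
                           lenient = FALSE) {
  validate_alignment(alignment)
  policy <- match.arg(policy)
  table <- hap_collapse(alignment, policy = policy)
  n <- attr(table, "n")
  nH <- attr(table, "n_hap")
  settings <- list(
    policy = policy,
    epsilon = as.integer(epsilon),
    count_alternative = count_alternative,
    both_corrected = both_corrected,
    lenient = lenient,
    hnd_is_product_assumption = TRUE
  )

  if (n < 2 || nH < 2) {
    if (!lenient) {
      stop_hapnet(
        paste0("Network metrics are undefined for n = ", n, ", haplotypes = ",
               nH, "; rerun with `lenient = TRUE` for an all-zero report."),
        "undefined_metric"
      )
    }
    dist <- hap_distances(table)
    net <- build_msn(dist, counts = table$count, epsilon = epsilon,
                     count_alternative = count_alternative)
    metrics <- tibble(
      dataset = dataset, n = n, n_hap = nH,
      n_classes = if (nH >= 1) 1L else 0L,
      Hd = 0, Bd = 0, HBd = 0, Nd = 0, HNd = 0,
      pi = if (n >= 2) hap_pi(table, dist) else 0
    )
    return(new_hap_complexity(metrics, table, net,
                              hap_class_decomposition(net),
                              settings, degenerate = TRUE))
  }

  dist <- hap_distances(table)
  net <- build_msn(dist, counts = table$count, epsilon = epsilon,
                   count_alternative = count_alternative)
  classes <- hap_class_decomposition(net)
  hd <- hap_hd(table$count, n)
  nd <- hap_nd(classes)
  bd <- hap_bd(classes, n)
  metrics <- tibble(
    dataset = dataset, n = n, n_hap = nH, n_classes = attr(classes, "n_classes"),
    Hd = hd, Bd = bd,
    HBd = hap_hbd(table$count, classes$n_individuals, n,
                  both_corrected = both_corrected),
    Nd = nd, HNd = hap_hnd(hd, nd),
    pi = hap_pi(table, dist)
  )
  new_hap_complexity(metrics, table, net, classes, settings,
                     degenerate = FALSE)
}

#' Complexity metrics for a precomputed network
#'
#' Computes every network metric from an externally built haplotype network
#' (e.g. read with [read_network()]): haplotype counts are the node counts,
#' classes come from node degrees. Nucleotide diversity needs sequences and
#' is reported as `NA`.
#'
#' @inheritParams hap_complexity
#' @param network A `hap_network`.
#' @return A `hap_complexity` object (with `table = NULL`).
#' @export
hap_complexity_network <- function(network,
                                   dataset = "dataset",
                                   count_alternative = NULL,
                                   both_corrected = FALSE,
                                   lenient = FALSE) {
  validate_hap_network(network)
  if (!is.null(count_alternative)) {
    network$count_alternative <- isTRUE(count_alternative)
  }
  n <- sum(network$nodes$count)
  nH <- nrow(network$nodes)
  settings <- list(
    policy = NA_character_,
    epsilon = NA_integer_,
    count_alternative = network$count_alternative,
    both_corrected = both_corrected,
    lenient = lenient,
    hnd_is_product_assumption = TRUE
  )
  classes <- hap_class_decomposition(network)
  if (n < 2 || nH < 2) {
    if (!lenient) {
      stop_hapnet(
        paste0("Network metrics are undefined for n = ", n, ", haplotypes = ",
               nH, "; rerun with `lenient = TRUE` for an all-zero report."),
        "undefined_metric"
      )
    }
    metrics <- tibble(
      dataset = dataset, n = n, n_hap = nH, n_classes = nrow(classes),
      Hd = 0, Bd = 0, HBd = 0, Nd = 0, HNd = 0, pi = NA_real_
    )
    return(new_hap_complexity(metrics, NULL, network, classes, settings,
                              degenerate = TRUE))
  }
  hd <- hap_hd(network$nodes$count, n)
  nd <- hap_nd(classes)
  metrics <- tibble(
    dataset = dataset, n = n, n_hap = nH, n_classes = attr(classes, "n_classes"),
    Hd = hd, Bd = hap_bd(classes, n),
    HBd = hap_hbd(network$nodes$count, classes$n_individuals, n,
                  both_corrected = both_corrected),
    Nd = nd, HNd = hap_hnd(hd, nd),
    pi = NA_real_
  )
  new_hap_complexity(metrics, NULL, network, classes, settings,
                     degenerate = FALSE)
}

new_hap_complexity <- function(metrics, table, network, classes, settings,
                               degenerate) {
  structure(
    list(metrics = metrics, table = table, network = network,
         classes = classes, settings = settings,
         degenerate = isTRUE(degenerate)),
    class = "hap_complexity"
  )
}

#' @export
print.hap_complexity <- function(x, ...) {
  m <- x$metrics
  cat("# Haplotype network complexity: ", m$dataset, "\n", sep = "")
  cat("#   n = ", m$n, ", haplotypes = ", m$n_hap, ", classes = ",
      m$n_classes, if (x$degenerate) "  [degenerate]" else "", "\n", sep = "")
  vals <- c(Hd = m$Hd, Bd = m$Bd, HBd = m$HBd, Nd = m$Nd, HNd = m$HNd,
            pi = m$pi)
  cat("#   ", paste(names(vals), format_2dp(vals), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a complexity report
#'
#' @param x A `hap_complexity` object.
#' @param ... Unused.
#' @return A one-row tibble: `dataset`, `n`, `n_hap`, `n_classes`, `Hd`,
#'   `Bd`, `HBd`, `Nd`, `HNd`, `pi`, `degenerate`.
#' @export
glance.hap_complexity <- function(x, ...) {
  dplyr::mutate(x$metrics, degenerate = x$degenerate)
}

#' Long tidy view of a complexity report
#'
#' @param x A `hap_complexity` object.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value`, `rounded` (2-decimal
#'   presentation view).
#' @export
tidy.hap_complexity <- function(x, ...) {
  m <- x$metrics
  long <- tidyr::pivot_longer(
    m[, c("Hd", "Bd", "HBd", "Nd", "HNd", "pi")],
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
  dplyr::mutate(long, rounded = round_half_away(.data$value, 2))
}

#' Write a complexity report to TSV or JSON
#'
#' The TSV has one row per report with fixed column order `dataset`, `n`,
#' `nH`, `nHc`, `Hd`, `Bd`, `HBd`, `Nd`, `HNd`, `pi` carrying the 2-decimal
#' presentation view (rounded half away from zero, as diversity tables are
#' conventionally printed), followed by full-precision duplicates suffixed
#' `_full`. JSON output nests `metrics` (full precision), `rounded`, and
#' `settings`, and round-trips through [read_report()].
#'
#' @param report A `hap_complexity` object.
#' @param path Output path, or `""` for stdout.
#' @param format `"tsv"` or `"json"`.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  if (!inherits(report, "hap_complexity")) {
    stop_hapnet("Expected a `hap_complexity` report.", "bad_input")
  }
  format <- match.arg(format)
  m <- report$metrics
  metric_cols <- c("Hd", "Bd", "HBd", "Nd", "HNd", "pi")
  if (format == "tsv") {
    row <- tibble(
      dataset = m$dataset, n = m$n, nH = m$n_hap, nHc = m$n_classes
    )
    for (col in metric_cols) row[[col]] <- format_2dp(m[[col]])
    for (col in metric_cols) row[[paste0(col, "_full")]] <- m[[col]]
    out <- tryCatch(
      readr::write_tsv(row, path, progress = FALSE),
      error = function(e) {
        stop_hapnet(paste0("Cannot write report to ", path, ": ",
                           conditionMessage(e)), "io")
      }
    )
  } else {
    payload <- list(
      dataset = m$dataset,
      n = m$n, nH = m$n_hap, nHc = m$n_classes,
      metrics = as.list(m[metric_cols]),
      rounded = as.list(stats::setNames(
        round_half_away(unlist(m[metric_cols]), 2), metric_cols
      )),
      settings = report$settings,
      degenerate = report$degenerate
    )
    tryCatch(
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           na = "null"),
      error = function(e) {
        stop_hapnet(paste0("Cannot write report to ", path, ": ",
                           conditionMessage(e)), "io")
      }
    )
  }
  invisible(report)
}

#' Read back a JSON complexity report
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return A list with elements `dataset`, `n`, `nH`, `nHc`, `metrics`,
#'   `rounded`, `settings`, `degenerate`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop_hapnet(paste0("File not found: ", path), "io")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
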
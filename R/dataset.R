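# Fascicle dataset container and its plain-text CSV serialisation.

#' Fascicle observation dataset
#'
#' One group of fascicle-scale observations: replicate elastic moduli, one
#' Poisson's ratio value, and a normalized relaxation curve sampled at ~30
#' time points.
#'
#' @param dataset_id short identifier, e.g. `"D1"`.
#' @param elastic_moduli positive fascicle elastic moduli in MPa.
#' @param poisson_value single dimensionless Poisson's ratio; `NA` allowed
#'   when the volumetric observable is unavailable.
#' @param times strictly increasing sampling times in seconds.
#' @param Ebar normalized moduli in (0, 1\], same length as `times`.
#' @param provenance `"fixture"` or `"file"`.
#' @param truth optional list recording the generating ground truth of a
#'   synthetic dataset (a [material_params()] plus a [fascicle_class()]).
#' @return An object of class `"fascicle_dataset"`.
#' @export
fascicle_dataset <- function(dataset_id, elastic_moduli, poisson_value,
                             times, Ebar,
                             provenance = c("fixture", "file"),
                             truth = NULL) {
  provenance <- match.arg(provenance)
  if (!is.character(dataset_id) || length(dataset_id) != 1L || !nzchar(dataset_id))
    stop("dataset_id must be a non-empty string", call. = FALSE)
  elastic_moduli <- as.numeric(elastic_moduli)
  if (length(elastic_moduli) == 0L || any(!is.finite(elastic_moduli)) ||
      any(elastic_moduli <= 0))
    stop("elastic_moduli must be positive", call. = FALSE)
  poisson_value <- as.numeric(poisson_value)
  if (length(poisson_value) != 1L ||
      (!is.na(poisson_value) && (!is.finite(poisson_value) || poisson_value <= 0)))
    stop("poisson_value must be a single positive value or NA", call. = FALSE)
  times <- as.numeric(times); Ebar <- as.numeric(Ebar)
  if (length(times) != length(Ebar) || length(times) < 2L)
    stop("times and Ebar must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(Ebar)) || any(Ebar <= 0) || any(Ebar > 1))
    stop("Ebar values must lie in (0, 1]", call. = FALSE)
  structure(list(dataset_id = dataset_id,
                 elastic_moduli = elastic_moduli,
                 poisson_value = poisson_value,
                 times = times, Ebar = Ebar,
                 provenance = provenance,
                 truth = truth),
            class = "fascicle_dataset")
}

#' @export
print.fascicle_dataset <- function(x, ...) {
  cat(sprintf("Fascicle dataset %s (%s)\n", x$dataset_id, x$provenance))
  cat(sprintf("  elastic moduli [MPa]: %s\n",
              paste(format(x$elastic_moduli), collapse = ", ")))
  cat(sprintf("  Poisson's ratio: %s\n", format(x$poisson_value)))
  cat(sprintf("  relaxation curve: %d points over [%g, %g] s, Ebar %0.3g -> %0.3g\n",
              length(x$times), min(x$times), max(x$times),
              x$Ebar[1L], x$Ebar[length(x$Ebar)]))
  if (!is.null(x$truth)) cat("  (synthetic; ground truth recorded)\n")
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a fascicle dataset to its CSV text format
#'
#' The format is a small header block (`dataset_id`, `poisson_value`,
#' `elastic_moduli` as a semicolon-separated list, `provenance`) followed by
#' a two-column `time_s,Ebar` table.  Numbers are stored at 17 significant
#' digits so the round-trip through [read_fascicle_dataset()] is exact for
#' the numeric payload.
#'
#' @param data a [fascicle_dataset()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_fascicle_dataset <- function(data, path) {
  stopifnot(inherits(data, "fascicle_dataset"))
  lines <- c(
    "# fascicle dataset v1",
    paste0("dataset_id,", data$dataset_id),
    paste0("poisson_value,", if (is.na(data$poisson_value)) "NA"
           else fmt17(data$poisson_value)),
    paste0("elastic_moduli,", paste(fmt17(data$elastic_moduli), collapse = ";")),
    paste0("provenance,", data$provenance),
    "time_s,Ebar",
    paste(fmt17(data$times), fmt17(data$Ebar), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fascicle dataset from its CSV text format
#'
#' @param path file written by [write_fascicle_dataset()].
#' @return A [fascicle_dataset()] with provenance `"file"`.
#' @export
read_fascicle_dataset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header_get <- function(key) {
    hit <- grep(paste0("^", key, ","), lines, value = TRUE)
    if (length(hit) != 1L)
      stop("malformed dataset file: missing header '", key, "'", call. = FALSE)
    sub(paste0("^", key, ","), "", hit)
  }
  id <- header_get("dataset_id")
  pv <- header_get("poisson_value")
  pv <- if (identical(pv, "NA")) NA_real_ else as.numeric(pv)
  em <- as.numeric(strsplit(header_get("elastic_moduli"), ";", fixed = TRUE)[[1L]])
  tab_start <- which(lines == "time_s,Ebar")
  if (length(tab_start) != 1L)
    stop("malformed dataset file: missing 'time_s,Ebar' table", call. = FALSE)
  body <- lines[(tab_start + 1L):length(lines)]
  parts <- strsplit(body, ",", fixed = TRUE)
  times <- as.numeric(vapply(parts, `[[`, "", 1L))
  ebar <- as.numeric(vapply(parts, `[[`, "", 2L))
  fascicle_dataset(id, em, pv, times, ebar, provenance = "file")
}
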
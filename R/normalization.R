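#' Protein-dispersion justification check
#'
#' Ratiometric protein correction of tissue reductive-capacity values is only
#' justified when sample protein content stays close to a representative
#' sample: a sample qualifies iff its protein concentration deviates from the
#' reference by strictly less than `tolerance` (default 50%) of the reference
#' value. The boundary is exclusive: a deviation of exactly 50% is *not*
#' justified.
#'
#' @param protein A data frame with columns `label` (unique) and `protein`
#'   (positive, arbitrary but uniform units).
#' @param reference `"median"` (default: the batch median protein
#'   concentration stands in for the representative sample), a sample label,
#'   or a numeric reference concentration.
#' @param tolerance Allowed fractional deviation (default 0.5).
#' @return The input as a tibble with added columns `reference_value`,
#'   `deviation` (fractional `|p - ref| / ref`) and `justified` (logical).
#' @examples
#' p <- data.frame(label = c("a", "b"), protein = c(2.0, 2.9))
#' check_dispersion(p, reference = 2.0)
#' @export
check_dispersion <- function(protein, reference = "median", tolerance = 0.5) {
  if (!all(c("label", "protein") %in% names(protein))) {
    stop("need columns `label` and `protein`", call. = FALSE)
  }
  protein <- tibble::as_tibble(protein)
  if (anyDuplicated(protein$label)) stop("sample labels must be unique", call. = FALSE)
  if (anyNA(protein$protein) || any(protein$protein <= 0)) {
    stop("protein concentrations must be positive", call. = FALSE)
  }
  ref <- resolve_reference(protein, reference)
  protein |>
    dplyr::mutate(
      reference_value = ref,
      deviation = abs(.data$protein - ref) / ref,
      justified = .data$deviation < tolerance
    )
}

resolve_reference <- function(protein, reference) {
  if (is.numeric(reference)) {
    if (reference <= 0) stop("reference protein value must be positive", call. = FALSE)
    return(reference)
  }
  if (identical(reference, "median")) return(stats::median(protein$protein))
  hit <- match(reference, protein$label)
  if (is.na(hit)) stop("reference sample not found: ", reference, call. = FALSE)
  protein$protein[hit]
}

#' Ratiometric protein-content correction
#'
#' Corrects per-sample integrated densities for unequal protein loading:
#' `corrected = density * reference / protein`, so a sample loaded at twice
#' the reference protein has its signal halved, and a reference-matched
#' sample is unchanged. The correction assumes signal is linear in protein
#' content; as an audit aid the output carries the R^2 of density on protein
#' over the justified samples (attribute `linearity`), since strong
#' nonlinearity would undermine the ratio.
#'
#' By default only samples passing the dispersion rule may be corrected;
#' `override = TRUE` corrects everything and leaves the `justified` flag in
#' the output for the analyst to act on.
#'
#' @param densities Data frame with columns `label` and `integrated_density`.
#' @param protein Data frame with columns `label` and `protein`; every
#'   density label must be present.
#' @param reference,tolerance Passed to [check_dispersion()].
#' @param override If `TRUE`, correct unjustified samples too (flagged).
#' @return Tibble `label`, `raw`, `protein`, `deviation`, `justified`,
#'   `corrected`; attribute `linearity` holds the density-vs-protein
#'   regression audit (tibble from [compare_methods()], or `NULL` when fewer
#'   than 3 justified samples exist).
#' @export
ratiometric_correct <- function(densities, protein, reference = "median",
                                tolerance = 0.5, override = FALSE) {
  if (!all(c("label", "integrated_density") %in% names(densities))) {
    stop("need columns `label` and `integrated_density` in `densities`",
         call. = FALSE)
  }
  disp <- check_dispersion(protein, reference = reference, tolerance = tolerance)
  missing <- setdiff(densities$label, disp$label)
  if (length(missing)) {
    stop("no protein entry for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(densities), "label",
                  raw = "integrated_density"),
    dplyr::select(disp, "label", "protein", "reference_value", "deviation",
                  "justified"),
    by = "label"
  )
  if (!override && any(!joined$justified)) {
    stop("correction not justified for: ",
         paste(joined$label[!joined$justified], collapse = ", "),
         " (deviation >= tolerance); pass override = TRUE to force",
         call. = FALSE)
  }
  out <- joined |>
    dplyr::mutate(corrected = .data$raw * .data$reference_value / .data$protein) |>
    dplyr::select("label", "raw", "protein", "deviation", "justified",
                  "corrected")
  just <- dplyr::filter(joined, .data$justified)
  attr(out, "linearity") <-
    if (nrow(just) >= 3 && stats::sd(just$protein) > .Machine$double.eps) {
      compare_methods(just$protein, just$raw)
    } else NULL
  out
}
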
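#' Background-corrected CD107a signal
#'
#' The degranulation readout for one tested TCR, corrected for both the
#' unstimulated baseline of the transfected T cells and the response of
#' mock-electroporated T cells:
#' \deqn{(\%CD107a_{TCR vs line} - \%CD107a_{TCR,unstim}) -
#'       (\%CD107a_{mock vs line} - \%CD107a_{mock,unstim})}
#' The result is in percentage points and may be negative.
#'
#' @param assay data.frame (rows of the reactivity table) or single-row list
#'   with fields \code{pct_cd107a_vs_line}, \code{pct_cd107a_unstim},
#'   \code{pct_cd107a_mock_vs_line}, \code{pct_cd107a_mock_unstim}.
#' @return Numeric vector of corrected percentages.
#' @export
background_corrected_cd107a <- function(assay) {
  (assay$pct_cd107a_vs_line - assay$pct_cd107a_unstim) -
    (assay$pct_cd107a_mock_vs_line - assay$pct_cd107a_mock_unstim)
}

#' Call TCR tumor reactivity from flow readouts
#'
#' A TCR enters the analysis only if its transgenic-TCR expression
#' (mTCRbeta) exceeds 2\%; otherwise it is \code{"excluded"}. Included TCRs
#' are \code{"reactive"} when the background-corrected CD107a signal is
#' strictly larger than twice the standard deviation of the unstimulated
#' CD107a signal (\code{sd_unstim}, in percentage points; 0.34 was measured
#' on the assay plates this rule was developed with), else
#' \code{"nonreactive"}.
#'
#' @param assay data.frame of assay rows (see [read_reactivity_table()]).
#' @param sd_unstim Standard deviation (\%) of the unstimulated CD107a
#'   signal across all wells; non-negative.
#' @return The input with columns \code{corrected} (NA when excluded) and
#'   \code{label} (\code{reactive}/\code{nonreactive}/\code{excluded})
#'   appended.
#' @export
call_tcr_reactive <- function(assay, sd_unstim = 0.34) {
  if (!is.numeric(sd_unstim) || length(sd_unstim) != 1 || sd_unstim < 0)
    stop_validation("sd_unstim must be a single non-negative number")
  corrected <- background_corrected_cd107a(assay)
  excluded <- assay$pct_mtcrb <= 2
  label <- ifelse(excluded, "excluded",
                  ifelse(corrected > 2 * sd_unstim, "reactive",
                         "nonreactive"))
  assay$corrected <- ifelse(excluded, NA_real_, corrected)
  assay$label <- label
  assay
}

#' Broadcast clonotype-level reactivity labels to cells
#'
#' Every cell whose clonotype was tested inherits that clonotype's binary
#' label; cells of untested clonotypes receive no label. Healthy-donor
#' control cells (supplied via \code{control_barcodes}) are labeled
#' nonreactive. Where a clonotype was tested through more than one chain
#' pair (dual-alpha TCRs), the labels must agree — the convention is that
#' the functional pair's readout defines the clonotype label.
#'
#' @param assays data.frame with \code{clonotype_id} and \code{label}
#'   columns (from [call_tcr_reactive()]); \code{excluded} rows are ignored.
#' @param clonotypes Clonotype table (see [read_contig_annotations()]).
#' @param control_barcodes Optional character vector of healthy-donor cell
#'   barcodes to label nonreactive.
#' @return data.frame with columns \code{barcode}, \code{clonotype_id},
#'   \code{label} (\code{"reactive"} or \code{"nonreactive"}).
#' @export
propagate_labels <- function(assays, clonotypes,
                             control_barcodes = character()) {
  assays <- assays[assays$label != "excluded", , drop = FALSE]
  # functional-pair rule: a clonotype tested through several chain pairs is
  # reactive if any pair elicited the corrected CD107a response
  lab_map <- vapply(split(assays$label, assays$clonotype_id), function(l)
    if ("reactive" %in% l) "reactive" else "nonreactive", character(1))
  unknown <- setdiff(names(lab_map), clonotypes$clonotype_id)
  if (length(unknown))
    stop_validation("labeled clonotype(s) absent from clonotype table: ",
                    paste(unknown, collapse = ", "))
  cells <- unique(clonotypes[, c("barcode", "clonotype_id")])
  cells <- cells[cells$clonotype_id %in% names(lab_map), , drop = FALSE]
  out <- data.frame(barcode = cells$barcode,
                    clonotype_id = cells$clonotype_id,
                    label = unname(lab_map[cells$clonotype_id]),
                    stringsAsFactors = FALSE)
  if (length(control_barcodes)) {
    out <- rbind(out, data.frame(barcode = control_barcodes,
                                 clonotype_id = NA_character_,
                                 label = "nonreactive",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
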
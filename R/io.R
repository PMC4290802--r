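# Panel TSV dialect: tab-separated, header row, UTF-8, '.' decimals.
# Columns: snp_id, r0, r1, r2 and EITHER s0, s1, s2 OR control_maf
# (expanded under HWE on read). Lines starting with '#' are comments
# (used by the CLI for provenance headers).

#' Read a SNP panel from TSV
#'
#' Expects columns `snp_id, r0, r1, r2` plus either explicit control
#' genotype counts `s0, s1, s2` or a `control_maf` column, in which case
#' the control row is derived under Hardy-Weinberg equilibrium for
#' `n_controls` individuals. Every row is validated; failures report the
#' offending data line.
#'
#' @param path Path to a tab-separated panel file.
#' @param n_controls Control sample size `S`; required when the file
#'   supplies `control_maf` instead of counts.
#' @return A panel tibble.
#' @export
read_panel <- function(path, n_controls = NULL) {
  panel <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  if (!"snp_id" %in% names(panel)) {
    stop("Panel file must have a `snp_id` column: ", path, call. = FALSE)
  }
  panel$snp_id <- as.character(panel$snp_id)
  has_counts <- all(c("s0", "s1", "s2") %in% names(panel))
  if (!has_counts) {
    if (!"control_maf" %in% names(panel)) {
      stop("Panel file must have either s0/s1/s2 or control_maf columns: ",
           path, call. = FALSE)
    }
    if (is.null(n_controls)) {
      stop("`n_controls` is required to expand `control_maf` into control ",
           "genotype counts.", call. = FALSE)
    }
    ctrl <- hwe_control_genotypes(panel$control_maf, n_controls)
    panel <- dplyr::bind_cols(panel, ctrl)
  }
  validate_panel_rows(panel, path)
  panel
}

validate_panel_rows <- function(panel, path) {
  ok <- tryCatch({
    check_panel(panel)
    TRUE
  }, error = function(e) e)
  if (isTRUE(ok)) return(invisible(panel))
  # re-run row-wise to report the first offending data line (1-based,
  # excluding the header)
  for (i in seq_len(nrow(panel))) {
    bad <- tryCatch({
      check_panel_counts(panel[i, , drop = FALSE])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(bad)) {
      stop("Invalid panel row at data line ", i, " of ", path, ": ", bad,
           call. = FALSE)
    }
  }
  stop("Invalid panel in ", path, ": ", conditionMessage(ok),
       call. = FALSE)
}

#' Write a SNP panel (or any result tibble) to TSV
#'
#' Emits the same dialect [read_panel()] consumes; integer-valued cells are
#' written without decimal points, so integer panels round-trip
#' byte-identically.
#'
#' @param panel A data frame.
#' @param path Output path.
#' @param comment_lines Optional character vector written as `#`-prefixed
#'   header lines (provenance).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, comment_lines = NULL) {
  if (!is.null(comment_lines)) {
    writeLines(paste0("# ", comment_lines), path)
    readr::write_tsv(panel, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(panel, path, progress = FALSE)
  }
  invisible(path)
}
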
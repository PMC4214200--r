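#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

## interchange column names <-> internal names
tc_csv_cols <- c(
  condition = "condition", replicate = "replicate", day = "day",
  acetate_mM = "acetate_mm", pCH4_atm = "p_ch4_atm", pH2_Pa = "p_h2_pa",
  HCO3_mM = "bicarbonate_mm", pH = "ph", temperature_K = "temperature_k"
)

#' Read a tidy time-course CSV/TSV
#'
#' One row per condition x replicate x day. Required columns:
#' `condition`, `replicate`, `day`, `acetate_mM`, `pCH4_atm` (or
#' `pCH4_Pa`, converted by 1 atm = 101325 Pa), `pH2_Pa`, `HCO3_mM`, `pH`;
#' optional `temperature_K` (default 328.15). Comma or tab delimiters are
#' autodetected and lines starting with `#` are ignored. Rows with
#' unparseable cells are reported with their line numbers.
#'
#' @param path File path.
#' @param temperature_k Temperature assigned when the file has no
#'   `temperature_K` column.
#' @return A tibble in the package's internal column convention
#'   (`acetate_mm`, `p_ch4_atm`, `p_h2_pa`, `bicarbonate_mm`, `ph`,
#'   `temperature_k`).
#' @export
read_timecourse_csv <- function(path, temperature_k = 328.15) {
  first <- readLines(path, n = 10)
  first <- first[!startsWith(first, "#")][1]
  delim <- if (grepl("\t", first)) "\t" else ","
  ## parse as character and convert with base strtod: exact round trip of
  ## doubles written at 17 significant digits
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, trim_ws = TRUE,
                           col_types = readr::cols(
                             .default = readr::col_character()))
  need <- c("condition", "replicate", "day", "acetate_mM", "pH2_Pa",
            "HCO3_mM", "pH")
  missing <- setdiff(need, names(raw))
  if (!any(c("pCH4_atm", "pCH4_Pa") %in% names(raw)))
    missing <- c(missing, "pCH4_atm (or pCH4_Pa)")
  if (length(missing))
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", "),
                 ". Expected header: condition, replicate, day, ",
                 "acetate_mM, pCH4_atm|pCH4_Pa, pH2_Pa, HCO3_mM, pH."))
  numeric_in <- intersect(c("replicate", "day", "acetate_mM", "pCH4_atm",
                            "pCH4_Pa", "pH2_Pa", "HCO3_mM", "pH",
                            "temperature_K"), names(raw))
  for (col in numeric_in) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad))
      abort(paste0("Non-numeric value(s) in column `", col,
                   "` at data row(s): ", paste(bad, collapse = ", ")))
    raw[[col]] <- vals
  }
  if (!"pCH4_atm" %in% names(raw))
    raw$pCH4_atm <- raw$pCH4_Pa / ATM_PA
  if (!"temperature_K" %in% names(raw))
    raw$temperature_K <- temperature_k
  out <- raw[, names(tc_csv_cols)]
  names(out) <- unname(tc_csv_cols)
  # keep the file's condition ordering (simulated data writes low/mid/high)
  out$condition <- factor(out$condition, levels = unique(out$condition))
  as_tibble(out)
}

#' Write a tidy time-course CSV
#'
#' Inverse of [read_timecourse_csv()]: writes the interchange header
#' (`condition, replicate, day, acetate_mM, pCH4_atm, pH2_Pa, HCO3_mM, pH,
#' temperature_K`), preceded by `#` comment lines naming units and, when
#' supplied, a configuration hash.
#'
#' @param x Time-course tibble in internal column convention.
#' @param path Output path.
#' @param config_hash Optional hash string recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(x, path, config_hash = NULL) {
  need <- unname(tc_csv_cols)
  missing <- setdiff(need, names(x))
  if (length(missing))
    abort(paste0("`x` is missing columns: ", paste(missing, collapse = ", ")))
  out <- as_tibble(x)[, need]
  names(out) <- names(tc_csv_cols)
  # 17 significant digits: doubles survive the write/read round trip exactly
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sub("e", "E", sprintf("%.17g", v)))
  hdr <- c(
    "# tidy tri-culture time course: acetate_mM [mmol/L], pCH4_atm [atm],",
    "# pH2_Pa [Pa], HCO3_mM [mmol/L], pH [-], temperature_K [K]"
  )
  if (!is.null(config_hash))
    hdr <- c(hdr, paste0("# config_hash: ", config_hash))
  writeLines(hdr, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

## generic CSV writer with unit comment + config hash header
write_result_csv <- function(x, path, comment, config_hash = NULL) {
  hdr <- paste0("# ", comment)
  if (!is.null(config_hash))
    hdr <- c(hdr, paste0("# config_hash: ", config_hash))
  writeLines(hdr, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
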
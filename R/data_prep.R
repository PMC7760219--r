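#' Somatic cell score transform
#'
#' `SCS = log2(SCC / 100,000) + 3`, the standard variance-stabilizing
#' transform of somatic cell count.
#'
#' @param scc Somatic cell count, cells/mL; must be strictly positive.
#' @return Somatic cell score (unitless).
#' @examples
#' scs_from_scc(c(1e5, 4e5)) # 3, 5
#' @export
scs_from_scc <- function(scc) {
  if (!is.numeric(scc)) stop("scc must be numeric")
  bad <- !is.na(scc) & scc <= 0
  if (any(bad)) stop("scc must be > 0 (", sum(bad), " offending values)")
  log2(scc / 1e5) + 3
}

#' @rdname scs_from_scc
#' @param scs Somatic cell score.
#' @export
scc_from_scs <- function(scs) 1e5 * 2^(scs - 3)

#' Collapse the four-class teat score into a binary trait
#'
#' Scheme `"a"` merges classes 2-4 against class 1 (any callosity ring);
#' scheme `"b"` merges classes 1-2 against 3-4 (rough ring or worse).
#'
#' @param ts Integer teat scores in 1..4.
#' @param scheme `"a"` or `"b"`.
#' @return Integer 0/1 vector (1 = affected class).
#' @export
collapse_ts <- function(ts, scheme = c("a", "b")) {
  scheme <- match.arg(scheme)
  ok <- is.na(ts) | (ts %in% 1:4)
  if (!all(ok)) stop("teat scores must lie in 1..4")
  cut <- if (scheme == "a") 2L else 3L
  as.integer(ts >= cut)
}

#' Parity-by-stage-of-lactation class
#'
#' Maps parity and lactation month onto the 36-class fixed-effect grid:
#' parity truncated to \{1, 2, 3+\}, months 12 and later pooled into the
#' final stage bin (records are admitted up to month 15 upstream).
#'
#' @param parity Lactation number (>= 1).
#' @param month Month of lactation (>= 1).
#' @return Integer class index in 1..36.
#' @export
parity_stage_class <- function(parity, month) {
  if (!is.numeric(parity) || !is.numeric(month)) stop("inputs must be numeric")
  bad <- (!is.na(parity) & parity < 1) | (!is.na(month) & month < 1)
  if (any(bad)) stop("parity and month must be >= 1")
  p <- pmin(as.integer(parity), 3L)
  m <- pmin(as.integer(month), 12L)
  (p - 1L) * 12L + m
}

quarter_levels <- function() c("FL", "FR", "RL", "RR")

#' Stack teat-score and test-day records into the analysis dataset
#'
#' Builds the stacked dataset in which each row carries either one teat
#' observation (one quarter of one scoring visit) or one test-day
#' production pair (MY, SCS) - never both, so the residual covariance
#' between the two blocks is structurally zero.  Filters applied, each
#' logged in the `filter_log` attribute:
#' * cows without all four quarter scores are dropped;
#' * production records outside the scoring lactation are dropped;
#' * records beyond `max_month` months in milk are dropped;
#' * cows absent from the pedigree (or with unknown sire) are dropped.
#'
#' @param teat Tibble of per-quarter teat records: `cow`, `herd`,
#'   `parity`, `month`, `hygiene` (1-4), `quarter` (FL/FR/RL/RR),
#'   `ts` (1-4).
#' @param production Tibble of test-day records: `cow`, `herd`, `parity`,
#'   `month`, `my` (kg/day) and `scc` (cells/mL) and/or `scs`.
#' @param pedigree Pedigree data frame (`id`, `sire`, `dam`) used to map
#'   each cow to her sire.
#' @param max_month Last admitted month of lactation (default 15).
#' @return A tibble with columns `block` ("teat"/"prod"), `cow`, `herd`,
#'   `sire`, `parity`, `month`, `ps_class`, `hygiene`, `quarter`, `ts`,
#'   `my`, `scs`; attribute `filter_log` records drop counts.
#' @export
stack_records <- function(teat, production, pedigree, max_month = 15) {
  teat <- tibble::as_tibble(teat)
  production <- tibble::as_tibble(production)
  need_t <- c("cow", "herd", "parity", "month", "hygiene", "quarter", "ts")
  if (length(miss <- setdiff(need_t, names(teat))))
    stop("teat records lack columns: ", paste(miss, collapse = ", "))
  need_p <- c("cow", "herd", "parity", "month", "my")
  if (length(miss <- setdiff(need_p, names(production))) && nrow(production))
    stop("production records lack columns: ", paste(miss, collapse = ", "))
  if (!"scs" %in% names(production)) {
    production$scs <- if (nrow(production)) {
      if (!"scc" %in% names(production))
        stop("production records need scc or scs")
      scs_from_scc(production$scc)
    } else numeric(0)
  }
  log <- list()

  teat$cow <- as.character(teat$cow)
  production$cow <- as.character(production$cow)
  if (!all(teat$quarter %in% quarter_levels()))
    stop("quarter must be one of ", paste(quarter_levels(), collapse = ", "))
  if (!all(teat$ts %in% 1:4)) stop("teat scores must lie in 1..4")
  if (!all(teat$hygiene %in% 1:4)) stop("hygiene scores must lie in 1..4")

  # exactly four quarter rows per scored cow
  nq <- table(teat$cow)
  full4 <- names(nq)[nq == 4L]
  dropped_cows <- setdiff(names(nq), full4)
  if (length(dropped_cows)) {
    warning(length(dropped_cows),
            " cow(s) without all four quarter scores dropped")
    log$incomplete_quarters <- sum(teat$cow %in% dropped_cows)
    teat <- teat[teat$cow %in% full4, ]
  }

  # one scoring visit per cow: parity at scoring
  scoring <- teat |>
    dplyr::distinct(.data$cow, .data$parity) |>
    dplyr::distinct(.data$cow, .keep_all = TRUE)

  n0 <- nrow(production)
  production <- production |>
    dplyr::inner_join(scoring, by = "cow", suffix = c("", ".score")) |>
    dplyr::filter(.data$parity == .data$parity.score) |>
    dplyr::select(-"parity.score")
  log$production_other_lactation <- n0 - nrow(production)

  n0 <- nrow(teat); n1 <- nrow(production)
  teat <- teat[teat$month <= max_month, ]
  production <- production[production$month <= max_month, ]
  log$beyond_max_month <- (n0 - nrow(teat)) + (n1 - nrow(production))

  # cow -> sire through the pedigree
  ped <- ped_normalize(pedigree)
  sire_of <- setNames(ped$sire, ped$id)
  known <- function(cw) cw %in% ped$id & !is.na(sire_of[cw])
  drop_t <- !known(teat$cow)
  drop_p <- !known(production$cow)
  if (any(drop_t) || any(drop_p)) {
    warning(length(unique(c(teat$cow[drop_t], production$cow[drop_p]))),
            " cow(s) absent from pedigree (or with unknown sire) dropped")
    log$not_in_pedigree <- sum(drop_t) + sum(drop_p)
    teat <- teat[!drop_t, ]
    production <- production[!drop_p, ]
  }

  teat_rows <- tibble::tibble(
    block = "teat", cow = teat$cow, herd = as.character(teat$herd),
    sire = unname(sire_of[teat$cow]),
    parity = as.integer(teat$parity), month = as.integer(teat$month),
    ps_class = parity_stage_class(teat$parity, teat$month),
    hygiene = as.integer(teat$hygiene), quarter = as.character(teat$quarter),
    ts = as.integer(teat$ts), my = NA_real_, scs = NA_real_)
  prod_rows <- tibble::tibble(
    block = "prod", cow = production$cow, herd = as.character(production$herd),
    sire = unname(sire_of[production$cow]),
    parity = as.integer(production$parity),
    month = as.integer(production$month),
    ps_class = parity_stage_class(production$parity, production$month),
    hygiene = NA_integer_, quarter = NA_character_, ts = NA_integer_,
    my = as.numeric(production$my), scs = as.numeric(production$scs))

  out <- dplyr::bind_rows(teat_rows, prod_rows)
  attr(out, "filter_log") <- tibble::tibble(
    step = names(log) %||% character(0),
    n_dropped = unname(unlist(log)) %||% integer(0))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write / read a stacked dataset
#'
#' The stacked table is written as tab-separated text with a JSON sidecar
#' holding the level dictionaries (herd, cow, sire ids and the class
#' grids), so a run can be reproduced from files alone.
#'
#' @param stacked Output of [stack_records()].
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stacked <- function(stacked, path) {
  utils::write.table(stacked, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sidecar <- list(
    herds = sort(unique(stacked$herd)),
    cows = sort(unique(stacked$cow)),
    sires = sort(unique(stacked$sire)),
    quarters = quarter_levels(),
    n_parity_stage_classes = 36L,
    n_rows = nrow(stacked))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stacked
#' @export
read_stacked <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = list(cow = "character",
                                            herd = "character",
                                            sire = "character"))
  tibble::as_tibble(df)
}

#' Read raw teat-score / test-day record files
#'
#' Thin delimited-text readers for the two raw inputs of
#' [stack_records()]; column names can be remapped via `columns`.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @param columns Optional named character vector mapping standard names
#'   (e.g. `cow`, `herd`, ...) to the file's column names.
#' @return A tibble.
#' @export
read_teat_records <- function(path, delim = "\t", columns = NULL) {
  read_mapped(path, delim, columns)
}

#' @rdname read_teat_records
#' @export
read_production_records <- function(path, delim = "\t", columns = NULL) {
  read_mapped(path, delim, columns)
}

read_mapped <- function(path, delim, columns) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = delim, header = TRUE,
                                            stringsAsFactors = FALSE))
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (!columns[[std]] %in% names(df))
        stop("column '", columns[[std]], "' not found in ", path)
      names(df)[names(df) == columns[[std]]] <- std
    }
  }
  df
}
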
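# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table data.table as.data.table setDT copy setorder
#'   setnames rbindlist fread fwrite := .N .I .SD setattr as.IDate
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# global RNG state (single explicit stream per call, no leakage).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Half-up decimal rounding (presentation convention for percentage tables;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# FAERS dates travel as yyyymmdd character strings; partial dates are yyyymm
# or yyyy, missing is "". Only full-precision 8-character dates convert.
is_full_date <- function(x) {
  !is.na(x) & nchar(x) == 8L & grepl("^[0-9]{8}$", x)
}

faers_date_to_idate <- function(x) {
  out <- rep(as.IDate(NA), length(x))
  ok <- is_full_date(x)
  if (any(ok)) out[ok] <- as.IDate(x[ok], format = "%Y%m%d")
  out
}

idate_to_faers <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  out[ok] <- format(x[ok], "%Y%m%d")
  out
}

# yyyyQq label for a date, used by the study-window filter.
date_quarter <- function(x) {
  y <- data.table::year(x)
  q <- (data.table::month(x) - 1L) %/% 3L + 1L
  y * 10L + q
}

quarter_label_to_num <- function(lab) {
  m <- regmatches(lab, regexec("^([0-9]{4})Q([1-4])$", lab))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("quarter labels must look like '2005Q1'", call. = FALSE)
  vapply(m, function(g) as.integer(g[2]) * 10L + as.integer(g[3]), 1L)
}
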
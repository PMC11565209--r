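#' Physical constants for diffusive conductance calculations
#'
#' Container for the two physical constants entering the anatomical maximum
#' stomatal conductance equation: the diffusivity of water vapour in air and
#' the molar volume of air.
#'
#' Defaults are the standard values at 25 degrees C and 101.3 kPa:
#' d = 2.46e-5 m^2 s^-1 and v = 2.44e-2 m^3 mol^-1.
#'
#' @param d Diffusivity of water vapour in air, m^2 s^-1. Must be positive.
#' @param v Molar volume of air, m^3 mol^-1. Must be positive.
#' @return An object of class `"gasx_constants"`: a named list with elements
#'   `d` and `v`.
#' @examples
#' gasx_constants()
#' gasx_constants(d = 2.5e-5)
#' @export
gasx_constants <- function(d = 24.6e-6, v = 24.4e-3) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(v), length(v) == 1L, is.finite(v))
  if (d <= 0) stop("diffusivity `d` must be > 0", call. = FALSE)
  if (v <= 0) stop("molar volume `v` must be > 0", call. = FALSE)
  structure(list(d = d, v = v), class = "gasx_constants")
}

#' @export
print.gasx_constants <- function(x, ...) {
  cat("Gas-exchange constants:\n")
  cat(sprintf("  d (water vapour diffusivity) = %.4g m^2 s^-1\n", x$d))
  cat(sprintf("  v (molar volume of air)      = %.4g m^3 mol^-1\n", x$v))
  invisible(x)
}

#' Construct a gas-exchange time/level series
#'
#' A `gasx_series` holds one plant's log for one measurement protocol:
#' elapsed time, incident light, net CO2 assimilation, stomatal conductance
#' to water vapour, and intercellular and ambient CO2 mole fractions.
#'
#' @param plant_id Plant identifier (single string).
#' @param accession Accession (genotype) identifier (single string).
#' @param protocol Either `"light_curve"` (stepwise A/Q response) or
#'   `"step_change"` (low-to-high irradiance step).
#' @param t Elapsed time in seconds, strictly increasing, 0-based within the
#'   protocol segment.
#' @param Q Photosynthetic photon flux density, umol m^-2 s^-1, >= 0.
#' @param A Net CO2 assimilation rate, umol m^-2 s^-1.
#' @param gs Stomatal conductance to water vapour, mol m^-2 s^-1, >= 0.
#' @param Ci Intercellular CO2 mole fraction, umol mol^-1.
#' @param Ca Ambient (cuvette) CO2 mole fraction, umol mol^-1, > 0. A warning
#'   is raised if any value strays more than 5% from the 400 umol mol^-1
#'   set-point the protocols assume.
#' @return An object of class `"gasx_series"`: a data frame with columns
#'   `t`, `Q`, `A`, `gs`, `Ci`, `Ca` and attributes `plant_id`, `accession`,
#'   `protocol`.
#' @seealso [read_gasx_table()], [validate_protocol()], [window_mean()]
#' @export
gasx_series <- function(plant_id, accession, protocol, t, Q, A, gs, Ci, Ca) {
  protocol <- match.arg(protocol, c("light_curve", "step_change"))
  stopifnot(is.character(plant_id), length(plant_id) == 1L,
            is.character(accession), length(accession) == 1L)
  n <- length(t)
  if (n < 2L) stop("a gasx_series needs at least 2 records", call. = FALSE)
  vars <- list(t = t, Q = Q, A = A, gs = gs, Ci = Ci, Ca = Ca)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v)) stop(sprintf("column `%s` must be numeric", nm), call. = FALSE)
    if (length(v) != n)
      stop(sprintf("column `%s` has length %d, expected %d", nm, length(v), n),
           call. = FALSE)
  }
  dup <- which(diff(t) <= 0)
  if (length(dup))
    stop(sprintf("time must be strictly increasing; violation at row %d (t = %g)",
                 dup[1L] + 1L, t[dup[1L] + 1L]), call. = FALSE)
  if (any(Q < 0, na.rm = TRUE)) stop("Q must be >= 0", call. = FALSE)
  if (any(gs < 0, na.rm = TRUE)) stop("gs must be >= 0", call. = FALSE)
  if (any(Ca <= 0, na.rm = TRUE)) stop("Ca must be > 0", call. = FALSE)
  if (any(abs(Ca - 400) > 0.05 * 400, na.rm = TRUE))
    warning("Ca deviates more than 5% from the 400 umol mol^-1 set-point",
            call. = FALSE)
  out <- data.frame(t = as.numeric(t), Q = as.numeric(Q), A = as.numeric(A),
                    gs = as.numeric(gs), Ci = as.numeric(Ci), Ca = as.numeric(Ca))
  structure(out, class = c("gasx_series", "data.frame"),
            plant_id = plant_id, accession = accession, protocol = protocol)
}

#' @export
print.gasx_series <- function(x, ...) {
  cat(sprintf("<gasx_series> plant %s (accession %s), protocol %s, %d records\n",
              attr(x, "plant_id"), attr(x, "accession"), attr(x, "protocol"),
              nrow(x)))
  cat(sprintf("  t: %g..%g s | Q: %g..%g umol m^-2 s^-1\n",
              min(x$t), max(x$t), min(x$Q), max(x$Q)))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
plot.gasx_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$A, xlab = "t (s)", ylab = "A (umol m-2 s-1)", ...)
  graphics::plot(x$t, x$gs, xlab = "t (s)", ylab = "gs (mol m-2 s-1)", ...)
  invisible(x)
}

# default header synonyms for the two instrument export dialects
.default_col_map <- function() {
  list(t     = c("t", "elapsed", "time", "TIME", "Elapsed"),
       Q     = c("Q", "Qin", "PARi", "PPFD", "Qamb_in"),
       A     = c("A", "Photo", "anet"),
       gs    = c("gs", "gsw", "Cond", "cond"),
       Ci    = c("Ci", "ci", "CI"),
       Ca    = c("Ca", "CO2_s", "CO2S", "CO2R", "ca"),
       plant_id  = c("plant_id", "plant", "id"),
       accession = c("accession", "genotype", "line"),
       protocol  = c("protocol"))
}

#' Dialect configuration for reading gas-exchange tables
#'
#' Column-name mapping and separator used by [read_gasx_table()]. Defaults
#' match common infrared gas-analyser export headers; each logical field may
#' be matched by any of several synonyms. Unknown extra columns are ignored
#' on read (they never cause errors).
#'
#' @param sep Field separator; `NA` auto-detects comma vs tab from the header
#'   line.
#' @param col_map Named list mapping the logical fields `t`, `Q`, `A`, `gs`,
#'   `Ci`, `Ca` (and optionally `plant_id`, `accession`, `protocol`) to
#'   character vectors of acceptable header names. Entries given here
#'   override the defaults field-by-field.
#' @return A list with class `"gasx_dialect"`.
#' @export
gasx_dialect <- function(sep = NA, col_map = list()) {
  cm <- .default_col_map()
  for (nm in names(col_map)) cm[[nm]] <- col_map[[nm]]
  structure(list(sep = sep, col_map = cm), class = "gasx_dialect")
}

.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
}

.match_col <- function(have, synonyms) {
  hit <- which(tolower(have) %in% tolower(synonyms))
  if (length(hit)) hit[1L] else NA_integer_
}

#' Read a gas-exchange table into gasx_series objects
#'
#' Reads a delimited text file (one plant-protocol per file, or long format
#' with a `plant_id` column) and returns one [gasx_series()] per
#' (plant, protocol) group, rows sorted by elapsed time. Units are taken as
#' given in the file.
#'
#' @param path Path to a delimited text file with a header naming at least
#'   the time, PPFD, A, gs, Ci and Ca columns (see [gasx_dialect()]).
#' @param dialect A [gasx_dialect()] controlling separator and column names.
#' @param plant_id,accession,protocol Fallbacks used when the file carries no
#'   such column. `protocol = NA` infers the protocol from the light trace:
#'   a single >= 5-fold upward step is classified as `"step_change"`,
#'   anything else as `"light_curve"`.
#' @return A list of `gasx_series`.
#' @export
read_gasx_table <- function(path, dialect = gasx_dialect(),
                            plant_id = NULL, accession = "unknown",
                            protocol = NA) {
  sep <- if (is.na(dialect$sep)) .detect_sep(path) else dialect$sep
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cm <- dialect$col_map
  need <- c("t", "Q", "A", "gs", "Ci", "Ca")
  idx <- vapply(need, function(f) .match_col(names(raw), cm[[f]]), integer(1))
  if (anyNA(idx)) {
    missing <- need[is.na(idx)]
    stop(sprintf("format error: missing mandatory column(s): %s (header: %s)",
                 paste(missing, collapse = ", "),
                 paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  num <- lapply(need, function(f) {
    col <- raw[[idx[[f]]]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) & nzchar(col))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' in column `%s` at row %d",
                   col[bad[1L]], f, bad[1L]), call. = FALSE)
    v
  })
  names(num) <- need
  pid_i <- .match_col(names(raw), cm$plant_id)
  acc_i <- .match_col(names(raw), cm$accession)
  pro_i <- .match_col(names(raw), cm$protocol)
  pid <- if (!is.na(pid_i)) raw[[pid_i]] else
    rep(if (is.null(plant_id)) tools::file_path_sans_ext(basename(path)) else plant_id,
        nrow(raw))
  acc <- if (!is.na(acc_i)) raw[[acc_i]] else rep(accession, nrow(raw))
  pro <- if (!is.na(pro_i)) raw[[pro_i]] else rep(NA_character_, nrow(raw))

  pro_key <- ifelse(is.na(pro), "<infer>", pro)
  groups <- split(seq_len(nrow(raw)), list(pid, pro_key), drop = TRUE, sep = "\r")
  out <- lapply(groups, function(rows) {
    o <- rows[order(num$t[rows])]
    p <- pro[o[1L]]
    if (is.na(p)) p <- if (is.na(protocol)) .infer_protocol(num$Q[o]) else protocol
    gasx_series(plant_id = pid[o[1L]], accession = acc[o[1L]], protocol = p,
                t = num$t[o], Q = num$Q[o], A = num$A[o], gs = num$gs[o],
                Ci = num$Ci[o], Ca = num$Ca[o])
  })
  names(out) <- vapply(out, attr, "", "plant_id")
  out
}

.infer_protocol <- function(Q) {
  lev <- unique(round(Q))
  if (length(lev) == 2L && max(lev) >= 5 * max(min(lev), 1)) "step_change"
  else "light_curve"
}

#' Write gasx_series to a long-format TSV
#'
#' Inverse of [read_gasx_table()]: emits one row per record with `plant_id`,
#' `accession`, `protocol` columns, at full double precision.
#'
#' @param series_list A list of [gasx_series()] objects.
#' @param path Output file path.
#' @param sep Field separator (tab by default; use `","` for CSV).
#' @return `path`, invisibly.
#' @export
write_gasx_table <- function(series_list, path, sep = "\t") {
  if (inherits(series_list, "gasx_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.frame(plant_id = attr(s, "plant_id"), accession = attr(s, "accession"),
               protocol = attr(s, "protocol"), as.data.frame(s))
  })
  long <- do.call(rbind, rows)
  utils::write.table(format(long, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean of a variable over a closed time window
#'
#' Arithmetic mean of one series variable over samples with
#' `t_start <= t <= t_end` (both ends included). Used for the steady-state
#' summaries ("last 5 minutes" windows).
#'
#' @param series A [gasx_series()].
#' @param variable One of `"A"`, `"gs"`, `"Ci"`, `"Ca"`, `"Q"`.
#' @param t_start,t_end Window bounds in seconds, `t_start < t_end`.
#' @return A list with elements `mean` and `n` (number of samples used).
#' @export
window_mean <- function(series, variable, t_start, t_end) {
  stopifnot(inherits(series, "gasx_series"))
  variable <- match.arg(variable, c("A", "gs", "Ci", "Ca", "Q", "Wi"))
  if (!(t_start < t_end)) stop("t_start must be < t_end", call. = FALSE)
  keep <- series$t >= t_start & series$t <= t_end
  if (!any(keep))
    stop(sprintf("empty window [%g, %g]: no samples", t_start, t_end),
         call. = FALSE)
  v <- if (variable == "Wi") series$A[keep] / series$gs[keep] else series[[variable]][keep]
  list(mean = mean(v), n = sum(keep))
}

#' Check a series against its nominal measurement protocol
#'
#' Reporting-only validation: verifies that a light-curve series visits the
#' 12 nominal PPFD levels (2000, 1500, 1250, 1000, 750, 500, 300, 200, 100,
#' 50, 20, 0 umol m^-2 s^-1) in non-increasing order, or that a step series
#' shows a low plateau near 100 followed by a high plateau near 1000 with
#' near-10 s sampling. Never mutates or rejects the data.
#'
#' @param series A [gasx_series()].
#' @param level_tol Relative tolerance for matching nominal PPFD levels
#'   (default 5%).
#' @return A data frame of class `"gasx_validation"` with columns `check`,
#'   `status` (`"pass"`/`"warn"`) and `note`.
#' @export
validate_protocol <- function(series, level_tol = 0.05) {
  stopifnot(inherits(series, "gasx_series"))
  checks <- list()
  add <- function(check, status, note = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = check, status = status,
                                                 note = note)
  if (attr(series, "protocol") == "light_curve") {
    nominal <- c(2000, 1500, 1250, 1000, 750, 500, 300, 200, 100, 50, 20, 0)
    lev <- .nominal_level(series$Q, nominal, level_tol)
    seen <- nominal[nominal %in% lev]
    if (length(seen) == length(nominal)) add("levels", "pass", "all 12 nominal PPFD levels present")
    else add("levels", "warn", sprintf("incomplete protocol: %d of 12 nominal levels present",
                                       length(seen)))
    ord <- lev[!is.na(lev)]
    if (all(diff(ord) <= 0)) add("order", "pass", "levels non-increasing")
    else add("order", "warn", "nominal levels not in non-increasing order")
  } else {
    lo <- stats::median(series$Q[series$Q <= (min(series$Q) + max(series$Q)) / 2])
    hi <- stats::median(series$Q[series$Q > (min(series$Q) + max(series$Q)) / 2])
    if (abs(lo - 100) <= level_tol * 100 * 2)
      add("baseline", "pass", sprintf("low plateau at %.0f", lo))
    else add("baseline", "warn", sprintf("low plateau at %.0f, expected ~100", lo))
    if (abs(hi - 1000) <= level_tol * 1000)
      add("step", "pass", sprintf("high plateau at %.0f", hi))
    else add("step", "warn", sprintf("high plateau at %.0f, expected ~1000", hi))
    dt <- stats::median(diff(series$t))
    if (abs(dt - 10) <= 1) add("sampling", "pass", sprintf("median dt = %.1f s", dt))
    else add("sampling", "warn", sprintf("median dt = %.1f s, expected ~10 s", dt))
  }
  out <- do.call(rbind, checks)
  class(out) <- c("gasx_validation", "data.frame")
  out
}

#' @export
print.gasx_validation <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("[%s] %-9s %s\n", toupper(x$status[i]), x$check[i], x$note[i]))
  invisible(x)
}

# map measured Q to nearest nominal level within tol (abs tol 10 for Q=0)
.nominal_level <- function(Q, nominal, tol = 0.05) {
  vapply(Q, function(q) {
    d <- abs(q - nominal)
    i <- which.min(d)
    ok <- if (nominal[i] == 0) d[i] <= 10 else d[i] <= tol * nominal[i]
    if (ok) nominal[i] else NA_real_
  }, numeric(1))
}

#' Read a stomatal anatomy table
#'
#' Reads a delimited table of per-field stomatal counts and per-stoma
#' geometry. Expected columns: `plant_id`, `accession`, `surface`
#' (`abaxial`/`adaxial`), `field_count` (stomata in the field of view),
#' `field_area_mm2`, and optionally `gcl_um` (guard cell length) and
#' `pore_um` (stomatal pore length), both in micrometres.
#'
#' @param path Path to a TSV/CSV file.
#' @return A validated data frame of anatomy records.
#' @export
read_anatomy_table <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  anatomy_records(df)
}

#' Validate stomatal anatomy records
#'
#' Checks the invariants of a per-field anatomy table: non-negative integer
#' counts, positive field areas, positive geometry where present, and
#' pore length strictly less than guard cell length whenever both are given.
#'
#' @param df A data frame with columns `plant_id`, `accession`, `surface`,
#'   `field_count`, `field_area_mm2` and optionally `gcl_um`, `pore_um`.
#' @return The data frame with class `"anatomy_records"` prepended.
#' @export
anatomy_records <- function(df) {
  need <- c("plant_id", "accession", "surface", "field_count", "field_area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("anatomy table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$surface %in% c("abaxial", "adaxial")))
    stop("surface must be 'abaxial' or 'adaxial'", call. = FALSE)
  if (any(df$field_count < 0) || any(df$field_count != round(df$field_count)))
    stop("field_count must be a non-negative integer", call. = FALSE)
  if (any(df$field_area_mm2 <= 0)) stop("field_area_mm2 must be > 0", call. = FALSE)
  if (!is.null(df$gcl_um) && any(df$gcl_um <= 0, na.rm = TRUE))
    stop("gcl_um must be > 0", call. = FALSE)
  if (!is.null(df$pore_um) && any(df$pore_um <= 0, na.rm = TRUE))
    stop("pore_um must be > 0", call. = FALSE)
  if (!is.null(df$gcl_um) && !is.null(df$pore_um)) {
    both <- !is.na(df$gcl_um) & !is.na(df$pore_um)
    if (any(df$pore_um[both] >= df$gcl_um[both]))
      stop("pore_um must be < gcl_um in every record", call. = FALSE)
  }
  class(df) <- unique(c("anatomy_records", class(df)))
  df
}
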
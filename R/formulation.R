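# Micelle formulation analytics: loading capacity/efficiency, stability,
# redispersion and dose arithmetic. All concentrations in g/L, doses in
# mg/kg, LC/LE in percent. Operations are pure functions of their inputs.

#' Loading capacity of a micellar formulation
#'
#' `LC = 100 * m_drug / (m_drug + m_excipient)` in wt %, with the
#' solubilized drug mass and the polymer feed mass per unit volume. The
#' polymer mass in solution is taken as the feed mass (no loss of polymer
#' during micelle preparation is assumed).
#'
#' @param solubilized dissolved drug concentration, g/L (>= 0).
#' @param polymer_feed polymer feed concentration, g/L (> 0).
#' @return loading capacity in wt %, in [0, 100).
#' @export
#' @examples
#' loading_capacity(9.0, 10) # 47.4 wt %
loading_capacity <- function(solubilized, polymer_feed) {
  check_nonneg(solubilized, "solubilized")
  check_pos(polymer_feed, "polymer_feed")
  100 * solubilized / (solubilized + polymer_feed)
}

#' Loading efficiency of a micellar formulation
#'
#' `LE = 100 * m_drug / m_drug_added` in percent. Measurement noise can
#' push the measured solubilized concentration slightly above the feed; in
#' that case the reported value is capped at 100 with a warning.
#'
#' @param solubilized dissolved drug concentration, g/L (>= 0).
#' @param drug_feed drug feed concentration, g/L (> 0).
#' @return loading efficiency in percent, in [0, 100].
#' @export
#' @examples
#' loading_efficiency(9.0, 10) # 90
loading_efficiency <- function(solubilized, drug_feed) {
  check_nonneg(solubilized, "solubilized")
  check_pos(drug_feed, "drug_feed")
  le <- 100 * solubilized / drug_feed
  if (any(le > 100)) {
    warning("loading efficiency above 100% (measurement noise); capping at 100")
    le <- pmin(le, 100)
  }
  le
}

#' Solubilized drug concentration implied by a loading capacity
#'
#' Algebraic inverse of [loading_capacity()]:
#' `solubilized = polymer_feed * lc / (100 - lc)`.
#'
#' @param lc loading capacity in wt %, 0 <= lc < 100.
#' @param polymer_feed polymer feed concentration, g/L (> 0).
#' @return solubilized drug concentration, g/L.
#' @export
solubility_from_lc <- function(lc, polymer_feed) {
  check_nonneg(lc, "lc")
  check_pos(polymer_feed, "polymer_feed")
  if (any(lc >= 100)) stop("lc must be < 100 wt %", call. = FALSE)
  polymer_feed * lc / (100 - lc)
}

#' Round LC/LE for reporting
#'
#' Raw values are carried at full precision throughout; reports print
#' integers (banker's/half-to-even rounding, R's `round()`) to match the
#' conventional presentation of loading data.
#'
#' @param x LC or LE value(s) in percent.
#' @return integer-rounded value(s).
#' @export
report_rounding <- function(x) round(x)

#' One solubilization measurement
#'
#' @param polymer_id,drug_id species identifiers.
#' @param polymer_feed,drug_feed feed concentrations, g/L (> 0).
#' @param solubilized measured dissolved drug, g/L.
#' @param day measurement day (>= 0).
#' @param medium `"water"`, `"saline"` or `"cell_culture_media"`.
#' @param tolerance relative measurement tolerance on
#'   `solubilized <= drug_feed` (default 5%).
#' @return a `formulation_record` (one-row data.frame).
#' @export
formulation_record <- function(polymer_id, drug_id, polymer_feed, drug_feed,
                               solubilized, day = 0,
                               medium = c("water", "saline",
                                          "cell_culture_media"),
                               tolerance = 0.05) {
  medium <- match.arg(medium)
  check_pos(polymer_feed, "polymer_feed")
  check_pos(drug_feed, "drug_feed")
  check_nonneg(solubilized, "solubilized")
  if (day < 0) stop("day must be >= 0", call. = FALSE)
  if (solubilized > drug_feed * (1 + tolerance)) {
    stop("solubilized (", solubilized, " g/L) exceeds drug feed (",
         drug_feed, " g/L) beyond the ", 100 * tolerance,
         "% measurement tolerance", call. = FALSE)
  }
  out <- data.frame(polymer_id = polymer_id, drug_id = drug_id,
                    polymer_feed = polymer_feed, drug_feed = drug_feed,
                    solubilized = solubilized, day = day, medium = medium,
                    stringsAsFactors = FALSE)
  class(out) <- c("formulation_record", "data.frame")
  out
}

#' Read a formulation measurement table from CSV
#'
#' Expected columns:
#' `polymer_id,drug_id,polymer_feed_gL,drug_feed_gL,solubilized_gL,day,medium`.
#' Every row is validated through [formulation_record()]; a violation is
#' reported with its line number.
#'
#' @param path CSV path.
#' @param tolerance per-record measurement tolerance (see
#'   [formulation_record()]).
#' @return data.frame of validated records.
#' @export
read_formulation_csv <- function(path, tolerance = 0.05) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("polymer_id", "drug_id", "polymer_feed_gL", "drug_feed_gL",
              "solubilized_gL", "day", "medium")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("formulation CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(raw$day)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$day))))
    stop("malformed day column at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    tryCatch(
      formulation_record(r$polymer_id, r$drug_id, r$polymer_feed_gL,
                         r$drug_feed_gL, r$solubilized_gL, r$day, r$medium,
                         tolerance = tolerance),
      error = function(e) {
        stop("line ", i + 1L, " of ", basename(path), ": ",
             conditionMessage(e), call. = FALSE)
      })
  })
  do.call(rbind, rows)
}

#' A stability time course for one formulation
#'
#' @param record the day-0 `formulation_record` the series belongs to.
#' @param days measurement days, strictly increasing, first must be 0.
#' @param solubilized dissolved drug at each day, g/L.
#' @return a `stability_series` object.
#' @export
stability_series <- function(record, days, solubilized) {
  if (length(days) != length(solubilized) || length(days) < 2L) {
    stop("need matching days/solubilized vectors with >= 2 points",
         call. = FALSE)
  }
  if (any(diff(days) <= 0)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  if (days[1] != 0) stop("first sampling day must be 0", call. = FALSE)
  check_nonneg(solubilized, "solubilized")
  structure(list(record = record, days = days, solubilized = solubilized),
            class = "stability_series")
}

#' Summarize a stability time course
#'
#' Loading capacity at every time point, the retention fraction
#' `LC(last) / LC(day 0)`, and the first day at which the formulation has
#' precipitated completely (solubilized drug below the detection
#' threshold), if any.
#'
#' @param series a [stability_series()].
#' @param detection_threshold complete-precipitation threshold, g/L
#'   (default 0.01).
#' @return list with `lc_by_day` (data.frame `day,solubilized,lc`),
#'   `retention_fraction`, and `time_to_complete_precipitation` (`NA` if
#'   the series never falls below threshold).
#' @export
stability_summary <- function(series, detection_threshold = 0.01) {
  stopifnot(inherits(series, "stability_series"))
  pf <- series$record$polymer_feed
  lc <- loading_capacity(series$solubilized, pf)
  if (lc[1] <= 0) {
    stop("day-0 loading capacity is zero; retention undefined", call. = FALSE)
  }
  below <- which(series$solubilized < detection_threshold)
  list(
    lc_by_day = data.frame(day = series$days,
                           solubilized = series$solubilized, lc = lc),
    retention_fraction = lc[length(lc)] / lc[1],
    time_to_complete_precipitation =
      if (length(below) > 0L) series$days[below[1]] else NA_real_
  )
}

#' Redispersion recovery of a lyophilized formulation
#'
#' Fraction of the pre-lyophilization loading capacity recovered after
#' redispersing the powder in an aqueous medium.
#'
#' @param lc_before LC before lyophilization, wt % (> 0).
#' @param lc_after LC after redispersion, wt %.
#' @param medium label of the redispersion medium.
#' @return list with `recovery` (fraction) and `medium`.
#' @export
redispersion_recovery <- function(lc_before, lc_after, medium = "saline") {
  if (lc_before <= 0) stop("lc_before must be > 0", call. = FALSE)
  check_nonneg(lc_after, "lc_after")
  list(recovery = lc_after / lc_before, medium = medium)
}

#' Drug concentration required by a dosing scheme
#'
#' A dose of d mg/kg delivered in an injection volume of v mL/kg requires
#' a formulation at d / v mg/mL = d / v g/L.
#'
#' @param dose dose in mg per kg body weight (>= 0).
#' @param injection_volume injection volume in mL per kg (> 0).
#' @param achievable_solubility optional achievable drug solubility of the
#'   formulation, g/L; when given, the result flags feasibility.
#' @return list with `required_gL` and, if requested, `feasible`.
#' @export
#' @examples
#' required_concentration(50, 10) # 5 g/L
required_concentration <- function(dose, injection_volume,
                                   achievable_solubility = NULL) {
  check_nonneg(dose, "dose")
  check_pos(injection_volume, "injection_volume")
  req <- dose / injection_volume
  out <- list(required_gL = req)
  if (!is.null(achievable_solubility)) {
    out$feasible <- achievable_solubility >= req
  }
  out
}

#' Convert a mass concentration to a molar concentration
#'
#' @param conc concentration in g/L.
#' @param molar_mass molar mass in g/mol (> 0).
#' @return concentration in mol/L.
#' @export
#' @examples
#' mass_to_molar(0.05776, 577.59) * 1e6 # about 100 uM
mass_to_molar <- function(conc, molar_mass) {
  check_nonneg(conc, "conc")
  if (!is.numeric(molar_mass) || molar_mass <= 0) {
    stop("molar_mass must be > 0", call. = FALSE)
  }
  conc / molar_mass
}

check_pos <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be > 0", call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be >= 0", call. = FALSE)
  }
  invisible(x)
}
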
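# Patient cohort data model: schema, validation, CSV io, factor-level
# mapping, molecular subtypes and Table-1-style summaries.

.cohort_columns <- c("patient_id", "age", "diameter_mm", "histology", "er",
                     "pr", "ki67", "her2", "grading", "node_status")

.cat_levels <- list(
  histology = c("ductal", "lobular", "unknown"),
  er        = c("pos", "neg"),
  pr        = c("pos", "neg"),
  ki67      = c("pos", "neg"),
  her2      = c("pos", "neg", "unknown"),
  grading   = c("1", "2", "3", "unknown")
)

#' Prognostic factors known to the model
#'
#' `sln_features()` lists every discrete prognostic factor the model can
#' carry; `base_features()` is the default calculator feature set (age class,
#' histologic type, ER, PR, grade).  Tumour diameter is not listed: it enters
#' the risk model continuously, not as a multiplier.
#'
#' @return Character vector of factor names.
#' @export
sln_features <- function() {
  c("age", "histology", "er", "pr", "ki67", "her2", "grading")
}

#' @rdname sln_features
#' @export
base_features <- function() c("age", "histology", "er", "pr", "grading")

#' Decade age bins
#'
#' The default age classes of the risk model: decades 21--30 through 81--90
#' plus an open class above 90.  Bins are half-open intervals
#' `[breaks[i], breaks[i+1])` jointly covering ages 18 to 119.
#'
#' @param breaks Increasing numeric vector of bin boundaries; must start at
#'   18 and end at 120 so every adult age maps to a bin.
#' @param labels One label per bin.
#' @return A list with elements `breaks` and `labels`, class `"sln_age_bins"`.
#' @export
age_bins <- function(breaks, labels) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2L || is.unsorted(breaks, strictly = TRUE))
    stop("age bin breaks must be strictly increasing")
  if (breaks[1L] != 18 || breaks[length(breaks)] != 120)
    stop("age bins must cover [18, 120): first break 18, last break 120")
  if (length(labels) != length(breaks) - 1L)
    stop("need exactly one label per age bin")
  if (anyDuplicated(labels)) stop("age bin labels must be unique")
  structure(list(breaks = breaks, labels = as.character(labels)),
            class = "sln_age_bins")
}

#' @rdname age_bins
#' @export
default_age_bins <- function() {
  age_bins(c(18, 31, 41, 51, 61, 71, 81, 91, 120),
           c("21-30", "31-40", "41-50", "51-60",
             "61-70", "71-80", "81-90", ">90"))
}

#' Age bins used for subgroup stratification
#'
#' Separate, coarser binning (<=45, 45--60, >60) used when reporting
#' subgroup performance; independent of the model's decade bins.
#'
#' @return An `"sln_age_bins"` object.
#' @export
stratification_age_bins <- function() {
  age_bins(c(18, 46, 61, 120), c("Age<=45", "45<Age<=60", "Age>60"))
}

#' Declare which prognostic factors enter the model
#'
#' A factor scheme fixes the ordered set of discrete prognostic factors whose
#' per-level multipliers are fitted, and how raw record values map onto
#' levels.  Unknown raw values always map to the reserved level `"unknown"`,
#' which carries an implicit multiplier of 1 and is never fitted.
#'
#' @param features Subset of [sln_features()]; order is kept.  May be empty,
#'   in which case the model depends on diameter alone.
#' @param age_bins An [age_bins()] object (used only if `"age"` is a feature).
#' @return An object of class `"sln_scheme"`.
#' @export
sln_scheme <- function(features = base_features(),
                       age_bins = default_age_bins()) {
  features <- as.character(features)
  bad <- setdiff(features, sln_features())
  if (length(bad))
    stop("unknown feature(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(features)) stop("duplicated feature names")
  if (!inherits(age_bins, "sln_age_bins")) stop("invalid age_bins")
  structure(list(features = features, age_bins = age_bins),
            class = "sln_scheme")
}

#' Model levels of each factor in a scheme
#'
#' Lists the fittable (non-unknown) levels of every factor declared in a
#' scheme, in declaration order.
#'
#' @param scheme An [sln_scheme()].
#' @return Named list of character vectors.
#' @export
factor_levels <- function(scheme) {
  stopifnot(inherits(scheme, "sln_scheme"))
  lv <- list(
    age       = scheme$age_bins$labels,
    histology = c("ductal", "lobular"),
    er        = c("pos", "neg"),
    pr        = c("pos", "neg"),
    ki67      = c("pos", "neg"),
    her2      = c("pos", "neg"),
    grading   = c("G1", "G2", "G3")
  )
  lv[scheme$features]
}

.age_level <- function(age, bins) {
  idx <- findInterval(age, bins$breaks)
  if (any(idx < 1L | idx >= length(bins$breaks)))
    stop("age outside all configured age bins: ",
         paste(age[idx < 1L | idx >= length(bins$breaks)], collapse = ", "))
  bins$labels[idx]
}

#' Map records to model factor levels
#'
#' Applies a scheme's mapping rules to every record: ages are binned, grades
#' 1/2/3 become G1/G2/G3, and raw `"unknown"` values pass through as the
#' level `"unknown"`.
#'
#' @param cohort A validated cohort data frame.
#' @param scheme An [sln_scheme()].
#' @return Data frame with one character column per scheme feature, one row
#'   per record; exactly one level per factor.
#' @export
map_to_levels <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "sln_scheme"))
  out <- vector("list", length(scheme$features))
  names(out) <- scheme$features
  for (f in scheme$features) {
    out[[f]] <- switch(f,
      age       = .age_level(cohort$age, scheme$age_bins),
      histology = cohort$histology,
      er        = cohort$er,
      pr        = cohort$pr,
      ki67      = cohort$ki67,
      her2      = cohort$her2,
      grading   = ifelse(cohort$grading == "unknown", "unknown",
                         paste0("G", cohort$grading))
    )
  }
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)[ ,
    scheme$features, drop = FALSE]
}

#' Tumour size category from diameter
#'
#' T1: diameter <= 20 mm; T2: 20 < diameter <= 50 mm; T3: > 50 mm.
#' Boundaries are inclusive on the upper side, matching the printed "<=".
#'
#' @param diameter_mm Numeric vector of diameters in mm.
#' @return Character vector in `{"T1","T2","T3"}`.
#' @export
t_category <- function(diameter_mm) {
  stopifnot(all(diameter_mm > 0))
  ifelse(diameter_mm <= 20, "T1", ifelse(diameter_mm <= 50, "T2", "T3"))
}

#' St. Gallen molecular subtype
#'
#' Deterministic rule from the four immunohistochemical markers with Ki67
#' dichotomized at 20%: hormone-receptor positive (ER+ or PR+) tumours are
#' Luminal A when HER2- and Ki67-negative, Luminal B when HER2+ or
#' Ki67-positive; hormone-receptor negative tumours are HER2-positive or
#' triple negative according to HER2.  HER2 unknown yields `"unknown"`.
#'
#' @param cohort A validated cohort data frame.
#' @return Character vector in
#'   `{"LuminalA","LuminalB","HER2pos","TripleNegative","unknown"}`.
#' @export
assign_subtype <- function(cohort) {
  hr <- cohort$er == "pos" | cohort$pr == "pos"
  out <- rep("unknown", nrow(cohort))
  known <- cohort$her2 != "unknown"
  h2 <- cohort$her2 == "pos"
  k  <- cohort$ki67 == "pos"
  out[known & hr & !h2 & !k]       <- "LuminalA"
  out[known & hr & (h2 | k)]       <- "LuminalB"
  out[known & !hr & h2]            <- "HER2pos"
  out[known & !hr & !h2]           <- "TripleNegative"
  out
}

.coerce_cohort <- function(df) {
  df$patient_id  <- as.character(df$patient_id)
  df$age         <- suppressWarnings(as.numeric(df$age))
  df$diameter_mm <- suppressWarnings(as.numeric(df$diameter_mm))
  df$node_status <- suppressWarnings(as.numeric(df$node_status))
  for (f in names(.cat_levels)) df[[f]] <- trimws(as.character(df[[f]]))
  df
}

.row_issues <- function(df) {
  issues <- list()
  flag <- function(bad, field, why) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad | is.na(bad))
      rows <- rows[bad[rows] | is.na(bad[rows])]
      issues[[length(issues) + 1L]] <<-
        data.frame(row = rows, field = field, problem = why)
    }
  }
  flag(is.na(df$age) | df$age < 18 | df$age != floor(df$age),
       "age", "must be an integer >= 18")
  flag(is.na(df$diameter_mm) | df$diameter_mm <= 0 |
         !is.finite(df$diameter_mm),
       "diameter_mm", "must be a positive number")
  for (f in names(.cat_levels))
    flag(!(df[[f]] %in% .cat_levels[[f]]), f,
         paste0("must be one of {", paste(.cat_levels[[f]], collapse = ", "),
                "}"))
  flag(is.na(df$node_status) | !(df$node_status %in% c(0, 1)),
       "node_status", "must be 0 or 1")
  if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), field = character(), problem = character())
}

#' Validate a cohort data frame
#'
#' Checks the record invariants: positive diameter, integer age >= 18,
#' enumerated categorical values, binary node status.
#'
#' @param cohort Data frame with the cohort columns (see [read_cohort()]).
#' @param strict If `TRUE` (default) any invalid row aborts with an error
#'   naming the row and field; if `FALSE` invalid rows are dropped and their
#'   count reported via a message and the `"n_skipped"` attribute.
#' @return The validated (possibly filtered) cohort, columns in canonical
#'   order, `node_status` as integer.
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- .coerce_cohort(as.data.frame(cohort))
  issues <- .row_issues(df)
  if (nrow(issues)) {
    if (strict) {
      shown <- utils::head(issues, 5L)
      stop("invalid cohort rows:\n",
           paste(sprintf("  row %d: %s %s", shown$row, shown$field,
                         shown$problem), collapse = "\n"),
           if (nrow(issues) > 5L)
             sprintf("\n  ... and %d more", nrow(issues) - 5L) else "")
    }
    bad_rows <- unique(issues$row)
    message("skipped ", length(bad_rows), " invalid row(s) of ", nrow(df))
    df <- df[-bad_rows, , drop = FALSE]
  }
  df$age <- as.integer(df$age)
  df$node_status <- as.integer(df$node_status)
  rownames(df) <- NULL
  out <- df[, .cohort_columns, drop = FALSE]
  attr(out, "n_skipped") <- if (nrow(issues)) length(unique(issues$row)) else 0L
  out
}

#' Read or write a cohort CSV
#'
#' The cohort file is UTF-8 comma-separated with a header row naming exactly
#' the columns `patient_id, age, diameter_mm, histology, er, pr, ki67, her2,
#' grading, node_status`; unknown values are the literal string `"unknown"`.
#' `read_cohort` followed by `write_cohort` (or vice versa) is the identity
#' on valid cohorts.
#'
#' @param path File path.
#' @param strict Passed to [validate_cohort()].
#' @return `read_cohort`: a validated cohort data frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = TRUE, fileEncoding = "UTF-8")
  validate_cohort(df, strict = strict)
}

#' @rdname read_cohort
#' @param cohort A validated cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Cohort composition summary
#'
#' Per-level counts and node-positivity, in the layout of a published
#' prognostic-factor distribution table: one row per level of each factor
#' (plus an overall row and tumour-size categories), with the share of the
#' cohort and the positivity rate within the level.  Percentages are
#' reported to 2 decimals, rounding half away from zero.
#'
#' @param cohort A validated, non-empty cohort data frame.
#' @param scheme Scheme whose factors to tabulate; defaults to all factors.
#' @return Data frame with columns `factor, level, n, pct, n_pos, pct_pos`.
#' @export
cohort_summary <- function(cohort, scheme = sln_scheme(sln_features())) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort")
  n <- nrow(cohort)
  y <- cohort$node_status
  rows <- list()
  add <- function(factor, level, idx) {
    k <- sum(idx); kp <- sum(y[idx])
    rows[[length(rows) + 1L]] <<- data.frame(
      factor = factor, level = level, n = k,
      pct = round_half_up(100 * k / n),
      n_pos = kp,
      pct_pos = if (k > 0) round_half_up(100 * kp / k) else NA_real_)
  }
  add("overall", "all", rep(TRUE, n))
  tc <- t_category(cohort$diameter_mm)
  for (lev in c("T1", "T2", "T3")) add("diameter", lev, tc == lev)
  lv <- map_to_levels(cohort, scheme)
  for (f in scheme$features) {
    levs <- factor_levels(scheme)[[f]]
    if (any(lv[[f]] == "unknown")) levs <- c(levs, "unknown")
    for (lev in levs) add(f, lev, lv[[f]] == lev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published cohort margins
#'
#' The per-factor cross-tabulation (level count and node-positive count)
#' printed for the 993-patient institutional cohort that motivated this
#' package, shipped as a plain-text table.  These aggregates are public;
#' the patient-level data are not.
#'
#' @return Data frame with columns `factor, level, n, n_pos`.
#' @export
published_margins <- function() {
  path <- system.file("extdata", "published_margins.csv",
                      package = "slnrisk", mustWork = TRUE)
  utils::read.csv(path, colClasses = c("character", "character",
                                       "integer", "integer"))
}

# Representative raw value for each margin level, used when expanding a
# margins table into record form.
.margin_rep <- list(
  diameter = c(T1 = 10, T2 = 30, T3 = 60),
  grading  = c(G1 = "1", G2 = "2", G3 = "3", unknown = "unknown")
)

#' Expand a margins table into a record-level cohort
#'
#' Builds a synthetic record-level cohort whose per-factor cross-tabulation
#' reproduces a margins table exactly.  This is possible because each factor
#' is tabulated independently: records are ordered positives-first and each
#' factor's levels are dealt out within the positive and negative blocks to
#' match its (level, positives) counts.  Joint distributions across factors
#' are arbitrary; only the margins are faithful.  Ages take the bin
#' midpoint; diameters take a representative value per T category.
#'
#' @param margins Data frame as returned by [published_margins()]: must
#'   contain an `overall` row and, per factor, level rows whose `n` and
#'   `n_pos` sum to the overall values.
#' @param age_bins Age bins whose labels match the margins' age levels.
#' @return A validated cohort data frame.
#' @export
margins_to_cohort <- function(margins, age_bins = default_age_bins()) {
  ov <- margins[margins$factor == "overall", , drop = FALSE]
  if (nrow(ov) != 1L) stop("margins must contain exactly one overall row")
  n <- ov$n; npos <- ov$n_pos
  y <- c(rep(1L, npos), rep(0L, n - npos))
  deal <- function(fac) {
    m <- margins[margins$factor == fac, , drop = FALSE]
    if (sum(m$n) != n || sum(m$n_pos) != npos)
      stop("margins for ", fac, " do not sum to the overall counts")
    c(rep(m$level, m$n_pos), rep(m$level, m$n - m$n_pos))
  }
  mid_age <- function(labels) {
    idx <- match(labels, age_bins$labels)
    lo <- age_bins$breaks[idx]; hi <- age_bins$breaks[idx + 1L]
    as.integer(floor((lo + hi - 1) / 2))
  }
  data.frame(
    patient_id  = sprintf("M%04d", seq_len(n)),
    age         = mid_age(deal("age")),
    diameter_mm = unname(.margin_rep$diameter[deal("diameter")]),
    histology   = deal("histology"),
    er          = deal("er"),
    pr          = deal("pr"),
    ki67        = deal("ki67"),
    her2        = deal("her2"),
    grading     = unname(.margin_rep$grading[deal("grading")]),
    node_status = y)
}
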